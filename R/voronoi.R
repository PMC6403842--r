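# Demixing analysis: Voronoi tessellation of the confined system and the
# inter-chain interfacial area. Every bead gets the convex polyhedron of
# points closer to it than to any other bead, clipped at the spherical wall;
# the total area of facets separating beads of different chains measures how
# much the chains intermingle, and the per-chain sums are the Voronoi
# envelopes.

#' Voronoi tessellation bounded by the confining sphere
#'
#' Computes every bead's Voronoi cell, clipped at the spherical wall. The
#' wall is realised by tangent planes derived from the configuration itself:
#' each bead is reflected across the sphere surface (the bisector with the
#' mirror image is the tangent plane in the bead's radial direction), and any
#' cell vertex still protruding beyond the sphere triggers a further tangent
#' clip in its own direction. The union of cells reproduces the sphere volume
#' to a fraction of a percent and rotates rigidly with the configuration.
#'
#' @param system A `chain_system` (confined), or a 3-column position matrix.
#' @param ring_index Per-bead ring ids (defaults to the system's).
#' @param sphere_radius Confining radius (defaults to the system's). All
#'   beads must lie strictly inside.
#' @param wall_tol Radial overshoot tolerance of the polyhedral wall
#'   approximation, as a fraction of the sphere radius (default 1e-3).
#' @return A `voro_tessellation`: list with `cells` (tibble: bead, ring,
#'   volume), `facets` (tibble: bead, neighbor — `NA` for wall facets —,
#'   area, ring, ring_neighbor; each interior facet appears once from each
#'   side), `total_volume` and `sphere_radius`.
#' @examples
#' tess <- tessellate(matrix(c(0, 0, 0), 1), 1L, sphere_radius = 3)
#' tess$total_volume / (4 / 3 * pi * 27) # ~1
#' @export
tessellate <- function(system, ring_index = NULL, sphere_radius = NULL,
                       wall_tol = 1e-3) {
  if (inherits(system, "chain_system")) {
    pos <- positions(system)
    ring_index <- ring_index %||% system$ring
    sphere_radius <- sphere_radius %||% attr(system, "sphere_radius")
  } else {
    pos <- as.matrix(system)
  }
  stopifnot(ncol(pos) == 3, is.finite(sphere_radius), sphere_radius > 0)
  ring_index <- ring_index %||% rep(1L, nrow(pos))
  res <- cpp_tessellate(pos, sphere_radius, wall_tol)
  cells <- tibble(bead = seq_len(nrow(pos)), ring = ring_index,
                  volume = res$volumes)
  facets <- tibble(bead = res$facet_bead, neighbor = res$facet_neighbor,
                   area = res$facet_area)
  # the two per-cell computations of a shared facet are geometrically the
  # same polygon but are rimmed by each cell's own wall discretisation;
  # averaging the two measurements makes the shared area exactly symmetric
  shared <- !is.na(facets$neighbor)
  if (any(shared)) {
    key <- paste(pmin(facets$bead[shared], facets$neighbor[shared]),
                 pmax(facets$bead[shared], facets$neighbor[shared]))
    facets$area[shared] <- stats::ave(facets$area[shared], key)
  }
  facets <- facets |>
    mutate(ring = ring_index[.data$bead],
           ring_neighbor = ifelse(is.na(.data$neighbor), NA_integer_,
                                  ring_index[.data$neighbor]))
  structure(list(cells = cells, facets = facets,
                 total_volume = sum(res$volumes),
                 sphere_radius = sphere_radius),
            class = "voro_tessellation")
}

#' @export
print.voro_tessellation <- function(x, ...) {
  cat(sprintf("<voro_tessellation> %d cells, %d facets, total volume %.2f\n",
              nrow(x$cells), nrow(x$facets), x$total_volume))
  invisible(x)
}

#' Inter-chain interfacial area (Voronoi envelopes)
#'
#' Sums the areas of Voronoi facets separating beads of different chains —
#' each such facet counted once for the total, and once per chain for that
#' chain's envelope, so the envelopes sum to exactly twice the total. Wall
#' facets are excluded.
#'
#' @param tess A [tessellate()] result.
#' @param frame Optional frame index carried into the output.
#' @return Tibble with one row per chain: `chain`, `envelope_area`,
#'   `total_interchain_area` (repeated), `frame`.
#' @export
interchain_area <- function(tess, frame = NA_integer_) {
  f <- tess$facets |>
    filter(!is.na(.data$neighbor), .data$ring != .data$ring_neighbor)
  total <- sum(f$area) / 2
  chains <- sort(unique(tess$cells$ring))
  env <- vapply(chains, function(ch) sum(f$area[f$ring == ch]), 0)
  tibble(chain = chains, envelope_area = env,
         total_interchain_area = total, frame = frame)
}

#' Inter-chain area along a trajectory
#'
#' Applies [tessellate()] and [interchain_area()] to each sampled frame of a
#' trajectory, in frame order.
#'
#' @param trajectory Tibble with columns frame, bead, ring, x, y, z (as
#'   stored in a `run_record`), or a list of position matrices.
#' @param ring_index Per-bead ring ids (required for a list of matrices).
#' @param sphere_radius Confining radius.
#' @param clamp Radially pull beads just inside the sphere when the soft wall
#'   let them protrude (default TRUE; excursions are ~0.1 sigma).
#' @param wall_tol Wall tolerance passed to [tessellate()].
#' @return Tibble: frame, chain, envelope_area, total_interchain_area.
#' @export
demixing_series <- function(trajectory, ring_index = NULL, sphere_radius,
                            clamp = TRUE, wall_tol = 1e-3) {
  if (is.data.frame(trajectory)) {
    frames <- split(trajectory, trajectory$frame)
    get_pos <- function(fr) cbind(fr$x, fr$y, fr$z)
    get_ring <- function(fr) fr$ring
    ids <- as.numeric(names(frames))
  } else {
    frames <- trajectory
    get_pos <- function(fr) as.matrix(fr)
    get_ring <- function(fr) ring_index
    ids <- seq_along(frames)
  }
  if (length(frames) < 1) abort("demixing_series needs at least one frame")
  out <- lapply(seq_along(frames), function(k) {
    pos <- get_pos(frames[[k]])
    if (clamp) {
      r <- sqrt(rowSums(pos^2))
      over <- r >= sphere_radius
      if (any(over)) {
        pos[over, ] <- pos[over, ] * (0.999 * sphere_radius / r[over])
      }
    }
    tess <- tessellate(pos, get_ring(frames[[k]]), sphere_radius, wall_tol)
    interchain_area(tess, frame = ids[k])
  })
  bind_rows(out)
}
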