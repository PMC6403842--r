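# The simulated state: beads in a tibble, connectivity in attributes.
#
# Columns: bead (global id), ring (ring id), x/y/z (positions, sigma units),
# phantom (excluded volume switched off, Top2B-like), ctcf (extruder stop
# site), cohesin (structural cohesin-ring bead rather than chromatin).
#
# Attributes: bonds (2-column integer matrix of backbone FENE bonds, one
# closed cycle per ring), harm_bonds (tibble i/j/k/r0/tag of auxiliary
# harmonic springs: handcuff joints, walk bonds, migrating extruder bonds),
# sphere_radius (confining sphere, NA when unconfined), bp_per_bead and
# nm_per_bead (coarse-grain calibration), velocities (internal integrator
# state), md_chunk (thermal-noise stream counter).

new_chain_system <- function(df, bonds, sphere_radius = NA_real_,
                             harm_bonds = empty_harm_bonds(),
                             bp_per_bead = 400, nm_per_bead = 10) {
  stopifnot(all(c("bead", "ring", "x", "y", "z", "phantom", "ctcf", "cohesin")
                %in% names(df)))
  out <- as_tibble(df)
  attr(out, "bonds") <- bonds
  attr(out, "harm_bonds") <- harm_bonds
  attr(out, "sphere_radius") <- sphere_radius
  attr(out, "bp_per_bead") <- bp_per_bead
  attr(out, "nm_per_bead") <- nm_per_bead
  attr(out, "md_chunk") <- 0L
  class(out) <- c("chain_system", class(out))
  out
}

empty_harm_bonds <- function() {
  tibble(i = integer(), j = integer(), k = double(), r0 = double(),
         tag = character())
}

#' Build a closed bead-spring ring
#'
#' Creates one circular (closed) chain of `n_beads` beads laid out as a planar
#' regular polygon with the requested bond spacing. The ring is closed: the
#' last bead is bonded back to the first. All phantom/CTCF flags start false.
#'
#' @param n_beads Number of beads (at least 3).
#' @param spacing Bond length between consecutive beads, in bead diameters
#'   (sigma).
#' @param ring Integer ring id assigned to all beads.
#' @param bp_per_bead,nm_per_bead Coarse-grain calibration: genomic content
#'   and physical diameter of one bead (defaults 400 bp and 10 nm).
#' @return A `chain_system` tibble (one row per bead).
#' @examples
#' sys <- build_ring(133)
#' nrow(sys)
#' nrow(system_bonds(sys))
#' @export
build_ring <- function(n_beads, spacing = 1, ring = 1L,
                       bp_per_bead = 400, nm_per_bead = 10) {
  if (!is.numeric(n_beads) || length(n_beads) != 1 || n_beads < 3) {
    abort("a ring needs at least 3 beads", class = "loopex_topology_error")
  }
  n_beads <- as.integer(n_beads)
  radius <- spacing / (2 * sin(pi / n_beads))
  th <- seq(0, 2 * pi, length.out = n_beads + 1)[seq_len(n_beads)]
  df <- tibble(
    bead = seq_len(n_beads), ring = as.integer(ring),
    x = radius * cos(th), y = radius * sin(th), z = 0,
    phantom = FALSE, ctcf = FALSE, cohesin = FALSE
  )
  bonds <- cbind(seq_len(n_beads), c(seq_len(n_beads)[-1], 1L))
  new_chain_system(df, bonds, bp_per_bead = bp_per_bead,
                   nm_per_bead = nm_per_bead)
}

#' @export
print.chain_system <- function(x, ...) {
  rs <- attr(x, "sphere_radius")
  cat(sprintf("<chain_system> %d beads, %d rings, %d bonds%s\n",
              nrow(x), length(unique(x$ring)), nrow(attr(x, "bonds")),
              if (is.finite(rs %||% NA_real_))
                sprintf(", sphere R = %.2f sigma", rs) else ""))
  NextMethod()
}

#' Accessors for chain-system connectivity and geometry
#'
#' `system_bonds()` returns the backbone bond list, `system_harm_bonds()` the
#' auxiliary harmonic springs, `positions()` the bare coordinate matrix and
#' `sphere_radius()` the confining radius (NA when unconfined).
#'
#' @param system A `chain_system`.
#' @return A tibble (bonds), a tibble (harmonic bonds), a numeric matrix
#'   (positions) or a scalar (radius).
#' @export
system_bonds <- function(system) {
  b <- attr(system, "bonds")
  tibble(i = b[, 1], j = b[, 2])
}

#' @rdname system_bonds
#' @export
system_harm_bonds <- function(system) attr(system, "harm_bonds")

#' @rdname system_bonds
#' @export
positions <- function(system) {
  cbind(x = system$x, y = system$y, z = system$z)
}

#' @rdname system_bonds
#' @export
sphere_radius <- function(system) attr(system, "sphere_radius")

set_positions <- function(system, pos) {
  system$x <- pos[, 1]
  system$y <- pos[, 2]
  system$z <- pos[, 3]
  system
}

#' Chromatin coarse-grain calibration per ring
#'
#' Summarises each chromatin ring: bead count, genomic span in bp and Mb
#' (beads times bp-per-bead) and contour length in nm. Cohesin rings are
#' excluded.
#'
#' @param system A `chain_system`.
#' @return A tibble with one row per chromatin ring.
#' @examples
#' chain_calibration(build_ring(4000))
#' @export
chain_calibration <- function(system) {
  system |>
    filter(!.data$cohesin) |>
    group_by(ring = .data$ring) |>
    summarise(n_beads = n(), .groups = "drop") |>
    mutate(
      bp = .data$n_beads * attr(system, "bp_per_bead"),
      mb = .data$bp / 1e6,
      nm = .data$n_beads * attr(system, "nm_per_bead")
    )
}

#' Validate chain-system invariants
#'
#' Checks that every ring's backbone bonds form a single closed cycle, that
#' all coordinates are finite, and that (when confined) no bead lies further
#' than half a bead diameter beyond the confining sphere.
#'
#' @param system A `chain_system`.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_chain_system <- function(system) {
  pos <- positions(system)
  if (!all(is.finite(pos))) {
    abort("non-finite bead coordinates", class = "loopex_state_error")
  }
  bonds <- attr(system, "bonds")
  for (r in unique(system$ring)) {
    beads <- system$bead[system$ring == r]
    sub <- bonds[bonds[, 1] %in% beads & bonds[, 2] %in% beads, , drop = FALSE]
    if (nrow(sub) != length(beads)) {
      abort(sprintf("ring %s: %d bonds for %d beads (not a closed cycle)",
                    r, nrow(sub), length(beads)),
            class = "loopex_topology_error")
    }
    deg <- table(factor(c(sub[, 1], sub[, 2]), levels = beads))
    if (any(deg != 2)) {
      abort(sprintf("ring %s is not a single closed cycle", r),
            class = "loopex_topology_error")
    }
  }
  rs <- attr(system, "sphere_radius")
  if (is.finite(rs %||% NA_real_)) {
    rad <- sqrt(rowSums(pos^2))
    if (any(rad > rs + 0.5)) {
      abort(sprintf("bead %d outside confining sphere (r = %.3f > R + 0.5)",
                    which.max(rad), max(rad)), class = "loopex_state_error")
    }
  }
  invisible(TRUE)
}

# Append a second system's beads/bonds (used to attach cohesin rings);
# bead ids of `extra` are shifted to follow `system`'s.
bind_systems <- function(system, extra) {
  off <- nrow(system)
  extra2 <- extra |>
    mutate(bead = .data$bead + off,
           ring = .data$ring + max(system$ring))
  bonds <- rbind(attr(system, "bonds"), attr(extra, "bonds") + off)
  hb <- bind_rows(attr(system, "harm_bonds"),
                  attr(extra, "harm_bonds") |>
                    mutate(i = .data$i + off, j = .data$j + off))
  out <- new_chain_system(bind_rows(as_tibble(system), as_tibble(extra2)),
                          bonds,
                          sphere_radius = attr(system, "sphere_radius"),
                          harm_bonds = hb,
                          bp_per_bead = attr(system, "bp_per_bead"),
                          nm_per_bead = attr(system, "nm_per_bead"))
  attr(out, "velocities") <- NULL
  out
}

# Beads of one chromatin ring, in backbone order (rings are stored in order).
ring_beads <- function(system, ring_id) {
  system$bead[system$ring == ring_id & !system$cohesin]
}

# wrap a position index into 1..n
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L
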