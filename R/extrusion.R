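# The two loop-extrusion mechanisms.
#
# 1. Cohesin handcuff: two 7-bead rings threaded on the chromatin fibre,
#    joined by two bonds between neighbouring beads, advancing by a walking
#    mechanism — three strong springs (K = 20 kBT/sigma^2, rest length 1,
#    formed at lengths up to 2) from nonconsecutive cohesin-ring beads to a
#    shifting chromatin bead; once shrunk near rest length they are
#    re-anchored one bead further along.  A 7-bead ring with unit bonds has
#    circumradius 0.5 / sin(pi/7) ~ 1.152 sigma, which bounds how short the
#    walk springs can get, so the replacement threshold sits just above it.
#
# 2. Simplified migrating-bond extruder for large systems: a single strong
#    spring (K = 100 kBT/sigma^2) between two beads; when they come close the
#    bond migrates outward one bead on each unstopped side.
#
# Both stop permanently at CTCF-flagged beads; one side stopping does not
# stop the other.

COHESIN_RING_SIZE <- 7L
WALK_BEADS <- c(1L, 3L, 5L)  # three nonconsecutive beads of a 7-ring

#' Thread a cohesin handcuff onto a chromatin ring
#'
#' Builds two 7-bead cohesin rings perpendicular to the fibre around beads
#' `site` and `site + 1` (with ring wrap-around), joins them with two bonds
#' between neighbouring beads, installs the walking springs, and relaxes the
#' local geometry with capped forces. The threading is verified geometrically
#' (the chromatin strand must pierce each cohesin ring exactly once).
#'
#' @param system A `chain_system`.
#' @param site Chromatin bead id where ring A is threaded; ring B takes the
#'   next bead along the ring.
#' @param ip [integrator_params()] for the placement relaxation.
#' @param relax_steps Capped-force relaxation steps after insertion.
#' @param walk_k Walk-spring stiffness, kBT/sigma^2.
#' @param replace_threshold Walk bonds at or below this length are
#'   re-anchored one bead further (sigma).
#' @param formation_max Maximum length at which a new walk bond may form
#'   (sigma).
#' @return List with elements `system` (beads and springs added) and
#'   `handcuff` (a `cohesin_handcuff` state object).
#' @export
load_handcuff <- function(system, site, ip = integrator_params(),
                          relax_steps = 2000, walk_k = 20,
                          replace_threshold = 1.25, formation_max = 2) {
  stopifnot(site %in% system$bead[!system$cohesin])
  ring_id <- system$ring[match(site, system$bead)]
  beads <- ring_beads(system, ring_id)
  n <- length(beads)
  i_site <- match(site, beads)
  site2 <- beads[wrap_index(i_site + 1L, n)]
  if (system$phantom[match(site, system$bead)]) {
    warn("handcuff loaded on a phantom bead; flags are independent")
  }
  hc_id <- sum(grepl("^walk_a_", attr(system, "harm_bonds")$tag)) / 3 + 1

  pos <- positions(system)
  mk_ring <- function(center_bead, prev_bead, next_bead) {
    ctr <- pos[match(center_bead, system$bead), ]
    tangent <- unit_vector(pos[match(next_bead, system$bead), ] -
                             pos[match(prev_bead, system$bead), ])
    a <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit_vector(pracma_cross(tangent, a))
    e2 <- pracma_cross(tangent, e1)
    rho <- 0.5 / sin(pi / COHESIN_RING_SIZE)
    th <- 2 * pi * (seq_len(COHESIN_RING_SIZE) - 1) / COHESIN_RING_SIZE
    t(sapply(th, function(t0) ctr + rho * (cos(t0) * e1 + sin(t0) * e2)))
  }
  prev_a <- beads[wrap_index(i_site - 1L, n)]
  next_b <- beads[wrap_index(i_site + 2L, n)]
  ring_a_xyz <- mk_ring(site, prev_a, site2)
  ring_b_xyz <- mk_ring(site2, site, next_b)

  cring <- function(xyz) {
    df <- tibble(bead = seq_len(COHESIN_RING_SIZE), ring = 1L,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 phantom = FALSE, ctcf = FALSE, cohesin = TRUE)
    bonds <- cbind(seq_len(COHESIN_RING_SIZE),
                   c(seq_len(COHESIN_RING_SIZE)[-1], 1L))
    new_chain_system(df, bonds)
  }
  n0 <- nrow(system)
  system <- bind_systems(system, cring(ring_a_xyz))
  ring_a_beads <- seq(n0 + 1L, n0 + COHESIN_RING_SIZE)
  n1 <- nrow(system)
  system <- bind_systems(system, cring(ring_b_xyz))
  ring_b_beads <- seq(n1 + 1L, n1 + COHESIN_RING_SIZE)

  # two joining bonds between neighbouring beads of each ring: pick the
  # adjacent bead pair of ring A closest to ring B and vice versa
  pa <- positions(system)[ring_a_beads, ]
  pb <- positions(system)[ring_b_beads, ]
  db <- as.matrix(stats::dist(rbind(pa, pb)))[1:7, 8:14]
  ka <- which.min(apply(db, 1, min))
  kb <- which.min(db[ka, ])
  ka2 <- wrap_index(ka + 1L, 7L)
  kb2_opts <- c(wrap_index(kb + 1L, 7L), wrap_index(kb - 1L, 7L))
  kb2 <- kb2_opts[which.min(db[ka2, kb2_opts])]
  joins <- tibble(
    i = ring_a_beads[c(ka, ka2)], j = ring_b_beads[c(kb, kb2)],
    k = 30, r0 = 1, tag = sprintf("join_h%d", hc_id)
  )

  hc <- structure(list(
    id = hc_id, chrom_ring = ring_id,
    ring_a_beads = ring_a_beads, ring_b_beads = ring_b_beads,
    anchor_a = site, anchor_b = site2,
    direction_a = -1L, direction_b = +1L,
    start_a = site, start_b = site2,
    stopped_a = FALSE, stopped_b = FALSE,
    walk_k = walk_k, replace_threshold = replace_threshold,
    formation_max = formation_max, stalls = 0L
  ), class = "cohesin_handcuff")

  walk <- bind_rows(
    tibble(i = ring_a_beads[WALK_BEADS],
           j = walk_target(hc, system, "a"), k = walk_k, r0 = 1,
           tag = sprintf("walk_a_h%d", hc_id)),
    tibble(i = ring_b_beads[WALK_BEADS],
           j = walk_target(hc, system, "b"), k = walk_k, r0 = 1,
           tag = sprintf("walk_b_h%d", hc_id))
  )
  attr(system, "harm_bonds") <- bind_rows(attr(system, "harm_bonds"), joins, walk)

  # resolve insertion clashes with capped forces before production; the cap
  # stays high (50 kBT/sigma) so the excluded-volume barrier remains far above
  # thermal energy and the threading cannot be lost during relaxation
  if (relax_steps > 0) {
    ffc <- force_field(force_cap = 50)
    system <- step_langevin(system, ffc, ip, relax_steps)
  }

  thr <- handcuff_invariants(system, hc)
  if (any(abs(thr$threading) != 1)) {
    anchors_phantom <- any(system$phantom[match(c(site, site2), system$bead)])
    if (anchors_phantom) {
      # a phantom site has no excluded volume to hold the ring in place, so
      # threading cannot be guaranteed there; the loading is still permitted
      warn("handcuff threading not maintained on a phantom site")
    } else {
      abort("handcuff placement failed: cohesin ring not threaded on the fibre",
            class = "loopex_placement_error")
    }
  }
  list(system = system, handcuff = hc)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# chromatin bead currently targeted by one side's walk springs
walk_target <- function(hc, system, side) {
  beads <- ring_beads(system, hc$chrom_ring)
  n <- length(beads)
  anchor <- if (side == "a") hc$anchor_a else hc$anchor_b
  dir <- if (side == "a") hc$direction_a else hc$direction_b
  beads[wrap_index(match(anchor, beads) + dir, n)]
}

#' Geometric invariants of a loaded handcuff
#'
#' Returns, per cohesin ring: the signed count of chromatin-strand passages
#' through the ring's disc (threading; must be +-1), the number of joining
#' bonds, and the maximum distance of walk-bond chromatin endpoints from the
#' anchor along the chain.
#'
#' @param system A `chain_system`.
#' @param hc A `cohesin_handcuff`.
#' @return Tibble with one row per cohesin ring.
#' @export
handcuff_invariants <- function(system, hc) {
  pos <- positions(system)
  chrom <- pos[system$ring == hc$chrom_ring & !system$cohesin, , drop = FALSE]
  hb <- attr(system, "harm_bonds")
  beads <- ring_beads(system, hc$chrom_ring)
  n <- length(beads)
  out <- lapply(c("a", "b"), function(side) {
    rb <- if (side == "a") hc$ring_a_beads else hc$ring_b_beads
    anchor <- if (side == "a") hc$anchor_a else hc$anchor_b
    pc <- cpp_pierce_count(pos[rb, , drop = FALSE], chrom, TRUE)
    wtag <- sprintf("walk_%s_h%d", side, hc$id)
    wj <- hb$j[hb$tag == wtag]
    off <- vapply(wj, function(jj) {
      d <- abs(match(jj, beads) - match(anchor, beads))
      min(d, n - d)
    }, 0)
    tibble(side = side, threading = pc$signed_count,
           pierce_count = pc$count,
           join_bonds = sum(hb$tag == sprintf("join_h%d", hc$id)) ,
           max_walk_offset = if (length(off)) max(off) else NA_real_)
  })
  bind_rows(out)
}

#' Advance the cohesin walking mechanism by one decision cycle
#'
#' For each cohesin ring independently: if all three walk springs have
#' shrunk to the replacement threshold, re-anchor them one chromatin bead
#' further along that ring's direction and advance the anchor — unless the
#' next bead is CTCF-flagged, in which case that side halts permanently, or
#' the new springs would exceed the formation length, in which case the cycle
#' is skipped (a stall, counted on the state object). Call between MD chunks.
#'
#' @param system A `chain_system` carrying the handcuff springs.
#' @param hc The `cohesin_handcuff` state.
#' @return List `(system, handcuff)` with updated springs and state.
#' @export
advance_walk <- function(system, hc) {
  pos <- positions(system)
  hb <- attr(system, "harm_bonds")
  beads <- ring_beads(system, hc$chrom_ring)
  n <- length(beads)

  for (side in c("a", "b")) {
    stopped <- if (side == "a") hc$stopped_a else hc$stopped_b
    if (stopped) next
    wtag <- sprintf("walk_%s_h%d", side, hc$id)
    rows <- which(hb$tag == wtag)
    len <- sqrt(rowSums((pos[hb$i[rows], , drop = FALSE] -
                           pos[hb$j[rows], , drop = FALSE])^2))
    if (!all(len <= hc$replace_threshold)) next
    anchor <- if (side == "a") hc$anchor_a else hc$anchor_b
    dir <- if (side == "a") hc$direction_a else hc$direction_b
    cand <- beads[wrap_index(match(anchor, beads) + dir, n)]
    if (system$ctcf[match(cand, system$bead)]) {
      if (side == "a") hc$stopped_a <- TRUE else hc$stopped_b <- TRUE
      next
    }
    new_target <- beads[wrap_index(match(anchor, beads) + 2L * dir, n)]
    new_len <- sqrt(rowSums((pos[hb$i[rows], , drop = FALSE] -
                               matrix(pos[new_target, ], length(rows), 3,
                                      byrow = TRUE))^2))
    if (any(new_len > hc$formation_max)) {
      hc$stalls <- hc$stalls + 1L
      next
    }
    hb$j[rows] <- new_target
    if (side == "a") hc$anchor_a <- cand else hc$anchor_b <- cand
  }
  attr(system, "harm_bonds") <- hb
  list(system = system, handcuff = hc)
}

#' Create a simplified migrating-bond extruder
#'
#' Installs one strong spring (default K = 100 kBT/sigma^2, rest length 1)
#' between two adjacent beads at `site` — the smallest initial loop — on the
#' given chromatin ring.
#'
#' @param system A `chain_system`.
#' @param site Chromatin bead id; the partner anchor is the next bead along
#'   the ring.
#' @param k Spring stiffness, kBT/sigma^2.
#' @param proximity_threshold Anchor separation at or below which the bond
#'   migrates outward (sigma).
#' @return List `(system, extruder)`.
#' @export
simple_extruder <- function(system, site, k = 100, proximity_threshold = 1.2) {
  ring_id <- system$ring[match(site, system$bead)]
  beads <- ring_beads(system, ring_id)
  n <- length(beads)
  left <- site
  right <- beads[wrap_index(match(site, beads) + 1L, n)]
  ex_id <- sum(grepl("^extruder_", attr(system, "harm_bonds")$tag)) + 1
  ex <- structure(list(
    id = ex_id, ring_id = ring_id,
    left_anchor = left, right_anchor = right,
    start_left = left, start_right = right,
    left_stopped = FALSE, right_stopped = FALSE,
    k = k, proximity_threshold = proximity_threshold
  ), class = "simple_extruder")
  attr(system, "harm_bonds") <- bind_rows(
    attr(system, "harm_bonds"),
    tibble(i = left, j = right, k = k, r0 = 1,
           tag = sprintf("extruder_%d", ex_id))
  )
  list(system = system, extruder = ex)
}

#' Migrate a simple extruder bond outward by one bead per side
#'
#' If the two anchors are within the proximity threshold, each unstopped
#' anchor moves one bead outward (left -1, right +1, wrapping around the
#' ring). An anchor about to move onto a CTCF bead, or about to meet the
#' other anchor, sets its stopped flag instead; when both are stopped the
#' extrusion is complete. The loop (the arc between the anchors on the
#' extruded side) never shrinks.
#'
#' @param system A `chain_system` carrying the extruder spring.
#' @param ex The `simple_extruder` state.
#' @return List `(system, extruder)`.
#' @export
step_simple_extrusion <- function(system, ex) {
  if (ex$left_stopped && ex$right_stopped) return(list(system = system, extruder = ex))
  pos <- positions(system)
  d <- sqrt(sum((pos[ex$left_anchor, ] - pos[ex$right_anchor, ])^2))
  if (d > ex$proximity_threshold) return(list(system = system, extruder = ex))
  beads <- ring_beads(system, ex$ring_id)
  n <- length(beads)
  new_left <- ex$left_anchor
  new_right <- ex$right_anchor
  if (!ex$left_stopped) {
    cand <- beads[wrap_index(match(ex$left_anchor, beads) - 1L, n)]
    if (system$ctcf[match(cand, system$bead)] || cand == ex$right_anchor ||
        cand == new_right) {
      ex$left_stopped <- TRUE
    } else {
      new_left <- cand
    }
  }
  if (!ex$right_stopped) {
    cand <- beads[wrap_index(match(ex$right_anchor, beads) + 1L, n)]
    if (system$ctcf[match(cand, system$bead)] || cand == new_left ||
        cand == ex$left_anchor) {
      ex$right_stopped <- TRUE
    } else {
      new_right <- cand
    }
  }
  ex$left_anchor <- new_left
  ex$right_anchor <- new_right
  hb <- attr(system, "harm_bonds")
  row <- which(hb$tag == sprintf("extruder_%d", ex$id))
  hb$i[row] <- new_left
  hb$j[row] <- new_right
  attr(system, "harm_bonds") <- hb
  list(system = system, extruder = ex)
}

#' Fraction of the extrudable chromatin already inside the loop
#'
#' The extruded-arc bead count divided by the total arc this extruder can
#' reach — the current loop plus the beads ahead of each anchor up to (but
#' not including) the first CTCF stop bead in its walking direction (or up
#' to the opposite anchor when no stop bead intervenes). About 0 just after
#' loading, exactly 1 when both sides have stopped at their border, and
#' monotone non-decreasing over a run: every advance moves one bead from the
#' "ahead" count into the loop.
#'
#' @param system A `chain_system`.
#' @param ex A `cohesin_handcuff` or `simple_extruder`.
#' @return A fraction in `[0, 1]`.
#' @export
extrusion_progress <- function(system, ex) {
  if (inherits(ex, "cohesin_handcuff")) {
    ring_id <- ex$chrom_ring
    a <- ex$anchor_a; b <- ex$anchor_b
  } else {
    ring_id <- ex$ring_id
    a <- ex$left_anchor; b <- ex$right_anchor
  }
  beads <- ring_beads(system, ring_id)
  n <- length(beads)
  ctcf <- system$ctcf[match(beads, system$bead)]
  ia <- match(a, beads); ib <- match(b, beads)
  # extruded arc runs from a to b in the +1 direction (through the start)
  loop <- (ib - ia) %% n + 1L
  outside <- if (loop >= n) integer() else
    seq_len(n - loop)  # offsets from b going +1, excluding the anchors
  ahead <- 0L
  for (k in outside) {   # from anchor b forward
    if (ctcf[wrap_index(ib + k, n)]) break
    ahead <- ahead + 1L
  }
  for (k in outside) {   # from anchor a backward
    if (ctcf[wrap_index(ia - k, n)]) break
    ahead <- ahead + 1L
  }
  ahead <- min(ahead, n - loop)  # the two scans may not overlap
  unname((loop - 2L) / max(1L, loop - 2L + ahead))
}

# one CSV-able row of extruder state
extruder_state <- function(system, ex, frame) {
  if (inherits(ex, "cohesin_handcuff")) {
    tibble(frame = frame, ring_id = ex$chrom_ring,
           anchor_left = ex$anchor_a, anchor_right = ex$anchor_b,
           progress = extrusion_progress(system, ex),
           stopped_left = ex$stopped_a, stopped_right = ex$stopped_b)
  } else {
    tibble(frame = frame, ring_id = ex$ring_id,
           anchor_left = ex$left_anchor, anchor_right = ex$right_anchor,
           progress = extrusion_progress(system, ex),
           stopped_left = ex$left_stopped, stopped_right = ex$right_stopped)
  }
}
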