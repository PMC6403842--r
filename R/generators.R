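# Synthetic-configuration factory for the three experiments: knotted
# single-TAD rings (133 beads), the three-TAD circle closed into a global
# trefoil (400 beads), and the topologically equilibrated 8-ring confined
# melt at 30% volume fraction. All constructions are deterministic given the
# config seed.

#' Experiment configuration
#'
#' Bundles the parameters of one reproduced experiment. Defaults are the
#' study conditions: a 133-bead single-TAD ring, a 400-bead three-TAD
#' circle, and an 8 x 300-bead melt at 30% volume fraction (the desk-scale
#' stand-in for the 8 x 4000-bead system; set `n_beads_per_ring = 4000` for
#' the full-size runs).
#'
#' @param experiment `"single_tad"`, `"three_tad"` or `"melt_demix"`.
#' @param n_beads_per_ring Beads per chromatin ring (defaults: 133 / 400 /
#'   300 by experiment).
#' @param n_rings Number of rings (melt only; default 8).
#' @param knot Torus-knot parameters `c(p, q)` for the initial knot
#'   (`c(2, 3)` = trefoil; `c(1, 1)` = unknotted control).
#' @param phantom_len Length of each reduced-excluded-volume (Top2B) border
#'   segment, beads.
#' @param ctcf_len CTCF stop beads flanking each phantom segment, per side.
#' @param volume_fraction Bead volume fraction in the confining sphere
#'   (melt; default 0.30, the chromatin concentration of eukaryotic nuclei).
#' @param phantom Set `FALSE` for the no-strand-passage control (CTCF beads
#'   kept, phantom flags off).
#' @param seed Integer seed; generation and dynamics derive all randomness
#'   from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("single_tad", "three_tad", "melt_demix"),
                              n_beads_per_ring = NULL, n_rings = 8L,
                              knot = c(2, 3), phantom_len = 5L, ctcf_len = 1L,
                              volume_fraction = 0.30, phantom = TRUE,
                              seed = 1L) {
  experiment <- match.arg(experiment)
  n_beads_per_ring <- n_beads_per_ring %||%
    switch(experiment, single_tad = 133L, three_tad = 400L, melt_demix = 300L)
  if (volume_fraction <= 0 || volume_fraction > 0.49) {
    abort("volume_fraction must lie in (0, 0.49]", class = "loopex_config_error")
  }
  if (length(knot) == 2 && gcd2(knot[1], knot[2]) != 1) {
    abort("torus parameters (p, q) with gcd > 1 give a link, not a knot",
          class = "loopex_config_error")
  }
  structure(list(experiment = experiment,
                 n_beads_per_ring = as.integer(n_beads_per_ring),
                 n_rings = as.integer(n_rings), knot = knot,
                 phantom_len = as.integer(phantom_len),
                 ctcf_len = as.integer(ctcf_len),
                 volume_fraction = volume_fraction, phantom = phantom,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)

#' Parametric torus-knot polygon
#'
#' Samples the standard (p,q) torus-knot curve and resamples it uniformly to
#' `n_beads` vertices with bond length ~= 1 sigma (the curve is rescaled so
#' its contour length equals `n_beads`). `(1, q)` gives an unknotted control
#' ring. `gcd(p, q)` must be 1 (otherwise the curve is a multi-component
#' link).
#'
#' @param p,q Coprime torus winding numbers.
#' @param n_beads Number of vertices (at least `3 * max(p, q)`).
#' @param major_R,minor_r Torus shape before rescaling (their ratio sets the
#'   tube clearance).
#' @return A `closed_curve` tibble.
#' @examples
#' identify_knot(torus_knot_coords(2, 3, 133))$name # "3_1"
#' @export
torus_knot_coords <- function(p, q, n_beads, major_R = 3, minor_r = 1.4) {
  if (gcd2(p, q) != 1) {
    abort("gcd(p, q) must be 1: a (p,q) torus curve with gcd > 1 is a link",
          class = "loopex_config_error")
  }
  if (n_beads < 3 * max(p, q)) {
    abort("too few beads to realise this torus knot",
          class = "loopex_config_error")
  }
  fine <- max(20L * n_beads, 2000L)
  t <- seq(0, 2 * pi, length.out = fine + 1)[seq_len(fine)]
  m <- cbind((major_R + minor_r * cos(q * t)) * cos(p * t),
             (major_R + minor_r * cos(q * t)) * sin(p * t),
             minor_r * sin(q * t))
  m <- resample_closed(m, n_beads)
  # rescale to unit bond length
  bl <- mean(sqrt(rowSums((m - m[c(2:nrow(m), 1), ])^2)))
  as_closed_curve(m / bl)
}

# resample a closed polyline to n equally spaced vertices (by arc length)
resample_closed <- function(m, n) {
  seg <- sqrt(rowSums((m[c(2:nrow(m), 1), ] - m)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  want <- seq(0, total, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(want, cum, rightmost.closed = TRUE)
  frac <- (want - cum[idx]) / pmax(seg[idx], 1e-300)
  nxt <- c(2:nrow(m), 1)
  m[idx, ] + (m[nxt[idx], ] - m[idx, ]) * frac
}

# write a border region (ctcf | phantom... | ctcf) into a system, centred so
# the segment occupies local indices start..start+len-1 of the given ring
apply_border <- function(system, ring_id, start_local, phantom_len, ctcf_len,
                         phantom = TRUE) {
  beads <- ring_beads(system, ring_id)
  n <- length(beads)
  ph <- beads[wrap_index(seq(start_local, length.out = phantom_len), n)]
  ct <- beads[wrap_index(c(seq(start_local - ctcf_len, length.out = ctcf_len),
                           seq(start_local + phantom_len, length.out = ctcf_len)), n)]
  ix <- match(ph, system$bead)
  if (phantom) system$phantom[ix] <- TRUE
  system$ctcf[match(ct, system$bead)] <- TRUE
  system
}

curve_to_system <- function(curve, ...) {
  m <- curve_matrix(curve)
  sys <- build_ring(nrow(m), ...)
  set_positions(sys, m)
}

#' Knotted single-TAD ring
#'
#' One closed chromatin ring (default 133 beads) carrying the requested
#' torus knot, with a TAD-border region: a short phantom (Top2B-like)
#' segment flanked by CTCF stop beads. The canonical extruder start site —
#' the bead diametrically opposite the border along the contour, equally
#' distant from both borders — is recorded in the attribute `start_site`.
#'
#' @param cfg An [experiment_config()] with `experiment = "single_tad"`.
#' @return A `chain_system` with attributes `start_site` and `border`
#'   (bead-id vector of the border region).
#' @export
single_tad_ring <- function(cfg = experiment_config("single_tad")) {
  stopifnot(cfg$experiment == "single_tad")
  n <- cfg$n_beads_per_ring
  curve <- if (all(cfg$knot == c(1, 1))) {
    as_closed_curve(circle_coords(n))
  } else {
    torus_knot_coords(cfg$knot[1], cfg$knot[2], n)
  }
  sys <- curve_to_system(curve)
  start_local <- 2L  # phantom beads 2..6, ctcf at 1 and 7 with defaults
  sys <- apply_border(sys, 1L, start_local, cfg$phantom_len, cfg$ctcf_len,
                      cfg$phantom)
  border_mid <- start_local + (cfg$phantom_len - 1) / 2
  attr(sys, "start_site") <- wrap_index(as.integer(round(border_mid + n / 2)), n)
  attr(sys, "border") <- which(sys$ctcf | sys$phantom)
  sys
}

circle_coords <- function(n) {
  r <- 1 / (2 * sin(pi / n))
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(r * cos(th), r * sin(th), 0)
}

#' Three-TAD circle with a delocalised trefoil
#'
#' A single 400-bead ring laid out as one global trefoil and partitioned
#' into three TADs of equal length (within one bead), separated by short
#' spacer regions each carrying a phantom segment flanked by CTCF beads.
#' Extruder start sites sit mid-TAD; the TAD layout is recorded in the
#' attribute `tads`.
#'
#' @param cfg An [experiment_config()] with `experiment = "three_tad"`.
#' @return A `chain_system` with attributes `tads` (tibble: tad, spacer
#'   start, start_site) and `border`.
#' @export
three_tad_circle <- function(cfg = experiment_config("three_tad")) {
  stopifnot(cfg$experiment == "three_tad")
  n <- cfg$n_beads_per_ring
  curve <- if (all(cfg$knot == c(1, 1))) {
    as_closed_curve(circle_coords(n))
  } else {
    torus_knot_coords(cfg$knot[1], cfg$knot[2], n)
  }
  sys <- curve_to_system(curve)
  spacer_w <- cfg$phantom_len + 2L * cfg$ctcf_len
  starts <- as.integer(round((seq_len(3) - 1) * n / 3)) + 2L
  for (s in starts) {
    sys <- apply_border(sys, 1L, s, cfg$phantom_len, cfg$ctcf_len, cfg$phantom)
  }
  mids <- vapply(seq_len(3), function(k) {
    lo <- starts[k] + spacer_w
    hi <- if (k < 3) starts[k + 1] - 1L else starts[1] - 1L + n
    wrap_index(as.integer(round((lo + hi) / 2)), n)
  }, 0L)
  attr(sys, "tads") <- tibble(tad = seq_len(3), spacer_start = starts,
                              start_site = mids)
  attr(sys, "border") <- which(sys$ctcf | sys$phantom)
  sys
}

#' Confining-sphere radius for a target volume fraction
#'
#' Solves `n * (pi/6) sigma^3 / ((4/3) pi R^3) = phi` for R, i.e.
#' `R = (n / (8 phi))^(1/3)` in bead diameters.
#'
#' @param n_total_beads Total bead count.
#' @param phi Volume fraction, in `(0, 0.49]`.
#' @return Radius in sigma.
#' @examples
#' sphere_radius_for_fraction(8, 1 / 8) # exactly 2
#' sphere_radius_for_fraction(32000, 0.30) # ~23.71
#' @export
sphere_radius_for_fraction <- function(n_total_beads, phi) {
  if (phi <= 0 || phi > 0.49) {
    abort("volume fraction must lie in (0, 0.49]", class = "loopex_config_error")
  }
  (n_total_beads / (8 * phi))^(1 / 3)
}

# Deterministic unknotted, unlinked start for the melt: each ring is a
# simple closed planar curve (an annular double spiral: out along one arm,
# back along the interleaved arm, closed by arcs at the inner and outer rim)
# laid in its own z-plane inside the sphere. Planar simple closed curves in
# distinct parallel planes are unknots with pairwise linking number zero by
# construction.
melt_start <- function(cfg = experiment_config("melt_demix")) {
  stopifnot(cfg$experiment == "melt_demix")
  n <- cfg$n_beads_per_ring
  k <- cfg$n_rings
  R <- sphere_radius_for_fraction(n * k, cfg$volume_fraction)
  zs <- seq(-0.75 * R, 0.75 * R, length.out = k)
  sys <- NULL
  for (r in seq_len(k)) {
    rd <- 0.92 * sqrt(R^2 - zs[r]^2) - 0.6
    m <- annular_spiral(n, rd)
    m <- cbind(m, zs[r])
    ring <- curve_to_system(as_closed_curve(m))
    sys <- if (is.null(sys)) ring else bind_systems(sys, ring)
  }
  attr(sys, "sphere_radius") <- R
  # per-ring border region at local beads 2..(1+phantom_len), CTCF flanks
  for (r in seq_len(k)) {
    sys <- apply_border(sys, r, 2L, cfg$phantom_len, cfg$ctcf_len, TRUE)
  }
  validate_chain_system(sys)
  sys
}

# Simple closed planar curve filling the annulus [r_in, rd]: two interleaved
# spiral arms closed by arcs strictly inside/outside the arm radii, so the
# polygon never self-intersects. A plane cannot hold n beads at unit spacing
# beyond its area, so the contour length is capped to keep the gap between
# neighbouring arms at gap_min; bead spacing shrinks accordingly (the
# capped-force push-off of the phantom phase restores bond lengths).
annular_spiral <- function(n_beads, rd, r_in = 1.2, gap_min = 0.55) {
  # total length budget: arms ~ Phi (rd + r_in), rims ~ pi (rd + r_in),
  # inter-arm gap = pi (rd - r_in) / Phi
  cap <- pi * (rd^2 - r_in^2) / gap_min + pi * (rd + r_in)
  L <- min(n_beads, cap)
  Phi <- (L - pi * (rd + r_in)) / (rd + r_in)
  if (!is.finite(Phi) || Phi < 2 * pi) {
    # short rings: a circle (shrunk to fit if need be)
    th <- seq(0, 2 * pi, length.out = 400)[-400]
    rr <- min(L / (2 * pi), rd - 0.2)
    return(resample_closed(cbind(rr * cos(th), rr * sin(th)), n_beads))
  }
  cc <- (rd - r_in) / Phi
  arm <- function(phis, shift) {
    cbind((r_in + cc * (phis - shift)) * cos(phis),
          (r_in + cc * (phis - shift)) * sin(phis))
  }
  n_fine <- 2500
  out_arm <- arm(seq(0, Phi, length.out = n_fine), 0)
  rim_out <- (rd + 0.45) * cbind(cos(seq(Phi, Phi + pi, length.out = 120)),
                                 sin(seq(Phi, Phi + pi, length.out = 120)))
  in_arm <- arm(seq(Phi + pi, pi, length.out = n_fine), pi)
  rim_in <- (r_in - 0.45) * cbind(cos(seq(pi, 0, length.out = 80)),
                                  sin(seq(pi, 0, length.out = 80)))
  resample_closed(rbind(out_arm, rim_out, in_arm, rim_in), n_beads)
}

#' Topologically equilibrated confined ring melt
#'
#' Builds the confined multi-ring system (default 8 rings, 30% volume
#' fraction) and topologically equilibrates it: with every bead phantom, the
#' thermally fluctuating chains pass freely through themselves and each
#' other; equilibration runs in windows until the knot/linking spectrum is
#' stationary. Excluded volume is then restored (outside the designated
#' Top2B border segments) through a capped-force push-off. The returned
#' system carries the attribute `melt_report` — per-ring knot types and the
#' pairwise linking matrix of the equilibrated state.
#'
#' @param cfg An [experiment_config()] with `experiment = "melt_demix"`.
#' @param window_steps MD steps per equilibration window.
#' @param min_windows,max_windows Window budget for the stationarity loop.
#' @param pushoff_steps Capped-force steps used to restore excluded volume.
#' @param progress Emit progress lines to stderr.
#' @return A `chain_system` with attributes `melt_report`, `sphere_radius`.
#' @export
equilibrated_melt <- function(cfg = experiment_config("melt_demix"),
                              window_steps = 60000L, min_windows = 4L,
                              max_windows = 10L, pushoff_steps = 4000L,
                              progress = FALSE) {
  sys <- melt_start(cfg)
  ip <- integrator_params(seed = cfg$seed)
  ff <- force_field()
  saved_phantom <- sys$phantom
  sys$phantom <- rep(TRUE, nrow(sys))  # phase 1: free passage everywhere
  # capped-force relaxation first: the space-filling starting curves have
  # tight corners whose in-bond repulsive cores would otherwise kick hard
  sys <- push_off(sys, ff, ip, n_steps = 2000, cap = 50)

  history <- list()
  for (w in seq_len(max_windows)) {
    sys <- step_langevin(sys, ff, ip, window_steps)
    dets <- vapply(system_curves(sys), function(cv) {
      dg <- min_crossing_diagram(cv, n_directions = 2, seed = cfg$seed + w)
      attr(alexander_polynomial(dg), "determinant")
    }, 0)
    history[[w]] <- dets
    if (progress) {
      inform(sprintf("melt equilibration window %d: %d/%d rings knotted",
                     w, sum(dets != 1), length(dets)))
    }
    if (w >= min_windows && knot_spectrum_stationary(history)) break
  }

  # phase 2: restore excluded volume (borders stay phantom) via push-off
  sys$phantom <- saved_phantom
  sys <- push_off(sys, ff, ip, n_steps = pushoff_steps, cap = 50)
  if (min_nonbonded_distance(sys) < 0.75) {
    abort("push-off failed to resolve clashes after equilibration",
          class = "loopex_generation_error")
  }
  sys <- step_langevin(sys, ff, ip, 5000L)

  report <- topology_report(sys, seed = cfg$seed)
  attr(sys, "melt_report") <- report
  sys
}

# stationarity heuristic: binned knot-determinant spectra of the last three
# windows are compared by a chi-square statistic; stationary when homogeneous
knot_spectrum_stationary <- function(history, alpha = 0.05) {
  k <- length(history)
  if (k < 3) return(FALSE)
  bin <- function(d) cut(d, breaks = c(-Inf, 1.5, 9.5, Inf),
                         labels = c("trivial", "simple", "complex"))
  tab <- sapply(history[(k - 2):k], function(d) table(bin(d)))
  if (all(colSums(tab) == 0)) return(FALSE)
  keep <- rowSums(tab) > 0
  if (sum(keep) < 2) return(TRUE)  # everything in one class: trivially stable
  p <- tryCatch(
    suppressWarnings(chisq.test(tab[keep, , drop = FALSE])$p.value),
    error = function(e) 1
  )
  is.na(p) || p > alpha
}
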