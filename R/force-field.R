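# Force-field and integrator parameter containers, plus the force evaluation
# surface. The conventions follow standard coarse-grained polymer MD in
# reduced Lennard-Jones units: sigma = 1 (bead diameter), kBT = 1, mass = 1.

#' Bead-spring force-field parameters
#'
#' The default combination is the conventional non-crossing pairing of a
#' finitely extensible (FENE) backbone bond with a purely repulsive,
#' truncated-and-shifted 12-6 (WCA) excluded-volume term: the bond diverges
#' before two beads can stretch far enough apart for another chain to slip
#' between them, so chain segments cannot pass through each other. Backbone
#' bonds always carry the WCA core between their two beads, so phantom
#' (excluded-volume-off) chains keep their contour length; the non-bonded WCA
#' term is skipped for any pair in which at least one bead is phantom.
#'
#' @param bond_style `"fene"` (default) or `"harmonic"` backbone bonds.
#' @param bond_k Bond stiffness, kBT/sigma^2 (FENE default 30).
#' @param bond_rmax FENE maximum extension, sigma (default 1.5).
#' @param bond_r0 Harmonic bond rest length, sigma.
#' @param ev_epsilon Excluded-volume energy scale, kBT; 0 switches all
#'   non-bonded interactions off.
#' @param ev_cutoff Repulsive cutoff, sigma (default `2^(1/6)`, WCA).
#' @param bend_kappa Bending stiffness, kBT (default 0: fully flexible; the
#'   unknotting mechanism does not depend on persistence length).
#' @param wall_stiffness Harmonic inward restoring force constant beyond the
#'   confining sphere, kBT/sigma^2.
#' @param force_cap Per-bead force magnitude cap, kBT/sigma; `Inf` (default)
#'   disables capping. A finite cap (e.g. 50) gives the soft push-off used to
#'   resolve overlaps in freshly generated configurations.
#' @return A `loopex_force_field` list.
#' @examples
#' force_field()
#' force_field(force_cap = 50) # soft push-off variant
#' @export
force_field <- function(bond_style = c("fene", "harmonic"), bond_k = 30,
                        bond_rmax = 1.5, bond_r0 = 1, ev_epsilon = 1,
                        ev_cutoff = 2^(1 / 6), bend_kappa = 0,
                        wall_stiffness = 100, force_cap = Inf) {
  bond_style <- match.arg(bond_style)
  stopifnot(ev_cutoff > 0, bond_k > 0, bond_rmax > 0)
  structure(list(bond_style = bond_style, bond_k = bond_k,
                 bond_rmax = bond_rmax, bond_r0 = bond_r0,
                 ev_epsilon = ev_epsilon, ev_cutoff = ev_cutoff,
                 bend_kappa = bend_kappa, wall_stiffness = wall_stiffness,
                 force_cap = force_cap),
            class = "loopex_force_field")
}

#' Langevin integrator parameters
#'
#' @param dt Timestep in reduced time tau (default 0.01).
#' @param gamma Friction per unit mass per tau (default 1).
#' @param temperature Target temperature in kBT (default 1).
#' @param seed Integer seed for the thermal-noise stream. Identical seeds (and
#'   identical inputs) reproduce trajectories exactly on one platform.
#' @return A `loopex_integrator` list.
#' @export
integrator_params <- function(dt = 0.01, gamma = 1, temperature = 1, seed = 1L) {
  stopifnot(dt > 0, gamma > 0, temperature >= 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 seed = as.double(seed)),
            class = "loopex_integrator")
}

# angle triplets (a,b,c) along each ring, only needed when bend_kappa > 0
ring_angles <- function(system) {
  out <- lapply(unique(system$ring), function(r) {
    b <- system$bead[system$ring == r]
    n <- length(b)
    if (n < 3) return(NULL)
    cbind(b, b[wrap_index(seq_len(n) + 1L, n)], b[wrap_index(seq_len(n) + 2L, n)])
  })
  do.call(rbind, out)
}

ff_to_cpp <- function(ff) {
  ff$force_cap <- if (is.finite(ff$force_cap)) ff$force_cap else 0
  ff
}

cpp_args <- function(system, ff) {
  hb <- attr(system, "harm_bonds")
  angles <- if (ff$bend_kappa > 0) ring_angles(system) else
    matrix(integer(), 0, 3)
  list(
    pos = positions(system),
    bonds = attr(system, "bonds") - 1L,
    hbonds = cbind(hb$i, hb$j) - 1L,
    hb_k = as.double(hb$k), hb_r0 = as.double(hb$r0),
    angles = matrix(as.integer(angles), ncol = 3) - 1L,
    phantom = system$phantom,
    sphere_r = {
      rs <- attr(system, "sphere_radius")
      if (is.finite(rs %||% NA_real_)) rs else -1
    },
    ff = ff_to_cpp(ff)
  )
}

#' Evaluate forces on every bead
#'
#' Computes the negative energy gradient of the full force field: backbone
#' bonds, auxiliary harmonic springs, non-bonded excluded volume (skipping
#' pairs with a phantom member), optional bending, and the confining-wall
#' restoring force. Near-coincident bead pairs with excluded volume on are
#' reported as clashes (capped force plus a warning), not an error.
#'
#' @param system A `chain_system`.
#' @param ff A [force_field()].
#' @return A tibble (bead, fx, fy, fz) with attributes `potential` (total
#'   potential energy, kBT) and `clashes`.
#' @examples
#' f <- compute_forces(build_ring(20), force_field())
#' max(abs(colSums(as.matrix(f[, -1])))) # net force ~ 0
#' @export
compute_forces <- function(system, ff = force_field()) {
  a <- cpp_args(system, ff)
  res <- cpp_compute_forces(a$pos, a$bonds, a$hbonds, a$hb_k, a$hb_r0,
                            a$angles, a$phantom, a$sphere_r, a$ff)
  if (res$clashes > 0) {
    warn(sprintf("%d near-coincident bead pair(s): force capped", res$clashes))
  }
  out <- tibble(bead = system$bead,
                fx = res$forces[, 1], fy = res$forces[, 2],
                fz = res$forces[, 3])
  attr(out, "potential") <- res$potential
  attr(out, "clashes") <- res$clashes
  out
}
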