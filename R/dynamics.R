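# Langevin dynamics driver. Integration uses the BAOAB splitting of the
# underdamped Langevin equation, a standard stable scheme for FENE/WCA bead
# polymers at dt = 0.01 tau. Thermal noise is drawn from a self-contained
# counter-seeded generator: the stream for a call is derived from the
# integrator seed and the system's chunk counter, so repeated short calls
# (as the extrusion pipelines make) are exactly reproducible and independent
# of R's RNG state.

chunk_seed <- function(seed, chunk) {
  # splitmix-style mix of (seed, chunk) into one 53-bit stream id
  s <- (seed * 2654435761 + chunk * 40503 + 1013904223) %% 2^48
  s * 1024 + (chunk %% 1024)
}

#' Advance the system by Langevin dynamics
#'
#' Runs `n_steps` of BAOAB Langevin integration at the target temperature.
#' Ring topology, flags and connectivity are unchanged; only positions (and
#' the stored velocities) advance. With excluded volume on and the default
#' timestep, chain segments cannot pass through each other, so the knot type
#' of every non-phantom ring is conserved.
#'
#' @param system A `chain_system`.
#' @param ff A [force_field()].
#' @param ip An [integrator_params()].
#' @param n_steps Number of timesteps (`0` is a no-op).
#' @param log_every If positive, write a step/energy/temperature line to
#'   stderr every so many steps.
#' @return The updated `chain_system`. The attribute
#'   `mean_kinetic_temperature` carries the run-averaged kinetic temperature
#'   (kBT), useful for thermostat checks.
#' @examples
#' sys <- build_ring(30)
#' sys2 <- step_langevin(sys, force_field(), integrator_params(seed = 7), 100)
#' @export
step_langevin <- function(system, ff = force_field(),
                          ip = integrator_params(), n_steps,
                          log_every = 0L) {
  stopifnot(n_steps >= 0)
  if (n_steps == 0) return(system)
  a <- cpp_args(system, ff)
  vel <- attr(system, "velocities")
  if (is.null(vel)) vel <- matrix(0, nrow(system), 3)
  chunk <- attr(system, "md_chunk") %||% 0L
  res <- cpp_run_langevin(a$pos, vel, a$bonds, a$hbonds, a$hb_k, a$hb_r0,
                          a$angles, a$phantom, a$sphere_r, a$ff,
                          ip$dt, ip$gamma, ip$temperature,
                          as.integer(n_steps), chunk_seed(ip$seed, chunk),
                          as.integer(log_every))
  system <- set_positions(system, res$pos)
  attr(system, "velocities") <- res$vel
  attr(system, "md_chunk") <- chunk + 1L
  attr(system, "mean_kinetic_temperature") <- res$mean_kinetic_temperature
  system
}

# Soft push-off: resolve overlaps of a freshly built configuration by running
# capped-force dynamics before production (cap 50 kBT/sigma by default).
push_off <- function(system, ff = force_field(), ip = integrator_params(),
                     n_steps = 3000, cap = 50) {
  caps <- unique(c(min(cap, 10), cap))
  for (cp in caps) {
    ffc <- ff
    ffc$force_cap <- cp
    system <- step_langevin(system, ffc, ip, n_steps)
  }
  system
}

# smallest non-bonded distance among beads with excluded volume on
min_nonbonded_distance <- function(system) {
  keep <- !system$phantom
  pos <- positions(system)[keep, , drop = FALSE]
  ids <- system$bead[keep]
  if (nrow(pos) < 2) return(Inf)
  bonds <- attr(system, "bonds")
  bonded <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  idx <- which(d == min(d), arr.ind = TRUE)[1, ]
  pr <- paste(min(ids[idx]), max(ids[idx]))
  while (pr %in% bonded) {
    d[idx[1], idx[2]] <- Inf
    d[idx[2], idx[1]] <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    pr <- paste(min(ids[idx]), max(ids[idx]))
  }
  d[idx[1], idx[2]]
}
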