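# Force field and Langevin integrator.

test_that("build_ring creates closed cycles and rejects degenerate input", {
  for (n in c(3L, 133L, 4000L)) {
    sys <- build_ring(n)
    expect_equal(nrow(sys), n)
    expect_equal(nrow(system_bonds(sys)), n)
    expect_setequal(unique(c(system_bonds(sys)$i, system_bonds(sys)$j)),
                    sys$bead)
    expect_true(validate_chain_system(sys))
    expect_false(any(sys$phantom) || any(sys$ctcf))
  }
  expect_error(build_ring(2), class = "loopex_topology_error")
})

test_that("pair forces match the WCA form and its exclusion rules", {
  # exactly zero at the cutoff
  f_cut <- compute_forces(two_bead_system(2^(1 / 6)))
  expect_equal(f_cut$fx, c(0, 0))

  # magnitude 24 eps/sigma at r = 1, equal and opposite, along the axis
  f1 <- compute_forces(two_bead_system(1))
  expect_equal(f1$fx[1], -24, tolerance = 1e-12)
  expect_equal(f1$fx[2], 24, tolerance = 1e-12)
  expect_equal(abs(f1$fy) + abs(f1$fz), c(0, 0))

  # numeric-differentiation oracle across separations
  for (r in c(0.85, 0.95, 1.05, 1.1)) {
    f <- compute_forces(two_bead_system(r))
    expect_equal(f$fx[2], oracle_wca_force(r), tolerance = 1e-4)
  }

  # a phantom member switches the pair interaction off entirely
  f_ph <- compute_forces(two_bead_system(1, phantom1 = TRUE))
  expect_equal(max(abs(as.matrix(f_ph[, -1]))), 0)
})

test_that("clashing beads are reported and force-capped, not fatal", {
  sysc <- two_bead_system(1e-8)
  expect_warning(f <- compute_forces(sysc), "near-coincident")
  expect_lte(max(abs(as.matrix(f[, -1]))), 100 + 1e-9)
})

test_that("net force on an isolated ring vanishes", {
  f <- compute_forces(build_ring(50))
  expect_lt(max(abs(colSums(as.matrix(f[, c("fx", "fy", "fz")])))), 1e-10)
})

test_that("step_langevin: no-op at zero steps, bitwise determinism, flags kept", {
  sys <- build_ring(60)
  ip <- integrator_params(seed = 11)
  expect_identical(positions(step_langevin(sys, force_field(), ip, 0)),
                   positions(sys))
  s1 <- step_langevin(sys, force_field(), ip, 1500)
  s2 <- step_langevin(sys, force_field(), ip, 1500)
  expect_identical(positions(s1), positions(s2))
  expect_false(identical(positions(s1), positions(sys)))
  expect_identical(s1$phantom, sys$phantom)
  expect_identical(attr(s1, "bonds"), attr(sys, "bonds"))
})

test_that("thermostat holds the target temperature within 5%", {
  sys <- build_ring(80)
  ip <- integrator_params(seed = 3)
  sys <- step_langevin(sys, force_field(), ip, 5000)   # burn-in
  sys <- step_langevin(sys, force_field(), ip, 100000)
  expect_equal(attr(sys, "mean_kinetic_temperature"), 1, tolerance = 0.05)
})

test_that("free-bead diffusion follows the Einstein relation", {
  # D = kBT / (m gamma); MSD ~ 6 D t for t >> 1/gamma. 64 non-interacting
  # beads per seed give independent samples of the displacement.
  gamma <- 2
  n_steps <- 20000L
  t_tot <- n_steps * 0.01
  n_free <- 64L
  msd <- vapply(1:8, function(s) {
    df <- tibble::tibble(bead = seq_len(n_free), ring = seq_len(n_free),
                         x = 0, y = 0, z = 0, phantom = TRUE, ctcf = FALSE,
                         cohesin = FALSE)
    sys <- loopex:::new_chain_system(df, bonds = matrix(integer(), 0, 2))
    sys <- step_langevin(sys, force_field(ev_epsilon = 0),
                         integrator_params(gamma = gamma, seed = s), n_steps)
    mean(rowSums(positions(sys)^2))
  }, 0)
  expect_equal(mean(msd), 6 * (1 / gamma) * t_tot, tolerance = 0.2)
})

test_that("confined beads stay within half a diameter of the wall", {
  sys <- build_ring(40)  # polygon radius ~6.4 sigma, fits in R = 7
  attr(sys, "sphere_radius") <- 7
  ip <- integrator_params(seed = 5)
  for (k in 1:5) {
    sys <- step_langevin(sys, force_field(), ip, 4000)
    expect_lt(max(sqrt(rowSums(positions(sys)^2))), 7 + 0.5)
  }
})

test_that("integration blow-up is reported with the step, not a crash", {
  sys <- build_ring(10)
  # absurd timestep makes the FENE springs explode
  expect_error(step_langevin(sys, force_field(), integrator_params(dt = 5), 2000),
               "blow-up|non-finite")
})

test_that("phantom dynamics preserve contour length through in-bond cores", {
  sys <- build_ring(60)
  sys$phantom <- rep(TRUE, 60)
  ip <- integrator_params(seed = 8)
  sys <- step_langevin(sys, force_field(), ip, 20000)
  pos <- positions(sys)
  bl <- sqrt(rowSums((pos - pos[c(2:60, 1), ])^2))
  expect_gt(min(bl), 0.7)
  expect_lt(max(bl), 1.4)
})
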