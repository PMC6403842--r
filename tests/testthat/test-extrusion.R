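# Cohesin handcuff and simplified migrating-bond extruder.

make_loaded_ring <- function(seed = 1, n = 133) {
  cfg <- experiment_config("single_tad", seed = seed)
  sys <- single_tad_ring(cfg)
  lh <- load_handcuff(sys, attr(sys, "start_site"),
                      integrator_params(seed = seed))
  lh
}

test_that("handcuff loads threaded, joined and anchored", {
  lh <- make_loaded_ring()
  inv <- handcuff_invariants(lh$system, lh$handcuff)
  expect_equal(abs(inv$threading), c(1, 1))  # each ring pierced exactly once
  expect_equal(inv$join_bonds, c(2, 2))
  expect_lte(max(inv$max_walk_offset), 2)
  expect_equal(lh$handcuff$anchor_b,
               loopex:::wrap_index(lh$handcuff$anchor_a + 1L, 133L))
  # initial loop arc (anchor to anchor through the start) is minimal
  expect_lt(extrusion_progress(lh$system, lh$handcuff), 0.02)
})

test_that("handcuff wraps around the ring seam and warns on phantom sites", {
  sys <- single_tad_ring(experiment_config("single_tad"))
  # move the border away from bead 1 so site n is an ordinary bead
  n <- nrow(sys)
  lh <- load_handcuff(sys, n, integrator_params(seed = 2))
  expect_equal(lh$handcuff$anchor_a, n)
  expect_equal(lh$handcuff$anchor_b, 1L)

  ph_site <- which(sys$phantom)[1]
  w <- capture_warnings(load_handcuff(sys, ph_site, integrator_params(seed = 3)))
  expect_true(any(grepl("phantom", w)))  # allowed, but flagged
})

test_that("advance_walk follows the shrink-retarget-stop rules", {
  lh <- make_loaded_ring(seed = 4)
  sys <- lh$system; hc <- lh$handcuff
  ip <- integrator_params(seed = 4)

  # drive until at least one advance happens; anchors only move outward
  a0 <- hc$anchor_a; b0 <- hc$anchor_b
  prog <- extrusion_progress(sys, hc)
  for (k in 1:60) {
    sys <- step_langevin(sys, force_field(), ip, 200)
    aw <- advance_walk(sys, hc); sys <- aw$system; hc <- aw$handcuff
    p <- extrusion_progress(sys, hc)
    expect_gte(p, prog - 1e-12)   # loop never shrinks
    prog <- p
  }
  expect_gt(prog, 0.02)           # walking actually advanced

  # walk bonds always target within 2 beads of the anchor
  inv <- handcuff_invariants(sys, hc)
  expect_lte(max(inv$max_walk_offset), 2)

  # condition not met: stretch the walk bonds far beyond the threshold
  hb <- attr(sys, "harm_bonds")
  sys_far <- sys
  rows <- grepl("walk_a", hb$tag)
  pos <- positions(sys_far)
  pos[hb$i[rows], ] <- pos[hb$i[rows], ] + 5  # move cohesin beads away
  sys_far <- loopex:::set_positions(sys_far, pos)
  aw2 <- advance_walk(sys_far, hc)
  expect_equal(aw2$handcuff$anchor_a, hc$anchor_a)
})

test_that("a CTCF bead halts one side permanently, not the other", {
  lh <- make_loaded_ring(seed = 5)
  sys <- lh$system; hc <- lh$handcuff
  # plant a CTCF flag directly ahead of side a, then force an advance attempt
  beads <- loopex:::ring_beads(sys, hc$chrom_ring)
  n <- length(beads)
  nxt <- beads[loopex:::wrap_index(match(hc$anchor_a, beads) - 1L, n)]
  sys$ctcf[match(nxt, sys$bead)] <- TRUE
  # shrink walk bonds artificially so the advance condition is met
  hb <- attr(sys, "harm_bonds")
  pos <- positions(sys)
  for (side in c("a", "b")) {
    rows <- which(hb$tag == sprintf("walk_%s_h%d", side, hc$id))
    for (r in rows) pos[hb$i[r], ] <- pos[hb$j[r], ] + c(0.5, 0, 0)
  }
  sys <- loopex:::set_positions(sys, pos)
  aw <- advance_walk(sys, hc)
  expect_true(aw$handcuff$stopped_a)
  expect_false(aw$handcuff$stopped_b)
  expect_equal(aw$handcuff$anchor_a, hc$anchor_a)
  # stopped side never moves again even if conditions hold
  aw2 <- advance_walk(aw$system, aw$handcuff)
  expect_equal(aw2$handcuff$anchor_a, hc$anchor_a)
})

test_that("simple extruder migrates, stops at CTCF and completes", {
  sys <- loopex:::curve_to_system(as_closed_curve(loopex:::circle_coords(40)))
  sys$ctcf[c(3, 20)] <- TRUE
  se <- simple_extruder(sys, 10L)
  sys <- se$system; ex <- se$extruder
  expect_equal(c(ex$left_anchor, ex$right_anchor), c(10L, 11L))

  # anchors further apart than the threshold: no movement
  ex_far <- ex
  pos <- positions(sys)
  pos[11, ] <- pos[10, ] + c(3, 0, 0)
  sys_far <- loopex:::set_positions(sys, pos)
  st <- step_simple_extrusion(sys_far, ex_far)
  expect_equal(st$extruder$left_anchor, 10L)

  # with anchors near: both migrate outward until CTCF stops each side
  ip <- integrator_params(seed = 7)
  prog <- extrusion_progress(sys, ex)
  for (k in 1:2000) {
    sys <- step_langevin(sys, force_field(), ip, 50)
    st <- step_simple_extrusion(sys, ex)
    sys <- st$system; ex <- st$extruder
    p <- extrusion_progress(sys, ex)
    expect_gte(p, prog - 1e-12)
    prog <- p
    if (ex$left_stopped && ex$right_stopped) break
  }
  expect_true(ex$left_stopped && ex$right_stopped)
  expect_equal(ex$left_anchor, 4L)   # adjacent to the CTCF bead at 3
  expect_equal(ex$right_anchor, 19L) # adjacent to the CTCF bead at 20
  expect_equal(extrusion_progress(sys, ex), 1.0)
})

test_that("extrusion leaves chromatin bonds and bead count untouched", {
  lh <- make_loaded_ring(seed = 6)
  sys <- lh$system; hc <- lh$handcuff
  bonds0 <- attr(sys, "bonds")
  n0 <- nrow(sys)
  ip <- integrator_params(seed = 6)
  for (k in 1:40) {
    sys <- step_langevin(sys, force_field(), ip, 200)
    aw <- advance_walk(sys, hc); sys <- aw$system; hc <- aw$handcuff
  }
  expect_identical(attr(sys, "bonds"), bonds0)
  expect_equal(nrow(sys), n0)
})

test_that("the extruded arc stays unknotted while the knot is pushed ahead", {
  lh <- make_loaded_ring(seed = 8)
  sys <- lh$system; hc <- lh$handcuff
  ip <- integrator_params(seed = 8)
  checked <- 0
  for (k in 1:120) {
    sys <- step_langevin(sys, force_field(), ip, 200)
    aw <- advance_walk(sys, hc); sys <- aw$system; hc <- aw$handcuff
    if (k %% 30 == 0 && extrusion_progress(sys, hc) > 0.2) {
      arc <- loopex:::extruded_arc_curve(sys, hc)
      if (!is.null(arc) && nrow(arc) > 10) {
        expect_equal(identify_knot(arc)$name, "0_1")
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 0)
})
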