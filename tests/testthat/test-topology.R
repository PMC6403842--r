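# Knot identification: simplification, projection, Alexander invariants,
# linking numbers.

test_that("simplification shrinks curves and preserves the polynomial", {
  circle <- cbind(cos(seq(0, 2 * pi, length.out = 101)[1:100]),
                  sin(seq(0, 2 * pi, length.out = 101)[1:100]), 0)
  s <- simplify_curve(circle)
  expect_lte(nrow(s), 10)

  tr <- raw_torus_knot(2, 3, 200)
  before <- alexander_polynomial(loopex:::min_crossing_diagram(
    as_closed_curve(tr), simplify = FALSE, n_directions = 6))
  after <- alexander_polynomial(loopex:::min_crossing_diagram(
    as_closed_curve(tr), simplify = TRUE, n_directions = 6))
  expect_identical(as.integer(before), as.integer(after))
  expect_identical(as.integer(after), c(1L, -1L, 1L))
})

test_that("projection counts crossings correctly on canonical curves", {
  circle <- cbind(cos(seq(0, 2 * pi, length.out = 41)[1:40]),
                  sin(seq(0, 2 * pi, length.out = 41)[1:40]), 0)
  d0 <- project_to_diagram(circle, c(0, 0, 1))
  expect_equal(d0$n_crossings, 0)

  tr <- simplify_curve(raw_torus_knot(2, 3, 150))
  d3 <- loopex:::min_crossing_diagram(tr, n_directions = 8)
  expect_equal(d3$n_crossings, 3)
  expect_equal(abs(sum(sign(d3$gauss$sign))), 6)  # all crossings same sign

  t37 <- loopex:::min_crossing_diagram(torus_knot_coords(3, 7, 200),
                                       n_directions = 10)
  expect_equal(t37$n_crossings, 14)
})

test_that("Alexander polynomial and determinant match the brute-force oracle", {
  cases <- list(
    list(curve = raw_torus_knot(2, 3, 140), coeffs = c(1, -1, 1), det = 3),
    list(curve = figure_eight_curve(), coeffs = c(1, -3, 1), det = 5),
    list(curve = raw_torus_knot(2, 5, 160), coeffs = c(1, -1, 1, -1, 1), det = 5)
  )
  for (cs in cases) {
    dg <- loopex:::min_crossing_diagram(as_closed_curve(cs$curve),
                                        n_directions = 8)
    poly <- alexander_polynomial(dg)
    expect_identical(as.integer(poly), as.integer(cs$coeffs))
    expect_equal(attr(poly, "determinant"), cs$det)
    expect_equal(oracle_determinant(dg), cs$det)
  }
  # 0-crossing diagram
  circ <- project_to_diagram(
    cbind(cos(seq(0, 2 * pi, length.out = 31)[1:30]),
          sin(seq(0, 2 * pi, length.out = 31)[1:30]), 0), c(0, 0, 1))
  p0 <- alexander_polynomial(circ)
  expect_identical(as.integer(p0), 1L)
  expect_equal(attr(p0, "determinant"), 1)
})

test_that("identify_knot names canonical knots and composites", {
  expect_equal(identify_knot(torus_knot_coords(2, 3, 133))$name, "3_1")
  expect_equal(identify_knot(figure_eight_curve())$name, "4_1")
  expect_equal(identify_knot(torus_knot_coords(3, 4, 160))$name, "8_19")

  granny <- connected_sum(raw_torus_knot(2, 3, 120), raw_torus_knot(2, 3, 120))
  kg <- identify_knot(granny)
  expect_equal(kg$name, "3_1#3_1")
  expect_equal(kg$determinant, 9)  # multiplicative: 3 x 3

  ks <- identify_knot(connected_sum(raw_torus_knot(2, 3, 120),
                                    figure_eight_curve()))
  expect_equal(ks$name, "3_1#4_1")
  expect_equal(ks$determinant, 15)

  t37 <- identify_knot(torus_knot_coords(3, 7, 200))
  expect_equal(t37$name, "unclassified")
  expect_equal(t37$crossing_estimate, 14L)
})

test_that("identification is invariant under isometries and reindexing", {
  base <- curve_fix <- raw_torus_knot(2, 5, 150)
  ref <- identify_knot(base)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  variants <- list(
    base %*% rot,
    base * 3.7,
    sweep(base, 2, c(10, -4, 2), "+"),
    base[c(40:150, 1:39), ]  # cyclic shift
  )
  for (v in variants) {
    k <- identify_knot(v)
    expect_equal(k$name, ref$name)
    expect_equal(k$determinant, ref$determinant)
  }
})

test_that("determinants of generated knots match the bundled table", {
  tab <- knot_invariant_table()
  gens <- list(
    `3_1` = raw_torus_knot(2, 3, 140), `5_1` = raw_torus_knot(2, 5, 160),
    `7_1` = raw_torus_knot(2, 7, 180), `9_1` = raw_torus_knot(2, 9, 220),
    `8_19` = raw_torus_knot(3, 4, 170), `4_1` = figure_eight_curve(140)
  )
  for (nm in names(gens)) {
    k <- identify_knot(gens[[nm]])
    expect_equal(k$name, nm)
    expect_equal(k$determinant, tab$determinant[tab$name == nm])
    expect_identical(k$alexander[[1]], tab$coeffs[tab$name == nm][[1]])
  }
})

test_that("simplification preserves the Alexander polynomial on random fixtures", {
  # perturbed, rotated, resampled knots of several types
  set.seed(202)
  shapes <- list(c(2, 3), c(2, 5), c(3, 4), c(2, 7))
  for (rep in 1:25) {
    pq <- shapes[[(rep - 1) %% length(shapes) + 1]]
    n <- sample(120:220, 1)
    m <- raw_torus_knot(pq[1], pq[2], n)
    m <- m + matrix(rnorm(length(m), sd = 0.05), ncol = 3)
    th <- runif(3, 0, 2 * pi)
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3)
    rz <- matrix(c(cos(th[3]), -sin(th[3]), 0,
                   sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    m <- m %*% rx %*% rz
    raw <- alexander_polynomial(loopex:::min_crossing_diagram(
      as_closed_curve(m), simplify = FALSE, n_directions = 4, seed = rep))
    simp <- alexander_polynomial(loopex:::min_crossing_diagram(
      as_closed_curve(m), simplify = TRUE, n_directions = 4, seed = rep))
    expect_identical(as.integer(raw), as.integer(simp))
  }
})

test_that("linking numbers match the Gauss double-sum oracle", {
  th <- seq(0, 2 * pi, length.out = 41)[1:40]
  circA <- cbind(cos(th), sin(th), 0 * th)
  circB <- cbind(1 + cos(th), 0 * th, sin(th))      # Hopf partner
  far <- cbind(10 + cos(th), sin(th), 0 * th)

  expect_equal(linking_number(circA, far), 0)
  lk_hopf <- linking_number(circA, circB)
  expect_equal(abs(lk_hopf), 1)
  expect_equal(lk_hopf, oracle_linking_number(circA, circB))

  # (2,4) torus link: |Lk| = 2
  mk24 <- function(phase) {
    tt <- seq(0, 2 * pi, length.out = 101)[1:100]
    cbind((3 + 1.2 * cos(2 * tt + phase)) * cos(tt),
          (3 + 1.2 * cos(2 * tt + phase)) * sin(tt),
          1.2 * sin(2 * tt + phase))
  }
  lk24 <- linking_number(mk24(0), mk24(pi))
  expect_equal(abs(lk24), 2)
  expect_equal(lk24, oracle_linking_number(mk24(0), mk24(pi)))

  # symmetry and sign flip under orientation reversal
  expect_equal(linking_number(circB, circA), lk_hopf)
  expect_equal(linking_number(circA[rev(seq_len(40)), ], circB), -lk_hopf)
})

test_that("catenation partners count nonzero-linking neighbours", {
  th <- seq(0, 2 * pi, length.out = 41)[1:40]
  mk <- function(cx, plane) {
    if (plane == "xy") cbind(cx + cos(th), sin(th), 0 * th)
    else cbind(cx + cos(th), 0 * th, sin(th))
  }
  # 3-ring Hopf chain: A-B and B-C linked, A-C neither linked nor touching
  chain <- list(mk(0, "xy"), mk(1, "xz"), mk(2.2, "xy"))
  cp <- catenation_partners(chain)
  expect_equal(cp$partners, c(1L, 2L, 1L))
  lk <- attr(cp, "linking")
  expect_true(all(lk == t(lk)))

  far <- lapply(seq(0, 70, by = 10), function(cx) mk(cx, "xy"))
  expect_true(all(catenation_partners(far)$partners == 0))
})

test_that("intersecting curves are rejected for linking", {
  th <- seq(0, 2 * pi, length.out = 41)[1:40]
  circA <- cbind(cos(th), sin(th), 0 * th)
  expect_error(linking_number(circA, circA), class = "loopex_geometry_error")
})
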