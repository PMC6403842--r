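# Voronoi tessellation inside the sphere and interfacial-area metrics.

test_that("a single central bead owns the whole sphere", {
  R <- 3
  tess <- tessellate(matrix(0, 1, 3), 1L, sphere_radius = R)
  expect_equal(tess$total_volume, 4 / 3 * pi * R^3, tolerance = 0.005)
  expect_equal(nrow(tess$cells), 1)
  ia <- interchain_area(tess)
  expect_equal(ia$total_interchain_area, 0)
})

test_that("two symmetric beads split the sphere by a near-full disc", {
  R <- 8; d <- 0.4
  pos <- rbind(c(0, 0, -d), c(0, 0, d))
  tess <- tessellate(pos, c(1L, 2L), sphere_radius = R)
  shared <- tess$facets |>
    dplyr::filter(!is.na(neighbor))
  expect_equal(nrow(shared), 2)  # one facet seen from both sides
  expect_equal(shared$area[1], shared$area[2], tolerance = 1e-9)
  expect_equal(shared$area[1], pi * R^2, tolerance = 0.01)
  ia <- interchain_area(tess)
  expect_equal(ia$total_interchain_area[1], pi * R^2, tolerance = 0.01)
  expect_equal(sum(ia$envelope_area), 2 * ia$total_interchain_area[1])
  expect_equal(tess$total_volume, 4 / 3 * pi * R^3, tolerance = 0.005)
})

test_that("cube-corner beads give congruent cells and oracle-checked areas", {
  R <- 6
  pos <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  colnames(pos) <- NULL
  ring <- rep(c(1L, 2L), 4)  # interleaved labelling
  tess <- tessellate(pos, ring, sphere_radius = R)
  expect_lt(diff(range(tess$cells$volume)) / mean(tess$cells$volume), 0.01)
  expect_equal(tess$total_volume, 4 / 3 * pi * R^3, tolerance = 0.005)

  # brute-force Monte-Carlo area oracle for one adjacent-corner facet
  a_mc <- oracle_facet_area(pos, 1, 2, R)
  f12 <- tess$facets |>
    dplyr::filter(bead == 1, neighbor == 2)
  expect_equal(f12$area, a_mc, tolerance = 0.05)

  # total inter-label area equals the sum over inter-label facets once
  ia <- interchain_area(tess)
  manual <- tess$facets |>
    dplyr::filter(!is.na(neighbor), ring != ring_neighbor, bead < neighbor)
  expect_equal(ia$total_interchain_area[1], sum(manual$area))
  expect_equal(sum(ia$envelope_area), 2 * ia$total_interchain_area[1])
})

test_that("coincident beads and out-of-sphere beads are rejected", {
  expect_error(tessellate(rbind(c(0, 0, 0), c(0, 0, 0)), c(1L, 2L),
                          sphere_radius = 2), "coincident")
  expect_error(tessellate(rbind(c(0, 0, 0), c(0, 0, 5)), c(1L, 2L),
                          sphere_radius = 2), "outside")
})

test_that("volume conservation and envelope identity hold on crowded frames", {
  # a dense random confined configuration resembling an analysis frame
  set.seed(31)
  n <- 500
  R <- sphere_radius_for_fraction(n, 0.3)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (R - 0.6) * runif(n)^(1 / 3)
  ring <- sample(1:4, n, replace = TRUE)
  tess <- tessellate(pts, ring, sphere_radius = R)
  expect_equal(tess$total_volume, 4 / 3 * pi * R^3, tolerance = 0.005)
  ia <- interchain_area(tess)
  expect_equal(sum(ia$envelope_area), 2 * ia$total_interchain_area[1],
               tolerance = 1e-9)
  # facet areas agree from both sides (tiny sliver facets are compared on an
  # absolute scale: their relative error is dominated by clipping round-off)
  f <- tess$facets |> dplyr::filter(!is.na(neighbor))
  key <- paste(pmin(f$bead, f$neighbor), pmax(f$bead, f$neighbor))
  both <- split(f$area, key)
  both <- both[vapply(both, length, 0L) == 2]
  expect_gt(length(both), 100)
  mism <- vapply(both, function(v) abs(v[1] - v[2]), 0)
  size <- vapply(both, max, 0)
  expect_lt(max(mism / pmax(size, 1e-3)), 1e-5)
})

test_that("areas are invariant under rigid rotation about the centre", {
  set.seed(7)
  n <- 120
  R <- 6
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (R - 0.8) * runif(n)^(1 / 3)
  ring <- rep(1:3, length.out = n)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ia1 <- interchain_area(tessellate(pts, ring, sphere_radius = R))
  ia2 <- interchain_area(tessellate(pts %*% rot, ring, sphere_radius = R))
  expect_equal(ia1$total_interchain_area[1], ia2$total_interchain_area[1],
               tolerance = 1e-6)
  expect_equal(ia1$envelope_area, ia2$envelope_area, tolerance = 1e-5)
})

test_that("demixing series: constant for static frames, decreasing on pull-apart", {
  th <- seq(0, 2 * pi, length.out = 61)[1:60]
  R <- 8
  ringA <- cbind(2 * cos(th), 2 * sin(th), 0)
  ringB <- cbind(2 * cos(th), 0.5 + 2 * sin(th) * 0, 2 * sin(th))  # interlocked-ish
  mk_frame <- function(sep, fr) {
    tibble::tibble(
      frame = fr, bead = 1:120, ring = rep(1:2, each = 60),
      x = c(ringA[, 1], ringB[, 1] + sep), y = c(ringA[, 2], ringB[, 2]),
      z = c(ringA[, 3], ringB[, 3])
    )
  }
  static <- dplyr::bind_rows(mk_frame(0.3, 1), mk_frame(0.3, 2))
  s1 <- demixing_series(static, sphere_radius = R)
  tot <- unique(round(s1$total_interchain_area, 9))
  expect_equal(length(tot), 1)

  seps <- seq(0.2, 4.2, length.out = 5)
  pulled <- dplyr::bind_rows(lapply(seq_along(seps),
                                    function(i) mk_frame(seps[i], i)))
  s2 <- demixing_series(pulled, sphere_radius = R)
  totals <- s2 |>
    dplyr::distinct(frame, total_interchain_area) |>
    dplyr::arrange(frame)
  expect_true(all(diff(totals$total_interchain_area) < 0))
})
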