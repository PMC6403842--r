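# Fixtures and independent oracles used across the suite. Everything is
# generated in code; oracles are deliberately simple brute-force
# implementations, independent of the package's computational paths.

# parametric (p,q) torus-knot polygon in its raw (unscaled) shape
raw_torus_knot <- function(p, q, n, R0 = 3, r0 = 1.4) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind((R0 + r0 * cos(q * t)) * cos(p * t),
        (R0 + r0 * cos(q * t)) * sin(p * t),
        r0 * sin(q * t))
}

# parametric figure-eight knot (4_1)
figure_eight_curve <- function(n = 120) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind((2 + cos(2 * t)) * cos(3 * t),
        (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
}

# connected sum of two curves: place them side by side and splice the
# closest pair of vertices (valid for well-separated summands)
connected_sum <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  shift <- max(a[, 1]) - min(b[, 1]) + 4
  b[, 1] <- b[, 1] + shift
  ia <- which.max(a[, 1])
  ib <- which.min(b[, 1])
  rbind(a[c(seq(ia, nrow(a)), seq_len(ia - 1)), ],
        b[c(seq(ib, nrow(b)), seq_len(ib - 1)), ])
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# discrete Gauss double-sum linking number (independent oracle): the solid
# angle of each segment pair via the van Oosterom-Strackee triangle formula
oracle_linking_number <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  solid <- function(p1, p2, p3) {
    n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2)); n3 <- sqrt(sum(p3^2))
    num <- sum(p1 * cross3(p2, p3))
    den <- n1 * n2 * n3 + sum(p1 * p2) * n3 + sum(p1 * p3) * n2 +
      sum(p2 * p3) * n1
    2 * atan2(num, den)
  }
  na <- nrow(a); nb <- nrow(b)
  total <- 0
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      # signed solid angle of the quadrilateral (a_i, a_i2) x (b_j, b_j2)
      r1 <- b[j, ] - a[i, ]; r2 <- b[j, ] - a[i2, ]
      r3 <- b[j2, ] - a[i2, ]; r4 <- b[j2, ] - a[i, ]
      total <- total + solid(r1, r2, r3) + solid(r1, r3, r4)
    }
  }
  round(total / (4 * pi))
}

# numeric-differentiation force oracle for an isolated WCA pair
oracle_wca_force <- function(r, eps = 1, cutoff = 2^(1 / 6), h = 1e-6) {
  u <- function(d) {
    if (d >= cutoff) return(0)
    4 * eps * ((1 / d)^12 - (1 / d)^6) + eps
  }
  -(u(r + h) - u(r - h)) / (2 * h)
}

# independent Alexander-determinant oracle: numeric determinant of the
# Wirtinger presentation matrix at t = -1, built directly from a diagram's
# Gauss code in plain R (shares no code with the C++ polynomial pipeline)
oracle_determinant <- function(diagram) {
  g <- diagram$gauss
  if (nrow(g) == 0) return(1)
  ids <- sort(unique(g$crossing))
  c_n <- length(ids)
  g$crossing <- match(g$crossing, ids)
  arc <- integer(nrow(g))
  cur <- 0L
  for (p in seq_len(nrow(g))) {
    arc[p] <- cur
    if (!g$over[p]) cur <- cur + 1L
  }
  arc <- arc %% c_n
  M <- matrix(0, c_n, c_n)
  t <- -1
  for (id in seq_len(c_n)) {
    po <- which(g$crossing == id & g$over)
    pu <- which(g$crossing == id & !g$over)
    o <- arc[po] + 1L
    i_in <- arc[pu] + 1L
    i_out <- (arc[pu] + 1L) %% c_n + 1L
    if (g$sign[pu] > 0) {
      M[id, o] <- M[id, o] + (1 - t)
      M[id, i_in] <- M[id, i_in] + t
      M[id, i_out] <- M[id, i_out] - 1
    } else {
      M[id, o] <- M[id, o] + (t - 1)
      M[id, i_in] <- M[id, i_in] + 1
      M[id, i_out] <- M[id, i_out] - t
    }
  }
  abs(round(det(M[-c_n, -c_n, drop = FALSE])))
}

# Monte-Carlo facet-area oracle: area of the Voronoi facet between beads i
# and j (inside the sphere), by rejection sampling on their bisector plane
oracle_facet_area <- function(pos, i, j, R, n_samples = 40000, seed = 99) {
  set.seed(seed)
  pi_ <- pos[i, ]; pj <- pos[j, ]
  mid <- (pi_ + pj) / 2
  nrm <- (pj - pi_) / sqrt(sum((pj - pi_)^2))
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(nrm, a); u <- u / sqrt(sum(u^2))
  v <- cross3(nrm, u)
  rad <- 2 * R
  pts_u <- runif(n_samples, -rad, rad)
  pts_v <- runif(n_samples, -rad, rad)
  hit <- 0L
  for (k in seq_len(n_samples)) {
    q <- mid + pts_u[k] * u + pts_v[k] * v
    if (sum(q^2) > R^2) next
    d2 <- rowSums((pos - matrix(q, nrow(pos), 3, byrow = TRUE))^2)
    if (which.min(d2) %in% c(i, j) &&
        abs(d2[i] - d2[j]) < 1e-9 + 2 * max(d2) * 1e-12) hit <- hit + 1L
    # on the bisector, d2[i] == d2[j]; nearest overall must be the pair
  }
  (2 * rad)^2 * hit / n_samples
}

# small helper: a two-bead system (two 'rings' of one bead each) for pair
# force checks; bypasses ring-cycle validation deliberately
two_bead_system <- function(r, phantom1 = FALSE) {
  df <- tibble::tibble(bead = 1:2, ring = 1:2, x = c(0, r), y = 0, z = 0,
                       phantom = c(phantom1, FALSE), ctcf = FALSE,
                       cohesin = FALSE)
  loopex:::new_chain_system(df, bonds = matrix(integer(), 0, 2))
}
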