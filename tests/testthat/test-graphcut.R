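test_that("the data term is -log(p + eps) clamped at zero", {
  p <- array(0, c(2, 2, 3))
  p[1, 1, 1] <- 1
  p[2, 2, 2] <- 1 / 3
  u <- build_data_term(p)
  expect_equal(u[1, 1, 1], 0)                      # certain pixel costs nothing
  expect_equal(u[1, 1, 2], -log(.Machine$double.eps))  # ~36.04
  expect_equal(u[1, 1, 2], 36.0437, tolerance = 1e-4)
  expect_equal(u[2, 2, 2], -log(1 / 3 + .Machine$double.eps))
  expect_true(all(u >= 0))
  expect_error(build_data_term(p - 1), "probabilities")
})

test_that("the smoothness matrix is constant Potts with zero diagonal", {
  expect_equal(build_smooth_term(3, 4),
               rbind(c(0, 4, 4), c(4, 0, 4), c(4, 4, 0)))
  expect_equal(build_smooth_term(3, 3)[1, 2], 3)   # baseline setting
  expect_equal(build_smooth_term(2, 1), rbind(c(0, 1), c(1, 0)))
  expect_error(build_smooth_term(3, 0), "> 0")
  expect_error(build_smooth_term(1, 4), ">= 2")
})

test_that("total_energy equals a direct double-loop summation", {
  set.seed(51)
  u <- array(runif(5 * 5 * 3), c(5, 5, 3))
  P <- build_smooth_term(3, 2)
  lab <- matrix(sample(1:3, 25, replace = TRUE), 5, 5)

  direct <- 0
  for (i in 1:5) for (j in 1:5) direct <- direct + u[i, j, lab[i, j]]
  for (i in 1:4) for (j in 1:5) direct <- direct + P[lab[i, j], lab[i + 1, j]]
  for (i in 1:5) for (j in 1:4) direct <- direct + P[lab[i, j], lab[i, j + 1]]
  expect_equal(total_energy(lab, u, P), direct)

  # uniform labeling has zero smoothness cost
  lab1 <- matrix(2L, 5, 5)
  expect_equal(total_energy(lab1, u, P), sum(u[, , 2]))

  # 2x1 grid, differing labels, zero unary: energy is exactly r
  u2 <- array(0, c(2, 1, 3))
  expect_equal(total_energy(matrix(c(1L, 2L), 2, 1), u2, build_smooth_term(3, 4)), 4)
})

test_that("vanishing smoothness reduces the cut to the unary argmin", {
  set.seed(52)
  u <- array(runif(6 * 7 * 3), c(6, 7, 3))
  lab <- segment_labels(u, build_smooth_term(3, 1e-9))
  am <- apply(u, c(1, 2), which.min)
  expect_true(all(lab == am))
})

test_that("a noiseless 3-band probability map is segmented exactly", {
  p <- array(0, c(12, 9, 3))
  p[1:4, , 1] <- 1; p[5:8, , 2] <- 1; p[9:12, , 3] <- 1
  u <- build_data_term(p)
  lab <- segment_labels(u, build_smooth_term(3, 4))
  expect_equal(as.vector(lab[, 1]), rep(1:3, each = 4))
  expect_true(all(lab == lab[, 1]))
  # analytic minimum: zero data cost + two band boundaries of Potts cost
  expect_equal(attr(lab, "energy"), 2 * 9 * 4)
})

test_that("binary cuts attain the exhaustive optimum", {
  set.seed(53)
  P2 <- build_smooth_term(2, 1.5)
  for (i in 1:50) {
    u <- array(runif(4 * 4 * 2, 0, 3), c(4, 4, 2))
    lab <- segment_labels(u, P2)
    expect_equal(attr(lab, "energy"), mrf_exact_min(u, P2), tolerance = 1e-9)
    expect_equal(total_energy(lab, u, P2), attr(lab, "energy"))
  }
})

test_that("alpha-expansion is near-exact on small 3-label instances", {
  set.seed(54)
  P3 <- build_smooth_term(3, 1)
  exact_hits <- 0L
  for (i in 1:30) {
    u <- array(runif(4 * 4 * 3, 0, 3), c(4, 4, 3))
    lab <- segment_labels(u, P3)
    opt <- mrf_exact_min(u, P3)
    expect_lte(attr(lab, "energy"), opt * 1.05 + 1e-9)
    if (abs(attr(lab, "energy") - opt) < 1e-9) exact_hits <- exact_hits + 1L
  }
  expect_gte(exact_hits, 27L)
})

test_that("expansion never increases the energy of a supplied initialization", {
  set.seed(55)
  for (i in 1:5) {
    u <- array(runif(8 * 8 * 3, 0, 4), c(8, 8, 3))
    P <- build_smooth_term(3, runif(1, 0.5, 3))
    init <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    lab <- segment_labels(u, P, init = init)
    expect_lte(attr(lab, "energy"), total_energy(init, u, P) + 1e-9)
  }
})

test_that("stronger Potts coupling never fragments the labeling more", {
  set.seed(56)
  for (i in 1:4) {
    u <- array(runif(10 * 12 * 3, 0, 2), c(10, 12, 3))
    disc <- vapply(c(0.2, 0.5, 1, 2, 4), function(r)
      discontinuity_count(segment_labels(u, build_smooth_term(3, r))),
      numeric(1))
    expect_true(all(diff(disc) <= 0))
  }
})

test_that("scaling the Potts constant scales only the smoothness part", {
  set.seed(57)
  u <- array(runif(6 * 6 * 3), c(6, 6, 3))
  lab <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
  P <- build_smooth_term(3, 2)
  e_data <- total_energy(lab, u, matrix(0, 3, 3))
  e1 <- total_energy(lab, u, P)
  e3 <- total_energy(lab, u, 3 * P)
  expect_equal(e3 - e_data, 3 * (e1 - e_data))
})

test_that("extract_csi reads the deepest choroid row, interpolates and smooths", {
  lab <- matrix(3L, 20, 11)
  lab[1:5, ] <- 1L
  lab[6:12, ] <- 2L
  expect_equal(extract_csi(lab), rep(12L, 11))

  # a column with no choroid pixels is interpolated from its neighbors
  lab2 <- lab
  lab2[, 6][lab2[, 6] == 2L] <- 3L
  expect_equal(extract_csi(lab2), rep(12L, 11))

  expect_error(extract_csi(matrix(1L, 5, 5)), "no choroid")
})

test_that("the compiled min-cut agrees with igraph max-flow", {
  set.seed(58)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    ne <- sample(3:14, 1)
    ef <- sample(n, ne, TRUE); et <- sample(n, ne, TRUE)
    keep <- ef != et; ef <- ef[keep]; et <- et[keep]
    ec <- runif(length(ef), 0, 5)
    cs <- runif(n, 0, 3); ct <- runif(n, 0, 3)
    mine <- choroidseg:::st_mincut_cpp(as.integer(n), as.integer(ef),
                                       as.integer(et), ec, cs, ct)
    g <- igraph::make_graph(rbind(c(rep(n + 1, n), 1:n, ef, et),
                                  c(1:n, rep(n + 2, n), et, ef)),
                            n = n + 2, directed = TRUE)
    ref <- igraph::max_flow(g, n + 1, n + 2,
                            capacity = c(cs, ct, ec, ec))
    expect_equal(mine$value, ref$value, tolerance = 1e-9)
  }
})
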