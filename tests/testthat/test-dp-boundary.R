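test_that("trace_optimal_path matches exhaustive enumeration on small cost images", {
  # hand-derived 2x2 case: admissible paths (1,1)=5, (1,2)=3, (2,1)=7, (2,2)=5
  res <- trace_optimal_path(cbind(c(1, 3), c(4, 2)))
  expect_equal(res$path, c(1L, 2L))
  expect_equal(res$total_cost, 3)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    m <- sample(2:8, 1)
    cost <- matrix(sample(0:9, n * m, replace = TRUE), n, m)
    res <- trace_optimal_path(cost)
    expect_equal(res$total_cost, dp_enumerate_min(cost))
    # the reported path realizes the reported cost and obeys the step bound
    expect_equal(sum(cost[cbind(res$path, seq_len(m))]), res$total_cost)
    expect_lte(max(abs(diff(res$path))), 1L)
  }
})

test_that("step_bound > 1 paths are optimal for the wider neighborhood", {
  set.seed(12)
  for (i in 1:5) {
    cost <- matrix(sample(0:9, 6 * 5, replace = TRUE), 6, 5)
    res <- trace_optimal_path(cost, step_bound = 2L)
    expect_equal(res$total_cost, dp_enumerate_min(cost, step = 2L))
    expect_lte(max(abs(diff(res$path))), 2L)
  }
})

test_that("ties break canonically and constant images give the flat top path", {
  res <- trace_optimal_path(matrix(7, 5, 6))
  expect_equal(res$path, rep(1L, 6))
  expect_equal(res$total_cost, 7 * 6)
})

test_that("adding a constant to all node costs shifts the cost, not the path", {
  set.seed(13)
  cost <- matrix(runif(8 * 10), 8, 10)
  base <- trace_optimal_path(cost)
  shifted <- trace_optimal_path(cost + 2.5)
  expect_equal(shifted$path, base$path)
  expect_equal(shifted$total_cost, base$total_cost + 2.5 * 10)
})

test_that("cost table initialization and backtracking are consistent", {
  set.seed(14)
  cost <- matrix(runif(6 * 7), 6, 7)
  res <- trace_optimal_path(cost)
  expect_equal(res$cost_table[, 1], cost[, 1])
  expect_equal(res$total_cost, min(res$cost_table[, ncol(cost)]))
  # path is reconstructible from the stored predecessors
  p <- res$path
  for (col in ncol(cost):2)
    expect_equal(res$predecessors[p[col], col], p[col - 1L])
})

test_that("invalid cost images are rejected", {
  expect_error(trace_optimal_path(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(trace_optimal_path(matrix(c(1, Inf, 2, 3), 2)), "non-finite")
  expect_error(trace_optimal_path("x"), "matrix")
})

test_that("detect_rpe is the DP trace of the inverted image and finds bright bands", {
  set.seed(15)
  img <- matrix(runif(20 * 15, 0, 50), 20, 15)
  expect_equal(detect_rpe(img),
               trace_optimal_path(max(img) - img)$path)

  # unique bright row
  img2 <- matrix(0, 12, 9)
  img2[7, ] <- 100
  expect_equal(detect_rpe(img2), rep(7L, 9))

  # column-constant image: every path ties, canonical flat path returned
  img3 <- matrix(rep(seq_len(10), each = 8), 8, 10)
  expect_equal(detect_rpe(img3), rep(1L, 10))
})

test_that("detect_rpe tracks the phantom RPE within 2 px", {
  ph <- generate_phantom(small_spec(seed = 21))
  rpe <- detect_rpe(ph$image)
  expect_lte(mean(abs(rpe - ph$rpe_true)), 2)
})

test_that("detect_bm finds the strongest sub-RPE gradient", {
  # unique gradient maximum: a one-row ramp d rows below the given curve
  # (flat elsewhere, so no competing band edge inside the search window)
  n <- 30; nc <- 12; rpe_row <- 8; d <- 5
  img <- matrix(10, n, nc)
  img[rpe_row + d, ] <- 45
  img[(rpe_row + d + 1):n, ] <- 80
  bm <- detect_bm(img, rep(rpe_row, nc))
  expect_equal(bm, rep(rpe_row + d, nc))

  # single candidate row
  set.seed(16)
  img4 <- matrix(runif(20 * 11, 1, 9), 20, 11)
  rpe <- rep(10L, 11)
  expect_equal(detect_bm(img4, rpe, search_depth = 1L), rpe + 1L)

  # window clipped at the bottom -> nearest valid row with a warning
  expect_warning(bm2 <- detect_bm(img4, rep(20L, 11)), "outside")
  expect_true(all(bm2 == 20L))
})

test_that("detect_bm tracks the phantom BM within 3 px", {
  ph <- generate_phantom(small_spec(seed = 22))
  rpe <- detect_rpe(ph$image)
  bm <- detect_bm(ph$image, rpe)
  expect_lte(mean(abs(bm - ph$bm_true)), 3)
  expect_true(all(bm >= rpe))
})

test_that("zero_above suppresses exactly the pixels above the boundary", {
  set.seed(17)
  img <- matrix(runif(10 * 8, 1, 5), 10, 8)
  expect_equal(zero_above(img, rep(1L, 8)), img)

  z <- zero_above(img, rep(10L, 8))
  expect_true(all(z[1:9, ] == 0))
  expect_equal(z[10, ], img[10, ])

  b <- sample(2:9, 8, replace = TRUE)
  z2 <- zero_above(img, b)
  removed <- sum(vapply(seq_len(8), function(c) sum(img[seq_len(b[c] - 1L), c]),
                        numeric(1)))
  expect_equal(sum(z2), sum(img) - removed)
  # input untouched
  expect_gt(min(img), 0)
})
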