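test_that("gaussian_density matches closed forms and a naive oracle", {
  mu <- rep(0, 5)
  expect_equal(gaussian_density(mu, mu, diag(5)), (2 * pi)^(-5 / 2))
  # Mahalanobis distance 2 with identity covariance
  x <- mu + c(2, 0, 0, 0, 0)
  expect_equal(gaussian_density(x, mu, diag(5)),
               (2 * pi)^(-5 / 2) * exp(-2))

  set.seed(41)
  for (i in 1:10) {
    mu <- rnorm(5)
    S <- random_spd(5)
    x <- rnorm(5, sd = 3)
    expect_equal(gaussian_density(x, mu, S), naive_mvn_density(x, mu, S),
                 tolerance = 1e-12)
  }

  bad <- diag(5); bad[1, 1] <- -1
  expect_error(gaussian_density(rep(0, 5), rep(0, 5), bad), "positive-definite")
})

test_that("supervised moment fit recovers known mixture parameters", {
  set.seed(42)
  truth <- toy_mixture()
  n_per <- c(3000, 4000, 3000)
  nr <- 100L; nc <- 100L
  X <- do.call(rbind, lapply(1:3, function(k) draw_component(n_per[k], truth, k)))
  lab <- rep(1:3, n_per)
  ord <- sample(length(lab))
  feats <- array(X[ord, ], dim = c(nr, nc, 5))
  mask <- matrix(lab[ord], nr, nc)

  fit <- fit_from_masks(feats, mask)
  expect_equal(fit$weights, n_per / sum(n_per))
  for (k in 1:3) {
    se <- sqrt(diag(truth$covariances[[k]]) / n_per[k])
    expect_true(all(abs(fit$means[k, ] - truth$means[k, ]) < 3 * se))
    expect_lt(max(abs(fit$covariances[[k]] - truth$covariances[[k]])), 0.5)
  }
})

test_that("fitting errors on degenerate or incomplete training labels", {
  set.seed(43)
  feats <- array(rnorm(20 * 20 * 5), dim = c(20, 20, 5))
  mask_missing <- matrix(1L, 20, 20); mask_missing[1:10, ] <- 2L  # no class 3
  expect_error(fit_from_masks(feats, mask_missing), "class 3")

  mask_few <- matrix(1L, 20, 20); mask_few[1, 1:3] <- 2L; mask_few[2, 1:7] <- 3L
  expect_error(fit_from_masks(feats, mask_few), "at least")

  # all descriptors of one class identical -> zero-rank sample covariance
  feats2 <- feats
  feats2[1:10, , ] <- 0
  mask2 <- matrix(3L, 20, 20)
  mask2[1:10, ] <- 1L
  mask2[11:15, ] <- 2L
  expect_error(fit_from_masks(feats2, mask2), "zero-rank")
})

test_that("pooling two training images equals fitting their concatenation", {
  set.seed(44)
  truth <- toy_mixture()
  mk <- function(seed) {
    set.seed(seed)
    X <- do.call(rbind, lapply(1:3, function(k) draw_component(200, truth, k)))
    list(f = array(X, dim = c(30, 20, 5)), m = matrix(rep(1:3, each = 200), 30, 20))
  }
  a <- mk(1); b <- mk(2)
  pooled <- fit_from_masks(list(a$f, b$f), list(a$m, b$m))
  XX <- rbind(matrix(a$f, 600, 5), matrix(b$f, 600, 5))
  onebig <- fit_from_masks(array(XX, dim = c(60, 20, 5)),
                           matrix(c(a$m, b$m), 60, 20))
  expect_equal(pooled$means, onebig$means, tolerance = 1e-12)
  expect_equal(pooled$weights, onebig$weights)
  for (k in 1:3)
    expect_equal(pooled$covariances[[k]], onebig$covariances[[k]], tolerance = 1e-12)
})

test_that("responsibilities match the naive posterior formula and normalize", {
  set.seed(45)
  model <- toy_mixture()
  X <- matrix(rnorm(200 * 5, sd = 6), 200, 5)
  P <- responsibilities(model, X)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-9)

  naive <- t(apply(X, 1, function(x) {
    num <- vapply(1:3, function(k)
      model$weights[k] * naive_mvn_density(x, model$means[k, ],
                                           model$covariances[[k]]),
      numeric(1))
    num / sum(num)
  }))
  expect_equal(P, naive, tolerance = 1e-9)
})

test_that("responsibilities handle symmetry and dominance limits", {
  S <- diag(5)
  equal <- texture_gmm(rep(1 / 3, 3), rbind(rep(1, 5), rep(1, 5), rep(1, 5)),
                       list(S, S, S))
  P <- responsibilities(equal, matrix(rnorm(50 * 5), 50, 5))
  expect_equal(P, matrix(1 / 3, 50, 3))

  model <- toy_mixture()
  P2 <- responsibilities(model, matrix(model$means[2, ], 1))
  expect_gt(P2[1, 2], 0.99)

  # array input keeps the image grid
  f <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5))
  Pa <- responsibilities(model, f)
  expect_equal(dim(Pa), c(6L, 4L, 3L))
  expect_equal(apply(Pa, c(1, 2), sum), matrix(1, 6, 4), tolerance = 1e-9)
})

test_that("EM increases the likelihood monotonically and repairs a perturbed model", {
  set.seed(46)
  truth <- toy_mixture()
  X <- do.call(rbind, lapply(1:3, function(k) draw_component(400, truth, k)))

  perturbed <- texture_gmm(c(0.5, 0.3, 0.2),
                           truth$means + 1.5,
                           lapply(truth$covariances, function(S) S * 2))
  ll0 <- choroidseg:::mixture_loglik(perturbed, X)
  refined <- em_refine(X, perturbed, max_iter = 50L)
  trace <- attr(refined, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-9))
  expect_gte(attr(refined, "loglik"), ll0)
  # near the truth it should come close to the generating parameters
  expect_lt(max(abs(sort(refined$weights) - sort(truth$weights))), 0.1)
})

test_that("EM is near a fixed point when data are drawn from the initial model", {
  set.seed(47)
  truth <- toy_mixture()
  n <- c(6000, 8000, 6000)
  X <- do.call(rbind, lapply(1:3, function(k) draw_component(n[k], truth, k)))
  one <- em_refine(X, truth, max_iter = 1L)
  expect_lt(max(abs(one$means - truth$means)), 0.1)
  expect_lt(max(abs(one$weights - truth$weights)), 0.02)
})

test_that("EM agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(48)
  truth <- toy_mixture()
  X <- do.call(rbind, lapply(1:3, function(k) draw_component(500, truth, k)))
  init <- texture_gmm(c(0.4, 0.3, 0.3), truth$means + 0.8,
                      lapply(truth$covariances, function(S) S * 1.5))

  params <- list(pro = init$weights,
                 mean = t(init$means),
                 variance = list(modelName = "VVV", d = 5L, G = 3L,
                                 sigma = array(unlist(init$covariances),
                                               dim = c(5, 5, 3)),
                                 cholsigma = array(unlist(lapply(init$covariances, chol)),
                                                   dim = c(5, 5, 3))))
  es <- mclust::estepVVV(data = X, parameters = params)
  mine <- responsibilities(init, X)
  expect_equal(mine, unname(es$z), tolerance = 1e-8)
  expect_equal(choroidseg:::mixture_loglik(init, X), es$loglik, tolerance = 1e-8)

  ref <- mclust::emVVV(data = X, parameters = params,
                       control = mclust::emControl(tol = 1e-8, itmax = 200))
  fit <- em_refine(X, init, max_iter = 200L, tol = 1e-10)
  expect_equal(attr(fit, "loglik"), ref$loglik,
               tolerance = 1e-4 * abs(ref$loglik))
})

test_that("mixture container validates its invariants", {
  expect_error(texture_gmm(c(0.5, 0.5), rbind(1:5), list(diag(5))), "one row")
  S <- diag(5); S[1, 2] <- 0.5  # asymmetric
  expect_error(texture_gmm(1, rbind(rep(0, 5)), list(S)), "symmetric")
  expect_error(texture_gmm(1, rbind(rep(0, 5)), list(-diag(5))),
               "positive-definite")
  m <- toy_mixture()
  expect_equal(sum(m$weights), 1)
  expect_equal(m$n_dims, 5L)
  expect_equal(m$K, 3L)
})
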