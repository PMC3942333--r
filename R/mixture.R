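#' Construct a Gaussian mixture over texture descriptors
#'
#' Container for a `K`-component multivariate Gaussian mixture: weights
#' `pi_k` (summing to 1), mean vectors `mu_k` and symmetric
#' positive-definite covariances `Gamma_k`. For choroid segmentation the
#' three components represent, in order, the area above Bruch's membrane,
#' the choroid, and the area beneath the choroid-sclera interface.
#'
#' @param weights Numeric vector of positive component weights (normalized
#'   if they do not already sum to 1).
#' @param means Matrix with one row per component, one column per
#'   descriptor dimension.
#' @param covariances List of per-component covariance matrices.
#' @return An object of class `"texture_gmm"`.
#' @export
texture_gmm <- function(weights, means, covariances) {
  K <- length(weights)
  if (!is.matrix(means) || nrow(means) != K)
    stop("`means` must be a matrix with one row per component")
  if (!is.list(covariances) || length(covariances) != K)
    stop("`covariances` must be a list with one matrix per component")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("component weights must be positive and finite")
  d <- ncol(means)
  for (k in seq_len(K)) {
    S <- covariances[[k]]
    if (!is.matrix(S) || any(dim(S) != d))
      stop(sprintf("covariance of component %d must be %d x %d", k, d, d))
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop(sprintf("covariance of component %d is not symmetric", k))
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("covariance of component %d is not positive-definite", k))
    covariances[[k]] <- (S + t(S)) / 2
  }
  structure(list(weights = weights / sum(weights),
                 means = means,
                 covariances = covariances,
                 K = K, n_dims = d),
            class = "texture_gmm")
}

#' @export
print.texture_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d components over %d-d descriptors\n",
              x$K, x$n_dims))
  cat("weights:", format(x$weights, digits = 4), "\n")
  invisible(x)
}

#' Multivariate Gaussian density of a descriptor
#'
#' Evaluates `N(x; mu, Gamma)` through the Cholesky factor of the
#' covariance, never through an explicit matrix inverse.
#'
#' @param x Numeric vector (one descriptor) or matrix with one descriptor
#'   per row.
#' @param mean Component mean vector.
#' @param covariance Symmetric positive-definite covariance matrix.
#' @param log If `TRUE` return the log density.
#' @return Numeric vector of (log) densities.
#' @examples
#' gaussian_density(rep(0, 5), rep(0, 5), diag(5))  # (2*pi)^(-5/2)
#' @export
gaussian_density <- function(x, mean, covariance, log = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- length(mean)
  if (ncol(x) != d) stop("descriptor dimensionality does not match the mean")
  R <- tryCatch(chol(covariance), error = function(e)
    stop("covariance is not positive-definite", call. = FALSE))
  ctr <- sweep(x, 2L, mean)
  w <- backsolve(R, t(ctr), transpose = TRUE)
  maha <- colSums(w^2)
  logdet <- 2 * sum(log(diag(R)))
  ld <- -0.5 * (d * log(2 * pi) + logdet + maha)
  if (log) ld else exp(ld)
}

# Log density matrix (N x K) for all components of a mixture.
log_density_matrix <- function(model, X) {
  N <- nrow(X)
  L <- matrix(0, N, model$K)
  for (k in seq_len(model$K))
    L[, k] <- gaussian_density(X, model$means[k, ], model$covariances[[k]],
                               log = TRUE)
  L
}

#' Fit the mixture from labeled training masks
#'
#' The supervised training path: instead of running EM per image, the
#' component parameters are moment estimates computed from manually labeled
#' masks. Descriptors of all training images are pooled; for each class
#' `k` the mean is the sample mean, the covariance is the sample covariance
#' with denominator `N_k` plus a trace-scaled ridge, and the weight is the
#' class pixel fraction among labeled pixels.
#'
#' @param features A descriptor array from [extract_descriptors()], or a
#'   list of them (one per training image).
#' @param masks An integer label matrix per image with values in `0:3`
#'   (0 = unlabeled, 1 = above BM, 2 = choroid, 3 = below CSI), matching
#'   the image grids.
#' @param ridge Relative ridge added to each covariance:
#'   `ridge * (tr(Gamma)/n_dims) * I` (default 1e-6). Guards against
#'   near-singular covariances on small training sets.
#' @param n_classes Number of classes/components (default 3).
#' @return A `"texture_gmm"` with components ordered by label id.
#' @export
fit_from_masks <- function(features, masks, ridge = 1e-6, n_classes = 3L) {
  if (is.array(features) && length(dim(features)) == 3L) features <- list(features)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(features) != length(masks) || length(features) < 1L)
    stop("`features` and `masks` must be non-empty lists of equal length")

  d <- dim(features[[1L]])[3L]
  Xs <- vector("list", length(features))
  ls <- vector("list", length(features))
  for (i in seq_along(features)) {
    fdim <- dim(features[[i]])
    if (any(dim(masks[[i]]) != fdim[1:2]))
      stop(sprintf("mask %d does not match its feature grid", i))
    lab <- as.integer(masks[[i]])
    keep <- lab >= 1L & lab <= n_classes
    Xs[[i]] <- feature_matrix(features[[i]])[keep, , drop = FALSE]
    ls[[i]] <- lab[keep]
  }
  X <- do.call(rbind, Xs)
  lab <- unlist(ls)
  N <- length(lab)

  weights <- numeric(n_classes)
  means <- matrix(0, n_classes, d)
  covs <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    idx <- which(lab == k)
    Nk <- length(idx)
    if (Nk < d + 1L)
      stop(sprintf("class %d has %d labeled pixels; at least %d are required",
                   k, Nk, d + 1L))
    Xk <- X[idx, , drop = FALSE]
    mu <- colMeans(Xk)
    ctr <- sweep(Xk, 2L, mu)
    S <- crossprod(ctr) / Nk
    if (max(abs(S)) == 0)
      stop(sprintf("class %d has zero-rank sample covariance (all descriptors identical)", k))
    S <- S + ridge * (sum(diag(S)) / d) * diag(d)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("class %d covariance is rank-deficient even after ridge regularization", k))
    weights[k] <- Nk / N
    means[k, ] <- mu
    covs[[k]] <- S
  }
  texture_gmm(weights, means, covs)
}

#' Per-pixel posterior class probabilities (responsibilities)
#'
#' The posterior probability that pixel `j` belongs to component `k`:
#' `p_jk = pi_k p(x_j | k) / sum_i pi_i p(x_j | i)`, evaluated in log space
#' so well-separated 5-d descriptors do not underflow. Pixels where every
#' component log density is `-Inf` receive a uniform posterior and are
#' counted in a message.
#'
#' @param model A `"texture_gmm"`.
#' @param features Descriptor array (`n_rows x n_cols x n_dims`) or an
#'   `N x n_dims` matrix.
#' @return An array `n_rows x n_cols x K` (or `N x K` matrix for matrix
#'   input); each pixel's K values sum to 1.
#' @export
responsibilities <- function(model, features) {
  stopifnot(inherits(model, "texture_gmm"))
  as_array <- is.array(features) && length(dim(features)) == 3L
  X <- if (as_array) feature_matrix(features) else as.matrix(features)
  if (ncol(X) != model$n_dims)
    stop("descriptor dimensionality does not match the model")

  LP <- sweep(log_density_matrix(model, X), 2L, log(model$weights), "+")
  mx <- do.call(pmax, as.data.frame(LP))
  bad <- !is.finite(mx)
  P <- exp(LP - mx)
  P <- P / rowSums(P)
  if (any(bad)) {
    P[bad, ] <- 1 / model$K
    message(sprintf("%d pixel(s) underflowed in every component; uniform posterior assigned",
                    sum(bad)))
  }
  if (as_array) {
    array(P, dim = c(dim(features)[1:2], model$K))
  } else {
    P
  }
}

# Total data log-likelihood of descriptors under a mixture.
mixture_loglik <- function(model, X) {
  LP <- sweep(log_density_matrix(model, X), 2L, log(model$weights), "+")
  mx <- do.call(pmax, as.data.frame(LP))
  sum(mx + log(rowSums(exp(LP - mx))))
}

#' Refine a mixture by expectation-maximization
#'
#' Standard EM updates: responsibilities in the E-step, then
#' `pi_k = mean_j p_jk`, responsibility-weighted means and covariances in
#' the M-step. Iterates until the relative log-likelihood change falls
#' below `tol` or `max_iter` is reached; the log-likelihood is asserted to
#' be non-decreasing. The supervised fit ([fit_from_masks()]) is the
#' primary training path; EM refinement is an optional alternative.
#'
#' @param features Descriptor array or `N x n_dims` matrix.
#' @param model Initial `"texture_gmm"`.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood change for convergence
#'   (default 1e-6).
#' @return A refined `"texture_gmm"` with attributes `loglik` (final data
#'   log-likelihood), `loglik_trace` and `iterations`.
#' @export
em_refine <- function(features, model, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(model, "texture_gmm"))
  X <- if (is.array(features) && length(dim(features)) == 3L)
    feature_matrix(features) else as.matrix(features)
  if (ncol(X) != model$n_dims)
    stop("descriptor dimensionality does not match the model")
  N <- nrow(X)
  d <- model$n_dims

  ll_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    LP <- sweep(log_density_matrix(model, X), 2L, log(model$weights), "+")
    mx <- do.call(pmax, as.data.frame(LP))
    P <- exp(LP - mx)
    rs <- rowSums(P)
    ll <- sum(mx + log(rs))
    if (ll < ll_prev - 1e-9)
      stop(sprintf("EM log-likelihood decreased at iteration %d", it))
    P <- P / rs
    trace <- c(trace, ll)

    converged <- is.finite(ll_prev) &&
      abs(ll - ll_prev) <= tol * (abs(ll_prev) + .Machine$double.eps)
    if (converged) break
    ll_prev <- ll

    Nk <- colSums(P)
    if (any(Nk / N < 1e-8))
      stop(sprintf("mixture component collapsed at iteration %d", it))
    weights <- Nk / N
    means <- model$means
    covs <- model$covariances
    for (k in seq_len(model$K)) {
      mu <- colSums(P[, k] * X) / Nk[k]
      ctr <- sweep(X, 2L, mu)
      S <- crossprod(ctr * sqrt(P[, k])) / Nk[k]
      S <- (S + t(S)) / 2
      ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
      if (!ok)
        stop(sprintf("covariance of component %d lost positive-definiteness at iteration %d",
                     k, it))
      means[k, ] <- mu
      covs[[k]] <- S
    }
    model <- texture_gmm(weights, means, covs)
  }
  attr(model, "loglik") <- trace[length(trace)]
  attr(model, "loglik_trace") <- trace
  attr(model, "iterations") <- length(trace)
  model
}
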