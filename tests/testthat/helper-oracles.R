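# Independent oracles and small fixtures shared across the test files.

# Exhaustive enumeration of every admissible DP path (|row step| <= bound),
# vectorized over the set of partial paths. Returns the minimum total cost.
dp_enumerate_min <- function(cost, step = 1L) {
  n <- nrow(cost)
  m <- ncol(cost)
  rows <- seq_len(n)
  acc <- cost[, 1L]
  if (m > 1L) {
    offs <- -step:step
    for (col in 2:m) {
      rows2 <- rep(rows, times = length(offs)) + rep(offs, each = length(rows))
      acc2 <- rep(acc, times = length(offs))
      ok <- rows2 >= 1L & rows2 <= n
      rows <- rows2[ok]
      acc <- acc2[ok] + cost[cbind(rows, col)]
    }
  }
  min(acc)
}

# Exact global minimum of the grid Potts energy by transfer-matrix dynamic
# programming over columns (states = all label assignments of one column).
# Feasible for nrow(unary) <= 4-ish. Independent of the alpha-expansion path.
mrf_exact_min <- function(unary, pairwise) {
  du <- dim(unary)
  nr <- du[1L]; ncl <- du[2L]; K <- du[3L]
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), nr)))
  S <- nrow(states)
  intra <- matrix(0, S, ncl)
  for (col in seq_len(ncl)) {
    u <- matrix(unary[, col, ], nr, K)
    e <- rowSums(matrix(u[cbind(rep(seq_len(nr), each = S), as.vector(states))],
                        S, nr))
    if (nr > 1L) {
      for (r in seq_len(nr - 1L))
        e <- e + pairwise[cbind(states[, r], states[, r + 1L])]
    }
    intra[, col] <- e
  }
  trans <- matrix(0, S, S)
  for (r in seq_len(nr))
    trans <- trans + outer(states[, r], states[, r], function(a, b) pairwise[cbind(a, b)])
  f <- intra[, 1L]
  if (ncl > 1L) {
    for (col in 2:ncl) f <- apply(f + trans, 2L, min) + intra[, col]
  }
  min(f)
}

# Naive closed-form multivariate normal density (explicit det and inverse).
naive_mvn_density <- function(x, mu, sigma) {
  d <- length(mu)
  q <- as.numeric(t(x - mu) %*% solve(sigma) %*% (x - mu))
  exp(-q / 2) / ((2 * pi)^(d / 2) * sqrt(det(sigma)))
}

# Random symmetric positive-definite matrix.
random_spd <- function(d) {
  a <- matrix(stats::rnorm(d * d), d)
  crossprod(a) + d * diag(d)
}

# Small fast phantom for unit tests (default-spec phantoms are reserved for
# the end-to-end acceptance study). Overrides in ... replace the defaults.
small_spec <- function(seed = 1L, ...) {
  defaults <- list(n_rows = 120L, n_cols = 96L, rpe_depth = 30,
                   rpe_amplitude = 4, choroid_thickness = 35,
                   choroid_variation = 6, n_vessels = 12L,
                   boundary_smooth = 21L, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Very small phantom for dataset/IO tests.
tiny_spec <- function() {
  phantom_spec(n_rows = 48L, n_cols = 32L, rpe_depth = 12, rpe_amplitude = 1.5,
               rpe_thickness = 4, choroid_thickness = 14, choroid_variation = 2,
               n_vessels = 3L, vessel_radius = c(1, 2), boundary_smooth = 11L)
}

# Count 4-connected neighbor pairs with differing labels.
discontinuity_count <- function(labels) {
  sum(labels[-nrow(labels), ] != labels[-1L, ]) +
    sum(labels[, -ncol(labels)] != labels[, -1L])
}

# A mixture of three well-separated 5-d Gaussians used by several tests.
toy_mixture <- function() {
  means <- rbind(rep(0, 5), rep(6, 5), c(12, 0, 12, 0, 12))
  texture_gmm(c(0.3, 0.4, 0.3), means,
              list(diag(5), 2 * diag(5), diag(c(1, 2, 1, 2, 1))))
}

# Draw n descriptors from one mixture component.
draw_component <- function(n, model, k) {
  d <- model$n_dims
  R <- chol(model$covariances[[k]])
  sweep(matrix(stats::rnorm(n * d), n, d) %*% R, 2L, model$means[k, ], "+")
}
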