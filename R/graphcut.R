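#' Unary (data) costs from class posteriors
#'
#' The data term of the segmentation energy: `-log(p + eps)` for each pixel
#' and label, clamped below at 0 so a certain pixel (`p = 1`) costs exactly
#' nothing.
#'
#' @param probs Posterior array `n_rows x n_cols x K` from
#'   [responsibilities()].
#' @param eps Floor constant inside the logarithm (default: double machine
#'   epsilon, `2.220446e-16`), so `p = 0` costs about 36.04.
#' @return A cost array of the same dimension.
#' @export
build_data_term <- function(probs, eps = .Machine$double.eps) {
  if (!is.array(probs) || length(dim(probs)) != 3L)
    stop("`probs` must be an n_rows x n_cols x K array")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1 + 1e-9))
    stop("`probs` must contain probabilities in [0, 1]")
  pmax(-log(probs + eps), 0)
}

#' Potts pairwise (smoothness) cost matrix
#'
#' A `K x K` matrix with zeros on the diagonal and the constant `r` off the
#' diagonal: neighboring pixels pay `r` whenever their labels differ.
#' Larger `r` enforces stronger spatial coherence and hence a cleaner
#' separation of the regions.
#'
#' @param K Number of labels (default 3).
#' @param r Off-diagonal constant (default 4).
#' @return A `K x K` numeric matrix.
#' @examples
#' build_smooth_term(3, 4)
#' @export
build_smooth_term <- function(K = 3L, r = 4) {
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be >= 2")
  if (!is.finite(r) || r <= 0) stop("`r` must be > 0")
  m <- matrix(r, K, K)
  diag(m) <- 0
  m
}

# 4-connected neighbor pairs of an nr x nc grid, as two index vectors
# (column-major pixel ids). Vertical pairs first, then horizontal.
grid_pairs <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  list(p = c(idx[-nr, , drop = FALSE], idx[, -nc, drop = FALSE]),
       q = c(idx[-1L, , drop = FALSE], idx[, -1L, drop = FALSE]))
}

#' Total labeling energy (data + smoothness)
#'
#' `C(f) = c_data(f) + c_smooth(f)`: the sum of the unary costs of the
#' assigned labels plus, for every unordered 4-connected neighbor pair, the
#' pairwise cost of their two labels.
#'
#' @param labels Integer matrix of labels in `1..K`.
#' @param unary Cost array `n_rows x n_cols x K`.
#' @param pairwise `K x K` pairwise cost matrix (zero diagonal).
#' @return Scalar energy.
#' @export
total_energy <- function(labels, unary, pairwise) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  du <- dim(unary)
  if (length(du) != 3L || any(dim(labels) != du[1:2]))
    stop("`unary` must be an array matching the label grid")
  K <- du[3L]
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..K")
  n <- du[1L] * du[2L]
  U <- matrix(unary, n, K)
  lab <- as.integer(labels)
  e_data <- sum(U[cbind(seq_len(n), lab)])
  pr <- grid_pairs(du[1L], du[2L])
  e_smooth <- sum(pairwise[cbind(lab[pr$p], lab[pr$q])])
  e_data + e_smooth
}

# One alpha-expansion move, solved exactly as a minimum s-t cut.
# Convention: a pixel on the SOURCE side of the cut takes label alpha
# (paying its i->sink capacity U[i, alpha]); on the sink side it keeps its
# current label (paying the source->i capacity U[i, f_i]).
expansion_move <- function(f, alpha, U, P, pairs) {
  n <- length(f)
  cap_src <- U[cbind(seq_len(n), f)]
  cap_sink <- U[, alpha]

  pv <- pairs$p; qv <- pairs$q
  fp <- f[pv]; fq <- f[qv]

  # fp == fq == alpha: no interaction (both ends stay alpha).
  eq <- fp == fq & fp != alpha
  ef <- integer(0); et <- integer(0); ec <- numeric(0)
  if (any(eq)) {
    ef <- pv[eq]; et <- qv[eq]
    ec <- P[cbind(fp[eq], rep(alpha, sum(eq)))]
  }
  # one end already alpha: charge the other end's "keep" side. A pixel can
  # have several alpha neighbors, so increments must accumulate (rowsum).
  pa <- fp == alpha & fq != alpha
  qa <- fq == alpha & fp != alpha
  if (any(pa) || any(qa)) {
    i <- c(qv[pa], pv[qa])
    add <- c(P[cbind(rep(alpha, sum(pa)), fq[pa])],
             P[cbind(fp[qa], rep(alpha, sum(qa)))])
    acc <- rowsum(add, i)
    ii <- as.integer(rownames(acc))
    cap_src[ii] <- cap_src[ii] + acc[, 1L]
  }

  n_aux <- 0L
  df <- fp != fq & fp != alpha & fq != alpha
  if (any(df)) {
    n_aux <- sum(df)
    aux <- n + seq_len(n_aux)
    ef <- c(ef, pv[df], aux)
    et <- c(et, aux, qv[df])
    ec <- c(ec, P[cbind(fp[df], rep(alpha, n_aux))],
            P[cbind(rep(alpha, n_aux), fq[df])])
    cap_src <- c(cap_src, P[cbind(fp[df], fq[df])])
    cap_sink <- c(cap_sink, numeric(n_aux))
  }

  res <- st_mincut_cpp(n + n_aux, ef, et, ec, cap_src, cap_sink)
  new_f <- f
  new_f[res$source_side[seq_len(n)]] <- alpha
  new_f
}

#' Multi-label segmentation by alpha-expansion graph cuts
#'
#' Minimizes the Potts energy of [total_energy()] over per-pixel labels. An
#' exact minimum cut over three terminals is NP-hard, so the optimization
#' iterates alpha-expansion moves: for each label alpha every pixel may
#' either keep its label or switch to alpha, and that binary subproblem is
#' solved exactly as a minimum s-t cut (compiled Dinic max-flow). Sweeps
#' over all labels repeat until no move lowers the energy. For `K = 2` the
#' first move already spans every labeling, so the result is the exact
#' global optimum; for `K >= 3` the energy is within a known constant
#' factor of the optimum and in practice almost always attains it.
#'
#' @param unary Cost array `n_rows x n_cols x K`.
#' @param pairwise `K x K` metric pairwise matrix (zero diagonal,
#'   symmetric), e.g. from [build_smooth_term()].
#' @param init Optional initial label matrix; default is the per-pixel
#'   argmin of the unary costs (first label on ties).
#' @param max_sweeps Maximum full sweeps over the labels (default 10).
#' @return Integer label matrix with attributes `energy` (final energy) and
#'   `energy_trace` (energy after each accepted move).
#' @export
segment_labels <- function(unary, pairwise, init = NULL, max_sweeps = 10L) {
  du <- dim(unary)
  if (length(du) != 3L) stop("`unary` must be an n_rows x n_cols x K array")
  if (any(!is.finite(unary))) stop("`unary` contains non-finite costs")
  K <- du[3L]
  if (!is.matrix(pairwise) || any(dim(pairwise) != K))
    stop("`pairwise` must be a K x K matrix")
  if (any(diag(pairwise) != 0) || max(abs(pairwise - t(pairwise))) > 0)
    stop("`pairwise` must be symmetric with a zero diagonal")
  nr <- du[1L]; nc <- du[2L]; n <- nr * nc
  U <- matrix(unary, n, K)

  if (is.null(init)) {
    f <- max.col(-U, ties.method = "first")
  } else {
    if (!is.matrix(init) || any(dim(init) != c(nr, nc)))
      stop("`init` must match the unary grid")
    f <- as.integer(init)
    if (any(f < 1L | f > K)) stop("`init` labels must lie in 1..K")
  }
  if (K == 2L) f <- rep(1L, n)  # one expansion of label 2 is then exact

  pairs <- grid_pairs(nr, nc)
  energy <- function(fv) {
    sum(U[cbind(seq_len(n), fv)]) + sum(pairwise[cbind(fv[pairs$p], fv[pairs$q])])
  }
  e <- energy(f)
  trace <- e
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (alpha in seq_len(K)) {
      if (all(f == alpha)) next
      f_new <- expansion_move(f, alpha, U, pairwise, pairs)
      e_new <- energy(f_new)
      if (e_new < e - 1e-9) {
        f <- f_new
        e <- e_new
        trace <- c(trace, e)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(matrix(f, nr, nc), energy = e, energy_trace = trace)
}

#' Extract the choroid-sclera interface from a label map
#'
#' Per column, the deepest pixel labeled 2 (choroid) defines the CSI.
#' Columns containing no choroid pixel are filled by linear interpolation
#' from neighboring columns (nearest value at the ends), and the curve is
#' median-smoothed across columns.
#'
#' @param labels Integer label matrix with values in `{1, 2, 3}`.
#' @param smooth_window Odd median filter window (default 15).
#' @return Integer vector of CSI row indices, one per column.
#' @export
extract_csi <- function(labels, smooth_window = 15L) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  smooth_window <- check_odd_window(smooth_window, "smooth_window")
  nc <- ncol(labels)
  csi <- rep(NA_real_, nc)
  for (cc in seq_len(nc)) {
    rows <- which(labels[, cc] == 2L)
    if (length(rows)) csi[cc] <- max(rows)
  }
  have <- which(!is.na(csi))
  if (!length(have)) stop("label map contains no choroid (label 2) pixels")
  if (length(have) < nc) {
    csi <- stats::approx(have, csi[have], xout = seq_len(nc), rule = 2)$y
  }
  k <- min(smooth_window, if (nc %% 2L == 1L) nc else nc - 1L)
  if (k >= 3L) csi <- stats::runmed(csi, k)
  as.integer(round(pmin(pmax(csi, 1), nrow(labels))))
}
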