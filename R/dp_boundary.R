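#' Trace the minimum-cost left-to-right path through a cost image
#'
#' Dynamic-programming boundary tracking: the columns of `cost_image` are the
#' graph layers and the rows are the nodes within a layer. Every
#' column-to-column transition may change the row by at most `step_bound`.
#' Each node carries the cost of its own pixel; the algorithm accumulates
#' `C(k, m) = cost[k, m] + min_i C(k + i, m - 1)` over the admissible offsets
#' `i` and backtracks from the cheapest node of the last column.
#'
#' Ties are broken deterministically: among equal-cost predecessors the
#' offsets are preferred in the order `0, -1, +1, -2, +2, ...`; among
#' equal-cost terminal nodes the smallest row index wins. On a constant cost
#' image the canonical result is therefore the flat path along row 1.
#'
#' @param cost_image Numeric matrix of finite node costs.
#' @param step_bound Maximum absolute row change between adjacent columns
#'   (default 1).
#' @return An object of class `"dp_path"`: a list with `path` (integer row
#'   index per column), `total_cost`, `cost_table` (cumulative costs) and
#'   `predecessors` (back-pointer rows, `NA` in the first column).
#' @examples
#' cost <- cbind(c(1, 3), c(4, 2))
#' trace_optimal_path(cost)$path      # 1 then 2
#' @export
trace_optimal_path <- function(cost_image, step_bound = 1L) {
  if (!is.matrix(cost_image) || !is.numeric(cost_image))
    stop("`cost_image` must be a numeric matrix")
  if (ncol(cost_image) < 1L || nrow(cost_image) < 1L)
    stop("`cost_image` must have at least one column and one row")
  if (!all(is.finite(cost_image)))
    stop("`cost_image` contains non-finite costs")
  step_bound <- as.integer(step_bound)
  if (step_bound < 1L) stop("`step_bound` must be >= 1")

  n <- nrow(cost_image)
  m <- ncol(cost_image)

  # offsets in tie-break preference order: 0, -1, +1, -2, +2, ...
  offsets <- c(0L, as.vector(rbind(-seq_len(step_bound), seq_len(step_bound))))

  ctab <- matrix(NA_real_, n, m)
  pred <- matrix(NA_integer_, n, m)
  ctab[, 1L] <- cost_image[, 1L]

  if (m > 1L) {
    for (col in 2:m) {
      prev <- ctab[, col - 1L]
      best <- rep(Inf, n)
      barg <- rep(NA_integer_, n)
      for (off in offsets) {
        ks <- seq.int(max(1L, 1L - off), min(n, n - off))
        if (length(ks) == 0L) next
        cand <- prev[ks + off]
        upd <- cand < best[ks]
        if (any(upd)) {
          kk <- ks[upd]
          best[kk] <- cand[upd]
          barg[kk] <- kk + off
        }
      }
      ctab[, col] <- best + cost_image[, col]
      pred[, col] <- barg
    }
  }

  k_end <- which.min(ctab[, m])  # first minimum = smallest row
  path <- integer(m)
  path[m] <- k_end
  if (m > 1L) {
    for (col in m:2) path[col - 1L] <- pred[path[col], col]
  }

  structure(
    list(path = path,
         total_cost = ctab[k_end, m],
         cost_table = ctab,
         predecessors = pred),
    class = "dp_path")
}

#' @export
print.dp_path <- function(x, ...) {
  cat("DP optimal path over", length(x$path), "columns, total cost",
      format(x$total_cost), "\n")
  invisible(x)
}

#' Detect the retinal pigment epithelium by dynamic programming
#'
#' The RPE is the brightest near-horizontal band of an EDI-OCT B-scan. The
#' DP tracker looks for the *darkest* path, so the image brightness is
#' inverted (`max(image) - image`) before tracing.
#'
#' @param image Numeric matrix, a B-scan (rows = depth).
#' @param step_bound Maximum row change per column for the traced path.
#' @return Integer vector of RPE row indices, one per column.
#' @seealso [trace_optimal_path()], [detect_bm()]
#' @export
detect_rpe <- function(image, step_bound = 1L) {
  check_bscan(image)
  trace_optimal_path(max(image) - image, step_bound = step_bound)$path
}

#' Locate Bruch's membrane below a traced RPE
#'
#' BM separates the RPE from the choroid and sits at the strongest axial
#' intensity gradient just below the RPE. Per column, the row in
#' `(rpe, rpe + search_depth]` maximizing the magnitude of the
#' central-difference axial gradient is selected (first row on ties), the
#' curve is median-smoothed across columns, and finally clipped to the image
#' and to lie at or below the RPE.
#'
#' @param image Numeric matrix, a B-scan.
#' @param rpe Integer vector of RPE rows, one per column.
#' @param search_depth Number of rows below the RPE to scan (default 8,
#'   about 31 um at 3.9 um/pixel).
#' @param smooth_window Odd median filter window applied across columns
#'   (default 5).
#' @return Integer vector of BM row indices, one per column.
#' @export
detect_bm <- function(image, rpe, search_depth = 8L, smooth_window = 5L) {
  check_bscan(image)
  check_curve(rpe, image, "rpe")
  search_depth <- as.integer(search_depth)
  if (search_depth < 1L) stop("`search_depth` must be >= 1")
  smooth_window <- check_odd_window(smooth_window, "smooth_window")

  n <- nrow(image)
  nc <- ncol(image)

  grad <- matrix(0, n, nc)
  if (n >= 3L) grad[2:(n - 1L), ] <- (image[3:n, ] - image[1:(n - 2L), ]) / 2
  grad[1L, ] <- image[2L, ] - image[1L, ]
  grad[n, ] <- image[n, ] - image[n - 1L, ]
  agrad <- abs(grad)

  bm <- integer(nc)
  clipped <- 0L
  for (cc in seq_len(nc)) {
    lo <- rpe[cc] + 1L
    hi <- min(rpe[cc] + search_depth, n)
    if (lo > n) {
      bm[cc] <- n
      clipped <- clipped + 1L
      next
    }
    rows <- lo:hi
    bm[cc] <- rows[which.max(agrad[rows, cc])]
  }
  if (clipped > 0L)
    warning(sprintf("BM search window fell outside the image in %d column(s); nearest valid row used",
                    clipped))

  k <- min(smooth_window, if (nc %% 2L == 1L) nc else nc - 1L)
  if (k >= 3L) bm <- as.integer(round(stats::runmed(bm, k)))
  pmin(pmax(bm, rpe), n)
}

#' Zero all pixels strictly above a boundary curve
#'
#' Used to suppress the retina above Bruch's membrane before texture
#' features are computed, so only the choroid and sclera contribute
#' structure. The input is not modified.
#'
#' @param image Numeric matrix, a B-scan.
#' @param boundary Integer vector of row indices, one per column.
#' @return A matrix identical to `image` except that in every column the
#'   pixels with row index strictly less than the boundary row are 0.
#' @export
zero_above <- function(image, boundary) {
  check_bscan(image)
  check_curve(boundary, image, "boundary")
  out <- image
  rowidx <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  bmat <- matrix(boundary, nrow(image), ncol(image), byrow = TRUE)
  out[rowidx < bmat] <- 0
  out
}
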