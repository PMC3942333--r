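#' Undecimated Haar wavelet frame decomposition along the axial direction
#'
#' A 1-D "a trous" (undecimated) wavelet frame applied down the rows of the
#' image, where OCT layer structure varies. The level-1 analysis filters are
#' the Haar pair `H(z) = (1 + z)/2` (lowpass, taps `c(1/2, 1/2)`) and
#' `G(z) = (z - 1)/2` (highpass, taps `c(-1/2, 1/2)`); at level `l` the
#' filters are upsampled by inserting `2^(l-1) - 1` zeros between taps, so
#' every subband keeps the input size and the transform is shift-invariant.
#' Borders are handled by half-sample symmetric extension.
#'
#' @param image Numeric matrix, a B-scan (rows = axial depth).
#' @param levels Number of decomposition levels (default 4).
#' @return A list of class `"subband_stack"` with `details` (list of
#'   `levels` matrices, level 1 first), `approximation` (final lowpass
#'   plane) and `levels`.
#' @examples
#' s <- wavelet_frame_decompose(matrix(5, 16, 8))
#' max(abs(s$details[[1]]))       # highpass annihilates constants: 0
#' s$approximation[1, 1]          # unit DC gain: 5
#' @export
wavelet_frame_decompose <- function(image, levels = 4L) {
  check_bscan(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  n <- nrow(image)
  if (2L^(levels - 1L) + 1L > n)
    stop(sprintf("level-%d filter (support %d) exceeds the axial extent (%d rows)",
                 levels, 2L^(levels - 1L) + 1L, n))

  details <- vector("list", levels)
  approx <- image
  for (l in seq_len(levels)) {
    d <- 2L^(l - 1L)
    shifted <- approx[fold_index(seq_len(n) + d, n), , drop = FALSE]
    details[[l]] <- (shifted - approx) / 2
    approx <- (shifted + approx) / 2
  }
  structure(list(details = details, approximation = approx, levels = levels),
            class = "subband_stack")
}

#' @export
print.subband_stack <- function(x, ...) {
  cat("Undecimated wavelet frame:", x$levels, "levels,",
      nrow(x$approximation), "x", ncol(x$approximation), "planes\n")
  invisible(x)
}

# Moving-average box filter with half-sample symmetric padding, via an
# integral image. window must be odd.
box_mean <- function(m, window) {
  if (window == 1L) return(m)
  p <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- fold_index(seq.int(1L - p, nr + p), nr)
  ci <- fold_index(seq.int(1L - p, nc + p), nc)
  pm <- m[ri, ci, drop = FALSE]
  # integral image with a zero first row/column
  ii <- rbind(0, apply(pm, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  s <- ii[r0 + window, c0 + window, drop = FALSE] -
    ii[r0, c0 + window, drop = FALSE] -
    ii[r0 + window, c0, drop = FALSE] +
    ii[r0, c0, drop = FALSE]
  s / (window * window)
}

#' Per-pixel wavelet energy features
#'
#' The texture descriptor of a pixel is the local energy of each subband:
#' the squared coefficients averaged over a `window` x `window`
#' neighborhood (half-sample symmetric borders). Plane order is detail
#' levels 1..L followed by the level-L approximation, giving the
#' 5-dimensional descriptor used by the mixture model when `levels = 4`.
#'
#' @param subbands A `"subband_stack"` from [wavelet_frame_decompose()].
#' @param window Odd side length of the averaging window (default 9).
#' @return A numeric array of dimension `c(n_rows, n_cols, levels + 1)`.
#' @export
energy_features <- function(subbands, window = 9L) {
  if (!inherits(subbands, "subband_stack"))
    stop("`subbands` must be a subband_stack")
  window <- check_odd_window(window)
  planes <- c(subbands$details, list(subbands$approximation))
  nr <- nrow(subbands$approximation); nc <- ncol(subbands$approximation)
  out <- array(0, dim = c(nr, nc, length(planes)))
  for (i in seq_along(planes)) out[, , i] <- box_mean(planes[[i]]^2, window)
  out
}

#' Extract per-pixel texture descriptors from a B-scan
#'
#' Composition of [wavelet_frame_decompose()] and [energy_features()]: a
#' 4-level undecimated Haar frame along the axial direction followed by
#' windowed energy averaging, yielding a 5-dimensional descriptor per pixel
#' (detail energies of levels 1-4 plus the level-4 approximation energy).
#'
#' @inheritParams wavelet_frame_decompose
#' @inheritParams energy_features
#' @return A numeric array of dimension `c(n_rows, n_cols, levels + 1)`.
#' @export
extract_descriptors <- function(image, levels = 4L, window = 9L) {
  energy_features(wavelet_frame_decompose(image, levels), window)
}

# Flatten a feature array (nr x nc x d) into an N x d matrix, pixels in
# column-major image order.
feature_matrix <- function(features) {
  if (!is.array(features) || length(dim(features)) != 3L)
    stop("`features` must be a 3-d array (rows x cols x descriptor dims)")
  d <- dim(features)
  matrix(features, nrow = d[1L] * d[2L], ncol = d[3L])
}
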