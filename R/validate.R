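# Internal validation helpers shared across modules.

# A B-scan is a plain numeric matrix: rows = axial depth (row 1 = inner
# retina, increasing downwards), columns = transversal position (A-scans).
check_bscan <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop(sprintf("`%s` must be at least 2 x 2", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  if (any(image < 0))
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  invisible(image)
}

# A boundary curve is one axial row index per column, 1-based.
check_curve <- function(curve, image, arg = "boundary") {
  if (!is.numeric(curve))
    stop(sprintf("`%s` must be numeric", arg), call. = FALSE)
  if (length(curve) != ncol(image))
    stop(sprintf("`%s` must have one row index per image column (%d), got %d",
                 arg, ncol(image), length(curve)), call. = FALSE)
  if (any(!is.finite(curve)) || any(curve < 1) || any(curve > nrow(image)))
    stop(sprintf("`%s` has row indices outside [1, %d]", arg, nrow(image)),
         call. = FALSE)
  invisible(curve)
}

check_odd_window <- function(window, arg = "window") {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1 || window != round(window) || window %% 2 == 0)
    stop(sprintf("`%s` must be an odd positive integer", arg), call. = FALSE)
  as.integer(window)
}

# Row-index folding for half-sample symmetric extension: index 0 maps to 1,
# n + 1 maps to n, and so on (edge sample repeated).
fold_index <- function(idx, n) {
  while (any(idx < 1L) || any(idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}
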