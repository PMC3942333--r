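#' Pipeline configuration
#'
#' All tunable constants of the segmentation pipeline with their default
#' values: 4 wavelet levels, a 9 x 9 energy window, K = 3 mixture
#' components, Potts constant `r = 4` (`baseline_r = 3` for the intensity
#' graph-cut baseline), machine-epsilon floor in the data term, an 8-pixel
#' BM gradient search depth, a 7-pixel RPE exclusion for the DP baseline,
#' and the scanner resolutions (3.9 um/pixel axial, 14 um/pixel
#' transversal).
#'
#' @param levels,window Wavelet levels and energy window side.
#' @param K Number of mixture components / labels.
#' @param r Potts smoothness constant of the full method.
#' @param eps Floor constant of the data term.
#' @param bm_search_depth,bm_smooth_window BM gradient search depth and
#'   median window.
#' @param csi_smooth_window Median window for the extracted CSI curve.
#' @param step_bound DP row step bound per column.
#' @param baseline_r Potts constant of the intensity graph-cut baseline.
#' @param dp_exclusion Rows below the RPE excluded by the DP baseline.
#' @param axial_res_um,transversal_res_um Pixel resolutions in micrometer.
#' @return A list of class `"choroid_config"`.
#' @export
choroid_config <- function(levels = 4L, window = 9L, K = 3L, r = 4,
                           eps = .Machine$double.eps,
                           bm_search_depth = 8L, bm_smooth_window = 5L,
                           csi_smooth_window = 15L, step_bound = 1L,
                           baseline_r = 3, dp_exclusion = 7L,
                           axial_res_um = 3.9, transversal_res_um = 14) {
  cfg <- list(levels = as.integer(levels), window = as.integer(window),
              K = as.integer(K), r = r, eps = eps,
              bm_search_depth = as.integer(bm_search_depth),
              bm_smooth_window = as.integer(bm_smooth_window),
              csi_smooth_window = as.integer(csi_smooth_window),
              step_bound = as.integer(step_bound),
              baseline_r = baseline_r,
              dp_exclusion = as.integer(dp_exclusion),
              axial_res_um = axial_res_um,
              transversal_res_um = transversal_res_um)
  if (any(unlist(cfg) <= 0)) stop("all configuration values must be positive")
  structure(cfg, class = "choroid_config")
}

#' Segment one B-scan with a trained texture model
#'
#' The full pipeline: RPE by dynamic programming on inverted brightness,
#' BM at the maximal gradient below the RPE, suppression of everything
#' above BM, wavelet texture descriptors, mixture responsibilities,
#' `-log(p + eps)` data costs with a Potts smoothness term minimized by
#' alpha-expansion, and finally the CSI read off as the deepest
#' choroid-labeled row per column. The CSI is clamped to lie at or below
#' BM so the anatomical ordering RPE <= BM <= CSI holds per column.
#'
#' @param image Numeric matrix, a B-scan.
#' @param model A `"texture_gmm"` over 5-d descriptors.
#' @param config A [choroid_config()].
#' @return A list of class `"choroid_segmentation"`: `rpe`, `bm`, `csi`
#'   (row per column), `labels`, `responsibilities`, `energy`.
#' @export
segment_bscan <- function(image, model, config = choroid_config()) {
  check_bscan(image)
  stopifnot(inherits(model, "texture_gmm"))
  if (model$n_dims != config$levels + 1L)
    stop("model dimensionality does not match the configured wavelet levels")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  rpe <- stage("detect_rpe", detect_rpe(image, config$step_bound))
  bm <- stage("detect_bm",
              detect_bm(image, rpe, config$bm_search_depth,
                        config$bm_smooth_window))
  suppressed <- stage("zero_above", zero_above(image, bm))
  feats <- stage("extract_descriptors",
                 extract_descriptors(suppressed, config$levels, config$window))
  resp <- stage("responsibilities", responsibilities(model, feats))
  unary <- stage("build_data_term", build_data_term(resp, config$eps))
  pairwise <- build_smooth_term(config$K, config$r)
  labels <- stage("segment_labels", segment_labels(unary, pairwise))
  csi <- stage("extract_csi", extract_csi(labels, config$csi_smooth_window))
  csi <- pmax(csi, bm)

  structure(list(rpe = rpe, bm = bm, csi = csi, labels = labels,
                 responsibilities = resp,
                 energy = attr(labels, "energy"),
                 config = config),
            class = "choroid_segmentation")
}

#' @export
print.choroid_segmentation <- function(x, ...) {
  cat(sprintf("Choroid segmentation of a %d x %d B-scan\n",
              nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  mean rows: RPE %.1f, BM %.1f, CSI %.1f (thickness %.1f px = %.0f um)\n",
              mean(x$rpe), mean(x$bm), mean(x$csi), mean(x$csi - x$bm),
              mean(x$csi - x$bm) * x$config$axial_res_um))
  cat(sprintf("  graph-cut energy: %.2f\n", x$energy))
  invisible(x)
}

#' Plot a segmentation overlay
#'
#' Displays the B-scan with the BM curve in green and the CSI curve in
#' red (and optionally the RPE in yellow).
#'
#' @param x A `"choroid_segmentation"`.
#' @param image The segmented B-scan.
#' @param show_rpe Also draw the RPE trace (default `TRUE`).
#' @param ... Passed to [graphics::image()].
#' @export
plot.choroid_segmentation <- function(x, image, show_rpe = TRUE, ...) {
  nr <- nrow(x$labels); nc <- ncol(x$labels)
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(image[nr:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "transversal (px)", ylab = "axial (px)",
                  yaxt = "n", useRaster = TRUE, ...)
  graphics::axis(2, at = pretty(seq_len(nr)), labels = rev(pretty(seq_len(nr))))
  flip <- function(v) nr + 1 - v
  if (show_rpe) graphics::lines(seq_len(nc), flip(x$rpe), col = "yellow", lwd = 1)
  graphics::lines(seq_len(nc), flip(x$bm), col = "green", lwd = 2)
  graphics::lines(seq_len(nc), flip(x$csi), col = "red", lwd = 2)
  invisible(x)
}

#' Signed and unsigned border positioning errors of one image
#'
#' Per-column row differences between a predicted and a reference boundary:
#' the signed error is the mean of `pred - ref` (positive when the
#' prediction is deeper), the unsigned error the mean absolute difference.
#' Micrometer values are the pixel values times the axial resolution.
#'
#' @param pred,ref Numeric vectors of equal length (row per column).
#' @param axial_res_um Axial resolution in um/pixel (default 3.9).
#' @return List with `signed_px`, `unsigned_px`, `signed_um`,
#'   `unsigned_um`.
#' @export
boundary_errors <- function(pred, ref, axial_res_um = 3.9) {
  if (length(pred) != length(ref))
    stop("`pred` and `ref` must have equal length")
  d <- as.numeric(pred) - as.numeric(ref)
  list(signed_px = mean(d), unsigned_px = mean(abs(d)),
       signed_um = mean(d) * axial_res_um,
       unsigned_um = mean(abs(d)) * axial_res_um)
}

#' Aggregate per-image boundary errors
#'
#' Mean and sample standard deviation, across images, of the per-image
#' signed and unsigned errors, in pixels and micrometers.
#'
#' @param reports List of [boundary_errors()] results (at least 2).
#' @param axial_res_um Axial resolution in um/pixel (default 3.9).
#' @return A data frame with one row per statistic (`signed`, `unsigned`)
#'   and columns `mean_px`, `sd_px`, `mean_um`, `sd_um`, `n`.
#' @export
aggregate_errors <- function(reports, axial_res_um = 3.9) {
  if (length(reports) < 2L) stop("at least 2 per-image reports are required")
  signed <- vapply(reports, function(r) r$signed_px, numeric(1))
  unsigned <- vapply(reports, function(r) r$unsigned_px, numeric(1))
  data.frame(statistic = c("signed", "unsigned"),
             mean_px = c(mean(signed), mean(unsigned)),
             sd_px = c(stats::sd(signed), stats::sd(unsigned)),
             mean_um = c(mean(signed), mean(unsigned)) * axial_res_um,
             sd_um = c(stats::sd(signed), stats::sd(unsigned)) * axial_res_um,
             n = length(reports))
}

# Depth-order k-means of raw intensities: cluster ids are relabeled
# {1,2,3} by the ascending mean row index of their pixels, so label
# semantics match the anatomical ordering. Returns labels and the
# depth-ordered cluster centers.
intensity_kmeans <- function(image, k, seed) {
  set.seed(seed)
  km <- tryCatch(stats::kmeans(as.vector(image), centers = k, nstart = 4L,
                               iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < k) {
    set.seed(seed + 1L)
    km <- stats::kmeans(as.vector(image), centers = k, nstart = 8L,
                        iter.max = 50L)
    if (length(unique(km$cluster)) < k) stop("k-means produced an empty cluster")
  }
  rowidx <- as.vector(matrix(seq_len(nrow(image)), nrow(image), ncol(image)))
  depth <- vapply(seq_len(k), function(j) mean(rowidx[km$cluster == j]),
                  numeric(1))
  relabel <- integer(k)
  relabel[order(depth)] <- seq_len(k)
  list(labels = matrix(relabel[km$cluster], nrow(image), ncol(image)),
       centers = as.numeric(km$centers)[order(depth)])
}

#' k-means intensity baseline
#'
#' Comparison baseline: k-means (`k = 3`) applied directly to the raw
#' pixel intensities, with clusters relabeled `{1,2,3}` by the ascending
#' mean depth of their pixels. Intended to run on the RPE-suppressed image
#' (after [zero_above()]), matching the shared first step of all methods.
#'
#' @param image Numeric matrix.
#' @param k Number of clusters (default 3).
#' @param seed RNG seed for the k-means initialization.
#' @return Integer label matrix.
#' @export
kmeans_baseline <- function(image, k = 3L, seed = 1L) {
  check_bscan(image)
  intensity_kmeans(image, as.integer(k), as.integer(seed))$labels
}

#' Intensity graph-cut baseline
#'
#' Comparison baseline: k-means prototypes on raw intensities define the
#' data term (absolute distance of each pixel's intensity to each class
#' prototype) and a Potts term with `r = 3` is minimized with the same
#' alpha-expansion solver as the full method.
#'
#' @param image Numeric matrix.
#' @param r Potts constant (default 3, the baseline setting).
#' @param k Number of labels (default 3).
#' @param seed RNG seed for the k-means initialization.
#' @return Integer label matrix with an `energy` attribute.
#' @export
graphcut_baseline <- function(image, r = 3, k = 3L, seed = 1L) {
  check_bscan(image)
  k <- as.integer(k)
  km <- intensity_kmeans(image, k, as.integer(seed))
  nr <- nrow(image); nc <- ncol(image)
  unary <- array(0, dim = c(nr, nc, k))
  for (j in seq_len(k)) unary[, , j] <- abs(image - km$centers[j])
  segment_labels(unary, build_smooth_term(k, r), init = km$labels)
}

#' Dynamic-programming brightest-path baseline
#'
#' Comparison baseline for the CSI: all rows down to `exclusion` pixels
#' below the RPE are masked out and the DP tracker is run once more on the
#' inverted brightness of the remainder, returning the whitest available
#' route as the CSI estimate.
#'
#' @param image Numeric matrix.
#' @param rpe Integer vector of RPE rows.
#' @param exclusion Rows below the RPE to exclude (default 7).
#' @return Integer vector of CSI row estimates, one per column.
#' @export
dp_baseline <- function(image, rpe, exclusion = 7L) {
  check_bscan(image)
  check_curve(rpe, image, "rpe")
  exclusion <- as.integer(exclusion)
  n <- nrow(image)
  if (any(rpe + exclusion >= n))
    stop("exclusion region reaches the bottom of the image in some column")
  cost <- max(image) - image
  big <- max(cost) * n + 1
  rowidx <- matrix(seq_len(n), n, ncol(image))
  rmat <- matrix(rpe, n, ncol(image), byrow = TRUE)
  cost[rowidx <= rmat + exclusion] <- big
  trace_optimal_path(cost)$path
}
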