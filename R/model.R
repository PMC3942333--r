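#' Fit a choroid segmentation model from labeled B-scans
#'
#' The training step of the pipeline. Each training image is taken through
#' the same preprocessing used at segmentation time (RPE tracing, BM
#' localization, suppression of everything above BM, wavelet texture
#' descriptors), and the 3-component Gaussian mixture is then fitted by
#' supervised moment estimation from the label masks
#' ([fit_from_masks()]). Optionally the fit is refined by EM on the pooled
#' training descriptors.
#'
#' @param images A B-scan matrix or list of them.
#' @param masks A label mask (values `0:3`) or list of them, matching the
#'   images.
#' @param config A [choroid_config()].
#' @param ridge Covariance ridge passed to [fit_from_masks()].
#' @param em If `TRUE`, refine the supervised fit by EM (off by default;
#'   the supervised moment fit is the primary path).
#' @return An object of class `"choroid_model"` with elements `mixture`
#'   (the `"texture_gmm"`), `config`, `n_train` and `call`. Use
#'   [predict.choroid_model()] to segment new B-scans.
#' @examples
#' \donttest{
#' train <- lapply(1:3, function(i)
#'   generate_phantom(phantom_spec(n_rows = 120, n_cols = 96,
#'                                 rpe_depth = 30, choroid_thickness = 35,
#'                                 n_vessels = 12, seed = i)))
#' fit <- fit_choroid_model(lapply(train, `[[`, "image"),
#'                          lapply(train, `[[`, "mask"))
#' test <- generate_phantom(phantom_spec(n_rows = 120, n_cols = 96,
#'                                       rpe_depth = 30,
#'                                       choroid_thickness = 35,
#'                                       n_vessels = 12, seed = 99))
#' seg <- predict(fit, test$image)
#' boundary_errors(seg$csi, test$csi_true)$unsigned_px
#' }
#' @export
fit_choroid_model <- function(images, masks, config = choroid_config(),
                              ridge = 1e-6, em = FALSE) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(images) != length(masks) || length(images) < 1L)
    stop("`images` and `masks` must be non-empty lists of equal length")
  stopifnot(inherits(config, "choroid_config"))

  feats <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    check_bscan(img, sprintf("images[[%d]]", i))
    if (any(dim(masks[[i]]) != dim(img)))
      stop(sprintf("mask %d does not match its image", i))
    rpe <- detect_rpe(img, config$step_bound)
    bm <- detect_bm(img, rpe, config$bm_search_depth, config$bm_smooth_window)
    feats[[i]] <- extract_descriptors(zero_above(img, bm),
                                      config$levels, config$window)
  }
  mix <- fit_from_masks(feats, masks, ridge = ridge, n_classes = config$K)
  if (em) {
    X <- do.call(rbind, lapply(feats, feature_matrix))
    mix <- em_refine(X, mix)
  }
  structure(list(mixture = mix, config = config,
                 n_train = length(images), em = em,
                 call = match.call()),
            class = "choroid_model")
}

#' @export
print.choroid_model <- function(x, ...) {
  cat("Choroid segmentation model\n")
  cat(sprintf("  trained on %d image(s), %s fit\n", x$n_train,
              if (isTRUE(x$em)) "moment + EM" else "supervised moment"))
  cat(sprintf("  mixture: K = %d over %d-d wavelet energy descriptors\n",
              x$mixture$K, x$mixture$n_dims))
  cat("  class weights:", format(x$mixture$weights, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.choroid_model <- function(object, ...) {
  mix <- object$mixture
  cat("Choroid segmentation model (3-class Gaussian texture mixture)\n\n")
  cls <- c("above BM", "choroid", "below CSI")[seq_len(mix$K)]
  for (k in seq_len(mix$K)) {
    cat(sprintf("component %d (%s): weight %.4f\n", k, cls[k], mix$weights[k]))
    cat("  mean descriptor:", format(mix$means[k, ], digits = 4), "\n")
    cat("  covariance trace:", format(sum(diag(mix$covariances[[k]])), digits = 4),
        "\n")
  }
  cat(sprintf("\nconfig: %d wavelet levels, %d x %d energy window, r = %g\n",
              object$config$levels, object$config$window,
              object$config$window, object$config$r))
  invisible(object)
}

#' @export
coef.choroid_model <- function(object, ...) {
  list(weights = object$mixture$weights,
       means = object$mixture$means,
       covariances = object$mixture$covariances)
}

#' Segment a new B-scan with a fitted model
#'
#' @param object A `"choroid_model"` from [fit_choroid_model()].
#' @param newdata A B-scan matrix.
#' @param ... Unused.
#' @return A `"choroid_segmentation"`, see [segment_bscan()].
#' @export
predict.choroid_model <- function(object, newdata, ...) {
  segment_bscan(newdata, object$mixture, object$config)
}
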