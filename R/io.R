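#' Read a grayscale B-scan image
#'
#' Reads an 8- or 16-bit PNG or TIFF raster as a numeric matrix scaled to
#' the 0-255 range (multi-channel images are averaged to luminance). TIFF
#' support requires the optional `tiff` package.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix, rows = axial depth.
#' @export
read_bscan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = {
                if (!requireNamespace("tiff", quietly = TRUE))
                  stop("reading TIFF requires the `tiff` package")
                tiff::readTIFF(path)
              },
              stop(sprintf("unsupported image format `.%s`", ext)))
  if (length(dim(x)) == 3L) x <- apply(x, c(1L, 2L), mean)
  x * 255
}

#' Write a grayscale B-scan image
#'
#' Writes the matrix as an 8-bit grayscale PNG (or TIFF if the `tiff`
#' package is available). Intensities are clamped to `[0, max_value]` and
#' scaled so `max_value` maps to white.
#'
#' @param image Numeric matrix.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param max_value Intensity mapped to white (default 255).
#' @export
write_bscan <- function(image, path, max_value = 255) {
  x <- pmin(pmax(image, 0), max_value) / max_value
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = ,
         tiff = {
           if (!requireNamespace("tiff", quietly = TRUE))
             stop("writing TIFF requires the `tiff` package")
           tiff::writeTIFF(x, path)
         },
         stop(sprintf("unsupported image format `.%s`", ext)))
  invisible(path)
}

#' Read / write a 3-class label mask raster
#'
#' Masks use the value map `{0: unlabeled, 1: above BM, 2: choroid,
#' 3: below CSI}`, stored as PNG gray levels `value / 255`.
#'
#' @param path PNG path.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  lab <- as.integer(round(x * 255))
  if (any(lab < 0L | lab > 3L))
    stop("mask raster contains values outside the {0,1,2,3} label map")
  matrix(lab, nrow(x), ncol(x))
}

#' @rdname read_label_mask
#' @param mask Integer matrix with values in `0:3`.
#' @export
write_label_mask <- function(mask, path) {
  if (any(!(mask %in% 0:3)))
    stop("mask values must lie in {0,1,2,3}")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read / write a boundary curve as CSV
#'
#' Two-column CSV with header `column,row`, one 1-based axial row index per
#' image column.
#'
#' @param path CSV path.
#' @return Integer vector of row indices ordered by column.
#' @export
read_boundary_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("column", "row") %in% names(d)))
    stop("boundary CSV must have columns `column` and `row`")
  as.integer(d$row[order(d$column)])
}

#' @rdname read_boundary_csv
#' @param curve Numeric vector of row indices.
#' @export
write_boundary_csv <- function(curve, path) {
  utils::write.csv(data.frame(column = seq_along(curve), row = as.integer(round(curve))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a texture mixture model to JSON
#'
#' The JSON object records `version`, `n_dims`, `K` and one
#' `{weight, mean, covariance}` entry per component, at full double
#' precision.
#'
#' @param model A `"texture_gmm"`.
#' @param path Output JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "texture_gmm"))
  obj <- list(version = 1L, n_dims = model$n_dims, K = model$K,
              components = lapply(seq_len(model$K), function(k)
                list(weight = model$weights[k],
                     mean = model$means[k, ],
                     covariance = model$covariances[[k]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json()` returns the reconstructed `"texture_gmm"`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- obj$K
  comps <- obj$components
  weights <- vapply(seq_len(K), function(k) comps$weight[k], numeric(1))
  means <- do.call(rbind, comps$mean)
  covs <- comps$covariance
  if (is.array(covs) && length(dim(covs)) == 3L)
    covs <- lapply(seq_len(K), function(k) covs[k, , ])
  texture_gmm(weights, means, covs)
}
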