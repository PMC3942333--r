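#' Specification of a synthetic EDI-OCT B-scan phantom
#'
#' Parameters of the layered phantom used to exercise every stage of the
#' segmentation pipeline without clinical data. The phantom emulates the
#' anatomy the method relies on: a bright RPE band whose lower edge is
#' Bruch's membrane, a heterogeneous choroid carrying dark vessel-like
#' inclusions (its texture signature), and a smoother, dimmer sclera below
#' the choroid-sclera interface. Interfaces are smooth seeded random
#' curves; speckle is multiplicative gamma noise with unit mean, with the
#' shape parameter set for a heavily frame-averaged acquisition.
#'
#' @param n_rows,n_cols Image size in pixels (default 248 x 384,
#'   half-resolution B-scans).
#' @param rpe_depth Mean axial row of the RPE brightness peak (default 60).
#' @param rpe_amplitude Standard deviation of the smooth RPE undulation in
#'   pixels (default 6).
#' @param rpe_thickness Full width of the bright band's upper taper in
#'   pixels; the Gaussian taper above the peak uses `rpe_thickness / 2` as
#'   its sigma (default 6).
#' @param bm_offset Rows between the RPE brightness peak and Bruch's
#'   membrane, the band's sharp lower edge (default 4).
#' @param choroid_thickness,choroid_variation Mean choroidal thickness and
#'   the standard deviation of its smooth variation, in pixels (defaults
#'   70 and 10).
#' @param intensity_retina,intensity_rpe,intensity_choroid,intensity_sclera
#'   Region mean intensities on a 0-255 scale (defaults 60, 200, 110, 90);
#'   the RPE band must be the brightest.
#' @param rpe_taper Intensity drop from the RPE peak to Bruch's membrane
#'   (default 30), keeping the peak row strictly brightest.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative
#'   speckle; larger is smoother, `Inf` disables noise (default 60,
#'   a heavily averaged regime).
#' @param n_vessels Number of dark elliptical vessel inclusions placed
#'   inside the choroid (default 40).
#' @param vessel_radius Range of vessel semi-axes in pixels (default
#'   `c(2, 5)`; the transversal semi-axis is 1.8x the axial one).
#' @param vessel_contrast Multiplicative darkening factor inside vessels
#'   (default 0.35).
#' @param boundary_smooth Moving-average window (pixels) applied to the
#'   random walks that generate the interfaces; larger gives smoother
#'   curves (default 41).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_rows = 248L, n_cols = 384L,
                         rpe_depth = 60, rpe_amplitude = 6,
                         rpe_thickness = 6, bm_offset = 4L,
                         choroid_thickness = 70, choroid_variation = 10,
                         intensity_retina = 60, intensity_rpe = 200,
                         intensity_choroid = 110, intensity_sclera = 90,
                         rpe_taper = 30,
                         speckle_shape = 60, n_vessels = 40L,
                         vessel_radius = c(2, 5), vessel_contrast = 0.35,
                         boundary_smooth = 41L, seed = 1L) {
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               rpe_depth = rpe_depth, rpe_amplitude = rpe_amplitude,
               rpe_thickness = rpe_thickness, bm_offset = as.integer(bm_offset),
               choroid_thickness = choroid_thickness,
               choroid_variation = choroid_variation,
               intensity_retina = intensity_retina,
               intensity_rpe = intensity_rpe,
               intensity_choroid = intensity_choroid,
               intensity_sclera = intensity_sclera,
               rpe_taper = rpe_taper,
               speckle_shape = speckle_shape,
               n_vessels = as.integer(n_vessels),
               vessel_radius = vessel_radius,
               vessel_contrast = vessel_contrast,
               boundary_smooth = as.integer(boundary_smooth),
               seed = as.integer(seed))
  ints <- c(spec$intensity_retina, spec$intensity_rpe,
            spec$intensity_choroid, spec$intensity_sclera)
  if (any(ints < 0) || any(ints > 255))
    stop("region intensities must lie in the 0-255 dynamic range")
  if (spec$intensity_rpe != max(ints))
    stop("the RPE band must be the brightest region")
  if (spec$n_rows < 16L || spec$n_cols < 16L)
    stop("phantom must be at least 16 x 16")
  if (spec$bm_offset < 1L) stop("`bm_offset` must be >= 1")
  if (length(spec$vessel_radius) != 2L || any(spec$vessel_radius <= 0))
    stop("`vessel_radius` must be a positive range c(min, max)")
  structure(spec, class = "phantom_spec")
}

# Smooth zero-mean random curve: a seeded random walk, moving-average
# low-pass filtered, centered, and scaled to the requested sd.
smooth_curve <- function(n, amplitude_sd, window) {
  if (amplitude_sd <= 0) return(numeric(n))
  pad <- window
  rw <- cumsum(stats::rnorm(n + 2L * pad))
  sm <- stats::filter(rw, rep(1 / window, window), sides = 2)
  sm <- sm[(pad + 1L):(pad + n)]
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (s == 0) return(numeric(n))
  as.numeric(sm / s * amplitude_sd)
}

#' Generate a synthetic EDI-OCT phantom with ground truth
#'
#' Builds one B-scan according to a [phantom_spec()]: smooth random RPE /
#' BM / CSI interfaces, a piecewise intensity model (Gaussian-tapered
#' bright band ending sharply at BM, uniform choroid and sclera means),
#' dark elliptical vessels confined to the choroid, and multiplicative
#' gamma speckle. The returned mask is exactly consistent with the true
#' curves: label 1 at and above BM, 2 from below BM down to the CSI, 3
#' below the CSI.
#'
#' @param spec A `"phantom_spec"`.
#' @return A list of class `"oct_phantom"` with `image`, `rpe_true`,
#'   `bm_true`, `csi_true`, `mask` and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 80, n_cols = 64,
#'                                     rpe_depth = 20,
#'                                     choroid_thickness = 25,
#'                                     n_vessels = 6, seed = 7))
#' range(ph$bm_true - ph$rpe_true)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols

  rpe <- round(spec$rpe_depth + smooth_curve(nc, spec$rpe_amplitude,
                                             spec$boundary_smooth))
  bm <- rpe + spec$bm_offset
  thick <- round(spec$choroid_thickness +
                   smooth_curve(nc, spec$choroid_variation,
                                spec$boundary_smooth))
  thick <- pmax(thick, 8)
  csi <- bm + thick

  sigma <- spec$rpe_thickness / 2
  if (min(rpe) - 2 * sigma < 1 || max(csi) > nr - 2)
    stop("infeasible phantom geometry: bands overlap the image border")

  rowidx <- matrix(seq_len(nr), nr, nc)
  rpem <- matrix(rpe, nr, nc, byrow = TRUE)
  bmm <- matrix(bm, nr, nc, byrow = TRUE)
  csim <- matrix(csi, nr, nc, byrow = TRUE)

  mask <- matrix(3L, nr, nc)
  mask[rowidx <= bmm] <- 1L
  mask[rowidx > bmm & rowidx <= csim] <- 2L

  img <- matrix(spec$intensity_sclera, nr, nc)
  img[mask == 2L] <- spec$intensity_choroid
  # above BM: retina background with the bright band. Above the peak the
  # band rises as a Gaussian; between the peak and BM it tapers linearly by
  # rpe_taper so the peak row stays the brightest and BM keeps the largest
  # gradient below it.
  above <- mask == 1L
  amp <- spec$intensity_rpe - spec$intensity_retina
  up <- above & rowidx <= rpem
  img[up] <- spec$intensity_retina +
    amp * exp(-((rowidx[up] - rpem[up])^2) / (2 * sigma^2))
  dn <- above & rowidx > rpem
  frac <- (rowidx[dn] - rpem[dn]) / pmax(bmm[dn] - rpem[dn], 1)
  img[dn] <- spec$intensity_rpe - spec$rpe_taper * frac

  # dark elliptical vessels, only inside the choroid
  if (spec$n_vessels > 0L) {
    for (v in seq_len(spec$n_vessels)) {
      c0 <- sample.int(nc, 1L)
      a <- stats::runif(1, spec$vessel_radius[1L], spec$vessel_radius[2L])
      b <- 1.8 * a
      lo <- bm[c0] + ceiling(a) + 1L
      hi <- csi[c0] - ceiling(a) - 1L
      if (lo >= hi) next
      r0 <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      rr <- max(1L, floor(r0 - a)):min(nr, ceiling(r0 + a))
      ccs <- max(1L, floor(c0 - b)):min(nc, ceiling(c0 + b))
      sub <- outer(((rr - r0) / a)^2, ((ccs - c0) / b)^2, "+") <= 1
      sub <- sub & (mask[rr, ccs, drop = FALSE] == 2L)
      block <- img[rr, ccs, drop = FALSE]
      block[sub] <- block[sub] * spec$vessel_contrast
      img[rr, ccs] <- block
    }
  }

  if (is.finite(spec$speckle_shape)) {
    img <- img * matrix(stats::rgamma(nr * nc, shape = spec$speckle_shape,
                                      rate = spec$speckle_shape), nr, nc)
  }
  img <- pmin(pmax(img, 0), 255)

  structure(list(image = img, rpe_true = as.integer(rpe),
                 bm_true = as.integer(bm), csi_true = as.integer(csi),
                 mask = mask, spec = spec),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("Synthetic EDI-OCT phantom %d x %d (seed %d): RPE ~ row %d, mean choroid thickness %.1f px\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$seed,
              as.integer(round(mean(x$rpe_true))),
              mean(x$csi_true - x$bm_true)))
  invisible(x)
}

#' Generate a seeded phantom dataset with a train/test split
#'
#' Draws `n_images` phantoms with per-image seeds derived deterministically
#' from `base_seed`, and a manifest assigning the first `n_train` images to
#' training (the default split of 10 training images mirrors a 100-scan
#' study with 90 test scans). Optionally writes images, masks, boundary
#' CSVs and the JSON manifest to a directory.
#'
#' @param spec A `"phantom_spec"` (its `seed` field is overridden per
#'   image).
#' @param n_images Number of phantoms (default 100).
#' @param base_seed Integer seed from which per-image seeds are derived.
#' @param n_train Number of training images (default 10).
#' @param dir Optional output directory; created if missing.
#' @return A list with `samples` (list of `"oct_phantom"`) and `manifest`
#'   (ids, per-image seeds, train/test split).
#' @export
generate_dataset <- function(spec = phantom_spec(), n_images = 100L,
                             base_seed = 1L, n_train = 10L, dir = NULL) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("`n_images` must be >= 1")
  n_train <- min(as.integer(n_train), n_images)
  seeds <- (as.double(base_seed) * 10007 + 7919 * seq_len(n_images)) %% 2147483629 + 1
  seeds <- as.integer(seeds)
  ids <- sprintf("phantom_%03d", seq_len(n_images))

  samples <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- seeds[i]
    samples[[i]] <- generate_phantom(sp)
  }
  names(samples) <- ids

  manifest <- list(n_images = n_images,
                   base_seed = as.integer(base_seed),
                   ids = ids, seeds = seeds,
                   train = ids[seq_len(n_train)],
                   test = if (n_train < n_images) ids[(n_train + 1L):n_images] else character(0))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n_images)) {
      s <- samples[[i]]
      write_bscan(s$image, file.path(dir, paste0(ids[i], ".png")))
      write_label_mask(s$mask, file.path(dir, paste0(ids[i], "_mask.png")))
      write_boundary_csv(s$rpe_true, file.path(dir, paste0(ids[i], "_rpe.csv")))
      write_boundary_csv(s$bm_true, file.path(dir, paste0(ids[i], "_bm.csv")))
      write_boundary_csv(s$csi_true, file.path(dir, paste0(ids[i], "_csi.csv")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(samples = samples, manifest = manifest)
}
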