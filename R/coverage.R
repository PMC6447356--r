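## Coverage quantification: per-participant threshold calibration on the
## bare-skin baseline, binary covered/uncovered segmentation of the
## post-application image, and region metrics.
##
## Applied product absorbs UV, so covered skin photographs darker than
## bare skin: a pixel is covered iff its working-channel intensity falls
## below the calibrated threshold mu_base - k * sigma_base.

#' Extract the working single-channel grid from a UV image
#'
#' Grayscale images pass through unchanged. RGB images are interpreted in
#' hue-saturation-value terms via the standard hexcone model and the value
#' channel (`max(R, G, B)`) is returned on the `[0, 255]` scale; an
#' achromatic RGB image therefore maps to its common channel exactly.
#'
#' @param img a [uv_image()].
#' @return Numeric H x W matrix of intensities in `[0, 255]`.
#' @export
working_channel <- function(img) {
  stopifnot(inherits(img, "uv_image"))
  if (img$channel_mode == "gray") return(img$pixels)
  pmax(img$pixels[, , 1L], img$pixels[, , 2L], img$pixels[, , 3L])
}

#' Per-pixel saturation of an RGB UV image
#'
#' Hexcone saturation `(max - min) / max`, defined as 0 where `max = 0`.
#' Used by the optional saturation gate in [segment_coverage()].
#'
#' @inheritParams working_channel
#' @return Numeric H x W matrix in `[0, 1]`.
#' @export
saturation_channel <- function(img) {
  stopifnot(inherits(img, "uv_image"))
  if (img$channel_mode == "gray") return(array(0, dim(img$pixels)))
  v <- pmax(img$pixels[, , 1L], img$pixels[, , 2L], img$pixels[, , 3L])
  mn <- pmin(img$pixels[, , 1L], img$pixels[, , 2L], img$pixels[, , 3L])
  s <- (v - mn) / v
  s[v == 0] <- 0
  s
}

#' Calibrate the covered/uncovered threshold from a baseline image
#'
#' Computes the mean and SD of baseline face intensity and sets the
#' threshold at `max(mu - k * sigma, floor)`. Calibrating per participant
#' absorbs skin-tone differences (darker baseline skin gets a lower
#' threshold), which a single global threshold cannot.
#'
#' @param baseline baseline (bare skin) [uv_image()].
#' @param face logical face mask.
#' @param k SD multiplier; default 3 puts the false-covered rate of bare
#'   Gaussian skin at about 0.13%.
#' @param floor minimum admissible threshold (grey levels).
#' @return Object of class `threshold_calibration`: `mu_base`,
#'   `sigma_base`, `k`, `floor`, `threshold`, `dims`, `source`.
#' @export
calibrate_threshold <- function(baseline, face, k = 3, floor = 0) {
  stopifnot(inherits(baseline, "uv_image"), is.logical(face))
  if (!any(face)) stop("empty face mask: cannot calibrate threshold")
  wc <- working_channel(baseline)
  if (!all(dim(face) == dim(wc))) stop("face mask dims do not match image")
  vals <- wc[face]
  mu <- mean(vals)
  sigma <- sd(vals)
  if (!is.finite(sigma)) sigma <- 0
  structure(list(mu_base = mu, sigma_base = sigma, k = k, floor = floor,
                 threshold = max(mu - k * sigma, floor),
                 dims = dim(wc), source = baseline$meta),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration mu=%.2f sigma=%.2f k=%g -> threshold=%.2f>\n",
              x$mu_base, x$sigma_base, x$k, x$threshold))
  invisible(x)
}

#' Flag a baseline image that already carries product
#'
#' Participants sometimes arrive already wearing an SPF product; such a
#' baseline would mis-calibrate the threshold. A provisional global
#' threshold is applied to the baseline and the covered fraction compared
#' with `max_covered`; flagged baselines require an explicit operator
#' override downstream.
#'
#' @param baseline baseline [uv_image()].
#' @param face logical face mask.
#' @param global_threshold provisional grey-level threshold below the
#'   plausible bare-skin range (default 110, under the darkest bare-skin
#'   baseline the generator emulates).
#' @param max_covered tolerated covered fraction (default 0.05).
#' @return List with `flagged` (logical), `covered_fraction`, and the
#'   threshold used.
#' @export
flag_baseline <- function(baseline, face, global_threshold = 110,
                          max_covered = 0.05) {
  stopifnot(inherits(baseline, "uv_image"))
  wc <- working_channel(baseline)
  frac <- mean(wc[face] < global_threshold)
  list(flagged = frac > max_covered, covered_fraction = frac,
       global_threshold = global_threshold)
}

#' Segment a post-application image into covered/uncovered
#'
#' A pixel is covered iff its working-channel intensity is strictly below
#' the calibrated threshold. Optional morphological cleanup follows: a
#' closing of the covered mask with a disc kernel, then removal of covered
#' components smaller than `min_blob` pixels.
#'
#' @param img post-application [uv_image()].
#' @param cal [calibrate_threshold()] result from the same participant.
#' @param min_blob minimum covered component size in pixels (default 5;
#'   1 disables).
#' @param close_radius disc radius for the closing in pixels (default 1;
#'   0 disables).
#' @param sat_band optional length-2 saturation band `[lo, hi]`; when
#'   supplied (RGB images), a pixel must also have hexcone saturation
#'   inside the band to count as covered.
#' @return Object of class `coverage_map`: `mask` (logical, TRUE =
#'   covered), `calibration`, `source`.
#' @export
segment_coverage <- function(img, cal, min_blob = 5L, close_radius = 1L,
                             sat_band = NULL) {
  stopifnot(inherits(img, "uv_image"), inherits(cal, "threshold_calibration"))
  wc <- working_channel(img)
  if (!all(dim(wc) == cal$dims)) {
    stop("image dims do not match the calibration's source image")
  }
  covered <- wc < cal$threshold
  if (!is.null(sat_band)) {
    s <- saturation_channel(img)
    covered <- covered & s >= sat_band[1L] & s <= sat_band[2L]
  }
  if (close_radius > 0) {
    ## at radius 1 the digital disc is the 4-neighbourhood diamond; the
    ## "disc" brush of size 3 would be a full box and over-close
    shape <- if (close_radius == 1) "diamond" else "disc"
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, shape)
    covered <- EBImage::closing(covered * 1, brush) > 0.5
  }
  if (min_blob > 1) {
    lab <- EBImage::bwlabel(covered * 1)
    sizes <- tabulate(as.integer(lab))
    drop <- which(sizes < min_blob)
    if (length(drop)) covered[matrix(as.integer(lab), nrow(covered)) %in% drop] <- FALSE
  }
  structure(list(mask = covered, calibration = cal, source = img$meta),
            class = "coverage_map")
}

#' Percent of a region left uncovered
#'
#' `100 * uncovered pixels in region / region pixels`.
#'
#' @param cov a [segment_coverage()] result.
#' @param region logical region mask.
#' @return Percentage in `[0, 100]`.
#' @export
percent_missed <- function(cov, region) {
  stopifnot(inherits(cov, "coverage_map"), is.logical(region))
  if (!all(dim(region) == dim(cov$mask))) stop("region dims do not match coverage map")
  n <- sum(region)
  if (n == 0L) stop("empty region: percent missed undefined")
  100 * sum(region & !cov$mask) / n
}

#' Binary fully-covered/missed call for a medial canthus
#'
#' The canthus counts as covered iff its covered fraction is at least
#' `tau`; the default 0.95 reads "fully covered" with a small tolerance
#' for stray pixels.
#'
#' @param cov a [segment_coverage()] result.
#' @param canthus logical canthus mask.
#' @param tau covered-fraction cutoff in `[0, 1]`, boundary inclusive.
#' @return `"covered"` or `"missed"`.
#' @export
classify_medial_canthus <- function(cov, canthus, tau = 0.95) {
  stopifnot(inherits(cov, "coverage_map"), is.logical(canthus))
  n <- sum(canthus)
  if (n == 0L) stop("empty canthus mask")
  frac <- sum(canthus & cov$mask) / n
  if (frac >= tau) "covered" else "missed"
}

#' Mean working-channel intensity over a region
#'
#' @param img a [uv_image()].
#' @param region logical region mask.
#' @return Mean grey level.
#' @export
mean_region_intensity <- function(img, region) {
  stopifnot(inherits(img, "uv_image"), is.logical(region))
  wc <- working_channel(img)
  if (!all(dim(region) == dim(wc))) stop("region dims do not match image")
  if (!any(region)) stop("empty region: mean intensity undefined")
  mean(wc[region])
}

#' Darkness increase of the face after product application
#'
#' Mean baseline face intensity minus mean post-application face
#' intensity; positive values mean the face photographed darker after
#' application (more UV absorbed). The baseline mean doubles as the
#' skin-tone covariate.
#'
#' @param baseline,applied [uv_image()]s of the same participant and dims.
#' @param face logical face mask.
#' @return List with `change` (grey levels) and `baseline_mean`.
#' @export
darkness_change <- function(baseline, applied, face) {
  if (!all(dim(working_channel(baseline)) == dim(working_channel(applied)))) {
    stop("baseline and applied image dims differ")
  }
  mu_b <- mean_region_intensity(baseline, face)
  mu_a <- mean_region_intensity(applied, face)
  list(change = mu_b - mu_a, baseline_mean = mu_b)
}

#' Export a coverage map as a 0/255 PNG (255 = covered)
#'
#' @param cov a [segment_coverage()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_png <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_map"))
  write_mask_png(cov$mask, path)
}
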