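## Analysis regions derived from landmarks: face box, eyelid boxes,
## medial-canthus boxes, non-eyelid remainder, and the vertical half-face
## split used for dose-response measurement.
##
## Masks are logical H x W matrices (row = y + 1, col = x + 1). Boxes are
## half-open [x0, x1) x [y0, y1) in 0-based pixel coordinates, so set
## algebra on boxes has no off-by-one ambiguity. "Left"/"right" are
## image-frame, not anatomical.

## round-half-up; used everywhere a float box edge becomes a pixel index
.px <- function(x) floor(x + 0.5)

## logical mask for half-open box, clipped to the image
rect_mask <- function(dims, x0, x1, y0, y1) {
  h <- dims[1L]; w <- dims[2L]
  m <- matrix(FALSE, h, w)
  xa <- max(.px(x0), 0); xb <- min(.px(x1) - 1, w - 1)
  ya <- max(.px(y0), 0); yb <- min(.px(y1) - 1, h - 1)
  if (xb < xa || yb < ya) return(m)
  m[(ya:yb) + 1, (xa:xb) + 1] <- TRUE
  m
}

#' Region-geometry parameters
#'
#' Margins controlling how analysis boxes are derived from landmarks. The
#' source study shows its boxes only graphically, so the geometry is fully
#' parameterised and echoed into the `region_set` provenance.
#'
#' @param forehead_margin multiple of the eye-to-brow distance by which the
#'   face box is extrapolated above the brow top (default 1.0).
#' @param lateral_margin lateral expansion of each eyelid box as a fraction
#'   of that eye's width (default 0.10).
#' @param canthus_frac medial-canthus box side as a fraction of the
#'   inter-inner-corner distance (default 0.6).
#' @param canthus_cap cap on the canthus box side as a fraction of the eye
#'   width (default 0.25).
#' @param nasal_offset shift of the canthus box toward the facial midline,
#'   as a fraction of the canthus box side (default 0.25).
#' @return A named list of class `region_params`.
#' @export
region_params <- function(forehead_margin = 1.0, lateral_margin = 0.10,
                          canthus_frac = 0.6, canthus_cap = 0.25,
                          nasal_offset = 0.25) {
  structure(list(forehead_margin = forehead_margin,
                 lateral_margin = lateral_margin,
                 canthus_frac = canthus_frac,
                 canthus_cap = canthus_cap,
                 nasal_offset = nasal_offset),
            class = "region_params")
}

#' Derive analysis regions from a landmark set
#'
#' Builds the named binary masks used throughout the coverage analysis:
#' `face` (jaw-bounded box extrapolated above the brows), `eyelid_left` /
#' `eyelid_right` (eye bounding boxes expanded up to the brow line and
#' laterally), their union `eyelid`, `canthus_left` / `canthus_right`
#' (squares on the inner eye corners shifted nasally), and `non_eyelid`
#' (face minus eyelid union). Eyelid and canthus masks are clipped to the
#' face so the subset invariants hold by construction.
#'
#' @param lm a [landmark_set()] with known `image_dims`.
#' @param params a [region_params()] list.
#' @return An object of class `region_set`: list with `masks` (named list
#'   of logical matrices), `dims`, and `provenance` (landmark indices and
#'   margins used).
#' @export
regions_from_landmarks <- function(lm, params = region_params()) {
  stopifnot(inherits(lm, "landmark_set"))
  if (is.null(lm$image_dims)) stop("landmark set has no image dims")
  dims <- lm$image_dims
  p <- lm$points

  jaw <- 1:17; chin <- 9L
  brows <- 18:27
  eyes <- list(left = 37:42, right = 43:48)   # image-frame left/right
  inner <- c(left = 40L, right = 43L)
  brow_of <- list(left = 18:22, right = 23:27)

  ## face: lateral jaw extent; top from forehead extrapolation; bottom chin
  eye_to_brow <- mean(p[unlist(eyes), "y"]) - mean(p[brows, "y"])
  if (eye_to_brow <= 0) stop("degenerate eye landmarks: brows not above eyes")
  top <- min(p[brows, "y"]) - params$forehead_margin * eye_to_brow
  face <- rect_mask(dims,
                    x0 = min(p[jaw, "x"]), x1 = max(p[jaw, "x"]) + 1,
                    y0 = top, y1 = p[chin, "y"] + 1)
  if (!any(face)) stop("face region empty after clipping to image")

  mid_x <- mean(p[28:31, "x"])
  eyelid <- list(); canthus <- list()
  for (side in c("left", "right")) {
    e <- p[eyes[[side]], , drop = FALSE]
    ew <- max(e[, "x"]) - min(e[, "x"])
    if (ew <= 0) stop("degenerate eye landmarks: zero eye width")
    lat <- params$lateral_margin * ew
    brow_top <- min(p[brow_of[[side]], "y"])
    eyelid[[side]] <- rect_mask(dims,
                                x0 = min(e[, "x"]) - lat,
                                x1 = max(e[, "x"]) + 1 + lat,
                                y0 = brow_top,
                                y1 = max(e[, "y"]) + 1) & face
    d_inner <- sqrt(sum((p[inner["left"], ] - p[inner["right"], ])^2))
    side_len <- min(params$canthus_frac * d_inner, params$canthus_cap * ew)
    corner <- p[inner[side], ]
    shift <- params$nasal_offset * side_len * sign(mid_x - corner["x"])
    cx <- corner["x"] + shift
    canthus[[side]] <- rect_mask(dims,
                                 x0 = cx - side_len / 2,
                                 x1 = cx + side_len / 2 + 1,
                                 y0 = corner["y"] - side_len / 2,
                                 y1 = corner["y"] + side_len / 2 + 1) & face
  }
  eyelid_union <- eyelid$left | eyelid$right
  masks <- list(face = face,
                eyelid_left = eyelid$left, eyelid_right = eyelid$right,
                eyelid = eyelid_union,
                canthus_left = canthus$left, canthus_right = canthus$right,
                non_eyelid = face & !eyelid_union)
  structure(list(masks = masks, dims = dims,
                 provenance = list(params = unclass(params),
                                   landmarks = list(jaw = jaw, chin = chin,
                                                    brows = brows, eyes = eyes,
                                                    inner_corners = inner),
                                   note = "left/right are image-frame")),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  areas <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<region_set %s>\n", paste(x$dims, collapse = "x")))
  print(areas)
  invisible(x)
}

#' Split the face mask into vertical halves at the nose bridge
#'
#' The midline is the mean x-coordinate of the nose-bridge landmarks
#' (points 28-31). Pixels with x strictly below the midline go left, the
#' rest right, so the two masks partition the face mask exactly.
#'
#' @param lm a [landmark_set()].
#' @param face logical face mask from [regions_from_landmarks()].
#' @return List with logical masks `left` and `right` and the `midline_x`
#'   used.
#' @export
split_face_halves <- function(lm, face) {
  stopifnot(inherits(lm, "landmark_set"), is.logical(face))
  mid_x <- mean(lm$points[28:31, "x"])
  xcoord <- matrix(rep(0:(ncol(face) - 1L), each = nrow(face)), nrow(face))
  left <- face & (xcoord < mid_x)
  list(left = left, right = face & !left, midline_x = mid_x)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Read a 0/255 PNG mask back as a logical matrix
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px >= 0.5
}
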