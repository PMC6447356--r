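## 68-point facial landmarks: container, synthetic template, PTS/JSON IO.
##
## Point semantics follow the standard 68-point annotation scheme
## (1-based): jaw 1-17 (chin = 9), brows 18-27, nose 28-36 (bridge 28-31),
## eyes 37-48 (inner corners 40 and 43), mouth 49-68. Pixel coordinates are
## 0-based, origin top-left, x rightward, y downward.

#' Construct a validated 68-point landmark set
#'
#' @param points numeric 68 x 2 matrix of (x, y) pixel coordinates,
#'   0-based, ordered by the standard 68-point scheme.
#' @param image_dims optional `c(height, width)` of the source image; when
#'   supplied, points are checked to lie inside the image.
#' @return An object of class `landmark_set` with elements `points`
#'   (68 x 2 matrix, columns `x`, `y`) and `image_dims`.
#' @export
landmark_set <- function(points, image_dims = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L) {
    stop(sprintf("expected 68 landmark points, found %d", nrow(points)))
  }
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  colnames(points) <- c("x", "y")
  if (!is.null(image_dims)) {
    image_dims <- as.integer(image_dims)
    stopifnot(length(image_dims) == 2L)
    h <- image_dims[1L]; w <- image_dims[2L]
    bad <- points[, "x"] < 0 | points[, "x"] > w - 1 |
      points[, "y"] < 0 | points[, "y"] > h - 1
    if (any(bad)) {
      stop(sprintf("landmark point(s) %s outside %dx%d image bounds",
                   paste(which(bad), collapse = ", "), h, w))
    }
  }
  ## the eye corners anchor every region; degenerate eyes are unusable
  for (eye in list(c(37L, 40L), c(43L, 46L))) {
    d <- sqrt(sum((points[eye[1L], ] - points[eye[2L], ])^2))
    if (d <= 0) stop("degenerate eye landmarks: zero inter-corner distance")
  }
  structure(list(points = points, image_dims = image_dims),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  dims <- if (is.null(x$image_dims)) "unknown dims" else
    paste(x$image_dims, collapse = "x")
  cat(sprintf("<landmark_set: 68 points, image %s>\n", dims))
  invisible(x)
}

## Normalised symmetric template. Units: fraction of the face scale S;
## u rightward from the midline, v downward from the mid-face.
.landmark_template_uv <- function() {
  theta <- pi * (0:16) / 16
  jaw <- cbind(-0.45 * cos(theta), -0.15 + 0.65 * sin(theta))
  brow_l <- cbind(c(-0.35, -0.29, -0.23, -0.17, -0.11),
                  c(-0.28, -0.31, -0.32, -0.31, -0.29))
  brow_r <- cbind(-rev(brow_l[, 1L]), rev(brow_l[, 2L]))
  nose_bridge <- cbind(rep(0, 4), c(-0.20, -0.13, -0.06, 0.01))
  nostrils <- cbind(c(-0.08, -0.04, 0, 0.04, 0.08),
                    c(0.09, 0.10, 0.11, 0.10, 0.09))
  eye_l <- cbind(c(-0.30, -0.25, -0.17, -0.12, -0.17, -0.25),
                 c(-0.18, -0.21, -0.21, -0.18, -0.15, -0.15))
  ## mirror of the left eye, reordered so 43 is the inner corner
  eye_r <- cbind(-eye_l[c(4L, 3L, 2L, 1L, 6L, 5L), 1L],
                 eye_l[c(4L, 3L, 2L, 1L, 6L, 5L), 2L])
  mouth_outer <- cbind(
    c(-0.15, -0.10, -0.04, 0, 0.04, 0.10, 0.15, 0.10, 0.04, 0, -0.04, -0.10),
    c(0.28, 0.25, 0.24, 0.245, 0.24, 0.25, 0.28, 0.32, 0.34, 0.345, 0.34, 0.32))
  mouth_inner <- cbind(c(-0.12, -0.04, 0, 0.04, 0.12, 0.04, 0, -0.04),
                       c(0.28, 0.27, 0.275, 0.27, 0.28, 0.30, 0.305, 0.30))
  rbind(jaw, brow_l, brow_r, nose_bridge, nostrils, eye_l, eye_r,
        mouth_outer, mouth_inner)
}

#' Generate a synthetic 68-point landmark set for an image
#'
#' Places a bilaterally symmetric 68-point face template inside an image,
#' optionally perturbing each coordinate with Gaussian jitter. This stands
#' in for an external landmark detector so the whole pipeline can run on
#' synthetic photographs.
#'
#' @param image_dims `c(height, width)` in pixels, each >= 64.
#' @param scale face scale as a fraction of `min(image_dims)` in (0, 1];
#'   the template (including forehead extrapolation headroom) fits inside
#'   the image for `scale <= 0.9`; default 0.8.
#' @param jitter_sd per-coordinate Gaussian jitter SD in pixels.
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [landmark_set()].
#' @export
generate_landmark_template <- function(image_dims, scale = 0.8,
                                       jitter_sd = 0, seed = NULL) {
  image_dims <- as.integer(image_dims)
  if (any(image_dims < 64L)) {
    stop(sprintf("image dims %s too small to contain the landmark template (need >= 64x64)",
                 paste(image_dims, collapse = "x")))
  }
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  h <- image_dims[1L]; w <- image_dims[2L]
  S <- scale * min(h, w)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2 - 0.09 * S  # centre the template's vertical extent
  uv <- .landmark_template_uv()
  pts <- cbind(x = cx + uv[, 1L] * S, y = cy + uv[, 2L] * S)
  draw <- function() {
    out <- pts
    if (jitter_sd > 0) {
      out <- out + matrix(rnorm(136L, sd = jitter_sd), ncol = 2L)
      out[, 1L] <- pmin(pmax(out[, 1L], 0), w - 1)
      out[, 2L] <- pmin(pmax(out[, 2L], 0), h - 1)
    }
    out
  }
  pts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (any(pts[, 1L] < 0 | pts[, 1L] > w - 1 | pts[, 2L] < 0 | pts[, 2L] > h - 1)) {
    stop("scaled landmark template does not fit inside the image")
  }
  landmark_set(pts, image_dims = image_dims)
}

## Index map sending each point to its mirror across the template midline.
landmark_mirror_index <- function() {
  m <- integer(68L)
  m[1:17] <- 17:1
  m[18:27] <- 27:18
  m[28:31] <- 28:31
  m[32:36] <- 36:32
  m[37:42] <- c(46L, 45L, 44L, 43L, 48L, 47L)
  m[43:48] <- c(40L, 39L, 38L, 37L, 42L, 41L)
  m[49:60] <- c(55L, 54L, 53L, 52L, 51L, 50L, 49L, 60L, 59L, 58L, 57L, 56L)
  m[61:68] <- c(65L, 64L, 63L, 62L, 61L, 68L, 67L, 66L)
  m
}

#' Write a landmark set to a PTS file
#'
#' Uses the plain-text PTS layout (`version: 1`, `n_points: 68`, points
#' between braces), coordinates with two decimals.
#'
#' @param lm a [landmark_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  lines <- c("version: 1",
             sprintf("n_points:  %d", nrow(lm$points)),
             "{",
             sprintf("%.2f %.2f", lm$points[, "x"], lm$points[, "y"]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a landmark set to JSON
#'
#' @inheritParams write_pts
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  obj <- list(points = unname(apply(lm$points, 1L, as.numeric, simplify = FALSE)))
  if (!is.null(lm$image_dims)) obj$image_dims <- as.integer(lm$image_dims)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a 68-point landmark file
#'
#' @param path file path to a PTS or JSON landmark file.
#' @param format `"auto"` (by extension), `"pts"` or `"json"`.
#' @param image_dims optional `c(height, width)` used for bounds
#'   validation; for JSON files that carry their own `image_dims` it may be
#'   omitted.
#' @return A validated [landmark_set()].
#' @export
load_landmarks <- function(path, format = c("auto", "pts", "json"),
                           image_dims = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "pts"
  }
  if (format == "pts") {
    lines <- trimws(readLines(path, warn = FALSE))
    np_line <- grep("^n_points:", lines, value = TRUE)
    open <- which(lines == "{"); close <- which(lines == "}")
    if (length(open) != 1L || length(close) != 1L || close < open) {
      stop(sprintf("malformed PTS file (missing braces): %s", path))
    }
    body <- lines[(open + 1L):(close - 1L)]
    body <- body[nzchar(body)]
    coords <- do.call(rbind, lapply(strsplit(body, "[[:space:]]+"),
                                    function(p) as.numeric(p[1:2])))
    n_declared <- if (length(np_line)) {
      as.integer(sub("^n_points:[[:space:]]*", "", np_line[1L]))
    } else nrow(coords)
    if (n_declared != 68L || nrow(coords) != 68L) {
      stop(sprintf("expected 68 landmark points, found %d in %s",
                   if (nrow(coords) != 68L) nrow(coords) else n_declared, path))
    }
    landmark_set(coords, image_dims = image_dims)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- if (is.matrix(obj$points)) obj$points else
      do.call(rbind, lapply(obj$points, function(p) as.numeric(p[1:2])))
    dims <- image_dims %||% obj$image_dims
    if (nrow(pts) != 68L) {
      stop(sprintf("expected 68 landmark points, found %d in %s", nrow(pts), path))
    }
    landmark_set(pts, image_dims = dims)
  }
}
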