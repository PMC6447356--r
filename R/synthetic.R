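## Synthetic participant bundles: UV-camera-like images with known
## ground-truth coverage.
##
## The generator emulates what the UV camera sees: bare skin photographs
## at a per-participant base intensity (set by Fitzpatrick skin type) with
## Gaussian pixel noise; applied product attenuates intensity
## multiplicatively by a(mass) = exp(-kappa * mass); application failures
## are contiguous blobs placed inside the face with per-region pixel
## budgets, so every region's true uncovered fraction is controlled to
## well within half a percentage point.

## Default base grey level per Fitzpatrick skin type (8-bit scale).
.skin_type_intensity <- c(I = 200, II = 180, III = 150, IV = 120)

## kappa chosen so that a 100 mg-equivalent application attenuates by ~40%
.default_kappa <- log(1 / 0.6) / 100

#' Attenuation factor of applied product
#'
#' Saturating dose-response `a(mass) = exp(-kappa * mass)`: more applied
#' mass always darkens further, with diminishing returns. The default
#' `kappa` gives ~40% attenuation at 100 mg-equivalent.
#'
#' @param mass applied mass in mg-equivalents (>= 0).
#' @param kappa attenuation rate per mg.
#' @return Multiplicative factor in (0, 1].
#' @export
mass_attenuation <- function(mass, kappa = .default_kappa) {
  stopifnot(mass >= 0)
  exp(-kappa * mass)
}

#' Specification of one synthetic participant
#'
#' @param participant_id identifier string.
#' @param skin_type `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param sex `"male"` or `"female"`.
#' @param age age in years.
#' @param base_intensity bare-skin grey level in `[1, 255]`; defaults by
#'   skin type (I 200, II 180, III 150, IV 120).
#' @param true_missed_fraction named list of per-region uncovered
#'   fractions in `[0, 1]`. Recognised names: `eyelid`, `non_eyelid`,
#'   `canthus`, `face`. If only `face` is given it applies to all regions;
#'   if `canthus` is omitted it inherits the eyelid fraction. May also be
#'   a list of such lists keyed by formulation.
#' @param applied_mass mg-equivalent mass driving the darkening; scalar or
#'   named per formulation.
#' @param noise_sd Gaussian pixel noise SD in grey levels.
#' @param image_dims `c(height, width)`, each >= 64.
#' @param channel_mode `"gray"` (default) or `"rgb"`; RGB adds a fixed
#'   low-saturation cast so the hue-saturation path is exercised.
#' @param kappa attenuation rate; see [mass_attenuation()].
#' @param landmark_jitter_sd per-point landmark jitter in pixels.
#' @return Object of class `participant_spec`.
#' @export
participant_spec <- function(participant_id = "P001",
                             skin_type = "II",
                             sex = "female",
                             age = 30,
                             base_intensity = NULL,
                             true_missed_fraction = list(eyelid = 0.14,
                                                         non_eyelid = 0.095),
                             applied_mass = 100,
                             noise_sd = 2,
                             image_dims = c(192L, 192L),
                             channel_mode = c("gray", "rgb"),
                             kappa = .default_kappa,
                             landmark_jitter_sd = 1) {
  channel_mode <- match.arg(channel_mode)
  skin_type <- match.arg(skin_type, c("I", "II", "III", "IV"))
  sex <- match.arg(sex, c("male", "female"))
  base_intensity <- base_intensity %||% .skin_type_intensity[[skin_type]]
  image_dims <- as.integer(image_dims)
  if (any(image_dims < 64L)) stop("image_dims must each be >= 64")
  if (base_intensity <= 0 || base_intensity > 255) {
    stop("base_intensity must lie in (0, 255]")
  }
  fr <- unlist(true_missed_fraction)
  if (any(fr < 0 | fr > 1)) stop("true_missed_fraction values must lie in [0, 1]")
  if (any(applied_mass < 0)) stop("applied_mass must be >= 0")
  ## covered skin must stay strictly darker than bare skin at any positive mass
  stopifnot(kappa > 0)
  structure(list(participant_id = participant_id, skin_type = skin_type,
                 sex = sex, age = age, base_intensity = base_intensity,
                 true_missed_fraction = true_missed_fraction,
                 applied_mass = applied_mass, noise_sd = noise_sd,
                 image_dims = image_dims, channel_mode = channel_mode,
                 kappa = kappa, landmark_jitter_sd = landmark_jitter_sd),
            class = "participant_spec")
}

## offsets of a digital disc of radius r, ordered centre-outward
.disc_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g$d2 <- g$dx^2 + g$dy^2
  g <- g[g$d2 <= r^2, ]
  g[order(g$d2), c("dx", "dy")]
}

## Atom shapes for blob placement. Each atom is morphologically open
## with respect to the radius-1 diamond (a union of 5-pixel pluses), so
## any union of placed atoms survives the pipeline's default
## morphological cleanup unchanged.
.blob_atoms <- local({
  atoms <- NULL
  function() {
    if (is.null(atoms)) {
      plus <- data.frame(dx = c(0L, 1L, -1L, 0L, 0L),
                         dy = c(0L, 0L, 0L, 1L, -1L))
      atoms <<- list(plus = plus,
                     disc2 = .disc_offsets(2L),
                     disc3 = .disc_offsets(3L))
    }
    atoms
  }
})

## Place exactly `target` uncovered pixels inside the cell mask `region`
## as contiguous open blobs (discs and plus-shaped atoms, overlap used to
## hit the exact count). Atoms must lie inside `region` union the already
## uncovered set, so per-cell pixel budgets are respected. Returns a
## logical mask of the newly placed pixels. Assumes the RNG is already
## seeded by the caller. Targets smaller than the 5-pixel atom cannot be
## placed stably and are skipped.
place_uncovered_blobs <- function(region, target, existing = NULL,
                                  radius_range = c(2L, 3L)) {
  h <- nrow(region); w <- ncol(region)
  U <- matrix(FALSE, h, w)
  if (target <= 0) return(U)
  E <- existing %||% matrix(FALSE, h, w)
  n_avail <- sum(region & !E)
  if (target > n_avail) {
    stop(sprintf("requested %d uncovered pixels but region budget is %d",
                 target, n_avail))
  }
  atoms <- .blob_atoms()
  sizes <- c(plus = 5L, disc2 = 13L, disc3 = 29L)
  use <- c("plus",
           if (radius_range[2L] >= 2L) "disc2",
           if (radius_range[2L] >= 3L) "disc3")
  placed <- 0L
  stalls <- 0L
  cand_pool <- which(region)
  while (placed < target && stalls < 400L) {
    remaining <- target - placed
    types <- use[sizes[use] <= max(remaining, 5L)]
    type <- types[sample.int(length(types), 1L)]
    off <- atoms[[type]]
    centre <- cand_pool[sample.int(length(cand_pool), 1L)]
    cy <- (centre - 1L) %% h
    cx <- (centre - 1L) %/% h
    px <- cx + off$dx; py <- cy + off$dy
    if (any(px < 0 | px >= w | py < 0 | py >= h)) { stalls <- stalls + 1L; next }
    idx <- py + 1L + px * h
    covered_already <- E[idx] | U[idx]
    ## the atom must sit inside the cell (or on already-uncovered ground)
    if (!all(region[idx] | covered_already)) { stalls <- stalls + 1L; next }
    new <- idx[!covered_already]
    if (length(new) == 0L || length(new) > remaining) { stalls <- stalls + 1L; next }
    U[new] <- TRUE
    placed <- placed + length(new)
    stalls <- 0L
  }
  ## a stalled placement (fragmented space) leaves a small shortfall; the
  ## caller's smoothing loop tolerates it
  U
}

## Resolve the per-region fraction map for one formulation.
.resolve_fractions <- function(fr) {
  if (!is.null(fr$eyelid) || !is.null(fr$non_eyelid)) {
    f_e <- fr$eyelid %||% fr$face %||% 0
    f_n <- fr$non_eyelid %||% fr$face %||% 0
  } else if (!is.null(fr$face)) {
    f_e <- fr$face; f_n <- fr$face
  } else {
    f_e <- 0; f_n <- 0
  }
  list(eyelid = f_e, non_eyelid = f_n, canthus = fr$canthus %||% f_e)
}

## count of uncovered 4-neighbours per pixel
.neighbour_count <- function(U) {
  h <- nrow(U); w <- ncol(U)
  nb <- matrix(0L, h, w)
  nb[-1, ] <- nb[-1, ] + U[-h, ]
  nb[-h, ] <- nb[-h, ] + U[-1, ]
  nb[, -1] <- nb[, -1] + U[, -w]
  nb[, -w] <- nb[, -w] + U[, -1]
  nb
}

## add k uncovered pixels inside `cell`, preferring pixels flush against
## existing blobs; used to settle the last pixel or two of a budget that
## the open atoms cannot reach exactly
.grow_uncovered <- function(U, cell, k) {
  for (i in seq_len(max(k, 0L))) {
    nb <- .neighbour_count(U)
    cand <- which(cell & !U & nb >= 2L)
    if (!length(cand)) cand <- which(cell & !U & nb >= 1L)
    if (!length(cand)) cand <- which(cell & !U)
    if (!length(cand)) break
    U[cand[sample.int(length(cand), 1L)]] <- TRUE
  }
  U
}

## Remove uncovered pixels that a radius-1 (diamond) closing of the
## covered mask would fill: real application gaps are smooth at the
## 1-pixel scale, and a truth mask that is stable under the pipeline's
## default cleanup keeps the ground truth and the measurement aligned.
.smooth_uncovered <- function(U, face) {
  covered <- (face & !U) * 1
  closed <- EBImage::closing(covered, EBImage::makeBrush(3L, "diamond")) > 0.5
  face & !closed
}

## Build the ground-truth uncovered mask for one formulation. The face is
## partitioned into four cells (canthus-in-eyelid, canthus-in-non-eyelid,
## eyelid remainder, non-eyelid remainder) with pixel budgets chosen so
## the canthus, eyelid, and non-eyelid uncovered fractions each hit their
## targets to the pixel; the canthus budget is split across its two
## overlap cells within the surrounding regions' budgets. Placement and
## smoothing iterate until the budgets are met by a morphologically
## stable mask.
.truth_uncovered <- function(regions, fractions) {
  f <- .resolve_fractions(fractions)
  m <- regions$masks
  face <- m$face
  canthus <- (m$canthus_left | m$canthus_right) & face
  cE <- canthus & m$eyelid
  cN <- canthus & m$non_eyelid
  t_c <- round(f$canthus * sum(canthus))
  budget_e <- round(f$eyelid * sum(m$eyelid))
  budget_n <- round(f$non_eyelid * sum(m$non_eyelid))
  ## split the canthus budget across its overlap cells, proportional to
  ## cell size but capped by cell size and the surrounding region budget
  cap_e <- min(sum(cE), budget_e)
  cap_n <- min(sum(cN), budget_n)
  if (t_c > cap_e + cap_n) {
    stop("infeasible missed fractions: canthus blobs exceed the eyelid budget")
  }
  U <- matrix(FALSE, nrow(face), ncol(face))
  if (budget_e >= sum(cE) && budget_n >= sum(cN)) {
    ## budgets do not bind inside the canthus: place on the whole union
    ## so blobs stay chunky across the eyelid-box edge
    U <- if (t_c >= sum(canthus)) canthus else
      place_uncovered_blobs(canthus, t_c, radius_range = c(2L, 3L))
    cells <- list(canthus = canthus,
                  eyelid = m$eyelid & !canthus,
                  non_eyelid = m$non_eyelid & !canthus)
    radii <- list(canthus = c(2L, 3L), eyelid = c(3L, 6L),
                  non_eyelid = c(3L, 6L))
    goal <- c(canthus = t_c,
              eyelid = min(budget_e - sum(U & cE), sum(cells$eyelid)),
              non_eyelid = min(budget_n - sum(U & cN), sum(cells$non_eyelid)))
  } else {
    ## budget-bound: allocate the canthus across its overlap cells,
    ## proportional to cell size but capped by the region budgets
    t_cE <- min(cap_e, round(t_c * sum(cE) / max(sum(canthus), 1L)))
    t_cN <- t_c - t_cE
    if (t_cN > cap_n) { t_cE <- t_cE + (t_cN - cap_n); t_cN <- cap_n }
    cells <- list(canthus_e = cE, canthus_n = cN,
                  eyelid = m$eyelid & !canthus,
                  non_eyelid = m$non_eyelid & !canthus)
    radii <- list(canthus_e = c(2L, 3L), canthus_n = c(2L, 3L),
                  eyelid = c(3L, 6L), non_eyelid = c(3L, 6L))
    goal <- c(canthus_e = t_cE, canthus_n = t_cN,
              eyelid = min(budget_e - t_cE, sum(cells$eyelid)),
              non_eyelid = min(budget_n - t_cN, sum(cells$non_eyelid)))
  }
  if (any(goal < 0)) {
    stop("infeasible missed fractions: canthus blobs exceed the non-eyelid budget")
  }
  for (cl in setdiff(names(cells), c("canthus"))) {
    U <- if (goal[[cl]] >= sum(cells[[cl]] & !U)) U | cells[[cl]] else
      U | place_uncovered_blobs(cells[[cl]], goal[[cl]], existing = U,
                                radius_range = radii[[cl]])
  }
  U2 <- U
  for (iter in 1:25) {
    U2 <- .smooth_uncovered(U, face)
    deficit <- vapply(names(cells), function(cl) {
      goal[[cl]] - sum(U2 & cells[[cl]])
    }, numeric(1))
    if (all(deficit == 0)) return(U2)
    if (all(deficit <= 2) || iter >= 25) {
      ## residuals the open atoms cannot express (counts of 1-4 or 6-7
      ## per cell) are settled as boundary nubs; they keep the recorded
      ## truth budget exact at the cost of a pixel or two that the
      ## measurement's cleanup may not see
      for (cl in names(cells)) {
        if (deficit[[cl]] > 0) {
          U2 <- .grow_uncovered(U2, cells[[cl]], deficit[[cl]])
        }
      }
      return(U2)
    }
    for (cl in names(cells)) {
      if (deficit[[cl]] > 0) {
        U2 <- U2 | place_uncovered_blobs(cells[[cl]], deficit[[cl]],
                                         existing = U2,
                                         radius_range = radii[[cl]])
      }
    }
    U <- U2
  }
  U2
}

## grayscale grid -> uv_image in the requested channel mode; the RGB cast
## keeps the value channel equal to the gray grid (max channel factor 1)
.as_mode <- function(gray, mode, meta) {
  if (mode == "gray") return(uv_image(gray, meta = meta))
  cast <- c(1, 0.95, 0.85)
  px <- array(0, c(dim(gray), 3L))
  for (ch in 1:3) px[, , ch] <- round(gray * cast[ch])
  uv_image(px, meta = meta)
}

#' Generate a synthetic participant bundle
#'
#' Produces a baseline image, one post-application image per formulation,
#' the landmark set, the exact ground-truth coverage masks, and the
#' derived regions. Uncovered pixels are contiguous blobs whose per-region
#' pixel budgets equal the requested missed fractions; covered pixels of
#' the applied image are the baseline pixels attenuated by
#' [mass_attenuation()], uncovered pixels are untouched baseline.
#'
#' @param spec a [participant_spec()].
#' @param seed integer seed; the bundle is a pure function of
#'   `(spec, seed)`.
#' @param formulations character vector of formulation names.
#' @param region_margins a [region_params()] used for the ground-truth
#'   geometry.
#' @return Object of class `participant_bundle`: `baseline`,
#'   `applied` (named list of [uv_image()]), `truth_covered` (named list
#'   of logical masks, TRUE = covered), `landmarks`, `regions`, `spec`,
#'   `seed`.
#' @export
generate_participant <- function(spec, seed = 1L,
                                 formulations = c("sunscreen", "moisturiser"),
                                 region_margins = region_params()) {
  stopifnot(inherits(spec, "participant_spec"))
  withr::with_seed(seed, {
    h <- spec$image_dims[1L]; w <- spec$image_dims[2L]
    lm <- generate_landmark_template(spec$image_dims,
                                     jitter_sd = spec$landmark_jitter_sd)
    regions <- regions_from_landmarks(lm, region_margins)
    base_gray <- matrix(spec$base_intensity, h, w)
    if (spec$noise_sd > 0) {
      base_gray <- base_gray + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
    }
    base_gray <- pmin(pmax(round(base_gray), 0), 255)
    baseline <- .as_mode(base_gray, spec$channel_mode,
                         list(participant = spec$participant_id,
                              condition = "baseline"))
    per_form <- !is.null(names(spec$true_missed_fraction)) &&
      all(names(spec$true_missed_fraction) %in% formulations) &&
      is.list(spec$true_missed_fraction[[1L]])
    applied <- list(); truth <- list()
    for (f in formulations) {
      fr <- if (per_form) spec$true_missed_fraction[[f]] else spec$true_missed_fraction
      mass <- if (length(spec$applied_mass) > 1L) spec$applied_mass[[f]] else spec$applied_mass
      U <- .truth_uncovered(regions, fr)
      covered <- regions$masks$face & !U
      a <- mass_attenuation(mass, spec$kappa)
      gray <- base_gray
      gray[covered] <- pmin(pmax(round(base_gray[covered] * a), 0), 255)
      applied[[f]] <- .as_mode(gray, spec$channel_mode,
                               list(participant = spec$participant_id,
                                    condition = f))
      truth[[f]] <- covered
    }
    structure(list(baseline = baseline, applied = applied,
                   truth_covered = truth, landmarks = lm, regions = regions,
                   spec = spec, seed = seed),
              class = "participant_bundle")
  })
}

#' @export
print.participant_bundle <- function(x, ...) {
  cat(sprintf("<participant_bundle %s: %s, formulations %s>\n",
              x$spec$participant_id,
              paste(x$spec$image_dims, collapse = "x"),
              paste(names(x$applied), collapse = ", ")))
  invisible(x)
}

#' True uncovered fraction of a bundle's region
#'
#' Convenience accessor used by recovery tests: the ground-truth percent
#' missed of a named region for one formulation.
#'
#' @param bundle a [generate_participant()] result.
#' @param formulation formulation name.
#' @param region region name in the bundle's region set.
#' @return Percentage in `[0, 100]`.
#' @export
truth_percent_missed <- function(bundle, formulation, region) {
  m <- bundle$regions$masks[[region]]
  covered <- bundle$truth_covered[[formulation]]
  100 * sum(m & !covered) / sum(m)
}

#' Generate dose-response records
#'
#' Simulates the half-face mass-series experiment: each participant
#' applies one formulation per face half at each mass, and the mean grey
#' level of that half is recorded. Mean intensity follows a straight line
#' `intercept + slope * mass` plus Gaussian noise, which is the model the
#' downstream regression fits.
#'
#' @param n_participants number of participants (default 4).
#' @param masses applied masses in mg (default 50, 100, 250).
#' @param intercept bare-skin mean grey level.
#' @param slopes named per-formulation slopes (grey levels per mg).
#' @param noise_sd residual SD in grey levels.
#' @param seed integer seed.
#' @return Data frame with columns `participant`, `side`, `formulation`,
#'   `mass`, `mean_intensity`.
#' @export
generate_dose_response <- function(n_participants = 4L,
                                   masses = c(50, 100, 250),
                                   intercept = 180,
                                   slopes = c(sunscreen = -0.2,
                                              moisturiser = -0.3),
                                   noise_sd = 1,
                                   seed = 1L) {
  stopifnot(n_participants >= 1, length(masses) >= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_participants)) {
      ## counterbalance which side gets sunscreen
      sides <- if (i %% 2L == 1L) c(sunscreen = "left", moisturiser = "right")
               else c(sunscreen = "right", moisturiser = "left")
      for (f in names(slopes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = sprintf("D%02d", i),
          side = unname(sides[[f]]),
          formulation = f,
          mass = masses,
          mean_intensity = intercept + slopes[[f]] * masses +
            rnorm(length(masses), sd = noise_sd))
      }
    }
    do.call(rbind, rows)
  })
}
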