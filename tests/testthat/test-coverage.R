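test_that("threshold calibration follows mu - k sigma with a floor", {
  face <- matrix(TRUE, 64, 64)
  uniform <- uv_image(matrix(180, 64, 64))
  cal <- calibrate_threshold(uniform, face)
  expect_equal(cal$threshold, 180)
  expect_equal(cal$sigma_base, 0)

  cal_floor <- calibrate_threshold(uniform, face, k = 3, floor = 200)
  expect_equal(cal_floor$threshold, 200)

  expect_error(calibrate_threshold(uniform, matrix(FALSE, 64, 64)), "empty")

  ## known mean/SD sample: mu 180, sigma 5, k 3 -> threshold 165
  vals <- c(175, 185)  # population sd 5 when expanded evenly
  px <- matrix(rep(vals, each = 2048), 64, 64)
  img <- uv_image(px)
  cal2 <- calibrate_threshold(img, face, k = 3)
  expect_equal(cal2$mu_base, 180)
  expect_equal(cal2$threshold, 180 - 3 * sd(px), tolerance = 1e-12)
  expect_equal(cal2$threshold, 165, tolerance = 0.01)
})

test_that("bare skin segmented against its own calibration shows the normal tail rate", {
  spec <- participant_spec(true_missed_fraction = list(eyelid = 0,
                                                       non_eyelid = 0),
                           noise_sd = 5, base_intensity = 180,
                           image_dims = c(192, 192))
  b <- generate_participant(spec, seed = 17)
  face <- b$regions$masks$face
  cal <- calibrate_threshold(b$baseline, face, k = 3)
  cov <- segment_coverage(b$baseline, cal, min_blob = 1, close_radius = 0)
  rate <- mean(cov$mask[face])
  ## pnorm(-3) = 0.00135; ~25k face pixels (binomial SE ~ 2.3e-4), wide band
  expect_gt(rate, 0.0004)
  expect_lt(rate, 0.0030)
  ## with the default small-component cleanup the rate collapses to ~0
  cov2 <- segment_coverage(b$baseline, cal)
  expect_lt(mean(cov2$mask[face]), 5e-4)
})

test_that("working channel passes gray through and takes the HSV value of RGB", {
  g <- matrix(seq(0, 255, length.out = 96 * 96), 96, 96)
  expect_identical(working_channel(uv_image(g)), g)

  v <- round(g)
  ach <- array(rep(v, 3), c(96, 96, 3))
  expect_equal(working_channel(uv_image(ach)), v)

  ## fixed low-saturation cast against the reference HSV conversion
  cast <- array(0, c(8, 8, 3))
  base <- matrix(seq(40, 250, length.out = 64), 8, 8)
  cast[, , 1] <- round(base); cast[, , 2] <- round(base * 0.95)
  cast[, , 3] <- round(base * 0.85)
  img <- uv_image(cast)
  wc <- working_channel(img)
  sat <- saturation_channel(img)
  for (i in 1:8) for (j in 1:8) {
    ref <- grDevices::rgb2hsv(cast[i, j, 1], cast[i, j, 2], cast[i, j, 3],
                              maxColorValue = 255)
    expect_equal(wc[i, j], 255 * ref["v", 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sat[i, j], ref["s", 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(uv_image(array(0, c(8, 8, 2))), "channel")
})

test_that("strong half-face contrast is segmented exactly", {
  lm <- generate_landmark_template(c(128, 128))
  rs <- regions_from_landmarks(lm)
  face <- rs$masks$face
  halves <- split_face_halves(lm, face)
  base <- uv_image(matrix(180, 128, 128))
  cal <- calibrate_threshold(base, face)   # sigma 0 -> threshold 180
  px <- matrix(180, 128, 128)
  px[halves$left] <- 100                    # >> 10 sigma of contrast
  cov <- segment_coverage(uv_image(px), cal)
  expect_identical(cov$mask & face, halves$left)
})

test_that("percent_missed is exact pixel counting", {
  region <- matrix(FALSE, 40, 40); region[1:25, 1:40] <- TRUE  # 1000 px
  mask <- matrix(TRUE, 40, 40)
  unc <- which(region)[1:166]
  mask[unc] <- FALSE
  cov <- structure(list(mask = mask), class = "coverage_map")
  expect_equal(percent_missed(cov, region), 16.6)
  expect_equal(percent_missed(structure(list(mask = region | TRUE),
                                        class = "coverage_map"), region), 0)
  expect_error(percent_missed(cov, matrix(FALSE, 40, 40)), "empty")

  ## covering any uncovered pixel never increases percent missed
  set.seed(42)
  for (i in 1:20) {
    m1 <- matrix(runif(1600) < 0.6, 40, 40)
    flip <- which(!m1)[sample.int(sum(!m1), 5)]
    m2 <- m1; m2[flip] <- TRUE
    c1 <- structure(list(mask = m1), class = "coverage_map")
    c2 <- structure(list(mask = m2), class = "coverage_map")
    expect_lte(percent_missed(c2, region), percent_missed(c1, region))
  }
})

test_that("region metrics match brute-force pixel loops", {
  set.seed(7)
  for (i in 1:5) {
    h <- sample(24:64, 1); w <- sample(24:64, 1)
    px <- matrix(round(runif(h * w, 0, 255)), h, w)
    region <- matrix(runif(h * w) < 0.4, h, w)
    region[1, 1] <- TRUE
    covered <- matrix(runif(h * w) < 0.7, h, w)
    cov <- structure(list(mask = covered), class = "coverage_map")
    expect_equal(percent_missed(cov, region),
                 oracle_percent_missed(covered, region))
    expect_equal(mean_region_intensity(uv_image(px), region),
                 oracle_mean_intensity(px, region))
  }
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  px2 <- matrix(10, 10, 10); px2[, 6:10] <- 20
  expect_equal(mean_region_intensity(uv_image(px2), matrix(TRUE, 10, 10)), 15)
})

test_that("medial canthus classification uses an inclusive threshold", {
  canthus <- matrix(FALSE, 20, 20); canthus[1:4, 1:5] <- TRUE  # 20 px
  full <- structure(list(mask = matrix(TRUE, 20, 20)), class = "coverage_map")
  none <- structure(list(mask = matrix(FALSE, 20, 20)), class = "coverage_map")
  expect_identical(classify_medial_canthus(full, canthus), "covered")
  expect_identical(classify_medial_canthus(none, canthus), "missed")
  m19 <- matrix(TRUE, 20, 20); m19[1, 1] <- FALSE  # 19/20 = 0.95 exactly
  cov19 <- structure(list(mask = m19), class = "coverage_map")
  expect_identical(classify_medial_canthus(cov19, canthus, tau = 0.95),
                   "covered")
  expect_identical(classify_medial_canthus(cov19, canthus, tau = 0.96),
                   "missed")
  expect_error(classify_medial_canthus(full, matrix(FALSE, 20, 20)), "empty")
})

test_that("darkness change matches the generator's closed form", {
  same <- uv_image(matrix(120, 64, 64))
  face <- matrix(TRUE, 64, 64)
  expect_equal(darkness_change(same, same, face)$change, 0)

  ## noiseless full coverage at attenuation 0.8: change = 0.2 * base
  kappa <- uvcover:::.default_kappa
  spec <- participant_spec(true_missed_fraction = list(eyelid = 0,
                                                       non_eyelid = 0),
                           noise_sd = 0, base_intensity = 180,
                           applied_mass = log(1.25) / kappa,
                           image_dims = c(128, 128))
  b <- generate_participant(spec, seed = 1)
  dc <- darkness_change(b$baseline, b$applied$sunscreen,
                        b$regions$masks$face)
  expect_equal(dc$change, 0.2 * 180, tolerance = 1e-9)
  expect_equal(dc$baseline_mean, 180)
  expect_error(darkness_change(same, uv_image(matrix(1, 32, 32)), face),
               "dims")
})

test_that("face percent missed is the pixel-weighted mean of its parts", {
  b <- cached_bundle()
  cal <- calibrate_threshold(b$baseline, b$regions$masks$face)
  cov <- segment_coverage(b$applied$moisturiser, cal)
  m <- b$regions$masks
  a_e <- sum(m$eyelid); a_n <- sum(m$non_eyelid)
  lhs <- percent_missed(cov, m$face)
  rhs <- (a_e * percent_missed(cov, m$eyelid) +
            a_n * percent_missed(cov, m$non_eyelid)) / (a_e + a_n)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("darkness change grows with applied mass at fixed coverage", {
  changes <- sapply(c(50, 100, 250), function(mass) {
    spec <- participant_spec(true_missed_fraction = list(eyelid = 0.1,
                                                         non_eyelid = 0.1),
                             applied_mass = mass, noise_sd = 0,
                             image_dims = c(128, 128))
    b <- generate_participant(spec, seed = 3)
    darkness_change(b$baseline, b$applied$sunscreen,
                    b$regions$masks$face)$change
  })
  expect_true(all(diff(changes) > 0))
})

test_that("segmentation and truth agree at default generator settings", {
  b <- cached_bundle()
  face <- b$regions$masks$face
  cal <- calibrate_threshold(b$baseline, face)
  cov <- segment_coverage(b$applied$sunscreen, cal)
  agreement <- mean((cov$mask == b$truth_covered$sunscreen)[face])
  expect_gte(agreement, 0.99)
  p <- withr::local_tempfile(fileext = ".png")
  write_coverage_png(cov, p)
  expect_identical(read_mask_png(p), cov$mask)
})

test_that("RGB bundles flow through the hue-saturation path unchanged", {
  b <- cached_bundle(channel_mode = "rgb", seed = 12)
  face <- b$regions$masks$face
  cal <- calibrate_threshold(b$baseline, face)
  cov <- segment_coverage(b$applied$sunscreen, cal,
                          sat_band = c(0, 0.5))
  est <- percent_missed(cov, face)
  expect_lt(abs(est - truth_percent_missed(b, "sunscreen", "face")), 1)
})
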