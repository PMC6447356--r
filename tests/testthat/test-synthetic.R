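test_that("participant generation is a pure function of spec and seed", {
  spec <- participant_spec(true_missed_fraction = list(eyelid = 0.2,
                                                       non_eyelid = 0.1))
  a <- generate_participant(spec, seed = 3)
  b <- generate_participant(spec, seed = 3)
  expect_identical(a$baseline$pixels, b$baseline$pixels)
  expect_identical(a$applied$sunscreen$pixels, b$applied$sunscreen$pixels)
  expect_identical(a$truth_covered, b$truth_covered)
  c_ <- generate_participant(spec, seed = 4)
  expect_false(identical(a$truth_covered$sunscreen, c_$truth_covered$sunscreen))
})

test_that("zero missed fraction covers the whole face; full miss leaves the baseline untouched", {
  spec0 <- participant_spec(true_missed_fraction = list(eyelid = 0,
                                                        non_eyelid = 0),
                            noise_sd = 0, image_dims = c(128, 128))
  b0 <- generate_participant(spec0, seed = 1)
  face <- b0$regions$masks$face
  expect_true(all(b0$truth_covered$sunscreen[face]))
  ## uniformly darkened: every face pixel strictly below baseline
  expect_true(all(b0$applied$sunscreen$pixels[face] <
                    b0$baseline$pixels[face]))

  spec1 <- participant_spec(true_missed_fraction = list(eyelid = 1,
                                                        non_eyelid = 1,
                                                        canthus = 1),
                            noise_sd = 0, image_dims = c(128, 128))
  b1 <- generate_participant(spec1, seed = 1)
  expect_identical(b1$applied$sunscreen$pixels, b1$baseline$pixels)
  expect_false(any(b1$truth_covered$sunscreen[b1$regions$masks$face]))
})

test_that("truth masks hit the requested per-region fractions within half a point", {
  for (f in c(0.05, 0.15, 0.30)) {
    b <- cached_bundle(f = f, seed = 20 + round(100 * f), dims = c(192L, 192L))
    for (region in c("eyelid", "non_eyelid", "face")) {
      expect_lt(abs(truth_percent_missed(b, "sunscreen", region) - 100 * f),
                0.5)
    }
    ## the canthus budget is controlled on the union of the two boxes
    cu <- b$regions$masks$canthus_left | b$regions$masks$canthus_right
    frac <- 100 * sum(cu & !b$truth_covered$sunscreen) / sum(cu)
    expect_lt(abs(frac - 100 * f), 0.5)
  }
})

test_that("covered-pixel intensity decreases strictly with applied mass", {
  means <- sapply(c(50, 100, 250), function(mass) {
    spec <- participant_spec(true_missed_fraction = list(eyelid = 0.1,
                                                         non_eyelid = 0.1),
                             applied_mass = mass, image_dims = c(128, 128))
    b <- generate_participant(spec, seed = 5)
    cov <- b$truth_covered$sunscreen
    mean(b$applied$sunscreen$pixels[cov])
  })
  expect_true(all(diff(means) < 0))
  ## attenuation is saturating and monotone
  expect_true(all(diff(mass_attenuation(c(0, 50, 100, 250))) < 0))
  expect_equal(mass_attenuation(0), 1)
})

test_that("infeasible region budgets raise a generation error", {
  spec <- participant_spec(true_missed_fraction = list(eyelid = 0.0,
                                                       canthus = 0.9),
                           image_dims = c(128, 128))
  expect_error(generate_participant(spec, seed = 1), "infeasible")
  expect_error(participant_spec(true_missed_fraction = list(eyelid = 1.2)),
               "\\[0, 1\\]")
  expect_error(participant_spec(image_dims = c(32, 128)), ">= 64")
})

test_that("fixture sets round-trip losslessly", {
  dir <- withr::local_tempdir()
  bundles <- list(cached_bundle(seed = 31), cached_bundle(f = 0.05, seed = 32))
  bundles[[2]]$spec$participant_id <- "P002"
  manifest <- write_fixture_set(bundles, dir)
  ## one row per file: baseline, 2x applied, 2x truth, landmarks, spec
  expect_equal(nrow(manifest), 2 * 7)
  expect_equal(length(unique(manifest$participant_id)), 2)

  back <- read_fixture_set(dir)
  expect_named(back, c("P001", "P002"))
  b <- bundles[[1]]; r <- back$P001
  expect_identical(r$baseline$pixels, b$baseline$pixels)
  expect_identical(r$applied$moisturiser$pixels, b$applied$moisturiser$pixels)
  expect_identical(r$truth_covered$sunscreen, b$truth_covered$sunscreen)
  expect_equal(r$landmarks$points, b$landmarks$points, tolerance = 0.005)
})

test_that("dose-response records are deterministic with the expected design", {
  rec <- generate_dose_response(seed = 2)
  expect_identical(rec, generate_dose_response(seed = 2))
  expect_equal(nrow(rec), 4 * 2 * 3)
  expect_setequal(unique(rec$mass), c(50, 100, 250))
  ## each participant applies each formulation to exactly one side
  sides <- tapply(rec$side, interaction(rec$participant, rec$formulation),
                  function(s) length(unique(s)))
  expect_true(all(sides == 1))
  noiseless <- generate_dose_response(noise_sd = 0, seed = 1)
  fit <- lm(mean_intensity ~ mass, data = noiseless,
            subset = formulation == "sunscreen")
  expect_equal(unname(coef(fit)[2]), -0.2, tolerance = 1e-9)
})
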