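test_that("population tables are deterministic and carry the study structure", {
  pop <- cached_population(seed = 11)
  expect_identical(pop, generate_population(population_spec(seed = 11)))
  expect_equal(length(unique(pop$participant)), 84)
  expect_setequal(unique(pop$formulation), c("sunscreen", "moisturiser"))
  expect_setequal(unique(pop$region), c("face", "eyelid", "non_eyelid"))
  expect_true(all(pop$percent_missed >= 0 & pop$percent_missed <= 100))

  demo <- unique(pop[, c("participant", "sex", "order", "skin_type",
                         "skin_group")])
  expect_equal(sum(demo$order == "sunscreen"), 60)
  expect_equal(sum(demo$order == "moisturiser"), 24)
  expect_equal(sum(demo$sex == "male"), 22)
  expect_equal(sum(demo$sex == "female"), 62)
  expect_identical(as.character(skin_group(demo$skin_type)),
                   as.character(demo$skin_group))
})

test_that("degenerate SDs collapse every draw onto the generating means", {
  tiny <- lapply(uvcover:::.default_region_sds,
                 function(x) setNames(rep(1e-9, 2), names(x)))
  pop <- generate_population(population_spec(
    region_sds = tiny, sex_effect = 0, skin_type_effect = 0, seed = 3))
  means <- uvcover:::.default_region_means
  for (region in names(means)) {
    for (f in c("sunscreen", "moisturiser")) {
      vals <- pop$percent_missed[pop$region == region & pop$formulation == f]
      expect_equal(vals, rep(means[[region]][[f]], length(vals)),
                   tolerance = 1e-6)
    }
  }
})

test_that("sampled region means and SDs track the generating parameters", {
  pop <- cached_population(seed = 11)
  means <- uvcover:::.default_region_means
  sds <- uvcover:::.default_region_sds
  for (region in names(means)) {
    for (f in c("sunscreen", "moisturiser")) {
      vals <- pop$percent_missed[pop$region == region & pop$formulation == f]
      se <- sds[[region]][[f]] / sqrt(length(vals))
      expect_lt(abs(mean(vals) - means[[region]][[f]]), 3.5 * se)
      expect_lt(abs(sd(vals) / sds[[region]][[f]] - 1), 0.35)
    }
  }
  ## within-participant correlation near rho = 0.5
  face <- pop[pop$region == "face", ]
  wide <- merge(face[face$formulation == "sunscreen",
                     c("participant", "percent_missed")],
                face[face$formulation == "moisturiser",
                     c("participant", "percent_missed")],
                by = "participant")
  expect_lt(abs(cor(wide[[2]], wide[[3]]) - 0.5), 0.3)
})

test_that("replicate sample means stay inside their own 99% confidence intervals", {
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    pop <- generate_population(population_spec(seed = 1000 + s))
    vals <- pop$percent_missed[pop$region == "face" &
                                 pop$formulation == "moisturiser"]
    half <- qt(0.995, length(vals) - 1) * sd(vals) / sqrt(length(vals))
    if (abs(mean(vals) - 16.6) <= half) hits <- hits + 1L
  }
  ## nominal coverage 99%; clamping at 0 costs < 0.05 pp of mean
  expect_gte(hits, 95L)
})

test_that("population_spec validates its inputs", {
  expect_error(population_spec(n_participants = 1), ">= 2")
  expect_error(population_spec(rho = 1.5), "rho")
  bad_sds <- uvcover:::.default_region_sds
  bad_sds$face["sunscreen"] <- 0
  expect_error(population_spec(region_sds = bad_sds), "> 0")
  expect_error(population_spec(order_counts = c(sunscreen = 10, moisturiser = 10)),
               "sum")
})
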