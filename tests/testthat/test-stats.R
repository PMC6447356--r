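test_that("normality gate keeps normal samples parametric at the nominal rate", {
  set.seed(101)
  paths <- replicate(200, normality_gate(rnorm(84, 10, 3))$path)
  rate <- mean(paths == "parametric")
  ## level-0.05 test: expect ~95% parametric routing
  expect_gt(rate, 0.89)
  expect_lt(rate, 0.995)
})

test_that("lognormal samples are rescued by the log transform", {
  set.seed(102)
  gates <- replicate(50, {
    g <- normality_gate(exp(rnorm(84, 0, 1)))
    paste(g$path, g$transform)
  })
  expect_gt(mean(gates == "transformed log"), 0.5)
})

test_that("degenerate and tiny samples route nonparametric with a warning", {
  expect_warning(g <- normality_gate(rep(5, 10)), "degenerate")
  expect_identical(g$path, "nonparametric")
  expect_warning(g2 <- normality_gate(c(1, 2, 3, 4)), "n < 5")
  expect_identical(g2$path, "nonparametric")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("transforms of non-positive samples record their shift", {
  set.seed(103)
  x <- exp(rnorm(84)) - 2  # skewed, has negatives
  g <- normality_gate(x)
  if (g$path == "transformed") {
    expect_gt(g$shift, 0)
    expect_true(all(x + g$shift > 0))
  }
  succeed()
})

test_that("paired comparison reproduces textbook values", {
  a <- c(5, 5, 5, 5)
  r0 <- paired_compare(a, a, gate = "parametric")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  ## differences -1, 1, -1, -2: mean -0.75, SD 1.2583, t = -1.19, df 3
  a2 <- c(0, 1, 0, 0); b2 <- c(1, 0, 1, 2)
  r <- paired_compare(a2, b2, gate = "parametric")
  expect_equal(r$statistic, -1.1921, tolerance = 1e-4)
  expect_equal(r$df, 3)

  expect_error(paired_compare(1:3, 1:4), "equal length")
  expect_error(paired_compare(1, 2), "n >= 2")
})

test_that("nonparametric fallbacks run the documented tests", {
  set.seed(104)
  a <- rexp(30); b <- rexp(30) + 0.5
  r_mw <- paired_compare(a, b, gate = "nonparametric")
  expect_identical(r_mw$test, "Mann-Whitney U")
  expect_equal(r_mw$statistic,
               unname(suppressWarnings(wilcox.test(a, b, exact = FALSE))$statistic))
  r_sr <- paired_compare(a, b, gate = "nonparametric", fallback = "signed-rank")
  expect_identical(r_sr$test, "Wilcoxon signed-rank")
  expect_true(all(c(r_mw$p_value, r_sr$p_value) >= 0 &
                    c(r_mw$p_value, r_sr$p_value) <= 1))
})

test_that("repeated-measures ANOVA squares the paired t statistic", {
  pop <- cached_population(seed = 11)
  face <- pop[pop$region == "face", ]
  wide <- merge(face[face$formulation == "sunscreen",
                     c("participant", "percent_missed")],
                face[face$formulation == "moisturiser",
                     c("participant", "percent_missed")],
                by = "participant")
  tt <- t.test(wide[[2]], wide[[3]], paired = TRUE)
  ra <- rm_anova(pop, region = "face")
  expect_equal(ra$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(ra$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(ra$df, 1)
  expect_equal(ra$df2, 83)

  flat <- pop
  flat$percent_missed <- 7
  expect_equal(rm_anova(flat, region = "face")$statistic, 0)

  incomplete <- pop[!(pop$participant == "P001" &
                        pop$formulation == "sunscreen"), ]
  expect_error(rm_anova(incomplete, region = "face"), "P001")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0.02, 2), 0.0396, tolerance = 1e-12)
  expect_equal(sidak_alpha(0.05, 2), 0.02532057, tolerance = 1e-6)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 3) >= p))
  expect_true(all(sidak_adjust(p, 3) <= 1))
  expect_equal(sidak_adjust(0.5, 1), 0.5)
})

test_that("subgroup comparison produces ANOVA plus Sidak-adjusted contrasts", {
  pop <- cached_population(seed = 11)
  res <- subgroup_compare(pop, group = "sex", region = "eyelid")
  expect_equal(nrow(res), 3)  # ANOVA + one contrast per formulation
  contrasts <- res[-1, ]
  expect_true(all(contrasts$p_sidak >= contrasts$p_raw))
  expect_true(all(contrasts$p_sidak <= 1))
  expect_equal(contrasts$p_sidak, sidak_adjust(contrasts$p_raw, 2),
               tolerance = 1e-12)
  ## generator puts females ~5 pp above males: ANOVA should notice at n=84
  expect_lt(res$p_value[1], 0.05)

  lone <- data.frame(participant = sprintf("Q%02d", 1:10),
                     formulation = rep(c("sunscreen", "moisturiser"), 5),
                     region = "eyelid",
                     percent_missed = rnorm(10, 15, 5),
                     sex = c("male", rep("female", 9)))
  expect_error(subgroup_compare(lone, group = "sex", region = "eyelid"),
               "fewer than 2")
})

test_that("ANCOVA recovers a planted covariate slope and flags aliasing", {
  set.seed(105)
  n <- 60
  tab <- data.frame(
    participant = sprintf("Q%03d", 1:n),
    formulation = "sunscreen", region = "face",
    sex = sample(c("male", "female"), n, replace = TRUE),
    skin_group = sample(c("I+II", "III+IV"), n, replace = TRUE),
    age = runif(n, 18, 57))
  tab$percent_missed <- 2 * tab$age + rnorm(n, 0, 3)
  res <- ancova_two_factor(tab)
  expect_setequal(res$term, c("sex", "skin_group", "sex:skin_group", "age"))
  ci <- attr(res, "covariate_ci")
  expect_gt(2, ci[1]); expect_lt(2, ci[2])
  expect_lt(res$p_value[res$term == "age"], 0.001)

  res3 <- ancova_two_factor(tab, ss_type = "III")
  expect_setequal(res3$term, c("sex", "skin_group", "sex:skin_group", "age"))

  aliased <- tab
  aliased$skin_group <- "I+II"
  expect_error(ancova_two_factor(aliased), "aliased|contrasts")
})

test_that("ANCOVA keeps its level when the covariate is pure noise", {
  set.seed(106)
  hits <- 0L
  for (i in 1:60) {
    n <- 40
    tab <- data.frame(
      participant = sprintf("Q%03d", 1:n),
      formulation = "sunscreen", region = "face",
      sex = rep(c("male", "female"), n / 2),
      skin_group = rep(c("I+II", "I+II", "III+IV", "III+IV"), n / 4),
      age = runif(n, 18, 57),
      percent_missed = rnorm(n, 15, 5))
    res <- ancova_two_factor(tab)
    if (res$p_value[res$term == "age"] < 0.05) hits <- hits + 1L
  }
  ## binomial(60, 0.05): 3 expected
  expect_lte(hits, 9L)
})

test_that("order-effect check accepts the 60/24 design and flags tiny groups", {
  pop <- cached_population(seed = 11)
  expect_silent(res <- order_effect_check(pop))
  expect_equal(nrow(res), length(unique(pop$region)) * 2)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(is.logical(attr(res, "consistent")))

  one <- data.frame(participant = sprintf("Q%02d", 1:9),
                    formulation = "sunscreen", region = "face",
                    percent_missed = rnorm(9, 15, 5),
                    order = c("moisturiser", rep("sunscreen", 8)))
  expect_error(order_effect_check(one), "n < 2")
  expect_error(order_effect_check(pop[pop$order == "sunscreen", ]), "empty")
})

test_that("order comparison holds its level under the null", {
  set.seed(107)
  hits <- 0L
  for (i in 1:40) {
    tab <- data.frame(
      participant = sprintf("Q%03d", 1:40),
      formulation = "sunscreen", region = "face",
      percent_missed = rnorm(40, 15, 5),
      order = rep(c("sunscreen", "moisturiser"), each = 20))
    res <- order_effect_check(tab)
    if (any(res$p_value < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 8L)  # nominal 2, binomial slack
})

test_that("dose-response regression recovers slopes and degenerates cleanly", {
  exact <- expand.grid(formulation = c("sunscreen", "moisturiser"),
                       mass = c(50, 100, 250),
                       participant = c("D01", "D02"))
  exact$mean_intensity <- 180 - 0.2 * exact$mass
  r <- dose_response_regression(exact)
  expect_equal(unname(r$slopes), c(-0.2, -0.2), tolerance = 1e-9)
  expect_equal(r$result$statistic, 0)
  expect_lt(mean(r$model$residuals^2), 1e-18)

  rec <- generate_dose_response(seed = 9)
  r2 <- dose_response_regression(rec)
  expect_gt(r2$slope_ci["sunscreen", "upper"], -0.2)
  expect_lt(r2$slope_ci["sunscreen", "lower"], -0.2)
  expect_gt(r2$slope_ci["moisturiser", "upper"], -0.3)
  expect_lt(r2$slope_ci["moisturiser", "lower"], -0.3)
  ## clearly different generator slopes: formulation effect detected
  expect_lt(r2$result$p_value, 0.05)

  expect_error(dose_response_regression(rec[rec$formulation == "sunscreen", ]),
               "both formulations")
  expect_error(dose_response_regression(rec[rec$mass == 50 |
                                              rec$formulation == "sunscreen", ]),
               "single mass")
})

test_that("binary tabulation reports counts and a truncated display percent", {
  out <- tabulate_binary(c(rep("missed", 66), rep("covered", 18)))
  expect_equal(out$n_missed, 66)
  expect_equal(out$n_total, 84)
  expect_equal(out$percent, 78)
  expect_equal(out$percent_exact, 100 * 66 / 84)
  expect_equal(tabulate_binary(rep("covered", 10))$percent, 0)
  expect_equal(tabulate_binary(rep("missed", 7))$percent, 100)
  expect_error(tabulate_binary(character(0)), "empty")
  expect_error(tabulate_binary(c("missed", "maybe")), "unknown")
})
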