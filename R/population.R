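## Study-population generator: per-participant paired percent-missed
## draws with the statistical structure the analysis assumes (bivariate
## normal per region with within-participant correlation across
## formulations, additive subgroup shifts, counterbalanced application
## order, binary medial-canthus outcomes).

## Region-wise generating means/SDs (percent missed) per formulation, and
## study-level defaults, taken from the study population the analysis is
## designed for: 84 participants (22 male / 62 female), order groups 60
## sunscreen-first / 24 moisturiser-first.
.default_region_means <- list(
  face       = c(sunscreen = 11.1, moisturiser = 16.6),
  eyelid     = c(sunscreen = 14.0, moisturiser = 20.9),
  non_eyelid = c(sunscreen = 9.5,  moisturiser = 13.6))
.default_region_sds <- list(
  face       = c(sunscreen = 5.0, moisturiser = 6.4),
  eyelid     = c(sunscreen = 8.3, moisturiser = 8.2),
  non_eyelid = c(sunscreen = 5.5, moisturiser = 6.9))

#' Specification of a synthetic study population
#'
#' @param n_participants number of participants (>= 2; default 84).
#' @param region_means named list (per region) of length-2 named vectors
#'   (`sunscreen`, `moisturiser`) of mean percent missed.
#' @param region_sds same shape, SDs of percent missed (> 0).
#' @param rho within-participant correlation between the two
#'   formulations' percent missed, in `[-1, 1]` (default 0.5).
#' @param sex_effect additive shift in percentage points: how much higher
#'   females score than males (default 5, echoing the subgroup analysis);
#'   applied mean-centred so population means are preserved.
#' @param skin_type_effect additive shift: how much higher skin types
#'   I+II score than III+IV (default 8); also mean-centred.
#' @param order_counts named counts of first-visit formulation,
#'   `c(sunscreen = ..., moisturiser = ...)`; default scales the 60/24
#'   split to `n_participants`.
#' @param sex_counts named counts `c(male = ..., female = ...)`; default
#'   scales 22/62.
#' @param skin_type_probs sampling probabilities for skin types I-IV.
#' @param age_range inclusive integer age range.
#' @param canthus_miss_prob probability that a participant misses the
#'   medial canthus on one visit (default 0.78).
#' @param seed integer seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_participants = 84L,
                            region_means = .default_region_means,
                            region_sds = .default_region_sds,
                            rho = 0.5,
                            sex_effect = 5,
                            skin_type_effect = 8,
                            order_counts = NULL,
                            sex_counts = NULL,
                            skin_type_probs = c(I = 0.25, II = 0.45,
                                                III = 0.20, IV = 0.10),
                            age_range = c(18L, 57L),
                            canthus_miss_prob = 0.78,
                            seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L) stop("n_participants must be >= 2")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  stopifnot(identical(sort(names(region_means)), sort(names(region_sds))))
  if (any(unlist(region_sds) <= 0)) stop("region SDs must be > 0")
  order_counts <- order_counts %||%
    c(sunscreen = round(n_participants * 60 / 84),
      moisturiser = n_participants - round(n_participants * 60 / 84))
  sex_counts <- sex_counts %||%
    c(male = round(n_participants * 22 / 84),
      female = n_participants - round(n_participants * 22 / 84))
  if (sum(order_counts) != n_participants || sum(sex_counts) != n_participants) {
    stop("order_counts and sex_counts must each sum to n_participants")
  }
  structure(list(n_participants = n_participants,
                 region_means = region_means, region_sds = region_sds,
                 rho = rho, sex_effect = sex_effect,
                 skin_type_effect = skin_type_effect,
                 order_counts = order_counts, sex_counts = sex_counts,
                 skin_type_probs = skin_type_probs, age_range = age_range,
                 canthus_miss_prob = canthus_miss_prob, seed = seed),
            class = "population_spec")
}

#' Collapse Fitzpatrick skin type to the two analysis groups
#'
#' Types I and II form one group, III and IV the other (the darker-skin
#' group is small, so four levels are collapsed for analysis).
#'
#' @param skin_type character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return Factor with levels `"I+II"`, `"III+IV"`.
#' @export
skin_group <- function(skin_type) {
  factor(ifelse(skin_type %in% c("I", "II"), "I+II", "III+IV"),
         levels = c("I+II", "III+IV"))
}

#' Generate a synthetic study table
#'
#' Draws the long-format ground-truth study table: one row per
#' participant x formulation x region with the true percent missed, plus
#' demographics, application order, and the binary medial-canthus
#' outcome. Per region, the (sunscreen, moisturiser) pair is bivariate
#' normal with the spec's means/SDs and correlation `rho`; draws are
#' clamped to `[0, 100]`. Subgroup effects are added as mean-centred
#' shifts so the marginal means stay at the spec values.
#'
#' @param pop a [population_spec()].
#' @return Long-format `data.frame` with columns `participant`,
#'   `formulation`, `region`, `percent_missed`, `sex`, `skin_type`,
#'   `skin_group`, `age`, `order`, `canthus_missed`, `canthus_frac`.
#' @export
generate_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  n <- pop$n_participants
  withr::with_seed(pop$seed, {
    ids <- sprintf("P%03d", seq_len(n))
    sex <- sample(rep(names(pop$sex_counts), pop$sex_counts))
    skin <- sample(names(pop$skin_type_probs), n, replace = TRUE,
                   prob = pop$skin_type_probs)
    age <- sample(seq(pop$age_range[1L], pop$age_range[2L]), n, replace = TRUE)
    ord <- sample(rep(names(pop$order_counts), pop$order_counts))

    ## mean-centred subgroup shifts (population means preserved)
    n_f <- sum(sex == "female")
    shift_sex <- ifelse(sex == "female",
                        pop$sex_effect * (n - n_f) / n,
                        -pop$sex_effect * n_f / n)
    grp <- as.character(skin_group(skin))
    n_light <- sum(grp == "I+II")
    shift_skin <- ifelse(grp == "I+II",
                         pop$skin_type_effect * (n - n_light) / n,
                         -pop$skin_type_effect * n_light / n)
    shift <- shift_sex + shift_skin

    rows <- list()
    for (region in names(pop$region_means)) {
      mu <- pop$region_means[[region]]
      sdv <- pop$region_sds[[region]]
      Sigma <- matrix(c(sdv[["sunscreen"]]^2,
                        pop$rho * sdv[["sunscreen"]] * sdv[["moisturiser"]],
                        pop$rho * sdv[["sunscreen"]] * sdv[["moisturiser"]],
                        sdv[["moisturiser"]]^2), 2L, 2L)
      draws <- MASS::mvrnorm(n, mu = c(mu[["sunscreen"]], mu[["moisturiser"]]),
                             Sigma = Sigma)
      draws <- draws + shift
      draws <- pmin(pmax(draws, 0), 100)
      for (f in c("sunscreen", "moisturiser")) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = ids, formulation = f, region = region,
          percent_missed = draws[, if (f == "sunscreen") 1L else 2L],
          sex = sex, skin_type = skin,
          skin_group = as.character(skin_group(skin)),
          age = age, order = ord)
      }
    }
    out <- do.call(rbind, rows)

    ## binary canthus outcome per participant x formulation (shared by
    ## both sides: missing the canthus is a bilateral habit)
    key <- expand.grid(participant = ids,
                       formulation = c("sunscreen", "moisturiser"),
                       stringsAsFactors = FALSE)
    key$canthus_missed <- rbinom(nrow(key), 1L, pop$canthus_miss_prob) == 1L
    key$canthus_frac <- ifelse(key$canthus_missed,
                               runif(nrow(key), 0.30, 0.90),
                               runif(nrow(key), 0, 0.02))
    out <- merge(out, key, by = c("participant", "formulation"), sort = FALSE)
    out <- out[order(out$participant, out$formulation, out$region), ]
    rownames(out) <- NULL
    out
  })
}
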