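## The study's statistical plan on coverage tables: Lilliefors-gated
## normality routing with log/sqrt rescue transforms, paired comparisons
## (paired t or Mann-Whitney fallback, optional signed-rank), one-within-
## factor repeated-measures ANOVA, Sidak-adjusted subgroup contrasts,
## two-factor ANCOVA with an age covariate, order-effect checks,
## dose-response regression, and binary tabulation. All tests at
## significance level 0.05.

#' One tidy test-result row
#'
#' @param test test name.
#' @param statistic test statistic value.
#' @param df,df2 degrees of freedom (df2 for F tests).
#' @param p_value p value.
#' @param direction character description of the effect direction.
#' @param path assumption path taken: `parametric`, `transformed`, or
#'   `nonparametric`.
#' @param ... further scalar columns (e.g. `region`, `term`).
#' @return One-row `data.frame`.
#' @export
test_result <- function(test, statistic, df = NA_real_, df2 = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        path = NA_character_, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  data.frame(test = test, statistic = statistic, df = df, df2 = df2,
             p_value = p_value, direction = direction, path = path, ...,
             stringsAsFactors = FALSE)
}

#' Normality gating with transform rescue
#'
#' Tests normality with the Kolmogorov-Smirnov test in its
#' Lilliefors form (parameters estimated from the sample), at alpha 0.05.
#' If normality is rejected, the test is retried after a log and then a
#' square-root transform (values shifted positive first when needed). If
#' all fail the sample is routed to the nonparametric path. Constant
#' samples (and samples of fewer than 5 values, below the Lilliefors
#' minimum) are routed nonparametric with a warning.
#'
#' @param x numeric sample, length >= 3.
#' @param alpha significance level for the normality test.
#' @return Object of class `normality_gate`: `path` (`parametric`,
#'   `transformed`, `nonparametric`), `transform` (`NA`, `"log"`,
#'   `"sqrt"`), `shift` applied before the transform, and `p_values` of
#'   the tests run.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality gating needs n >= 3")
  out <- list(path = "nonparametric", transform = NA_character_,
              shift = 0, p_values = c())
  if (sd(x) == 0 || !is.finite(sd(x))) {
    warning("degenerate (constant) sample: routed nonparametric")
    out$p_values <- c(raw = NA_real_)
    return(structure(out, class = "normality_gate"))
  }
  if (length(x) < 5L) {
    warning("sample too small for the Lilliefors test (n < 5): routed nonparametric")
    out$p_values <- c(raw = NA_real_)
    return(structure(out, class = "normality_gate"))
  }
  p_raw <- nortest::lillie.test(x)$p.value
  out$p_values <- c(raw = p_raw)
  if (p_raw > alpha) {
    out$path <- "parametric"
    return(structure(out, class = "normality_gate"))
  }
  shift_log <- if (min(x) <= 0) 1 - min(x) else 0
  xl <- log(x + shift_log)
  p_log <- if (sd(xl) > 0) nortest::lillie.test(xl)$p.value else 0
  out$p_values <- c(out$p_values, log = p_log)
  if (p_log > alpha) {
    out$path <- "transformed"; out$transform <- "log"; out$shift <- shift_log
    return(structure(out, class = "normality_gate"))
  }
  shift_sqrt <- if (min(x) < 0) -min(x) else 0
  xs <- sqrt(x + shift_sqrt)
  p_sqrt <- if (sd(xs) > 0) nortest::lillie.test(xs)$p.value else 0
  out$p_values <- c(out$p_values, sqrt = p_sqrt)
  if (p_sqrt > alpha) {
    out$path <- "transformed"; out$transform <- "sqrt"; out$shift <- shift_sqrt
    return(structure(out, class = "normality_gate"))
  }
  structure(out, class = "normality_gate")
}

#' @export
print.normality_gate <- function(x, ...) {
  cat(sprintf("<normality_gate: %s%s, p = %s>\n", x$path,
              if (!is.na(x$transform)) paste0("(", x$transform, ")") else "",
              paste(sprintf("%s=%.3g", names(x$p_values), x$p_values),
                    collapse = ", ")))
  invisible(x)
}

## apply a gate's transform to a sample (shift shared across samples is
## the caller's responsibility; here the gate's own shift is reused)
.apply_transform <- function(x, gate) {
  switch(gate$transform,
         log = log(x + gate$shift),
         sqrt = sqrt(x + gate$shift),
         x)
}

## the documented positivity shift for a transform, over all samples of a
## comparison jointly (a per-sample shift can leave the other sample
## non-positive)
.joint_shift <- function(values, gate) {
  shift <- gate$shift %||% 0
  if (identical(gate$transform, "log") && min(values) + shift <= 0) {
    shift <- 1 - min(values)
  }
  if (identical(gate$transform, "sqrt") && min(values) + shift < 0) {
    shift <- -min(values)
  }
  shift
}

## combine per-sample gates for a two-sample comparison: parametric only
## if both samples pass raw; else the weakest common transform; else
## nonparametric
.combine_gates <- function(ga, gb) {
  paths <- c(ga$path, gb$path)
  if (all(paths == "parametric")) return(list(path = "parametric", gate = ga))
  if ("nonparametric" %in% paths) return(list(path = "nonparametric", gate = ga))
  ## at least one transformed, none nonparametric: use a shared transform
  tr <- unique(stats::na.omit(c(ga$transform, gb$transform)))[1L]
  shift <- max(ga$shift, gb$shift)
  list(path = "transformed",
       gate = list(transform = tr, shift = shift))
}

#' Paired comparison of two formulations
#'
#' Two-sided paired t-test when both samples pass the normality gate
#' (after a shared transform if needed); otherwise the nonparametric
#' fallback. The default fallback is the (unpaired) Mann-Whitney U test,
#' mirroring the analysis plan this package reproduces; a
#' Wilcoxon signed-rank alternative, arguably the better match for a
#' paired design, is available via `fallback`.
#'
#' @param a,b numeric vectors of equal length, paired by participant
#'   (e.g. `a` = sunscreen, `b` = moisturiser).
#' @param gate optional pre-computed path: `"parametric"`,
#'   `"transformed"`, `"nonparametric"`, or a list from
#'   [normality_gate()]-style gating; by default both samples are gated.
#' @param fallback nonparametric fallback: `"mann-whitney"` (default) or
#'   `"signed-rank"`.
#' @return A [test_result()] row.
#' @export
paired_compare <- function(a, b, gate = NULL,
                           fallback = c("mann-whitney", "signed-rank")) {
  fallback <- match.arg(fallback)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("paired comparison needs n >= 2")
  if (is.null(gate)) {
    gate <- suppressWarnings(.combine_gates(normality_gate(a), normality_gate(b)))
  } else if (is.character(gate)) {
    gate <- list(path = gate, gate = list(transform = "log", shift = 0))
  }
  direction <- if (mean(b) > mean(a)) "b > a" else
    if (mean(b) < mean(a)) "a > b" else "none"
  if (gate$path %in% c("parametric", "transformed")) {
    ta <- a; tb <- b
    path <- gate$path
    if (path == "transformed") {
      g <- gate$gate
      g$shift <- .joint_shift(c(a, b), g)
      ta <- .apply_transform(a, g)
      tb <- .apply_transform(b, g)
    }
    if (sd(ta - tb) == 0) {
      ## identical pairs: no evidence of any difference
      return(test_result("paired t-test", statistic = 0,
                         df = length(a) - 1L, p_value = 1,
                         direction = "none", path = path))
    }
    tt <- t.test(ta, tb, paired = TRUE)
    test_result("paired t-test", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                direction = direction, path = path)
  } else {
    if (fallback == "mann-whitney") {
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      test_result("Mann-Whitney U", statistic = unname(wt$statistic),
                  p_value = wt$p.value, direction = direction,
                  path = "nonparametric")
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
      test_result("Wilcoxon signed-rank", statistic = unname(wt$statistic),
                  p_value = wt$p.value, direction = direction,
                  path = "nonparametric")
    }
  }
}

#' Repeated-measures ANOVA for the formulation effect
#'
#' One-within-factor (formulation) repeated-measures ANOVA on one
#' region's percent missed, with participant as the blocking stratum.
#' With two formulation levels the F statistic is algebraically the
#' square of the paired t statistic.
#'
#' @param table long-format study table with columns `participant`,
#'   `formulation`, `region`, `percent_missed`.
#' @param region region to analyse.
#' @param outcome outcome column name (default `"percent_missed"`).
#' @return A [test_result()] row.
#' @export
rm_anova <- function(table, region = "face", outcome = "percent_missed") {
  sub <- table[table$region == region, ]
  if (!nrow(sub)) stop(sprintf("no rows for region '%s'", region))
  counts <- table(sub$participant)
  n_forms <- length(unique(sub$formulation))
  incomplete <- names(counts)[counts < n_forms]
  if (length(incomplete)) {
    stop(sprintf("incomplete paired data for participant(s): %s",
                 paste(incomplete, collapse = ", ")))
  }
  sub$participant <- factor(sub$participant)
  sub$formulation <- factor(sub$formulation)
  fml <- as.formula(paste(outcome, "~ formulation + Error(participant)"))
  fit <- aov(fml, data = sub)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  i <- grep("formulation", rownames(tab))
  f_val <- tab[i, "F value"]
  ## all-equal outcomes leave only floating-point dust in both strata
  if (tab[i, "Sum Sq"] < 1e-9 && tab[nrow(tab), "Sum Sq"] < 1e-9) f_val <- 0
  means <- tapply(sub[[outcome]], sub$formulation, mean)
  direction <- paste(names(means)[order(-means)], collapse = " > ")
  p <- if (f_val == 0) 1 else tab[i, "Pr(>F)"]
  test_result("repeated-measures ANOVA", statistic = f_val,
              df = tab[i, "Df"], df2 = tab[nrow(tab), "Df"],
              p_value = if (is.finite(p)) p else 1,
              direction = if (f_val == 0) "none" else direction,
              path = "parametric", region = region)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p raw p value(s).
#' @param m number of comparisons in the family.
#' @return Adjusted p value(s), never below `p` nor above 1.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, pmax(p, 1 - (1 - p)^m))
}

#' Sidak per-test alpha for a family-wise level
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons.
#' @return Per-test alpha `1 - (1 - alpha)^(1/m)`.
#' @export
sidak_alpha <- function(alpha = 0.05, m = 1) {
  stopifnot(m >= 1)
  1 - (1 - alpha)^(1 / m)
}

#' Subgroup comparison with Sidak-adjusted contrasts
#'
#' One-way ANOVA across the `group x formulation` cells of one region's
#' percent missed, followed by independent two-sample t contrasts between
#' the groups within each formulation, Sidak-adjusted for the number of
#' contrasts.
#'
#' @param table long-format study table.
#' @param group grouping column: `"sex"` or `"skin_group"`.
#' @param region region to analyse.
#' @param outcome outcome column name.
#' @return `data.frame` of [test_result()] rows: one ANOVA row plus one
#'   contrast row per formulation, with columns `p_raw` and `p_sidak` on
#'   the contrast rows.
#' @export
subgroup_compare <- function(table, group = c("sex", "skin_group"),
                             region = "eyelid", outcome = "percent_missed") {
  group <- match.arg(group)
  sub <- table[table$region == region, ]
  if (!nrow(sub)) stop(sprintf("no rows for region '%s'", region))
  levels_g <- unique(sub[[group]])
  if (length(levels_g) < 2L) stop(sprintf("need >= 2 '%s' groups", group))
  for (g in levels_g) if (sum(sub[[group]] == g) < 2L) {
    stop(sprintf("subgroup '%s' has fewer than 2 observations", g))
  }
  cell <- interaction(sub[[group]], sub$formulation, drop = TRUE)
  fit <- aov(sub[[outcome]] ~ cell)
  at <- anova(fit)
  rows <- test_result("one-way ANOVA (group x formulation cells)",
                      statistic = at[1L, "F value"], df = at[1L, "Df"],
                      df2 = at[2L, "Df"], p_value = at[1L, "Pr(>F)"],
                      direction = NA_character_, path = "parametric",
                      region = region, term = group,
                      p_raw = NA_real_, p_sidak = NA_real_)
  forms <- unique(sub$formulation)
  m <- length(forms)
  for (f in forms) {
    sf <- sub[sub$formulation == f, ]
    g1 <- sf[[outcome]][sf[[group]] == levels_g[1L]]
    g2 <- sf[[outcome]][sf[[group]] == levels_g[2L]]
    tt <- t.test(g1, g2, var.equal = TRUE)
    rows <- rbind(rows, test_result(
      sprintf("%s contrast (%s)", group, f),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = sidak_adjust(tt$p.value, m),
      direction = sprintf("%s %s %s", levels_g[1L],
                          if (mean(g1) > mean(g2)) ">" else "<=", levels_g[2L]),
      path = "parametric", region = region, term = f,
      p_raw = tt$p.value, p_sidak = sidak_adjust(tt$p.value, m)))
  }
  rows
}

#' Two-factor ANCOVA with an age covariate
#'
#' Linear-model ANCOVA of percent missed on sex, skin group, their
#' interaction, and age, for one region and formulation. Sums of squares
#' are Type II by default (each term after the others at its level,
#' appropriate for the near-balanced synthetic designs); Type III is
#' available and uses sum-to-zero contrasts.
#'
#' @param table long-format study table.
#' @param region region to analyse.
#' @param formulation formulation subset to analyse.
#' @param covariate covariate column (default `"age"`).
#' @param factors two factor columns (default sex and skin group).
#' @param ss_type `"II"` (default) or `"III"`.
#' @param outcome outcome column name.
#' @return `data.frame` of [test_result()] rows (one per term), with the
#'   covariate slope and its 95% CI attached as attributes
#'   `covariate_slope` and `covariate_ci`.
#' @export
ancova_two_factor <- function(table, region = "face",
                              formulation = "sunscreen",
                              covariate = "age",
                              factors = c("sex", "skin_group"),
                              ss_type = c("II", "III"),
                              outcome = "percent_missed") {
  ss_type <- match.arg(ss_type)
  sub <- table[table$region == region & table$formulation == formulation, ]
  if (!nrow(sub)) stop("no rows for the requested region/formulation")
  for (f in factors) sub[[f]] <- factor(sub[[f]])
  fml <- as.formula(sprintf("%s ~ %s * %s + %s", outcome,
                            factors[1L], factors[2L], covariate))
  contrasts_arg <- if (ss_type == "III") {
    setNames(list("contr.sum", "contr.sum"), factors)
  } else NULL
  fit <- lm(fml, data = sub, contrasts = contrasts_arg)
  if (any(is.na(coef(fit)))) {
    stop(sprintf("rank-deficient ANCOVA design; aliased term(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  at <- car::Anova(fit, type = ss_type)
  terms_keep <- setdiff(rownames(at), c("Residuals", "(Intercept)"))
  df2 <- at["Residuals", "Df"]
  rows <- do.call(rbind, lapply(terms_keep, function(tm) {
    test_result(sprintf("ANCOVA (%s, type %s)", formulation, ss_type),
                statistic = at[tm, "F value"], df = at[tm, "Df"], df2 = df2,
                p_value = at[tm, "Pr(>F)"], direction = NA_character_,
                path = "parametric", region = region, term = tm)
  }))
  attr(rows, "covariate_slope") <- unname(coef(fit)[covariate])
  attr(rows, "covariate_ci") <- unname(confint(fit)[covariate, ])
  rows
}

#' Application-order effect check
#'
#' Compares percent missed between the sunscreen-first and
#' moisturiser-first groups, per region and formulation, using a
#' two-sample t-test or Mann-Whitney per the normality gate. The
#' crossover design pools the groups only if effects are consistent
#' (no significant order differences).
#'
#' @param table long-format study table with an `order` column.
#' @param alpha significance level for the consistency call.
#' @return `data.frame` of [test_result()] rows with attribute
#'   `consistent` (`TRUE` if no comparison fell below `alpha`).
#' @export
order_effect_check <- function(table, alpha = 0.05) {
  if (is.null(table$order)) stop("study table has no 'order' column")
  groups <- unique(table$order)
  if (length(groups) < 2L) stop("one order group is empty")
  rows <- NULL
  for (region in unique(table$region)) {
    for (f in unique(table$formulation)) {
      sub <- table[table$region == region & table$formulation == f, ]
      g1 <- sub$percent_missed[sub$order == groups[1L]]
      g2 <- sub$percent_missed[sub$order == groups[2L]]
      if (length(g1) < 2L || length(g2) < 2L) {
        stop(sprintf("order group with n < 2 for %s/%s", region, f))
      }
      comb <- suppressWarnings(.combine_gates(normality_gate(g1),
                                              normality_gate(g2)))
      if (comb$path %in% c("parametric", "transformed")) {
        gsh <- comb$gate
        if (comb$path == "transformed") gsh$shift <- .joint_shift(c(g1, g2), gsh)
        t1 <- if (comb$path == "transformed") .apply_transform(g1, gsh) else g1
        t2 <- if (comb$path == "transformed") .apply_transform(g2, gsh) else g2
        tt <- t.test(t1, t2)
        row <- test_result("order effect (two-sample t)",
                           statistic = unname(tt$statistic),
                           df = unname(tt$parameter), p_value = tt$p.value,
                           direction = NA_character_, path = comb$path,
                           region = region, term = f)
      } else {
        wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE))
        row <- test_result("order effect (Mann-Whitney U)",
                           statistic = unname(wt$statistic),
                           p_value = wt$p.value, direction = NA_character_,
                           path = "nonparametric", region = region, term = f)
      }
      rows <- rbind(rows, row)
    }
  }
  attr(rows, "consistent") <- !any(rows$p_value < alpha, na.rm = TRUE)
  rows
}

#' Dose-response regression of image darkness on applied mass
#'
#' Fits `mean_intensity ~ mass * formulation` to half-face mass-series
#' records and reports the per-formulation slopes (with 95% CIs from the
#' shared-variance model) and the Type II F test for the formulation
#' effect.
#'
#' @param records `data.frame` with columns `formulation`, `mass`,
#'   `mean_intensity` (see [generate_dose_response()]).
#' @return List with `result` (a [test_result()] row for the formulation
#'   effect), `slopes` (named per-formulation estimates), `slope_ci`
#'   (2 x 2 matrix of 95% CIs), and the fitted `model`.
#' @export
dose_response_regression <- function(records) {
  forms <- unique(records$formulation)
  if (length(forms) < 2L) {
    stop(sprintf("dose-response regression needs both formulations; found: %s",
                 paste(forms, collapse = ", ")))
  }
  for (f in forms) {
    masses <- unique(records$mass[records$formulation == f])
    if (length(masses) < 2L) {
      stop(sprintf("formulation '%s' has a single mass level", f))
    }
  }
  records$formulation <- factor(records$formulation)
  fit <- lm(mean_intensity ~ mass * formulation, data = records)
  cf <- coef(fit)
  ref <- levels(records$formulation)[1L]
  other <- levels(records$formulation)[2L]
  slopes <- c(cf[["mass"]],
              cf[["mass"]] + cf[[grep("^mass:", names(cf), value = TRUE)]])
  names(slopes) <- c(ref, other)
  V <- suppressWarnings(stats::vcov(fit))  # exact fits warn in summary.lm
  i_mass <- which(names(cf) == "mass")
  i_int <- grep("^mass:", names(cf))
  se <- c(sqrt(V[i_mass, i_mass]),
          sqrt(V[i_mass, i_mass] + V[i_int, i_int] + 2 * V[i_mass, i_int]))
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  slope_ci <- cbind(lower = slopes - tcrit * se, upper = slopes + tcrit * se)
  sigma2 <- mean(fit$residuals^2)
  ## an exact-line fit makes the F table degenerate; handled below
  at <- tryCatch(suppressWarnings(car::Anova(fit, type = "II")),
                 error = function(e) NULL)
  if (!is.null(at) && "formulation" %in% rownames(at) &&
      is.finite(at["formulation", "F value"])) {
    f_val <- at["formulation", "F value"]
    p_val <- at["formulation", "Pr(>F)"]
    df1 <- at["formulation", "Df"]; df2 <- at["Residuals", "Df"]
  } else {
    ## exact-fit degenerate case: zero residual and zero effect SS
    f_val <- 0; p_val <- 1; df1 <- 1; df2 <- fit$df.residual
  }
  if (!is.finite(f_val) && sigma2 < 1e-20) { f_val <- 0; p_val <- 1 }
  res <- test_result("dose-response formulation effect", statistic = f_val,
                     df = df1, df2 = df2, p_value = p_val,
                     direction = sprintf("slope %s = %.4g, %s = %.4g",
                                         ref, slopes[[ref]], other,
                                         slopes[[other]]),
                     path = "parametric")
  list(result = res, slopes = slopes, slope_ci = slope_ci, model = fit)
}

#' Tabulate binary covered/missed outcomes
#'
#' @param outcomes character vector of `"covered"` / `"missed"` calls.
#' @return List with `n_missed`, `n_total`, `percent_exact`, and
#'   `percent` (display value, truncated to the whole percent as in the
#'   study report style).
#' @export
tabulate_binary <- function(outcomes) {
  if (!length(outcomes)) stop("empty outcome list")
  bad <- setdiff(unique(outcomes), c("covered", "missed"))
  if (length(bad)) stop(sprintf("unknown outcome value(s): %s",
                                paste(bad, collapse = ", ")))
  n_missed <- sum(outcomes == "missed")
  n_total <- length(outcomes)
  exact <- 100 * n_missed / n_total
  list(n_missed = n_missed, n_total = n_total,
       percent_exact = exact, percent = floor(exact))
}
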