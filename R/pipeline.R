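## End-to-end orchestration: configuration, per-participant coverage
## reports, and full synthetic-study runs (generation -> regions ->
## coverage -> statistics), with self-describing CSV outputs.

#' Default run configuration
#'
#' A nested list of every tunable constant in the pipeline; pass
#' overrides as a nested list and they are merged over the defaults. The
#' full configuration (and seed) is echoed into every output so runs are
#' self-describing.
#'
#' @param overrides nested list of overrides.
#' @return Configuration list of class `run_config`.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    population = list(n_participants = 84L, rho = 0.5,
                      sex_effect = 5, skin_type_effect = 8,
                      canthus_miss_prob = 0.78),
    participant = list(image_dims = c(192L, 192L), noise_sd = 2,
                       applied_mass = 100, channel_mode = "gray",
                       landmark_jitter_sd = 1),
    regions = list(forehead_margin = 1.0, lateral_margin = 0.10,
                   canthus_frac = 0.6, canthus_cap = 0.25,
                   nasal_offset = 0.25),
    coverage = list(k = 3, floor = 0, min_blob = 5L, close_radius = 1L,
                    tau = 0.95, baseline_global_threshold = 110,
                    baseline_max_covered = 0.05),
    stats = list(fallback = "mann-whitney", ss_type = "II", alpha = 0.05),
    output = list(digits_summary = 1L))
  cfg <- modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the [default_config()]
#'   structure.
#' @return A `run_config` list (defaults merged with the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  default_config(yaml::read_yaml(path))
}

.region_params_from_config <- function(cfg) {
  do.call(region_params, cfg$regions)
}

#' Run the coverage pipeline for one participant
#'
#' Derives regions from the landmarks, calibrates the threshold on the
#' baseline, segments each post-application image, and assembles the
#' long-format coverage report: one row per formulation x region
#' (face, eyelid, non-eyelid) with the percent missed, the binary
#' medial-canthus outcomes, the darkness change, and the baseline mean
#' (skin-tone covariate).
#'
#' @param baseline baseline [uv_image()].
#' @param applied named list of post-application [uv_image()]s, one per
#'   formulation.
#' @param landmarks a [landmark_set()].
#' @param cfg a [default_config()] list.
#' @param participant participant identifier for the report.
#' @param order which formulation was applied first (visit numbering).
#' @param allow_flagged_baseline set `TRUE` to override the
#'   product-on-baseline flag (operator decision).
#' @return `data.frame` with columns `participant`, `visit`,
#'   `formulation`, `region`, `percent_missed`, `canthus_left`,
#'   `canthus_right`, `darkness_change`, `mu_base`.
#' @export
run_participant <- function(baseline, applied, landmarks,
                            cfg = default_config(),
                            participant = "P001",
                            order = names(applied)[1L],
                            allow_flagged_baseline = FALSE) {
  stopifnot(inherits(baseline, "uv_image"), length(applied) >= 1L)
  regions <- regions_from_landmarks(landmarks, .region_params_from_config(cfg))
  flag <- flag_baseline(baseline, regions$masks$face,
                        cfg$coverage$baseline_global_threshold,
                        cfg$coverage$baseline_max_covered)
  if (flag$flagged && !allow_flagged_baseline) {
    stop(sprintf(paste0("baseline for %s appears to carry product already ",
                        "(covered fraction %.3f under the provisional global ",
                        "threshold); remove product and re-image, or set ",
                        "allow_flagged_baseline = TRUE"),
                 participant, flag$covered_fraction))
  }
  cal <- calibrate_threshold(baseline, regions$masks$face,
                             k = cfg$coverage$k, floor = cfg$coverage$floor)
  rows <- list()
  for (f in names(applied)) {
    cov <- segment_coverage(applied[[f]], cal,
                            min_blob = cfg$coverage$min_blob,
                            close_radius = cfg$coverage$close_radius)
    dc <- darkness_change(baseline, applied[[f]], regions$masks$face)
    cl <- classify_medial_canthus(cov, regions$masks$canthus_left,
                                  tau = cfg$coverage$tau)
    cr <- classify_medial_canthus(cov, regions$masks$canthus_right,
                                  tau = cfg$coverage$tau)
    visit <- if (identical(f, order)) 1L else 2L
    for (region in c("face", "eyelid", "non_eyelid")) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant, visit = visit, formulation = f,
        region = region,
        percent_missed = percent_missed(cov, regions$masks[[region]]),
        canthus_left = cl, canthus_right = cr,
        darkness_change = dc$change, mu_base = dc$baseline_mean)
    }
  }
  do.call(rbind, rows)
}

## participant_spec built from one participant's rows of the population
## table plus the pipeline config
.spec_from_population <- function(prow, truth_by_form, cfg, kappa = .default_kappa) {
  participant_spec(
    participant_id = prow$participant[1L],
    skin_type = prow$skin_type[1L],
    sex = prow$sex[1L],
    age = prow$age[1L],
    true_missed_fraction = truth_by_form,
    applied_mass = cfg$participant$applied_mass,
    noise_sd = cfg$participant$noise_sd,
    image_dims = cfg$participant$image_dims,
    channel_mode = cfg$participant$channel_mode,
    landmark_jitter_sd = cfg$participant$landmark_jitter_sd)
}

#' Run a complete synthetic study
#'
#' Generates a study population, renders each participant's image bundle
#' from the drawn ground truth, measures every image through the coverage
#' pipeline, and runs the full statistical battery on the measured table.
#' A failing participant is logged and skipped; their failure cannot
#' affect the other participants' numbers.
#'
#' @param cfg a [default_config()] list; `cfg$seed` drives every draw.
#' @param out_dir optional directory for CSV/summary outputs.
#' @return List of class `study_run`: `population` (ground-truth table),
#'   `reports` (measured coverage table), `study_table` (measured values
#'   merged with demographics), `stats` (tidy results table), `summary`
#'   (character vector), `failed` (named list of per-participant
#'   errors), `config`.
#' @export
run_study <- function(cfg = default_config(), out_dir = NULL) {
  pop_spec <- population_spec(
    n_participants = cfg$population$n_participants,
    rho = cfg$population$rho,
    sex_effect = cfg$population$sex_effect,
    skin_type_effect = cfg$population$skin_type_effect,
    canthus_miss_prob = cfg$population$canthus_miss_prob,
    seed = cfg$seed)
  population <- generate_population(pop_spec)
  if (length(unique(population$participant)) < 2L) {
    stop("fewer than 2 complete participants: aborting study run")
  }

  reports <- list(); failed <- list()
  for (pid in unique(population$participant)) {
    prow <- population[population$participant == pid, ]
    truth_by_form <- list()
    for (f in unique(prow$formulation)) {
      fr <- prow[prow$formulation == f, ]
      truth_by_form[[f]] <- list(
        eyelid = fr$percent_missed[fr$region == "eyelid"] / 100,
        non_eyelid = fr$percent_missed[fr$region == "non_eyelid"] / 100,
        canthus = fr$canthus_frac[1L])
    }
    pseed <- (cfg$seed * 10007L + match(pid, unique(population$participant))) %% .Machine$integer.max
    ## A drawn canthus miss can exceed what the participant's eyelid and
    ## non-eyelid budgets admit inside the canthus boxes. The binary
    ## canthus outcome only needs the miss to stay on its side of the
    ## fully-covered cutoff, so an infeasible request is stepped down a
    ## ladder that stays above the cutoff until the last resort (0).
    ## Each formulation is generated (and stepped down) on its own; the
    ## baseline and landmarks are identical across the calls because the
    ## participant seed is shared.
    ladder <- c(0.45, 0.25, 0.15, 0.10, 0.07, 0.06, 0)
    res <- tryCatch({
      baseline <- NULL; landmarks <- NULL; applied <- list()
      for (f in names(truth_by_form)) {
        tbf <- truth_by_form[[f]]
        b_f <- NULL
        for (attempt in 0:7) {
          spec <- .spec_from_population(prow, tbf, cfg)
          b_f <- tryCatch(
            generate_participant(spec, seed = pseed, formulations = f,
                                 region_margins = .region_params_from_config(cfg)),
            error = function(e) e)
          if (!inherits(b_f, "error")) break
          if (!grepl("infeasible", conditionMessage(b_f))) stop(b_f)
          fc <- tbf$canthus
          tbf$canthus <- if (fc > 0.05) {
            nxt <- ladder[ladder < fc][1L]
            if (is.na(nxt)) 0 else nxt
          } else 0
        }
        if (inherits(b_f, "error")) stop(b_f)
        baseline <- baseline %||% b_f$baseline
        landmarks <- landmarks %||% b_f$landmarks
        applied[[f]] <- b_f$applied[[f]]
      }
      run_participant(baseline, applied, landmarks,
                      cfg = cfg, participant = pid,
                      order = prow$order[1L])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[pid]] <- conditionMessage(res)
    } else {
      reports[[pid]] <- res
    }
  }
  if (length(reports) < 2L) {
    stop("fewer than 2 complete participants: aborting study run")
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL

  demo <- unique(population[, c("participant", "sex", "skin_type",
                                "skin_group", "age", "order")])
  study_table <- merge(reports, demo, by = "participant", sort = FALSE)
  study_table <- study_table[order(study_table$participant,
                                   study_table$formulation,
                                   study_table$region), ]
  rownames(study_table) <- NULL

  stats_out <- run_stats_battery(study_table, cfg)
  summary_txt <- .study_summary(study_table, stats_out, cfg)

  out <- structure(list(population = population, reports = reports,
                        study_table = study_table, stats = stats_out$results,
                        canthus = stats_out$canthus, summary = summary_txt,
                        failed = failed, config = cfg),
                   class = "study_run")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

#' Run the statistical battery on a measured study table
#'
#' Applies the full analysis plan: per-region normality-gated paired
#' comparison and repeated-measures ANOVA for the formulation effect,
#' subgroup contrasts (sex and skin group) with Sidak adjustment, the
#' two-factor ANCOVA with age covariate per formulation, the
#' application-order consistency check, and the binary medial-canthus
#' tabulation. Individual analyses that fail (e.g. an empty subgroup in
#' a tiny run) are recorded as note rows rather than aborting the run.
#'
#' @param study_table long-format measured study table.
#' @param cfg a [default_config()] list.
#' @return List with `results` (tidy `data.frame`: test, region, term,
#'   statistic, df, p, path, note) and `canthus` (per-formulation
#'   tabulations).
#' @export
run_stats_battery <- function(study_table, cfg = default_config()) {
  results <- list()
  note_row <- function(test, region, msg) {
    data.frame(test = test, statistic = NA_real_, df = NA_real_,
               df2 = NA_real_, p_value = NA_real_,
               direction = NA_character_, path = NA_character_,
               region = region, term = NA_character_,
               p_raw = NA_real_, p_sidak = NA_real_, note = msg)
  }
  pad <- function(df) {
    for (col in c("region", "term")) if (is.null(df[[col]])) df[[col]] <- NA_character_
    for (col in c("p_raw", "p_sidak")) if (is.null(df[[col]])) df[[col]] <- NA_real_
    if (is.null(df$note)) df$note <- NA_character_
    df[, c("test", "statistic", "df", "df2", "p_value", "direction",
           "path", "region", "term", "p_raw", "p_sidak", "note")]
  }
  regions <- unique(study_table$region)
  forms <- unique(study_table$formulation)
  for (region in regions) {
    sub <- study_table[study_table$region == region, ]
    wide <- merge(sub[sub$formulation == forms[1L], c("participant", "percent_missed")],
                  sub[sub$formulation == forms[2L], c("participant", "percent_missed")],
                  by = "participant", suffixes = c("_a", "_b"))
    res <- tryCatch(
      paired_compare(wide$percent_missed_a, wide$percent_missed_b,
                     fallback = cfg$stats$fallback),
      error = function(e) conditionMessage(e))
    results[[length(results) + 1L]] <- if (is.character(res)) {
      note_row("paired comparison", region, res)
    } else { res$region <- region; pad(res) }
    res <- tryCatch(rm_anova(study_table, region = region),
                    error = function(e) conditionMessage(e))
    results[[length(results) + 1L]] <- if (is.character(res)) {
      note_row("repeated-measures ANOVA", region, res)
    } else pad(res)
  }
  for (grp in c("sex", "skin_group")) {
    res <- tryCatch(subgroup_compare(study_table, group = grp, region = "eyelid"),
                    error = function(e) conditionMessage(e))
    results[[length(results) + 1L]] <- if (is.character(res)) {
      note_row(sprintf("subgroup (%s)", grp), "eyelid", res)
    } else pad(res)
  }
  for (f in forms) {
    res <- tryCatch(
      ancova_two_factor(study_table, region = "face", formulation = f,
                        ss_type = cfg$stats$ss_type),
      error = function(e) conditionMessage(e))
    results[[length(results) + 1L]] <- if (is.character(res)) {
      note_row(sprintf("ANCOVA (%s)", f), "face", res)
    } else pad(res)
  }
  res <- tryCatch(order_effect_check(study_table, alpha = cfg$stats$alpha),
                  error = function(e) conditionMessage(e))
  results[[length(results) + 1L]] <- if (is.character(res)) {
    note_row("order effect", NA_character_, res)
  } else pad(res)

  canthus <- list()
  if (!is.null(study_table$canthus_left)) {
    for (f in forms) {
      sub <- unique(study_table[study_table$formulation == f,
                                c("participant", "canthus_left", "canthus_right")])
      outcome <- ifelse(sub$canthus_left == "missed" |
                          sub$canthus_right == "missed", "missed", "covered")
      canthus[[f]] <- tabulate_binary(outcome)
    }
  }
  list(results = do.call(rbind, results), canthus = canthus)
}

.study_summary <- function(study_table, stats_out, cfg) {
  d <- cfg$output$digits_summary
  lines <- c(sprintf("Synthetic coverage study: %d participants (seed %d)",
                     length(unique(study_table$participant)), cfg$seed),
             "Note: left/right are image-frame, not anatomical.")
  for (region in unique(study_table$region)) {
    sub <- study_table[study_table$region == region, ]
    mm <- tapply(sub$percent_missed, sub$formulation, mean)
    ss <- tapply(sub$percent_missed, sub$formulation, sd)
    lines <- c(lines, sprintf(
      "  %-10s mean missed: %s", region,
      paste(sprintf("%s %.*f%% (SD %.*f)", names(mm), d, mm, d, ss),
            collapse = ", ")))
  }
  for (f in names(stats_out$canthus)) {
    tb <- stats_out$canthus[[f]]
    lines <- c(lines, sprintf(
      "  medial canthus missed (%s): %d of %d (%d%%)", f,
      tb$n_missed, tb$n_total, tb$percent))
  }
  res <- stats_out$results
  pc <- res[res$test == "paired t-test" | res$test == "Mann-Whitney U" |
              res$test == "Wilcoxon signed-rank", ]
  for (i in seq_len(nrow(pc))) {
    lines <- c(lines, sprintf("  %s [%s]: p = %.3g (%s)", pc$test[i],
                              pc$region[i], pc$p_value[i], pc$direction[i]))
  }
  lines
}

#' Write a study run's outputs to a directory
#'
#' Writes `population.csv`, `coverage_reports.csv`, `study_table.csv`,
#' `stats_results.csv`, `summary.txt`, and a YAML echo of the full
#' configuration. Every CSV carries a `# seed:` header line (readers
#' should use `comment.char = "#"`); no timestamps are written, so
#' identical runs produce byte-identical files.
#'
#' @param run a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "study_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# seed: %d", run$config$seed), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(run$population, "population.csv")
  wr(run$reports, "coverage_reports.csv")
  wr(run$study_table, "study_table.csv")
  wr(run$stats, "stats_results.csv")
  writeLines(run$summary, file.path(out_dir, "summary.txt"))
  yaml::write_yaml(unclass(run$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a CSV written by [write_study_outputs()]
#'
#' @param path CSV path (with the `# seed:` header).
#' @return `data.frame`.
#' @export
read_study_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @export
print.study_run <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  if (length(x$failed)) {
    cat(sprintf("Failed participants: %s\n",
                paste(names(x$failed), collapse = ", ")))
  }
  invisible(x)
}
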