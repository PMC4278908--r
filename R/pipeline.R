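#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run: schedule
#' configuration, synthetic cohort design (omit to analyse user-supplied
#' sessions), preprocessing parameters, response-window parameters and
#' statistics options. All randomness is funnelled through `seed` with
#' per-participant substreams, so `(config, seed)` fully determines every
#' output artifact.
#'
#' @param schedule A [schedule_config()].
#' @param design A [cohort_design()] (its own seed field is overridden by
#'   `seed`), or `NULL` when sessions are supplied externally.
#' @param preprocess Named list of [preprocess_emg()] arguments.
#' @param artifacts Named list of [mark_artifacts()] arguments, or `NULL`
#'   to skip automated artifact marking.
#' @param response A [response_window_config()].
#' @param t_var_equal Pooled-variance independent t-tests if `TRUE`,
#'   Welch otherwise.
#' @param subset `"none"`, `"successful"` (successful-acquisition subset)
#'   or `"aware"` (fully contingency-aware subset) for the extinction
#'   reanalysis.
#' @param seed Master seed.
#' @param out_dir Optional output directory for the TSV/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(schedule = schedule_config(),
                            design = cohort_design(),
                            preprocess = list(),
                            artifacts = list(),
                            response = response_window_config(),
                            t_var_equal = TRUE,
                            subset = c("none", "successful", "aware"),
                            seed = 1L,
                            out_dir = NULL) {
  subset <- match.arg(subset)
  structure(
    list(schedule = schedule, design = design, preprocess = preprocess,
         artifacts = artifacts, response = response,
         t_var_equal = t_var_equal, subset = subset,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# Simulate + preprocess + score one participant; returns trials and the
# one-row score record. Keeps only tables in memory.
process_participant <- function(pt_row, schedule_cfg, preprocess_args,
                                artifact_args, response_cfg) {
  cfg <- schedule_cfg
  cfg$seed <- derive_seed(pt_row$seed, 1L)
  sched <- build_schedule(cfg)
  rec <- simulate_emg_session(sched, pt_row$params[[1]], seed = pt_row$seed)
  sig <- do.call(preprocess_emg, c(list(rec), preprocess_args))
  if (!is.null(artifact_args)) {
    sig <- do.call(mark_artifacts, c(list(sig), artifact_args))
  }
  resp <- detect_responses(sig, response_cfg, schedule = sched)
  list(
    trials = dplyr::mutate(resp, id = pt_row$id, .before = 1),
    scores = score_participant(resp, id = pt_row$id)
  )
}

#' Group-level statistics of a scored cohort
#'
#' Computes the full statistical layer on a cohort score table: the 2x2
#' mixed ANOVAs for acquisition and extinction, per-group paired t-tests
#' (CS+ vs CS-) per phase, the between-group independent t on the
#' strength of conditioning (differential) per phase, Pearson
#' correlations of the patients' differentials with illness duration, BDI
#' and age, the sex chi-square, and the extinction reanalyses on the
#' successful-acquisition and fully-aware subsets.
#'
#' @param cohort Tibble with one row per scorable participant: `group`,
#'   proportional score columns, differentials, and optionally `sex`,
#'   `age`, `illness_duration_years`, `bdi`, `cs_plus_correct`,
#'   `cs_minus_correct`.
#' @param t_var_equal Pooled independent t if `TRUE`.
#' @return A list with `anova` (named list of `startle_anova`), `tests`
#'   (tibble of t/r/chi-square results) and `stats_table` (one long tidy
#'   tibble of every statistic).
#' @export
cohort_statistics <- function(cohort, t_var_equal = TRUE) {
  cc <- if ("scorable" %in% names(cohort)) {
    dplyr::filter(cohort, .data$scorable)
  } else {
    cohort
  }
  groups <- sort(unique(cc$group))
  anovas <- list(
    acquisition = mixed_anova_2x2(cc, "acquisition"),
    extinction = mixed_anova_2x2(cc, "extinction")
  )
  subset_ok <- filter_successful_acquisition(cc)
  if (length(unique(subset_ok$group)) == 2 &&
      all(table(subset_ok$group) >= 2)) {
    anovas$extinction_successful <- mixed_anova_2x2(subset_ok, "extinction")
  }
  if (all(c("cs_plus_correct", "cs_minus_correct") %in% names(cc))) {
    aware <- cc[classify_awareness(cc$cs_plus_correct, cc$cs_minus_correct) ==
                  "fully_aware", ]
    if (length(unique(aware$group)) == 2 && all(table(aware$group) >= 2)) {
      anovas$extinction_aware <- mixed_anova_2x2(aware, "extinction")
    }
  }

  tests <- list()
  for (g in groups) {
    gg <- cc[cc$group == g, ]
    tests[[paste0("paired_acq_", g)]] <-
      dplyr::mutate(paired_t(gg$acq_prop_csm, gg$acq_prop_csp),
                    test = paste0("acquisition CS- vs CS+ (", g, ")"))
    tests[[paste0("paired_ext_", g)]] <-
      dplyr::mutate(paired_t(gg$ext_prop_csm, gg$ext_prop_csp),
                    test = paste0("extinction CS- vs CS+ (", g, ")"))
  }
  g1 <- cc[cc$group == groups[1], ]
  g2 <- cc[cc$group == groups[2], ]
  tests$diff_acq <- dplyr::mutate(
    independent_t(g1$acq_differential, g2$acq_differential, t_var_equal),
    test = "acquisition differential between groups")
  tests$diff_ext <- dplyr::mutate(
    independent_t(g1$ext_differential, g2$ext_differential, t_var_equal),
    test = "extinction differential between groups")
  t_tbl <- dplyr::bind_rows(tests)

  corr <- NULL
  mdd <- cc[cc$group == "MDD", ]
  if (nrow(mdd) >= 3 && "illness_duration_years" %in% names(mdd)) {
    corr <- dplyr::bind_rows(
      dplyr::mutate(pearson_r(mdd$illness_duration_years, mdd$ext_differential),
                    test = "illness duration vs extinction differential (MDD)"),
      dplyr::mutate(pearson_r(mdd$illness_duration_years, mdd$acq_differential),
                    test = "illness duration vs acquisition differential (MDD)"),
      if ("bdi" %in% names(mdd)) {
        dplyr::mutate(pearson_r(mdd$bdi, mdd$acq_differential),
                      test = "BDI vs acquisition differential (MDD)")
      },
      if ("age" %in% names(mdd)) {
        dplyr::mutate(pearson_r(mdd$age, mdd$ext_differential),
                      test = "age vs extinction differential (MDD)")
      }
    )
  }
  chisq <- NULL
  if ("sex" %in% names(cc)) {
    tab <- table(cc$group, cc$sex)
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chisq <- dplyr::mutate(chi_square_2x2(tab), test = "sex by group")
    }
  }

  stats_table <- dplyr::bind_rows(
    purrr::imap(anovas, \(a, nm) dplyr::mutate(tidy(a), analysis = paste0("anova_", nm),
                                               statistic_name = "F",
                                               statistic = .data$f)) |>
      dplyr::bind_rows() |>
      dplyr::select("analysis", term = "effect", "statistic_name", "statistic",
                    "df_num", "df_den", "p", "eta_p_sq"),
    t_tbl |>
      dplyr::mutate(analysis = "t_test", statistic_name = "t",
                    df_num = NA_integer_) |>
      dplyr::select("analysis", term = "test", "statistic_name",
                    statistic = "t", "df_num", df_den = "df", "p"),
    if (!is.null(corr)) {
      corr |>
        dplyr::mutate(analysis = "pearson_r", statistic_name = "r",
                      df_num = NA_integer_) |>
        dplyr::select("analysis", term = "test", "statistic_name",
                      statistic = "r", "df_num", df_den = "df", "p")
    },
    if (!is.null(chisq)) {
      chisq |>
        dplyr::mutate(analysis = "chi_square", statistic_name = "chisq",
                      df_num = NA_integer_) |>
        dplyr::select("analysis", term = "test", "statistic_name",
                      statistic = "chisq", "df_num", df_den = "df", "p")
    }
  )
  list(anova = anovas, tests = t_tbl, correlations = corr, chisq = chisq,
       stats_table = stats_table)
}

#' Run the full pipeline
#'
#' Executes simulate (when a design is present) -> preprocess -> score ->
#' statistics, streaming one participant at a time so only tables are
#' retained, and optionally writes `trials.tsv`, `scores.tsv`,
#' `stats.tsv` and a reproducibility manifest (`manifest.json`) to
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `startle_results`: `participants`, `trials`,
#'   `scores` (score table joined with group/covariates), `stats` (from
#'   [cohort_statistics()]) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$design)) {
    abort("run_pipeline currently requires a synthetic design; use the \
stage functions directly for external recordings",
          class = "startlekit_config_error")
  }
  design <- config$design
  design$seed <- config$seed
  pt <- draw_cohort_params(design)
  per <- purrr::map(seq_len(nrow(pt)), function(i) {
    process_participant(pt[i, ], config$schedule, config$preprocess,
                        config$artifacts, config$response)
  })
  trials <- dplyr::bind_rows(purrr::map(per, "trials"))
  scores <- dplyr::bind_rows(purrr::map(per, "scores")) |>
    dplyr::left_join(
      dplyr::select(pt, "id", "group", "sex", "age",
                    "illness_duration_years", "bdi",
                    "cs_plus_correct", "cs_minus_correct"),
      by = "id"
    )
  stats <- cohort_statistics(scores, t_var_equal = config$t_var_equal)
  manifest <- list(
    package = "startlekit",
    version = as.character(utils::packageVersion("startlekit")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_participants = nrow(pt),
    n_unscorable = sum(!scores$scorable),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  res <- structure(
    list(participants = pt, trials = trials, scores = scores,
         stats = stats, manifest = manifest),
    class = "startle_results"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(trials, file.path(config$out_dir, "trials.tsv"))
    readr::write_tsv(dplyr::select(scores, -dplyr::any_of("params")),
                     file.path(config$out_dir, "scores.tsv"))
    readr::write_tsv(stats$stats_table, file.path(config$out_dir, "stats.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.startle_results <- function(x, ...) {
  cat(sprintf("<startle_results> %d participants (%d unscorable)\n",
              nrow(x$scores), sum(!x$scores$scorable)))
  for (nm in names(x$stats$anova)) {
    cat("\n--", nm, "--\n")
    print(x$stats$anova[[nm]])
  }
  invisible(x)
}

#' Read an externally recorded session
#'
#' Loads a continuous EMG signal (headered TSV, see [write_signal_tsv()])
#' together with its events table (see [write_events_tsv()]) and attaches
#' the events to the recording.
#'
#' @param signal_path Path to the signal TSV.
#' @param events_path Path to the events TSV.
#' @return A list with `recording` (an [emg_recording()] whose `events`
#'   holds the events tibble) and `events`.
#' @export
read_session <- function(signal_path, events_path) {
  rec <- read_signal_tsv(signal_path)
  ev <- read_events_tsv(events_path)
  rec$events <- list(events = ev)
  list(recording = rec, events = ev)
}
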