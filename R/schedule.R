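#' Schedule configuration for a differential fear conditioning session
#'
#' Builds the configuration of the three-phase paradigm: a startle
#' habituation phase, a partial-reinforcement acquisition phase and an
#' immediate (instructed) extinction phase. Defaults follow the standard
#' design: 9 habituation tones; 10 CS+ and 10 CS- of 8 s per conditioning
#' phase; 50% of acquisition CS+ co-terminating with a 100-ms shock (US);
#' 50-ms startle probes at 4.5 or 7 s on 60% of each CS type plus 4
#' intertrial-interval (ITI) probes; ITIs of 12, 14 or 16 s.
#'
#' @param n_habituation_tones Number of startle tones in the habituation
#'   phase.
#' @param habituation_itis_s Admissible ITI durations (s) between
#'   habituation tones; also used between conditioning trials.
#' @param n_cs_plus,n_cs_minus CS+ / CS- presentations per conditioning
#'   phase.
#' @param cs_duration_s CS presentation length in seconds.
#' @param reinforcement_fraction Proportion of acquisition CS+ followed by
#'   the US. Must give an integer count.
#' @param us_duration_ms US (shock) duration; the US co-terminates with the
#'   CS+.
#' @param probe_fraction_cs Proportion of each CS type carrying a startle
#'   probe. Must give integer counts for both CS types.
#' @param probe_offsets_s Admissible probe onsets relative to CS onset.
#' @param n_iti_probes ITI startle probes per conditioning phase.
#' @param iti_durations_s Admissible ITI durations (s) between conditioning
#'   trials.
#' @param startle_duration_ms Startle probe (white-noise burst) duration.
#' @param extinction_reinforced Always `FALSE`: no US is ever delivered in
#'   extinction.
#' @param max_run Pseudorandomization constraint: maximum number of
#'   consecutive trials of the same CS type.
#' @param lead_in_s Quiet baseline before the first event.
#' @param phase_gap_s Quiet gap between phases (s).
#' @param seed Integer seed controlling all schedule randomness.
#'
#' @return A list of class `schedule_config`.
#' @export
#' @examples
#' cfg <- schedule_config(seed = 1)
#' sched <- build_schedule(cfg)
#' dplyr::count(sched$events, phase, trial_type)
schedule_config <- function(n_habituation_tones = 9,
                            habituation_itis_s = c(12, 14, 16),
                            n_cs_plus = 10,
                            n_cs_minus = 10,
                            cs_duration_s = 8,
                            reinforcement_fraction = 0.5,
                            us_duration_ms = 100,
                            probe_fraction_cs = 0.6,
                            probe_offsets_s = c(4.5, 7),
                            n_iti_probes = 4,
                            iti_durations_s = c(12, 14, 16),
                            startle_duration_ms = 50,
                            extinction_reinforced = FALSE,
                            max_run = 2,
                            lead_in_s = 10,
                            phase_gap_s = 20,
                            seed = 1L) {
  cfg <- list(
    n_habituation_tones = as.integer(n_habituation_tones),
    habituation_itis_s = as.numeric(habituation_itis_s),
    n_cs_plus = as.integer(n_cs_plus),
    n_cs_minus = as.integer(n_cs_minus),
    cs_duration_s = cs_duration_s,
    reinforcement_fraction = reinforcement_fraction,
    us_duration_ms = us_duration_ms,
    probe_fraction_cs = probe_fraction_cs,
    probe_offsets_s = as.numeric(probe_offsets_s),
    n_iti_probes = as.integer(n_iti_probes),
    iti_durations_s = as.numeric(iti_durations_s),
    startle_duration_ms = startle_duration_ms,
    extinction_reinforced = isTRUE(extinction_reinforced),
    max_run = as.integer(max_run),
    lead_in_s = lead_in_s,
    phase_gap_s = phase_gap_s,
    seed = as.integer(seed)
  )
  validate_schedule_config(cfg)
  structure(cfg, class = "schedule_config")
}

validate_schedule_config <- function(cfg) {
  near_int <- function(x) abs(x - round(x)) < 1e-9
  if (!near_int(cfg$reinforcement_fraction * cfg$n_cs_plus)) {
    abort("reinforcement_fraction * n_cs_plus must be an integer",
          class = "startlekit_config_error")
  }
  if (!near_int(cfg$probe_fraction_cs * cfg$n_cs_plus) ||
      !near_int(cfg$probe_fraction_cs * cfg$n_cs_minus)) {
    abort("probe_fraction_cs must give integer probe counts for both CS types",
          class = "startlekit_config_error")
  }
  dur <- c(cfg$cs_duration_s, cfg$us_duration_ms, cfg$startle_duration_ms,
           cfg$habituation_itis_s, cfg$iti_durations_s)
  if (any(dur <= 0)) {
    abort("all durations must be positive", class = "startlekit_config_error")
  }
  if (cfg$extinction_reinforced) {
    abort("extinction is never reinforced", class = "startlekit_config_error")
  }
  if (cfg$n_cs_plus > 0 && cfg$n_iti_probes > (cfg$n_cs_plus + cfg$n_cs_minus - 1)) {
    abort("more ITI probes than intertrial gaps", class = "startlekit_config_error")
  }
  invisible(cfg)
}

# sample() that never falls into the 1:x trap for length-1 vectors
sample_from <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# CS-type sequence under the max-run pseudorandomization constraint,
# by bounded rejection sampling from the seeded RNG stream.
draw_cs_sequence <- function(n_plus, n_minus, max_run, max_tries = 1000L) {
  base <- c(rep("CSplus", n_plus), rep("CSminus", n_minus))
  if (length(base) == 0L) return(character(0))
  if (n_plus == 0L || n_minus == 0L) {
    if (length(base) > max_run) {
      abort("run-length constraint infeasible for a single CS type",
            class = "startlekit_schedule_error")
    }
    return(base)
  }
  for (i in seq_len(max_tries)) {
    s <- sample_from(base)
    r <- rle(s)
    if (max(r$lengths) <= max_run) return(s)
  }
  abort(sprintf("no admissible sequence found in %d tries", max_tries),
        class = "startlekit_schedule_error")
}

# Balanced 50/50 assignment of the two probe offsets within one CS type
# (odd counts: the extra trial's offset is drawn at random).
assign_offsets <- function(n, offsets) {
  if (n == 0L) return(numeric(0))
  if (length(offsets) == 1L) return(rep(offsets, n))
  half <- n %/% 2L
  pool <- c(rep(offsets[1L], half), rep(offsets[2L], half))
  if (n %% 2L == 1L) pool <- c(pool, sample_from(offsets, 1L))
  sample_from(pool)
}

# One conditioning phase laid out in time. `mirror` (from acquisition)
# fixes trial order, probe placement, offsets, ITI durations and ITI-probe
# gaps, so extinction replays acquisition's sequence without reinforcement.
layout_conditioning_phase <- function(cfg, phase, start_s, reinforced_allowed,
                                      mirror = NULL) {
  n_trials <- cfg$n_cs_plus + cfg$n_cs_minus
  if (n_trials == 0L) {
    empty <- tibble(
      phase = character(0), index = integer(0), trial_type = character(0),
      onset = numeric(0), duration = numeric(0), probe_onset = numeric(0),
      reinforced = logical(0), us_onset = numeric(0)
    )
    return(list(events = empty, end_s = start_s, plan = NULL))
  }

  if (is.null(mirror)) {
    cs_seq <- draw_cs_sequence(cfg$n_cs_plus, cfg$n_cs_minus, cfg$max_run)
    n_probe_plus <- as.integer(round(cfg$probe_fraction_cs * cfg$n_cs_plus))
    n_probe_minus <- as.integer(round(cfg$probe_fraction_cs * cfg$n_cs_minus))
    idx_plus <- which(cs_seq == "CSplus")
    idx_minus <- which(cs_seq == "CSminus")
    probed <- logical(n_trials)
    probed[sample_from(idx_plus, n_probe_plus)] <- TRUE
    probed[sample_from(idx_minus, n_probe_minus)] <- TRUE
    offset <- rep(NA_real_, n_trials)
    offset[probed & cs_seq == "CSplus"] <- assign_offsets(n_probe_plus, cfg$probe_offsets_s)
    offset[probed & cs_seq == "CSminus"] <- assign_offsets(n_probe_minus, cfg$probe_offsets_s)
    n_reinf <- as.integer(round(cfg$reinforcement_fraction * cfg$n_cs_plus))
    reinf <- logical(n_trials)
    if (reinforced_allowed && n_reinf > 0L) {
      reinf[sample_from(idx_plus, n_reinf)] <- TRUE
    }
    itis <- sample_from(cfg$iti_durations_s, n_trials, replace = TRUE)
    gaps_with_probe <- if (cfg$n_iti_probes > 0L) {
      sort(sample_from(seq_len(max(n_trials - 1L, 1L)), cfg$n_iti_probes))
    } else {
      integer(0)
    }
    plan <- list(cs_seq = cs_seq, probed = probed, offset = offset,
                 reinf = reinf, itis = itis, gaps_with_probe = gaps_with_probe)
  } else {
    plan <- mirror
    plan$reinf <- rep(FALSE, n_trials)
  }

  onset <- start_s + c(0, cumsum(rep(cfg$cs_duration_s, n_trials - 1L) +
                                   plan$itis[seq_len(n_trials - 1L)]))
  trials <- tibble(
    phase = phase,
    index = NA_integer_,
    trial_type = plan$cs_seq,
    onset = onset,
    duration = cfg$cs_duration_s,
    probe_onset = onset + plan$offset,
    reinforced = plan$reinf,
    us_onset = ifelse(plan$reinf,
                      onset + cfg$cs_duration_s - cfg$us_duration_ms / 1000,
                      NA_real_)
  )
  iti_rows <- NULL
  if (length(plan$gaps_with_probe) > 0L) {
    gap_start <- onset[plan$gaps_with_probe] + cfg$cs_duration_s
    gap_len <- plan$itis[plan$gaps_with_probe]
    probe_t <- gap_start + gap_len / 2
    iti_rows <- tibble(
      phase = phase, index = NA_integer_, trial_type = "ITIprobe",
      onset = probe_t, duration = cfg$startle_duration_ms / 1000,
      probe_onset = probe_t, reinforced = FALSE, us_onset = NA_real_
    )
  }
  ev <- dplyr::arrange(dplyr::bind_rows(trials, iti_rows), .data$onset)
  ev$index <- seq_len(nrow(ev))
  end_s <- onset[n_trials] + cfg$cs_duration_s + plan$itis[n_trials]
  list(events = ev, end_s = end_s, plan = plan)
}

#' Build a pseudorandomized session schedule
#'
#' Lays out the full session: habituation tones, then acquisition with
#' partial reinforcement and probe assignment, then extinction replaying
#' acquisition's trial and probe sequence with no US. Pseudorandomization
#' never places more than `max_run` consecutive trials of the same CS type;
#' reinforced and probed CS+ are drawn uniformly without replacement; probe
#' offsets are balanced between the admissible onsets within each CS type.
#'
#' @param config A [schedule_config()].
#' @return An object of class `session_schedule`: a list with `config`,
#'   `events` (a tibble sorted by onset with columns `phase`, `index`,
#'   `trial_type`, `onset`, `duration`, `probe_onset`, `reinforced`,
#'   `us_onset`, all times in session seconds) and `phase_boundaries`.
#' @export
build_schedule <- function(config) {
  validate_schedule_config(config)
  with_seed(config$seed, {
    cfg <- config
    t <- cfg$lead_in_s
    # habituation: tones separated by draws from the habituation ITI set
    hab <- NULL
    if (cfg$n_habituation_tones > 0L) {
      itis <- sample_from(cfg$habituation_itis_s, cfg$n_habituation_tones, replace = TRUE)
      onsets <- t + c(0, cumsum(itis[seq_len(cfg$n_habituation_tones - 1L)]))
      hab <- tibble(
        phase = "habituation", index = seq_len(cfg$n_habituation_tones),
        trial_type = "habituation_tone", onset = onsets,
        duration = cfg$startle_duration_ms / 1000, probe_onset = onsets,
        reinforced = FALSE, us_onset = NA_real_
      )
      t <- onsets[cfg$n_habituation_tones] + itis[cfg$n_habituation_tones]
    }
    hab_end <- t
    t <- t + cfg$phase_gap_s
    acq <- layout_conditioning_phase(cfg, "acquisition", t, reinforced_allowed = TRUE)
    t2 <- acq$end_s + cfg$phase_gap_s
    ext <- layout_conditioning_phase(cfg, "extinction", t2, reinforced_allowed = FALSE,
                                     mirror = acq$plan)
    events <- dplyr::bind_rows(hab, acq$events, ext$events)
    boundaries <- tibble(
      phase = c("habituation", "acquisition", "extinction"),
      start_s = c(cfg$lead_in_s, t, t2),
      end_s = c(hab_end, acq$end_s, ext$end_s)
    )
    structure(
      list(config = cfg, events = events, phase_boundaries = boundaries),
      class = "session_schedule"
    )
  })
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule>\n")
  cat(sprintf("  %d events over %.1f s (seed %d)\n",
              nrow(x$events), session_duration(x), x$config$seed))
  print(dplyr::count(x$events, .data$phase, .data$trial_type))
  invisible(x)
}

session_duration <- function(schedule) {
  max(schedule$phase_boundaries$end_s)
}

#' All probe events of a schedule, in session-wide probe order
#'
#' Returns one row per startle probe (habituation tones, probed CS trials
#' and ITI probes) with the session-wide probe ordinal used by the
#' habituation model of the synthetic generator.
#'
#' @param schedule A `session_schedule`.
#' @return A tibble sorted by `probe_onset` with a `probe_ordinal` column.
#' @export
probe_events <- function(schedule) {
  schedule$events |>
    dplyr::filter(!is.na(.data$probe_onset)) |>
    dplyr::arrange(.data$probe_onset) |>
    dplyr::mutate(probe_ordinal = dplyr::row_number())
}

#' Write / read a schedule events table as tab-separated text
#'
#' The on-disk dialect is BIDS-events-like: columns `onset`, `duration`,
#' `phase`, `trial_type`, `probe_onset`, `reinforced` (0/1), `us_onset`,
#' with `n/a` for absent values.
#'
#' @param schedule A `session_schedule`.
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns the events tibble.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- schedule$events |>
    dplyr::mutate(reinforced = as.integer(.data$reinforced)) |>
    dplyr::select("onset", "duration", "phase", "trial_type",
                  "probe_onset", "reinforced", "us_onset")
  readr::write_tsv(ev, path, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                        col_types = readr::cols(
                          onset = "d", duration = "d", phase = "c",
                          trial_type = "c", probe_onset = "d",
                          reinforced = "i", us_onset = "d"
                        ))
  if (is.unsorted(ev$onset)) {
    abort("events table is not sorted by onset", class = "startlekit_parse_error")
  }
  bad <- !is.na(ev$probe_onset) & ev$probe_onset < ev$onset
  if (any(bad)) {
    abort("probe_onset precedes event onset", class = "startlekit_parse_error")
  }
  ev |>
    dplyr::mutate(reinforced = .data$reinforced == 1L) |>
    dplyr::group_by(.data$phase) |>
    dplyr::mutate(index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("phase", "index", "trial_type", "onset", "duration",
                  "probe_onset", "reinforced", "us_onset")
}
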