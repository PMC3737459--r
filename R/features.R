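# Feature extraction: raw 5-channel trials -> 12 x 5 standardized,
# baseline-corrected feature matrix.
#
# Per-channel processing before standardization:
#   scl        raw series
#   hr         band-pass the pulse waveform (0.5-3 Hz), peak-detect with
#              40-180 beats/min bounds, use the beats/min rate series
#   resp       peak-detect (no filter, 5-180 events/min bounds), rate series
#   zyg, corr  band-pass (1-500 Hz, clamped below Nyquist), full-wave rectify
# Then z-score each channel over all of a participant's trials pooled, and
# summarize each trial as mean(music window) - mean(baseline window), where
# the first 10 s of baseline and of music are excluded (startle guard):
# baseline window [10, 30) s, music window [10, 40) s after music onset.

#' Process one trial's channels into analysis series
#'
#' Applies the per-channel filters, converts the cardiac and respiration
#' channels to event-rate series, and rectifies the EMG channels. This is the
#' representation that per-participant standardization operates on.
#'
#' @param trial Tibble with columns `time_s`, `scl`, `ppg`, `resp`, `zyg`,
#'   `corr`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param filter_specs Filter table, default [default_filter_specs()].
#' @param bounds Rate-bounds table, default [default_rate_bounds()].
#' @return Tibble with columns `time_s`, `scl`, `hr`, `resp`, `zyg`, `corr`
#'   (hr/resp in events per minute; EMG rectified).
#' @export
process_trial <- function(trial, sample_rate_hz,
                          filter_specs = default_filter_specs(),
                          bounds = default_rate_bounds()) {
  spec_of <- function(ch) filter_specs[filter_specs$channel == ch, ]
  bnd_of <- function(ch) bounds[bounds$channel == ch, ]

  hr_wave <- suppressWarnings(
    apply_filter(trial$ppg, spec_of("hr"), sample_rate_hz)
  )
  hr <- detect_rate_series(hr_wave, bnd_of("hr"), sample_rate_hz)$rate
  resp_series <- apply_filter(trial$resp, spec_of("resp"), sample_rate_hz)
  resp <- detect_rate_series(resp_series, bnd_of("resp"), sample_rate_hz)$rate
  zyg <- abs(suppressWarnings(
    apply_filter(trial$zyg, spec_of("zyg"), sample_rate_hz)
  ))
  corr <- abs(suppressWarnings(
    apply_filter(trial$corr, spec_of("corr"), sample_rate_hz)
  ))

  tibble::tibble(
    time_s = trial$time_s,
    scl = apply_filter(trial$scl, spec_of("scl"), sample_rate_hz),
    hr = hr, resp = resp, zyg = zyg, corr = corr
  )
}

#' Standardize one participant's processed trials
#'
#' Converts each channel to z-scores using the mean and SD pooled across all
#' of the participant's trials (baseline and music samples alike), so a
#' channel's units and individual reactivity level drop out.
#'
#' @param trials List of processed trial tibbles ([process_trial()]).
#' @return List of tibbles of the same shape, in z-units.
#' @export
standardize_participant <- function(trials) {
  stopifnot(length(trials) >= 1)
  pooled <- dplyr::bind_rows(trials)
  for (ch in .channels) {
    m <- mean(pooled[[ch]])
    s <- stats::sd(pooled[[ch]])
    if (!is.finite(s) || s <= 0) {
      abort(paste0("channel ", ch, " has zero pooled SD; cannot standardize"))
    }
    trials <- purrr::map(trials, function(tr) {
      tr[[ch]] <- (tr[[ch]] - m) / s
      tr
    })
  }
  trials
}

#' Baseline-corrected feature of one standardized trial
#'
#' `mean(z, music window) - mean(z, baseline window)` per channel, with the
#' baseline window covering the final 20 s of the white-noise baseline and
#' the music window seconds 10-40 of the excerpt.
#'
#' @param trial Standardized trial tibble (`time_s` plus channel columns).
#' @param baseline_dur_s Baseline duration in seconds (default 30).
#' @param music_dur_s Music duration in seconds (default 40).
#' @return One-row tibble with columns `scl`, `hr`, `resp`, `zyg`, `corr`.
#' @export
extract_feature <- function(trial, baseline_dur_s = 30, music_dur_s = 40) {
  t <- trial$time_s
  total <- baseline_dur_s + music_dur_s
  dt <- stats::median(diff(t))
  if (max(t) + 1.5 * dt < total) {
    abort("trial shorter than baseline + music duration")
  }
  if (baseline_dur_s < 20) abort("baseline window [10, 30) s extends past the baseline segment")
  if (music_dur_s < 40) abort("music window [10, 40) s extends past the music segment")
  base_win <- t >= baseline_dur_s - 20 & t < baseline_dur_s
  music_win <- t >= baseline_dur_s + 10 & t < baseline_dur_s + 40
  if (!any(base_win) || !any(music_win)) abort("empty feature window")
  out <- purrr::map(.channels, function(ch) {
    mean(trial[[ch]][music_win]) - mean(trial[[ch]][base_win])
  })
  names(out) <- .channels
  tibble::as_tibble(out)
}

#' Extract the per-excerpt feature matrix from a study
#'
#' Runs the full feature pipeline: per-trial channel processing,
#' per-participant pooled standardization, baseline-corrected trial features,
#' then an unweighted average over participants per excerpt, joined with the
#' per-excerpt mean valence and arousal ratings.
#'
#' @param study A `physio_study` ([simulate_study()] or [read_study()]).
#' @param filter_specs,bounds Overrides for [process_trial()].
#' @return A tibble with one row per excerpt: `excerpt`, `quadrant`, `scl`,
#'   `hr`, `resp`, `zyg`, `corr` (participant-averaged z-unit features),
#'   `mean_valence`, `mean_arousal`.
#' @examples
#' \donttest{
#' study <- simulate_study(study_design(n_participants = 2, seed = 1))
#' extract_features(study)
#' }
#' @export
extract_features <- function(study,
                             filter_specs = default_filter_specs(),
                             bounds = default_rate_bounds()) {
  stopifnot(inherits(study, "physio_study"))
  d <- study$design
  per_participant <- study$recordings |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_split()

  feats <- purrr::map(per_participant, function(rec) {
    processed <- purrr::map(
      rec$data, process_trial,
      sample_rate_hz = d$sample_rate_hz,
      filter_specs = filter_specs, bounds = bounds
    )
    z <- standardize_participant(processed)
    f <- purrr::map(z, extract_feature,
      baseline_dur_s = d$baseline_dur_s, music_dur_s = d$music_dur_s
    ) |> purrr::list_rbind()
    dplyr::bind_cols(
      rec[, c("participant", "excerpt", "quadrant")], f
    )
  }) |> purrr::list_rbind()

  rating_means <- study$ratings |>
    dplyr::group_by(.data$excerpt) |>
    dplyr::summarise(
      mean_valence = mean(.data$valence),
      mean_arousal = mean(.data$arousal),
      .groups = "drop"
    )

  feats |>
    dplyr::group_by(.data$excerpt, .data$quadrant) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(.channels), mean),
      .groups = "drop"
    ) |>
    dplyr::left_join(rating_means, by = "excerpt") |>
    dplyr::arrange(match(.data$excerpt, d$excerpts$excerpt))
}
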