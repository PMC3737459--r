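# Synthetic study generator.
#
# Every trial is baseline (white noise listening) followed by music. Channel
# construction, per trial:
#   scl  — participant offset + slow AR(1) wander + planted music-window level
#          shift (valence-driven) + white measurement noise
#   ppg  — periodic asymmetric raised-cosine pulse train; instantaneous rate
#          follows the planted heart-rate law, with beat-to-beat jitter
#   resp — quasi-sinusoid whose instantaneous rate follows the planted
#          respiration law
#   zyg / corr — amplitude-modulated broadband noise; the music-window
#          amplitude carries the planted valence effect (the feature stage
#          rectifies EMG, so a mean shift would be invisible)
# Planted effects ramp in over the first 2 s of music rather than stepping,
# to mimic the sluggish onset of autonomic responses.

.EFFECT_RAMP_S <- 2
.SCL_WANDER_SD <- 0.05 # intrinsic electrodermal wander (AR1 stationary SD)
.SCL_WANDER_PHI <- 0.995

# deterministic per-trial substream: output independent of generation order
.trial_seed <- function(seed, participant, excerpt_idx) {
  as.integer((as.double(seed %% 1000003L) * 48271 +
    participant * 1299709 + excerpt_idx * 15485863) %% 2147483629)
}

# music-window channel laws for one excerpt under an effect model
.planted_levels <- function(excerpt_row, effects, hr_offset = 0, resp_offset = 0) {
  dv <- excerpt_row$latent_valence - 5
  da <- excerpt_row$latent_arousal - 5
  # interaction mode: valence reaches physiology only through its interplay
  # with arousal, so no single feature carries a linear valence signal
  v_drive <- if (effects$valence_interaction) dv * da / 2 else dv
  hr <- effects$hr_base_bpm + hr_offset + effects$hr_arousal_slope * da
  resp <- effects$resp_base + resp_offset +
    effects$resp_arousal_slope * da + effects$resp_valence_slope * v_drive
  list(
    hr_music_bpm = hr,
    resp_music_rate = resp,
    scl_shift = effects$scl_valence_slope * v_drive,
    zyg_amp = 1 + effects$zyg_valence_slope * v_drive,
    corr_amp = 1 + effects$corr_valence_slope * v_drive
  )
}

.check_rate <- function(rate, lo, hi, channel, excerpt) {
  if (any(rate < lo | rate > hi)) {
    abort(paste0(
      "planted ", channel, " rate ", round(min(rate), 1), "-",
      round(max(rate), 1), " outside [", lo, ", ", hi, "] for excerpt ",
      excerpt, "; reduce the corresponding slope"
    ))
  }
}

# asymmetric raised-cosine pulse: fast upstroke (30% of width), slower decay
.pulse_shape <- function(n_samp) {
  s <- seq(0, 1, length.out = n_samp)
  a <- 0.3
  ifelse(s <= a,
    (1 - cos(pi * s / a)) / 2,
    (1 + cos(pi * (s - a) / (1 - a))) / 2
  )
}

# beat times from an instantaneous-rate function over [0, dur)
.beat_times <- function(rate_fun, dur, jitter_cv) {
  times <- numeric(0)
  t <- runif(1) * 60 / rate_fun(0) # random initial phase
  while (t < dur) {
    times <- c(times, t)
    gap <- 60 / rate_fun(t)
    if (jitter_cv > 0) gap <- gap * max(0.5, 1 + rnorm(1, 0, jitter_cv))
    t <- t + gap
  }
  times
}

#' Simulate one physiological trial
#'
#' Generates the five-channel recording of one participant listening to a
#' white-noise baseline followed by one music excerpt. Used by
#' [simulate_study()]; exposed so single trials with known planted structure
#' can be built directly (e.g. as fixtures with known beat times).
#'
#' @param excerpt_row One row of an excerpt table ([classical_excerpts()]).
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @param seed Integer seed for this trial's substream.
#' @param participant Participant id recorded in the output (default 1).
#' @param offsets Optional named list of per-participant offsets
#'   (`scl`, `ppg`, `resp`, `zyg`, `corr` additive; `hr_bpm`, `resp_rate` on
#'   the rate laws); defaults to all zero.
#'
#' @return A tibble with columns `participant`, `excerpt`, `time_s`, `scl`,
#'   `ppg`, `resp`, `zyg`, `corr`, carrying attributes `beat_times`
#'   (planted cardiac beat onsets, seconds) and `planted` (the music-window
#'   channel laws used).
#' @examples
#' ex <- classical_excerpts()[1, ]
#' trial <- simulate_trial(ex, study_design(n_participants = 1), effect_model(), seed = 7)
#' head(trial)
#' @export
simulate_trial <- function(excerpt_row, design, effects, seed,
                           participant = 1L, offsets = NULL) {
  if (is.null(offsets)) {
    offsets <- list(
      scl = 0, ppg = 0, resp = 0, zyg = 0, corr = 0,
      hr_bpm = 0, resp_rate = 0
    )
  }
  fs <- design$sample_rate_hz
  tb <- design$baseline_dur_s
  tm <- design$music_dur_s
  dur <- tb + tm
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  ns <- effects$channel_noise_sd

  lv <- .planted_levels(excerpt_row, effects, offsets$hr_bpm, offsets$resp_rate)
  .check_rate(c(effects$hr_base_bpm + offsets$hr_bpm, lv$hr_music_bpm),
    40, 180, "heart-rate", excerpt_row$excerpt
  )
  .check_rate(c(effects$resp_base + offsets$resp_rate, lv$resp_music_rate),
    5, 60, "respiration", excerpt_row$excerpt
  )
  if (lv$zyg_amp <= 0 || lv$corr_amp <= 0) {
    abort(paste0(
      "planted EMG amplitude non-positive for excerpt ", excerpt_row$excerpt,
      " (channel ", if (lv$zyg_amp <= 0) "zyg" else "corr", ")"
    ))
  }

  set.seed(seed)
  ramp <- pmin(1, pmax(0, (t - tb) / .EFFECT_RAMP_S))

  # --- SCL: offset + planted shift + AR(1) wander + measurement noise
  innov_sd <- .SCL_WANDER_SD * sqrt(1 - .SCL_WANDER_PHI^2)
  wander <- as.numeric(stats::filter(rnorm(n, 0, innov_sd),
    .SCL_WANDER_PHI,
    method = "recursive"
  ))
  scl <- offsets$scl + lv$scl_shift * ramp + wander +
    if (ns[["scl"]] > 0) rnorm(n, 0, ns[["scl"]]) else 0

  # --- PPG: pulse train under the planted rate law
  hr_base <- effects$hr_base_bpm + offsets$hr_bpm
  hr_fun <- function(tt) {
    hr_base + (lv$hr_music_bpm - hr_base) *
      pmin(1, pmax(0, (tt - tb) / .EFFECT_RAMP_S))
  }
  beats <- .beat_times(hr_fun, dur, effects$beat_jitter_cv)
  ppg <- numeric(n)
  gaps <- diff(c(beats, dur))
  for (b in seq_along(beats)) {
    width <- min(0.45, 0.9 * gaps[b])
    i0 <- floor(beats[b] * fs) + 1
    i1 <- min(n, floor((beats[b] + width) * fs) + 1)
    if (i1 > i0) ppg[i0:i1] <- ppg[i0:i1] + .pulse_shape(i1 - i0 + 1)
  }
  ppg <- ppg + offsets$ppg +
    if (ns[["ppg"]] > 0) rnorm(n, 0, ns[["ppg"]]) else 0

  # --- respiration: quasi-sinusoid under the planted rate law
  resp_base <- effects$resp_base + offsets$resp_rate
  resp_rate_t <- resp_base + (lv$resp_music_rate - resp_base) * ramp
  phase <- 2 * pi * cumsum(resp_rate_t / 60) / fs + runif(1) * 2 * pi
  resp <- sin(phase) + offsets$resp +
    if (ns[["resp"]] > 0) rnorm(n, 0, ns[["resp"]]) else 0

  # --- EMG: amplitude-modulated broadband noise
  zyg_amp <- 1 + (lv$zyg_amp - 1) * ramp
  corr_amp <- 1 + (lv$corr_amp - 1) * ramp
  zyg <- zyg_amp * rnorm(n) + offsets$zyg +
    if (ns[["zyg"]] > 0) rnorm(n, 0, ns[["zyg"]]) else 0
  corr <- corr_amp * rnorm(n) + offsets$corr +
    if (ns[["corr"]] > 0) rnorm(n, 0, ns[["corr"]]) else 0

  out <- tibble::tibble(
    participant = as.integer(participant),
    excerpt = excerpt_row$excerpt,
    time_s = t,
    scl = scl, ppg = ppg, resp = resp, zyg = zyg, corr = corr
  )
  attr(out, "beat_times") <- beats
  attr(out, "planted") <- lv
  out
}

#' Simulate a complete listening study
#'
#' Generates all trials (every participant hears every excerpt) plus the
#' per-trial valence/arousal ratings. Each trial uses an RNG substream
#' derived deterministically from the study seed and the (participant,
#' excerpt) pair, so identical inputs give identical output regardless of
#' generation order.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#'
#' @return An object of class `physio_study`: a list with
#'   \describe{
#'   \item{recordings}{tibble with one row per trial: `participant`,
#'     `excerpt`, `quadrant`, and a `data` list-column of per-trial sample
#'     tibbles (`time_s`, `scl`, `ppg`, `resp`, `zyg`, `corr`).}
#'   \item{ratings}{tibble `participant`, `excerpt`, `valence`, `arousal`
#'     (integers 1-9).}
#'   \item{truth}{tibble of planted music-window levels per trial, for
#'     oracle checks: `hr_music_bpm`, `resp_music_rate`, `scl_shift`,
#'     `zyg_amp`, `corr_amp`, `n_music_beats`.}
#'   \item{design, effects}{the inputs.}
#'   }
#' @examples
#' study <- simulate_study(study_design(n_participants = 2, seed = 1), effect_model())
#' study$ratings
#' @export
simulate_study <- function(design, effects = effect_model()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_model"))
  exc <- design$excerpts
  ns <- effects$channel_noise_sd

  rows <- tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    excerpt_idx = seq_len(nrow(exc))
  )

  # per-participant offsets from a participant-level substream (excerpt 0)
  offsets_for <- function(p) {
    set.seed(.trial_seed(design$seed, p, 0L))
    f <- effects$participant_sd_frac
    list(
      scl = rnorm(1, 0, f * ns[["scl"]]),
      ppg = rnorm(1, 0, f * ns[["ppg"]]),
      resp = rnorm(1, 0, f * ns[["resp"]]),
      zyg = rnorm(1, 0, f * ns[["zyg"]]),
      corr = rnorm(1, 0, f * ns[["corr"]]),
      # modest inter-individual resting-rate variation; removed downstream by
      # per-participant standardization but kept for realism
      hr_bpm = rnorm(1, 0, 3),
      resp_rate = rnorm(1, 0, 1)
    )
  }
  all_offsets <- purrr::map(seq_len(design$n_participants), offsets_for)

  one_trial <- function(p, ei) {
    ex <- exc[ei, ]
    tseed <- .trial_seed(design$seed, p, ei)
    trial <- simulate_trial(ex, design, effects,
      seed = tseed,
      participant = p, offsets = all_offsets[[p]]
    )
    # ratings drawn from the same substream, after the channels
    vr <- sample_ratings(ex, effects)
    beats <- attr(trial, "beat_times")
    lv <- attr(trial, "planted")
    attr(trial, "beat_times") <- NULL
    attr(trial, "planted") <- NULL
    list(
      recording = tibble::tibble(
        participant = as.integer(p), excerpt = ex$excerpt,
        quadrant = ex$quadrant,
        data = list(trial[, c("time_s", "scl", "ppg", "resp", "zyg", "corr")])
      ),
      rating = tibble::tibble(
        participant = as.integer(p), excerpt = ex$excerpt,
        valence = vr$valence, arousal = vr$arousal
      ),
      truth = tibble::tibble(
        participant = as.integer(p), excerpt = ex$excerpt,
        hr_music_bpm = lv$hr_music_bpm, resp_music_rate = lv$resp_music_rate,
        scl_shift = lv$scl_shift, zyg_amp = lv$zyg_amp, corr_amp = lv$corr_amp,
        n_music_beats = sum(beats >= design$baseline_dur_s)
      )
    )
  }

  parts <- purrr::pmap(rows, function(participant, excerpt_idx) {
    one_trial(participant, excerpt_idx)
  })

  structure(
    list(
      recordings = purrr::list_rbind(purrr::map(parts, "recording")),
      ratings = purrr::list_rbind(purrr::map(parts, "rating")),
      truth = purrr::list_rbind(purrr::map(parts, "truth")),
      design = design,
      effects = effects
    ),
    class = "physio_study"
  )
}

#' @export
print.physio_study <- function(x, ...) {
  cat(
    "<physio_study> ", x$design$n_participants, " participants x ",
    nrow(x$design$excerpts), " excerpts (", nrow(x$recordings),
    " trials @ ", x$design$sample_rate_hz, " Hz)\n",
    sep = ""
  )
  invisible(x)
}

#' Draw one valence/arousal rating
#'
#' Ratings are the excerpt's latent value plus Gaussian between-participant
#' noise, rounded to the integer 1-9 scale and clipped at its ends.
#'
#' @param excerpt_row One row of an excerpt table.
#' @param effects An [effect_model()] (uses `rating_noise_sd`).
#' @return A list with integer `valence` and `arousal`.
#' @examples
#' set.seed(1)
#' sample_ratings(classical_excerpts()[1, ], effect_model())
#' @export
sample_ratings <- function(excerpt_row, effects) {
  draw <- function(latent) {
    as.integer(round(pmin(9, pmax(1, latent + rnorm(1, 0, effects$rating_noise_sd)))))
  }
  list(
    valence = draw(excerpt_row$latent_valence),
    arousal = draw(excerpt_row$latent_arousal)
  )
}

#' Write a simulated study to disk
#'
#' One CSV per trial (`<participant>_<excerpt>.csv` with columns `time_s`,
#' `scl`, `ppg`, `resp`, `zyg`, `corr`), a `ratings.csv`, and a
#' `manifest.json` echoing the design and seed.
#'
#' @param study A `physio_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "physio_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::pwalk(
    study$recordings,
    function(participant, excerpt, quadrant, data) {
      readr::write_csv(
        data,
        file.path(dir, paste0("P", participant, "_", excerpt, ".csv"))
      )
    }
  )
  readr::write_csv(study$ratings, file.path(dir, "ratings.csv"))
  d <- study$design
  manifest <- list(
    n_participants = d$n_participants,
    excerpts = d$excerpts,
    sample_rate_hz = d$sample_rate_hz,
    baseline_dur_s = d$baseline_dur_s,
    music_dur_s = d$music_dur_s,
    seed = d$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a study from the on-disk CSV layout
#'
#' Inverse of [write_study()] (the `effects` and planted `truth` are not
#' stored on disk and come back as `NULL`).
#'
#' @param dir Directory written by [write_study()].
#' @return A `physio_study`.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  excerpts <- tibble::as_tibble(manifest$excerpts)
  design <- study_design(
    n_participants = manifest$n_participants,
    excerpts = excerpts,
    sample_rate_hz = manifest$sample_rate_hz,
    baseline_dur_s = manifest$baseline_dur_s,
    music_dur_s = manifest$music_dur_s,
    seed = manifest$seed
  )
  ratings <- readr::read_csv(file.path(dir, "ratings.csv"),
    show_col_types = FALSE
  )
  recordings <- tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    excerpt = excerpts$excerpt
  ) |>
    dplyr::left_join(
      excerpts[, c("excerpt", "quadrant")],
      by = "excerpt"
    ) |>
    dplyr::mutate(
      data = purrr::map2(
        .data$participant, .data$excerpt,
        function(p, e) {
          readr::read_csv(file.path(dir, paste0("P", p, "_", e, ".csv")),
            show_col_types = FALSE
          )
        }
      )
    )
  structure(
    list(
      recordings = recordings, ratings = ratings, truth = NULL,
      design = design, effects = NULL
    ),
    class = "physio_study"
  )
}
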