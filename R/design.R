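#' Study design for a synthetic listening session
#'
#' Describes the layout every generated study follows: each participant hears
#' every excerpt once, each trial being a white-noise baseline followed
#' immediately by the music excerpt, with five physiological channels sampled
#' continuously throughout.
#'
#' @param n_participants Number of participants with complete data (default 20).
#' @param excerpts Excerpt table as produced by [classical_excerpts()]:
#'   one row per excerpt with `excerpt`, `quadrant`, `latent_valence`,
#'   `latent_arousal`.
#' @param sample_rate_hz Sampling rate of all channels in Hz. Default 100;
#'   the original acquisition hardware ran at 1000 Hz, which is supported but
#'   slower to simulate.
#' @param baseline_dur_s Duration of the white-noise baseline in seconds
#'   (default 30). Must be at least 20 s, since the baseline feature window
#'   is the final 20 s of noise.
#' @param music_dur_s Duration of the music excerpt in seconds (default 40).
#' @param seed Integer seed controlling every random component of the study.
#'
#' @return An object of class `study_design` (a list).
#' @examples
#' study_design(n_participants = 4, seed = 1)
#' @export
study_design <- function(n_participants = 20,
                         excerpts = classical_excerpts(),
                         sample_rate_hz = 100,
                         baseline_dur_s = 30,
                         music_dur_s = 40,
                         seed = 1L) {
  if (n_participants < 1) abort("n_participants must be >= 1")
  if (baseline_dur_s < 20) {
    abort("baseline_dur_s must be >= 20 (the baseline feature window needs 20 s)")
  }
  if (music_dur_s <= 10) abort("music_dur_s must be > 10")
  if (sample_rate_hz <= 0) abort("sample_rate_hz must be positive")
  validate_excerpts(excerpts)
  structure(
    list(
      n_participants = as.integer(n_participants),
      excerpts = tibble::as_tibble(excerpts),
      sample_rate_hz = sample_rate_hz,
      baseline_dur_s = baseline_dur_s,
      music_dur_s = music_dur_s,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(
    "<study_design> ", x$n_participants, " participants x ",
    nrow(x$excerpts), " excerpts; ", x$baseline_dur_s, " s baseline + ",
    x$music_dur_s, " s music @ ", x$sample_rate_hz, " Hz; seed ", x$seed,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Planted physiological effect model
#'
#' Defines how the latent valence and arousal of an excerpt shape the five
#' generated channels during the music segment, relative to baseline.
#' Directions follow the psychophysiology literature this pipeline targets:
#' heart rate and respiration rise with arousal; skin conductance and
#' corrugator (frowning) EMG are higher for negative valence; respiration and
#' zygomaticus (smiling) EMG are higher for positive valence. Latent values
#' enter all laws centered on the scale midpoint 5.
#'
#' @param hr_base_bpm Resting heart rate in beats/min (default 72).
#' @param hr_arousal_slope Heart-rate increase per arousal unit, beats/min
#'   (default 2.5).
#' @param resp_base Resting respiration rate in breaths/min (default 15).
#' @param resp_arousal_slope Respiration increase per arousal unit,
#'   breaths/min (default 1).
#' @param resp_valence_slope Respiration increase per valence unit,
#'   breaths/min (default 0.4, positive).
#' @param scl_valence_slope Skin-conductance music-minus-baseline shift per
#'   valence unit, in conductance units (default -0.10, negative: SCL higher
#'   for unpleasant excerpts).
#' @param corr_valence_slope Fractional corrugator EMG amplitude change per
#'   valence unit (default -0.12, negative).
#' @param zyg_valence_slope Fractional zygomaticus EMG amplitude change per
#'   valence unit (default 0.06, positive and small).
#' @param rating_noise_sd Between-participant SD of valence/arousal ratings
#'   around the excerpt's latent value, in rating units (default 1.8, the
#'   inter-subject variability the rating model is anchored to).
#' @param channel_noise_sd Named numeric vector of additive measurement-noise
#'   SDs for channels `scl`, `ppg`, `resp`, `zyg`, `corr` (channel units).
#' @param participant_sd_frac Per-participant random baseline offsets are
#'   drawn with SD equal to this fraction of the channel noise SD
#'   (default 0.5).
#' @param beat_jitter_cv Coefficient of variation of beat-to-beat interval
#'   jitter in the cardiac pulse train (default 0.03).
#' @param valence_interaction If `TRUE`, every valence-coupled channel
#'   responds to the valence-by-arousal interaction
#'   (`(valence - 5) * (arousal - 5) / 2`) instead of valence alone. This
#'   plants a valence link that no linear function of the five features can
#'   capture, for comparing linear and non-linear models. Default `FALSE`.
#'
#' @return An object of class `effect_model` (a list).
#' @examples
#' effect_model()
#' effect_model(hr_arousal_slope = 0) # no cardiac arousal effect
#' @export
effect_model <- function(hr_base_bpm = 72,
                         hr_arousal_slope = 2.5,
                         resp_base = 15,
                         resp_arousal_slope = 1,
                         resp_valence_slope = 0.4,
                         scl_valence_slope = -0.10,
                         corr_valence_slope = -0.12,
                         zyg_valence_slope = 0.06,
                         rating_noise_sd = 1.8,
                         channel_noise_sd = c(
                           scl = 0.05, ppg = 0.05, resp = 0.10,
                           zyg = 0.02, corr = 0.02
                         ),
                         participant_sd_frac = 0.5,
                         beat_jitter_cv = 0.03,
                         valence_interaction = FALSE) {
  if (rating_noise_sd <= 0) abort("rating_noise_sd must be > 0")
  want <- c("scl", "ppg", "resp", "zyg", "corr")
  if (!all(want %in% names(channel_noise_sd))) {
    abort("channel_noise_sd must name all of scl, ppg, resp, zyg, corr")
  }
  if (any(channel_noise_sd < 0)) abort("channel_noise_sd must be >= 0")
  structure(
    list(
      hr_base_bpm = hr_base_bpm,
      hr_arousal_slope = hr_arousal_slope,
      resp_base = resp_base,
      resp_arousal_slope = resp_arousal_slope,
      resp_valence_slope = resp_valence_slope,
      scl_valence_slope = scl_valence_slope,
      corr_valence_slope = corr_valence_slope,
      zyg_valence_slope = zyg_valence_slope,
      rating_noise_sd = rating_noise_sd,
      channel_noise_sd = channel_noise_sd[want],
      participant_sd_frac = participant_sd_frac,
      beat_jitter_cv = beat_jitter_cv,
      valence_interaction = isTRUE(valence_interaction)
    ),
    class = "effect_model"
  )
}

#' Effect model with every planted slope set to zero
#'
#' Convenience null model: channels retain their resting dynamics and noise
#' but no excerpt-dependent effect, so downstream features carry no signal.
#'
#' @param ... Passed to [effect_model()] to override non-slope components.
#' @return An `effect_model`.
#' @export
null_effect_model <- function(...) {
  effect_model(
    hr_arousal_slope = 0, resp_arousal_slope = 0, resp_valence_slope = 0,
    scl_valence_slope = 0, corr_valence_slope = 0, zyg_valence_slope = 0,
    ...
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat(
    "  HR:   ", x$hr_base_bpm, " bpm + ", x$hr_arousal_slope,
    " bpm/arousal unit\n",
    sep = ""
  )
  cat(
    "  Resp: ", x$resp_base, " br/min + ", x$resp_arousal_slope,
    "/arousal + ", x$resp_valence_slope, "/valence unit\n",
    sep = ""
  )
  cat(
    "  SCL slope ", x$scl_valence_slope, "/valence; Corr ",
    x$corr_valence_slope, ", Zyg ", x$zyg_valence_slope, " (fractional)\n",
    sep = ""
  )
  cat(
    "  rating noise SD ", x$rating_noise_sd,
    if (x$valence_interaction) "; valence x arousal interaction mode" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}
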