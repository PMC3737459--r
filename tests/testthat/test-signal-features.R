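test_that("filters pass through, remove DC, and attenuate out-of-band power", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 2 * t)

  # none/none spec is the identity
  expect_identical(apply_filter(x, filter_spec("scl"), fs), x)

  # out-of-band 0.1 Hz component attenuated >= 20 dB relative to in-band 2 Hz
  y <- apply_filter(x, filter_spec("hr", hp_hz = 0.5, lp_hz = 3), fs)
  keep <- t >= 5 & t <= 55 # discard filter edges
  amp_at <- function(sig, f) {
    n <- sum(keep)
    sp <- abs(stats::fft(sig[keep]))[seq_len(n %/% 2)]
    freqs <- (seq_len(n %/% 2) - 1) * fs / n
    max(sp[abs(freqs - f) < 0.05])
  }
  gain_01 <- amp_at(y, 0.1) / amp_at(x, 0.1)
  gain_2 <- amp_at(y, 2) / amp_at(x, 2)
  expect_gt(20 * log10(gain_2 / gain_01), 20)

  # constant series through any high-pass is ~0 away from the edges
  z <- apply_filter(rep(3, length(t)), filter_spec("zyg", hp_hz = 1, lp_hz = 40), fs)
  expect_lt(abs(mean(z[keep])), 1e-6)

  # low-pass at/above Nyquist clamps with a warning (EMG spec at 100 Hz)
  expect_warning(
    apply_filter(x, filter_spec("zyg", hp_hz = 1, lp_hz = 500), fs),
    "clamped to 45"
  )
  expect_error(apply_filter(c(1, NA, 2), filter_spec("hr", 0.5, 3), fs), "non-finite")
})

test_that("rate detection recovers known frequencies and rejects out-of-bound ones", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  # pure 1 Hz tone under cardiac bounds -> 60 events/min everywhere
  det <- detect_rate_series(sin(2 * pi * t), rate_bounds("hr", 40, 180), fs)
  expect_true(all(abs(det$rate - 60) < 1))

  # 0.05 Hz tone implies 3/min, below the 5/min respiration floor
  expect_error(
    detect_rate_series(sin(2 * pi * 0.05 * t), rate_bounds("resp", 5, 180), fs),
    "resp"
  )

  # series far too short for the channel's slowest admissible rate
  expect_error(
    detect_rate_series(sin(2 * pi * t[t < 5]), rate_bounds("resp", 5, 180), fs),
    "too short"
  )
})

test_that("detected event times match a pulse fixture with known peaks", {
  fs <- 100
  dur <- 60
  n <- dur * fs
  set.seed(4)
  onsets <- cumsum(c(0.4, 0.75 * (1 + rnorm(70, 0, 0.05))))
  onsets <- onsets[onsets < dur - 1]
  width <- 0.4
  x <- numeric(n)
  peak_idx <- integer(0)
  shape <- function(s) ifelse(s <= 0.3, (1 - cos(pi * s / 0.3)) / 2,
    (1 + cos(pi * (s - 0.3) / 0.7)) / 2
  )
  for (on in onsets) {
    i0 <- floor(on * fs) + 1
    i1 <- min(n, i0 + round(width * fs))
    s <- seq(0, 1, length.out = i1 - i0 + 1)
    x[i0:i1] <- x[i0:i1] + shape(s)
    peak_idx <- c(peak_idx, i0 + which.max(shape(s)) - 1L)
  }
  det <- detect_rate_series(x, rate_bounds("hr", 40, 180), fs)
  truth <- (peak_idx - 1) / fs
  expect_equal(length(det$event_times), length(truth))
  expect_true(all(abs(det$event_times - truth) <= 1 / fs + 1e-9))
})

test_that("per-participant standardization yields pooled z-scores", {
  mk <- function(val) {
    tibble::tibble(
      time_s = 1:10, scl = val + rnorm(10), hr = val + rnorm(10),
      resp = val + rnorm(10), zyg = val + rnorm(10), corr = val + rnorm(10)
    )
  }
  set.seed(8)
  z <- standardize_participant(list(mk(0), mk(5)))
  pooled <- dplyr::bind_rows(z)
  for (ch in c("scl", "hr", "resp", "zyg", "corr")) {
    expect_lt(abs(mean(pooled[[ch]])), 1e-9)
    expect_lt(abs(sd(pooled[[ch]]) - 1), 1e-9)
  }

  # hand case: within-trial-constant channels at 0 and 10 -> z = -1 / +1
  mkc <- function(val) {
    tibble::tibble(
      time_s = 1:4, scl = val, hr = val, resp = val, zyg = val, corr = val
    )
  }
  zc <- standardize_participant(list(mkc(0), mkc(10)))
  pooled_sd <- sd(c(rep(0, 4), rep(10, 4))) # 5.345...
  expect_equal(unique(zc[[1]]$scl), -5 / pooled_sd)
  expect_equal(unique(zc[[2]]$scl), 5 / pooled_sd)

  # degenerate constant channel
  expect_error(standardize_participant(list(mkc(1))), "zero pooled SD")
})

test_that("feature windows use exactly the final 20 s of baseline and music 10-40 s", {
  fs <- 100
  t <- seq(0, 70 - 1 / fs, by = 1 / fs)
  base_win <- t >= 10 & t < 30
  music_win <- t >= 40 & t < 70
  expect_equal(sum(base_win), 20 * fs)
  expect_equal(sum(music_win), 30 * fs)

  # garbage outside the windows must not leak into the feature
  z <- numeric(length(t))
  z[t < 10] <- 99 # baseline startle region, excluded
  z[t >= 30 & t < 40] <- -99 # music startle region, excluded
  z[music_win] <- 1
  trial <- tibble::tibble(
    time_s = t, scl = z, hr = z, resp = z, zyg = z, corr = z
  )
  f <- extract_feature(trial)
  expect_equal(unlist(f), c(scl = 1, hr = 1, resp = 1, zyg = 1, corr = 1))

  # identical windows -> zero feature
  trial0 <- dplyr::mutate(trial, dplyr::across(-"time_s", ~0))
  expect_true(all(unlist(extract_feature(trial0)) == 0))

  # a window extending past the segment is an error
  expect_error(extract_feature(trial[t < 60, ]), "shorter")
})

test_that("features are invariant to constant channel offsets", {
  design <- study_design(n_participants = 1, seed = 31, sample_rate_hz = 50)
  study <- simulate_study(design, effect_model())
  shifted <- study
  shifted$recordings$data <- purrr::map(
    shifted$recordings$data,
    function(d) dplyr::mutate(d, scl = scl + 7)
  )
  f1 <- extract_features(study)
  f2 <- extract_features(shifted)
  expect_equal(f1$scl, f2$scl, tolerance = 1e-9)
})

test_that("zero-noise rate extraction matches the planted rate within 2%", {
  ex <- classical_excerpts()[6, ]
  design <- study_design(n_participants = 1, seed = 13)
  eff <- effect_model(
    beat_jitter_cv = 0,
    channel_noise_sd = c(scl = 0.01, ppg = 0, resp = 0, zyg = 0.02, corr = 0.02)
  )
  trial <- simulate_trial(ex, design, eff, seed = 3)
  planted <- attr(trial, "planted")
  proc <- process_trial(trial, design$sample_rate_hz)
  music <- proc$time_s >= 40 # past the effect ramp
  expect_lt(
    abs(mean(proc$hr[music]) - planted$hr_music_bpm) / planted$hr_music_bpm, 0.02
  )
  expect_lt(
    abs(mean(proc$resp[music]) - planted$resp_music_rate) / planted$resp_music_rate,
    0.02
  )
})

test_that("the feature matrix is the participant mean of individual features", {
  design <- study_design(n_participants = 2, seed = 17, sample_rate_hz = 50)
  study <- simulate_study(design, effect_model())
  fm <- extract_features(study)
  expect_equal(fm$excerpt, classical_excerpts()$excerpt)

  single <- function(p) {
    sub <- study
    sub$recordings <- sub$recordings[sub$recordings$participant == p, ]
    sub$ratings <- sub$ratings[sub$ratings$participant == p, ]
    sub$design$n_participants <- 1L
    extract_features(sub)
  }
  f1 <- single(1)
  f2 <- single(2)
  for (ch in c("scl", "hr", "resp", "zyg", "corr")) {
    expect_equal(fm[[ch]], (f1[[ch]] + f2[[ch]]) / 2, tolerance = 1e-9)
  }
  expect_equal(fm$mean_valence, (f1$mean_valence + f2$mean_valence) / 2)
})
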