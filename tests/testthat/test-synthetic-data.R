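test_that("study generation produces the full trial grid deterministically", {
  design <- study_design(n_participants = 2, seed = 42, sample_rate_hz = 50)
  study <- simulate_study(design, effect_model())

  expect_equal(nrow(study$recordings), 2 * 12)
  expect_equal(nrow(study$ratings), 2 * 12)
  expect_true(all(study$ratings$valence %in% 1:9))
  expect_true(all(study$ratings$arousal %in% 1:9))

  n_expected <- round((30 + 40) * 50)
  expect_true(all(vapply(study$recordings$data, nrow, integer(1)) == n_expected))
  expect_false(anyNA(dplyr::bind_rows(study$recordings$data)))

  # identical seed => identical output; different seed => different
  study2 <- simulate_study(design, effect_model())
  expect_identical(study$ratings, study2$ratings)
  expect_identical(study$recordings$data[[5]], study2$recordings$data[[5]])
  study3 <- simulate_study(
    study_design(n_participants = 2, seed = 43, sample_rate_hz = 50),
    effect_model()
  )
  expect_false(identical(study$ratings, study3$ratings))
})

test_that("the on-disk CSV layout round-trips byte-identically", {
  design <- study_design(
    n_participants = 1, seed = 7, sample_rate_hz = 50,
    excerpts = classical_excerpts()[c(1, 4, 7, 10), ]
  )
  study <- simulate_study(design, effect_model())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(study, d1)
  write_study(simulate_study(design, effect_model()), d2)
  for (f in list.files(d1)) {
    expect_identical(
      tools::md5sum(file.path(d1, f))[[1]],
      tools::md5sum(file.path(d2, f))[[1]]
    )
  }
  back <- read_study(d1)
  expect_equal(back$ratings$valence, study$ratings$valence)
  expect_equal(
    back$recordings$data[[2]]$ppg, study$recordings$data[[2]]$ppg,
    tolerance = 1e-9
  )
})

test_that("rating sampler matches its latent-plus-noise law", {
  ex <- classical_excerpts()[5, ] # latent valence 5.75, arousal 6.25
  # near-zero noise: rating = round(latent)
  eff0 <- effect_model(rating_noise_sd = 1e-9)
  set.seed(1)
  r <- sample_ratings(ex, eff0)
  expect_identical(r$valence, 6L)
  expect_identical(r$arousal, 6L)

  # clipping: latent at the ceiling never exceeds 9
  ex9 <- ex
  ex9$latent_valence <- 9
  set.seed(2)
  eff_loud <- effect_model(rating_noise_sd = 3)
  draws <- replicate(200, sample_ratings(ex9, eff_loud)$valence)
  expect_true(all(draws <= 9L & draws >= 1L))

  # Monte-Carlo: at a mid-scale latent the clipped/rounded SD ~ 1.78
  ex5 <- ex
  ex5$latent_valence <- 5
  set.seed(3)
  draws <- replicate(10000, sample_ratings(ex5, effect_model())$valence)
  expect_lt(abs(sd(draws) - 1.78), 0.1)
})

test_that("cardiac pulse train carries the planted beat structure", {
  ex <- classical_excerpts()[3, ] # high arousal
  design <- study_design(n_participants = 1, seed = 1)
  eff <- effect_model(
    beat_jitter_cv = 0,
    channel_noise_sd = c(scl = 0.05, ppg = 0, resp = 0.05, zyg = 0.02, corr = 0.02)
  )
  trial <- simulate_trial(ex, design, eff, seed = 11)
  beats <- attr(trial, "beat_times")
  planted <- attr(trial, "planted")

  # planted music-window beat count = integral of the instantaneous rate +- 1
  hr_base <- eff$hr_base_bpm
  hr_music <- planted$hr_music_bpm
  rate_at <- function(t) hr_base + (hr_music - hr_base) * pmin(1, pmax(0, (t - 30) / 2))
  expected_beats <- stats::integrate(rate_at, 30, 70)$value / 60
  expect_lte(abs(sum(beats >= 30) - expected_beats), 1)

  # detection recovers those beats in the music window within +- 1
  wave <- apply_filter(trial$ppg, filter_spec("hr", 0.5, 3), design$sample_rate_hz)
  det <- detect_rate_series(wave, rate_bounds("hr", 40, 180), design$sample_rate_hz)
  expect_lte(abs(sum(det$event_times >= 30) - sum(beats >= 30)), 1)
})

test_that("with zero planted slopes the features carry no affect signal", {
  eff <- null_effect_model(
    channel_noise_sd = c(scl = 0, ppg = 0, resp = 0, zyg = 0, corr = 0)
  )
  study <- simulate_study(study_design(n_participants = 3, seed = 5), eff)
  fm <- extract_features(study)
  ex <- classical_excerpts()
  # every planted-direction correlation is non-significant
  expect_gt(pearson_cor(fm$hr, ex$latent_arousal)$p, 0.05)
  expect_gt(pearson_cor(fm$resp, ex$latent_arousal)$p, 0.05)
  expect_gt(pearson_cor(fm$scl, ex$latent_valence)$p, 0.05)
  expect_gt(pearson_cor(fm$corr, ex$latent_valence)$p, 0.05)
  expect_gt(pearson_cor(fm$zyg, ex$latent_valence)$p, 0.05)
  # and features average out near zero across excerpts
  expect_lt(max(abs(colMeans(fm[, c("scl", "hr", "resp", "zyg", "corr")]))), 0.3)
})

test_that("with default effects the heart-rate feature tracks latent arousal", {
  study <- simulate_study(study_design(n_participants = 2, seed = 21), effect_model())
  fm <- extract_features(study)
  r <- pearson_cor(fm$hr, classical_excerpts()$latent_arousal)
  expect_gt(r$r, 0.7)
})

test_that("physiologically impossible planted rates abort naming the channel", {
  ex <- classical_excerpts()[3, ] # arousal 7.15
  design <- study_design(n_participants = 1, seed = 1)
  expect_error(
    simulate_trial(ex, design, effect_model(hr_arousal_slope = 60), seed = 1),
    "heart-rate"
  )
  expect_error(
    simulate_trial(ex, design, effect_model(resp_arousal_slope = 30), seed = 1),
    "respiration"
  )
  expect_error(study_design(n_participants = 0), "n_participants")
  bad <- classical_excerpts()
  bad$quadrant[1] <- "Excited"
  expect_error(study_design(excerpts = bad), "quadrant")
})

test_that("null data rarely admits a stepwise predictor", {
  # with no planted effect, forward entry at alpha 0.10 over 5 candidates
  # should return the empty model in the majority of fits (expected empty
  # rate ~ 0.9^5 ~ 0.59 under independence); both rating dimensions of each
  # replicate study are fitted
  eff <- null_effect_model()
  empty <- 0
  total <- 0
  for (s in 1:25) {
    design <- study_design(n_participants = 4, seed = 300 + s, sample_rate_hz = 50)
    fm <- extract_features(simulate_study(design, eff))
    for (target in c("valence", "arousal")) {
      fit <- suppressWarnings(stepwise_forward(fm, target, alpha_enter = 0.10))
      empty <- empty + (length(fit$selected) == 0)
      total <- total + 1
    }
  }
  # 3-sigma binomial band around the predicted empty rate 0.9^5
  p0 <- 0.9^5
  band <- 3 * sqrt(p0 * (1 - p0) / total)
  expect_gt(empty / total, p0 - band)
  expect_lt(empty / total, p0 + band)
})
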