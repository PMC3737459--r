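test_that("weight initialization is uniform on the configured range", {
  cfg <- mlp_config(seed = 1)

  # degenerate range -> all zero
  w0 <- init_weights(mlp_config(init_low = 0, init_high = 0))
  expect_true(all(unlist(w0) == 0))

  # determinism under an identical RNG state
  set.seed(3)
  wa <- init_weights(cfg)
  set.seed(3)
  wb <- init_weights(cfg)
  expect_identical(wa, wb)

  # Monte-Carlo moment check against U(0, 0.05): mean 0.025
  set.seed(4)
  draws <- unlist(replicate(250, init_weights(cfg), simplify = FALSE))
  expect_gte(length(draws), 10000)
  expect_lt(abs(mean(draws) - 0.025), 0.002)
  expect_true(all(draws >= 0 & draws < 0.05))
})

test_that("forward pass matches closed-form evaluations", {
  cfg <- mlp_config()
  w0 <- init_weights(mlp_config(init_low = 0, init_high = 0))

  # zero network: outputs exactly (0.5, 0.5) -> rating (5, 5)
  o <- mlp_forward(w0, rep(0.3, 5), cfg)
  expect_equal(drop(o), c(0.5, 0.5))
  expect_equal(drop(unit_to_rating(o)), c(5, 5))

  # hand-set single-path subnetwork, no input squashing:
  # o = sigma(2 * sigma(x1)), x1 = 0 -> sigma(1) = 0.731...
  cfg_ns <- mlp_config(input_sigmoid = FALSE)
  w <- w0
  w$W_hi[1, 1] <- 1
  w$W_oh[1, 1] <- 2
  w$W_oh[1, 2:5] <- 0
  w$W_oh[2, ] <- 0
  o <- mlp_forward(w, c(0, 0.2, 0.4, 0.6, 0.8), cfg_ns)
  expect_equal(o[1, 1], 1 / (1 + exp(-2 * 0.5)), tolerance = 1e-12)

  # monotonicity along an all-positive path
  w2 <- w
  w2$W_hi[1, 1] <- 2
  o2 <- mlp_forward(w2, c(0.9, 0.2, 0.4, 0.6, 0.8), cfg_ns)
  o1 <- mlp_forward(w, c(0.9, 0.2, 0.4, 0.6, 0.8), cfg_ns)
  expect_gte(o2[1, 1], o1[1, 1])

  expect_warning(mlp_forward(w, c(2, 0, 0, 0, 0), cfg_ns), "outside")
  expect_error(mlp_forward(w, c(0.1, 0.2), cfg_ns), "width")
})

test_that("backprop gradients match central finite differences", {
  set.seed(7)
  for (flags in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))) {
    cfg <- mlp_config(input_sigmoid = flags[1], use_bias = flags[2])
    for (rep in 1:4) {
      w <- random_weights(cfg)
      x <- matrix(runif(8 * 5), 8, 5)
      y <- matrix(runif(8 * 2), 8, 2)
      g <- mlp_gradient(w, x, y, cfg)
      fd <- fd_gradient(w, x, y, cfg)
      expect_lt(max(abs(g$W_hi - fd$W_hi)), 1e-6)
      expect_lt(max(abs(g$W_oh - fd$W_oh)), 1e-6)
      if (cfg$use_bias) {
        expect_lt(max(abs(g$b_h - fd$b_h)), 1e-6)
        expect_lt(max(abs(g$b_o - fd$b_o)), 1e-6)
      }
    }
  }
})

test_that("one training epoch applies exactly the summed gradient step", {
  set.seed(9)
  cfg <- mlp_config(max_epochs = 1, learning_rate = 0.1)
  w <- init_weights(cfg)
  x <- matrix(runif(40), 8, 5)
  y <- matrix(runif(16), 8, 2)
  g <- mlp_gradient(w, x, y, cfg)
  fit <- train_mlp(x, y, cfg, weights = w)
  expect_equal(fit$weights$W_hi, w$W_hi - 0.1 * g$W_hi, tolerance = 1e-12)
  expect_equal(fit$weights$W_oh, w$W_oh - 0.1 * g$W_oh, tolerance = 1e-12)
  expect_equal(fit$weights$b_h, w$b_h - 0.1 * g$b_h, tolerance = 1e-12)
  expect_equal(fit$weights$b_o, w$b_o - 0.1 * g$b_o, tolerance = 1e-12)
})

test_that("training traces start at the already-optimal point when it is one", {
  # single pair with target (0.5, 0.5) and zero weights: MSE 0 from epoch 0
  cfg <- mlp_config(init_low = 0, init_high = 0, max_epochs = 200)
  set.seed(2)
  fit <- train_mlp(
    matrix(runif(5), 1, 5), matrix(c(0.5, 0.5), 1, 2), cfg
  )
  expect_equal(fit$trace$mse[1], 0, tolerance = 1e-24)
  expect_equal(fit$final_mse, 0, tolerance = 1e-24)
})

test_that("full-length training descends and never diverges across seeds", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(40), 8, 5)
    y <- matrix(runif(16, 0.1, 0.9), 8, 2)
    fit <- train_mlp(x, y, mlp_config(max_epochs = 20000))
    expect_lte(fit$final_mse, fit$trace$mse[1])
    expect_true(all(is.finite(fit$trace$mse)))
  }
})

test_that("rating scale maps invert exactly and predictions stay inside (1, 9)", {
  r <- seq(1, 9, by = 0.25)
  expect_equal(unit_to_rating(rating_to_unit(r)), r, tolerance = 1e-12)

  fm <- toy_features(seed = 11)
  ens <- suppressWarnings(run_trials(
    fm,
    config = mlp_config(n_trials = 3, max_epochs = 2000, seed = 5)
  ))
  p <- c(ens$predictions$predicted_valence, ens$predictions$predicted_arousal)
  expect_true(all(p > 1 & p < 9))
})

test_that("ensembles are reproducible and respect the train/test split", {
  fm <- toy_features(seed = 12)
  cfg <- mlp_config(n_trials = 3, max_epochs = 1000, seed = 42)

  # an ensemble of one reproduces a single train call
  cfg1 <- mlp_config(n_trials = 1, max_epochs = 1000, seed = 42)
  ens1 <- suppressWarnings(run_trials(fm, config = cfg1))
  set.seed(42)
  train <- fm[match(ens1$train_excerpts, fm$excerpt), ]
  sp <- scaling_params(train)
  single <- train_mlp(
    scale_inputs(train, sp),
    cbind(rating_to_unit(train$mean_valence), rating_to_unit(train$mean_arousal)),
    cfg1
  )
  expect_equal(ens1$fits[[1]]$weights, single$weights, tolerance = 1e-12)

  # identical per-trial seeds -> identical trials, zero ensemble spread
  ens_same <- suppressWarnings(
    run_trials(fm, config = cfg, trial_seeds = rep(7L, 3))
  )
  spread <- ens_same$predictions |>
    dplyr::group_by(excerpt) |>
    dplyr::summarise(s = sd(predicted_valence))
  expect_true(all(spread$s == 0))

  expect_error(
    run_trials(fm, train_excerpts = c("M1", "M3"), test_excerpts = c("M3")),
    "overlap"
  )
  fm_const <- fm
  fm_const$hr <- 1
  expect_error(run_trials(fm_const, config = cfg), "constant training feature")
})

test_that("ensembles trained on default synthetic studies predict held-out excerpts", {
  ens <- default_ensemble()
  es <- summarize_errors(ens$mean_predictions)
  # mean per-dimension test error within 1.5 rating units
  expect_true(all(es$summary$mean_error <= 1.5))
})

test_that("ensemble weights and scaling round-trip through JSON", {
  fm <- toy_features(seed = 13)
  ens <- suppressWarnings(run_trials(
    fm,
    config = mlp_config(n_trials = 2, max_epochs = 500, seed = 8)
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(ens, path)
  back <- read_ensemble_json(path)
  expect_equal(back$weights[[2]]$W_hi, ens$fits[[2]]$weights$W_hi, tolerance = 1e-12)
  expect_equal(back$scaling$min, ens$scaling$min, tolerance = 1e-12)
  expect_equal(back$test_excerpts, ens$test_excerpts)
  # restored weights predict identically
  x <- scale_inputs(fm[match(ens$test_excerpts, fm$excerpt), ], back$scaling)
  expect_equal(
    suppressWarnings(mlp_forward(back$weights[[1]], x, back$config)),
    suppressWarnings(mlp_forward(ens$fits[[1]]$weights, x, ens$config)),
    tolerance = 1e-12
  )
})
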