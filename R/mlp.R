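#' Configuration of the 5-5-2 backpropagation network
#'
#' The network maps the five scaled physiological features to scaled valence
#' and arousal through one hidden layer. The hidden layer is kept the same
#' size as the input layer as an overfitting guard, so `n_hidden` must equal
#' `n_in`. Weights start uniform on `[init_low, init_high)`; training is
#' full-batch gradient descent for exactly `max_epochs` epochs (no early
#' stopping), aiming at a mean squared error below `mse_target` on the scaled
#' targets. Inputs are passed through the logistic function before weighting
#' when `input_sigmoid` is on (the default, mirroring the training protocol
#' this package implements); the conventional variant without the input
#' squashing is available by switching it off.
#'
#' @param n_in,n_hidden,n_out Layer sizes (defaults 5, 5, 2).
#' @param learning_rate Gradient-descent step on the summed epoch update
#'   (default 0.1).
#' @param max_epochs Training epochs (default 80000).
#' @param mse_target Convergence criterion on the final scaled MSE
#'   (default 0.02); reported, not used to stop early.
#' @param init_low,init_high Uniform weight-initialization range
#'   (defaults 0 and 0.05).
#' @param input_sigmoid Squash inputs with the logistic function before the
#'   first weight layer (default `TRUE`).
#' @param use_bias Include bias terms on hidden and output units, initialized
#'   like weights (default `TRUE`). Without biases a sigmoid-output network
#'   with all-positive initial weights cannot reach targets below 0.5.
#' @param n_trials Number of independently re-initialized networks in an
#'   ensemble run (default 20).
#' @param trace_every Record the training MSE every this many epochs
#'   (default 100; epoch 0 and the final epoch are always recorded).
#' @param seed Integer seed for the ensemble run.
#' @return An object of class `mlp_config` (a list).
#' @export
mlp_config <- function(n_in = 5, n_hidden = 5, n_out = 2,
                       learning_rate = 0.1, max_epochs = 80000,
                       mse_target = 0.02, init_low = 0, init_high = 0.05,
                       input_sigmoid = TRUE, use_bias = TRUE,
                       n_trials = 20, trace_every = 100, seed = 1L) {
  if (n_hidden != n_in) {
    abort("n_hidden must equal n_in (overfitting guard)")
  }
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (init_high < init_low || init_low < 0) {
    abort("need init_high >= init_low >= 0")
  }
  structure(
    list(
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out), learning_rate = learning_rate,
      max_epochs = as.integer(max_epochs), mse_target = mse_target,
      init_low = init_low, init_high = init_high,
      input_sigmoid = isTRUE(input_sigmoid), use_bias = isTRUE(use_bias),
      n_trials = as.integer(n_trials), trace_every = as.integer(trace_every),
      seed = as.integer(seed)
    ),
    class = "mlp_config"
  )
}

#' Initialize network weights
#'
#' Every weight (and bias, when enabled) is drawn i.i.d. uniform on
#' `[init_low, init_high)` from the current RNG stream.
#'
#' @param config An [mlp_config()].
#' @return A list of class `mlp_weights`: `W_hi` (hidden x input), `b_h`,
#'   `W_oh` (output x hidden), `b_o`. With `use_bias = FALSE` the biases are
#'   zero.
#' @examples
#' set.seed(1)
#' init_weights(mlp_config())
#' @export
init_weights <- function(config) {
  u <- function(n) runif(n, config$init_low, config$init_high)
  w <- list(
    W_hi = matrix(u(config$n_hidden * config$n_in), config$n_hidden, config$n_in),
    b_h = if (config$use_bias) u(config$n_hidden) else numeric(config$n_hidden),
    W_oh = matrix(u(config$n_out * config$n_hidden), config$n_out, config$n_hidden),
    b_o = if (config$use_bias) u(config$n_out) else numeric(config$n_out)
  )
  structure(w, class = "mlp_weights")
}

#' Forward pass of the network
#'
#' @param weights An `mlp_weights` list.
#' @param x Input matrix (rows = patterns, columns = scaled features in
#'   `[0, 1]`) or a single input vector. Values outside `[0, 1]` trigger a
#'   warning but are not clipped.
#' @param config An [mlp_config()] (for the `input_sigmoid` / `use_bias`
#'   flags).
#' @return Matrix of outputs in (0, 1), one row per pattern, columns
#'   (valence, arousal).
#' @export
mlp_forward <- function(weights, x, config = mlp_config()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(weights$W_hi)) abort("input width must match input units")
  if (any(x < 0 | x > 1)) {
    warn("inputs outside [0, 1]; passing through unclipped")
  }
  .mlp_forward_cpp(
    x, weights$W_hi, weights$b_h, weights$W_oh, weights$b_o,
    config$input_sigmoid, config$use_bias
  )
}

#' Summed backpropagation gradient over a batch
#'
#' Gradient of the summed squared-error loss
#' `E = 0.5 * sum over patterns and outputs of (output - target)^2`
#' with respect to every weight and bias; this is the quantity a full-batch
#' epoch update subtracts (scaled by the learning rate).
#'
#' @param weights An `mlp_weights` list.
#' @param x Input matrix (patterns x features).
#' @param y Target matrix (patterns x outputs), on the 0-1 scale.
#' @inheritParams mlp_forward
#' @return List `W_hi`, `b_h`, `W_oh`, `b_o` of gradients plus the batch
#'   `mse` (mean over patterns and outputs of squared error).
#' @export
mlp_gradient <- function(weights, x, y, config = mlp_config()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  .mlp_gradient_cpp(
    x, y, weights$W_hi, weights$b_h, weights$W_oh, weights$b_o,
    config$input_sigmoid, config$use_bias
  )
}

#' Train the network on scaled pattern pairs
#'
#' Full-batch gradient descent: each epoch presents every pattern once in a
#' randomized order, accumulates the backpropagation deltas, and applies the
#' summed update once at the epoch's end. Training always runs the full
#' `max_epochs`; `converged` records whether the final MSE beat `mse_target`.
#'
#' @param x Input matrix (patterns x features), entries in `[0, 1]`.
#' @param y Target matrix (patterns x outputs), entries in `[0, 1]`.
#' @param config An [mlp_config()].
#' @param weights Optional starting `mlp_weights`; drawn with
#'   [init_weights()] from the current RNG stream when `NULL`.
#' @return Object of class `physio_mlp`: list with `weights` (trained),
#'   `trace` (tibble `epoch`, `mse`), `final_mse`, `converged`, `config`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(40), 8, 5)
#' y <- matrix(runif(16), 8, 2)
#' fit <- train_mlp(x, y, mlp_config(max_epochs = 500))
#' fit$final_mse
#' @export
train_mlp <- function(x, y, config = mlp_config(), weights = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (any(x < 0 | x > 1)) warn("training inputs outside [0, 1]")
  if (any(y < 0 | y > 1)) abort("training targets must lie in [0, 1]")
  if (is.null(weights)) weights <- init_weights(config)
  res <- .mlp_train_cpp(
    x, y, weights$W_hi, weights$b_h, weights$W_oh, weights$b_o,
    config$learning_rate, config$max_epochs,
    config$input_sigmoid, config$use_bias, config$trace_every
  )
  w <- structure(res$weights, class = "mlp_weights")
  structure(
    list(
      weights = w,
      trace = tibble::tibble(epoch = res$trace_epoch, mse = res$trace_mse),
      final_mse = res$final_mse,
      converged = res$final_mse < config$mse_target,
      config = config
    ),
    class = "physio_mlp"
  )
}

#' @export
print.physio_mlp <- function(x, ...) {
  cat(
    "<physio_mlp> ", x$config$n_in, "-", x$config$n_hidden, "-",
    x$config$n_out, " network; final MSE ",
    signif(x$final_mse, 4),
    if (x$converged) " (converged)" else " (did not reach target)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.physio_mlp <- function(x, ...) {
  tibble::tibble(
    final_mse = x$final_mse,
    converged = x$converged,
    epochs = x$config$max_epochs,
    learning_rate = x$config$learning_rate
  )
}

#' Input/target scaling for network training
#'
#' Inputs are min-max scaled to `[0, 1]` using the training excerpts only;
#' ratings map linearly from the 1-9 scale to `[0, 1]` via `(r - 1) / 8`.
#' Test inputs are scaled with the training parameters and not clipped, so
#' distribution shift stays visible.
#'
#' @param train_features Tibble of training-excerpt rows with the five
#'   feature columns.
#' @return An object of class `mlp_scaling`: list of per-feature `min` and
#'   `max` vectors.
#' @export
scaling_params <- function(train_features) {
  X <- as.matrix(train_features[, .channels])
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  if (any(maxs <= mins)) {
    abort(paste0(
      "constant training feature(s): ",
      paste(.channels[maxs <= mins], collapse = ", ")
    ))
  }
  structure(list(min = mins, max = maxs), class = "mlp_scaling")
}

#' @rdname scaling_params
#' @param features Tibble with the five feature columns.
#' @param scaling An `mlp_scaling`.
#' @return `scale_inputs()`: numeric matrix of scaled features.
#' @export
scale_inputs <- function(features, scaling) {
  X <- as.matrix(features[, .channels])
  sweep(sweep(X, 2, scaling$min), 2, scaling$max - scaling$min, "/")
}

#' @rdname scaling_params
#' @param r Ratings on the 1-9 scale.
#' @export
rating_to_unit <- function(r) (r - 1) / 8

#' @rdname scaling_params
#' @param o Network outputs in (0, 1).
#' @export
unit_to_rating <- function(o) 8 * o + 1

#' Train an ensemble of networks and predict held-out excerpts
#'
#' Repeats the training protocol `n_trials` times with independent weight
#' re-initializations on the same training excerpts, then maps each network's
#' test-set outputs back to the 1-9 rating scale. Per-trial RNG substreams
#' derive from `config$seed` unless `trial_seeds` is given explicitly.
#'
#' @param features Feature matrix tibble ([extract_features()]) containing
#'   both training and test excerpts, with `mean_valence` / `mean_arousal`.
#' @param train_excerpts,test_excerpts Disjoint character vectors of excerpt
#'   ids. Defaults: two of the three excerpts per quadrant train
#'   (M1, M2, M4, M5, M7, M8, M10, M11), the third tests
#'   (M3, M6, M9, M12).
#' @param config An [mlp_config()].
#' @param trial_seeds Optional integer vector (length `n_trials`) of per-trial
#'   seeds; passing identical seeds yields identical trials.
#' @return Object of class `physio_ensemble`: list with `fits` (list of
#'   `physio_mlp`), `predictions` (tibble `trial`, `excerpt`,
#'   `predicted_valence`, `predicted_arousal`), `mean_predictions` (per test
#'   excerpt, with observed means joined), `scaling`, `config`,
#'   `train_excerpts`, `test_excerpts`.
#' @examples
#' \donttest{
#' study <- simulate_study(study_design(n_participants = 2, seed = 1))
#' fm <- extract_features(study)
#' ens <- run_trials(fm, config = mlp_config(n_trials = 2, max_epochs = 2000))
#' ens$mean_predictions
#' }
#' @export
run_trials <- function(features,
                       train_excerpts = c(
                         "M1", "M2", "M4", "M5", "M7", "M8", "M10", "M11"
                       ),
                       test_excerpts = c("M3", "M6", "M9", "M12"),
                       config = mlp_config(),
                       trial_seeds = NULL) {
  if (length(intersect(train_excerpts, test_excerpts)) > 0) {
    abort("train and test excerpt sets overlap")
  }
  missing <- setdiff(c(train_excerpts, test_excerpts), features$excerpt)
  if (length(missing) > 0) {
    abort(paste0("excerpts absent from features: ", paste(missing, collapse = ", ")))
  }
  train <- features[match(train_excerpts, features$excerpt), ]
  test <- features[match(test_excerpts, features$excerpt), ]

  scaling <- scaling_params(train)
  x_train <- scale_inputs(train, scaling)
  y_train <- cbind(
    rating_to_unit(train$mean_valence),
    rating_to_unit(train$mean_arousal)
  )
  x_test <- scale_inputs(test, scaling)

  if (is.null(trial_seeds)) {
    trial_seeds <- (config$seed + 7919L * (seq_len(config$n_trials) - 1L)) %%
      2147483647L
  }
  stopifnot(length(trial_seeds) == config$n_trials)

  fits <- vector("list", config$n_trials)
  preds <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    set.seed(trial_seeds[tr])
    fits[[tr]] <- train_mlp(x_train, y_train, config)
    out <- mlp_forward(fits[[tr]]$weights, x_test, config)
    preds[[tr]] <- tibble::tibble(
      trial = tr,
      excerpt = test_excerpts,
      predicted_valence = unit_to_rating(out[, 1]),
      predicted_arousal = unit_to_rating(out[, 2])
    )
  }
  predictions <- purrr::list_rbind(preds)
  mean_predictions <- predictions |>
    dplyr::group_by(.data$excerpt) |>
    dplyr::summarise(
      predicted_valence = mean(.data$predicted_valence),
      predicted_arousal = mean(.data$predicted_arousal),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      test |>
        dplyr::select("excerpt",
          observed_valence = "mean_valence",
          observed_arousal = "mean_arousal"
        ),
      by = "excerpt"
    ) |>
    dplyr::arrange(match(.data$excerpt, test_excerpts))

  structure(
    list(
      fits = fits, predictions = predictions,
      mean_predictions = mean_predictions, scaling = scaling,
      config = config, train_excerpts = train_excerpts,
      test_excerpts = test_excerpts
    ),
    class = "physio_ensemble"
  )
}

#' @export
print.physio_ensemble <- function(x, ...) {
  conv <- sum(vapply(x$fits, function(f) f$converged, logical(1)))
  cat(
    "<physio_ensemble> ", length(x$fits), " trained networks (",
    conv, " converged); test excerpts: ",
    paste(x$test_excerpts, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.physio_ensemble <- function(x, ...) x$predictions

#' @export
glance.physio_ensemble <- function(x, ...) {
  mses <- vapply(x$fits, function(f) f$final_mse, numeric(1))
  tibble::tibble(
    n_trials = length(x$fits),
    n_converged = sum(mses < x$config$mse_target),
    mean_final_mse = mean(mses),
    max_final_mse = max(mses)
  )
}

#' Serialize ensemble weights and scaling to JSON
#'
#' Writes one JSON file holding each trial's trained weights, the training
#' scaling parameters, and the configuration; [read_ensemble_json()] restores
#' them (weights and scaling only; fitted traces are not stored).
#'
#' @param ensemble A `physio_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "physio_ensemble"))
  payload <- list(
    config = unclass(ensemble$config),
    scaling = list(
      min = as.list(ensemble$scaling$min),
      max = as.list(ensemble$scaling$max)
    ),
    train_excerpts = ensemble$train_excerpts,
    test_excerpts = ensemble$test_excerpts,
    weights = purrr::map(ensemble$fits, function(f) {
      list(
        W_hi = f$weights$W_hi, b_h = f$weights$b_h,
        W_oh = f$weights$W_oh, b_o = f$weights$b_o
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @param path Path to a file written by [write_ensemble_json()].
#' @return `read_ensemble_json()`: a list with `config` ([mlp_config()]),
#'   `scaling`, `train_excerpts`, `test_excerpts`, and `weights` (a list of
#'   `mlp_weights`).
#' @export
read_ensemble_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(mlp_config, p$config)
  as_mat <- function(rows) {
    do.call(rbind, purrr::map(rows, ~ unlist(.x, use.names = FALSE)))
  }
  weights <- purrr::map(p$weights, function(w) {
    structure(
      list(
        W_hi = as_mat(w$W_hi),
        b_h = unlist(w$b_h, use.names = FALSE),
        W_oh = as_mat(w$W_oh),
        b_o = unlist(w$b_o, use.names = FALSE)
      ),
      class = "mlp_weights"
    )
  })
  scaling <- structure(
    list(
      min = unlist(p$scaling$min),
      max = unlist(p$scaling$max)
    ),
    class = "mlp_scaling"
  )
  list(
    config = cfg, scaling = scaling,
    train_excerpts = unlist(p$train_excerpts),
    test_excerpts = unlist(p$test_excerpts),
    weights = weights
  )
}
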