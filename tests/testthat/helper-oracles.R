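# Shared helpers: independent oracles and small fixtures built in code.

# Central finite-difference gradient of the summed squared-error loss
# E = 0.5 * sum((forward(x) - y)^2), the quantity backpropagation computes.
fd_gradient <- function(weights, x, y, config, eps = 1e-6) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  loss <- function(w) {
    o <- mlp_forward(w, x, config)
    0.5 * sum((o - y)^2)
  }
  grad_of <- function(part) {
    g <- weights[[part]]
    for (i in seq_along(g)) {
      wp <- weights
      wp[[part]][i] <- wp[[part]][i] + eps
      wm <- weights
      wm[[part]][i] <- wm[[part]][i] - eps
      g[i] <- (loss(wp) - loss(wm)) / (2 * eps)
    }
    g
  }
  list(
    W_hi = grad_of("W_hi"), b_h = grad_of("b_h"),
    W_oh = grad_of("W_oh"), b_o = grad_of("b_o")
  )
}

random_weights <- function(config, scale = 1) {
  structure(
    list(
      W_hi = matrix(
        rnorm(config$n_hidden * config$n_in, sd = scale),
        config$n_hidden, config$n_in
      ),
      b_h = rnorm(config$n_hidden, sd = scale),
      W_oh = matrix(
        rnorm(config$n_out * config$n_hidden, sd = scale),
        config$n_out, config$n_hidden
      ),
      b_o = rnorm(config$n_out, sd = scale)
    ),
    class = "mlp_weights"
  )
}

# tiny-but-complete feature tibble for model-stage tests (no signal pipeline)
toy_features <- function(seed = 1, n = 12) {
  set.seed(seed)
  tibble::tibble(
    excerpt = paste0("M", seq_len(n)),
    quadrant = rep(c("Agitated", "Happy", "Peaceful", "Sad"), length.out = n),
    scl = rnorm(n), hr = rnorm(n), resp = rnorm(n),
    zyg = rnorm(n), corr = rnorm(n),
    mean_valence = runif(n, 2, 8), mean_arousal = runif(n, 2, 8)
  )
}

# one default-condition study + features, generated once per test run and
# shared across test files (generation is the expensive step)
shared_env <- new.env(parent = emptyenv())
default_features <- function(seed = 101) {
  key <- paste0("feat", seed)
  if (is.null(shared_env[[key]])) {
    study <- simulate_study(study_design(seed = seed), effect_model())
    shared_env[[key]] <- extract_features(study)
  }
  shared_env[[key]]
}
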