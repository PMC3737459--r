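#' Signed input contributions of a trained network
#'
#' Decomposes a single-hidden-layer network's influence per input and output,
#' preserving sign: within each hidden unit the input weights are normalized
#' by the unit's total absolute input weight, scaled by the unit's weight to
#' the output, and summed over hidden units; the result is then normalized
#' per output so absolute contributions sum to 1. Unlike an absolute-weight
#' share, this keeps the direction of each feature's influence (a negative
#' contribution means the feature is higher when the predicted rating is
#' lower). Biases are excluded: contributions partition the influence of the
#' inputs.
#'
#' @param weights An `mlp_weights` list (`W_hi` hidden x input, `W_oh`
#'   output x hidden).
#' @param input_names,output_names Dimension labels (defaults: the five
#'   feature names; valence, arousal).
#' @return A tibble with one row per input x output: `output`, `input`,
#'   `contribution` (signed; per output the absolute values sum to 1).
#' @examples
#' w <- list(W_hi = matrix(c(3, 1), 1, 2), W_oh = matrix(2, 1, 1))
#' milne_contributions(w, input_names = c("a", "b"), output_names = "y")
#' @export
milne_contributions <- function(weights,
                                input_names = .channels,
                                output_names = c("valence", "arousal")) {
  W_hi <- weights$W_hi # n_hid x n_in
  W_oh <- weights$W_oh # n_out x n_hid
  n_in <- ncol(W_hi)
  n_out <- nrow(W_oh)
  stopifnot(length(input_names) == n_in, length(output_names) == n_out)

  row_abs <- rowSums(abs(W_hi))
  if (any(row_abs == 0)) {
    abort("a hidden unit has all-zero input weights; contributions undefined")
  }
  shares <- W_hi / row_abs # per hidden unit, signed input shares
  raw <- W_oh %*% shares # n_out x n_in
  denom <- rowSums(abs(raw))
  if (any(denom == 0)) {
    abort("all raw contributions are zero for an output; undefined")
  }
  cm <- raw / denom

  tibble::tibble(
    output = rep(output_names, each = n_in),
    input = rep(input_names, times = n_out),
    contribution = as.vector(t(cm))
  )
}

#' Mean contributions across an ensemble
#'
#' @param ensemble A `physio_ensemble` ([run_trials()]).
#' @return A tibble `trial`, `output`, `input`, `contribution`.
#' @export
ensemble_contributions <- function(ensemble) {
  purrr::imap(
    ensemble$fits,
    function(fit, tr) {
      dplyr::mutate(milne_contributions(fit$weights), trial = tr, .before = 1)
    }
  ) |> purrr::list_rbind()
}

#' Repeated-measures ANOVA on contribution sizes
#'
#' One-way repeated-measures ANOVA of the absolute contribution sizes with
#' feature as the repeated measure and training trial as the subject, on
#' uncorrected degrees of freedom (k - 1, (k - 1)(n - 1)). Answers whether
#' the features contribute unequally to one output across the ensemble.
#'
#' @param contributions Tibble with columns `trial`, `input`, `contribution`
#'   for a single output (filter [ensemble_contributions()] first), or a
#'   trials x features numeric matrix of absolute contributions.
#' @return A one-row tibble `f_statistic`, `df1`, `df2`, `p`.
#' @export
contribution_anova <- function(contributions) {
  if (is.matrix(contributions)) {
    long <- tibble::tibble(
      trial = rep(seq_len(nrow(contributions)), ncol(contributions)),
      input = rep(
        colnames(contributions) %||% paste0("f", seq_len(ncol(contributions))),
        each = nrow(contributions)
      ),
      size = as.vector(contributions)
    )
  } else {
    if ("output" %in% names(contributions) &&
      length(unique(contributions$output)) > 1) {
      abort("filter to a single output before the ANOVA")
    }
    long <- tibble::tibble(
      trial = contributions$trial,
      input = contributions$input,
      size = abs(contributions$contribution)
    )
  }
  k <- length(unique(long$input))
  n <- length(unique(long$trial))
  if (k < 2 || n < 2) abort("need >= 2 features and >= 2 trials")
  if (nrow(long) != n * k || anyDuplicated(long[, c("trial", "input")])) {
    abort("contributions must form a complete trials x features grid")
  }
  long$trial <- factor(long$trial)
  long$input <- factor(long$input)
  fit <- aov(size ~ input + Error(trial), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ms_effect <- tab["input", "Mean Sq"]
  ms_error <- tab["Residuals", "Mean Sq"]
  if (!is.finite(ms_error) || ms_error <= 1e-12 * max(ms_effect, 1)) {
    abort("zero residual variance; F undefined")
  }
  tibble::tibble(
    f_statistic = tab["input", "F value"],
    df1 = tab["input", "Df"],
    df2 = tab["Residuals", "Df"],
    p = tab["input", "Pr(>F)"]
  )
}

#' Features contributing above the null threshold
#'
#' The null threshold is the contribution size expected were all inputs
#' equal: 1 / number of inputs (0.2 for five features). Reports, per output,
#' the features whose mean absolute contribution strictly exceeds it,
#' ordered by size, with the sign of the (trial-mean) contribution.
#'
#' @param contributions Tibble `output`, `input`, `contribution` — either one
#'   network's ([milne_contributions()]) or an ensemble's
#'   ([ensemble_contributions()]), in which case trial means are taken.
#' @param threshold Null threshold; default `1 / n_inputs`.
#' @return A tibble `output`, `input`, `contribution` (trial mean), `size`,
#'   `sign`, containing only above-threshold rows, sorted by `output` then
#'   descending `size`.
#' @export
threshold_report <- function(contributions, threshold = NULL) {
  means <- contributions |>
    dplyr::group_by(.data$output, .data$input) |>
    dplyr::summarise(contribution = mean(.data$contribution), .groups = "drop")
  if (is.null(threshold)) {
    threshold <- 1 / length(unique(means$input))
  }
  means |>
    dplyr::mutate(
      size = abs(.data$contribution),
      sign = ifelse(.data$contribution >= 0, "+", "-")
    ) |>
    dplyr::filter(.data$size > threshold) |>
    dplyr::arrange(.data$output, dplyr::desc(.data$size))
}
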