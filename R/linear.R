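#' Pearson correlation between a feature and mean ratings
#'
#' Standard Pearson r with a two-tailed t-test on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. a per-excerpt
#'   feature and the per-excerpt mean rating.
#' @return A one-row tibble: `r`, `df`, `p`.
#' @examples
#' pearson_cor(1:10, (1:10) + rnorm(10))
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p = ct$p.value
  )
}

#' Correlate every feature with the mean ratings
#'
#' @param features Feature matrix tibble ([extract_features()]).
#' @return A tibble with one row per feature x dimension: `target`,
#'   `feature`, `r`, `df`, `p`.
#' @export
correlate_features <- function(features) {
  tidyr::expand_grid(
    target = c("valence", "arousal"),
    feature = .channels
  ) |>
    dplyr::mutate(purrr::map2(
      .data$target, .data$feature,
      function(tg, ft) {
        y <- features[[paste0("mean_", tg)]]
        pearson_cor(features[[ft]], y)
      }
    ) |> purrr::list_rbind())
}

#' Stepwise forward linear regression
#'
#' Builds a linear model of one rating dimension from the five physiological
#' features by forward entry: at each step the candidate whose addition has
#' the smallest partial-F p-value enters if that p-value is below
#' `alpha_enter`; after every addition, any member whose p-value has risen
#' above `alpha_keep` is dropped. Ties break on fixed column order
#' (scl, hr, resp, zyg, corr). The empty model (intercept only, predicting
#' the training mean) is a legitimate outcome. A warning is logged when the
#' case-to-predictor ratio drops below 5.
#'
#' @param features Feature tibble with the five feature columns and a
#'   `mean_<target>` column (see [extract_features()]).
#' @param target `"valence"` or `"arousal"`.
#' @param alpha_enter Entry threshold on the partial-F p-value (default 0.10).
#' @param alpha_keep Removal threshold (default 0.15; must be
#'   >= `alpha_enter`).
#' @return An object of class `physio_lm`: list with `target`, `selected`
#'   (ordered character vector), `coefficients` (named, incl. `(Intercept)`),
#'   `r_squared`, `f_statistic`, `df`, `p_values` (per selected predictor),
#'   `train_mean`, and the underlying `fit` (`lm` or `NULL` for the empty
#'   model).
#' @examples
#' \donttest{
#' study <- simulate_study(study_design(n_participants = 2, seed = 1))
#' fm <- extract_features(study)
#' stepwise_forward(fm, "arousal")
#' }
#' @export
stepwise_forward <- function(features, target = c("valence", "arousal"),
                             alpha_enter = 0.10, alpha_keep = 0.15) {
  target <- match.arg(target)
  y_col <- paste0("mean_", target)
  if (!y_col %in% names(features)) abort(paste0("missing column ", y_col))
  dat <- features[, c(.channels, y_col)]
  if (anyNA(dat)) abort("missing values in features or ratings")
  names(dat)[names(dat) == y_col] <- ".y"
  n <- nrow(dat)
  if (n < 3) abort("need at least 3 excerpts")

  selected <- character(0)
  repeat {
    candidates <- setdiff(.channels, selected)
    if (length(candidates) == 0) break
    # partial-F p-value of adding each candidate (== t-test of its slope)
    p_add <- vapply(candidates, function(cand) {
      fit <- lm(
        stats::reformulate(c(selected, cand), response = ".y"),
        data = dat
      )
      cf <- summary(fit)$coefficients
      if (!cand %in% rownames(cf) || anyNA(cf[cand, ])) {
        return(1)
      }
      cf[cand, "Pr(>|t|)"]
    }, numeric(1))
    best <- candidates[which.min(p_add)] # which.min ties -> first in order
    if (min(p_add) >= alpha_enter) break
    selected <- c(selected, best)

    # backward removal pass at alpha_keep
    repeat {
      if (length(selected) == 0) break
      fit <- lm(stats::reformulate(selected, response = ".y"), data = dat)
      cf <- summary(fit)$coefficients
      p_cur <- cf[selected, "Pr(>|t|)"]
      if (max(p_cur) <= alpha_keep) break
      drop <- selected[which.max(p_cur)]
      selected <- setdiff(selected, drop)
    }

    # with an (essentially) exact fit, further partial-F tests are numerical
    # noise on zero residuals; stop entering
    if (length(selected) > 0) {
      fit <- lm(stats::reformulate(selected, response = ".y"), data = dat)
      if (summary(fit)$r.squared > 1 - 1e-12) break
    }
  }

  if (length(selected) > 0) {
    fit <- lm(stats::reformulate(selected, response = ".y"), data = dat)
    X <- stats::model.matrix(fit)
    if (kappa(crossprod(X), exact = TRUE) > 1e10) {
      abort("selected predictors are collinear (condition number > 1e10)")
    }
    sm <- summary(fit)
    if (n / length(selected) < 5) {
      warn(paste0(
        "case-to-predictor ratio ", round(n / length(selected), 1),
        " is below 5; interpret the model with caution"
      ))
    }
    out <- list(
      target = target,
      selected = selected,
      coefficients = stats::coef(fit),
      r_squared = sm$r.squared,
      f_statistic = unname(sm$fstatistic["value"]),
      df = unname(sm$fstatistic[c("numdf", "dendf")]),
      p_values = sm$coefficients[selected, "Pr(>|t|)", drop = TRUE],
      train_mean = mean(dat$.y),
      alpha_enter = alpha_enter,
      alpha_keep = alpha_keep,
      fit = fit
    )
  } else {
    out <- list(
      target = target,
      selected = character(0),
      coefficients = c("(Intercept)" = mean(dat$.y)),
      r_squared = 0,
      f_statistic = NA_real_,
      df = c(NA_real_, NA_real_),
      p_values = numeric(0),
      train_mean = mean(dat$.y),
      alpha_enter = alpha_enter,
      alpha_keep = alpha_keep,
      fit = NULL
    )
  }
  structure(out, class = "physio_lm")
}

#' @export
print.physio_lm <- function(x, ...) {
  cat("<physio_lm> target:", x$target, "\n")
  if (length(x$selected) == 0) {
    cat("  empty model; predicts training mean", round(x$train_mean, 3), "\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    cat(
      "  R^2 =", round(x$r_squared, 3),
      " F(", x$df[1], ",", x$df[2], ") =", round(x$f_statistic, 2), "\n"
    )
  }
  invisible(x)
}

#' Predict ratings from a stepwise linear model
#'
#' Intercept plus the selected features' linear combination; the empty model
#' predicts the training-set mean rating. Predictions are not clipped to the
#' 1-9 scale (an extrapolating linear model may leave it).
#'
#' @param object A `physio_lm`.
#' @param newdata Tibble supplying the selected feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted ratings.
#' @export
predict.physio_lm <- function(object, newdata, ...) {
  missing <- setdiff(object$selected, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("newdata lacks predictor(s): ", paste(missing, collapse = ", ")))
  }
  if (length(object$selected) == 0) {
    return(rep(object$train_mean, nrow(newdata)))
  }
  b <- object$coefficients
  unname(
    drop(as.matrix(newdata[, object$selected]) %*% b[object$selected]) +
      b["(Intercept)"]
  )
}

#' @export
tidy.physio_lm <- function(x, ...) {
  if (length(x$selected) == 0) {
    return(tibble::tibble(
      term = "(Intercept)", estimate = unname(x$coefficients),
      p.value = NA_real_
    ))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @export
glance.physio_lm <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_selected = length(x$selected),
    r.squared = x$r_squared,
    statistic = x$f_statistic,
    df = x$df[1],
    df.residual = x$df[2]
  )
}
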