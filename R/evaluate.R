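#' Per-dimension prediction error
#'
#' Absolute difference between predicted and observed rating along one
#' dimension (the one-dimensional Euclidean distance).
#'
#' @param predicted,observed Ratings on the 1-9 scale.
#' @return Non-negative error in rating units.
#' @examples
#' dimension_error(6.825, 6.8)
#' @export
dimension_error <- function(predicted, observed) {
  abs(predicted - observed)
}

#' Error and accuracy summary over test excerpts
#'
#' From per-excerpt predictions and observed mean ratings, computes per
#' dimension: the per-excerpt absolute errors, their unweighted mean, the
#' error percentage (mean error over the 8-unit span of the 1-9 scale), the
#' complementary accuracy percentage, the RMSE on the 0-1 scaled space, and
#' the Pearson correlation (and its square) between predicted and observed
#' values. The combined two-dimensional Euclidean distance per excerpt is
#' reported as a supplementary column.
#'
#' @param records Tibble with columns `excerpt`, `predicted_valence`,
#'   `predicted_arousal`, `observed_valence`, `observed_arousal` (e.g.
#'   `mean_predictions` from [run_trials()], or linear-model predictions).
#' @return A list of class `error_summary` with `per_excerpt` (tibble:
#'   `excerpt`, `valence_error`, `arousal_error`, `euclidean_error`) and
#'   `summary` (tibble per dimension: `mean_error`, `error_pct`,
#'   `accuracy_pct`, `rmse_scaled`, `r`, `r_squared`). `r` is `NA` when
#'   either series is constant.
#' @examples
#' recs <- tibble::tibble(
#'   excerpt = c("M3", "M6"),
#'   predicted_valence = c(4, 6), predicted_arousal = c(7, 7),
#'   observed_valence = c(3.95, 6.8), observed_arousal = c(7.15, 7.5)
#' )
#' summarize_errors(recs)
#' @export
summarize_errors <- function(records) {
  stopifnot(nrow(records) >= 1)
  need <- c(
    "excerpt", "predicted_valence", "predicted_arousal",
    "observed_valence", "observed_arousal"
  )
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")))
  }
  per_excerpt <- tibble::tibble(
    excerpt = records$excerpt,
    valence_error = dimension_error(
      records$predicted_valence, records$observed_valence
    ),
    arousal_error = dimension_error(
      records$predicted_arousal, records$observed_arousal
    ),
    euclidean_error = sqrt(
      (records$predicted_valence - records$observed_valence)^2 +
        (records$predicted_arousal - records$observed_arousal)^2
    )
  )
  one_dim <- function(pred, obs) {
    mean_error <- mean(abs(pred - obs))
    error_pct <- 100 * mean_error / 8
    r <- if (length(pred) >= 3 && var(pred) > 0 && var(obs) > 0) {
      cor(pred, obs)
    } else {
      NA_real_
    }
    tibble::tibble(
      mean_error = mean_error,
      error_pct = error_pct,
      accuracy_pct = 100 - error_pct,
      rmse_scaled = sqrt(mean(((pred - obs) / 8)^2)),
      r = r,
      r_squared = if (is.na(r)) NA_real_ else r^2
    )
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(
      one_dim(records$predicted_valence, records$observed_valence),
      dimension = "valence", .before = 1
    ),
    dplyr::mutate(
      one_dim(records$predicted_arousal, records$observed_arousal),
      dimension = "arousal", .before = 1
    )
  )
  structure(
    list(per_excerpt = per_excerpt, summary = summary),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.error_summary <- function(x, ...) x$per_excerpt

#' @export
glance.error_summary <- function(x, ...) x$summary

#' Quadrant mean ratings
#'
#' Unweighted mean of the per-excerpt mean valence and arousal within each
#' emotion quadrant of the valence-arousal grid. Computation is kept at full
#' precision; round for display as needed.
#'
#' @param table Tibble with columns `quadrant`, and either
#'   `mean_valence`/`mean_arousal` or `latent_valence`/`latent_arousal`.
#' @return Tibble `quadrant`, `quadrant_valence`, `quadrant_arousal`.
#' @examples
#' quadrant_means(classical_excerpts())
#' @export
quadrant_means <- function(table) {
  vcol <- if ("mean_valence" %in% names(table)) "mean_valence" else "latent_valence"
  acol <- if ("mean_arousal" %in% names(table)) "mean_arousal" else "latent_arousal"
  if (!all(c(vcol, acol, "quadrant") %in% names(table))) {
    abort("need quadrant and valence/arousal columns")
  }
  bad <- setdiff(unique(table$quadrant), .quadrants)
  if (length(bad) > 0) {
    abort(paste0("unknown quadrant label(s): ", paste(bad, collapse = ", ")))
  }
  table |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::summarise(
      quadrant_valence = mean(.data[[vcol]]),
      quadrant_arousal = mean(.data[[acol]]),
      .groups = "drop"
    )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> extract -> correlations -> stepwise regression ->
#' network ensemble -> prediction errors -> contribution analysis, and
#' returns every stage's output in one report. The regression models used for
#' the head-to-head comparison with the network are refit on the training
#' excerpts only, so both model families predict the same held-out excerpts.
#'
#' @param design A [study_design()] (or `NULL` to use defaults with `seed`).
#' @param effects An [effect_model()].
#' @param config An [mlp_config()].
#' @param train_excerpts,test_excerpts Excerpt split (defaults as in
#'   [run_trials()]).
#' @param alpha_enter,alpha_keep Stepwise thresholds ([stepwise_forward()]).
#' @param seed Seed used when `design` is `NULL`, and echoed in the report.
#' @return A list of class `physio_report`: `features`, `correlations`,
#'   `regressions` (full 12-excerpt fits per dimension), `ensemble`,
#'   `nn_errors`, `lm_errors` (both `error_summary`, on the test excerpts),
#'   `contributions`, `contribution_anova`, `threshold_report`,
#'   `quadrant_means`, `config_hash`, plus the inputs.
#' @examples
#' \donttest{
#' rep <- run_pipeline(
#'   design = study_design(n_participants = 2, seed = 1),
#'   config = mlp_config(n_trials = 2, max_epochs = 2000)
#' )
#' rep$nn_errors
#' }
#' @export
run_pipeline <- function(design = NULL, effects = effect_model(),
                         config = mlp_config(),
                         train_excerpts = c(
                           "M1", "M2", "M4", "M5", "M7", "M8", "M10", "M11"
                         ),
                         test_excerpts = c("M3", "M6", "M9", "M12"),
                         alpha_enter = 0.10, alpha_keep = 0.15,
                         seed = 1L) {
  if (length(intersect(train_excerpts, test_excerpts)) > 0) {
    abort("pipeline aborted at train stage: train/test excerpts overlap")
  }
  if (is.null(design)) design <- study_design(seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  study <- stage("simulate", simulate_study(design, effects))
  features <- stage("extract", extract_features(study))
  correlations <- stage("correlate", correlate_features(features))
  regressions <- stage("linreg", list(
    valence = suppressWarnings(
      stepwise_forward(features, "valence", alpha_enter, alpha_keep)
    ),
    arousal = suppressWarnings(
      stepwise_forward(features, "arousal", alpha_enter, alpha_keep)
    )
  ))
  ensemble <- stage(
    "train",
    run_trials(features, train_excerpts, test_excerpts, config)
  )

  test_rows <- features[match(test_excerpts, features$excerpt), ]
  train_rows <- features[match(train_excerpts, features$excerpt), ]
  # comparison regressions are refit on the training excerpts only
  lm_train <- stage("linreg-train", list(
    valence = suppressWarnings(
      stepwise_forward(train_rows, "valence", alpha_enter, alpha_keep)
    ),
    arousal = suppressWarnings(
      stepwise_forward(train_rows, "arousal", alpha_enter, alpha_keep)
    )
  ))
  lm_records <- tibble::tibble(
    excerpt = test_rows$excerpt,
    predicted_valence = predict(lm_train$valence, test_rows),
    predicted_arousal = predict(lm_train$arousal, test_rows),
    observed_valence = test_rows$mean_valence,
    observed_arousal = test_rows$mean_arousal
  )
  nn_records <- ensemble$mean_predictions |>
    dplyr::select(
      "excerpt", "predicted_valence", "predicted_arousal",
      observed_valence = "observed_valence",
      observed_arousal = "observed_arousal"
    )

  contributions <- stage("contributions", ensemble_contributions(ensemble))
  anovas <- stage("contribution-anova", {
    purrr::map(
      c(valence = "valence", arousal = "arousal"),
      function(o) {
        contribution_anova(dplyr::filter(contributions, .data$output == o))
      }
    ) |> purrr::list_rbind(names_to = "output")
  })

  structure(
    list(
      design = design, effects = effects, config = config,
      train_excerpts = train_excerpts, test_excerpts = test_excerpts,
      features = features,
      correlations = correlations,
      regressions = regressions,
      lm_train = lm_train,
      ensemble = ensemble,
      nn_errors = stage("evaluate", summarize_errors(nn_records)),
      lm_errors = stage("evaluate", summarize_errors(lm_records)),
      contributions = contributions,
      contribution_anova = anovas,
      threshold_report = stage("threshold", threshold_report(contributions)),
      quadrant_means = quadrant_means(design$excerpts),
      config_hash = sum(utf8ToInt(paste(
        design$seed, design$n_participants, config$seed, config$max_epochs,
        collapse = "|"
      )))
    ),
    class = "physio_report"
  )
}

#' @export
print.physio_report <- function(x, ...) {
  cat("<physio_report>\n")
  cat("  network accuracy (%):\n")
  print(x$nn_errors$summary[, c("dimension", "mean_error", "accuracy_pct")])
  cat("  linear-model accuracy (%):\n")
  print(x$lm_errors$summary[, c("dimension", "mean_error", "accuracy_pct")])
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `predictions.csv`, `errors.csv`, `features.csv`,
#' `contributions.csv` and a `report.json` carrying the summary tables, the
#' seeds and a config hash.
#'
#' @param report A `physio_report` ([run_pipeline()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "physio_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(
    report$ensemble$mean_predictions,
    file.path(dir, "predictions.csv")
  )
  readr::write_csv(
    dplyr::bind_rows(
      nn = report$nn_errors$per_excerpt,
      lm = report$lm_errors$per_excerpt, .id = "model"
    ),
    file.path(dir, "errors.csv")
  )
  readr::write_csv(report$features, file.path(dir, "features.csv"))
  readr::write_csv(report$contributions, file.path(dir, "contributions.csv"))
  jsonlite::write_json(
    list(
      seed = report$design$seed,
      n_participants = report$design$n_participants,
      config_hash = report$config_hash,
      nn_summary = report$nn_errors$summary,
      lm_summary = report$lm_errors$summary,
      contribution_anova = report$contribution_anova,
      quadrant_means = report$quadrant_means,
      package_version = as.character(utils::packageVersion("physioaffect"))
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The file may contain sections `design`, `effects`, `nn`, `split`
#' (`train` / `test` excerpt id vectors), `linreg` (`alpha_enter`,
#' `alpha_keep`) and a top-level `seed`; each maps onto the arguments of
#' [study_design()], [effect_model()], [mlp_config()] and [run_pipeline()].
#' Omitted entries use the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `physio_report` ([run_pipeline()]).
#' @export
run_pipeline_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- cfg$seed %||% 1L
  design_args <- cfg$design %||% list()
  if (is.null(design_args$seed)) design_args$seed <- seed
  effects_args <- cfg$effects %||% list()
  if (!is.null(effects_args$channel_noise_sd)) {
    effects_args$channel_noise_sd <- unlist(effects_args$channel_noise_sd)
  }
  nn_args <- cfg$nn %||% list()
  if (is.null(nn_args$seed)) nn_args$seed <- seed
  run_pipeline(
    design = do.call(study_design, design_args),
    effects = do.call(effect_model, effects_args),
    config = do.call(mlp_config, nn_args),
    train_excerpts = cfg$split$train %||%
      c("M1", "M2", "M4", "M5", "M7", "M8", "M10", "M11"),
    test_excerpts = cfg$split$test %||% c("M3", "M6", "M9", "M12"),
    alpha_enter = cfg$linreg$alpha_enter %||% 0.10,
    alpha_keep = cfg$linreg$alpha_keep %||% 0.15,
    seed = seed
  )
}
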