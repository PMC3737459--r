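#' Default music-excerpt grid
#'
#' Twelve classical excerpts (M1-M12), three per quadrant of the
#' valence-arousal grid, with the latent (population-mean) valence and
#' arousal values each excerpt is generated to evoke. The latent values are
#' the mean participant ratings reported for this stimulus set, so synthetic
#' studies cover the same region of the grid as the original design:
#' Agitated (low valence, high arousal), Happy (high/high),
#' Peaceful (high valence, low arousal), Sad (low/low).
#'
#' @return A tibble with columns `excerpt`, `quadrant`, `latent_valence`,
#'   `latent_arousal`.
#' @examples
#' classical_excerpts()
#' @export
classical_excerpts <- function() {
  tibble::tibble(
    excerpt = paste0("M", 1:12),
    quadrant = rep(c("Agitated", "Happy", "Peaceful", "Sad"), each = 3),
    latent_valence = c(
      5, 3.35, 3.95, # Agitated
      6.6, 5.75, 6.8, # Happy
      6.6, 5.95, 5.75, # Peaceful
      4.85, 4.05, 4.3 # Sad
    ),
    latent_arousal = c(
      6.35, 7.45, 7.15,
      6.35, 6.25, 7.5,
      2.85, 2.65, 2.8,
      2.55, 4.15, 3.75
    )
  )
}

# quadrant membership implied by latent values about the scale midpoint 5
.quadrant_of <- function(valence, arousal) {
  dplyr::case_when(
    valence > 5 & arousal > 5 ~ "Happy",
    valence < 5 & arousal > 5 ~ "Agitated",
    valence < 5 & arousal <= 5 ~ "Sad",
    valence > 5 & arousal <= 5 ~ "Peaceful",
    TRUE ~ NA_character_
  )
}

validate_excerpts <- function(excerpts) {
  stopifnot(is.data.frame(excerpts))
  required <- c("excerpt", "quadrant", "latent_valence", "latent_arousal")
  missing <- setdiff(required, names(excerpts))
  if (length(missing) > 0) {
    abort(paste0("excerpts table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(excerpts$excerpt)) abort("duplicated excerpt ids")
  bad_quad <- setdiff(unique(excerpts$quadrant), .quadrants)
  if (length(bad_quad) > 0) {
    abort(paste0("unknown quadrant label(s): ", paste(bad_quad, collapse = ", ")))
  }
  v <- excerpts$latent_valence
  a <- excerpts$latent_arousal
  if (any(v < 1 | v > 9) || any(a < 1 | a > 9)) {
    abort("latent valence/arousal must lie in [1, 9]")
  }
  implied <- .quadrant_of(v, a)
  # an excerpt sitting exactly on the valence midline (v == 5) is tolerated in
  # either quadrant of its arousal half, matching the stimulus grid in use
  mismatch <- !is.na(implied) & implied != excerpts$quadrant & v != 5
  if (any(mismatch)) {
    abort(paste0(
      "quadrant label inconsistent with latent values for: ",
      paste(excerpts$excerpt[mismatch], collapse = ", ")
    ))
  }
  invisible(excerpts)
}
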