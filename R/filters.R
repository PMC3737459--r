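#' Per-channel filter specification
#'
#' @param channel One of `"scl"`, `"hr"`, `"resp"`, `"zyg"`, `"corr"`.
#' @param hp_hz High-pass cutoff in Hz, or `NA` for none.
#' @param lp_hz Low-pass cutoff in Hz, or `NA` for none.
#' @return A one-row tibble.
#' @seealso [default_filter_specs()]
#' @export
filter_spec <- function(channel, hp_hz = NA_real_, lp_hz = NA_real_) {
  channel <- match.arg(channel, .channels)
  tibble::tibble(channel = channel, hp_hz = hp_hz, lp_hz = lp_hz)
}

#' Default channel filters
#'
#' SCL and respiration pass unfiltered; the cardiac pulse channel is
#' band-passed 0.5-3 Hz before peak detection; both EMG channels are
#' band-passed 1-500 Hz. When 500 Hz is at or above Nyquist for the actual
#' sampling rate, [apply_filter()] clamps the cutoff to 0.45 x sample rate.
#'
#' @return A tibble with columns `channel`, `hp_hz`, `lp_hz`.
#' @export
default_filter_specs <- function() {
  dplyr::bind_rows(
    filter_spec("scl"),
    filter_spec("hr", hp_hz = 0.5, lp_hz = 3),
    filter_spec("resp"),
    filter_spec("zyg", hp_hz = 1, lp_hz = 500),
    filter_spec("corr", hp_hz = 1, lp_hz = 500)
  )
}

#' Zero-phase band-pass filter
#'
#' Applies a 2nd-order Butterworth filter forward and backward
#' ([signal::filtfilt()]), so the output has no phase lag. With both cutoffs
#' `NA` the series passes through untouched.
#'
#' @param series Numeric vector of samples.
#' @param spec One row of a filter-spec tibble ([filter_spec()]).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Filtered numeric vector, same length as `series`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 10, by = 0.01))
#' y <- apply_filter(x, filter_spec("hr", 0.5, 3), 100)
#' @export
apply_filter <- function(series, spec, sample_rate_hz) {
  if (any(!is.finite(series))) abort("non-finite samples in input series")
  hp <- spec$hp_hz
  lp <- spec$lp_hz
  if (is.na(hp) && is.na(lp)) {
    return(series)
  }
  nyq <- sample_rate_hz / 2
  if (!is.na(lp) && lp >= nyq) {
    lp <- 0.45 * sample_rate_hz
    warn(paste0(
      "low-pass cutoff at/above Nyquist; clamped to ", lp, " Hz (0.45 x sample rate)"
    ))
  }
  if (!is.na(hp) && hp >= nyq) {
    abort("high-pass cutoff at or above Nyquist")
  }
  flt <- if (!is.na(hp) && !is.na(lp)) {
    signal::butter(2, c(hp, lp) / nyq, type = "pass")
  } else if (!is.na(hp)) {
    signal::butter(2, hp / nyq, type = "high")
  } else {
    signal::butter(2, lp / nyq, type = "low")
  }
  as.numeric(signal::filtfilt(flt, series))
}

#' Event-rate bounds for rate channels
#'
#' Detected events closer together than `60 / max_per_min` seconds are
#' suppressed, and inter-event intervals implying rates outside
#' `[min_per_min, max_per_min]` are rejected. Defaults: heart rate 40-180
#' beats/min, respiration 5-180 breaths/min.
#'
#' @param channel `"hr"` or `"resp"`.
#' @param min_per_min,max_per_min Events per minute.
#' @return A one-row tibble.
#' @export
rate_bounds <- function(channel, min_per_min, max_per_min) {
  stopifnot(min_per_min > 0, max_per_min > min_per_min)
  tibble::tibble(
    channel = channel, min_per_min = min_per_min, max_per_min = max_per_min
  )
}

#' @rdname rate_bounds
#' @export
default_rate_bounds <- function() {
  dplyr::bind_rows(
    rate_bounds("hr", 40, 180),
    rate_bounds("resp", 5, 180)
  )
}

#' Convert a periodic signal to an event-rate series
#'
#' Peaks are located on a lightly smoothed copy of the series (moving average
#' over half the minimum admissible inter-event interval, refined to the local
#' maximum of the raw series), with an enforced minimum separation of
#' `60 / max_per_min` seconds and a prominence guard: a candidate must be
#' separated from its neighbours by a dip of at least a quarter of the
#' signal's robust amplitude range. Inter-event intervals implying rates
#' outside
#' the bounds are rejected; the rate series is linearly interpolated across
#' rejected stretches and held constant beyond the first/last accepted
#' interval, on the original sample grid.
#'
#' @param series Numeric vector (already filtered per the channel's spec).
#' @param bounds One row of a rate-bounds tibble ([rate_bounds()]).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A list with `event_times` (seconds, all detected events) and
#'   `rate` (numeric vector, events/min, one value per input sample).
#' @examples
#' fs <- 100
#' x <- sin(2 * pi * 1 * seq(0, 60, by = 1 / fs))
#' r <- detect_rate_series(x, rate_bounds("hr", 40, 180), fs)
#' mean(r$rate) # ~60 events/min
#' @export
detect_rate_series <- function(series, bounds, sample_rate_hz) {
  n <- length(series)
  min_gap_s <- 60 / bounds$max_per_min
  if (n / sample_rate_hz < 2 * (60 / bounds$min_per_min)) {
    abort(paste0(
      "series too short for ", bounds$channel, " rate detection (need >= ",
      2 * 60 / bounds$min_per_min, " s)"
    ))
  }

  # smooth for peak localization only; window = half the minimum interval
  win <- max(1L, as.integer(round(0.5 * min_gap_s * sample_rate_hz)))
  if (win %% 2L == 0L) win <- win + 1L
  smoothed <- as.numeric(stats::filter(series, rep(1 / win, win), sides = 2))
  smoothed[is.na(smoothed)] <- series[is.na(smoothed)]

  pk <- pracma::findpeaks(smoothed,
    minpeakdistance = max(1L, round(min_gap_s * sample_rate_hz)),
    minpeakheight = mean(smoothed)
  )
  if (is.null(pk) || nrow(pk) < 2) {
    abort(paste0("fewer than 2 events detected on channel ", bounds$channel))
  }
  idx <- sort(as.integer(pk[, 2]))

  # prominence guard: drop candidates not separated from their neighbours by
  # a dip of at least 25% of the signal's (robust) amplitude range, so noise
  # wrinkles riding near a true event's crest are not counted as events
  min_prom <- 0.25 * diff(stats::quantile(smoothed, c(0.05, 0.95), names = FALSE))
  repeat {
    if (length(idx) < 2) break
    seg_bounds <- c(1L, idx, n)
    valleys <- vapply(seq_along(idx), function(i) {
      left <- min(smoothed[seg_bounds[i]:idx[i]])
      right <- min(smoothed[idx[i]:seg_bounds[i + 2]])
      max(left, right)
    }, numeric(1))
    prom <- smoothed[idx] - valleys
    weak <- which(prom < min_prom)
    if (length(weak) == 0) break
    idx <- idx[-weak[which.min(prom[weak])]]
  }
  if (length(idx) < 2) {
    abort(paste0("fewer than 2 events detected on channel ", bounds$channel))
  }
  # refine each event to the raw-series maximum near the smoothed peak
  half <- (win - 1L) %/% 2L
  idx <- vapply(idx, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(series[lo:hi]) - 1L
  }, integer(1))
  idx <- unique(idx)
  event_times <- (idx - 1) / sample_rate_hz

  gaps <- diff(event_times)
  rates <- 60 / gaps
  ok <- rates >= bounds$min_per_min & rates <= bounds$max_per_min
  if (sum(ok) < 1) {
    abort(paste0(
      "no inter-event interval within [", bounds$min_per_min, ", ",
      bounds$max_per_min, "]/min on channel ", bounds$channel,
      " over 0-", round(n / sample_rate_hz, 1), " s"
    ))
  }
  mid <- (head(event_times, -1) + tail(event_times, -1)) / 2
  grid <- (seq_len(n) - 1) / sample_rate_hz
  rate <- if (sum(ok) == 1) {
    rep(rates[ok], n)
  } else {
    approx(mid[ok], rates[ok], xout = grid, method = "linear", rule = 2)$y
  }
  list(event_times = event_times, rate = rate)
}
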