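#' Repair dropped frames by timestamp interpolation
#'
#' VR engines occasionally drop frames; the resulting timestamp gaps bias a
#' linear drift correction. Gaps exceeding `gap_factor` nominal periods are
#' filled with evenly spaced inserted stamps. Inserted samples carry no
#' measured data: they are invalid, all-`NA`, and flagged
#' `provenance = "timestamp_interpolated"`; downstream classification never
#' lets an event onset fall on one.
#'
#' @param rec a gaze recording.
#' @param nominal_rate nominal rate in Hz; defaults to the recording's.
#' @param gap_factor gap threshold in nominal periods (default 1.5,
#'   separating frame jitter from true drops).
#' @return The recording with inserted stamps.
#' @export
regularize_et_timestamps <- function(rec, nominal_rate = et_rate(rec),
                                     gap_factor = 1.5) {
  if (nominal_rate <= 0) abort("`nominal_rate` must be positive.", class = "vrgaze_config_error")
  period <- 1 / nominal_rate
  gaps <- diff(rec$t)
  idx <- which(gaps > gap_factor * period)
  if (length(idx) == 0) return(rec)
  inserts <- purrr::map_dfr(idx, function(i) {
    k <- round(gaps[i] / period) - 1          # number of missing frames
    k <- max(k, 1)
    tt <- rec$t[i] + seq_len(k) * (gaps[i] / (k + 1))
    tibble(t = tt)
  })
  inserts$valid <- FALSE
  inserts$provenance <- "timestamp_interpolated"
  out <- dplyr::arrange(dplyr::bind_rows(as_tibble(rec), inserts), t)
  restore_rec(out, rec)
}

#' Affine clock model between the eye-tracking and EEG clocks
#'
#' Two recording devices keep their own clocks: a constant offset (removed by
#' subtracting the first EEG timestamp) plus a slow linear drift accumulated
#' over the recording. The model maps eye-tracking time `t` to EEG time
#' (relative to EEG start) as
#' `(t - t0_et) + drift_total * (t - t0_et) / (t1_et - t0_et)`.
#'
#' @param offset first EEG timestamp (seconds, EEG clock).
#' @param drift_total drift accumulated over the whole recording, seconds
#'   (positive when the EEG clock covers a longer duration). Signed.
#' @param t0_et,t1_et first/last eye-tracking timestamps.
#' @param method `"endpoint"` or `"least_squares"`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(offset, drift_total, t0_et, t1_et,
                        method = c("endpoint", "least_squares")) {
  method <- match.arg(method)
  if (!(t1_et > t0_et)) abort("t1_et must exceed t0_et.", class = "vrgaze_data_error")
  slope <- 1 + drift_total / (t1_et - t0_et)
  if (slope <= 0) abort("clock model must be strictly increasing.", class = "vrgaze_data_error")
  structure(list(offset = offset, drift_total = drift_total,
                 t0_et = t0_et, t1_et = t1_et, method = method, slope = slope),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> method=%s offset=%.6f s drift_total=%+.6f s over %.1f s (slope %.9f)\n",
              x$method, x$offset, x$drift_total, x$t1_et - x$t0_et, x$slope))
  invisible(x)
}

#' Estimate the eye-tracking to EEG clock drift
#'
#' The endpoint method uses only the time axes: the offset is the first EEG
#' timestamp, and the difference in total duration between the two streams is
#' spread linearly over the eye-tracking timeline. The least-squares method
#' fits the affine map to the matched endpoints plus any shared marker pairs.
#'
#' @param et_times eye-tracking timestamps (seconds, ET clock).
#' @param eeg_times EEG timestamps, or `c(first, last)` (seconds, EEG clock).
#' @param method `"endpoint"` (default) or `"least_squares"`.
#' @param markers optional data frame with columns `t_et`, `t_eeg` of shared
#'   marker times used by the least-squares fit.
#' @return A [clock_model()].
#' @export
estimate_clock_drift <- function(et_times, eeg_times,
                                 method = c("endpoint", "least_squares"),
                                 markers = NULL) {
  method <- match.arg(method)
  if (length(et_times) < 2 || length(eeg_times) < 2) {
    abort("both streams need at least two timestamps.", class = "vrgaze_data_error")
  }
  t0 <- et_times[1]; t1 <- et_times[length(et_times)]
  e0 <- eeg_times[1]; e1 <- eeg_times[length(eeg_times)]
  if (!(t1 > t0) || !(e1 > e0)) {
    abort("zero-duration stream.", class = "vrgaze_data_error")
  }
  if (method == "endpoint") {
    drift <- (e1 - e0) - (t1 - t0)
    return(clock_model(offset = e0, drift_total = drift, t0_et = t0, t1_et = t1,
                       method = "endpoint"))
  }
  x <- c(t0, t1); y <- c(e0 - e0, e1 - e0)
  if (!is.null(markers)) {
    x <- c(x, markers$t_et)
    y <- c(y, markers$t_eeg - e0)
  }
  fit <- stats::lm.fit(cbind(1, x - t0), y)
  slope <- unname(fit$coefficients[2])
  drift <- slope * (t1 - t0) - (t1 - t0)
  m <- clock_model(offset = e0, drift_total = drift, t0_et = t0, t1_et = t1,
                   method = "least_squares")
  m$intercept_rel <- unname(fit$coefficients[1])
  m
}

#' Map an eye-tracking time to the EEG timeline
#'
#' @param t_et time(s) on the eye-tracking clock.
#' @param model a [clock_model()].
#' @return Seconds on the EEG timeline, relative to the EEG start (the first
#'   ET timestamp maps to 0 for a drift-free, offset-only pair of clocks).
#' @export
to_eeg_time <- function(t_et, model) {
  (t_et - model$t0_et) * model$slope + (model$intercept_rel %||% 0)
}

#' Map event onsets to EEG sample offsets
#'
#' @param onset_ts_et onset times on the eye-tracking clock.
#' @param model a [clock_model()].
#' @param eeg_rate EEG sampling rate, Hz.
#' @param n_samples optional EEG sample count used to flag out-of-range
#'   onsets.
#' @return A tibble with `t_et`, `t_eeg`, `sample` (0-based sample offset
#'   from the EEG start: `round(t_eeg * eeg_rate)`, ties to even; the
#'   corresponding R matrix column is `sample + 1`) and `in_range`.
#' @export
map_onsets_to_eeg <- function(onset_ts_et, model, eeg_rate, n_samples = Inf) {
  t_eeg <- to_eeg_time(onset_ts_et, model)
  s <- round(t_eeg * eeg_rate)
  tibble(t_et = onset_ts_et, t_eeg = t_eeg, sample = s,
         in_range = s >= 0 & s < n_samples)
}

#' @exportS3Method generics::tidy
tidy.clock_model <- function(x, ...) {
  tibble(term = c("offset", "drift_total", "slope"),
         estimate = c(x$offset, x$drift_total, x$slope))
}

#' @exportS3Method generics::glance
glance.clock_model <- function(x, ...) {
  tibble(offset = x$offset, drift_total = x$drift_total,
         span_et = x$t1_et - x$t0_et, slope = x$slope, method = x$method)
}

#' Write / read a clock model as a key=value text file
#'
#' @param model a [clock_model()].
#' @param path file path.
#' @return `write_clock_model()` returns `path` invisibly.
#' @export
write_clock_model <- function(model, path) {
  lines <- c(sprintf("offset=%.17g", model$offset),
             sprintf("drift_total=%.17g", model$drift_total),
             sprintf("t0_et=%.17g", model$t0_et),
             sprintf("t1_et=%.17g", model$t1_et),
             sprintf("method=%s", model$method))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  clock_model(offset = as.numeric(vals[["offset"]]),
              drift_total = as.numeric(vals[["drift_total"]]),
              t0_et = as.numeric(vals[["t0_et"]]),
              t1_et = as.numeric(vals[["t1_et"]]),
              method = vals[["method"]])
}
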