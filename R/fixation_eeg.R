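#' Extract gaze-onset-locked EEG epochs
#'
#' Cuts one trial per onset out of the continuous matrix, over the half-open
#' index window `[round(onset + w0*rate), round(onset + w1*rate))`. Onsets
#' whose window would reach outside the matrix are dropped and counted.
#'
#' @param eeg an [eeg_recording()].
#' @param onset_samples 0-based EEG sample offsets of the onsets (the
#'   `sample` column of [map_onsets_to_eeg()]).
#' @param window `c(start, end)` in seconds relative to onset; default
#'   `c(-0.200, 0.500)` for ERPs (use `c(-0.875, 1.175)` for
#'   time-frequency work, which needs an edge buffer).
#' @return An `epoch_set`: list with `data` (trials x channels x time array,
#'   µV), `times` (s relative to onset), `rate`, `channels`, `onsets` (kept
#'   0-based onset samples) and `dropped`.
#' @export
extract_epochs <- function(eeg, onset_samples, window = c(-0.200, 0.500)) {
  rate <- eeg$rate
  offs <- seq(round(window[1] * rate), round(window[2] * rate) - 1)
  nt <- ncol(eeg$data)
  starts <- round(onset_samples + window[1] * rate)   # 0-based
  keep <- starts >= 0 & (starts + length(offs)) <= nt
  kept <- onset_samples[keep]
  data <- array(NA_real_, dim = c(length(kept), nrow(eeg$data), length(offs)))
  for (i in seq_along(kept)) {
    ix <- round(kept[i] + window[1] * rate) + seq_along(offs)  # 1-based columns
    data[i, , ] <- eeg$data[, ix, drop = FALSE]
  }
  structure(list(data = data, times = offs / rate, rate = rate,
                 channels = eeg$channels, onsets = kept,
                 dropped = sum(!keep)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d samples @ %g Hz, %d dropped\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate, x$dropped))
  invisible(x)
}

#' Average fixation-onset ERP
#'
#' Plain arithmetic mean over trials. No baseline correction is applied: in
#' continuous free viewing, gazes and saccades alternate without a neutral
#' pre-stimulus interval, so low-frequency drift is handled upstream by the
#' recording high-pass instead.
#'
#' @param epochs an `epoch_set`.
#' @return A channels x time matrix (µV) with the epoch times in the
#'   `times` attribute.
#' @export
average_erp <- function(epochs) {
  if (dim(epochs$data)[1] == 0) abort("no trials to average.", class = "vrgaze_data_error")
  out <- apply(epochs$data, c(2, 3), mean)
  rownames(out) <- epochs$channels
  attr(out, "times") <- epochs$times
  out
}

#' Zero-phase FIR high-pass filter
#'
#' Windowed-sinc (Hamming) high-pass applied by symmetric-kernel
#' convolution, hence zero phase. The transition band is 25% of the cutoff,
#' centred on it, and the order follows the Hamming approximation
#' `N = ceiling(3.3 * rate / transition_bw)` (rounded up to even). The DC
#' gain is exactly zero.
#'
#' @param eeg an [eeg_recording()].
#' @param cutoff high-pass cutoff in Hz; must be below Nyquist.
#' @return The filtered recording.
#' @export
highpass <- function(eeg, cutoff) {
  rate <- eeg$rate
  if (cutoff >= rate / 2) abort("`cutoff` must be below Nyquist.", class = "vrgaze_config_error")
  h <- highpass_kernel(cutoff, rate)
  m <- eeg$data
  for (ch in seq_len(nrow(m))) m[ch, ] <- conv_same(m[ch, ], h)
  eeg$data <- m
  eeg
}

highpass_kernel <- function(cutoff, rate) {
  tb <- 0.25 * cutoff
  N <- ceiling(3.3 * rate / tb)
  if (N %% 2 == 1) N <- N + 1
  n <- 0:N
  M <- N / 2
  fc <- cutoff / rate
  lp <- 2 * fc * sinc_fn(2 * fc * (n - M))
  lp <- lp * (0.54 - 0.46 * cos(2 * pi * n / N))   # Hamming window
  lp <- lp / sum(lp)                               # unit DC gain
  hp <- -lp
  hp[M + 1] <- hp[M + 1] + 1                       # spectral inversion
  hp
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FFT convolution returning the central (same-length) part; edges are
# padded by reflection to limit transients.
conv_same <- function(x, h) {
  M <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- rev(x[seq_len(min(M, n))])
  pad_r <- rev(x[seq(n - min(M, n) + 1, n)])
  xp <- c(pad_l, x, pad_r)
  L <- length(xp) + length(h) - 1
  nfft <- stats::nextn(L, 2)
  y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) *
                fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[(length(pad_l) + M + 1):(length(pad_l) + M + n)]
}

#' Morlet-wavelet time-frequency decomposition
#'
#' Per trial, channel and frequency, power is the squared magnitude of the
#' convolution with a complex Morlet wavelet of a fixed number of cycles
#' (default 3, favouring time over frequency resolution — appropriate when
#' the question is the timing of fixation-locked activity). Wavelets are
#' normalized to unit gain at their centre frequency, so a sinusoid of
#' amplitude A yields power A²/4 at its own frequency regardless of the
#' analysis bandwidth (for white noise the expected power then grows in
#' proportion to frequency, because the bandwidth does). Edges contaminated by the wavelet are dealt with by epoching
#' wider than the display window and cropping to `crop`.
#'
#' @param epochs an `epoch_set` (epoch it wide, e.g. `c(-0.875, 1.175)`).
#' @param freqs analysis frequencies in Hz, default `seq(2, 45, 0.5)`.
#' @param cycles wavelet width in cycles, default 3.
#' @param crop display window in seconds, default `c(-0.500, 0.800)`.
#' @return A `tf_map`: list with `power` (trials x frequencies x time, µV²),
#'   `freqs`, `times`, `cycles`, `channel`.
#' @param channel channel name or index to decompose (single channel),
#'   default the first.
#' @export
morlet_tf <- function(epochs, freqs = seq(2, 45, 0.5), cycles = 3,
                      crop = c(-0.500, 0.800), channel = 1) {
  if (is.character(channel)) channel <- match(channel, epochs$channels)
  rate <- epochs$rate
  x <- epochs$data[, channel, , drop = FALSE]
  ntrial <- dim(x)[1]; ntime <- dim(x)[3]
  # wavelet support +/- 3 SDs of the Gaussian envelope
  sigma_min <- cycles / (2 * pi * min(freqs))
  if (ntime / rate < 2 * 3 * sigma_min) {
    abort("epoch shorter than the wavelet at the lowest frequency.",
          class = "vrgaze_config_error")
  }
  keep <- which(epochs$times >= crop[1] & epochs$times <= crop[2])
  X <- t(matrix(x, nrow = ntrial, ncol = ntime))    # time x trials
  nfft <- stats::nextn(2 * ntime, 2)
  XF <- mvfft(rbind(X, matrix(0, nfft - ntime, ntrial)))
  power <- array(NA_real_, dim = c(ntrial, length(freqs), length(keep)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- cycles / (2 * pi * f)
    half <- ceiling(3 * sigma * rate)
    tt <- (-half:half) / rate
    wav <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
    wav <- wav / sum(exp(-tt^2 / (2 * sigma^2)))    # unit gain at f
    WF <- fft(c(wav, rep(0, nfft - length(wav))))
    Y <- mvfft(XF * WF, inverse = TRUE) / nfft
    # 'same' alignment: convolution output k + half corresponds to input k
    rows <- keep + half
    power[, fi, ] <- t(Mod(Y[rows, , drop = FALSE])^2)
  }
  structure(list(power = power, freqs = freqs, times = epochs$times[keep],
                 cycles = cycles, channel = epochs$channels[channel]),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$power)
  if (length(d) == 3) {
    cat(sprintf("<tf_map> %d trial(s) x %d freqs (%g-%g Hz) x %d times, channel %s\n",
                d[1], d[2], min(x$freqs), max(x$freqs), d[3], x$channel))
  } else {
    cat(sprintf("<tf_map> averaged, %d freqs x %d times (%s)\n", d[1], d[2],
                attr(x, "units") %||% "µV²"))
  }
  invisible(x)
}

#' Average a time-frequency map over trials
#'
#' @param tf a `tf_map` with a trial dimension.
#' @return A `tf_map` whose `power` is frequencies x time.
#' @export
tf_average <- function(tf) {
  if (length(dim(tf$power)) != 3) return(tf)
  tf$power <- apply(tf$power, c(2, 3), mean)
  tf
}

#' Decibel baseline normalization
#'
#' Converts trial-averaged power to dB change relative to the mean power in
#' a pre-onset baseline window, per frequency:
#' `10 * log10(P(f, t) / mean_baseline P(f, .))`. The default baseline
#' (-500 to -200 ms) ends before the saccade leading into the gaze, keeping
#' saccadic activity out of the reference.
#'
#' @param tf_avg a trial-averaged `tf_map` (see [tf_average()]).
#' @param baseline `c(start, end)` in seconds relative to onset.
#' @return The `tf_map` in dB (attribute `units = "dB"`).
#' @export
db_baseline <- function(tf_avg, baseline = c(-0.500, -0.200)) {
  if (length(dim(tf_avg$power)) == 3) tf_avg <- tf_average(tf_avg)
  bl <- tf_avg$times >= baseline[1] & tf_avg$times <= baseline[2]
  if (!any(bl)) abort("baseline window outside the epoch.", class = "vrgaze_config_error")
  ref <- rowMeans(tf_avg$power[, bl, drop = FALSE])
  if (any(ref <= 0)) abort("zero baseline power.", class = "vrgaze_data_error")
  tf_avg$power <- 10 * log10(tf_avg$power / ref)
  attr(tf_avg, "units") <- "dB"
  tf_avg
}

#' Trial-versus-average shift correlation
#'
#' How sensitive are fixation-locked measures to the exact onset time? The
#' unshifted trial average (ERP time course, or trial-averaged ERSP
#' flattened over the frequency-time plane, both over `window`) is Pearson-
#' correlated with every single trial re-extracted at onsets shifted by a
#' whole number of eye-tracking samples (default -1, 0, +1, i.e. ±11 ms at
#' 90 Hz). A measure robust to small timing errors shows similar medians
#' across shifts. Data are high-pass filtered (default 5 Hz) first, since
#' the question is not about low-frequency drifts.
#'
#' @param eeg an [eeg_recording()] (continuous).
#' @param onsets_et gaze-onset times on the eye-tracking clock.
#' @param model a [clock_model()].
#' @param et_rate eye-tracking rate in Hz (defines the shift unit).
#' @param mode `"erp"` or `"ersp"`.
#' @param shifts integer shifts in eye-tracking samples.
#' @param channel channel for the analysis (name or index), default "Oz"
#'   when present, else the first channel.
#' @param window correlation window in seconds, default `c(-0.200, 0.500)`.
#' @param hp_cutoff high-pass cutoff in Hz (NULL to skip).
#' @param freqs,cycles ERSP decomposition parameters.
#' @return A list with `r` (tibble: `shift`, `trial`, `r`) and `medians`
#'   (tibble: `shift`, `median_r`, `n_trials`).
#' @export
shift_correlation <- function(eeg, onsets_et, model, et_rate = 90,
                              mode = c("erp", "ersp"),
                              shifts = c(-1L, 0L, 1L), channel = NULL,
                              window = c(-0.200, 0.500), hp_cutoff = 5,
                              freqs = seq(2, 45, 0.5), cycles = 3) {
  mode <- match.arg(mode)
  if (length(onsets_et) < 2) abort("need at least 2 trials.", class = "vrgaze_data_error")
  channel <- channel %||% (if ("Oz" %in% eeg$channels) "Oz" else 1)
  if (is.character(channel)) channel <- match(channel, eeg$channels)
  if (!is.null(hp_cutoff)) eeg <- highpass(eeg, hp_cutoff)
  eeg1 <- eeg_recording(eeg$data[channel, , drop = FALSE], eeg$rate,
                        eeg$start_t, eeg$channels[channel])
  epoch_win <- if (mode == "erp") window else c(-0.875, 1.175)

  trial_mat <- function(shift) {
    on <- map_onsets_to_eeg(onsets_et + shift / et_rate, model, eeg1$rate,
                            n_samples = ncol(eeg1$data))
    ep <- extract_epochs(eeg1, on$sample[on$in_range], window = epoch_win)
    if (mode == "erp") {
      keep <- ep$times >= window[1] & ep$times <= window[2]
      ep$data[, 1, keep, drop = FALSE] |> (\(a) matrix(a, nrow = dim(a)[1]))()
    } else {
      tf <- morlet_tf(ep, freqs = freqs, cycles = cycles, crop = window)
      matrix(tf$power, nrow = dim(tf$power)[1])   # flatten freq x time
    }
  }

  base <- trial_mat(0L)
  if (nrow(base) < 2) abort("need at least 2 trials.", class = "vrgaze_data_error")
  avg <- colMeans(base)
  res <- purrr::map_dfr(shifts, function(s) {
    tm <- if (s == 0L) base else trial_mat(s)
    r <- apply(tm, 1, function(x) suppressWarnings(cor(x, avg)))
    tibble(shift = s, trial = seq_len(nrow(tm)), r = r)
  })
  medians <- res |>
    dplyr::group_by(.data$shift) |>
    dplyr::summarise(median_r = median(.data$r, na.rm = TRUE),
                     n_trials = dplyr::n(), .groups = "drop")
  list(r = res, medians = medians)
}
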