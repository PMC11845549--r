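#' Event-duration summaries per kind
#'
#' @param seq an event sequence.
#' @return A tibble per kind: `n`, `median_s`, `q1_s`, `q3_s`, `mean_s`,
#'   `sd_s`.
#' @export
duration_summary <- function(seq) {
  as_tibble(seq) |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_s = median(.data$duration_s),
      q1_s = unname(quantile(.data$duration_s, 0.25)),
      q3_s = unname(quantile(.data$duration_s, 0.75)),
      mean_s = mean(.data$duration_s),
      sd_s = sd(.data$duration_s),
      .groups = "drop")
}

#' Saccadic main sequence
#'
#' Pearson correlation between saccade amplitude and peak velocity — the
#' stereotyped "main sequence" of saccadic kinematics; a positive r is a
#' physiological-plausibility check on the classifier output.
#'
#' @param seq an event sequence with saccade amplitudes.
#' @return A one-row tibble with `r` and `n_saccades`; `r` is `NA` when
#'   either variable has zero variance or fewer than 3 saccades qualify.
#' @export
main_sequence <- function(seq) {
  s <- as_tibble(seq) |>
    dplyr::filter(.data$kind == "saccade",
                  !is.na(.data$amplitude_deg), !is.na(.data$peak_vel_dps))
  if (nrow(s) < 3 || sd(s$amplitude_deg) == 0 || sd(s$peak_vel_dps) == 0) {
    return(tibble(r = NA_real_, n_saccades = nrow(s)))
  }
  tibble(r = cor(s$amplitude_deg, s$peak_vel_dps), n_saccades = nrow(s))
}

#' Align a sampled series to gaze onsets
#'
#' Builds the onsets x sample-offsets matrix behind the onset-locked
#' velocity and dispersion figures: each row is the series around one gaze
#' onset, snapped to recorded frames (no interpolation — the underlying
#' figures are frame-based). Offsets reaching past the series edges are
#' `NA`.
#'
#' @param series a tibble with columns `t` and one value column (e.g.
#'   `w_eye` from [gaze_velocity()] or `dispersion` from
#'   [dispersion_change()]).
#' @param onsets gaze-onset times.
#' @param window time window around onset in seconds, default
#'   `c(-0.220, 0.418)`.
#' @param rate nominal sampling rate used to turn the window into sample
#'   offsets, default 90.
#' @param value name of the value column; defaults to the first non-`t`
#'   column.
#' @return A numeric matrix, rows = onsets; sample offsets in the
#'   `offsets` attribute, their nominal times in `times`.
#' @export
onset_aligned_matrix <- function(series, onsets, window = c(-0.220, 0.418),
                                 rate = 90, value = NULL) {
  value <- value %||% setdiff(names(series), "t")[1]
  offs <- seq(round(window[1] * rate), round(window[2] * rate))
  n <- length(series$t)
  m <- matrix(NA_real_, nrow = length(onsets), ncol = length(offs))
  snap <- idx_nearest(series$t, onsets)          # snap onsets to frames
  for (i in seq_along(onsets)) {
    ix <- snap[i] + offs
    ok <- ix >= 1 & ix <= n
    m[i, ok] <- series[[value]][ix[ok]]
  }
  attr(m, "offsets") <- offs
  attr(m, "times") <- offs / rate
  m
}

#' Dispersion change series
#'
#' Euclidean distance between consecutive hit points, in world units — the
#' position-domain counterpart of the angular velocity.
#'
#' @param rec a gaze recording.
#' @return A tibble with `t` (earlier sample) and `dispersion` (`NA` when a
#'   hit point is absent).
#' @export
dispersion_change <- function(rec) {
  n <- nrow(rec)
  if (n < 2) return(tibble(t = numeric(), dispersion = numeric()))
  h <- vec3(rec, "hit")
  d <- vnorm(h[-1, , drop = FALSE] - h[-n, , drop = FALSE])
  tibble(t = rec$t[-n], dispersion = d)
}

#' Viewing-distance summary per event kind
#'
#' Median and IQR, per kind, of each event's mean distance from the eye
#' origin to its hit points.
#'
#' @param seq an event sequence.
#' @param rec the gaze recording.
#' @return A tibble per kind with `n`, `median_dist`, `q1_dist`, `q3_dist`.
#' @export
gaze_distance_summary <- function(seq, rec) {
  o <- vec3(rec, "eye")
  h <- vec3(rec, "hit")
  dist <- vnorm(o - h)
  lo <- idx_ge(rec$t, seq$t_on)
  hi <- idx_le(rec$t, seq$t_off)
  ev_dist <- vapply(seq_len(nrow(seq)), function(i) {
    if (hi[i] < lo[i]) return(NA_real_)
    d <- dist[lo[i]:hi[i]]
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }, numeric(1))
  tibble(kind = seq$kind, dist = ev_dist) |>
    dplyr::filter(!is.na(.data$dist)) |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n = dplyr::n(),
                     median_dist = median(.data$dist),
                     q1_dist = unname(quantile(.data$dist, 0.25)),
                     q3_dist = unname(quantile(.data$dist, 0.75)),
                     .groups = "drop")
}

# Per-frame labels implied by an event sequence over a recording's frames.
# Each frame interval [t_i, t_{i+1}) is labeled by the events overlapping it,
# with priority invalid > saccade > outlier > gaze: a frame during which a
# saccade was in flight at any point is a saccade frame, which matches how a
# frame-based velocity classifier sees it (event boundaries with sub-frame
# timing necessarily claim whole frames). outlier_* collapses to "outlier";
# frames outside every event are NA. The last sample takes the label at its
# own timestamp.
sample_labels <- function(seq, rec) {
  n <- nrow(rec)
  t0 <- rec$t
  t1 <- c(rec$t[-1], rec$t[n])
  kinds <- ifelse(startsWith(seq$kind, "outlier"), "outlier", seq$kind)
  prio <- c(invalid = 1, saccade = 2, outlier = 3, gaze = 4)
  pv <- unname(prio[kinds])
  lv <- names(prio)
  ne <- nrow(seq)
  # events overlapping frame i: those with t_on < t1[i] and t_off > t0[i]
  first_ev <- pmin(findInterval(t0, seq$t_off, left.open = TRUE) + 1, ne)
  last_ev <- pmax(pmin(findInterval(pmax(t1, t0 + 1e-12), seq$t_on,
                                    left.open = FALSE), ne), 1L)
  covered <- seq$t_on[first_ev] < pmax(t1, t0 + 1e-12) &
    seq$t_off[first_ev] > t0
  best <- ifelse(covered, pv[first_ev], NA_real_)
  multi <- which(last_ev > first_ev & covered)
  for (i in multi) {
    best[i] <- min(pv[first_ev[i]:last_ev[i]])
  }
  lv[best]
}

#' Snap an event sequence to a recording's frame grid
#'
#' Rebuilds an event sequence at the measurement resolution of the eye
#' tracker: frames are labeled by [compare_labels()]'s overlap rule and
#' maximal same-label runs become events. Durations become multiples of the
#' frame period. Use this on a continuous-time reference (simulator truth)
#' before duration-based comparisons with classifier output — an instrument
#' sampling at 90 Hz cannot observe sub-frame durations, so duration
#' statistics (and the outlier cut derived from them) must be computed on
#' the same grid for both sequences.
#'
#' @param seq an event sequence (possibly with continuous event times).
#' @param rec the gaze recording supplying the frame grid.
#' @return A frame-aligned event sequence.
#' @export
snap_events_to_frames <- function(seq, rec) {
  lab <- sample_labels(seq, rec)
  keep <- !is.na(lab)
  t <- rec$t[keep]
  lab <- lab[keep]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n <- length(t)
  frame_end <- c(t[-1], t[n] + (t[n] - t[n - 1]))
  on <- t[starts]
  off <- frame_end[ends]
  new_event_seq(tibble(kind = r$values, t_on = on, t_off = off,
                       duration_s = off - on))
}

#' Sample-by-sample label comparison
#'
#' Cross-tabulates predicted against reference event kinds per eye-tracking
#' sample over `{gaze, saccade, invalid, outlier}`.
#'
#' @param pred_seq,ref_seq event sequences covering the same recording.
#' @param rec the gaze recording supplying the sample grid.
#' @return A 4 x 4 confusion matrix (rows = predicted, columns = reference);
#'   samples not covered by both sequences are dropped and counted in the
#'   `n_uncovered` attribute.
#' @export
compare_labels <- function(pred_seq, ref_seq, rec) {
  span_mismatch <- max(abs(range(pred_seq$t_on[1], max(pred_seq$t_off)) -
                             range(ref_seq$t_on[1], max(ref_seq$t_off))))
  if (span_mismatch > 1) {
    abort("predicted and reference sequences cover different timelines.",
          class = "vrgaze_data_error")
  }
  lv <- c("gaze", "saccade", "invalid", "outlier")
  p <- factor(sample_labels(pred_seq, rec), levels = lv)
  r <- factor(sample_labels(ref_seq, rec), levels = lv)
  keep <- !is.na(p) & !is.na(r)
  m <- table(predicted = p[keep], reference = r[keep])
  out <- unclass(as.matrix(m))
  attr(out, "n_uncovered") <- sum(!keep)
  out
}

#' Sample-level agreement rate
#'
#' With `collapse_outliers = TRUE` (default) the long-event outlier labels
#' are folded back into their base kinds (`outlier_gaze` counts as `gaze`)
#' on both sides before comparing: the outlier stage is a data-cleaning
#' step for the EEG analysis, not a classification claim, and a ground
#' truth has no outlier class of its own. Set `FALSE` for the raw 4-class
#' diagonal of [compare_labels()].
#'
#' @inheritParams compare_labels
#' @param collapse_outliers fold `outlier_*` into the base kinds first.
#' @return Fraction of compared samples with matching labels.
#' @export
label_agreement <- function(pred_seq, ref_seq, rec, collapse_outliers = TRUE) {
  if (collapse_outliers) {
    pred_seq$kind <- sub("^outlier_", "", pred_seq$kind)
    ref_seq$kind <- sub("^outlier_", "", ref_seq$kind)
  }
  m <- compare_labels(pred_seq, ref_seq, rec)
  sum(diag(m)) / sum(m)
}

#' Histogram of gaze-onset shifts against reference onsets
#'
#' Each predicted gaze onset is matched to a reference onset within
#' `max_shift` seconds; matching is greedy by ascending absolute shift,
#' without replacement, so a reference onset is consumed by at most one
#' prediction. Shifts are binned at eye-tracking sample resolution. When a
#' prediction sits exactly midway between two reference onsets, one half
#' count goes to each of the two bins (both references are consumed).
#' Predictions with no reference within the window count as unmatched.
#'
#' @param pred_onsets,ref_onsets sorted onset times (s).
#' @param max_shift matching window in seconds, default 0.110.
#' @param rate eye-tracking rate (Hz) defining the bin width, default 90.
#' @return A list with `hist` (tibble: `shift_samples`, `count`),
#'   `unmatched` (count) and `median_shift_samples` (matched shifts only).
#' @export
onset_shift_histogram <- function(pred_onsets, ref_onsets, max_shift = 0.110,
                                  rate = 90) {
  nb <- floor(max_shift * rate)
  bins <- seq(-nb, nb)
  counts <- stats::setNames(rep(0, length(bins)), bins)
  shifts <- numeric()
  ref_free <- rep(TRUE, length(ref_onsets))
  # candidate pairs within the window, processed by ascending |shift|
  lo <- idx_ge(ref_onsets, pred_onsets - max_shift)
  hi <- idx_le(ref_onsets, pred_onsets + max_shift)
  np <- pmax(hi - lo + 1, 0)
  pred_ix <- rep(seq_along(pred_onsets), np)
  ref_ix <- unlist(purrr::map2(lo, hi, function(a, b) if (b >= a) a:b else integer()))
  cand <- tibble(pred = pred_ix, ref = ref_ix,
                 shift = ref_onsets[ref_ix] - pred_onsets[pred_ix])
  matched <- rep(FALSE, length(pred_onsets))
  if (nrow(cand) > 0) {
    cand <- dplyr::arrange(cand, abs(.data$shift), .data$shift)
    for (r in seq_len(nrow(cand))) {
      i <- cand$pred[r]; j <- cand$ref[r]
      if (matched[i] || !ref_free[j]) next
      s <- cand$shift[r]
      # exact tie in both directions: half a count to each side
      tie <- cand$pred == i & !cand$ref %in% j & abs(abs(cand$shift) - abs(s)) < 1e-12 &
        sign(cand$shift) != sign(s)
      tie_rows <- which(tie & ref_free[cand$ref])
      b1 <- as.character(pmin(pmax(round(s * rate), -nb), nb))
      if (length(tie_rows) > 0 && s != 0) {
        j2 <- cand$ref[tie_rows[1]]
        s2 <- cand$shift[tie_rows[1]]
        b2 <- as.character(pmin(pmax(round(s2 * rate), -nb), nb))
        counts[b1] <- counts[b1] + 0.5
        counts[b2] <- counts[b2] + 0.5
        ref_free[j2] <- FALSE
        shifts <- c(shifts, (s + s2) / 2)
      } else {
        counts[b1] <- counts[b1] + 1
        shifts <- c(shifts, s)
      }
      matched[i] <- TRUE
      ref_free[j] <- FALSE
    }
  }
  list(hist = tibble(shift_samples = bins, count = unname(counts)),
       unmatched = sum(!matched),
       median_shift_samples = if (length(shifts) == 0) NA_real_
                              else median(shifts) * rate)
}

#' Full validation report for a classified recording
#'
#' @param seq a classified event sequence.
#' @param rec the gaze recording.
#' @param ref_seq optional reference (e.g. hand-labeled or simulator truth)
#'   event sequence.
#' @return A list with `durations`, `main_sequence`, `distances`, and — when
#'   a reference is given — `confusion`, `agreement`, `onset_shifts`.
#' @export
validation_report <- function(seq, rec, ref_seq = NULL) {
  rep <- list(durations = duration_summary(seq),
              main_sequence = main_sequence(seq),
              distances = gaze_distance_summary(seq, rec))
  if (!is.null(ref_seq)) {
    rep$confusion <- compare_labels(seq, ref_seq, rec)
    rep$agreement <- sum(diag(rep$confusion)) / sum(rep$confusion)
    rep$onset_shifts <- onset_shift_histogram(
      gaze_onsets(seq), ref_seq$t_on[ref_seq$kind == "gaze"],
      rate = et_rate(rec))
  }
  rep
}
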