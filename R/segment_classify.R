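#' Adaptive MAD velocity threshold
#'
#' Robust saccade threshold: `median(v) + k * MAD(v)` with the raw (unscaled)
#' median absolute deviation `MAD = median(|v - median(v)|)`.
#'
#' @param velocities numeric velocities (invalid/`NA` entries are dropped).
#' @param k MAD multiplier, default 3.
#' @return Threshold in degrees/second, or `NA` with fewer than 3 values
#'   (the caller then falls back to the global threshold).
#' @export
mad_threshold <- function(velocities, k = 3) {
  v <- velocities[!is.na(velocities)]
  if (length(v) < 3) return(NA_real_)
  median(v) + k * mad_raw(v)
}

#' Data-driven segment boundaries
#'
#' Long free-exploration recordings are non-stationary: a single global
#' threshold only finds the very largest saccades. The data-driven remedy
#' computes a global MAD threshold, finds maximal suprathreshold velocity
#' runs (candidate large saccades), ranks them by the sum of velocities
#' within the run, and keeps the top `K = round(target_hz * duration)` runs
#' (default 2 per second). Each kept run contributes one boundary at its
#' peak-velocity sample, so boundaries bisect saccades rather than
#' fixations.
#'
#' @param vs a conditioned velocity series.
#' @param k MAD multiplier for the global threshold.
#' @param target_hz average boundary frequency to aim for, default 2.
#' @return A `segment_set`: list with `boundaries` (sorted times), `method`,
#'   and the `global_threshold`.
#' @export
data_driven_boundaries <- function(vs, k = 3, target_hz = 2) {
  thr <- mad_threshold(vs$w_eye[vs$valid], k = k)
  duration <- diff(range(vs$t)) + mean(vs$dt)
  keep <- list(boundaries = numeric(), method = "data_driven",
               global_threshold = thr)
  if (is.na(thr)) return(structure(keep, class = "segment_set"))
  supra <- vs$valid & !is.na(vs$w_eye) & vs$w_eye > thr
  runs <- flag_runs(supra)
  if (nrow(runs) == 0) return(structure(keep, class = "segment_set"))
  runs$score <- purrr::map2_dbl(runs$start, runs$end,
                                function(a, b) sum(vs$w_eye[a:b]))
  runs$peak_t <- purrr::map2_dbl(runs$start, runs$end, function(a, b) {
    vs$t[a:b][which.max(vs$w_eye[a:b])]
  })
  K <- round(target_hz * duration)
  runs <- dplyr::arrange(runs, dplyr::desc(score), peak_t)
  sel <- head(runs, K)
  keep$boundaries <- sort(sel$peak_t)
  structure(keep, class = "segment_set")
}

#' Fixed 10-second segment boundaries
#'
#' @param rec a gaze recording (or velocity series; anything with `t`).
#' @param interval boundary spacing in seconds, default 10.
#' @return A `segment_set` with `floor(duration / interval)` boundaries.
#' @export
fixed_boundaries <- function(rec, interval = 10) {
  t0 <- rec$t[1]
  duration <- rec$t[nrow(rec)] - t0
  nb <- floor(duration / interval)
  structure(list(boundaries = t0 + interval * seq_len(nb),
                 method = "fixed_10s", global_threshold = NA_real_),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %s: %d boundaries\n", x$method, length(x$boundaries)))
  invisible(x)
}

#' Label velocity intervals within adaptive segments
#'
#' A separate MAD threshold is computed inside each segment; intervals with
#' velocity strictly above their segment's threshold are labeled `saccade`,
#' valid intervals at or below it `gaze`, invalid intervals `invalid`.
#' Segments with fewer than 3 valid velocities inherit the global threshold.
#'
#' @param vs a conditioned velocity series.
#' @param segments a `segment_set`.
#' @param k MAD multiplier.
#' @param min_threshold numerical floor on the threshold, degrees/second
#'   (default 1e-3). Only relevant for degenerate segments whose velocity
#'   spread is zero (e.g. perfectly still synthetic fixations), where
#'   `median + k * MAD` collapses to ~0 and floating-point dust would
#'   otherwise read as saccadic; far below any physiological threshold.
#' @return `vs` with `label` and `threshold` columns.
#' @export
classify_samples <- function(vs, segments, k = 3, min_threshold = 1e-3) {
  global_thr <- mad_threshold(vs$w_eye[vs$valid], k = k)
  seg_id <- findInterval(vs$t, segments$boundaries)
  thr <- vapply(split(seq_len(nrow(vs)), seg_id), function(ix) {
    th <- mad_threshold(vs$w_eye[ix][vs$valid[ix]], k = k)
    if (is.na(th)) global_thr else th
  }, numeric(1))
  vs$threshold <- pmax(thr[as.character(seg_id)], min_threshold)
  vs$label <- dplyr::case_when(
    !vs$valid | is.na(vs$w_eye) ~ "invalid",
    vs$w_eye > vs$threshold ~ "saccade",
    .default = "gaze")
  vs
}

#' Build events from labeled intervals
#'
#' Maximal same-label runs of intervals become events spanning the first to
#' the last sample of the run; the peak velocity is the maximum within the
#' run.
#'
#' @param labeled a labeled velocity series from [classify_samples()].
#' @return An event-sequence tibble (`kind`, `t_on`, `t_off`, `duration_s`,
#'   `peak_vel_dps`, ...). Events tile the classified span without overlap.
#' @export
build_events <- function(labeled) {
  r <- rle(labeled$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # interval i spans samples i..i+1, so a run a..b spans t[a] .. t[b] + dt[b]
  ev <- tibble(
    kind = r$values,
    t_on = labeled$t[starts],
    t_off = labeled$t[ends] + labeled$dt[ends],
    peak_vel_dps = purrr::map2_dbl(starts, ends, function(a, b) {
      w <- labeled$w_eye[a:b]
      if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
    }))
  ev$duration_s <- ev$t_off - ev$t_on
  new_event_seq(ev)
}

#' Merge biologically implausible short events
#'
#' Saccades shorter than `min_saccade` (20 ms; generous for a 90-Hz tracker)
#' and gazes shorter than `min_gaze` (40 ms) are absorbed into the
#' immediately preceding event, which keeps its kind and extends its offset.
#' A too-short first event is absorbed forward into the following event.
#' Merging is iterated to a fixed point, since each merge can fuse two
#' same-kind neighbours and create new short events.
#'
#' @param seq an event sequence.
#' @param min_saccade,min_gaze minimum plausible durations in seconds.
#' @return The repaired event sequence.
#' @export
merge_short_events <- function(seq, min_saccade = 0.020, min_gaze = 0.040) {
  kind <- seq$kind; t_on <- seq$t_on; t_off <- seq$t_off
  peak <- seq$peak_vel_dps
  is_short <- function(k, d) {
    (k == "saccade" & d < min_saccade) | (k == "gaze" & d < min_gaze)
  }
  repeat {
    n <- length(kind)
    if (n < 2) break
    # single left-to-right pass over a stack: shorts are absorbed into the
    # previous event, same-kind neighbours fuse on push
    k2 <- character(n); on2 <- numeric(n); off2 <- numeric(n); pk2 <- numeric(n)
    top <- 0L
    for (i in seq_len(n)) {
      ki <- kind[i]; oi <- t_on[i]; fi <- t_off[i]; pi <- peak[i]
      absorb <- top > 0L && is_short(ki, fi - oi)
      if (absorb || (top > 0L && k2[top] == ki)) {
        off2[top] <- fi
        pk2[top] <- max(pk2[top], pi, na.rm = TRUE)
      } else {
        top <- top + 1L
        k2[top] <- ki; on2[top] <- oi; off2[top] <- fi
        pk2[top] <- if (is.na(pi)) -Inf else pi
      }
    }
    k2 <- k2[seq_len(top)]; on2 <- on2[seq_len(top)]
    off2 <- off2[seq_len(top)]; pk2 <- pk2[seq_len(top)]
    # a too-short first event is absorbed forward into its successor
    if (top > 1L && is_short(k2[1], off2[1] - on2[1])) {
      on2[2] <- on2[1]
      pk2[2] <- max(pk2[2], pk2[1], na.rm = TRUE)
      k2 <- k2[-1]; on2 <- on2[-1]; off2 <- off2[-1]; pk2 <- pk2[-1]
    }
    stable <- length(k2) == length(kind)
    kind <- k2; t_on <- on2; t_off <- off2; peak <- pk2
    if (stable) break
  }
  peak[!is.finite(peak)] <- NA_real_
  new_event_seq(tibble(kind = kind, t_on = t_on, t_off = t_off,
                       duration_s = t_off - t_on, peak_vel_dps = peak),
                attr(seq, "recording_id"))
}

#' Reject implausibly long events
#'
#' Gazes and saccades with durations more than `k_out` raw MADs above the
#' pooled median of their kind are relabeled `outlier_gaze` /
#' `outlier_saccade`. Durations are pooled across all supplied sequences
#' (across subjects when several are given); with a single sequence its own
#' distribution is used. One-sided: only too-long events are outliers.
#' Degenerate spread (MAD = 0): nothing is flagged when all durations are
#' equal, otherwise any duration strictly above the median is flagged.
#'
#' @param seqs an event sequence or a list of them.
#' @param k_out MAD multiplier, default 3.5.
#' @return The sequence(s) with outliers relabeled, same structure as input.
#' @export
reject_long_outliers <- function(seqs, k_out = 3.5) {
  single <- is.data.frame(seqs)
  lst <- if (single) list(seqs) else seqs
  for (kind in c("gaze", "saccade")) {
    durs <- unlist(lapply(lst, function(s) s$duration_s[s$kind == kind]))
    if (length(durs) == 0) next
    med <- median(durs); spread <- mad_raw(durs)
    cut <- if (spread == 0) {
      if (all(durs == med)) Inf else med
    } else {
      med + k_out * spread
    }
    lst <- lapply(lst, function(s) {
      flag <- s$kind == kind & s$duration_s > cut
      s$kind[flag] <- paste0("outlier_", kind)
      s
    })
  }
  if (single) lst[[1]] else lst
}

#' Assign gaze centroids and majority hit objects
#'
#' For each gaze event, the centroid is the mean of its samples' hit points
#' and the focused object is the identifier hit most often during the event
#' (ties broken by earliest first occurrence; all-absent stays absent).
#'
#' @param seq an event sequence.
#' @param rec the preprocessed gaze recording the events came from.
#' @return The sequence with `centroid_*` and `hit_object` filled for gazes.
#' @export
assign_gaze_object <- function(seq, rec) {
  gz <- which(seq$kind %in% c("gaze", "outlier_gaze"))
  lo <- idx_ge(rec$t, seq$t_on)
  hi <- idx_le(rec$t, seq$t_off)
  for (i in gz) {
    if (hi[i] < lo[i]) next
    ix <- lo[i]:hi[i]
    h <- vec3(rec[ix, ], "hit")
    ok <- !is.na(h[, 1])
    if (any(ok)) {
      cen <- colMeans(h[ok, , drop = FALSE])
      seq$centroid_x[i] <- cen[1]; seq$centroid_y[i] <- cen[2]; seq$centroid_z[i] <- cen[3]
    }
    obj <- rec$hit_object[ix]
    obj <- obj[!is.na(obj)]
    if (length(obj) > 0) {
      counts <- table(factor(obj, levels = unique(obj)))  # unique() keeps first-occurrence order
      seq$hit_object[i] <- names(counts)[which.max(counts)]
    }
  }
  seq
}

#' Compute saccade amplitudes from flanking gaze centroids
#'
#' The amplitude of each saccade is the angle between the centroids of the
#' two flanking gaze events, seen from the eye position at saccade onset
#' (see [saccade_amplitude()]). Saccades lacking a flanking gaze centroid
#' keep an absent amplitude.
#'
#' @param seq an event sequence with gaze centroids assigned.
#' @param rec the gaze recording.
#' @return The sequence with `amplitude_deg` filled for saccades.
#' @export
add_saccade_amplitudes <- function(seq, rec) {
  sac <- which(seq$kind %in% c("saccade", "outlier_saccade"))
  gaze_kinds <- c("gaze", "outlier_gaze")
  near <- idx_nearest(rec$t, seq$t_on)
  for (i in sac) {
    if (i == 1 || i == nrow(seq)) next
    if (!(seq$kind[i - 1] %in% gaze_kinds) || !(seq$kind[i + 1] %in% gaze_kinds)) next
    prev <- c(seq$centroid_x[i - 1], seq$centroid_y[i - 1], seq$centroid_z[i - 1])
    nxt <- c(seq$centroid_x[i + 1], seq$centroid_y[i + 1], seq$centroid_z[i + 1])
    j <- near[i]
    o <- c(rec$eye_x[j], rec$eye_y[j], rec$eye_z[j])
    d <- c(rec$dir_x[j], rec$dir_y[j], rec$dir_z[j])
    if (anyNA(o) || anyNA(d)) next
    seq$amplitude_deg[i] <- saccade_amplitude(prev, nxt, o, d)
  }
  seq
}

#' Reject events overlapping unrepaired invalid data
#'
#' Events containing any sample that is invalid and was not repaired by
#' short-gap interpolation are relabeled `invalid`. Gaze events whose onset
#' falls on an inserted (`timestamp_interpolated`) stamp are additionally
#' flagged `eeg_ok = FALSE`, disqualifying them as EEG trial onsets.
#'
#' @param seq an event sequence.
#' @param rec the gaze recording.
#' @return The sequence with invalid overlaps relabeled and an `eeg_ok`
#'   column on gaze events.
#' @export
reject_invalid_overlap <- function(seq, rec) {
  hard_invalid <- !rec$valid & rec$provenance != "interpolated"
  seq$eeg_ok <- seq$kind %in% c("gaze", "outlier_gaze")
  csum <- cumsum(c(0, hard_invalid))
  lo <- idx_ge(rec$t, seq$t_on)
  hi <- idx_le(rec$t, seq$t_off)
  has_inv <- hi >= lo & (csum[pmin(hi, length(hard_invalid)) + 1] - csum[lo]) > 0
  seq$kind[has_inv] <- "invalid"
  on_ins <- rec$provenance[pmin(lo, nrow(rec))] == "timestamp_interpolated"
  seq$eeg_ok <- seq$eeg_ok & !on_ins & seq$kind == "gaze"
  seq
}

#' Classify a gaze recording into gazes and saccades
#'
#' End-to-end classifier: movement-corrected velocity, clipping and
#' Savitzky-Golay smoothing, segmentation (data-driven or fixed 10-s),
#' per-segment adaptive MAD thresholds, event construction, short-event
#' merging, long-event outlier rejection, centroid/object assignment,
#' saccade amplitudes, and rejection of events overlapping invalid data.
#' Run [preprocess_gaze()] (and, if frames were dropped,
#' [regularize_et_timestamps()]) first.
#'
#' @param rec a preprocessed gaze recording.
#' @param method `"data_driven"` (default) or `"fixed_10s"` segmentation.
#' @param k MAD multiplier for thresholds.
#' @param target_hz data-driven boundary rate (Hz).
#' @param clip,sg_window,sg_order velocity conditioning, see
#'   [condition_velocity()].
#' @param min_saccade,min_gaze merge minima in seconds.
#' @param k_out outlier MAD multiplier.
#' @param min_threshold numerical threshold floor, see [classify_samples()].
#' @return An event-sequence tibble; the conditioned velocity series is
#'   attached as attribute `velocity`.
#' @export
classify_gaze <- function(rec, method = c("data_driven", "fixed_10s"),
                          k = 3, target_hz = 2, clip = 1000,
                          sg_window = 3, sg_order = 2,
                          min_saccade = 0.020, min_gaze = 0.040,
                          k_out = 3.5, min_threshold = 1e-3) {
  method <- match.arg(method)
  vs <- gaze_velocity(rec) |>
    condition_velocity(clip = clip, sg_window = sg_window, sg_order = sg_order)
  segs <- if (method == "data_driven") {
    data_driven_boundaries(vs, k = k, target_hz = target_hz)
  } else {
    fixed_boundaries(rec)
  }
  seq <- classify_samples(vs, segs, k = k, min_threshold = min_threshold) |>
    build_events() |>
    merge_short_events(min_saccade = min_saccade, min_gaze = min_gaze) |>
    reject_long_outliers(k_out = k_out) |>
    assign_gaze_object(rec) |>
    add_saccade_amplitudes(rec) |>
    reject_invalid_overlap(rec)
  attr(seq, "velocity") <- vs
  attr(seq, "method") <- method
  seq
}

#' Gaze-onset times usable as EEG trial onsets
#'
#' @param seq a classified event sequence.
#' @return Onset times (ET clock) of gaze events not disqualified by
#'   inserted timestamps.
#' @export
gaze_onsets <- function(seq) {
  if (!"eeg_ok" %in% names(seq)) return(seq$t_on[seq$kind == "gaze"])
  seq$t_on[seq$kind == "gaze" & seq$eeg_ok]
}

#' @exportS3Method generics::glance
glance.event_seq <- function(x, ...) {
  tibble(
    n_gaze = sum(x$kind == "gaze"),
    n_saccade = sum(x$kind == "saccade"),
    n_invalid = sum(x$kind == "invalid"),
    n_outlier = sum(startsWith(x$kind, "outlier")),
    median_gaze_s = median(x$duration_s[x$kind == "gaze"]),
    median_saccade_s = median(x$duration_s[x$kind == "saccade"]),
    span_s = max(x$t_off) - min(x$t_on))
}
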