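#' Validity handling of the raw gaze stream
#'
#' Blinks and tracking losses arrive as invalid samples. Data immediately
#' around a substantial invalid period is unreliable (eyelid closing and
#' reopening), so for every maximal invalid run longer than `min_run`
#' seconds, all samples within `pad` seconds before its start or after its
#' end are marked invalid as well. Short flickers (runs of at most
#' `min_run`) are left untouched.
#'
#' @param rec a gaze recording.
#' @param min_run minimum invalid-run duration (s) that triggers expansion;
#'   default 0.020 (strictly longer runs expand).
#' @param pad expansion margin in seconds on each side; default 0.023.
#' @return The recording with the `valid` flags expanded.
#' @export
expand_invalid <- function(rec, min_run = 0.020, pad = 0.023) {
  runs <- flag_runs(!rec$valid)
  if (nrow(runs) == 0) return(rec)
  t <- rec$t
  newly <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(runs))) {
    t0 <- t[runs$start[i]]
    t1 <- t[runs$end[i]]
    if (t1 - t0 > min_run) {
      newly <- newly | (t >= t0 - pad & t <= t1 + pad)
    }
  }
  rec$valid <- rec$valid & !newly
  rec
}

# Maximal runs of TRUE in a logical vector, as start/end row indices.
flag_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Interpolate short invalid gaps
#'
#' Invalid runs shorter than `max_gap` seconds (default 250 ms) are filled by
#' linear interpolation of eye origin, eye direction, head position/direction
#' and hit point between the flanking valid samples; interpolated directions
#' are re-normalized. Filled samples become valid with
#' `provenance = "interpolated"`. The hit-object identity is categorical and
#' is not interpolated (left absent). Runs of `max_gap` or longer, and runs
#' touching either end of the recording, stay invalid — no extrapolation.
#'
#' Apply [expand_invalid()] first so that the expansion margin is part of the
#' gap being judged against `max_gap`.
#'
#' @param rec a gaze recording.
#' @param max_gap longest gap (s) that is still interpolated; default 0.250,
#'   read strictly.
#' @return The recording with short gaps filled.
#' @export
interpolate_short_gaps <- function(rec, max_gap = 0.250) {
  runs <- flag_runs(!rec$valid)
  if (nrow(runs) == 0) return(rec)
  t <- rec$t
  n <- nrow(rec)
  num_prefixes <- c("eye", "dir", "head", "hdir", "hit")
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    if (a == 1 || b == n) next            # edge gap: no extrapolation
    if (t[b] - t[a] >= max_gap) next      # long gap stays invalid
    lo <- a - 1; hi <- b + 1
    if (!rec$valid[lo] || !rec$valid[hi]) next
    w <- (t[a:b] - t[lo]) / (t[hi] - t[lo])
    for (p in num_prefixes) {
      v0 <- unlist(rec[lo, paste0(p, c("_x", "_y", "_z"))])
      v1 <- unlist(rec[hi, paste0(p, c("_x", "_y", "_z"))])
      if (anyNA(v0) || anyNA(v1)) {
        # no flanking value to interpolate from (e.g. sky hit): leave absent
        rec[a:b, paste0(p, c("_x", "_y", "_z"))] <- NA_real_
        next
      }
      m <- outer(1 - w, v0) + outer(w, v1)
      if (p %in% c("dir", "hdir")) m <- unitize(m)
      rec[a:b, paste0(p, c("_x", "_y", "_z"))] <- as.data.frame(m)
    }
    rec$hit_object[a:b] <- NA_character_
    rec$valid[a:b] <- TRUE
    rec$provenance[a:b] <- "interpolated"
  }
  rec
}

#' Fraction of interpolated samples
#'
#' @param rec a gaze recording.
#' @return Proportion of samples with `provenance == "interpolated"`.
#' @export
interpolated_fraction <- function(rec) {
  mean(rec$provenance == "interpolated")
}

#' 5-point running median filter
#'
#' Each output value is the median of the window centered on it; at the
#' series edges the window shrinks symmetrically (3-point at the second and
#' penultimate value, passthrough at the first and last). Windows never
#' span missing values: each maximal non-`NA` run is filtered on its own,
#' and `NA`s pass through.
#'
#' @param x numeric vector.
#' @param width odd window width, default 5.
#' @return Filtered vector of the same length.
#' @export
median_filter5 <- function(x, width = 5) {
  if (width %% 2 != 1 || width < 1) {
    abort("`width` must be odd and positive.", class = "vrgaze_config_error")
  }
  n <- length(x)
  if (n == 0 || width == 1) return(x)
  half <- (width - 1) / 2
  out <- x
  # filter within maximal non-NA runs so windows never span a gap
  runs <- flag_runs(!is.na(x))
  for (r in seq_len(nrow(runs))) {
    a <- runs$start[r]; b <- runs$end[r]
    len <- b - a + 1
    if (len >= width) {
      out[a:b] <- stats::runmed(x[a:b], width, endrule = "median")
    } else if (len >= 3) {
      w2 <- len - (1 - len %% 2)    # largest odd window that fits
      out[a:b] <- stats::runmed(x[a:b], w2, endrule = "median")
    }
  }
  out
}

#' Median-filter positions and hit points of a recording
#'
#' Applies [median_filter5()] component-wise to the eye origin, head
#' position and hit points. Direction vectors are left untouched: they are
#' renormalized and used raw by the velocity projection.
#'
#' @param rec a gaze recording.
#' @param width odd window width, default 5.
#' @return The filtered recording.
#' @export
median_filter_positions <- function(rec, width = 5) {
  for (p in c("eye", "head", "hit")) {
    for (ax in c("_x", "_y", "_z")) {
      col <- paste0(p, ax)
      rec[[col]] <- median_filter5(rec[[col]], width = width)
    }
  }
  rec
}

#' Standard preprocessing chain
#'
#' Runs, in order: [renormalize_directions()], [expand_invalid()],
#' [interpolate_short_gaps()], [median_filter_positions()]. This is the
#' validity-then-filter order assumed by the classifier.
#'
#' @param rec a gaze recording.
#' @inheritParams expand_invalid
#' @inheritParams interpolate_short_gaps
#' @param median_width odd window width for the position median filter.
#' @return The preprocessed recording.
#' @export
preprocess_gaze <- function(rec, min_run = 0.020, pad = 0.023,
                            max_gap = 0.250, median_width = 5) {
  rec |>
    renormalize_directions() |>
    expand_invalid(min_run = min_run, pad = pad) |>
    interpolate_short_gaps(max_gap = max_gap) |>
    median_filter_positions(width = median_width)
}
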