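# Small recordings and tables built in code for the unit tests.

# A minimal valid recording: static observer at the origin looking down +z
# at a wall z = 5, with per-sample hit points supplied explicitly.
make_rec <- function(t, hit, valid = TRUE, eye = c(0, 1.6, 0),
                     dir = NULL, nominal_rate = 90, hit_object = NA_character_) {
  n <- length(t)
  hit <- matrix(hit, ncol = 3)
  if (is.null(dir)) {
    dir <- t(apply(hit, 1, function(h) {
      d <- h - eye
      if (anyNA(d)) c(0, 0, 1) else d / sqrt(sum(d^2))
    }))
  } else {
    dir <- matrix(dir, ncol = 3, nrow = n, byrow = TRUE)
  }
  gaze_recording(tibble::tibble(
    t = t,
    eye_x = eye[1], eye_y = eye[2], eye_z = eye[3],
    dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3],
    hit_x = hit[, 1], hit_y = hit[, 2], hit_z = hit[, 3],
    hit_object = rep_len(hit_object, n),
    valid = rep_len(valid, n)),
    nominal_rate = nominal_rate)
}

# Velocity series with explicit values, regular spacing.
make_vs <- function(w, rate = 90, valid = TRUE) {
  n <- length(w)
  tibble::tibble(t = (seq_len(n) - 1) / rate, dt = 1 / rate,
                 w_eye = w, valid = rep_len(valid, n))
}

# Event sequence shorthand: kinds and durations back to back from t = 0.
make_seq <- function(kinds, durations) {
  t_off <- cumsum(durations)
  t_on <- t_off - durations
  vrgaze:::new_event_seq(tibble::tibble(
    kind = kinds, t_on = t_on, t_off = t_off, duration_s = durations))
}

# Deterministic unit vector cloud for geometry property tests.
random_units <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
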