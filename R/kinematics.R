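#' Hit-point shift between two samples
#'
#' The first step of the movement-corrected angular velocity: the shift of
#' the gaze-ray hit point in allocentric (world) coordinates, ignoring where
#' it was seen from. If the viewed point did not move, this shift is zero and
#' stays zero through all following operations — walking past a fixated
#' object contributes nothing.
#'
#' @param hit_t1,hit_t2 hit points at the earlier/later sample (3-vectors or
#'   n x 3 matrices).
#' @return `hit_t2 - hit_t1`.
#' @export
hit_shift <- function(hit_t1, hit_t2) hit_t2 - hit_t1

#' Component of a shift in the plane orthogonal to the viewing direction
#'
#' Orthogonal rejection of the hit-point shift from the viewing direction:
#' `v - <v, eye> * eye`. Only the component perpendicular to the gaze ray
#' corresponds to a change of viewing direction; the parallel component is a
#' change of viewing distance.
#'
#' @param v_eye_vec shift vector(s): 3-vector or n x 3 matrix.
#' @param eye_vec unit viewing direction(s), matching shape.
#' @param tol tolerance on the unit-norm precondition.
#' @return The in-plane component, same shape as `v_eye_vec`.
#' @export
in_plane_component <- function(v_eye_vec, eye_vec, tol = 1e-6) {
  one <- !is.matrix(v_eye_vec)
  if (one) {
    v_eye_vec <- matrix(v_eye_vec, 1)
    eye_vec <- matrix(eye_vec, 1)
  }
  n <- vnorm(eye_vec)
  if (any(abs(n[is.finite(n)] - 1) > tol)) {
    abort("`eye_vec` must be unit-norm.", class = "vrgaze_contract_error")
  }
  dp <- rowSums(v_eye_vec * eye_vec)
  out <- v_eye_vec - dp * eye_vec
  if (one) out <- drop(out)
  out
}

#' Movement-corrected angular velocity for one sample pair
#'
#' The angle subtended at the first sample's eye position by the in-plane
#' hit shift, over the viewing distance:
#' `atan2(||in_plane||, ||eye_origin - hit_point||)` in degrees, divided by
#' the time difference. Both the viewing direction and the distance are
#' taken at the earlier sample. Invariant under observer translation while
#' the hit point is fixed.
#'
#' @param s1,s2 single-row slices of a gaze recording (earlier, later).
#' @return Angular velocity in degrees/second, or `NA` when a hit point is
#'   absent, the viewing distance is zero, or the time step is not positive.
#' @export
angular_velocity_step <- function(s1, s2) {
  h1 <- c(s1$hit_x, s1$hit_y, s1$hit_z)
  h2 <- c(s2$hit_x, s2$hit_y, s2$hit_z)
  o1 <- c(s1$eye_x, s1$eye_y, s1$eye_z)
  d1 <- c(s1$dir_x, s1$dir_y, s1$dir_z)
  dt <- s2$t - s1$t
  if (anyNA(h1) || anyNA(h2) || dt <= 0) return(NA_real_)
  dist <- vnorm(o1 - h1)
  if (dist == 0) return(NA_real_)
  ip <- vnorm(in_plane_component(hit_shift(h1, h2), d1))
  deg(atan2(ip, dist)) / dt
}

#' Movement-corrected angular velocity series of a recording
#'
#' Vectorized [angular_velocity_step()] over all consecutive sample pairs.
#' An interval is valid only when both samples are valid, both hit points
#' are present, the viewing distance at the earlier sample is positive and
#' the time step is positive. Each interval is timestamped at its earlier
#' sample.
#'
#' @param rec a preprocessed gaze recording (unit-norm directions).
#' @return A velocity-series tibble with columns `t` (earlier sample), `dt`,
#'   `w_eye` (degrees/second, `NA` on invalid intervals) and `valid`.
#' @export
gaze_velocity <- function(rec) {
  n <- nrow(rec)
  if (n < 2) return(tibble(t = numeric(), dt = numeric(), w_eye = numeric(), valid = logical()))
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  h <- vec3(rec, "hit")
  o <- vec3(rec, "eye")
  d <- vec3(rec, "dir")
  dt <- rec$t[i2] - rec$t[i1]
  shift <- h[i2, , drop = FALSE] - h[i1, , drop = FALSE]
  dist <- vnorm(o[i1, , drop = FALSE] - h[i1, , drop = FALSE])
  d1 <- d[i1, , drop = FALSE]
  dp <- rowSums(shift * d1)
  ip <- vnorm(shift - dp * d1)
  ok <- rec$valid[i1] & rec$valid[i2] &
    !is.na(ip) & !is.na(dist) & dist > 0 & dt > 0
  w <- rep(NA_real_, n - 1)
  w[ok] <- deg(atan2(ip[ok], dist[ok])) / dt[ok]
  tibble(t = rec$t[i1], dt = dt, w_eye = w, valid = ok)
}

#' Clip and smooth a velocity series
#'
#' Velocities above `clip` (default 1000 degrees/second, a biological
#' ceiling) are set to `clip`; the series is then passed through a
#' Savitzky-Golay filter applied within each maximal valid run, so invalid
#' intervals never leak into a filter window. Runs shorter than the window
#' pass through unchanged. Smoothed values are clamped back to
#' `[0, clip]`.
#'
#' @param vs a velocity series from [gaze_velocity()].
#' @param clip ceiling in degrees/second.
#' @param sg_window odd filter window length in samples. The default 3 with
#'   `sg_order = 2` is an exact fit, i.e. no additional smoothing: at 90 Hz
#'   saccades span only 3-5 frames, and any wider quadratic window smears
#'   their onsets and offsets by about a frame per side and inflates
#'   saccade durations accordingly. Set 5 (or more) to smooth.
#' @param sg_order polynomial order (default 2); must be < `sg_window`.
#' @return The conditioned velocity series.
#' @export
condition_velocity <- function(vs, clip = 1000, sg_window = 3, sg_order = 2) {
  if (sg_window %% 2 != 1 || sg_window < sg_order + 1) {
    abort("`sg_window` must be odd and at least `sg_order` + 1.",
          class = "vrgaze_config_error")
  }
  w <- pmin(vs$w_eye, clip)
  runs <- flag_runs(vs$valid & !is.na(w))
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    if (b - a + 1 >= sg_window) {
      w[a:b] <- signal::sgolayfilt(w[a:b], p = sg_order, n = sg_window)
    }
  }
  vs$w_eye <- pmin(pmax(w, 0), clip)
  vs
}

#' Head angular velocity series
#'
#' Angle between consecutive head-direction vectors (arccos of the clamped
#' dot product), in degrees, over the time step.
#'
#' @param rec a gaze recording with unit-norm `hdir_*` columns.
#' @return A tibble with `t` (earlier sample), `dt`, `w_head` and `valid`.
#' @export
head_angular_velocity <- function(rec) {
  n <- nrow(rec)
  if (n < 2) return(tibble(t = numeric(), dt = numeric(), w_head = numeric(), valid = logical()))
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  h <- vec3(rec, "hdir")
  dp <- pmin(pmax(rowSums(h[i1, , drop = FALSE] * h[i2, , drop = FALSE]), -1), 1)
  dt <- rec$t[i2] - rec$t[i1]
  w <- deg(acos(dp)) / dt
  tibble(t = rec$t[i1], dt = dt, w_head = w, valid = !is.na(w))
}

#' Eye direction in the head reference frame
#'
#' @param eye_dir_world unit 3-vector (or n x 3 matrix) in world coordinates.
#' @param head_rotation 3 x 3 orthonormal world-to-head rotation matrix.
#' @param tol orthonormality tolerance.
#' @return The eye-in-head direction(s), unit norm.
#' @export
eye_in_head <- function(eye_dir_world, head_rotation, tol = 1e-6) {
  if (max(abs(crossprod(head_rotation) - diag(3))) > tol) {
    abort("`head_rotation` must be orthonormal.", class = "vrgaze_contract_error")
  }
  if (is.matrix(eye_dir_world)) {
    eye_dir_world %*% t(head_rotation)
  } else {
    drop(head_rotation %*% eye_dir_world)
  }
}

#' Saccade amplitude between flanking gaze centroids
#'
#' Same geometric construction as the movement-corrected velocity — in-plane
#' component of the centroid shift over the viewing distance, seen from the
#' saccade-onset viewpoint — but *not* divided by time: an amplitude is an
#' angle, not a rate.
#'
#' @param prev_centroid,next_centroid mean hit points of the flanking gaze
#'   events (3-vectors).
#' @param eye_origin_at_onset,eye_vec_at_onset eye position and unit viewing
#'   direction at the saccade onset.
#' @return Amplitude in degrees, or `NA` if a centroid is missing.
#' @export
saccade_amplitude <- function(prev_centroid, next_centroid,
                              eye_origin_at_onset, eye_vec_at_onset) {
  if (anyNA(prev_centroid) || anyNA(next_centroid)) return(NA_real_)
  dist <- vnorm(eye_origin_at_onset - prev_centroid)
  if (is.na(dist) || dist == 0) return(NA_real_)
  ip <- vnorm(in_plane_component(hit_shift(prev_centroid, next_centroid),
                                 eye_vec_at_onset))
  deg(atan2(ip, dist))
}
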