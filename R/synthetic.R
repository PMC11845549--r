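#' Simple 3D scene for ray-casting
#'
#' A ground plane at height 0 plus axis-aligned boxes (a toy stand-in for a
#' city block: the observer walks between facades and looks at walls,
#' objects and the ground). The vertical axis is y (y-up).
#'
#' @param boxes tibble with columns `id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax`.
#' @param bounds walkable-area limits `c(xmin, xmax, zmin, zmax)`.
#' @return A `scene_model`.
#' @export
scene_model <- function(boxes = default_boxes(), bounds = c(-6, 6, -6, 6)) {
  stopifnot(all(boxes$xmax > boxes$xmin), all(boxes$ymax > boxes$ymin),
            all(boxes$zmax > boxes$zmin), !anyDuplicated(boxes$id))
  structure(list(boxes = as_tibble(boxes), bounds = bounds),
            class = "scene_model")
}

# A ring of facades around the walkable area plus two low street objects
# just outside it. Nothing stands inside the walkable bounds, so a fixated
# surface point can never be occluded while the observer walks.
default_boxes <- function() {
  tibble(
    id = c("house_n1", "house_n2", "house_e", "house_s1", "house_s2",
           "house_w", "statue", "bench"),
    xmin = c(-14, 2, 9, -14, 2, -14, 6.8, -9),
    xmax = c(-2, 14, 14, -2, 14, -9, 8.2, -7),
    ymin = rep(0, 8),
    ymax = c(6, 5, 7, 6, 4, 5, 3, 1),
    zmin = c(9, 9, -6, -16, -16, -6, 6.8, 6.5),
    zmax = c(14, 14, 6, -9, -9, 6, 8.2, 8.5))
}

#' Cast gaze rays against a scene
#'
#' Nearest forward intersection of each ray with the ground plane or any
#' box (slab method); absent (all-`NA` row) when the ray escapes to the sky.
#'
#' @param origin n x 3 matrix (or 3-vector) of ray origins.
#' @param direction n x 3 matrix (or 3-vector) of unit ray directions.
#' @param scene a [scene_model()].
#' @return A tibble with `hit_x/hit_y/hit_z` and `hit_object`.
#' @export
raycast <- function(origin, direction, scene) {
  if (!is.matrix(origin)) origin <- matrix(origin, 1)
  if (!is.matrix(direction)) direction <- matrix(direction, 1)
  n <- nrow(origin)
  eps <- 1e-9
  best_t <- rep(Inf, n)
  best_obj <- rep(NA_character_, n)
  # ground plane y = 0
  tg <- -origin[, 2] / direction[, 2]
  ok <- is.finite(tg) & tg > eps & direction[, 2] < 0
  best_t[ok] <- tg[ok]
  best_obj[ok] <- "ground"
  for (b in seq_len(nrow(scene$boxes))) {
    bx <- scene$boxes[b, ]
    lo <- c(bx$xmin, bx$ymin, bx$zmin)
    hi <- c(bx$xmax, bx$ymax, bx$zmax)
    tn <- rep(-Inf, n); tf <- rep(Inf, n); miss <- rep(FALSE, n)
    for (ax in 1:3) {
      o <- origin[, ax]; d <- direction[, ax]
      par <- abs(d) < eps
      miss <- miss | (par & (o < lo[ax] | o > hi[ax]))
      t1 <- (lo[ax] - o) / d
      t2 <- (hi[ax] - o) / d
      a <- pmin(t1, t2); z <- pmax(t1, t2)
      tn <- ifelse(par, tn, pmax(tn, a))
      tf <- ifelse(par, tf, pmin(tf, z))
    }
    hit <- !miss & tn <= tf & tf > eps
    tb <- ifelse(tn > eps, tn, tf)           # inside the box: exit face
    upd <- hit & tb < best_t
    best_t[upd] <- tb[upd]
    best_obj[upd] <- bx$id
  }
  got <- is.finite(best_t)
  p <- origin + direction * best_t
  p[!got, ] <- NA_real_
  tibble(hit_x = p[, 1], hit_y = p[, 2], hit_z = p[, 3], hit_object = best_obj)
}

#' Simulation configuration
#'
#' Defaults describe a 90-Hz VR gaze stream with main-sequence saccade
#' kinematics and gaze-onset-locked EEG on a linearly drifting clock; see
#' the methods vignette for the rationale behind each value.
#'
#' @param duration recording length, s.
#' @param et_rate eye-tracking rate, Hz.
#' @param fix_mean,fix_shape gamma fixation-duration distribution (mean s,
#'   shape).
#' @param sacc_amp_median,sacc_amp_sigma log-normal saccade-amplitude
#'   distribution (median degrees, log-sd).
#' @param ms_slope_ms,ms_intercept_ms main-sequence duration law
#'   `duration_ms = slope * amplitude_deg + intercept`.
#' @param head_speed_sd sd of the head random walk, world units per sqrt(s).
#' @param head_follow fraction of each gaze shift the head direction
#'   follows (cosmetic).
#' @param dir_noise_sd angular measurement noise, degrees.
#' @param blink_rate_per_min,blink_mean_s blink insertion rate and mean
#'   duration (gamma, shape 4).
#' @param frame_drop_p per-sample frame-drop probability.
#' @param jitter_sd timestamp jitter sd, s.
#' @param eeg_rate EEG rate, Hz.
#' @param eeg_noise_sd background-noise sd, µV.
#' @param noise_exponent 1/f^exponent spectral slope of the background.
#' @param evoked_latency,evoked_width,evoked_amplitude Gaussian evoked
#'   template (s, s, µV) added at each gaze onset.
#' @param osc_freq,osc_amp,osc_gain,osc_window ongoing oscillation (Hz, µV),
#'   its post-onset amplitude gain, and the window (s) the gain applies in.
#' @param drift_total EEG-vs-ET clock drift accumulated over the recording,
#'   s.
#' @param eeg_start first EEG timestamp on the EEG clock, s.
#' @param seed RNG seed fixing every draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 60, et_rate = 90,
                       fix_mean = 0.20, fix_shape = 4,
                       sacc_amp_median = 8, sacc_amp_sigma = 0.6,
                       ms_slope_ms = 2.2, ms_intercept_ms = 21,
                       head_speed_sd = 0.15, head_follow = 0.6,
                       dir_noise_sd = 0, blink_rate_per_min = 0,
                       blink_mean_s = 0.150, frame_drop_p = 0,
                       jitter_sd = 0, eeg_rate = 512,
                       eeg_noise_sd = 10, noise_exponent = 1,
                       evoked_latency = 0.100, evoked_width = 0.060,
                       evoked_amplitude = 5,
                       osc_freq = 10, osc_amp = 0, osc_gain = 0.5,
                       osc_window = c(0.050, 0.450),
                       drift_total = 0.053, eeg_start = 0, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(duration > 0, et_rate > 0, fix_mean > 0, fix_shape > 0,
                      sacc_amp_median > 0, eeg_rate > 0, blink_rate_per_min >= 0,
                      frame_drop_p >= 0, frame_drop_p < 1))
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rotate unit vectors v by `angle_deg` about a random axis orthogonal to v.
rotate_random <- function(v, angle_deg) {
  axis <- rnorm(3)
  axis <- axis - sum(axis * v) * v
  nrm <- vnorm(axis)
  if (nrm < 1e-12) axis <- c(v[2], -v[1], 0) else axis <- axis / nrm
  rotate_about(v, axis, angle_deg)
}

# Rodrigues rotation of v about unit axis k.
rotate_about <- function(v, k, angle_deg) {
  th <- rad(angle_deg)
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Spherical interpolation between unit vectors.
slerp <- function(a, b, w) {
  dp <- max(min(sum(a * b), 1), -1)
  th <- acos(dp)
  if (th < 1e-9) return(a)
  (sin((1 - w) * th) * a + sin(w * th) * b) / sin(th)
}

# Rowwise slerp for n x 3 matrices.
slerp_rows <- function(a, b, w) {
  dp <- pmin(pmax(rowSums(a * b), -1), 1)
  th <- acos(dp)
  tiny <- th < 1e-9
  sth <- ifelse(tiny, 1, sin(th))
  out <- (sin((1 - w) * th) * a + sin(w * th) * b) / sth
  out[tiny, ] <- a[tiny, ]
  out
}

# Rotate each row of unit-vector matrix v by angle_deg[i] about an
# independent random axis orthogonal to it (Rodrigues with k orthogonal to
# v, so the k.v term vanishes).
rotate_random_rows <- function(v, angle_deg) {
  n <- nrow(v)
  a <- matrix(rnorm(3 * n), n, 3)
  a <- a - rowSums(a * v) * v
  nrm <- vnorm(a)
  fix <- which(nrm < 1e-12 | !is.finite(nrm))
  if (length(fix) > 0) a[fix, ] <- cbind(v[fix, 2], -v[fix, 1], 0)
  k <- a / vnorm(a)
  th <- rad(angle_deg)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  v * cos(th) + kxv * sin(th)
}

#' Simulate a VR scanpath with ground truth
#'
#' Alternating fixations and saccades over a [scene_model()]: fixation
#' durations are gamma-distributed; saccade amplitudes log-normal, with the
#' saccade duration following the configured main-sequence law and the eye
#' direction sweeping along a raised-cosine velocity profile. The head
#' performs a bounded random walk, and the eye direction is recomputed every
#' frame so that the fixated scene point stays fixed while the observer
#' translates — the geometry the movement-corrected velocity must null out.
#' Hit points come from per-sample ray-casts.
#'
#' @param config a [sim_config()].
#' @param scene a [scene_model()].
#' @return A list with `rec` (noise-free [gaze_recording()]) and `truth`
#'   (list: `events` tibble with `kind`, `t_on`, `t_off`, `object`,
#'   `amplitude_deg`; `onsets` = true gaze-onset times; `config`).
#' @export
simulate_scanpath <- function(config = sim_config(), scene = scene_model()) {
  with_seed(config$seed, simulate_scanpath_impl(config, scene))
}

simulate_scanpath_impl <- function(config, scene) {
  rate <- config$et_rate
  n <- floor(config$duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  if (config$jitter_sd > 0) {
    t <- t + rnorm(n, 0, config$jitter_sd)
    t <- t[1] + cumsum(c(0, pmax(diff(t), 1e-4)))   # keep strictly increasing
  }
  bounds <- scene$bounds
  eye_h <- 1.6

  # head random walk (x, z), reflected at the walkable bounds
  step_sd <- config$head_speed_sd / sqrt(rate)
  hx <- reflect_walk(cumsum(c(0, rnorm(n - 1, 0, step_sd))), bounds[1], bounds[2])
  hz <- reflect_walk(cumsum(c(0, rnorm(n - 1, 0, step_sd))), bounds[3], bounds[4])
  origin <- cbind(hx, eye_h, hz)

  # event schedule in continuous time; each event row carries the fixation
  # target active at its end (tx/ty/tz), so saccade rows hold their landing
  # point and their predecessor's row holds the launch point
  ev <- list(); onsets <- numeric()
  t_cur <- 0
  p_cur <- pick_target(origin[1, ], scene)
  amp_ms <- function(A) (config$ms_slope_ms * A + config$ms_intercept_ms) / 1000
  onsets <- c(onsets, 0)
  repeat {
    fd <- rgamma(1, shape = config$fix_shape, rate = config$fix_shape / config$fix_mean)
    ev[[length(ev) + 1]] <- tibble(kind = "gaze", t_on = t_cur, t_off = t_cur + fd,
                                   object = p_cur$object, amplitude_deg = NA_real_,
                                   tx = p_cur$point[1], ty = p_cur$point[2],
                                   tz = p_cur$point[3])
    t_cur <- t_cur + fd
    if (t_cur >= config$duration) break
    # pick the next target by rotating the gaze ray by a sampled amplitude
    o_now <- origin[min(max(findInterval(t_cur, t), 1), n), ]
    d_now <- unit3(p_cur$point - o_now)
    A <- min(rlnorm(1, log(config$sacc_amp_median), config$sacc_amp_sigma), 60)
    p_next <- NULL
    for (try in 1:25) {
      d_new <- rotate_random(d_now, A)
      if (d_new[2] > 0.3) next                    # keep gaze below the sky
      hit <- raycast(o_now, d_new, scene)
      if (!is.na(hit$hit_x[1])) {
        p_next <- list(point = c(hit$hit_x[1], hit$hit_y[1], hit$hit_z[1]),
                       object = hit$hit_object[1])
        break
      }
    }
    if (is.null(p_next)) p_next <- pick_target(o_now, scene)
    sdur <- amp_ms(A)
    ev[[length(ev) + 1]] <- tibble(kind = "saccade", t_on = t_cur,
                                   t_off = t_cur + sdur,
                                   object = NA_character_, amplitude_deg = A,
                                   tx = p_next$point[1], ty = p_next$point[2],
                                   tz = p_next$point[3])
    t_cur <- t_cur + sdur
    onsets <- c(onsets, t_cur)
    p_cur <- p_next
    if (t_cur >= config$duration) break
  }
  events <- dplyr::bind_rows(ev)
  keep <- events$t_on < max(t)
  events <- events[keep, ]
  events$t_off <- pmin(events$t_off, max(t))
  onsets <- onsets[onsets < max(t)]

  # per-sample gaze state: during a fixation the eye tracks its (fixed)
  # scene point from the moving head; during a saccade it sweeps between
  # the flanking targets along a raised-cosine velocity profile
  ei <- pmax(findInterval(t, events$t_on), 1)
  tgt_now <- as.matrix(events[, c("tx", "ty", "tz")])
  in_sac <- events$kind[ei] == "saccade"
  d1 <- unitize(tgt_now[ei, , drop = FALSE] - origin)
  dir <- d1
  if (any(in_sac)) {
    i <- which(in_sac)
    ph <- (t[i] - events$t_on[ei[i]]) / (events$t_off[ei[i]] - events$t_on[ei[i]])
    ph <- pmin(pmax(ph, 0), 1)
    s <- ph - sin(2 * pi * ph) / (2 * pi)         # raised-cosine velocity profile
    d0 <- unitize(tgt_now[ei[i] - 1, , drop = FALSE] - origin[i, , drop = FALSE])
    dir[i, ] <- slerp_rows(d0, d1[i, , drop = FALSE], s)
  }
  hits <- raycast(origin, dir, scene)

  # head direction lazily follows the gaze azimuth (cosmetic)
  hdir <- matrix(NA_real_, n, 3)
  hdir[1, ] <- unit3(c(dir[1, 1], 0, dir[1, 3]))
  alpha <- 0.05 * config$head_follow / 0.6
  for (i in 2:n) {
    tgt <- unit3(c(dir[i, 1], 0, dir[i, 3]))
    hdir[i, ] <- unit3(slerp(hdir[i - 1, ], tgt, alpha))
  }

  rec <- gaze_recording(
    tibble(t = t,
           eye_x = origin[, 1], eye_y = origin[, 2], eye_z = origin[, 3],
           dir_x = dir[, 1], dir_y = dir[, 2], dir_z = dir[, 3],
           head_x = origin[, 1], head_y = origin[, 2], head_z = origin[, 3],
           hdir_x = hdir[, 1], hdir_y = hdir[, 2], hdir_z = hdir[, 3],
           hit_x = hits$hit_x, hit_y = hits$hit_y, hit_z = hits$hit_z,
           hit_object = hits$hit_object,
           valid = TRUE, provenance = "measured"),
    nominal_rate = rate, meta = list(simulated = TRUE, seed = config$seed))
  truth <- list(events = events[, c("kind", "t_on", "t_off", "object", "amplitude_deg")],
                onsets = onsets, config = config, t0_et = t[1], t1_et = t[n])
  list(rec = rec, truth = truth)
}

unit3 <- function(v) v / vnorm(v)

reflect_walk <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

pick_target <- function(origin, scene) {
  for (try in 1:50) {
    yaw <- runif(1, 0, 2 * pi)
    pitch <- runif(1, rad(-35), rad(5))
    d <- c(cos(pitch) * cos(yaw), sin(pitch), cos(pitch) * sin(yaw))
    hit <- raycast(origin, d, scene)
    if (!is.na(hit$hit_x[1])) {
      return(list(point = c(hit$hit_x[1], hit$hit_y[1], hit$hit_z[1]),
                  object = hit$hit_object[1]))
    }
  }
  list(point = c(origin[1], 0, origin[3] + 3), object = "ground")
}

#' Simulator truth as a reference event sequence
#'
#' @param truth the `truth` element of [simulate_scanpath()].
#' @return An event-sequence tibble usable as the reference in
#'   [compare_labels()] and [onset_shift_histogram()].
#' @export
truth_event_seq <- function(truth) {
  ev <- truth$events
  new_event_seq(tibble(kind = ev$kind, t_on = ev$t_on, t_off = ev$t_off,
                       duration_s = ev$t_off - ev$t_on,
                       hit_object = ev$object,
                       amplitude_deg = ev$amplitude_deg))
}

#' Corrupt a clean simulated recording with sensor noise
#'
#' Adds angular measurement noise to the eye directions (hit points are
#' recomputed by ray-cast so geometry stays consistent), inserts blink runs
#' as invalid samples with absent eye data, and drops frames.
#'
#' @param rec a clean simulated [gaze_recording()].
#' @param config a [sim_config()]; the relevant fields are `dir_noise_sd`,
#'   `blink_rate_per_min`, `blink_mean_s`, `frame_drop_p` and `seed`.
#' @param scene the [scene_model()] the recording was cast against.
#' @return The corrupted recording.
#' @export
corrupt_recording <- function(rec, config, scene = scene_model()) {
  with_seed(config$seed + 1L, corrupt_impl(rec, config, scene))
}

corrupt_impl <- function(rec, config, scene) {
  n <- nrow(rec)
  if (config$dir_noise_sd > 0) {
    d <- vec3(rec, "dir")
    d <- rotate_random_rows(d, rnorm(n, 0, config$dir_noise_sd))
    rec <- set_vec3(rec, "dir", d)
    hits <- raycast(vec3(rec, "eye"), d, scene)
    rec$hit_x <- hits$hit_x; rec$hit_y <- hits$hit_y; rec$hit_z <- hits$hit_z
    rec$hit_object <- hits$hit_object
  }
  dur_min <- (rec$t[n] - rec$t[1]) / 60
  n_blink <- rpois(1, config$blink_rate_per_min * dur_min)
  if (n_blink > 0) {
    starts <- sort(runif(n_blink, rec$t[1], rec$t[n]))
    durs <- rgamma(n_blink, shape = 4, rate = 4 / config$blink_mean_s)
    for (b in seq_len(n_blink)) {
      ix <- which(rec$t >= starts[b] & rec$t <= starts[b] + durs[b])
      if (length(ix) == 0) next
      rec$valid[ix] <- FALSE
      rec[ix, c(paste0("dir_", c("x", "y", "z")), paste0("hit_", c("x", "y", "z")))] <- NA_real_
      rec$hit_object[ix] <- NA_character_
    }
  }
  if (config$frame_drop_p > 0) {
    drop <- runif(n) < config$frame_drop_p
    drop[c(1, n)] <- FALSE
    rec <- restore_rec(as_tibble(rec)[!drop, ], rec)
  }
  rec
}

#' Gaussian evoked template of a simulation
#'
#' @param config a [sim_config()].
#' @param rate sampling rate, Hz (default the config's EEG rate).
#' @return A tibble with `t` (s after gaze onset) and `uv`.
#' @export
evoked_template <- function(config, rate = config$eeg_rate) {
  tt <- seq(0, config$evoked_latency + 3 * config$evoked_width, 1 / rate)
  sigma <- config$evoked_width / 2
  tibble(t = tt,
         uv = config$evoked_amplitude * exp(-(tt - config$evoked_latency)^2 / (2 * sigma^2)))
}

#' Simulate gaze-onset-locked EEG on a drifting clock
#'
#' One channel ("Oz") of 1/f^exponent background noise, a Gaussian evoked
#' template added at each true gaze onset, and an ongoing oscillation whose
#' amplitude is multiplied by a configured gain inside a post-onset window
#' (gain < 1 emulates the post-fixation alpha-power drop). The EEG timeline
#' drifts linearly against the eye-tracking clock by the configured total.
#'
#' @param truth the `truth` element of [simulate_scanpath()] (or any list
#'   with `onsets`, `t0_et`, `t1_et`).
#' @param config a [sim_config()].
#' @return A list with `eeg` (an [eeg_recording()]), `model` (the true
#'   [clock_model()]) and `template` (tibble from [evoked_template()]).
#' @export
simulate_eeg <- function(truth, config = truth$config) {
  with_seed(config$seed + 2L, simulate_eeg_impl(truth, config))
}

simulate_eeg_impl <- function(truth, config) {
  rate <- config$eeg_rate
  model <- clock_model(offset = config$eeg_start, drift_total = config$drift_total,
                       t0_et = truth$t0_et, t1_et = truth$t1_et)
  pad <- 2                                  # seconds beyond the last onset
  nt <- ceiling((to_eeg_time(truth$t1_et, model) + pad) * rate)
  x <- colored_noise(nt, config$noise_exponent) * config$eeg_noise_sd
  tgrid <- (seq_len(nt) - 1) / rate
  onset_eeg <- to_eeg_time(truth$onsets, model)
  tpl <- evoked_template(config, rate)$uv
  for (o in onset_eeg) {
    i0 <- round(o * rate)                   # 0-based onset sample
    ix <- i0 + seq_along(tpl)               # 1-based columns from onset
    ok <- ix >= 1 & ix <= nt
    x[ix[ok]] <- x[ix[ok]] + tpl[ok]
  }
  if (config$osc_amp > 0) {
    env <- rep(1, nt)
    for (o in onset_eeg) {
      ix <- which(tgrid >= o + config$osc_window[1] & tgrid <= o + config$osc_window[2])
      env[ix] <- config$osc_gain
    }
    x <- x + config$osc_amp * env * sin(2 * pi * config$osc_freq * tgrid + runif(1, 0, 2 * pi))
  }
  eeg <- eeg_recording(matrix(x, 1), rate = rate, start_t = config$eeg_start,
                       channels = "Oz")
  # the EEG-clock stamps of the shared recording start/end (what an LSL
  # stream provides for endpoint drift estimation)
  eeg_span <- config$eeg_start + c(0, to_eeg_time(truth$t1_et, model))
  list(eeg = eeg, model = model, template = evoked_template(config, rate),
       eeg_span = eeg_span)
}

# 1/f^exponent noise via spectral shaping, unit variance. Shaped at the
# next power-of-two length (R's FFT is slow for lengths with large prime
# factors) and truncated.
colored_noise <- function(n, exponent) {
  if (n < 2) return(rnorm(n))
  m <- stats::nextn(n, 2)
  w <- rnorm(m)
  W <- fft(w)
  f <- c(1, seq_len(m - 1))                 # avoid dividing DC by zero
  f <- pmin(f, m - f + 1)                   # mirror for negative frequencies
  W <- W / f^(exponent / 2)
  W[1] <- 0
  x <- Re(fft(W, inverse = TRUE)) / m
  as.numeric(scale(x[seq_len(n)]))
}
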