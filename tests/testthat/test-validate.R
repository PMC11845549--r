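test_that("duration summaries report robust statistics per kind", {
  s <- make_seq(rep("gaze", 3), c(1, 2, 3))
  d <- duration_summary(s)
  expect_equal(d$median_s, 2)
  s1 <- make_seq("saccade", 0.05)
  d1 <- duration_summary(s1)
  expect_equal(d1$median_s, 0.05)
  expect_equal(d1$q3_s - d1$q1_s, 0)
  # simulated gamma fixation durations are recovered within 10% at n ~ 500
  cfg <- sim_config(duration = 150, seed = 31, fix_mean = 0.18)
  sp <- simulate_scanpath(cfg)
  rec <- preprocess_gaze(sp$rec)
  seq <- classify_gaze(rec)
  med <- duration_summary(seq)$median_s[duration_summary(seq)$kind == "gaze"]
  tr_ev <- sp$truth$events
  true_med <- median((tr_ev$t_off - tr_ev$t_on)[tr_ev$kind == "gaze"])
  expect_gt(sum(seq$kind == "gaze"), 400)
  expect_lt(abs(med - true_med) / true_med, 0.10)
})

test_that("main sequence correlation behaves on exact, degenerate and simulated input", {
  s <- make_seq(rep("saccade", 5), rep(0.05, 5))
  s$amplitude_deg <- 1:5
  s$peak_vel_dps <- 100 * (1:5)
  expect_equal(main_sequence(s)$r, 1)
  s$amplitude_deg <- rep(3, 5)
  expect_true(is.na(main_sequence(s)$r))
  # classifier output on simulated main-sequence kinematics
  sp <- simulate_scanpath(sim_config(duration = 120, seed = 32))
  seq <- classify_gaze(preprocess_gaze(sp$rec))
  ms <- main_sequence(seq)
  expect_gt(ms$n_saccades, 100)
  expect_gt(ms$r, 0.8)
})

test_that("onset-aligned matrices snap to frames and show the saccade-then-quiet profile", {
  series <- tibble::tibble(t = (0:999) / 90, w_eye = rep(1, 1000))
  m <- onset_aligned_matrix(series, onsets = c(2, 5, 8))
  expect_equal(nrow(m), 3)
  expect_true(all(m == 1, na.rm = TRUE))
  expect_equal(ncol(m), length(attr(m, "offsets")))
  # rows near the series edge are padded with NA
  m2 <- onset_aligned_matrix(series, onsets = 0.05)
  expect_true(anyNA(m2[1, ]))
  # simulated stream: median velocity peaks before gaze onset and falls after
  sp <- simulate_scanpath(sim_config(duration = 60, seed = 33))
  rec <- preprocess_gaze(sp$rec)
  vs <- condition_velocity(gaze_velocity(rec))
  seq <- classify_gaze(rec)
  mm <- onset_aligned_matrix(vs[, c("t", "w_eye")], gaze_onsets(seq))
  med <- apply(mm, 2, median, na.rm = TRUE)
  offs <- attr(mm, "offsets")
  expect_gt(max(med[offs < 0]), max(med[offs > 2]) + 50)
})

test_that("dispersion change is the distance between consecutive hit points", {
  hit <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0))
  rec <- make_rec((0:2) / 90, hit, eye = c(0, 1.6, -5))
  d <- dispersion_change(rec)
  expect_equal(d$dispersion, c(0, 5))
  expect_true(all(d$dispersion >= 0))
  rec$hit_x[2] <- NA
  expect_true(all(is.na(dispersion_change(rec)$dispersion)))
})

test_that("gaze distance summaries are translation invariant", {
  t <- (0:9) / 90
  hit <- matrix(rep(c(0, 0, 5), 10), ncol = 3, byrow = TRUE)
  rec <- make_rec(t, hit, eye = c(0, 0, 0))
  s <- make_seq("gaze", 10 / 90); s$t_on <- -1e-9
  g <- gaze_distance_summary(s, rec)
  expect_equal(g$median_dist, 5)
  # rigid translation of scene + observer changes nothing
  rec2 <- rec
  for (col in c("eye_x", "hit_x")) rec2[[col]] <- rec2[[col]] + 100
  for (col in c("eye_y", "hit_y")) rec2[[col]] <- rec2[[col]] - 3
  expect_equal(gaze_distance_summary(s, rec2)$median_dist, 5, tolerance = 1e-12)
  expect_equal(nrow(gaze_distance_summary(s[0, ], rec)), 0)
})

test_that("compare_labels cross-tabulates per frame and conserves the sample count", {
  t <- (0:89) / 90
  hit <- matrix(rep(c(0, 0, 5), 90), ncol = 3, byrow = TRUE)
  rec <- make_rec(t, hit)
  a <- make_seq(c("gaze", "saccade", "gaze"), c(0.4, 0.1, 0.5))
  m <- compare_labels(a, a, rec)
  expect_equal(sum(m) + attr(m, "n_uncovered"), 90)
  expect_equal(sum(diag(m)), sum(m))
  # complementary labels land off the diagonal
  b <- make_seq(c("saccade", "gaze", "saccade"), c(0.4, 0.1, 0.5))
  m2 <- compare_labels(a, b, rec)
  # only the two frames straddling shared event boundaries can coincide
  expect_lte(sum(diag(m2)), 2)
  expect_gt(sum(m2) - sum(diag(m2)), 80)
  expect_error(compare_labels(a, make_seq("gaze", 200), rec),
               class = "vrgaze_data_error")
})

test_that("onset shift histograms match greedily at sample resolution", {
  on <- c(1, 2, 3, 4)
  h <- onset_shift_histogram(on, on)
  expect_equal(h$unmatched, 0)
  expect_equal(h$hist$count[h$hist$shift_samples == 0], 4)
  expect_equal(sum(h$hist$count), 4)

  # a +11 ms shift lands in the +1-sample bin
  h2 <- onset_shift_histogram(2, 2 + 0.011)
  expect_equal(h2$hist$count[h2$hist$shift_samples == 1], 1)

  # an onset 200 ms away from any reference stays unmatched
  h3 <- onset_shift_histogram(c(1, 5), c(1, 5.2))
  expect_equal(h3$unmatched, 1)

  # exact two-sided tie contributes half a count to each bin
  h4 <- onset_shift_histogram(5, c(5 - 0.022, 5 + 0.022))
  expect_equal(h4$hist$count[h4$hist$shift_samples == -2], 0.5)
  expect_equal(h4$hist$count[h4$hist$shift_samples == 2], 0.5)
  expect_equal(h4$unmatched, 0)

  # each reference onset is consumed at most once
  h5 <- onset_shift_histogram(c(1.00, 1.01), c(1.005))
  expect_equal(sum(h5$hist$count), 1)
  expect_equal(h5$unmatched, 1)
})

test_that("snap_events_to_frames quantizes durations to the frame grid", {
  t <- (0:89) / 90
  rec <- make_rec(t, matrix(rep(c(0, 0, 5), 90), ncol = 3, byrow = TRUE))
  s <- make_seq(c("gaze", "saccade", "gaze"), c(0.4031, 0.0562, 0.5407))
  snapped <- snap_events_to_frames(s, rec)
  expect_equal(snapped$kind, c("gaze", "saccade", "gaze"))
  expect_equal(snapped$duration_s * 90, round(snapped$duration_s * 90),
               tolerance = 1e-9)
  expect_equal(sum(snapped$duration_s), 90 / 90, tolerance = 1e-9)
})
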