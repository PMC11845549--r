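test_that("mad_threshold follows median + k * raw MAD with a small-sample fallback", {
  expect_equal(mad_threshold(rep(7, 10)), 7)
  expect_equal(mad_threshold(1:9, k = 3), 5 + 3 * 2)
  expect_true(is.na(mad_threshold(c(1, 2))))
  # bounded influence of a single huge outlier
  base <- mad_threshold(c(1:9))
  shifted <- mad_threshold(c(1:9, 1e6))
  expect_lt(shifted - base, 3 * 3)  # median and MAD each move at most one rank
})

test_that("data-driven boundaries hit the 2 Hz target and degrade gracefully", {
  set.seed(21)
  # 60 s at 90 Hz with a saccade-like spike every ~0.4 s: >= 120 runs
  n <- 60 * 90
  w <- abs(rnorm(n, 10, 2))
  spikes <- seq(20, n - 20, by = 36)
  for (s in spikes) w[s + 0:2] <- c(300, 500, 280)
  vs <- make_vs(w)
  segs <- data_driven_boundaries(vs)
  expect_equal(length(segs$boundaries), round(2 * 60))
  expect_true(all(diff(segs$boundaries) > 0))

  # boundaries sit on peak-velocity samples of the selected runs
  peaks <- vs$t[spikes + 1]
  expect_true(all(segs$boundaries %in% peaks))

  # no suprathreshold run: single segment
  vs2 <- make_vs(rep(5, 900))
  expect_length(data_driven_boundaries(vs2)$boundaries, 0)

  # fewer runs than the target: all runs become boundaries
  w3 <- rep(10, 900); w3[c(100, 400, 700)] <- 500
  expect_length(data_driven_boundaries(make_vs(w3))$boundaries, 3)
})

test_that("fixed 10-s boundaries count floor(duration/10)", {
  rec35 <- make_rec(seq(0, 35, by = 1 / 90),
                    matrix(rep(c(0, 0, 5), 3151), ncol = 3, byrow = TRUE))
  b <- fixed_boundaries(rec35)
  expect_equal(b$boundaries, c(10, 20, 30))
  rec5 <- make_rec(seq(0, 5, by = 1 / 90),
                   matrix(rep(c(0, 0, 5), 451), ncol = 3, byrow = TRUE))
  expect_length(fixed_boundaries(rec5)$boundaries, 0)
  for (dur in c(9.9, 10, 21.5, 40)) {
    t <- seq(0, dur, by = 1 / 90)
    r <- make_rec(t, matrix(rep(c(0, 0, 5), length(t)), ncol = 3, byrow = TRUE))
    expect_length(fixed_boundaries(r)$boundaries,
                  floor((t[length(t)] - t[1]) / 10))
  }
})

test_that("classify_samples thresholds per segment and labels invalid intervals", {
  vs <- make_vs(c(10, 10, 300, 400, 10, 10))
  segs <- fixed_boundaries(tibble::tibble(t = vs$t))  # single segment
  lab <- classify_samples(vs, segs, k = 3)
  # oracle: median 10 + 3 * MAD -> threshold below 300
  thr <- median(vs$w_eye) + 3 * median(abs(vs$w_eye - median(vs$w_eye)))
  expect_equal(lab$label, ifelse(vs$w_eye > thr, "saccade", "gaze"))
  expect_equal(lab$label, c("gaze", "gaze", "saccade", "saccade", "gaze", "gaze"))

  # all-equal velocities: nothing exceeds median + k * 0
  vs2 <- make_vs(rep(25, 10))
  expect_true(all(classify_samples(vs2, segs, k = 3)$label == "gaze"))

  # invalid intervals labeled invalid
  vs3 <- make_vs(c(10, NA, 10, 500, 10), valid = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(classify_samples(vs3, segs, k = 3)$label[2], "invalid")

  # labels near a boundary depend only on their own segment's threshold
  w <- c(rep(10, 45), rep(100, 45))
  vs4 <- make_vs(w)
  segs4 <- structure(list(boundaries = vs4$t[46], method = "data_driven",
                          global_threshold = NA_real_), class = "segment_set")
  lab4 <- classify_samples(vs4, segs4, k = 3)
  expect_equal(unique(lab4$threshold[1:45]), 10)
  expect_equal(unique(lab4$threshold[46:90]), 100)
})

test_that("build_events tiles the timeline from label runs", {
  vs <- make_vs(c(10, 10, 300, 320, 10))
  vs$label <- c("gaze", "gaze", "saccade", "saccade", "gaze")
  ev <- build_events(vs)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$kind, c("gaze", "saccade", "gaze"))
  expect_equal(ev$t_off[-3], ev$t_on[-1])              # no overlap, no gap
  expect_equal(ev$peak_vel_dps[2], 320)
  expect_equal(ev$t_off[3] - ev$t_on[1], 5 / 90, tolerance = 1e-9)

  vs$label <- rep("gaze", 5)
  expect_equal(nrow(build_events(vs)), 1)
})

test_that("merge_short_events absorbs implausible events and reaches a fixed point", {
  # an 11-ms saccade between two gazes: everything fuses into one gaze
  s <- make_seq(c("gaze", "saccade", "gaze"), c(0.100, 0.011, 0.100))
  out <- merge_short_events(s)
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "gaze")
  expect_equal(out$duration_s, 0.211)

  # both above minimum: unchanged
  s2 <- make_seq(c("gaze", "saccade"), c(0.100, 0.030))
  expect_equal(nrow(merge_short_events(s2)), 2)

  # a too-short leading saccade is absorbed forward
  s3 <- make_seq(c("saccade", "gaze"), c(0.011, 0.100))
  out3 <- merge_short_events(s3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$kind, "gaze")
  expect_equal(out3$t_on, 0)

  # chains of short events terminate and end with no short survivors
  set.seed(22)
  kinds <- rep(c("gaze", "saccade"), 50)
  durs <- runif(100, 0.005, 0.3)
  out4 <- merge_short_events(make_seq(kinds, durs))
  expect_true(all(out4$duration_s[out4$kind == "saccade"] >= 0.020 |
                    seq_len(nrow(out4))[out4$kind == "saccade"] == 1))
  expect_true(all(out4$duration_s[out4$kind == "gaze"] >= 0.040 |
                    seq_len(nrow(out4))[out4$kind == "gaze"] == 1))
  expect_equal(out4$t_off[nrow(out4)], sum(durs))
})

test_that("long-event outlier rejection is one-sided with degenerate-MAD rules", {
  durs <- c(rep(0.1, 9), 10)
  s <- make_seq(rep("gaze", 10), durs)
  out <- reject_long_outliers(s)
  expect_equal(sum(out$kind == "outlier_gaze"), 1)
  expect_equal(out$kind[10], "outlier_gaze")

  # all equal durations: nothing flagged
  s2 <- make_seq(rep("saccade", 6), rep(0.05, 6))
  expect_true(all(reject_long_outliers(s2)$kind == "saccade"))

  # flagging is invariant to the order sequences are supplied in
  a <- make_seq(rep("gaze", 5), c(0.1, 0.12, 0.11, 0.1, 2))
  b <- make_seq(rep("gaze", 5), c(0.09, 0.1, 0.13, 0.12, 0.1))
  r1 <- reject_long_outliers(list(a, b))
  r2 <- reject_long_outliers(list(b, a))
  expect_equal(r1[[1]]$kind, r2[[2]]$kind)
  expect_equal(sum(r1[[1]]$kind == "outlier_gaze"), 1)
})

test_that("gaze events get the majority hit object with first-occurrence tie-break", {
  t <- (0:5) / 90
  hit <- matrix(rep(c(0, 0, 5), 6), ncol = 3, byrow = TRUE)
  rec <- make_rec(t, hit, hit_object = c("A", "A", "B", NA, NA, NA))
  s <- make_seq(c("gaze", "gaze"), c(3 / 90, 3 / 90))
  s$t_on <- c(0, 3 / 90) - 1e-6; s$t_off <- c(3 / 90, 6 / 90) - 1e-6
  out <- assign_gaze_object(s, rec)
  expect_equal(out$hit_object[1], "A")      # A:2 vs B:1
  expect_true(is.na(out$hit_object[2]))     # all absent
  expect_equal(out$centroid_z[1], 5)

  rec2 <- make_rec(t[1:2], hit[1:2, ], hit_object = c("A", "B"))
  s2 <- make_seq("gaze", 2 / 90)
  expect_equal(assign_gaze_object(s2, rec2)$hit_object, "A")  # tie -> first seen
})

test_that("events overlapping unrepaired invalid data are rejected", {
  t <- (0:29) / 90
  hit <- matrix(rep(c(0, 0, 5), 30), ncol = 3, byrow = TRUE)
  rec <- make_rec(t, hit)
  rec$valid[13:15] <- FALSE                    # un-interpolated invalid run
  rec$provenance[20:22] <- "interpolated"      # repaired run stays eligible
  s <- make_seq(c("gaze", "gaze", "gaze"), c(10 / 90, 10 / 90, 10 / 90))
  out <- reject_invalid_overlap(s, rec)
  expect_equal(out$kind, c("gaze", "invalid", "gaze"))
  expect_equal(out$eeg_ok, c(TRUE, FALSE, TRUE))

  # gaze onset on an inserted stamp is disqualified as an EEG event
  rec2 <- make_rec(t, hit)
  rec2$provenance[1] <- "timestamp_interpolated"
  rec2$valid[1] <- FALSE
  s2 <- make_seq("gaze", 10 / 90)
  out2 <- reject_invalid_overlap(s2, rec2)
  expect_equal(out2$kind, "invalid")
  expect_false(out2$eeg_ok)
})

test_that("the classifier is deterministic: identical inputs give byte-identical tables", {
  sp <- simulate_scanpath(sim_config(duration = 20, seed = 23))
  rec <- preprocess_gaze(sp$rec)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(classify_gaze(rec), f1)
  write_events(classify_gaze(rec), f2)
  expect_identical(readLines(f1), readLines(f2))
})
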