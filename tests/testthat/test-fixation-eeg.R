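test_that("epoch extraction uses half-open rounded index windows and counts drops", {
  eeg <- eeg_recording(matrix(seq_len(8000), 1), 512, channels = "Oz")
  ep <- extract_epochs(eeg, 5120, window = c(-0.2, 0.5))
  expect_equal(dim(ep$data)[3], 358)                 # [5018, 5376)
  expect_equal(ep$data[1, 1, 1], 5019)               # 0-based 5018 -> column 5019
  expect_equal(ep$dropped, 0)
  # onset too close to the start is dropped and counted
  ep2 <- extract_epochs(eeg, c(10, 5120), window = c(-0.2, 0.5))
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$dropped, 1)
  expect_equal(dim(ep2$data)[1] + ep2$dropped, 2)
  # shift equivariance: shifting onsets by k samples shifts content by k
  ep3 <- extract_epochs(eeg, 5125, window = c(-0.2, 0.5))
  expect_equal(ep3$data[1, 1, ], ep$data[1, 1, ] + 5)
})

test_that("average_erp is the trial mean, linear, and fails on empty input", {
  x <- array(0, dim = c(3, 1, 10))
  x[1, 1, ] <- 1:10; x[2, 1, ] <- 1:10; x[3, 1, ] <- 1:10
  ep <- structure(list(data = x, times = (0:9) / 512, rate = 512,
                       channels = "Oz", onsets = 1:3, dropped = 0),
                  class = "epoch_set")
  expect_equal(unname(average_erp(ep)[1, ]), as.numeric(1:10))
  ep2 <- ep; ep2$data <- ep$data * 3
  expect_equal(average_erp(ep2), 3 * average_erp(ep), ignore_attr = TRUE)
  ep0 <- ep; ep0$data <- ep$data[0, , , drop = FALSE]
  expect_error(average_erp(ep0), class = "vrgaze_data_error")
})

test_that("the 5-Hz high-pass kills DC, passes 20 Hz, and attenuates 1 Hz by 20 dB", {
  rate <- 512
  t <- (0:(8 * rate - 1)) / rate
  mk <- function(x) eeg_recording(matrix(x, 1), rate, channels = "Oz")
  # DC
  out <- highpass(mk(rep(3, length(t))), 5)
  expect_lt(max(abs(out$data)), 1e-9)
  # 20 Hz passband (interior, away from edge transients)
  s20 <- sin(2 * pi * 20 * t)
  y20 <- highpass(mk(s20), 5)$data[1, ]
  mid <- seq(2 * rate, 6 * rate)
  gain20 <- sqrt(mean(y20[mid]^2) / mean(s20[mid]^2))
  expect_gt(gain20, 0.95); expect_lt(gain20, 1.05)
  # 1 Hz stopband
  s1 <- sin(2 * pi * 1 * t)
  y1 <- highpass(mk(s1), 5)$data[1, ]
  gain1 <- sqrt(mean(y1[mid]^2) / mean(s1[mid]^2))
  expect_lt(20 * log10(gain1), -20)
  expect_error(highpass(mk(s1), 300), class = "vrgaze_config_error")
})

test_that("Morlet power peaks at the stimulus frequency and scales with amplitude squared", {
  rate <- 512
  x <- sin(2 * pi * 10 * (0:20479) / rate)
  eeg <- eeg_recording(matrix(x, 1), rate, channels = "Oz")
  on <- seq(1000, 18000, by = 1200)
  ep <- extract_epochs(eeg, on, window = c(-0.875, 1.175))
  tf <- tf_average(morlet_tf(ep))
  expect_equal(tf$freqs[which.max(rowMeans(tf$power))], 10)
  expect_equal(mean(tf$power[tf$freqs == 10, ]), 0.25, tolerance = 0.01)
  # doubling the amplitude quadruples the power
  ep2 <- ep; ep2$data <- ep$data * 2
  tf2 <- tf_average(morlet_tf(ep2))
  expect_equal(mean(tf2$power[tf2$freqs == 10, ]),
               4 * mean(tf$power[tf$freqs == 10, ]), tolerance = 1e-6)
  # too short an epoch for the lowest-frequency wavelet
  ep3 <- extract_epochs(eeg, on, window = c(-0.1, 0.1))
  expect_error(morlet_tf(ep3), class = "vrgaze_config_error")
})

test_that("white-noise Morlet power follows the analysis bandwidth (prop. to frequency)", {
  set.seed(51)
  rate <- 512
  eeg <- eeg_recording(matrix(rnorm(rate * 120), 1), rate, channels = "Oz")
  ep <- extract_epochs(eeg, seq(1000, 58000, by = 700), window = c(-0.875, 1.175))
  tf <- tf_average(morlet_tf(ep, freqs = seq(5, 40, 1)))
  prof <- rowMeans(tf$power)
  # unit-gain wavelets: expected power grows linearly with frequency, so the
  # normalized profile power/freq is flat across mid frequencies
  flat <- prof / tf$freqs
  mid <- tf$freqs >= 8 & tf$freqs <= 35
  expect_lt(max(flat[mid]) / min(flat[mid]), 1.35)
})

test_that("total power of a unit sinusoid grows linearly with epoch length", {
  rate <- 512
  x <- sin(2 * pi * 10 * (0:60000) / rate)
  eeg <- eeg_recording(matrix(x, 1), rate, channels = "Oz")
  tot <- sapply(c(1, 2), function(len) {
    ep <- extract_epochs(eeg, 30000, window = c(-0.875 * len, 1.175 * len))
    tf <- tf_average(morlet_tf(ep, freqs = 10, crop = c(-0.875 * len, 1.175 * len)))
    sum(tf$power)
  })
  expect_equal(tot[2] / tot[1], 2, tolerance = 0.05)
})

test_that("dB baselining has closed-form behaviour and detects an injected alpha drop", {
  # closed form on a constructed power map
  tfa <- structure(list(power = rbind(c(rep(2, 50), rep(4, 50)),
                                      c(rep(10, 50), rep(1, 50))),
                        freqs = c(10, 20),
                        times = seq(-0.6, 0.39, length.out = 100),
                        cycles = 3, channel = "Oz"),
                   class = "tf_map")
  db <- db_baseline(tfa, baseline = c(-0.5, -0.2))
  expect_equal(db$power[1, 100], 10 * log10(2), tolerance = 1e-9)
  expect_equal(db$power[2, 100], -10, tolerance = 1e-9)
  expect_equal(db$power[1, 1], 0, tolerance = 1e-9)
  expect_error(db_baseline(tfa, baseline = c(-5, -4)), class = "vrgaze_config_error")

  # a post-onset alpha gain of 0.5 shows as negative dB in the alpha band
  cfg <- sim_config(duration = 200, seed = 52, eeg_noise_sd = 2,
                    evoked_amplitude = 0, osc_amp = 6, osc_gain = 0.5,
                    osc_window = c(0.05, 0.45))
  tr <- list(onsets = seq(2, 195, by = 1.4), t0_et = 0, t1_et = 200, config = cfg)
  se <- simulate_eeg(tr, cfg)
  on <- map_onsets_to_eeg(tr$onsets, se$model, cfg$eeg_rate, ncol(se$eeg$data))
  ep <- extract_epochs(se$eeg, on$sample[on$in_range], window = c(-0.875, 1.175))
  db2 <- db_baseline(tf_average(morlet_tf(ep)))
  alpha <- db2$freqs >= 9 & db2$freqs <= 11
  post <- db2$times > 0.1 & db2$times < 0.4
  pre <- db2$times > -0.45 & db2$times < -0.25
  expect_lt(mean(db2$power[alpha, post]), -2)
  expect_gt(abs(mean(db2$power[alpha, post])), abs(mean(db2$power[alpha, pre])) + 1)
})

test_that("shift correlation is exact in the degenerate case and errors on too few trials", {
  # a noiseless evoked recording: every trial equals the average, r = 1 at no shift
  cfg <- sim_config(duration = 40, seed = 53, eeg_noise_sd = 0.001,
                    evoked_amplitude = 5)
  tr <- list(onsets = seq(2, 37, by = 1.5), t0_et = 0, t1_et = 40, config = cfg)
  se <- simulate_eeg(tr, cfg)
  sc <- shift_correlation(se$eeg, tr$onsets, se$model, 90, mode = "erp",
                          shifts = 0L)
  expect_true(all(sc$r$r > 0.999))
  expect_error(shift_correlation(se$eeg, 2, se$model, 90), class = "vrgaze_data_error")
})
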