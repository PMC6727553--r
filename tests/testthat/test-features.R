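test_that("epoch segmentation counts and truncation follow the 10 s / 2 s grid", {
  expect_equal(nrow(segment_epochs(sine_recording(60))), 30)  # 6 x 5
  r67 <- recording(rep(0, 67 * 200), 200, rep(0, 67 * 500), 500)
  plan <- segment_epochs(r67)
  expect_equal(max(plan$epoch), 6)          # trailing 7 s discarded
  expect_equal(max(plan$t1), 60)
  # a full 26-h session at a nominal 1-Hz bookkeeping rate
  r26h <- recording(numeric(26 * 3600), 1, numeric(26 * 3600), 1)
  expect_equal(max(segment_epochs(r26h)$epoch), 9360)
  expect_error(segment_epochs(recording(rep(0, 1000), 200, rep(0, 2500), 500)),
               "too short")
  expect_error(segment_epochs(sine_recording(60), epoch_s = 10, segment_s = 3),
               "multiple")
})

test_that("periodogram concentrates tones correctly and satisfies Parseval", {
  t <- seq_len(400) / 200
  pg <- periodogram(sin(2 * pi * 4 * t), 200)
  expect_equal(pg$power[pg$freq == 4], 0.5, tolerance = 1e-12)
  expect_equal(sum(pg$power), 0.5, tolerance = 1e-12)

  pg_dc <- periodogram(rep(3, 400), 200)
  expect_equal(pg_dc$power[1], 9, tolerance = 1e-12)
  expect_equal(sum(pg_dc$power[-1]), 0, tolerance = 1e-12)

  # Parseval on white noise, against the direct time-domain mean square
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(400)
    pg <- periodogram(x, 200)
    expect_equal(sum(pg$power), mean(x^2), tolerance = 1e-9)
  }
  expect_error(periodogram(rnorm(399), 200), "segment length")
})

test_that("band powers in dB behave at tones, silence, and by enumeration", {
  t <- seq_len(400) / 200
  pg <- periodogram(sin(2 * pi * 4 * t), 200)
  sp_delta <- band_power_db(pg, 0.5, 5)
  sp_theta <- band_power_db(pg, 6, 9)
  expect_gte(sp_delta - sp_theta, 60)

  pg0 <- periodogram(rep(0, 400), 200)
  for (b in seq_len(nrow(band_definitions()))) {
    bd <- band_definitions()[b, ]
    expect_equal(band_power_db(pg0, bd$lo_hz, bd$hi_hz), -120)
  }

  # 7-Hz tone: theta band holds the 6 bins 6.0..8.5 Hz; recompute by hand
  pg7 <- periodogram(sin(2 * pi * 7 * t), 200)
  bins <- pg7$power[pg7$freq >= 6 & pg7$freq < 9]
  expect_length(bins, 6)
  expect_equal(band_power_db(pg7, 6, 9),
               10 * log10(mean(bins) + 1e-12), tolerance = 1e-12)
  expect_equal(band_power_db(pg7, 6, 9),
               10 * log10(0.5 / 6 + 1e-12), tolerance = 1e-6)

  expect_error(band_power_db(pg7, 0.1, 0.2), "no bins")
})

test_that("power ratios partition as expected", {
  t <- seq_len(400) / 200
  pg4 <- periodogram(sin(2 * pi * 4 * t), 200)
  expect_gte(power_ratio(pg4, 0.5, 5), 0.999)
  pg_dc <- periodogram(rep(2, 400), 200)
  expect_equal(power_ratio(pg_dc, 0, 0.5), 1.0)
  # equal-power tones at 2 and 12 Hz split delta and alpha evenly
  pg2 <- periodogram(sin(2 * pi * 2 * t) + sin(2 * pi * 12 * t), 200)
  expect_equal(power_ratio(pg2, 0.5, 5), 0.5, tolerance = 1e-9)
  expect_equal(power_ratio(pg2, 10.5, 15), 0.5, tolerance = 1e-9)
  # zero signal: ratio defined as 0
  expect_equal(power_ratio(periodogram(rep(0, 400), 200), 0.5, 5), 0)
})

test_that("EMG band-pass kills DC, passes 50 Hz, attenuates 200 Hz", {
  n <- 5000
  t <- seq_len(n) / 500
  dc <- emg_bandpass(rep(1, n), 500)
  expect_lt(mean(abs(dc[1000:4000])), 0.01)      # >= 40 dB down

  mid <- emg_bandpass(sin(2 * pi * 50 * t), 500)
  expect_equal(max(abs(mid[1000:4000])), 1, tolerance = 0.05)

  hi <- emg_bandpass(sin(2 * pi * 200 * t), 500)
  expect_lt(max(abs(hi[1000:4000])), 0.1)        # >= 20 dB down
  expect_error(emg_bandpass(rnorm(100), 200), "too low")
})

test_that("EMG energy matches the rectified-sine closed form and direct sums", {
  t <- seq_len(1000) / 500  # 2 s, whole cycles of 50 Hz
  A <- 7
  expect_equal(emg_energy(A * sin(2 * pi * 50 * t)), A * 2 / pi,
               tolerance = 0.04)
  expect_equal(emg_energy(rep(0, 100)), 0)
  set.seed(4)
  x <- rnorm(500)
  expect_equal(emg_energy(x), sum(abs(x)) / length(x), tolerance = 1e-12)
})

test_that("feature extraction has the right shape, content, and determinism", {
  rec <- sine_recording(10, eeg_hz = 2, eeg_amp = 50, emg_sd = 0)
  rec$emg <- rep(0, 5000)
  fm <- extract_features(rec)
  expect_equal(nrow(fm), 5)
  expect_true(all(feature_names() %in% names(fm)))
  expect_true(all(fm$pr_delta >= 0.999))
  expect_true(all(fm$emg_energy == 0))

  # synthetic deep-NREM epoch satisfies its defining delta contract
  ep <- synthesize_epoch("N2", seed = 11)
  rec2 <- recording(ep$eeg, 200, ep$emg, 500)
  fm2 <- extract_features(rec2)
  expect_gte(sum(fm2$pr_delta > 0.5), 3)

  # determinism and ratio-partition invariant on a noisy recording
  set.seed(5)
  noisy <- recording(rnorm(200 * 30, sd = 20), 200, rnorm(500 * 30, sd = 20), 500)
  f1 <- extract_features(noisy)
  f2 <- extract_features(noisy)
  expect_identical(f1, f2)
  expect_true(all(f1$pr_lo + f1$pr_delta + f1$pr_alpha <= 1 + 1e-12))
})
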