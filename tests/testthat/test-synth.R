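test_that("gen_ecg produces an annotated tidy signal", {
  ecg <- gen_ecg(duration = 10, rate = 360, hr_bpm = 60, seed = 1)
  expect_s3_class(ecg, "tbl_df")
  expect_identical(names(ecg)[1:2], c("time", "value"))
  expect_identical(nrow(ecg), 3600L)
  expect_equal(signal_rate(ecg), 360)
  ev <- signal_events(ecg)
  expect_identical(nrow(ev), 9L)   # 9 beats fit in 10 s with edge margins
  expect_true(all(diff(ev$time) > 0.5))
  # R peaks dominate: the annotated times sit near local maxima
  expect_gt(max(ecg$value), 0.8)
  expect_identical(gen_ecg(10, seed = 3)$value, gen_ecg(10, seed = 3)$value)
  expect_false(identical(gen_ecg(10, seed = 3)$value,
                         gen_ecg(10, seed = 4)$value))
})

test_that("gen_eeg produces unit-scale background with spikes", {
  eeg <- gen_eeg(duration = 8, rate = 256, n_spikes = 12, seed = 2)
  expect_identical(nrow(eeg), 2048L)
  expect_equal(signal_rate(eeg), 256)
  ev <- signal_events(eeg)
  expect_identical(nrow(ev), 12L)
  expect_true(all(ev$time > 0 & ev$time < 8))
  # spikes stand far above the unit-sd background
  expect_gt(max(abs(eeg$value)), 3)
})

test_that("gen_phantom lies in [0, 1] with structure", {
  img <- gen_phantom(64, seed = 1)
  expect_identical(dim(img), c(64L, 64L))
  expect_true(all(img >= 0 & img <= 1))
  expect_gt(sd(img), 0.05)
})

test_that("noise_spec validates its kind", {
  expect_error(noise_spec("purple", 0.1), "kind")
  sp <- noise_spec("gaussian", 0.2, seed = 5)
  expect_identical(sp$kind, "gaussian")
})

test_that("add_noise is reproducible and adds the requested power", {
  clean <- gen_ecg(8, seed = 1)
  n1 <- add_noise(clean, noise_spec("gaussian", 0.2, seed = 9))
  n2 <- add_noise(clean, noise_spec("gaussian", 0.2, seed = 9))
  expect_identical(n1$value, n2$value)
  expect_equal(sd(n1$value - clean$value), 0.2, tolerance = 0.02)
})

test_that("every noise kind runs on a signal", {
  clean <- gen_eeg(4, n_spikes = 8, seed = 1)
  for (k in c("gaussian", "speckle", "rician", "poisson", "muscle_burst",
              "ocular_drift", "baseline_wander", "motion_spike")) {
    lv <- if (k == "poisson") 50 else 0.3
    out <- add_noise(clean, noise_spec(k, lv, seed = 3))
    expect_identical(nrow(out), nrow(clean))
    expect_true(all(is.finite(out$value)))
    expect_gt(sd(out$value - clean$value), 0)
  }
})

test_that("noise_sd_for_snr hits the requested input SNR", {
  clean <- gen_ecg(8, seed = 2)
  sdn <- noise_sd_for_snr(clean, 10)
  noisy <- add_noise(clean, noise_spec("gaussian", sdn, seed = 4))
  got <- snr_db(clean$value, noisy$value)
  expect_equal(got, 10, tolerance = 0.5)
})

test_that("baseline wander is concentrated at low frequency", {
  clean <- gen_ecg(8, seed = 3)
  noisy <- add_noise(clean, noise_spec("baseline_wander", 0.5, seed = 7))
  w <- noisy$value - clean$value
  n <- length(w)
  p <- Mod(fft(w - mean(w)))^2
  f <- seq(0, 360 - 360 / n, by = 360 / n)
  f <- pmin(f, 360 - f)
  expect_gt(sum(p[f <= 2.5]) / sum(p), 0.9)
})

test_that("mix_sources stores the mixing matrix and rejects singularity", {
  S <- laplace_sources(2, 100, seed = 1)
  A <- matrix(c(1, 0.5, 0.2, 1), 2)
  X <- mix_sources(S, A)
  expect_equal(attr(X, "mixing"), A)
  expect_equal(X, A %*% S, ignore_attr = TRUE)
  expect_error(mix_sources(S, matrix(1, 2, 2)), "singular")
})

test_that("split_dev_test partitions reproducibly", {
  sp <- split_dev_test(100, dev_frac = 0.7, seed = 1)
  expect_identical(length(sp$dev), 70L)
  expect_identical(sort(c(sp$dev, sp$test)), 1:100)
  expect_identical(sp, split_dev_test(100, dev_frac = 0.7, seed = 1))
})
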