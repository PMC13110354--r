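test_that("denoise_signal returns a tidy signal of the same length", {
  fx <- noisy_ecg_fixture(seed = 1, duration = 6)
  out <- denoise_signal(fx$noisy, method = "gauss", window = 32, hop = 4)
  expect_s3_class(out, "tbl_df")
  expect_identical(nrow(out), nrow(fx$noisy))
  expect_identical(out$time, fx$noisy$time)
  dg <- attr(out, "diagnostics")
  expect_true(is.list(dg))
  expect_true(all(c("ica", "sigma_hat") %in% names(dg)))
})

test_that("classical-score denoising improves SNR on noisy ECG", {
  fx <- noisy_ecg_fixture(seed = 2, duration = 6)
  out <- denoise_signal(fx$noisy, method = "gauss", window = 32, hop = 2,
                        artifact_bands = fx$bands)
  before <- snr_db(fx$clean$value, fx$noisy$value)
  after <- snr_db(fx$clean$value, out$value)
  expect_gt(after, before)
})

test_that("the etwd method runs end to end with a small GA budget", {
  fx <- noisy_ecg_fixture(seed = 3, duration = 6)
  out <- denoise_signal(fx$noisy, method = "etwd", window = 32, hop = 4,
                        ga_fit = ga_config(population_size = 20,
                                           generations = 15, seed = 3),
                        artifact_bands = fx$bands)
  expect_identical(nrow(out), nrow(fx$noisy))
  dg <- attr(out, "diagnostics")
  expect_true(is_etwd_params(dg$etwd_params))
  expect_gt(snr_db(fx$clean$value, out$value),
            snr_db(fx$clean$value, fx$noisy$value))
})

test_that("sparse_etwd adds the wavelet stage and its hyperparameters", {
  fx <- noisy_ecg_fixture(seed = 4, duration = 6)
  out <- denoise_signal(fx$noisy, method = "sparse_etwd", window = 32,
                        hop = 4,
                        ga_fit = ga_config(population_size = 15,
                                           generations = 10, seed = 4))
  dg <- attr(out, "diagnostics")
  expect_true(all(c("lam_s", "p") %in% names(dg)))
  expect_identical(nrow(out), nrow(fx$noisy))
})

test_that("denoising is deterministic in the seed", {
  fx <- noisy_ecg_fixture(seed = 5, duration = 6)
  a <- denoise_signal(fx$noisy, method = "tanh", window = 32, hop = 8,
                      seed = 7)
  b <- denoise_signal(fx$noisy, method = "tanh", window = 32, hop = 8,
                      seed = 7)
  expect_identical(a$value, b$value)
})

test_that("denoise_signal validates its input", {
  expect_error(denoise_signal(c(1, NA, 3)), "non-finite")
  expect_error(denoise_signal(rnorm(6)), "shorter")
})

test_that("denoise_image reduces MSE on the noisy phantom", {
  clean <- gen_phantom(48, seed = 1)
  noisy <- add_noise(clean, noise_spec("gaussian", 0.15, seed = 2))
  out <- denoise_image(noisy, method = "gauss", seed = 1)
  expect_identical(dim(out), dim(noisy))
  expect_lt(metric_mse(clean, out), metric_mse(clean, noisy))
})

test_that("run_benchmark aggregates runs, summary and tests", {
  bm <- run_benchmark("image", methods = c("gauss", "tanh"), repeats = 2,
                      seed = 1)
  expect_s3_class(bm, "denoise_benchmark")
  expect_identical(nrow(bm$runs), 4L)
  expect_identical(nrow(bm$summary), 2L)
  expect_identical(bm$tests$baseline, "gauss")
  expect_true(all(c("snr_db_mean", "mse_mean") %in% names(bm$summary)))
})

test_that("plot constructors return ggplot objects", {
  fits <- lapply(1:2, function(s)
    run_strategy(function(th) sum(th^2), "ga",
                 ga_config(population_size = 20, generations = 10,
                           bounds = rbind(rep(-2, 2), rep(2, 2)),
                           seed = s)))
  expect_s3_class(autoplot(convergence_report(fits)), "ggplot")
  clean <- gen_ecg(6, seed = 1)
  noisy <- add_noise(clean, noise_spec("gaussian", 0.1, seed = 2))
  expect_s3_class(plot_denoise(clean, noisy), "ggplot")
})
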