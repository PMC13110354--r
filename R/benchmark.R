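#' Reference image-denoising benchmark (MSE column)
#'
#' Published mean-squared-error values for six denoising methods on
#' two medical images (signals normalized to `[0, 1]`), used as inputs
#' to the metric self-consistency checks: with `peak = 1`,
#' `PSNR = 10 log10(1/MSE)` and `RMSE = sqrt(MSE)` must reproduce the
#' tabulated companions of each MSE to printed precision.
#'
#' @return A tibble with columns `method`, `image`, `mse`.
#' @examples
#' ref <- reference_image_mse()
#' metric_psnr(ref$mse[ref$method == "etwd" & ref$image == 1])  # 22.68
#' @export
reference_image_mse <- function() {
  tibble(
    method = rep(c("gauss", "pow3", "skew", "tanh", "etwd", "sparse_etwd"),
                 each = 2),
    image = rep(c(1L, 2L), times = 6),
    mse = c(0.0065, 0.0160,
            0.0083, 0.0910,
            0.0072, 0.0510,
            0.0360, 0.0330,
            0.0054, 0.0140,
            0.0059, 0.0150))
}

#' Benchmark denoising methods on synthetic fixtures
#'
#' Reproduces the evaluation protocol on generated data: for each
#' repeat, draw a fresh clean fixture and noise realization, denoise
#' with every requested method, and score against the clean reference;
#' results are summarized as mean +/- sd per method with paired
#' t-tests (Bonferroni-corrected across the method family) and Cohen's
#' d against a baseline method.
#'
#' @param modality `"ecg"`, `"eeg"` or `"image"`.
#' @param methods Character vector of methods (see [denoise_signal()]).
#' @param repeats Number of independent repeats (seeds).
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param duration Signal length in seconds (signals only).
#' @param input_snr_db Gaussian-noise input SNR for ECG/image runs.
#' @param baseline Method the significance tests compare against.
#' @param ... Passed on to [denoise_signal()]/[denoise_image()].
#' @return A list of class `denoise_benchmark`: `runs` (tibble of every
#'   repeat x method metric row), `summary` (mean +/- sd per method),
#'   `tests` (paired comparisons vs `baseline`).
#' @export
run_benchmark <- function(modality = c("ecg", "eeg", "image"),
                          methods = c("gauss", "pow3", "skew", "tanh",
                                      "etwd", "sparse_etwd"),
                          repeats = 10, seed = 1, duration = 8,
                          input_snr_db = 10, baseline = "gauss", ...) {
  modality <- match.arg(modality)
  runs <- list()
  for (r in seq_len(repeats)) {
    sr <- seed + r
    fx <- .benchmark_fixture(modality, duration, input_snr_db, sr)
    for (m in methods) {
      den <- if (modality == "image")
        denoise_image(fx$noisy, method = m, seed = sr, ...)
      else denoise_signal(fx$noisy, method = m, seed = sr,
                          window = 32, hop = 2,
                          artifact_bands = fx$bands, ...)
      rep_row <- metric_report(fx$clean, den, method = m,
                               signal = modality)
      rep_row$repeat_id <- r
      rep_row$input_snr_db <- snr_db(.as_num(fx$clean),
                                     .as_num(fx$noisy))
      runs[[length(runs) + 1L]] <- rep_row
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("mse", "mae", "snr_db", "psnr", "cc"),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
  tests <- NULL
  if (baseline %in% methods && repeats >= 2) {
    wide <- runs |>
      dplyr::select("method", "repeat_id", "snr_db") |>
      tidyr::pivot_wider(names_from = "method", values_from = "snr_db")
    tests <- dplyr::bind_rows(lapply(setdiff(methods, baseline), function(m) {
      tt <- paired_tests(wide[[m]], wide[[baseline]],
                         n_methods = length(methods))
      tt$method <- m; tt$baseline <- baseline
      tt
    }))
  }
  structure(list(runs = runs, summary = summary, tests = tests,
                 modality = modality, seed = seed),
            class = "denoise_benchmark")
}

# study fixtures: ECG = Gaussian noise at `input_snr_db` plus baseline
# wander of equal power; EEG = muscle bursts (1.5 x background sd) plus
# ocular drift (1.0 x); image = phantom + Gaussian at `input_snr_db`
.benchmark_fixture <- function(modality, duration, input_snr_db, seed) {
  if (modality == "ecg") {
    clean <- gen_ecg(duration, seed = seed)
    sdn <- noise_sd_for_snr(clean, input_snr_db)
    noisy <- add_noise(clean, noise_spec("baseline_wander", sdn,
                                         seed = seed + 100L))
    noisy <- add_noise(noisy, noise_spec("gaussian", sdn, seed = seed + 200L))
    bands <- list(c(0, 0.8))
  } else if (modality == "eeg") {
    clean <- gen_eeg(duration, seed = seed)
    noisy <- add_noise(clean, noise_spec("muscle_burst", 1.5,
                                         seed = seed + 100L))
    noisy <- add_noise(noisy, noise_spec("ocular_drift", 1.0,
                                         seed = seed + 200L))
    bands <- list(c(0, 1), c(32, Inf))
  } else {
    clean <- gen_phantom(64, seed = seed)
    sdn <- noise_sd_for_snr(clean, input_snr_db)
    noisy <- add_noise(clean, noise_spec("gaussian", sdn, seed = seed + 200L))
    bands <- NULL
  }
  list(clean = clean, noisy = noisy, bands = bands)
}

#' @export
print.denoise_benchmark <- function(x, ...) {
  cat(sprintf("<denoise_benchmark> %s, %d repeats\n", x$modality,
              max(x$runs$repeat_id)))
  print(x$summary)
  invisible(x)
}
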