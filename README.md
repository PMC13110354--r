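# etwdenoise

Blind-source-separation denoising for biomedical signals (EEG, ECG) and
grayscale medical images, built around the four-parameter
**exponentiated transmuted Weibull distribution (ETWD)** as a source
amplitude model:

1. **Model** — `detwd()` / `petwd()` / `qetwd()` / `retwd()` implement
   the ETWD with scale `alpha`, shape `beta`, transmuting coefficient
   `lambda` and exponentiation power `nu`, plus eleven classical
   sub-models (`etwd_submodel()`), the log-likelihood and its analytic
   gradient.
2. **Estimator** — `fit_etwd()` maximizes the likelihood with an
   authored genetic algorithm (population 100, tournament 3, uniform
   crossover 0.8, Gaussian mutation 0.05, elitism 2, 200 generations);
   particle-swarm and differential-evolution strategies are available
   through `run_strategy()`.
3. **Separation** — the fitted ETWD yields a score function for a
   FastICA fixed-point iteration (`fastica()`) on overlapping signal
   windows or image patches, followed by Laplacian-ML **sparse code
   shrinkage** in the ICA basis and, optionally, wavelet-domain Lp
   thresholding with GA-tuned hyperparameters (`sparse_etwd`).
4. **Evaluation** — CC/MSE/MAE/SNR/PSNR metrics, paired t-tests with
   Bonferroni correction and Cohen's d, Pan-Tompkins R-peak detection,
   wavelet spike detection, and deterministic synthetic ECG/EEG/phantom
   generators, tied together by `run_benchmark()`.

Everything takes and returns tidy objects where that fits: signals are
`tibble(time, value)`, reports are tibbles, fit objects support
`tidy()` / `glance()` / `autoplot()`.

## Worked example

Denoise a synthetic EEG contaminated by muscle bursts and ocular
drift, and check that spike detection improves downstream:

```r
library(etwdenoise)

clean <- gen_eeg(duration = 8, seed = 1)
noisy <- add_noise(clean, noise_spec("muscle_burst", 1.5, seed = 2))
noisy <- add_noise(noisy, noise_spec("ocular_drift", 1.0, seed = 3))

den <- denoise_signal(noisy, method = "etwd", window = 32, hop = 2,
                      artifact_bands = list(c(0, 1), c(32, Inf)))

round(snr_db(clean$value, noisy$value), 2)   # input SNR
#> [1] 2.9
round(snr_db(clean$value, den$value), 2)     # output SNR
#> [1] 8.25

truth <- signal_events(clean)$time
event_f1(detect_spikes(noisy), truth)
#> # A tibble: 1 × 6
#>   precision recall    f1 n_matched n_detected n_true
#>       <dbl>  <dbl> <dbl>     <int>      <int>  <int>
#> 1     0.875    0.7 0.778        14         16     20
event_f1(detect_spikes(den), truth)
#> # A tibble: 1 × 6
#>   precision recall    f1 n_matched n_detected n_true
#>       <dbl>  <dbl> <dbl>     <int>      <int>  <int>
#> 1     0.905   0.95 0.927        19         21     20
```

Fitting the distribution itself:

```r
x <- retwd(1000, etwd_params(2, 1.5, 0.3, 1.2), seed = 7)
fit <- fit_etwd(x, ga_config(population_size = 60, generations = 80,
                             seed = 1))
fit
#> <etwd_fit> GA, n = 1000, -logLik = 1423.959
#> <etwd_params> alpha = 1.743, beta = 1.327, lambda = 0.3643, nu = 1.667
glance(fit)
#> # A tibble: 1 × 6
#>   neg_loglik     n strategy generations grad_norm converged_trace
#>        <dbl> <int> <chr>          <int>     <dbl> <lgl>
#> 1      1424.  1000 ga                80      18.9 TRUE
```

Note that the recovered parameters differ from the generating ones
while fitting the data essentially perfectly — the family is weakly
identified at this sample size (distant parameter vectors can be
closer than the Kolmogorov–Smirnov resolution). The `vignettes/methods.Rmd`
vignette quantifies this and the other design decisions.

Method comparison with significance tests:

```r
bm <- run_benchmark("eeg", methods = c("gauss", "etwd"), repeats = 10,
                    seed = 1)
bm$summary   # mean/sd of mse, mae, snr_db, psnr, cc per method
bm$tests     # paired t-test vs the baseline, Bonferroni at 0.05/6
```

## Command line

A thin CLI over the same functions ships in `inst/cli/etwdenoise.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/etwdenoise.R", package = "etwdenoise"))')" \
  simulate --modality ecg --duration 8 --noise gaussian --level 0.1 --out noisy.csv
# subcommands: simulate | fit | denoise | metrics | benchmark
```

## Tests and reproduction

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "etwdenoise",
                               load_package = "installed")'
```

`tests/testthat/test-acceptance.R` asserts the headline claims at full
strength. Four assertions fail **by design of their targets**, not of
the code, and are left in place deliberately:

- per-parameter GA recovery to ±0.15 at n = 1000 (the exact global MLE
  already misses this bar; weak identifiability),
- a 3 dB median SNR gain on the ECG fixture (an oracle shrinkage in
  the learned ICA basis tops out near 2.3 dB there; the EEG fixture
  clears the bar at ~4.3 dB), and
- the etwd ≥ gauss ordering on *mean* gain for each modality (the two
  methods are statistically tied on means on both fixtures —
  differences of a few tenths of a dB against ~1 dB per-seed spread —
  so the ordering flips with the seed set).

All are analyzed in the methods vignette.

Reproducing the headline numbers end to end:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script runs only against the installed package, derives all
randomness from `--seed`, and writes the recomputed quantities
(image-table PSNR/RMSE consistency, Bonferroni threshold, GA recovery
errors, separation correlations, ECG/EEG denoising gains, downstream
F1 before/after, shrinkage identities) as JSON.
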