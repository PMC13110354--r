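---
title: "Methods: ETWD source modeling, GA likelihood fitting and sparse code shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ETWD source modeling, GA likelihood fitting and sparse code shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(etwdenoise)
```

This vignette records the mathematical choices behind the package: the
distribution family, the estimator, the separation and shrinkage
pipeline, and the places where a design decision had to be made. It also
documents the measured limitations of the method.

## The exponentiated transmuted Weibull distribution (ETWD)

The four-parameter family has cumulative distribution function

$$F(x) = \left[1 + (\lambda - 1)t - \lambda t^2\right]^\nu,
  \qquad t = e^{-(x/\alpha)^\beta},\ x > 0,$$

with scale $\alpha > 0$, shape $\beta > 0$, transmuting coefficient
$\lambda \in [-1, 1]$ and exponentiation power $\nu > 0$. The density
follows by differentiation:

$$f(x) = \frac{\nu\beta}{\alpha}\left(\frac{x}{\alpha}\right)^{\beta-1}
  t\,(1 - \lambda + 2\lambda t)\,G^{\nu-1},
  \qquad G = 1 + (\lambda - 1)t - \lambda t^2.$$

`detwd()`, `petwd()`, `qetwd()` and `retwd()` implement this family.
The quantile function is closed-form: setting $q = p^{1/\nu}$ reduces
$F(x) = p$ to the quadratic $\lambda t^2 + (1-\lambda)t + (q-1) = 0$
whose root in $[0,1]$ is taken analytically (with a bisection fallback
for degenerate coefficients), and $x = \alpha(-\ln t)^{1/\beta}$.

Eleven classical lifetime distributions arise as constrained
sub-models (`etwd_submodel()`); the test suite verifies the Weibull,
exponential, Rayleigh, transmuted-Weibull and exponentiated-Weibull
reductions against closed forms at $10^{-12}$.

One correction was required relative to the printed log-likelihood in
the source material: the constant block
$\log\nu + \log\beta - \beta\log\alpha$ must be multiplied by the
sample size $n$ (it comes out of a product over $n$ observations).
`etwd_loglik()` carries the $n$; a test checks the log-likelihood
against `sum(detwd(x, p, log = TRUE))`.

The analytic gradient (`etwd_loglik_grad()`) was derived independently
and is validated against central finite differences at $10^{-4}$
relative error. At the box boundary $|\lambda| = 1$ a one-sided
difference quotient is used and flagged.

## GA maximum likelihood

`fit_etwd()` minimizes the negative log-likelihood with an authored
genetic algorithm (`run_strategy()`), using the reference
configuration: population 100, tournament selection of size 3, uniform
crossover at rate 0.8, Gaussian mutation at rate 0.05, elitism 2,
200 generations. Two knobs the configuration leaves open are fixed as
package defaults: per-gene swap probability 0.5 in uniform crossover,
and mutation standard deviation equal to 10% of each parameter's box
width. Particle-swarm and differential-evolution alternatives are
provided with standard literature defaults (inertia 0.729,
$c_1 = c_2 = 1.49445$; DE rand/1/bin with $F = 0.5$, $CR = 0.9$).

Elitism makes the best-fitness trace nonincreasing by construction,
which the tests assert on every run. One test cross-checks the GA
optimum against `DEoptim` as an *independent* optimizer (never as the
implementation).

### Limitation: weak identifiability

The family is heavily overparameterized at moderate sample sizes.
For the truth $(\alpha, \beta, \lambda, \nu) = (3, 4, 0.5, 2)$ and
$n = 1000$, the *exact global* maximum-likelihood estimate (verified
with DEoptim at NP = 80, 500 iterations, polished by L-BFGS) has
per-parameter mean absolute error of roughly $(0.35, 0.67, 0.34, 0.73)$
across seeds. The reason is that distant parameter vectors describe
nearly identical distributions: a typical global MLE such as
$(2.538, 3.123, 0.076, 2.911)$ differs from the truth by at most
$\sup_x |F_1(x) - F_2(x)| = 0.015$, well below the Kolmogorov–Smirnov
resolution $1.36/\sqrt{1000} = 0.043$ at that sample size. No estimator
can recover the individual parameters to $\pm 0.15$ from $n = 1000$
observations; the corresponding acceptance test is deliberately left
failing, with the measured errors reported. For denoising this does
not matter: only the implied *score function* enters the pipeline, and
near-equivalent parameter vectors give near-identical scores.

## FastICA with the ETWD score

The signal (or image) is embedded into overlapping windows
(`embed_signal()`, 8×8 patches via `embed_image()`), centered and
whitened (`center_whiten()`), and rotated by the fixed-point iteration
(`fastica()`)

$$W_{k+1} = W_k + D\left[\mathrm{E}\,\varphi(u)u^{\top} -
  \mathrm{diag}(\mathrm{E}\,\varphi_l u_l)\right]W_k,\qquad
  D = \mathrm{diag}\!\left(\frac{1}{\mathrm{E}\,\varphi_l u_l -
  \mathrm{E}\,\varphi_l'}\right),$$

with symmetric decorrelation after every step. Three implementation
points matter:

1. **Symmetrization.** The ETWD lives on $x > 0$, whitened components
   are signed; the score used is
   $\varphi(u) = \mathrm{sign}(u)\,\psi(|u| + \varepsilon)$ with
   $\psi = -(\log f)'$, the score of the symmetrized density.
2. **$\mathrm{E}\,\varphi'$ by difference quotient.** For cusped
   scores (Laplace-like, $\beta \le 1$) the pointwise derivative misses
   the delta mass the distributional derivative carries at the origin.
   Computing $\mathrm{E}\,\varphi'$ as a symmetric difference quotient
   of $\varphi$ (step $10^{-2}$) captures it; with the pointwise
   derivative the sign of $D$ flips and the iteration is attracted to
   spurious fixed points 45° away from the sources.
3. **Noise smoothing.** On noisy data each whitened component is
   source *plus* Gaussian noise. A sign-like score has zero contrast
   curvature at Gaussianity, so it cannot rank near-Gaussian
   directions. The pipeline therefore evaluates the score of the
   noise-convolved density, approximated as
   $\varphi_s(u) = (u/r)\,\psi(r)$ with $r = \sqrt{u^2 + s^2}$, where
   $s$ is the white-noise standard deviation mapped through the
   whitening transform (`score_smooth` in `fastica()`). Without this,
   the ETWD score loses several dB against the Gaussian nonlinearity
   on the EEG fixture; with it, it wins.

## Sparse code shrinkage

Shrinkage is applied in the *original* embedding space through the
closest row-orthonormal matrix $W_o$ to the data-space separation
matrix (polar factor). With orthonormal rows, additive white noise of
standard deviation $\sigma$ keeps the same $\sigma$ in every rotated
component, while sparse components keep their full variance. Each
component is shrunk with the Laplacian marginal-likelihood rule

$$g(u) = \mathrm{sign}(u)\max\!\left(0, |u| -
  \sqrt{2}\,\sigma^2/b\right),\qquad
  b_l = \sqrt{\max(v_l - \sigma_l^2, 0)}/\sqrt{2},$$

where $v_l$ is the component variance. Shrinking in the whitened
domain instead would be wrong: whitening flattens every direction to
the noise floor and the same rule then destroys the signal (measured:
output SNR dropped below input).

**Colored-noise decomposition.** Structured artifacts — ocular drift,
muscle bursts, baseline wander — carry far more power than the white
floor but live outside the diagnostic band, and amplitude statistics
alone cannot flag them. When `artifact_bands` are declared (EEG:
below 1 Hz and above 32 Hz; ECG: below 0.8 Hz), each component's noise
variance is taken as
$\sigma_l^2 = \sigma_{\text{white}}^2 + \phi_l v_l$, where $\phi_l$ is
the fraction of the back-projected component's spectral power inside
the artifact bands. A component dominated by artifact then receives a
near-zero Laplace scale and is suppressed.

The optional `sparse_etwd` stage adds wavelet-domain $L_p$
thresholding: a hand-written periodized orthogonal Daubechies-4 DWT
(no wavelet package exists in the target R environment; perfect
reconstruction and Parseval are tested), thresholds from the proximal
operator of $\lambda_s |s|^p$ (soft threshold at $p = 1$, Newton on
the proximal equation with a hard-threshold region for $p < 1$), and
GA-tuned $(\lambda_s, p)$ minimizing the total loss
$L_{\text{MLE}} + P(s)$ (`fit_sparsity()`, `total_loss()`).

## Metrics and evaluation conventions

- `snr_db(clean, denoised)` $= 10\log_{10}(\sum x^2 / \sum r^2)$; the
  literal ratio $\mu/\sigma$ is also provided (`snr_literal()`)
  because both conventions appear in the evaluation tables and only
  the dB form matches the printed numbers.
- `metric_psnr(mse, peak = 1)` $= 10\log_{10}(\text{peak}^2/\text{MSE})$.
  With peak 1, the published image table's PSNR and RMSE columns are
  recomputable from its MSE column; the test suite checks all entries
  (one entry in the source table is misrounded by one final digit).
- `paired_tests()` reports a paired t-test, the Bonferroni-adjusted
  threshold ($0.05/6 = 0.0083$ for the six-method family) and Cohen's
  d on paired differences.
- Downstream tasks: Pan–Tompkins R-peak detection (`detect_rpeaks()`,
  realized with a zero-phase Butterworth 5–15 Hz band-pass rather than
  the historical 200 Hz fixed-point cascade) and wavelet spike
  detection (`detect_spikes()`), scored by greedy one-to-one event
  matching (`event_f1()`).

## Synthetic fixtures

All evaluation runs on deterministic generators (`gen_ecg()`,
`gen_eeg()`, `gen_phantom()`, `add_noise()`); sizes are package
choices made for desk-scale compute:

- **ECG**: 360 Hz, Gaussian-bump PQRST morphology, 2% RR jitter,
  annotated beats. Benchmark noise: baseline wander and white noise,
  each at the level that alone gives 10 dB input SNR.
- **EEG**: 256 Hz, band-limited delta/theta/alpha/beta background at
  unit sd, annotated biphasic spikes. Benchmark noise: muscle bursts
  (1.5× background sd) plus ocular drift (1×).
- **Image**: 64×64 piecewise-constant phantom in $[0,1]$ plus Gaussian
  noise.

The benchmark (`run_benchmark()`) embeds signals with window 32 and
hop 2 — denser overlap-add averaging than the library default
(64 / 8), chosen for the 8-second fixtures within the compute budget.

### Limitation: the ECG gain ceiling

On the ECG fixture the `etwd` pipeline gains about 2.1 dB (median over
10 seeds), short of the 3 dB bar the EEG fixture clears (~4.3 dB).
This is a ceiling of the prescribed pipeline, not an implementation
gap: an *oracle* shrinkage in the learned ICA basis — per-component
thresholds picked using the clean signal — tops out near 2.3 dB on
this fixture, so the Laplacian-ML rule is already at the basis
ceiling; a spectral Wiener oracle reaches only ~3.4 dB. Larger windows
(128 taps on 16-second records) reach ~2.5 dB at ten times the cost.
The corresponding acceptance assertions are left failing with the
measured numbers reported.

### Limitation: etwd vs gauss on mean gains

On both fixtures the `etwd` score clears or approaches its median bar
(EEG ~4.3 dB against the 3 dB bar) but is statistically tied with the
`gauss` score on *mean* gain: paired differences are a few tenths of
a dB against a ~1 dB per-seed spread, with p-values nowhere near the
Bonferroni threshold. The ordering of the two means therefore flips
with the seed set — and even with ulp-level numerics changes, since
FastICA iterations diverge chaotically from perturbed score values.
The ordering assertions are left as written and fail on the test's
seed set.

### Downstream detection fixtures

R-peak detection (Pan–Tompkins) is far more robust than raw SNR
suggests: at the benchmark noise level (10 dB) it scores F1 = 1.0 on
every seed, before any denoising. The before/after detection test
therefore uses a harsher ECG fixture (−6 dB input SNR, same wander +
white construction), where the baseline detector is genuinely
degraded (median F1 ≈ 0.85) and denoising improves it (≈ 0.90). At
−10 dB denoising *hurts* detection (0.63 → 0.53) — the shrinkage
starts removing QRS energy along with noise — so the improvement is a
measured property of the operating point, not a construction
guarantee.

```{r example}
fx_clean <- gen_ecg(8, seed = 1)
sdn <- noise_sd_for_snr(fx_clean, 10)
noisy <- add_noise(fx_clean, noise_spec("baseline_wander", sdn, seed = 2))
noisy <- add_noise(noisy, noise_spec("gaussian", sdn, seed = 3))
den <- denoise_signal(noisy, method = "etwd", window = 32, hop = 2,
                      artifact_bands = list(c(0, 0.8)))
snr_db(fx_clean$value, noisy$value)   # input SNR
snr_db(fx_clean$value, den$value)     # output SNR
```
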