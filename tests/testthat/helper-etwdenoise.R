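# shared helpers for the test suite

# random valid ETWD parameter vectors over a well-conditioned box
random_params <- function(n, seed) {
  withr_seed(seed, lapply(seq_len(n), function(i) {
    etwd_params(alpha = runif(1, 0.5, 5), beta = runif(1, 0.5, 5),
                lambda = runif(1, -1, 1), nu = runif(1, 0.3, 4))
  }))
}

# integrate the pdf over the positive half-line. The substitution
# s = (x/alpha)^beta tames the x^(beta*nu - 1) origin singularity
# (exponent becomes nu - 1), which defeats the quadrature in x-space
# for small beta * nu; the integrand still evaluates detwd itself.
pdf_mass <- function(params) {
  a <- params$alpha; b <- params$beta
  g <- function(s) detwd(a * s^(1 / b), params) * (a / b) * s^(1 / b - 1)
  stats::integrate(g, 0, Inf, rel.tol = 1e-9, subdivisions = 600L)$value
}

# central finite-difference gradient of the log-likelihood
fd_loglik_grad <- function(params, x, h = 1e-6) {
  th <- as.double(params)
  vapply(seq_along(th), function(j) {
    tp <- th; tm <- th
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (etwd_loglik(etwd_params(tp[1], tp[2], tp[3], tp[4]), x) -
       etwd_loglik(etwd_params(tm[1], tm[2], tm[3], tm[4]), x)) / (2 * h)
  }, numeric(1))
}

# symmetric Laplace sources (unit scale), N x T
laplace_sources <- function(n_src, n_obs, seed) {
  withr_seed(seed, matrix(sample(c(-1, 1), n_src * n_obs, replace = TRUE) *
                            rexp(n_src * n_obs), nrow = n_src))
}

# worst matched absolute correlation between estimated and true sources
# under a greedy one-to-one assignment
matched_cor <- function(U, S) {
  C <- abs(stats::cor(t(U), t(S)))
  vals <- numeric(0)
  while (length(C) > 0 && nrow(C) > 0 && ncol(C) > 0) {
    i <- which(C == max(C), arr.ind = TRUE)[1, ]
    vals <- c(vals, C[i[1], i[2]])
    C <- C[-i[1], -i[2], drop = FALSE]
  }
  min(vals)
}

# the noisy ECG / EEG fixtures of the benchmark protocol
noisy_ecg_fixture <- function(seed, duration = 8, input_snr_db = 10) {
  clean <- gen_ecg(duration, seed = seed)
  sdn <- noise_sd_for_snr(clean, input_snr_db)
  noisy <- add_noise(clean, noise_spec("baseline_wander", sdn,
                                       seed = seed + 100L))
  noisy <- add_noise(noisy, noise_spec("gaussian", sdn, seed = seed + 200L))
  list(clean = clean, noisy = noisy, bands = list(c(0, 0.8)))
}

noisy_eeg_fixture <- function(seed, duration = 8) {
  clean <- gen_eeg(duration, seed = seed)
  noisy <- add_noise(clean, noise_spec("muscle_burst", 1.5,
                                       seed = seed + 100L))
  noisy <- add_noise(noisy, noise_spec("ocular_drift", 1.0,
                                       seed = seed + 200L))
  list(clean = clean, noisy = noisy, bands = list(c(0, 1), c(32, Inf)))
}
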