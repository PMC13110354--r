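#' Tidy signal helpers
#'
#' Signals travel through the package as tibbles with columns `time`
#' (seconds) and `value`; ground-truth event annotations (beat or spike
#' times) ride along in the `events` attribute. `signal_rate()` reads
#' the sampling rate off the time grid; `signal_events()` extracts the
#' annotation tibble.
#'
#' @param data A tidy signal tibble.
#' @return `signal_rate()`: Hz; `signal_events()`: an `event_set`
#'   tibble or `NULL`.
#' @export
signal_rate <- function(data) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  1 / median(diff(data$time))
}

#' @rdname signal_rate
#' @export
signal_events <- function(data) attr(data, "events")

.new_signal <- function(value, rate, events = NULL) {
  out <- tibble(time = (seq_along(value) - 1) / rate, value = value)
  if (!is.null(events)) attr(out, "events") <- .event_set(events)
  out
}

#' Synthetic ECG with annotated beats
#'
#' A clean lead-II-like ECG built per beat from five Gaussian bumps
#' (P, Q, R, S, T) with fixed widths and amplitudes normalized so the
#' R wave has unit amplitude; beat-to-beat intervals carry a mild
#' seeded jitter (2% of the RR interval). True R-peak times are
#' annotated in the `events` attribute. Baseline wander and motion
#' spikes are *not* added here; compose with [add_noise()].
#'
#' @param duration Length in seconds.
#' @param rate Sampling rate in Hz (360 by default).
#' @param hr_bpm Mean heart rate in beats per minute.
#' @param seed Integer seed; output is a pure function of the
#'   arguments.
#' @return Tidy signal tibble with an `events` annotation.
#' @examples
#' ecg <- gen_ecg(duration = 10, hr_bpm = 60, seed = 1)
#' nrow(signal_events(ecg))   # 9 beats fit in 10 s with edge margins
#' @export
gen_ecg <- function(duration, rate = 360, hr_bpm = 60, seed = 1) {
  if (rate <= 0 || hr_bpm <= 0) abort("`rate` and `hr_bpm` must be positive.")
  if (duration <= 2 * 60 / hr_bpm) abort("`duration` must cover > 2 beats.")
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  rr <- 60 / hr_bpm
  n_beats <- floor((duration - 0.4) / rr)
  jitter <- withr_seed(seed, rnorm(n_beats, sd = 0.02 * rr))
  beats <- 0.3 + (seq_len(n_beats) - 1) * rr + jitter
  beats <- beats[beats < duration - 0.35]
  # per-wave (offset s, amplitude, width s) relative to the R peak
  waves <- rbind(P = c(-0.20, 0.15, 0.025),
                 Q = c(-0.028, -0.12, 0.010),
                 R = c(0.00, 1.00, 0.011),
                 S = c(0.028, -0.25, 0.010),
                 T = c(0.26, 0.32, 0.055))
  x <- numeric(n)
  for (b in beats)
    for (k in seq_len(nrow(waves)))
      x <- x + waves[k, 2] *
        exp(-((tt - b - waves[k, 1])^2) / (2 * waves[k, 3]^2))
  .new_signal(x, rate, events = beats)
}

#' Synthetic EEG with annotated epileptiform spikes
#'
#' Background activity is a seeded sum of band-limited noise in the
#' classical delta/theta/alpha/beta bands with 1/f-flavored weights,
#' normalized to unit standard deviation. `n_spikes` biphasic sharp
#' transients (~20-70 ms) with amplitude about five times the
#' background are injected at annotated times. Muscle bursts and
#' ocular drift are added separately via [add_noise()].
#'
#' @param duration Seconds (>= 1).
#' @param rate Sampling rate in Hz (256 by default).
#' @param n_spikes Number of injected spikes (default 20).
#' @param seed Integer seed.
#' @return Tidy signal tibble with spike annotations.
#' @export
gen_eeg <- function(duration, rate = 256, n_spikes = 20, seed = 1) {
  if (duration < 1) abort("`duration` must be at least 1 s.")
  n <- round(duration * rate)
  if (n_spikes > floor(duration / 0.25))
    abort("Too many spikes for this duration (need >= 0.25 s spacing).")
  withr_seed(seed, {
    bands <- list(delta = c(1, 4), theta = c(4, 8),
                  alpha = c(8, 13), beta = c(13, 30))
    wts <- c(1.0, 0.7, 0.8, 0.35)
    x <- numeric(n)
    for (k in seq_along(bands))
      x <- x + wts[k] * .bandlimited_noise(n, rate, bands[[k]][1],
                                           bands[[k]][2])
    x <- x / sqrt(mean(x^2))
    spikes <- numeric(0)
    if (n_spikes > 0) {
      slots <- seq(0.5, duration - 0.5, length.out = n_spikes)
      spikes <- slots + runif(n_spikes, -0.1, 0.1)
      tt <- (seq_len(n) - 1) / rate
      for (s in spikes) {
        w <- runif(1, 0.020, 0.070) / 2       # half-width of each lobe
        amp <- 5 * (1 + 0.2 * rnorm(1))
        x <- x + amp * exp(-((tt - s)^2) / (2 * (w / 2.355)^2)) -
          0.6 * amp * exp(-((tt - s - 1.2 * w)^2) / (2 * (w / 1.8)^2))
      }
    }
    .new_signal(x, rate, events = if (n_spikes > 0) spikes else NULL)
  })
}

# white noise band-passed with a hard FFT mask
.bandlimited_noise <- function(n, rate, lo, hi) {
  e <- rnorm(n)
  f <- seq(0, rate - rate / n, by = rate / n)
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  mask <- f >= lo & f <= hi
  out <- Re(fft(fft(e) * mask, inverse = TRUE)) / n
  out / max(sd(out), 1e-12)
}

#' Synthetic grayscale phantom image
#'
#' Overlapping ellipses and a rectangle over a smooth diagonal
#' intensity gradient, clipped to `[0, 1]` — a structural stand-in for
#' anatomical images with edges, homogeneous regions and gentle
#' shading. Purely synthetic; geometry is drawn from the seed.
#'
#' @param size Side length in pixels (>= 32).
#' @param seed Integer seed.
#' @return `size x size` numeric matrix in `[0, 1]`.
#' @export
gen_phantom <- function(size = 64, seed = 1) {
  if (size < 32) abort("`size` must be at least 32.")
  withr_seed(seed, {
    gx <- matrix(rep(seq(0, 1, length.out = size), size), size)
    img <- 0.15 + 0.25 * (gx + t(gx)) / 2
    u <- (row(img) - 1) / (size - 1); v <- (col(img) - 1) / (size - 1)
    for (k in 1:4) {
      cx <- runif(1, 0.25, 0.75); cy <- runif(1, 0.25, 0.75)
      ax <- runif(1, 0.08, 0.3); ay <- runif(1, 0.08, 0.3)
      th <- runif(1, 0, pi); lev <- runif(1, -0.35, 0.45)
      ur <- (u - cx) * cos(th) + (v - cy) * sin(th)
      vr <- -(u - cx) * sin(th) + (v - cy) * cos(th)
      img <- img + lev * ((ur / ax)^2 + (vr / ay)^2 < 1)
    }
    r0 <- sort(runif(2, 0.1, 0.9)); c0 <- sort(runif(2, 0.1, 0.9))
    img <- img + 0.2 * (u >= r0[1] & u <= r0[2] & v >= c0[1] & v <= c0[2])
    pmin(pmax(img, 0), 1)
  })
}

#' Noise / artifact specification
#'
#' Describes one noise or artifact process to be applied by
#' [add_noise()]. Image kinds: `gaussian` (additive, sd = `level`; use
#' 25/255 for the 8-bit sigma-25 convention on normalized images),
#' `speckle` (multiplicative, `x * (1 + N(0, level^2))`), `rician`
#' (`sqrt((x + N1)^2 + N2^2)` with sd = `level`), `poisson` (quantum
#' noise; `level` scales the photon count as `counts = x * level`).
#' Signal artifact kinds: `muscle_burst` (windowed >20 Hz bursts, sd =
#' `level` inside bursts), `ocular_drift` (<5 Hz drift, sd = `level`),
#' `baseline_wander` (0.5-2 Hz sinusoid mixture, sd = `level`),
#' `motion_spike` (sparse exponential-decay transients of amplitude
#' `level`).
#'
#' @param kind One of the kinds above.
#' @param level Nonnegative magnitude in native units.
#' @param seed Integer seed; [add_noise()] is deterministic given the
#'   spec.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind, level, seed = 1) {
  kinds <- c("gaussian", "speckle", "rician", "poisson", "muscle_burst",
             "ocular_drift", "baseline_wander", "motion_spike")
  if (!kind %in% kinds)
    abort(sprintf("Unknown noise kind '%s'.", kind))
  if (level < 0) abort("`level` must be nonnegative.")
  structure(list(kind = kind, level = level, seed = seed),
            class = "noise_spec")
}

#' Apply a noise or artifact process
#'
#' Adds the process described by a [noise_spec()] to a tidy signal, a
#' numeric vector or an image matrix. `level = 0` returns the input
#' unchanged. Signal artifact kinds need a sampling rate (taken from
#' the tidy signal's time column, or `rate`).
#'
#' @param x Tidy signal tibble, numeric vector, or matrix (image).
#' @param spec A [noise_spec()].
#' @param rate Sampling rate for bare-vector signals.
#' @return Same shape as `x`, with the noise applied.
#' @examples
#' ecg <- gen_ecg(10, seed = 1)
#' noisy <- add_noise(ecg, noise_spec("baseline_wander", 0.3, seed = 2))
#' @export
add_noise <- function(x, spec, rate = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$level == 0) return(x)
  is_df <- is.data.frame(x)
  if (is_df) { v <- x$value; rate <- signal_rate(x) } else v <- x
  out <- withr_seed(spec$seed, .apply_noise(v, spec, rate))
  if (is_df) { x$value <- out; x } else out
}

.apply_noise <- function(v, spec, rate) {
  lv <- spec$level
  n <- length(v)
  switch(spec$kind,
    gaussian = v + rnorm(n, sd = lv),
    speckle = v * (1 + rnorm(n, sd = lv)),
    rician = {
      out <- sqrt((v + rnorm(n, sd = lv))^2 + rnorm(n, sd = lv)^2)
      if (is.matrix(v)) matrix(out, nrow(v)) else out
    },
    poisson = {
      counts <- pmax(v, 0) * lv
      out <- rpois(n, counts) / lv
      if (is.matrix(v)) matrix(out, nrow(v)) else out
    },
    muscle_burst = {
      if (is.null(rate)) abort("Artifact kinds need a sampling rate.")
      dur <- n / rate
      nb <- max(1L, round(dur / 4))
      noise <- lv * .highpass_noise(n, rate, 20)
      env <- numeric(n)
      starts <- runif(nb, 0, dur - 0.8)
      for (s in starts) {
        blen <- round(runif(1, 0.3, 0.8) * rate)
        i0 <- round(s * rate) + 1L
        idx <- i0:min(n, i0 + blen - 1L)
        env[idx] <- pmax(env[idx],
                         0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx))))
      }
      v + noise * env
    },
    ocular_drift = {
      if (is.null(rate)) abort("Artifact kinds need a sampling rate.")
      d <- .bandlimited_noise(n, rate, max(0.1, rate / n), 2)
      v + lv * d / max(sd(d), 1e-12)
    },
    baseline_wander = {
      if (is.null(rate)) abort("Artifact kinds need a sampling rate.")
      tt <- (seq_len(n) - 1) / rate
      fr <- runif(3, 0.5, 2); ph <- runif(3, 0, 2 * pi)
      w <- rowSums(sapply(seq_len(3), function(k) sin(2 * pi * fr[k] * tt + ph[k])))
      v + lv * w / sd(w)
    },
    motion_spike = {
      if (is.null(rate)) abort("Artifact kinds need a sampling rate.")
      dur <- n / rate
      ns <- max(1L, round(dur / 5))
      tt <- (seq_len(n) - 1) / rate
      out <- v
      pos <- runif(ns, 0.05 * dur, 0.95 * dur)
      for (s in pos) {
        sgn <- sign(runif(1) - 0.5); if (sgn == 0) sgn <- 1
        out <- out + sgn * lv * exp(-pmax(tt - s, 0) / 0.05) * (tt >= s)
      }
      out
    })
}

.highpass_noise <- function(n, rate, lo) {
  e <- rnorm(n)
  f <- seq(0, rate - rate / n, by = rate / n)
  f <- pmin(f, rate - f)
  mask <- f >= lo
  out <- Re(fft(fft(e) * mask, inverse = TRUE)) / n
  out / max(sd(out), 1e-12)
}

#' Mix independent sources through a known matrix
#'
#' `X = A S` for ground-truth separation experiments; the mixing
#' matrix is stored in the `mixing` attribute so separation quality
#' can be scored against the truth.
#'
#' @param S `N x T` source matrix (rows = sources).
#' @param A `N x N` full-rank mixing matrix.
#' @return `N x T` matrix of observed mixtures with attribute `mixing`.
#' @export
mix_sources <- function(S, A) {
  stopifnot(is.matrix(S), is.matrix(A), nrow(A) == ncol(A),
            nrow(A) == nrow(S))
  if (abs(det(A)) < 1e-12) abort("Mixing matrix is singular.")
  X <- A %*% S
  attr(X, "mixing") <- A
  X
}

#' Reproducible development/test split
#'
#' Partitions `n` items into a development set (default 70%) and a
#' held-out test set, reproducibly from the seed.
#'
#' @param n Number of items.
#' @param dev_frac Development fraction.
#' @param seed Integer seed.
#' @return List with integer index vectors `dev` and `test`.
#' @export
split_dev_test <- function(n, dev_frac = 0.7, seed = 1) {
  stopifnot(n >= 2, dev_frac > 0, dev_frac < 1)
  idx <- withr_seed(seed, sample.int(n))
  ndev <- max(1L, round(dev_frac * n))
  list(dev = sort(idx[seq_len(ndev)]), test = sort(idx[-seq_len(ndev)]))
}

#' Scale additive noise to a target input SNR
#'
#' Returns the noise standard deviation that makes white Gaussian
#' noise added to `x` sit at `snr_db` decibels below the signal
#' energy.
#'
#' @param x Clean signal (vector or tidy signal).
#' @param snr_db Target input SNR in dB.
#' @return Scalar standard deviation.
#' @export
noise_sd_for_snr <- function(x, snr_db) {
  v <- .as_num(x)
  sqrt(mean(v^2) / 10^(snr_db / 10))
}
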