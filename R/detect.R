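#' R-peak detection (Pan-Tompkins)
#'
#' The classic QRS detection cascade: band-pass 5-15 Hz (zero-phase
#' Butterworth realization), differentiation, squaring, 150 ms
#' moving-window integration, then adaptive dual thresholds on the
#' integrated envelope with a 200 ms refractory period. Peak positions
#' are refined to the local maximum of the band-passed signal.
#'
#' @param data Tidy signal (data frame with `time`, `value`) or a
#'   numeric vector with `rate` supplied.
#' @param rate Sampling rate in Hz (>= 100); inferred from `time` when
#'   a data frame is given.
#' @return A tibble of class `event_set` with column `time` (seconds,
#'   strictly increasing).
#' @examples
#' ecg <- gen_ecg(duration = 10, hr_bpm = 60, seed = 1)
#' nrow(detect_rpeaks(ecg))   # 9 beats fit in 10 s with edge margins
#' @export
detect_rpeaks <- function(data, rate = NULL) {
  xs <- .tidy_signal(data, rate)
  x <- xs$value; fs <- xs$rate
  if (fs < 100) abort("Pan-Tompkins needs a sampling rate >= 100 Hz.")
  if (length(x) < fs) abort("Signal too short (< 1 s).")
  bp <- .bandpass(x, fs, lo = 5, hi = 15)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  wlen <- max(1L, as.integer(round(0.150 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 1))
  mwi[is.na(mwi)] <- 0
  refractory <- as.integer(round(0.200 * fs))
  # candidate peaks of the integrated envelope
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(cand) == 0) return(.event_set(numeric(0)))
  # adaptive dual thresholds (signal / noise running estimates)
  spki <- max(mwi[seq_len(min(2 * fs, length(mwi)))]) / 3
  npki <- mean(mwi[seq_len(min(2 * fs, length(mwi)))]) / 2
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] >= thr && i - last > refractory) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) return(.event_set(numeric(0)))
  # refine to the band-passed local maximum (undo the MWI group delay)
  half <- as.integer(round(0.100 * fs))
  ref <- vapply(peaks, function(i) {
    lo <- max(1L, i - wlen); hi <- min(length(bp), i + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # drop refinements collapsing onto the same beat
  keep <- c(TRUE, diff(ref) > refractory)
  .event_set((ref[keep] - 1) / fs)
}

.bandpass <- function(x, fs, lo, hi) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

.event_set <- function(times) {
  out <- tibble(time = as.numeric(times))
  class(out) <- c("event_set", class(out))
  out
}

#' Wavelet-domain spike detection
#'
#' Flags transient spikes by thresholding the magnitudes of the two
#' finest wavelet detail bands at `k` times the robust noise estimate
#' of each band, then clusters crossings closer than `cluster_ms`
#' milliseconds into single events. Doubling `k` can only remove
#' events.
#'
#' @param data Tidy signal or numeric vector.
#' @param rate Sampling rate in Hz (>= 128).
#' @param k Threshold multiple of the per-band MAD sigma (default 4).
#' @param cluster_ms Clustering window in milliseconds.
#' @return A tibble of class `event_set` with column `time` (seconds).
#' @export
detect_spikes <- function(data, rate = NULL, k = 4, cluster_ms = 50) {
  xs <- .tidy_signal(data, rate)
  x <- xs$value; fs <- xs$rate
  if (fs < 128) abort("Spike detection needs a sampling rate >= 128 Hz.")
  if (length(x) < fs) abort("Signal too short (< 1 s).")
  w <- wt_dwt(x, levels = 2)
  hits <- numeric(0)
  for (j in 1:2) {
    d <- w$details[[j]]
    sig <- median(abs(d)) / 0.6745
    if (sig == 0) sig <- .Machine$double.eps
    idx <- which(abs(d) > k * sig)
    # coefficient i of level j sits near sample (i - 1/2) * 2^j
    hits <- c(hits, ((idx - 0.5) * 2^j - 1) / fs)
  }
  if (length(hits) == 0) return(.event_set(numeric(0)))
  hits <- sort(hits)
  gap <- cluster_ms / 1000
  grp <- cumsum(c(1, diff(hits) > gap))
  .event_set(as.numeric(tapply(hits, grp, mean)))
}

#' Event-level precision, recall and F1
#'
#' Greedy one-to-one matching of detected event times to true event
#' times within a tolerance window, in order of increasing time
#' difference; each truth event can absorb at most one detection.
#' Degenerate conventions: both sets empty gives precision = recall =
#' F1 = 1 (nothing to find, nothing claimed); an empty detection set
#' against a nonempty truth gives precision = NA (flagged), recall =
#' F1 = 0; F1 = 0 whenever precision + recall = 0.
#'
#' @param detected,truth `event_set` tibbles (or vectors of times in
#'   seconds).
#' @param tol Matching tolerance in seconds (> 0).
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_matched`,
#'   `n_detected`, `n_true`.
#' @examples
#' event_f1(c(1, 2, 5), c(1.01, 2.04, 3, 4), tol = 0.05)
#' @export
event_f1 <- function(detected, truth, tol = 0.05) {
  if (tol <= 0) abort("`tol` must be positive.")
  dt <- if (is.data.frame(detected)) detected$time else as.numeric(detected)
  tr <- if (is.data.frame(truth)) truth$time else as.numeric(truth)
  nd <- length(dt); nt <- length(tr)
  if (nd == 0 && nt == 0)
    return(tibble(precision = 1, recall = 1, f1 = 1,
                  n_matched = 0L, n_detected = 0L, n_true = 0L))
  matched <- 0L
  if (nd > 0 && nt > 0) {
    pairs <- expand.grid(d = seq_len(nd), t = seq_len(nt))
    pairs$gap <- abs(dt[pairs$d] - tr[pairs$t])
    pairs <- pairs[pairs$gap <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$gap), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (i in seq_len(nrow(pairs))) {
      di <- pairs$d[i]; ti <- pairs$t[i]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE; used_t[ti] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  precision <- if (nd == 0) NA_real_ else matched / nd
  recall <- if (nt == 0) NA_real_ else matched / nt
  pr <- if (is.na(precision)) 0 else precision
  rc <- if (is.na(recall)) 0 else recall
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  tibble(precision = precision, recall = recall, f1 = f1,
         n_matched = matched, n_detected = nd, n_true = nt)
}

# normalize the two accepted signal forms to list(value, rate)
.tidy_signal <- function(data, rate = NULL) {
  if (is.data.frame(data)) {
    if (is.null(rate)) rate <- signal_rate(data)
    list(value = data$value, rate = rate)
  } else {
    if (is.null(rate)) abort("Supply `rate` when passing a bare vector.")
    list(value = as.numeric(data), rate = rate)
  }
}
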