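#' Lp sparsity penalty
#'
#' `P(s) = lam_s * sum(|s_i|^p)` with `0 < p <= 1`, the penalty that
#' prices retained wavelet detail coefficients. `lam_s` controls the
#' sparsity intensity and `p` the strength of the concavity (p = 1 is
#' the lasso/soft-threshold case).
#'
#' @param s Numeric vector of coefficients.
#' @param lam_s Nonnegative penalty weight.
#' @param p Exponent in (0, 1].
#' @return Scalar penalty value.
#' @examples
#' sparsity_penalty(c(1, -2), lam_s = 0.5, p = 1)   # 1.5
#' @export
sparsity_penalty <- function(s, lam_s, p) {
  if (p <= 0 || p > 1) abort("`p` must lie in (0, 1].")
  if (lam_s < 0) abort("`lam_s` must be nonnegative.")
  lam_s * sum(abs(s)^p)
}

#' Laplacian-prior maximum-likelihood shrinkage
#'
#' The componentwise shrinkage used in sparse code shrinkage when the
#' source density is Laplacian with scale `b` and the additive noise is
#' Gaussian with standard deviation `sigma_n`:
#' \deqn{g(u) = \mathrm{sign}(u)\,\max(0, |u| - \sqrt{2}\sigma_n^2/b).}
#' It is zero near the origin (noise-dominated values are removed) and
#' shifts large values by a constant, so `|g(u)| <= |u|` always and
#' `sigma_n = 0` gives the identity.
#'
#' @param u Numeric vector (rotated/sparse-domain values).
#' @param b Laplace scale of the source component, positive.
#' @param sigma_n Gaussian noise standard deviation, nonnegative.
#' @return Shrunk values, same length as `u`.
#' @export
laplace_shrink <- function(u, b, sigma_n) {
  if (b <= 0) abort("Laplace scale `b` must be positive.")
  if (sigma_n < 0) abort("`sigma_n` must be nonnegative.")
  thr <- sqrt(2) * sigma_n^2 / b
  sign(u) * pmax(0, abs(u) - thr)
}

# scalar proximal operator of lam * sigma^2 * |s|^p
# p = 1: soft threshold. p < 1: hard-threshold region + Newton refinement.
.lp_prox <- function(s, lam, p, sigma_n) {
  w <- lam * sigma_n^2
  if (w == 0) return(s)
  if (p == 1) return(sign(s) * pmax(0, abs(s) - w))
  # threshold below which the proximal solution is exactly zero
  tau0 <- (2 * w * (1 - p))^(1 / (2 - p))
  tau <- tau0 + w * p * tau0^(p - 1)
  out <- numeric(length(s))
  big <- abs(s) > tau
  if (any(big)) {
    x <- abs(s[big])
    y <- x                                    # Newton on y + w p y^(p-1) = x
    for (k in seq_len(30)) {
      fy <- y + w * p * y^(p - 1) - x
      fpy <- 1 + w * p * (p - 1) * y^(p - 2)
      step <- fy / fpy
      y <- pmax(y - step, tau0)               # keep on the stable branch
    }
    bad <- !is.finite(y) | y <= 0
    y[bad] <- x[bad]                          # hard-threshold fallback
    out[big] <- sign(s[big]) * y
  }
  out
}

#' Lp-penalized thresholding of wavelet detail coefficients
#'
#' Applies the proximal operator of the penalty
#' `lam_s * sigma_n^2 * |s|^p` to every detail coefficient, leaving the
#' approximation band untouched. For `p = 1` this is plain soft
#' thresholding with threshold `lam_s * sigma_n^2`; for `p < 1` small
#' coefficients are zeroed outright (hard-threshold region) and larger
#' ones shrunk by a Newton solve of the stationarity condition. Larger
#' `lam_s` never increases any output magnitude.
#'
#' @param coeffs A `wavelet_coeffs` object.
#' @param lam_s Penalty weight (>= 0).
#' @param p Exponent in (0, 1].
#' @param sigma_n Noise standard deviation (defaults to
#'   [estimate_sigma()] of `coeffs`).
#' @return A `wavelet_coeffs` object with thresholded details.
#' @export
lp_threshold <- function(coeffs, lam_s, p = 1, sigma_n = NULL) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  if (p <= 0 || p > 1) abort("`p` must lie in (0, 1].")
  if (lam_s < 0) abort("`lam_s` must be nonnegative.")
  if (is.null(sigma_n)) sigma_n <- estimate_sigma(coeffs)
  map_details(coeffs, function(d) .lp_prox(d, lam_s, p, sigma_n))
}

#' Total sparse-fitting loss
#'
#' The objective minimized when tuning the sparsity hyperparameters:
#' `L_total = L_MLE + P(s)`, where `L_MLE` is the ETWD *negative*
#' log-likelihood of the magnitudes of the detail coefficients retained
#' after [lp_threshold()] (magnitudes are nonnegative, matching the
#' ETWD support), and `P(s)` is [sparsity_penalty()] evaluated on the
#' thresholded coefficients. With `lam_s = 0` no coefficient moves and
#' the loss is exactly the likelihood term.
#'
#' @param coeffs A `wavelet_coeffs` object (pre-threshold).
#' @param params [etwd_params()] describing the coefficient magnitudes.
#' @param lam_s,p Sparsity hyperparameters.
#' @param sigma_n Noise sd used by the threshold (defaults to the MAD
#'   estimate).
#' @return Scalar loss.
#' @export
total_loss <- function(coeffs, params, lam_s, p = 1, sigma_n = NULL) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  if (is.null(sigma_n)) sigma_n <- estimate_sigma(coeffs)
  thr <- lp_threshold(coeffs, lam_s, p, sigma_n)
  s <- coeffs_details(thr)
  kept <- abs(s) > 0
  pen <- sparsity_penalty(s[kept], lam_s, p)
  if (!any(kept)) {
    warn("No coefficients survive the threshold; returning penalty only.")
    return(pen)
  }
  nll <- -suppressWarnings(etwd_loglik(params, abs(s[kept])))
  nll + pen
}
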