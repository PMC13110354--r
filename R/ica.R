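#' Sliding-window embedding of a 1-D signal
#'
#' Turns a single-channel signal into the multichannel matrix FastICA
#' and sparse code shrinkage operate on: overlapping windows of length
#' `window` taken every `hop` samples become the columns of a
#' `window x n_windows` matrix. A final window ending exactly at the
#' last sample is appended when the hop grid does not reach it, so
#' every sample is covered and the overlap-add inverse
#' ([unembed_signal()], uniform averaging) reconstructs the input
#' exactly when the matrix is left untouched.
#'
#' @param x Numeric signal (or data frame with a `value` column).
#' @param window Window length (rows of the embedding).
#' @param hop Hop between window starts, >= 1.
#' @return A matrix with attributes `window`, `hop`, `n`, `starts`.
#' @examples
#' Z <- embed_signal(sin(1:100 / 5), window = 8, hop = 1)
#' ncol(Z)   # 93
#' @export
embed_signal <- function(x, window = 64, hop = 8) {
  if (is.data.frame(x)) x <- x$value
  n <- length(x)
  if (hop <= 0) abort("`hop` must be >= 1.")
  if (window > n) abort("`window` exceeds the signal length.")
  starts <- seq(1L, n - window + 1L, by = hop)
  if (starts[length(starts)] + window - 1L < n)
    starts <- c(starts, n - window + 1L)
  Z <- vapply(starts, function(s) x[s:(s + window - 1L)], numeric(window))
  attr(Z, "window") <- window; attr(Z, "hop") <- hop
  attr(Z, "n") <- n; attr(Z, "starts") <- starts
  Z
}

#' @rdname embed_signal
#' @param Z Embedded matrix from `embed_signal()` (possibly processed).
#' @export
unembed_signal <- function(Z) {
  starts <- attr(Z, "starts"); n <- attr(Z, "n")
  window <- attr(Z, "window")
  if (is.null(starts)) abort("`Z` is missing its embedding metadata.")
  acc <- numeric(n); cnt <- numeric(n)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + window - 1L)
    acc[idx] <- acc[idx] + Z[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

#' Patch embedding of a grayscale image
#'
#' Vectorizes `patch x patch` blocks taken every `stride` pixels into
#' the columns of a `patch^2 x n_patches` matrix; extra patches flush
#' with the right/bottom edges guarantee full coverage. The inverse
#' ([unembed_image()]) overlap-adds with uniform weights.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param patch Patch side length.
#' @param stride Step between patch origins, >= 1.
#' @return Matrix with attributes describing the patch geometry.
#' @examples
#' P <- embed_image(matrix(runif(64 * 64), 64), patch = 8, stride = 4)
#' ncol(P)   # 225
#' @export
embed_image <- function(img, patch = 8, stride = 4) {
  stopifnot(is.matrix(img))
  if (stride <= 0) abort("`stride` must be >= 1.")
  d <- dim(img)
  if (patch > min(d)) abort("`patch` exceeds the image size.")
  gr <- seq(1L, d[1] - patch + 1L, by = stride)
  gc <- seq(1L, d[2] - patch + 1L, by = stride)
  if (gr[length(gr)] + patch - 1L < d[1]) gr <- c(gr, d[1] - patch + 1L)
  if (gc[length(gc)] + patch - 1L < d[2]) gc <- c(gc, d[2] - patch + 1L)
  origins <- expand.grid(r = gr, c = gc)
  Z <- vapply(seq_len(nrow(origins)), function(k) {
    r <- origins$r[k]; c <- origins$c[k]
    as.numeric(img[r:(r + patch - 1L), c:(c + patch - 1L)])
  }, numeric(patch^2))
  attr(Z, "patch") <- patch; attr(Z, "dim_img") <- d
  attr(Z, "origins") <- origins
  Z
}

#' @rdname embed_image
#' @param Z Embedded patch matrix (possibly processed).
#' @export
unembed_image <- function(Z) {
  patch <- attr(Z, "patch"); d <- attr(Z, "dim_img")
  origins <- attr(Z, "origins")
  if (is.null(origins)) abort("`Z` is missing its patch metadata.")
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (k in seq_len(nrow(origins))) {
    r <- origins$r[k]:(origins$r[k] + patch - 1L)
    c <- origins$c[k]:(origins$c[k] + patch - 1L)
    acc[r, c] <- acc[r, c] + matrix(Z[, k], patch, patch)
    cnt[r, c] <- cnt[r, c] + 1
  }
  acc / cnt
}

#' Center and whiten a multichannel data matrix
#'
#' Subtracts the row means and applies the eigen-decomposition
#' whitening transform `V = D^{-1/2} E^T` so the output has identity
#' sample covariance, the precondition for FastICA. Eigenvalues below
#' `tol` times the largest are dropped (rank reduction) with a warning.
#'
#' @param X `K x T` matrix, `K >= 2` channels, `T > K` samples.
#' @param tol Relative eigenvalue cutoff for rank reduction.
#' @return List: `Z` (whitened, possibly fewer rows), `mean`, `V`
#'   (whitening matrix), `V_inv` (unwhitening, `K x rank`).
#' @export
center_whiten <- function(X, tol = 1e-10) {
  stopifnot(is.matrix(X), nrow(X) >= 2, ncol(X) > nrow(X))
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * e$values[1]
  if (!all(keep))
    warn(sprintf("Rank-deficient covariance: reducing from %d to %d channels.",
                 nrow(X), sum(keep)))
  vals <- e$values[keep]; vecs <- e$vectors[, keep, drop = FALSE]
  V <- diag(1 / sqrt(vals), nrow = length(vals)) %*% t(vecs)
  V_inv <- vecs %*% diag(sqrt(vals), nrow = length(vals))
  Z <- V %*% Xc
  a <- attributes(X)
  for (nm in setdiff(names(a), c("dim", "dimnames")))
    attr(Z, nm) <- a[[nm]]
  list(Z = Z, mean = mu, V = V, V_inv = V_inv)
}

#' Closest orthogonal matrix
#'
#' Symmetric orthogonalization `W (W^T W)^{-1/2}`: the orthogonal
#' matrix nearest to `W` in Frobenius norm (equivalently the orthogonal
#' polar factor of the SVD).
#'
#' @param W Square full-rank matrix.
#' @return Orthogonal matrix of the same size.
#' @export
orthogonalize <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  s <- svd(W)
  if (min(s$d) < 1e-12 * max(s$d)) abort("`W` is numerically singular.")
  s$u %*% t(s$v)
}

# score-function registry ----------------------------------------------------
# each entry: phi(u) and its derivative phi'(u).
# `smooth > 0` replaces the raw ETWD score by the score of the
# noise-smoothed component density, phi(u) = u/r * psi(r) with
# r = sqrt(u^2 + smooth^2): what is observed is source plus Gaussian
# noise, whose log-density derivative is smooth at the origin. The raw
# score of a Laplace-limit ETWD (beta ~ 1) is sign-like and has zero
# contrast curvature at Gaussianity, so the fixed-point iteration
# cannot rank near-Gaussian directions; the smoothed score restores
# the curvature at the scale of the noise.
.score_fun <- function(score, params = NULL, smooth = 0) {
  if (identical(score, "etwd") || identical(score, "sparse_etwd")) {
    if (is.null(params))
      abort("The 'etwd' score needs fitted `etwd_params`.")
    if (smooth > 0) {
      return(list(
        phi = function(u) {
          r <- sqrt(u^2 + smooth^2)
          v <- (u / r) * .etwd_psi(r, params)
          v[!is.finite(v)] <- 0
          v
        },
        dphi = function(u) {
          h <- 1e-5
          r1 <- sqrt((u + h)^2 + smooth^2); r2 <- sqrt((u - h)^2 + smooth^2)
          (((u + h) / r1) * .etwd_psi(r1, params) -
             ((u - h) / r2) * .etwd_psi(r2, params)) / (2 * h)
        }))
    }
    return(list(phi = function(u) etwd_score(u, params),
                dphi = function(u) etwd_score_deriv(u, params)))
  }
  switch(score,
    tanh = list(phi = function(u) tanh(u),
                dphi = function(u) 1 - tanh(u)^2),
    pow3 = list(phi = function(u) u^3,
                dphi = function(u) 3 * u^2),
    skew = list(phi = function(u) u^2,
                dphi = function(u) 2 * u),
    gauss = list(phi = function(u) u * exp(-u^2 / 2),
                 dphi = function(u) (1 - u^2) * exp(-u^2 / 2)),
    abort(sprintf("Unknown score function '%s'.", score)))
}

#' FastICA fixed-point separation
#'
#' Symmetric (parallel) FastICA on whitened data. Each iteration
#' applies the fixed-point update
#' \deqn{W_{k+1} = W_k + D\,(E[\varphi(u)u^T] -
#'   \mathrm{diag}(E[\varphi_l(u_l)u_l]))\,W_k,\qquad
#'   D = \mathrm{diag}\Big(\frac{1}{E[\varphi_l(u_l)u_l] -
#'   E[\varphi_l'(u_l)]}\Big),}
#' with expectations taken as sample means over columns, followed by
#' symmetric decorrelation `W <- (W W^T)^{-1/2} W`. Convergence is
#' declared when `1 - min |diag(W_{k+1} W_k^T)| < tol`. Initialization
#' is a random orthogonal matrix drawn from `seed`. Each recovered
#' source is sign-flipped so its skewness (or, when that is near zero,
#' its largest-magnitude sample) is positive.
#'
#' @param Z Whitened `N x T` matrix (see [center_whiten()]).
#' @param score Score name: `"tanh"`, `"pow3"`, `"skew"`, `"gauss"`, or
#'   `"etwd"` (which requires `params`).
#' @param params [etwd_params()] for the `"etwd"` score.
#' @param max_iter,tol Iteration cap and convergence tolerance.
#' @param seed Integer seed for the random orthogonal initialization.
#' @param fd_step Step of the symmetric difference quotient used for
#'   `E[phi'(u)]` (components are unit variance, so this is a relative
#'   step). The quotient converges to the analytic derivative for
#'   smooth scores and correctly accounts for the origin jump of
#'   cusped (Laplace-limit) scores.
#' @param score_smooth For the `"etwd"` score only: Gaussian-noise
#'   smoothing width of the source density. When positive, the engine
#'   uses the score of the *noisy* component density,
#'   `phi(u) = u/r * psi(r)` with `r = sqrt(u^2 + score_smooth^2)` --
#'   smooth at the origin, with contrast curvature at the noise scale.
#'   0 (default) uses the raw symmetrized score.
#' @param restarts Number of fresh random initializations tried when
#'   an attempt fails to converge (the fixed-point iteration can cycle
#'   from unlucky starting rotations); the first converged attempt is
#'   returned, otherwise the last attempt with a warning.
#' @return Object of class `ica_fit`: `W` (orthogonal separation matrix
#'   in whitened space), `U` (`N x T` estimated sources), `iterations`,
#'   `converged`, `score`.
#' @export
fastica <- function(Z, score = "tanh", params = NULL,
                    max_iter = 200, tol = 1e-6, seed = 1, fd_step = 1e-2,
                    score_smooth = 0, restarts = 3) {
  stopifnot(is.matrix(Z))
  sf <- .score_fun(score, params, smooth = score_smooth)
  # scores with beta < 1 diverge at the origin; winsorize at a high sample
  # quantile so the moment estimates in the update stay finite
  raw_phi <- sf$phi
  phi <- function(u) {
    v <- raw_phi(u)
    fin <- is.finite(v)
    if (all(fin) && score %in% c("tanh", "pow3", "skew", "gauss")) return(v)
    cap <- quantile(abs(v[fin]), 0.999, names = FALSE)
    if (!is.finite(cap) || cap == 0) cap <- 1
    v[!fin] <- sign(u[!fin]) * cap
    m <- matrix(pmin(pmax(v, -cap), cap), nrow(u))
    m
  }
  N <- nrow(Z); Tn <- ncol(Z)
  run_attempt <- function(init_seed) {
    W <- withr_seed(init_seed, orthogonalize(matrix(rnorm(N * N), N)))
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      PU <- phi(U)
      Ephi_uu <- tcrossprod(PU, U) / Tn        # E[phi(u) u^T]
      diag_pu <- diag(Ephi_uu)                 # E[phi_l(u_l) u_l]
      # E[phi'] via a symmetric difference quotient of phi: O(h^2)-exact
      # for smooth scores and, unlike the pointwise derivative, it also
      # captures the distributional mass that cusped scores (ETWD with
      # beta <= 1, Laplace limit) carry at the origin -- omitting it
      # flips the sign of the step matrix D and stabilizes spurious
      # fixed points.
      Edphi <- rowMeans((phi(U + fd_step) - phi(U - fd_step)) /
                          (2 * fd_step))
      denom <- diag_pu - Edphi
      denom[abs(denom) < 1e-12] <- denom[abs(denom) < 1e-12] + 1e-8
      D <- diag(1 / denom, nrow = N)
      W_new <- W + D %*% (Ephi_uu - diag(diag_pu, nrow = N)) %*% W
      W_new <- orthogonalize(W_new)
      delta <- 1 - min(abs(diag(W_new %*% t(W))))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
    list(W = W, converged = converged, it = it, delta = delta)
  }
  att <- run_attempt(seed)
  # restart only genuinely stuck attempts: an oscillating iteration ends
  # far from any fixed point (delta near 1), while a slowly creeping one
  # (small final delta) is already next to a solution and is kept as is
  tries <- 0L
  while (!att$converged && att$delta > 0.5 && tries < restarts) {
    tries <- tries + 1L
    cand <- run_attempt(seed + 7919L * tries)  # fresh random rotation
    if (cand$converged || cand$delta < att$delta) att <- cand
  }
  W <- att$W; converged <- att$converged; it <- att$it
  if (!converged)
    warn(sprintf("FastICA did not converge in %d iterations (%d restarts).",
                 max_iter, restarts))
  U <- W %*% Z
  # deterministic sign convention
  for (l in seq_len(N)) {
    u <- U[l, ]
    sk <- mean((u - mean(u))^3)
    flip <- if (abs(sk) > 1e-8) sk < 0 else u[which.max(abs(u))] < 0
    if (flip) { U[l, ] <- -u; W[l, ] <- -W[l, ] }
  }
  structure(list(W = W, U = U, iterations = it, converged = converged,
                 delta = att$delta, score = score, params = params),
            class = "ica_fit")
}

#' @export
print.ica_fit <- function(x, ...) {
  cat(sprintf("<ica_fit> %d components, score = %s, %d iterations%s\n",
              nrow(x$W), x$score, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
glance.ica_fit <- function(x, ...) {
  tibble(components = nrow(x$W), score = x$score,
         iterations = x$iterations, converged = x$converged,
         orthogonality_error = max(abs(tcrossprod(x$W) - diag(nrow(x$W)))))
}

#' Sparse code shrinkage
#'
#' Denoises a (whitened) data matrix by rotating into the ICA basis,
#' applying a componentwise shrinkage, and rotating back:
#' `x_hat = W^T g(W z)`. `shrink` receives the row index and the row of
#' `W z` and returns the shrunk row, so each component can use its own
#' shrinkage parameters.
#'
#' @param Z Data matrix (`N x T`), typically whitened.
#' @param W Orthogonal rotation (within 1e-6); see [orthogonalize()].
#' @param shrink Function `(l, u) -> shrunk u`; defaults to identity.
#' @return Denoised matrix of the same shape (embedding attributes of
#'   `Z` are preserved).
#' @export
sparse_code_shrinkage <- function(Z, W, shrink = function(l, u) u) {
  stopifnot(is.matrix(Z), is.matrix(W))
  if (max(abs(tcrossprod(W) - diag(nrow(W)))) > 1e-6)
    abort("`W` is not orthogonal; apply `orthogonalize()` first.")
  S <- W %*% Z
  for (l in seq_len(nrow(S))) S[l, ] <- shrink(l, S[l, ])
  out <- t(W) %*% S
  a <- attributes(Z)
  for (nm in setdiff(names(a), c("dim", "dimnames")))
    attr(out, nm) <- a[[nm]]
  out
}
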