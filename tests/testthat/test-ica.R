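test_that("signal embedding inverts exactly", {
  x <- withr_seed(1, rnorm(500))
  for (hop in c(2, 8, 16)) {
    Z <- embed_signal(x, window = 32, hop = hop)
    expect_identical(nrow(Z), 32L)
    expect_equal(unembed_signal(Z), x, tolerance = 1e-12)
  }
})

test_that("image embedding inverts exactly", {
  img <- withr_seed(2, matrix(rnorm(48 * 40), 48, 40))
  Z <- embed_image(img, patch = 8, stride = 4)
  expect_identical(nrow(Z), 64L)
  expect_equal(unembed_image(Z), img, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("center_whiten yields identity covariance", {
  X <- withr_seed(3, matrix(rnorm(6 * 4000), 6))
  X[2, ] <- 3 * X[2, ] + X[1, ]
  cw <- center_whiten(X)
  C <- tcrossprod(cw$Z) / ncol(cw$Z)
  expect_equal(C, diag(nrow(cw$Z)), tolerance = 1e-10)
  expect_equal(rowMeans(cw$Z), rep(0, nrow(cw$Z)), tolerance = 1e-12)
  # V and V_inv invert each other on the retained subspace
  expect_equal(cw$V %*% cw$V_inv, diag(nrow(cw$Z)), tolerance = 1e-10)
})

test_that("rank-deficient data triggers dimension reduction", {
  X <- withr_seed(4, matrix(rnorm(3 * 500), 3))
  X <- rbind(X, X[1, ] + X[2, ])
  expect_warning(cw <- center_whiten(X), "Rank-deficient")
  expect_identical(nrow(cw$Z), 3L)
})

test_that("orthogonalize returns the closest orthogonal matrix", {
  M <- withr_seed(5, matrix(rnorm(16), 4))
  W <- orthogonalize(M)
  expect_equal(W %*% t(W), diag(4), tolerance = 1e-12)
  # polar factor: W = U V^T of the SVD
  s <- svd(M)
  expect_equal(W, s$u %*% t(s$v), tolerance = 1e-12)
})

test_that("fastica separates Laplace mixtures with classical scores", {
  S <- laplace_sources(3, 3000, seed = 6)
  A <- withr_seed(7, matrix(rnorm(9), 3))
  X <- mix_sources(S, A)
  cw <- center_whiten(X)
  for (sc in c("tanh", "gauss")) {
    ica <- fastica(cw$Z, score = sc, seed = 1)
    expect_s3_class(ica, "ica_fit")
    expect_true(ica$converged)
    expect_gt(matched_cor(ica$U, S), 0.95)
    # W stays orthogonal
    expect_equal(ica$W %*% t(ica$W), diag(3), tolerance = 1e-8)
  }
})

test_that("fastica with the ETWD score separates Laplace mixtures", {
  S <- laplace_sources(2, 3000, seed = 8)
  A <- matrix(c(1, 0.6, -0.4, 1), 2)
  cw <- center_whiten(mix_sources(S, A))
  ica <- fastica(cw$Z, score = "etwd",
                 params = etwd_params(1, 1, 0, 1), seed = 2)
  expect_gt(matched_cor(ica$U, S), 0.95)
})

test_that("fastica is deterministic in the seed", {
  S <- laplace_sources(2, 1000, seed = 9)
  cw <- center_whiten(mix_sources(S, matrix(c(1, 0.3, 0.5, 1), 2)))
  a <- fastica(cw$Z, "tanh", seed = 3)
  b <- fastica(cw$Z, "tanh", seed = 3)
  expect_identical(a$W, b$W)
})

test_that("glance summarizes an ica_fit", {
  S <- laplace_sources(2, 1000, seed = 10)
  cw <- center_whiten(mix_sources(S, matrix(c(1, 0.3, 0.5, 1), 2)))
  gl <- glance(fastica(cw$Z, "tanh", seed = 1))
  expect_true(all(c("iterations", "converged", "score") %in% names(gl)))
  expect_identical(nrow(gl), 1L)
})

test_that("sparse_code_shrinkage with identity g returns its input", {
  Z <- withr_seed(11, matrix(rnorm(4 * 200), 4))
  W <- orthogonalize(withr_seed(12, matrix(rnorm(16), 4)))
  expect_equal(sparse_code_shrinkage(Z, W), Z, tolerance = 1e-10)
})

test_that("sparse_code_shrinkage rejects non-orthonormal rows", {
  Z <- matrix(rnorm(4 * 50), 4)
  expect_error(sparse_code_shrinkage(Z, matrix(rnorm(16), 4) * 2),
               "orthogonal")
})

test_that("sparse_code_shrinkage applies g componentwise in the basis", {
  Z <- withr_seed(13, matrix(rnorm(3 * 400), 3))
  W <- orthogonalize(withr_seed(14, matrix(rnorm(9), 3)))
  out <- sparse_code_shrinkage(Z, W, function(l, u) u * 0)
  expect_equal(out, Z * 0, tolerance = 1e-12)
  half <- sparse_code_shrinkage(Z, W, function(l, u) u / 2)
  expect_equal(half, Z / 2, tolerance = 1e-10)
})
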