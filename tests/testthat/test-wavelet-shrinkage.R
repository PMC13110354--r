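test_that("1-D DWT reconstructs perfectly and preserves energy", {
  x <- withr_seed(1, rnorm(128))
  for (fam in c("d4", "haar")) {
    w <- wt_dwt(x, family = fam, levels = 4)
    expect_equal(wt_idwt(w), x, tolerance = 1e-12)
    energy <- sum(w$approximation^2) + sum(unlist(w$details)^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-10)
  }
})

test_that("DWT handles lengths that are not powers of two", {
  x <- withr_seed(2, rnorm(301))
  w <- wt_dwt(x, levels = 3)
  expect_equal(wt_idwt(w), x, tolerance = 1e-12)
  expect_error(wt_dwt(rnorm(8), levels = 5), "Too many levels")
})

test_that("2-D DWT reconstructs images perfectly", {
  img <- withr_seed(3, matrix(rnorm(64 * 48), 64, 48))
  w <- wt_dwt(img, levels = 3)
  expect_true(w$two_d)
  back <- wt_idwt(w)
  expect_equal(back, img, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("estimate_sigma recovers the noise sd from the finest band", {
  x <- sin(seq(0, 6 * pi, length.out = 4096)) +
    withr_seed(4, rnorm(4096, sd = 0.25))
  expect_equal(estimate_sigma(x), 0.25, tolerance = 0.03)
})

test_that("laplace_shrink satisfies the shrinkage identities", {
  b <- 0.7; s <- 0.3
  u <- seq(-4, 4, by = 0.05)
  g <- laplace_shrink(u, b, s)
  expect_identical(laplace_shrink(0, b, s), 0)        # g(0) = 0
  expect_true(all(abs(g) <= abs(u) + 1e-15))          # non-expansive
  expect_true(all(abs(diff(g)) <= diff(u)[1] + 1e-12))
  expect_equal(laplace_shrink(u, b, 0), u)            # sigma = 0 identity
  expect_equal(g, -laplace_shrink(-u, b, s))          # odd
  # threshold value: zero below sqrt(2) sigma^2 / b
  thr <- sqrt(2) * s^2 / b
  expect_identical(laplace_shrink(thr * 0.99, b, s), 0)
  expect_gt(laplace_shrink(thr * 1.5, b, s), 0)
})

test_that("sparsity_penalty matches its definition", {
  s <- c(-2, 0, 1, 3)
  expect_equal(sparsity_penalty(s, 0.5, 1), 0.5 * sum(abs(s)))
  expect_equal(sparsity_penalty(s, 2, 0.5), 2 * sum(abs(s)^0.5))
  expect_identical(sparsity_penalty(numeric(0), 1, 1), 0)
})

test_that("lp_threshold with p = 1 is soft thresholding of the details", {
  x <- withr_seed(5, rnorm(128))
  w <- wt_dwt(x, levels = 3)
  lam <- 0.8
  sig <- estimate_sigma(x)
  out <- lp_threshold(w, lam_s = lam, p = 1)
  tau <- lam * sig^2
  for (j in seq_along(w$details)) {
    d <- w$details[[j]]
    expect_equal(out$details[[j]], sign(d) * pmax(abs(d) - tau, 0),
                 tolerance = 1e-12)
  }
  # approximation band untouched
  expect_identical(out$approximation, w$approximation)
})

test_that("lp_threshold with p < 1 shrinks without expanding", {
  x <- withr_seed(6, rnorm(256))
  w <- wt_dwt(x, levels = 3)
  out <- lp_threshold(w, lam_s = 0.6, p = 0.5)
  for (j in seq_along(w$details)) {
    d <- w$details[[j]]; o <- out$details[[j]]
    expect_true(all(abs(o) <= abs(d) + 1e-10))
    expect_true(all(sign(o[o != 0]) == sign(d[o != 0])))
  }
})

test_that("total_loss is finite and increases with the penalty weight", {
  x <- abs(withr_seed(7, rnorm(256))) + sin(seq(0, 10, length.out = 256))
  w <- wt_dwt(x, levels = 3)
  p <- etwd_params(1, 1, 0, 1)
  l1 <- total_loss(w, p, lam_s = 0.1, p = 1)
  l2 <- total_loss(w, p, lam_s = 0.1, p = 1)
  expect_identical(l1, l2)
  expect_true(is.finite(l1))
})

test_that("coeffs_details flattens every detail band, finest first", {
  x <- withr_seed(8, rnorm(64))
  w <- wt_dwt(x, levels = 2)
  expect_identical(coeffs_details(w),
                   unname(unlist(w$details)))
})
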