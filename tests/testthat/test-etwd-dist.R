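test_that("etwd_params validates its inputs", {
  p <- etwd_params(2, 1.5, 0.3, 1.2)
  expect_s3_class(p, "etwd_params")
  expect_identical(unname(as.double(p)), c(2, 1.5, 0.3, 1.2))
  expect_true(is_etwd_params(p))
  expect_error(etwd_params(-1, 1), "alpha")
  expect_error(etwd_params(1, 0), "beta")
  expect_error(etwd_params(1, 1, 1.5), "lambda")
  expect_error(etwd_params(1, 1, 0, 0), "nu")
  expect_error(etwd_params(NA, 1))
})

test_that("pdf integrates to one and matches the cdf derivative", {
  p <- etwd_params(3, 4, 0.5, 2)
  expect_equal(pdf_mass(p), 1, tolerance = 1e-9)
  # d/dx petwd == detwd at interior points
  x <- c(0.5, 1, 2, 3, 4.5)
  h <- 1e-6
  fd <- (petwd(x + h, p) - petwd(x - h, p)) / (2 * h)
  expect_equal(fd, detwd(x, p), tolerance = 1e-6)
})

test_that("cdf is a valid distribution function", {
  for (p in random_params(5, seed = 11)) {
    x <- seq(1e-4, 30, length.out = 400)
    Fv <- petwd(x, p)
    expect_true(all(diff(Fv) >= -1e-12))
    expect_true(all(Fv >= 0 & Fv <= 1))
    expect_equal(petwd(0, p), 0)
    expect_equal(petwd(1e6, p), 1, tolerance = 1e-12)
  }
})

test_that("quantile inverts the cdf", {
  pr <- c(1e-6, 0.01, 0.25, 0.5, 0.75, 0.99, 1 - 1e-6)
  for (p in random_params(8, seed = 7)) {
    q <- qetwd(pr, p)
    expect_true(all(is.finite(q) & q >= 0))
    expect_equal(petwd(q, p), pr, tolerance = 1e-10)
  }
})

test_that("density limits at the origin follow the shape parameter", {
  expect_equal(detwd(0, etwd_params(1, 2)), 0)          # beta > 1
  expect_equal(detwd(0, etwd_params(2, 1)), 1 / 2)      # beta = 1, Weibull limit
  expect_true(is.infinite(detwd(0, etwd_params(1, 0.5))))  # beta < 1
})

test_that("retwd is reproducible and distributed as the model", {
  p <- etwd_params(2, 1.5, -0.4, 1.3)
  x1 <- retwd(2000, p, seed = 42)
  x2 <- retwd(2000, p, seed = 42)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0))
  ks <- suppressWarnings(stats::ks.test(x1, function(q) petwd(q, p)))
  expect_gt(ks$p.value, 1e-4)
})

test_that("log-likelihood equals the sum of log densities", {
  p <- etwd_params(1.5, 2.2, 0.6, 0.8)
  x <- retwd(200, p, seed = 3)
  expect_equal(etwd_loglik(p, x), sum(detwd(x, p, log = TRUE)),
               tolerance = 1e-10)
})

test_that("analytic gradient matches finite differences", {
  for (p in random_params(6, seed = 21)) {
    if (abs(p$lambda) > 0.95) next  # FD step would leave the box
    x <- retwd(300, p, seed = 5)
    g <- etwd_loglik_grad(p, x)
    expect_equal(as.numeric(g), fd_loglik_grad(p, x),
                 tolerance = 1e-4)
  }
})

test_that("symmetrized score and its derivative match finite differences", {
  p <- etwd_params(2, 2.5, 0.3, 1.5)
  u <- c(-3, -1.2, -0.4, 0.4, 1.2, 3)
  h <- 1e-6
  # phi = -d/du log f_sym(u); check against FD of the symmetrized log density
  logf <- function(u) detwd(abs(u) + 1e-8, p, log = TRUE) - log(2)
  fd <- -(vapply(u, function(v) (logf(v + h) - logf(v - h)) / (2 * h),
                 numeric(1)))
  expect_equal(etwd_score(u, p), fd, tolerance = 1e-5)
  fd2 <- vapply(u, function(v)
    (etwd_score(v + h, p) - etwd_score(v - h, p)) / (2 * h), numeric(1))
  expect_equal(etwd_score_deriv(u, p), fd2, tolerance = 1e-4)
  # odd symmetry
  expect_equal(etwd_score(u, p), -etwd_score(-u, p))
})

test_that("the Laplace limit has the sign score", {
  p <- etwd_params(1.5, 1, 0, 1)
  u <- c(-2, -0.5, 0.5, 2)
  expect_equal(etwd_score(u, p), sign(u) / 1.5, tolerance = 1e-6)
})

test_that("sub-model reductions match closed forms", {
  x <- seq(0.05, 6, length.out = 80)
  a <- 1.7; b <- 2.6; l <- 0.4; nu <- 1.9
  # Weibull
  cw <- etwd_submodel("weibull")
  expect_identical(cw$parameter, c("alpha", "beta", "lambda", "nu"))
  expect_equal(detwd(x, etwd_params(a, b, 0, 1)),
               stats::dweibull(x, shape = b, scale = a), tolerance = 1e-13)
  # exponential
  expect_equal(detwd(x, etwd_params(a, 1, 0, 1)),
               stats::dexp(x, rate = 1 / a), tolerance = 1e-13)
  # Rayleigh
  expect_equal(detwd(x, etwd_params(a, 2, 0, 1)),
               stats::dweibull(x, shape = 2, scale = a), tolerance = 1e-13)
  # transmuted Weibull
  t <- exp(-(x / a)^b)
  fw <- stats::dweibull(x, shape = b, scale = a)
  expect_equal(detwd(x, etwd_params(a, b, l, 1)),
               fw * (1 - l + 2 * l * t), tolerance = 1e-13)
  # exponentiated Weibull
  expect_equal(detwd(x, etwd_params(a, b, 0, nu)),
               nu * fw * (1 - t)^(nu - 1), tolerance = 1e-13)
})

test_that("etwd_submodel covers eleven families and rejects unknown names", {
  fams <- c("weibull", "exponential", "rayleigh", "transmuted_weibull",
            "exponentiated_weibull", "transmuted_exponential",
            "transmuted_rayleigh", "exponentiated_exponential",
            "exponentiated_rayleigh", "exponentiated_transmuted_exponential",
            "exponentiated_transmuted_rayleigh")
  for (f in fams) {
    tb <- etwd_submodel(f)
    expect_identical(nrow(tb), 4L)
  }
  expect_error(etwd_submodel("gamma"), "Unknown")
})

test_that("score_eq26 reproduces the printed formula verbatim", {
  u <- c(0.5, 1, 2)
  a <- 1.2; b <- 0.8; g <- 1.5
  d <- a + b * g * u^(g - 1)
  expect_equal(score_eq26(u, a, b, g),
               d + (-b * g * (g - 1) * u^(g - 2)) / d)
})

test_that("withr_seed restores the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(withr_seed(9, rnorm(10)))
  expect_identical(.Random.seed, before)
  expect_identical(withr_seed(9, rnorm(3)), withr_seed(9, rnorm(3)))
})
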