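sphere_config <- function(seed, d = 4, generations = 60) {
  ga_config(population_size = 40, generations = generations,
            bounds = rbind(rep(-5, d), rep(5, d)), seed = seed)
}

test_that("ga_config validates and carries the reference defaults", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 100)
  expect_identical(cfg$tournament_size, 3)
  expect_identical(cfg$crossover_rate, 0.8)
  expect_identical(cfg$mutation_rate, 0.05)
  expect_identical(cfg$elitism_count, 2)
  expect_identical(cfg$generations, 200)
  expect_error(ga_config(crossover_rate = 1.5))
  expect_error(ga_config(elitism_count = 100, population_size = 50))
})

test_that("all three strategies minimize the sphere function", {
  for (s in c("ga", "pso", "de")) {
    res <- run_strategy(function(th) sum(th^2), s, sphere_config(1))
    expect_s3_class(res, "strategy_fit")
    expect_lt(res$value, 0.1)
    expect_true(all(abs(res$par) < 1))
    expect_identical(res$strategy, s)
  }
})

test_that("strategy runs are deterministic in the seed", {
  f <- function(th) sum((th - 1)^2)
  a <- run_strategy(f, "ga", sphere_config(5))
  b <- run_strategy(f, "ga", sphere_config(5))
  c3 <- run_strategy(f, "ga", sphere_config(6))
  expect_identical(a$par, b$par)
  expect_identical(a$trace, b$trace)
  expect_false(identical(a$par, c3$par))
})

test_that("the best-fitness trace is nonincreasing (elitism)", {
  for (s in c("ga", "pso", "de")) {
    res <- run_strategy(function(th) sum(th^2) + cos(sum(th)), s,
                        sphere_config(3))
    expect_true(all(diff(res$trace) <= 1e-12))
  }
})

test_that("solutions respect the search box", {
  cfg <- ga_config(population_size = 30, generations = 30,
                   bounds = rbind(c(0.5, 2), c(1, 3)), seed = 2)
  res <- run_strategy(function(th) -sum(th), "ga", cfg)  # pushes to upper
  expect_true(all(res$par >= c(0.5, 2) - 1e-12))
  expect_true(all(res$par <= c(1, 3) + 1e-12))
})

test_that("fit_etwd recovers a one-parameter exponential scale", {
  p <- etwd_params(2, 1, 0, 1)
  x <- retwd(1500, p, seed = 8)
  cfg <- ga_config(population_size = 50, generations = 80, seed = 1,
                   bounds = rbind(c(0.1, 0.999, 0, 0.999),
                                  c(10, 1.001, 1e-9, 1.001)))
  fit <- fit_etwd(x, cfg)
  expect_s3_class(fit, "etwd_fit")
  # with the other three parameters pinned, alpha is the MLE mean
  expect_equal(fit$params$alpha, mean(x), tolerance = 0.02)
})

test_that("GA likelihood matches an independent optimizer", {
  skip_if_not_installed("DEoptim")
  x <- retwd(400, etwd_params(2, 1.8, 0.3, 1.2), seed = 12)
  nll <- function(th) {
    p <- tryCatch(etwd_params(th[1], th[2], th[3], th[4]),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- -suppressWarnings(etwd_loglik(p, x))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- fit_etwd(x, ga_config(seed = 4))   # reference configuration
  de <- withr_seed(99, DEoptim::DEoptim(
    nll, lower = c(1e-3, 1e-3, -1, 1e-3), upper = c(20, 15, 1, 15),
    control = DEoptim::DEoptim.control(NP = 60, itermax = 150,
                                       trace = FALSE)))
  # the authored GA must land within 2 nats of the independent optimum
  # (a broken likelihood or optimizer misses by hundreds)
  expect_lt(fit$neg_loglik, de$optim$bestval + 2)
})

test_that("tidy and glance summarize an etwd_fit", {
  x <- retwd(300, etwd_params(1.5, 2, 0, 1), seed = 2)
  fit <- fit_etwd(x, ga_config(population_size = 30, generations = 30,
                               seed = 3))
  td <- tidy(fit)
  expect_identical(td$term, c("alpha", "beta", "lambda", "nu"))
  expect_identical(nrow(td), 4L)
  gl <- glance(fit)
  expect_identical(gl$n, 300L)
  expect_true(gl$converged_trace)
})

test_that("early stopping shortens the run", {
  x <- retwd(500, etwd_params(2, 1.5, 0, 1), seed = 6)
  cfg <- ga_config(population_size = 30, generations = 200, seed = 1,
                   early_stop_patience = 10)
  fit <- fit_etwd(x, cfg)
  expect_lt(length(fit$trace), 200L)
})

test_that("convergence_report aggregates traces", {
  fits <- lapply(1:3, function(s)
    run_strategy(function(th) sum(th^2), "ga", sphere_config(s,
                                                             generations = 25)))
  rep <- convergence_report(fits)
  expect_s3_class(rep, "convergence_report")
  expect_identical(nrow(rep), 25L)
  expect_true(all(rep$sd >= 0))
  expect_equal(rep$lower, rep$mean - rep$sd)
  expect_error(convergence_report(fits[1]), "at least 2")
  expect_error(convergence_report(list(1:3, 1:4)), "unequal")
})

test_that("fit_sparsity returns hyperparameters in their boxes", {
  x <- sin(seq(0, 8 * pi, length.out = 256)) +
    withr_seed(4, rnorm(256, sd = 0.3))
  cs <- wt_dwt(x, levels = 3)
  sp <- fit_sparsity(cs, config = ga_config(population_size = 20,
                                            generations = 15, seed = 1))
  expect_true(sp$lam_s >= 0 && sp$lam_s <= 2)
  expect_true(sp$p >= 0.2 && sp$p <= 1)
  expect_true(is.finite(sp$loss))
})
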