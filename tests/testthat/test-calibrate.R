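test_that("the logistic curve obeys its closed form", {
  expect_equal(logistic(0.5, alpha = -2, beta = 4), 0.5)  # alpha + beta x = 0
  expect_equal(logistic(c(0, 0.3, 1), alpha = 1.5, beta = 0),
               rep(1 / (1 + exp(-1.5)), 3))
  expect_equal(logistic(1, alpha = 0, beta = 4), 1 / (1 + exp(-4)))
  # overflow-safe at extreme linear predictors
  expect_equal(logistic(1, alpha = 0, beta = 2000), 1)
  expect_equal(logistic(1, alpha = 0, beta = -2000), 0)
})

test_that("maximum-likelihood fit flags null slopes and separation", {
  d <- sim_logistic(4000, alpha = 0.8, beta = 0, seed = 51)
  fit <- fit_lr(d$x, d$y)
  se_beta <- sqrt(fit$vcov[2, 2])
  expect_lt(abs(fit$beta), 3 * se_beta)
  expect_false(fit$separated)

  x <- c(runif(30, 0, 0.4), runif(30, 0.6, 1))
  y <- rep(c(0L, 1L), each = 30)
  expect_true(fit_lr(x, y)$separated)

  expect_error(fit_lr(runif(10), rep(1L, 10)), class = "idh_degenerate_fit_error")
})

test_that("prior-dominated Bayesian fit shrinks to zero", {
  d <- sim_fractions(300, seed = 53)
  fit <- fit_blr(d$x, d$y, prior_variance = 1e-6, chains = 2,
                 warmup = 300, draws = 400, seed = 53)
  expect_lt(abs(fit$alpha), 0.05)
  expect_lt(abs(fit$beta), 0.05)
})

test_that("Bayesian fits are reproducible under a fixed seed and pass diagnostics", {
  d <- sim_fractions(400, seed = 55)
  a <- fit_blr(d$x, d$y, chains = 2, warmup = 300, draws = 400, seed = 9)
  b <- fit_blr(d$x, d$y, chains = 2, warmup = 300, draws = 400, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$diagnostics$rhat < 1.01))
  expect_true(all(a$diagnostics$ess > 100))
  expect_equal(nrow(a$draws), 2 * 400)  # two chains' worth of draws
})

test_that("informative prior shrinks posterior means relative to non-informative", {
  d <- sim_fractions(500, seed = 57)
  inf <- fit_blr(d$x, d$y, prior_variance = 1, chains = 2,
                 warmup = 400, draws = 600, seed = 5)
  non <- fit_blr(d$x, d$y, prior_variance = 1000, chains = 2,
                 warmup = 400, draws = 600, seed = 6)
  expect_lt(abs(inf$beta), abs(non$beta))
  expect_lt(abs(inf$alpha), abs(non$alpha))
  expect_true(sign(inf$beta) == sign(non$beta))
})

test_that("posterior slope uncertainty decreases with sample size", {
  sds <- vapply(c(100, 1000, 10000), function(n) {
    d <- sim_fractions(n, seed = 59)
    fit <- fit_blr(d$x, d$y, chains = 2, warmup = 400, draws = 600, seed = 3)
    sd(fit$draws[, "beta"])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("confidence scores average the curve over posterior draws", {
  d <- sim_fractions(400, seed = 61)
  fit <- fit_blr(d$x, d$y, chains = 2, warmup = 400, draws = 600, seed = 4)
  grid <- seq(0, 1, length.out = 101)
  got <- confidence(fit, grid)
  want <- vapply(grid, function(xx) {
    mean(1 / (1 + exp(-(fit$draws[, "alpha"] + fit$draws[, "beta"] * xx))))
  }, numeric(1))
  expect_equal(got$p_wildtype, want)
  # envelope: the average lies inside the per-draw extremes
  for (i in c(1, 51, 101)) {
    curves <- plogis(fit$draws[, "alpha"] + fit$draws[, "beta"] * grid[i])
    expect_gte(got$p_wildtype[i], min(curves))
    expect_lte(got$p_wildtype[i], max(curves))
  }
  # strictly increasing when every draw has positive slope
  if (all(fit$draws[, "beta"] > 0)) expect_true(all(diff(got$p_wildtype) > 0))
})

test_that("a degenerate posterior reproduces the plain logistic formula", {
  fit <- structure(list(method = "BLR",
                        draws = cbind(alpha = rep(-1.5, 50), beta = rep(5, 50)),
                        alpha = -1.5, beta = 5),
                   class = "idh_calibrator")
  x <- c(0, 0.25, 0.5, 1)
  got <- confidence(fit, x, call = rep("wildtype", 4))
  expect_equal(got$p_wildtype, logistic(x, -1.5, 5))
  expect_equal(got$p_predicted_class, got$p_wildtype)
  got_m <- confidence(fit, x, call = rep("mutant", 4))
  expect_equal(got_m$p_predicted_class, 1 - got$p_wildtype)
})

test_that("confidence at the curve midpoint is one half", {
  fit <- fit_lr(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), c(0, 0, 1, 0, 1, 1))
  x_mid <- -fit$alpha / fit$beta
  expect_equal(confidence(fit, x_mid)$p_wildtype, 0.5)
})

test_that("calibrator serialization records the fit", {
  d <- sim_fractions(200, seed = 63)
  fit <- fit_blr(d$x, d$y, chains = 2, warmup = 300, draws = 300, seed = 2)
  path <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, csv)))
  write_calibrator_json(fit, path, draws_csv = csv)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$method, "BLR")
  expect_equal(obj$prior_variance, 1000)
  expect_equal(obj$n_draws, 600)
  expect_equal(nrow(read.csv(csv)), 600)
})

test_that("split R-hat and ESS behave on independent and on stuck chains", {
  set.seed(65)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(iid), 1.01)
  expect_gt(mcmc_ess(iid), 2000)
  shifted <- iid + rep(c(0, 0, 0, 5), each = 1000)  # one chain off target
  expect_gt(split_rhat(shifted), 1.1)
})
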