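test_that("generation is deterministic and balanced across observers", {
  a <- simulate_fields(n_fields = 138, n_observers = 4, seed = 7)
  b <- simulate_fields(n_fields = 138, n_observers = 4, seed = 7)
  expect_identical(a, b)
  expect_equal(unname(table(a$observer)), c(35, 35, 34, 34),
               ignore_attr = TRUE)
  expect_identical(nrow(a), 138L)
  # coordinates form clusters spanning at most ~3 km
  expect_lt(max(dist(a[, c("x", "y")])), 4000)
  validate_fields(a)
})

test_that("a zero-beta truth yields response variance close to sigma^2", {
  reg <- make_registry(3)
  truth <- truth_record(betas = numeric(0), intercept = 0.5, sigma = 0.02,
                        registry = reg)
  f <- simulate_fields(n_fields = 4000, n_observers = 4, truth = truth,
                       registry = reg, seed = 11)
  y <- compute_response(f)
  expect_equal(var(y), 0.02^2, tolerance = 0.08)
  # no covariate explains variance
  fit <- fit_ols(build_design(f, names(reg), reg))
  expect_lt(fit$r2, 0.01)
})

test_that("the sqrt-scale response follows the stated linear model", {
  reg <- make_registry(2, betas = c(0.02, -0.01))
  truth <- truth_record(betas = c(x1 = 0.02, x2 = -0.01), intercept = 0.3,
                        sigma = 1e-9, registry = reg)
  f <- simulate_fields(n_fields = 200, n_observers = 4, truth = truth,
                       registry = reg, seed = 3)
  y <- compute_response(f)
  lp <- 0.3 + 0.02 * f$x1 - 0.01 * f$x2
  expect_equal(y, pmin(1, pmax(0, lp)), tolerance = 1e-6)
})

test_that("the correlation hook imposes the requested dependence", {
  reg <- covariate_registry()
  R <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
              dimnames = list(c("clay", "sand"), c("clay", "sand")))
  truth <- default_truth()
  f <- simulate_fields(n_fields = 3000, truth = truth, registry = reg,
                       seed = 77, correlation = R)
  expect_gt(cor(f$clay, f$sand), 0.6)
  # margins are preserved under the copula
  expect_lt(abs(mean(f$clay) - 21.08), 3 * 5.71 / sqrt(3000))
  expect_lt(abs(sd(f$sand) - 9.62), 4 * 9.62 / sqrt(3000))
  # identity correlation: independent draws
  f0 <- simulate_fields(n_fields = 3000, truth = truth, registry = reg,
                        seed = 78)
  expect_lt(abs(cor(f0$clay, f0$sand)), 0.06)
  # invalid hooks are rejected
  bad <- R
  rownames(bad) <- c("clay", "storage_units")
  expect_error(simulate_fields(50, 4, truth, reg, correlation = bad),
               class = "weevil_config_error")
  R2 <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
               dimnames = list(c("clay", "storage_units"),
                               c("clay", "storage_units")))
  expect_error(simulate_fields(50, 4, truth, reg, correlation = R2),
               class = "weevil_config_error")
})

test_that("simulate_fields validates its configuration", {
  expect_error(simulate_fields(n_fields = 2, n_observers = 4),
               class = "weevil_validation_error")
  reg <- make_registry(2)
  bad <- truth_record(betas = c(x2 = 1), intercept = 0, sigma = 0.1,
                      registry = reg)
  expect_error(simulate_fields(50, 2, truth = bad,
                               registry = make_registry(1)),
               class = "weevil_config_error")
})

test_that("full-model confidence intervals cover the true effects", {
  # parameter recovery: ~95% coverage of 95% CIs over 200 replicates
  reg <- covariate_registry()
  truth <- default_truth()
  vars <- names(truth$betas)
  pool <- c(vars, "observer_2", "observer_3")
  total <- 0L
  covered <- 0L
  beta_all <- c(truth$betas, observer_2 = unname(truth$observer_effects["obs2"]),
                observer_3 = unname(truth$observer_effects["obs3"]))
  for (r in 1:200) {
    f <- simulate_fields(seed = 5000 + r, truth = truth, registry = reg)
    # a near-degenerate binary covariate is occasionally constant in a
    # replicate; the full model then drops it (rank protection)
    X <- weevilrisk:::encode_covariates(f, pool, reg)
    use <- pool[apply(X, 2, function(v) length(unique(v)) > 1)]
    fit <- fit_ols(build_design(f, use, reg))
    est <- fit$coefficients[use]
    se <- fit$se[use]
    ok <- abs(est - beta_all[use]) <= 1.96 * se
    total <- total + length(ok)
    covered <- covered + sum(ok)
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.98)
})

test_that("calibration errors without signal and tightens with less noise", {
  reg <- make_registry(3, betas = c(0.05, 0, 0))
  truth <- truth_record(betas = c(x1 = 0.05), intercept = 0.1, sigma = 0.1,
                        registry = reg)
  # no signal at all: explained variance cannot be steered by sigma
  null_truth <- truth_record(betas = numeric(0), intercept = 0.4,
                             sigma = 0.1, registry = reg)
  expect_error(
    suppressWarnings(
      calibrate_sigma(registry = reg, truth = null_truth,
                      target_r2_band = c(0.5, 0.6), n_reps = 2, seed = 2,
                      n_fields = 60)),
    class = "weevil_calibration_error")
  # noiseless limit: R^2 of the true model approaches 1
  tr0 <- truth
  tr0$sigma <- 1e-8
  f <- simulate_fields(100, 4, tr0, reg, seed = 5)
  fit <- fit_ols(build_design(f, "x1", reg))
  expect_gt(fit$r2, 0.999)
})

test_that("calibrate_sigma lands the median best-model R^2 in the band", {
  reg <- make_registry(3, betas = c(0.08, -0.05, 0))
  truth <- truth_record(betas = c(x1 = 0.08, x2 = -0.05), intercept = 0.2,
                        sigma = 0.5, registry = reg)
  band <- c(0.35, 0.5)
  sig <- suppressWarnings(
    calibrate_sigma(registry = reg, truth = truth, target_r2_band = band,
                    n_reps = 5, seed = 42, n_fields = 80))
  expect_gt(attr(sig, "median_r2"), band[1])
  expect_lt(attr(sig, "median_r2"), band[2])
  expect_gt(sig, 0)
})
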