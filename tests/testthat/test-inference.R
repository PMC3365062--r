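test_that("baseline profile applies the mean / mode / zero rules", {
  f <- simulate_fields(n_fields = 120, seed = 61)
  prof <- baseline_profile(f)
  # continuous -> sample mean
  expect_equal(prof$values$clay, mean(f$clay))
  expect_identical(prof$notes$clay, "mean")
  # every monthly insecticide count -> zero, overriding the mean rule
  for (m in c("insecticide_dec", "insecticide_jan",
              "insecticide_feb", "insecticide_mar")) {
    expect_identical(prof$values[[m]], 0)
    expect_identical(prof$notes[[m]], "zero")
  }
  expect_gt(mean(f$insecticide_dec), 0)  # the mean rule would disagree
  # ordinal/categorical -> mode
  expect_identical(prof$values$n_hillings, 2L)
  expect_identical(prof$notes$rotation2007, "mode")
  # constant column baselines at the constant
  g <- f
  g$clay <- 7.5
  expect_equal(baseline_profile(g)$values$clay, 7.5)
})

test_that("bimodal ordinal ties resolve to the lower level", {
  reg <- structure(list(
    ord = covariate_spec("ord", "ordinal", "cultural", levels = 1:3,
                         level_probs = c(.4, .4, .2))),
    class = "covariate_registry")
  covs <- data.frame(ord = c(1L, 1L, 2L, 2L, 3L))
  f <- make_fields(covs, y_sqrt = rep(0.3, 5))
  prof <- baseline_profile(f, reg)
  expect_identical(prof$values$ord, 1L)
})

test_that("standardized impacts are squared-prediction differences", {
  f <- simulate_fields(n_fields = 138, seed = 71)
  # hand-built averages: perimeter/area with weight 1 and estimate 0.519,
  # organic matter attenuated by weight 0.21, hillings perturbed downward
  avg <- data.frame(
    name = c("(Intercept)", "perimeter_area", "organic_matter", "n_hillings"),
    weight = c(1, 1, 0.21, 0.7),
    natural = c(0.43, 0.519, -0.012, 0.127),
    stringsAsFactors = FALSE)
  avg$shrinkage <- avg$natural * avg$weight
  avg$se <- 0.1
  avg$ci_low <- avg$natural - 0.2
  avg$ci_high <- avg$natural + 0.2
  class(avg) <- c("averaged_parameters", "data.frame")
  imp <- standardized_impacts(avg, fields = f)
  b0 <- attr(imp, "baseline_sqrt")
  # +1 SD of the encoded column for the continuous variable, w_p = 1:
  # the shrinkage impact IS the natural impact
  sd_pa <- sd(f$perimeter_area)
  expect_equal(imp$delta_infestation[imp$name == "perimeter_area"],
               100 * ((b0 + 0.519 * sd_pa)^2 - b0^2), tolerance = 1e-9)
  # number of hillings moves down one unit
  expect_identical(imp$perturbation[imp$name == "n_hillings"], "-1 unit")
  expect_equal(imp$delta_infestation[imp$name == "n_hillings"],
               100 * ((b0 - 0.7 * 0.127)^2 - b0^2), tolerance = 1e-9)
  # attenuation: |shrunk impact| below the natural-average impact
  sd_om <- sd(f$organic_matter)
  nat_impact <- (b0 - 0.012 * sd_om)^2 - b0^2
  shr <- imp$delta_infestation[imp$name == "organic_matter"] / 100
  expect_lt(abs(shr), abs(nat_impact))
  # a zero shrinkage coefficient has zero impact
  avg0 <- avg
  avg0$shrinkage[avg0$name == "organic_matter"] <- 0
  imp0 <- standardized_impacts(avg0, fields = f)
  expect_equal(imp0$delta_infestation[imp0$name == "organic_matter"], 0)
})

test_that("the insecticide model recovers early-season efficacy", {
  truth <- default_truth()
  # large n to pin signs: December/January negative, later months near zero
  reg <- covariate_registry()
  f <- simulate_fields(n_fields = 1200, truth = truth, registry = reg,
                       seed = 81)
  im <- insecticide_model(f)
  est <- im$estimate
  names(est) <- im$variable
  expect_lt(est[["insecticide_dec"]], 0)
  expect_lt(est[["insecticide_jan"]], 0)
  expect_lt(abs(est[["insecticide_feb"]]), 0.04)
  # all-zero months are dropped with a warning
  g <- simulate_fields(n_fields = 30, seed = 82)
  g$insecticide_mar <- 0L
  expect_warning(im2 <- insecticide_model(g), "insecticide_mar")
  expect_false("insecticide_mar" %in% im2$variable)
  # too few fields for four coefficients plus intercept
  h <- simulate_fields(n_fields = 20, seed = 83)[1:4, ]
  h$insecticide_dec <- c(0L, 1L, 2L, 1L)
  h$insecticide_jan <- c(1L, 0L, 2L, 2L)
  h$insecticide_feb <- c(0L, 1L, 0L, 2L)
  h$insecticide_mar <- c(1L, 2L, 0L, 1L)
  expect_error(insecticide_model(h),
               class = "weevil_insufficient_data_error")
})

test_that("harvest adaptation recovers a planted regression exactly", {
  set.seed(91)
  expected <- runif(12, 0.05, 0.5)
  f <- data.frame(harvest_day = 207.4 - 15.97 * expected)
  res <- harvest_adaptation(f, expected)
  expect_equal(res$slope, -15.97, tolerance = 1e-9)
  expect_equal(res$intercept, 207.4, tolerance = 1e-9)
  expect_identical(res$df, 10L)
  expect_lt(res$p, 1e-12)
  # with noise at the study scale: slope within 2 SEs, df = n - 2
  expected2 <- runif(138, 0.05, 0.5)
  f2 <- data.frame(harvest_day = 207.4 - 15.97 * expected2 + rnorm(138, 0, 8))
  res2 <- harvest_adaptation(f2, expected2)
  expect_identical(res2$df, 136L)
  expect_lt(abs(res2$slope - (-15.97)), 2 * res2$se_slope)
  # degenerate expected values are rejected
  expect_error(harvest_adaptation(f2, rep(0.2, 138)),
               class = "weevil_validation_error")
})

test_that("a null harvest relationship yields a flat regression", {
  set.seed(95)
  expected <- runif(200, 0.1, 0.4)
  f <- data.frame(harvest_day = rnorm(200, 201, 9.5))
  res <- harvest_adaptation(f, expected)
  expect_lt(abs(res$slope), 3 * res$se_slope)
})
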