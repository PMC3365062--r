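test_that("enumeration counts all non-empty subsets", {
  f <- quick_sim(n = 40, p = 3, seed = 2)
  reg <- make_registry(3)
  ms <- enumerate_and_fit(f, c("x1", "x2", "x3"), registry = reg)
  expect_identical(nrow(ms$table), 7L)        # 2^3 - 1
  ms1 <- enumerate_and_fit(f, "x1", registry = reg)
  expect_identical(nrow(ms1$table), 1L)
  # guard rail refuses large pools without the override
  reg21 <- make_registry(21)
  expect_error(enumerate_and_fit(quick_sim(n = 50, p = 21, seed = 3),
                                 paste0("x", 1:21), registry = reg21),
               class = "weevil_guard_error")
})

test_that("subset fits agree with directly fitted models", {
  f <- quick_sim(n = 50, p = 3, betas = c(0.04, -0.02, 0), sigma = 0.04,
                 seed = 9)
  reg <- make_registry(3, betas = c(0.04, -0.02, 0))
  ms <- enumerate_and_fit(f, c("x1", "x2", "x3"), registry = reg)
  vars_list <- model_variables(ms)
  for (i in seq_len(nrow(ms$table))) {
    fit <- fit_ols(build_design(f, vars_list[[i]], reg))
    expect_equal(ms$table$rss[i], fit$rss, tolerance = 1e-9)
    expect_equal(ms$table$aic[i], fit$aic, tolerance = 1e-9)
    expect_equal(ms$table$r2[i], fit$r2, tolerance = 1e-9)
  }
})

test_that("Akaike weights follow exp(-delta/2), normalized", {
  mk <- function(aics) weevilrisk:::new_model_set(
    data.frame(mask = seq_along(aics), k = 3L, rss = 1, aic = aics),
    variables = c("a", "b"), n = 20)
  # two models with equal AIC share the weight
  expect_equal(mk(c(5, 5))$table$weight, c(0.5, 0.5), tolerance = 1e-15)
  # deltas (0, 2, 4): normalized exp(0), exp(-1), exp(-2)
  w <- mk(c(10, 12, 14))$table$weight
  expect_equal(w, c(0.66524, 0.24473, 0.09003), tolerance = 1e-5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # a single model carries weight 1
  expect_equal(mk(3)$table$weight, 1)
  empty <- structure(list(table = data.frame(mask = integer(),
                                             aic = numeric())),
                     class = "model_set")
  expect_error(akaike_weights(empty), class = "weevil_validation_error")
})

test_that("the confidence set keeps the inclusive delta boundary", {
  aics <- 100 + c(0, 1.9, 2.0, 2.1)
  ms <- weevilrisk:::new_model_set(
    data.frame(mask = 1:4, k = 3L, rss = 1, aic = aics),
    variables = c("a", "b"), n = 20)
  cs <- confidence_set(ms, delta_max = 2)
  expect_identical(nrow(cs$table), 3L)
  expect_equal(sum(cs$table$weight), 1, tolerance = 1e-12)
  # identical AICs: everything retained with equal weights
  ms2 <- weevilrisk:::new_model_set(
    data.frame(mask = 1:4, k = 3L, rss = 1, aic = rep(7, 4)),
    variables = c("a", "b"), n = 20)
  cs2 <- confidence_set(ms2)
  expect_identical(nrow(cs2$table), 4L)
  expect_equal(cs2$table$weight, rep(0.25, 4), tolerance = 1e-15)
  # monotonicity: enlarging delta_max never drops a model
  f <- quick_sim(n = 50, p = 4, seed = 12)
  reg <- make_registry(4)
  msr <- enumerate_and_fit(f, paste0("x", 1:4), registry = reg)
  sizes <- vapply(c(0.5, 1, 2, 4, 8),
                  function(d) nrow(confidence_set(msr, d)$table), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("parameter weights sum model weights over containing models", {
  # masks: 1 = {a}, 3 = {a, b} -> a in both, b only in the second
  ms <- weevilrisk:::new_model_set(
    data.frame(mask = c(1L, 3L), k = c(3L, 4L), rss = 1, aic = c(10, 11)),
    variables = c("a", "b"), n = 20)
  ms <- akaike_weights(ms)
  expect_equal(parameter_weight("a", ms), 1, tolerance = 1e-12)
  expect_equal(parameter_weight("b", ms), ms$table$weight[2],
               tolerance = 1e-15)
  expect_error(parameter_weight("zz", ms), class = "weevil_config_error")
  # a parameter in no model of the (sub)set has weight 0
  ms_b <- weevilrisk:::new_model_set(
    data.frame(mask = 1L, k = 3L, rss = 1, aic = 10),
    variables = c("a", "b"), n = 20)
  expect_identical(parameter_weight("b", ms_b), 0)
})

test_that("natural and shrinkage averages follow their definitions", {
  # two models both containing p, weights 0.6/0.4, estimates 1/2:
  # natural (0.6*1 + 0.4*2) / 1 = 1.4, shrinkage 1.4 * 1
  cs <- make_cset(
    weights = c(0.6, 0.4),
    fits = list(list(coef = c(`(Intercept)` = 0, p = 1),
                     var = c(`(Intercept)` = 0.1, p = 0.04)),
                list(coef = c(`(Intercept)` = 0, p = 2),
                     var = c(`(Intercept)` = 0.1, p = 0.09))),
    variables = "p")
  avg <- average_parameters(cs)
  row <- avg[avg$name == "p", ]
  expect_equal(row$weight, 1, tolerance = 1e-12)
  expect_equal(row$natural, 1.4, tolerance = 1e-12)
  expect_equal(row$shrinkage, 1.4, tolerance = 1e-12)
  # unconditional SE: sqrt(sum (w/wp) (var + (b - natural)^2))
  se_expected <- sqrt(0.6 * (0.04 + (1 - 1.4)^2) + 0.4 * (0.09 + (2 - 1.4)^2))
  expect_equal(row$se, se_expected, tolerance = 1e-12)
  expect_equal(c(row$ci_low, row$ci_high),
               1.4 + c(-1.96, 1.96) * se_expected, tolerance = 1e-12)

  # a parameter in a single model of weight 0.4: natural 2, shrinkage 0.8
  cs2 <- make_cset(
    weights = c(0.6, 0.4),
    fits = list(list(coef = c(`(Intercept)` = 0),
                     var = c(`(Intercept)` = 0.1)),
                list(coef = c(`(Intercept)` = 0, p = 2),
                     var = c(`(Intercept)` = 0.1, p = 0.09))),
    variables = "p")
  avg2 <- average_parameters(cs2)
  row2 <- avg2[avg2$name == "p", ]
  expect_equal(row2$weight, 0.4, tolerance = 1e-12)
  expect_equal(row2$natural, 2, tolerance = 1e-12)
  expect_equal(row2$shrinkage, 0.8, tolerance = 1e-12)
})

test_that("shrinkage equals natural times the parameter weight, exactly", {
  f <- quick_sim(n = 70, p = 5, betas = c(0.05, -0.03, 0.02, 0, 0),
                 sigma = 0.05, seed = 31)
  reg <- make_registry(5, betas = c(0.05, -0.03, 0.02, 0, 0))
  cs <- confidence_set(enumerate_and_fit(f, paste0("x", 1:5), registry = reg))
  avg <- average_parameters(cs)
  ok <- !is.na(avg$natural)
  expect_identical(avg$shrinkage[ok], avg$natural[ok] * avg$weight[ok])
  expect_true(all(avg$ci_low[ok] <= avg$natural[ok] &
                  avg$natural[ok] <= avg$ci_high[ok]))
  expect_equal(sum(cs$table$weight), 1, tolerance = 1e-12)
})

test_that("exhaustive search matches an independent brute-force oracle", {
  set.seed(77)
  for (r in 1:10) {
    p <- sample(3:7, 1)
    n <- sample(25:50, 1)
    betas <- round(rnorm(p, 0, 0.02), 3)
    reg <- make_registry(p, betas = betas)
    f <- quick_sim(n = n, p = p, betas = betas, sigma = 0.05,
                   seed = 700 + r)
    ms <- enumerate_and_fit(f, paste0("x", 1:p), registry = reg)
    best_mine <- sort(match(
      model_variables(ms)[[which.min(ms$table$aic)]], paste0("x", 1:p)))
    d <- build_design(f, paste0("x", 1:p), reg)
    oracle <- brute_force_best(d$X[, -1, drop = FALSE], d$y)
    expect_identical(best_mine, oracle$best)
    expect_equal(min(ms$table$aic), oracle$aic, tolerance = 1e-8)
  }
})

test_that("class comparison is symmetric under identical class lists", {
  f <- quick_sim(n = 60, p = 4, betas = c(0.04, 0, -0.03, 0), sigma = 0.04,
                 seed = 41)
  reg <- make_registry(4, betas = c(0.04, 0, -0.03, 0))
  cc <- compare_classes(f, local_vars = paste0("x", 1:4),
                        landscape_vars = paste0("x", 1:4),
                        controls = character(), registry = reg)
  expect_equal(cc$summary$weight, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(cc$summary$delta_aic, rep(0, 3), tolerance = 1e-9)
})

test_that("a signal-free class loses the three-way comparison", {
  # x1,x2 carry signal (local); x3,x4 are noise (landscape): the local
  # class best should sit near the combined best
  reg4 <- make_registry(4, betas = c(0.05, -0.04, 0, 0))
  f <- quick_sim(n = 90, p = 4, betas = c(0.05, -0.04, 0, 0), sigma = 0.04,
                 seed = 53)
  cc <- compare_classes(f, local_vars = c("x1", "x2"),
                        landscape_vars = c("x3", "x4"),
                        controls = character(), registry = reg4)
  s <- cc$summary
  expect_lt(abs(s$delta_aic[s$class == "local"]), 8)
  expect_gt(s$delta_aic[s$class == "landscape"],
            s$delta_aic[s$class == "local"])
})
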