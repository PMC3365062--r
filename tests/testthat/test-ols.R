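design_xy <- function(x, y) {
  list(X = cbind(`(Intercept)` = 1, x = x), y = y, variables = "x")
}

test_that("OLS recovers exact and closed-form solutions", {
  # exact line
  f1 <- fit_ols(design_xy(c(0, 1, 2), c(1, 2, 3)))
  expect_equal(unname(f1$coefficients), c(1, 1), tolerance = 1e-12)
  expect_equal(f1$rss, 0, tolerance = 1e-20)
  expect_equal(f1$r2, 1)
  # hand-derived simple regression: slope 0.5, intercept 1/6, RSS 1/6
  f2 <- fit_ols(design_xy(c(0, 1, 2), c(0, 1, 1)))
  expect_equal(unname(f2$coefficients), c(1 / 6, 1 / 2), tolerance = 1e-12)
  expect_equal(f2$rss, 1 / 6, tolerance = 1e-12)
})

test_that("rank deficiency and short data are classed errors", {
  X <- cbind(`(Intercept)` = 1, a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_error(fit_ols(list(X = X, y = rnorm(4), variables = c("a", "b"))),
               "b", class = "weevil_singular_error")
  expect_error(fit_ols(design_xy(c(0, 1), c(1, 2))),
               class = "weevil_insufficient_data_error")
})

test_that("OLS agrees with a numeric RSS minimizer and with lm", {
  set.seed(20)
  for (r in 1:20) {
    n <- sample(10:30, 1)
    p <- sample(1:4, 1)
    X <- cbind(`(Intercept)` = 1,
               matrix(rnorm(n * p), n, p,
                      dimnames = list(NULL, paste0("v", 1:p))))
    y <- rnorm(n)
    fit <- fit_ols(list(X = X, y = y, variables = paste0("v", 1:p)))
    # oracle 1: direct numeric minimization of the RSS
    rssf <- function(b) sum((y - X %*% b)^2)
    opt <- optim(rep(0, p + 1), rssf, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_lt(abs(fit$rss - opt$value), 1e-6)
    expect_lt(max(abs(fit$coefficients - opt$par)), 1e-3)
    # oracle 2: lm's QR path, coefficients and SEs
    lmfit <- lm(y ~ X - 1)
    expect_equal(unname(fit$coefficients), unname(coef(lmfit)),
                 tolerance = 1e-9)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-8)
  }
})

test_that("the criterion matches its definition and conventions", {
  # intercept-only on y = (0,1,2): RSS 2, n 3, K 2 -> 3 ln(2/3) + 4
  f0 <- fit_ols(list(X = cbind(`(Intercept)` = c(1, 1, 1)), y = c(0, 1, 2),
                     variables = character()))
  expect_equal(f0$aic, 3 * log(2 / 3) + 4, tolerance = 1e-12)
  expect_equal(f0$aic, 2.7836, tolerance = 1e-4)
  # equal RSS and K give equal AIC
  expect_identical(aic(list(rss = 1.5, n = 10, k_params = 3)),
                   aic(list(rss = 1.5, n = 10, k_params = 3)))
  # a column orthogonal to the residuals leaves RSS unchanged: AIC + 2
  y <- c(0, 1, 2, 1)
  X1 <- cbind(`(Intercept)` = rep(1, 4))
  X2 <- cbind(X1, c = c(1, -1, 1, -1))
  fa <- fit_ols(list(X = X1, y = y, variables = character()))
  fb <- fit_ols(list(X = X2, y = y, variables = "c"))
  expect_equal(fb$rss, fa$rss, tolerance = 1e-12)
  expect_equal(fb$aic - fa$aic, 2, tolerance = 1e-10)
  # degenerate and undefined cases
  expect_error(aic(list(rss = 0, n = 5, k_params = 2)),
               class = "weevil_degenerate_fit_error")
  expect_error(aic(list(rss = 1, n = 3, k_params = 3), corrected = TRUE),
               class = "weevil_validation_error")
  # small-sample correction adds 2K(K+1)/(n-K-1)
  base <- aic(list(rss = 2, n = 20, k_params = 4))
  corr <- aic(list(rss = 2, n = 20, k_params = 4), corrected = TRUE)
  expect_equal(corr - base, 2 * 4 * 5 / 15, tolerance = 1e-12)
})

test_that("criterion differences are invariant to the omitted constant", {
  set.seed(4)
  n <- 25
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  f1 <- fit_ols(design_xy(x, y))
  f0 <- fit_ols(list(X = cbind(`(Intercept)` = rep(1, n)), y = y,
                     variables = character()))
  # full Gaussian -2 logLik + 2K recomputation
  full_aic <- function(rss, n, K)
    n * (log(2 * pi) + log(rss / n) + 1) + 2 * K
  d_mine <- f1$aic - f0$aic
  d_full <- full_aic(f1$rss, n, f1$k_params) - full_aic(f0$rss, n, f0$k_params)
  expect_equal(d_mine, d_full, tolerance = 1e-10)
})
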