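# Ordinary least squares with information-criterion scoring: the engine
# behind the stepwise, all-subsets and averaging stages.

#' Fit ordinary least squares on a design
#'
#' Coefficients minimize the residual sum of squares (QR decomposition);
#' standard errors use the unbiased residual-variance estimator
#' RSS / (n - p). The criterion score is attached via [aic()].
#'
#' @param design A [build_design()] object (or a list with `X`, `y`,
#'   `variables`).
#' @param corrected Use the small-sample corrected criterion (AICc).
#' @return A list of class `"weevil_fit"`: `variables`, `coefficients`,
#'   `se`, `rss`, `n`, `k_params` (coefficients incl. intercept, + 1 for the
#'   residual variance), `aic`, `r2`, and set-relative `delta`/`weight`
#'   (NA until placed in a model set).
#' @export
fit_ols <- function(design, corrected = FALSE) {
  X <- design$X
  y <- design$y
  if (is.null(y)) stop_weevil("weevil_validation_error", "design has no response")
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p)
    stop_weevil("weevil_insufficient_data_error",
                "need more observations (%d) than parameters (%d)", n, p)
  qx <- qr(X)
  if (qx$rank < p) {
    piv <- qx$pivot
    bad <- colnames(X)[piv[(qx$rank + 1):p]]
    stop_weevil("weevil_singular_error",
                "design is rank deficient; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - drop(X %*% coefs)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) min(1, max(0, 1 - rss / tss)) else NA_real_
  fit <- structure(list(variables = design$variables,
                        coefficients = coefs, se = se,
                        residuals = res, rss = rss, n = n,
                        k_params = p + 1L, r2 = r2,
                        corrected = corrected,
                        delta = NA_real_, weight = NA_real_),
                   class = "weevil_fit")
  # a saturated (zero-RSS) fit has no finite criterion; aic() errors on it
  fit$aic <- if (rss > 0) aic(fit, corrected = corrected) else NA_real_
  fit
}

#' Akaike information criterion of an OLS fit
#'
#' `AIC = n * log(RSS / n) + 2K` with `K` the number of regression
#' coefficients (including the intercept) plus one for the residual
#' variance. Additive constants of the Gaussian log-likelihood are omitted:
#' only criterion differences between models fitted to the same response
#' are meaningful. With `corrected = TRUE` the small-sample term
#' `2K(K + 1) / (n - K - 1)` is added.
#'
#' @param fit A `"weevil_fit"` (or a list with `rss`, `n`, `k_params`).
#' @param corrected Apply the small-sample correction.
#' @return The criterion value.
#' @export
aic <- function(fit, corrected = FALSE) {
  rss <- fit$rss
  n <- fit$n
  K <- fit$k_params
  if (!is.finite(rss) || rss <= 0)
    stop_weevil("weevil_degenerate_fit_error",
                "residual sum of squares must be positive (saturated or degenerate fit)")
  out <- n * log(rss / n) + 2 * K
  if (corrected) {
    if (n <= K + 1)
      stop_weevil("weevil_validation_error",
                  "corrected criterion undefined for n <= K + 1")
    out <- out + 2 * K * (K + 1) / (n - K - 1)
  }
  out
}

#' @export
print.weevil_fit <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit: %d observations, %d coefficients\n",
              x$n, length(x$coefficients)))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, digits))
  cat(sprintf("RSS %.4g   R^2 %.3f   %s %.2f\n", x$rss, x$r2,
              if (isTRUE(x$corrected)) "AICc" else "AIC", x$aic))
  invisible(x)
}

#' @export
coef.weevil_fit <- function(object, ...) object$coefficients

#' @export
residuals.weevil_fit <- function(object, ...) object$residuals

# Fast internal AIC of y on X (no SEs). Returns NA if X is rank deficient.
.aic_quick <- function(X, y, corrected = FALSE) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NA_real_)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  K <- ncol(X) + 1L
  if (rss <= 0) return(NA_real_)
  out <- n * log(rss / n) + 2 * K
  if (corrected) out <- out + 2 * K * (K + 1) / (n - K - 1)
  out
}
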