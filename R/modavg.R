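# Central model-fitting entry point: forward stepwise global model,
# all-subsets enumeration, confidence set, and model averaging, returned as
# one classed object with the usual methods.

#' Multimodel screening of weevil-infestation predictors
#'
#' Runs the full information-theoretic analysis on a field-record table:
#' (1) forward AIC-guided construction of the global model over `pool` with
#' a `tolerance`-AIC stopping rule; (2) exhaustive enumeration of all
#' non-empty subsets of the selected variables; (3) the confidence set of
#' models within `delta_max` AIC of the best; (4) Akaike model and parameter
#' weights and natural/shrinkage model averaging with unconditional
#' standard errors.
#'
#' @param fields Field-record data frame (see [simulate_fields()] /
#'   [read_fields()]).
#' @param pool Candidate variables; defaults to every registry covariate
#'   plus the observer-control indicators.
#' @param tolerance Stepwise AIC tolerance (default 2.0).
#' @param delta_max Confidence-set AIC radius (default 2.0).
#' @param registry Covariate registry.
#' @param corrected Use AICc throughout.
#' @param max_vars,force Enumeration guard rail; `force = TRUE` by default
#'   here because the stepwise stage decides the subset-space size.
#' @return An object of class `"weevil_modavg"` with components
#'   `trajectory` (a `"step_trajectory"`), `model_set` summary statistics,
#'   `confidence_set`, `averages` (an `"averaged_parameters"` table),
#'   `best` (the minimum-AIC `"weevil_fit"`), and the data/registry needed
#'   by `predict()` and `residuals()`.
#' @seealso [compare_classes()], [standardized_impacts()], [correlogram()]
#' @export
weevil_modavg <- function(fields, pool = NULL, tolerance = 2, delta_max = 2,
                          registry = covariate_registry(),
                          corrected = FALSE, max_vars = 20, force = TRUE) {
  validate_fields(fields, registry)
  if (is.null(pool)) pool <- c(names(registry), OBSERVER_INDICATORS)
  traj <- build_global_model(fields, pool, tolerance, registry, corrected)
  if (!length(traj$selected))
    stop_weevil("weevil_no_candidate_error",
                "forward selection admitted no variables; nothing to average")
  mset <- enumerate_and_fit(fields, traj$selected, registry, corrected,
                            max_vars = max_vars, force = force)
  cset <- confidence_set(mset, delta_max)
  avg <- average_parameters(cset)
  best_idx <- which.min(mset$table$aic)
  best_vars <- .mask_vars(mset$table$mask[best_idx], mset$variables)
  best <- fit_ols(build_design(fields, best_vars, registry), corrected)
  best$delta <- 0
  structure(list(
    call = match.call(),
    fields = fields, registry = registry, pool = pool,
    tolerance = tolerance, delta_max = delta_max, corrected = corrected,
    trajectory = traj,
    n_models = nrow(mset$table),
    confidence_set = cset,
    averages = avg,
    best = best,
    r2_range = range(cset$table$r2)
  ), class = "weevil_modavg")
}

#' @export
print.weevil_modavg <- function(x, ...) {
  cat("Multimodel inference for weevil infestation (sqrt-proportion scale)\n")
  cat(sprintf("  fields: %d   candidate pool: %d variables\n",
              nrow(x$fields), length(x$pool)))
  cat(sprintf("  global model: %d variables (forward AIC, tolerance %.1f)\n",
              length(x$trajectory$selected), x$tolerance))
  cat(sprintf("  models fitted: %s   confidence set (delta <= %.1f): %d models\n",
              format(x$n_models, big.mark = ","), x$delta_max,
              nrow(x$confidence_set$table)))
  cat(sprintf("  confidence-set R^2 range: %.1f%% - %.1f%%\n",
              100 * x$r2_range[1], 100 * x$r2_range[2]))
  invisible(x)
}

#' @export
summary.weevil_modavg <- function(object, ...) {
  structure(list(modavg = object), class = "summary.weevil_modavg")
}

#' @export
print.summary.weevil_modavg <- function(x, ...) {
  print(x$modavg)
  cat("\n")
  print(x$modavg$averages)
  w <- x$modavg$confidence_set$table$weight
  cat(sprintf("\nModel weights within the confidence set span %.4f..%.4f\n",
              min(w), max(w)))
  invisible(x)
}

#' Model-averaged coefficients
#'
#' @param object A `"weevil_modavg"`.
#' @param type `"shrinkage"` (natural average times parameter weight; the
#'   prediction scale) or `"natural"` (conditional on containing models).
#' @param ... Unused.
#' @return Named numeric vector (including the intercept).
#' @export
coef.weevil_modavg <- function(object, type = c("shrinkage", "natural"), ...) {
  type <- match.arg(type)
  out <- object$averages[[if (type == "shrinkage") "shrinkage" else "natural"]]
  names(out) <- object$averages$name
  out[is.na(out)] <- 0
  out
}

#' Predict infestation from the averaged model
#'
#' Predictions use the shrinkage (weight-multiplied) averaged coefficients.
#' The sqrt-scale prediction is clamped to \[0, 1\] before back-transforming
#' by squaring.
#'
#' @param object A `"weevil_modavg"`.
#' @param newdata Field-record data frame (defaults to the fitted data).
#' @param type `"proportion"` (back-transformed) or `"sqrt"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.weevil_modavg <- function(object, newdata = object$fields,
                                  type = c("proportion", "sqrt"), ...) {
  type <- match.arg(type)
  b <- coef(object, type = "shrinkage")
  vars <- setdiff(names(b), "(Intercept)")
  X <- encode_covariates(newdata, vars, object$registry)
  lp <- b[["(Intercept)"]] + drop(X %*% b[vars])
  if (type == "sqrt") return(lp)
  pmin(1, pmax(0, lp))^2
}

#' Residuals of the averaged or best model
#'
#' @param object A `"weevil_modavg"`.
#' @param type `"best"` (residuals of the minimum-AIC model; the default
#'   used for spatial diagnostics) or `"averaged"` (response minus the
#'   shrinkage-averaged sqrt-scale prediction).
#' @param ... Unused.
#' @return Numeric vector (sqrt scale).
#' @export
residuals.weevil_modavg <- function(object, type = c("best", "averaged"),
                                    ...) {
  type <- match.arg(type)
  if (type == "best") return(object$best$residuals)
  compute_response(object$fields) -
    predict(object, object$fields, type = "sqrt")
}

#' Diagnostic plot: stepwise trajectory and parameter weights
#'
#' @param x A `"weevil_modavg"`.
#' @param ... Passed to the trajectory panel.
#' @export
plot.weevil_modavg <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$trajectory, ...)
  a <- x$averages[x$averages$name != "(Intercept)", ]
  a <- a[order(a$weight, decreasing = TRUE), ]
  graphics::barplot(a$weight, names.arg = a$name, las = 2,
                    cex.names = 0.6, ylab = "parameter weight",
                    main = "Akaike parameter weights")
  invisible(x)
}
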