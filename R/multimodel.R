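# Exhaustive all-subsets evaluation, Akaike weights, confidence sets,
# parameter weights and the two model-averaging conventions.

new_model_set <- function(table, variables, n, X = NULL, y = NULL,
                          corrected = FALSE) {
  table$delta <- table$aic - min(table$aic)
  w <- exp(-table$delta / 2)
  table$weight <- w / sum(w)
  structure(list(table = table, variables = variables, n = n,
                 X = X, y = y, corrected = corrected,
                 best_aic = min(table$aic)),
            class = "model_set")
}

# Membership of variable j (1-based within set$variables) in each model.
.mask_has <- function(mask, j) bitwAnd(as.integer(mask), bitwShiftL(1L, j - 1L)) != 0L

# Variables of a single model mask.
.mask_vars <- function(mask, variables)
  variables[bitwAnd(as.integer(mask), bitwShiftL(1L, seq_along(variables) - 1L)) != 0L]

#' Fit all non-empty additive variable combinations
#'
#' Evaluates every non-empty subset of `variables` (each model with an
#' intercept): `2^p - 1` models, scored by RSS and AIC computed from
#' cross-products (one small Cholesky solve per subset, in compiled code).
#' The full design is checked for rank once; every subset of a full-rank
#' design is full rank. Enumeration is deterministic given the table.
#'
#' @param fields Field-record data frame.
#' @param variables Candidate variables (registry names and/or observer
#'   indicators). At most `max_vars` unless `force = TRUE`; hard cap 24.
#' @param registry Covariate registry.
#' @param corrected Use AICc.
#' @param max_vars Guard rail on the subset-space size (default 20).
#' @param force Override the guard rail (the 2^24 hard cap remains).
#' @return A `"model_set"`: `table` (one row per model: `mask`, `k`,
#'   `rss`, `aic`, `r2`, `delta`, `weight`), `variables`, `n`, plus the
#'   design kept for later refits.
#' @export
enumerate_and_fit <- function(fields, variables,
                              registry = covariate_registry(),
                              corrected = FALSE, max_vars = 20,
                              force = FALSE) {
  p <- length(variables)
  if (p < 1)
    stop_weevil("weevil_validation_error", "need at least one variable")
  if (p > 24)
    stop_weevil("weevil_guard_error",
                "%d variables exceeds the 2^24 enumeration cap", p)
  if (p > max_vars && !force)
    stop_weevil("weevil_guard_error",
                "%d variables exceeds the guard rail of %d (2^%d - 1 = %s models); pass force = TRUE to override",
                p, max_vars, p, format(2^p - 1, big.mark = ","))
  des <- build_design(fields, variables, registry)
  X <- des$X
  y <- des$y
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_weevil("weevil_singular_error",
                "full design is rank deficient; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  G <- crossprod(X)
  gy <- drop(crossprod(X, y))
  yty <- sum(y^2)
  m <- enum_subsets_rss(G, gy, yty)
  rss <- m[, 3]
  if (anyNA(rss)) {
    warn_weevil("dropping %d numerically singular subset(s)", sum(is.na(rss)))
    m <- m[!is.na(rss), , drop = FALSE]
    rss <- m[, 3]
  }
  k <- m[, 2] + 1  # + residual variance
  aic_v <- n * log(rss / n) + 2 * k
  if (corrected) aic_v <- aic_v + 2 * k * (k + 1) / (n - k - 1)
  tss <- sum((y - mean(y))^2)
  tab <- data.frame(mask = m[, 1], k = as.integer(k), rss = rss,
                    aic = aic_v, r2 = pmin(1, pmax(0, 1 - rss / tss)))
  new_model_set(tab, des$variables, n, X = X, y = y, corrected = corrected)
}

#' Akaike weights within a model set
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`; weights sum to one within the set and are
#' read as the relative probability that model i is the best in the set.
#'
#' @param set A `"model_set"`.
#' @return The set with `delta` and `weight` recomputed.
#' @export
akaike_weights <- function(set) {
  if (!inherits(set, "model_set") || nrow(set$table) == 0L)
    stop_weevil("weevil_validation_error", "need a non-empty model_set")
  if (any(!is.finite(set$table$aic)))
    stop_weevil("weevil_validation_error", "model AICs must be finite")
  set$table$delta <- set$table$aic - min(set$table$aic)
  w <- exp(-set$table$delta / 2)
  set$table$weight <- w / sum(w)
  set$best_aic <- min(set$table$aic)
  set
}

#' Confidence set of similarly-supported models
#'
#' Retains the models within `delta_max` AIC of the set's best model
#' (inclusive boundary) and renormalizes Akaike weights within the retained
#' set. Retained models are refitted to recover coefficients and their
#' sampling variances for averaging.
#'
#' @param set A `"model_set"` from [enumerate_and_fit()].
#' @param delta_max AIC radius (default 2.0).
#' @return A `"model_set"` (subclass `"confidence_set"`) with a `fits`
#'   list (per-model coefficient and variance vectors) when the design is
#'   available.
#' @export
confidence_set <- function(set, delta_max = 2) {
  if (!inherits(set, "model_set") || nrow(set$table) == 0L)
    stop_weevil("weevil_validation_error", "need a non-empty model_set")
  set <- akaike_weights(set)
  keep <- set$table$delta <= delta_max
  out <- set
  out$table <- set$table[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out <- new_model_set(out$table, set$variables, set$n,
                       X = set$X, y = set$y, corrected = set$corrected)
  out$delta_max <- delta_max
  if (!is.null(out$X)) out$fits <- .refit_masks(out)
  class(out) <- c("confidence_set", class(out))
  out
}

# Refit each retained model from the stored design: named coefficients and
# their variances (unbiased residual-variance estimator).
.refit_masks <- function(set) {
  X <- set$X
  y <- set$y
  n <- set$n
  lapply(set$table$mask, function(mask) {
    j <- which(bitwAnd(as.integer(mask),
                       bitwShiftL(1L, seq_along(set$variables) - 1L)) != 0L)
    Xi <- X[, c(1L, j + 1L), drop = FALSE]
    cp <- chol(crossprod(Xi))
    b <- backsolve(cp, forwardsolve(t(cp), crossprod(Xi, y)))
    res <- y - drop(Xi %*% b)
    sigma2 <- sum(res^2) / (n - ncol(Xi))
    vars <- diag(chol2inv(cp)) * sigma2
    b <- drop(b)
    names(b) <- names(vars) <- colnames(Xi)
    list(coef = b, var = vars)
  })
}

#' Akaike parameter weight
#'
#' The sum of (normalized) Akaike weights over all models in the set that
#' contain the parameter: the probability that the parameter is in the best
#' model of the set. A parameter in every model has weight exactly 1.
#'
#' @param name Variable name (or `"(Intercept)"`, weight 1 by construction).
#' @param cset A weighted `"model_set"` (typically a [confidence_set()]).
#' @return Numeric in \[0, 1\].
#' @export
parameter_weight <- function(name, cset) {
  if (!inherits(cset, "model_set"))
    stop_weevil("weevil_validation_error", "cset must be a model_set")
  if (identical(name, "(Intercept)")) return(sum(cset$table$weight))
  j <- match(name, cset$variables)
  if (is.na(j))
    stop_weevil("weevil_config_error", "unknown parameter '%s'", name)
  has <- vapply(cset$table$mask, .mask_has, logical(1), j = j)
  sum(cset$table$weight[has])
}

#' Model-averaged parameter estimates
#'
#' For each parameter: the parameter weight `w_p`; the natural average
#' (Akaike-weighted mean of the estimates over the models containing the
#' parameter, normalized by `w_p`); the shrinkage average for prediction
#' (natural average times `w_p`, exactly); the unconditional standard error
#' `sqrt( sum_i (w_i / w_p) * (var(b_i) + (b_i - natural)^2) )` over the
#' containing models; and a normal-approximation 95% CI
#' (natural ± 1.96 SE). Parameters absent from every model are reported
#' with weight 0 and undefined averages.
#'
#' @param cset A [confidence_set()] (must carry refitted models).
#' @return A data frame of class `"averaged_parameters"`: `name`, `weight`,
#'   `natural`, `shrinkage`, `se`, `ci_low`, `ci_high`.
#' @export
average_parameters <- function(cset) {
  if (!inherits(cset, "confidence_set") || is.null(cset$fits))
    stop_weevil("weevil_validation_error",
                "cset must be a confidence_set with refitted models")
  w <- cset$table$weight
  pars <- c("(Intercept)", cset$variables)
  rows <- lapply(pars, function(p) {
    has <- vapply(cset$fits, function(f) p %in% names(f$coef), logical(1))
    wp <- sum(w[has])
    if (!any(has) || wp <= 0)
      return(data.frame(name = p, weight = 0, natural = NA_real_,
                        shrinkage = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE))
    b <- vapply(cset$fits[has], function(f) f$coef[[p]], numeric(1))
    v <- vapply(cset$fits[has], function(f) f$var[[p]], numeric(1))
    wi <- w[has]
    natural <- sum(wi * b) / wp
    se <- sqrt(sum((wi / wp) * (v + (b - natural)^2)))
    data.frame(name = p, weight = wp, natural = natural,
               shrinkage = natural * wp, se = se,
               ci_low = natural - 1.96 * se,
               ci_high = natural + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("averaged_parameters", "data.frame")
  out
}

#' @export
print.averaged_parameters <- function(x, digits = 4, ...) {
  cat("Model-averaged parameter estimates\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("Model set: %s models over %d variables (n = %d)\n",
              format(nrow(x$table), big.mark = ","), length(x$variables), x$n))
  best <- which.min(x$table$aic)
  cat(sprintf("  best AIC %.2f (model mask %d, k = %d, R^2 %.3f)\n",
              x$table$aic[best], x$table$mask[best], x$table$k[best],
              x$table$r2[best]))
  if (inherits(x, "confidence_set"))
    cat(sprintf("  confidence set within %.1f AIC; weights span %.4f..%.4f\n",
                x$delta_max, min(x$table$weight), max(x$table$weight)))
  invisible(x)
}

#' Variables of each model in a set
#'
#' @param set A `"model_set"`.
#' @return A list of character vectors, one per model row.
#' @export
model_variables <- function(set) {
  lapply(set$table$mask, .mask_vars, variables = set$variables)
}

#' Compare local-only, landscape-only and combined model classes
#'
#' For each class (local, landscape, and the two combined) the full
#' procedure is rerun within the class: forward stepwise global model over
#' the class pool (control indicators compete in every pool), all-subsets
#' enumeration of the selected variables, and the minimum-AIC model taken
#' as the class best. The three best models are then compared by AIC
#' difference from the combined best and by three-way Akaike weights.
#'
#' @param fields Field-record data frame.
#' @param local_vars,landscape_vars Disjoint non-control predictor lists.
#' @param controls Control indicators included in every pool (default the
#'   observer indicators).
#' @param tolerance Stepwise AIC tolerance.
#' @param registry Covariate registry.
#' @param corrected Use AICc.
#' @param max_vars,force Passed to [enumerate_and_fit()] (`force = TRUE`
#'   by default: the class pools are data-driven).
#' @return A list of class `"class_comparison"`: `summary` (data frame with
#'   `class`, `n_selected`, `best_aic`, `delta_aic`, `weight`, `r2`) and
#'   `best_fits` (per-class `"weevil_fit"`).
#' @export
compare_classes <- function(fields, local_vars, landscape_vars,
                            controls = OBSERVER_INDICATORS,
                            tolerance = 2,
                            registry = covariate_registry(),
                            corrected = FALSE, max_vars = 20,
                            force = TRUE) {
  if (!length(local_vars) || !length(landscape_vars))
    stop_weevil("weevil_validation_error",
                "both variable classes must be non-empty")
  overlap <- intersect(local_vars, landscape_vars)
  if (length(overlap) && !identical(sort(local_vars), sort(landscape_vars)))
    stop_weevil("weevil_validation_error",
                "classes must be disjoint (overlap: %s)",
                paste(overlap, collapse = ", "))
  pools <- list(combined = union(local_vars, landscape_vars),
                local = local_vars, landscape = landscape_vars)
  one_class <- function(vars) {
    pool <- c(vars, setdiff(controls, vars))
    traj <- build_global_model(fields, pool, tolerance, registry, corrected)
    if (!length(traj$selected)) {
      d0 <- build_design(fields, character(), registry)
      fit <- fit_ols(d0, corrected)
      return(list(selected = character(), best_aic = fit$aic, fit = fit,
                  r2 = fit$r2))
    }
    ms <- enumerate_and_fit(fields, traj$selected, registry, corrected,
                            max_vars = max_vars, force = force)
    best <- which.min(ms$table$aic)
    vars_best <- .mask_vars(ms$table$mask[best], ms$variables)
    fit <- fit_ols(build_design(fields, vars_best, registry), corrected)
    list(selected = traj$selected, best_aic = ms$table$aic[best], fit = fit,
         r2 = ms$table$r2[best])
  }
  res <- lapply(pools, one_class)
  best_aics <- vapply(res, `[[`, numeric(1), "best_aic")
  delta <- best_aics - best_aics[["combined"]]
  w <- exp(-(best_aics - min(best_aics)) / 2)
  w <- w / sum(w)
  summary <- data.frame(
    class = names(pools),
    n_selected = vapply(res, function(r) length(r$selected), integer(1)),
    best_aic = best_aics, delta_aic = delta, weight = w,
    r2 = vapply(res, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 best_fits = lapply(res, `[[`, "fit")),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, digits = 3, ...) {
  cat("Relative support for local, landscape and combined model classes\n")
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
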