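# Derived analyses: standardized predicted impacts, the insecticide
# efficacy regression, and the post-hoc harvest-adaptation regression.

.INSECTICIDE_MONTHS <- c("insecticide_dec", "insecticide_jan",
                         "insecticide_feb", "insecticide_mar")

#' Baseline covariate profile for standardized predictions
#'
#' The reference field at which impacts are evaluated: continuous variables
#' and non-pesticide counts at their sample mean, ordinal and categorical
#' variables (including observer) at their sample mode (ties broken toward
#' the lower/first level), and every monthly insecticide count forced to
#' zero — a field with no pesticide applications, overriding the mean rule.
#'
#' @param fields Field-record data frame (non-empty).
#' @param registry Covariate registry.
#' @return A list of class `"baseline_profile"`: `values` (named list on
#'   the raw variable scale) and `notes` (rule applied per variable:
#'   `"mean"`, `"mode"` or `"zero"`).
#' @export
baseline_profile <- function(fields, registry = covariate_registry()) {
  if (!is.data.frame(fields) || nrow(fields) == 0L)
    stop_weevil("weevil_validation_error", "fields must be non-empty")
  mode_of <- function(v, levels) {
    tab <- table(factor(v, levels = levels))
    levels[[which.max(tab)]]  # first maximum: lower-level tie rule
  }
  values <- list()
  notes <- list()
  for (s in registry) {
    v <- fields[[s$name]]
    if (s$name %in% .INSECTICIDE_MONTHS) {
      values[[s$name]] <- 0
      notes[[s$name]] <- "zero"
    } else if (s$kind %in% c("continuous", "count")) {
      values[[s$name]] <- mean(v)
      notes[[s$name]] <- "mean"
    } else if (s$kind == "ordinal") {
      values[[s$name]] <- mode_of(v, s$levels)
      notes[[s$name]] <- "mode"
    } else {
      values[[s$name]] <- mode_of(v, s$levels)
      notes[[s$name]] <- "mode"
    }
  }
  values[["observer"]] <- mode_of(fields$observer, OBSERVER_LEVELS)
  notes[["observer"]] <- "mode"
  structure(list(values = values, notes = notes),
            class = "baseline_profile")
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat("Baseline profile (mean / mode / zero rules)\n")
  df <- data.frame(variable = names(x$values),
                   baseline = vapply(x$values, function(v)
                     if (is.numeric(v)) format(signif(v, 4)) else as.character(v),
                     character(1)),
                   rule = unlist(x$notes[names(x$values)]),
                   row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

# One-row data frame holding the baseline field on the raw scale.
.baseline_record <- function(profile, registry) {
  rec <- profile$values
  df <- data.frame(rec[names(registry)], stringsAsFactors = FALSE)
  names(df) <- names(registry)
  df$observer <- rec$observer
  df
}

#' Standardized predicted impacts of the averaged model
#'
#' Starting from the sqrt-scale prediction at the baseline profile (using
#' the shrinkage-averaged coefficients), each model variable is perturbed —
#' continuous variables and counts by +1 sample SD of the encoded column,
#' ordinal variables by +1 unit (the number of hillings by -1 unit, the
#' only direction keeping predictions within observed bounds), binary
#' indicators by +1 — and the impact reported as the difference of squared
#' (back-transformed) sqrt-scale predictions, in percentage points.
#' Variables with parameter weight below 1 are thereby attenuated in exact
#' proportion to their weight. Negative perturbed sqrt predictions are
#' clamped at zero with a warning.
#'
#' @param avg An `"averaged_parameters"` table (or a `"weevil_modavg"`).
#' @param profile A [baseline_profile()]; computed from `fields` if `NULL`.
#' @param fields Field-record data frame supplying SDs.
#' @param registry Covariate registry.
#' @param downward Variables perturbed by -1 unit (default
#'   `"n_hillings"`).
#' @return A data frame of class `"impact_estimates"`: `name`,
#'   `perturbation`, `delta_infestation` (percentage points).
#' @export
standardized_impacts <- function(avg, profile = NULL, fields,
                                 registry = covariate_registry(),
                                 downward = "n_hillings") {
  if (inherits(avg, "weevil_modavg")) avg <- avg$averages
  if (is.null(profile)) profile <- baseline_profile(fields, registry)
  base_rec <- .baseline_record(profile, registry)
  shrink <- avg$shrinkage
  names(shrink) <- avg$name
  shrink[is.na(shrink)] <- 0
  vars <- setdiff(avg$name, "(Intercept)")
  x0 <- drop(encode_covariates(base_rec, vars, registry))
  names(x0) <- vars
  b0 <- shrink[["(Intercept)"]] + sum(shrink[vars] * x0)
  Xall <- encode_covariates(fields, setdiff(vars, OBSERVER_INDICATORS),
                            registry)
  rows <- lapply(vars, function(v) {
    if (v %in% OBSERVER_INDICATORS) return(NULL)  # controls: no impact bar
    spec <- registry[[v]]
    if (spec$kind %in% c("continuous", "count")) {
      delta <- stats::sd(Xall[, v])
      lab <- "+1 SD"
    } else if (spec$kind == "ordinal") {
      delta <- if (v %in% downward) -1 else 1
      lab <- if (delta < 0) "-1 unit" else "+1 unit"
    } else {
      delta <- 1
      lab <- "+1 unit"
    }
    pert <- b0 + shrink[[v]] * delta
    if (pert < 0) {
      warn_weevil("perturbed sqrt-scale prediction for '%s' clamped at 0", v)
      pert <- 0
    }
    data.frame(name = v, perturbation = lab,
               delta_infestation = 100 * (min(1, pert)^2 - min(1, max(0, b0))^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline_sqrt") <- b0
  class(out) <- c("impact_estimates", "data.frame")
  out
}

#' @export
print.impact_estimates <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized predicted impacts (baseline sqrt prediction %.4f)\n",
              attr(x, "baseline_sqrt")))
  df <- as.data.frame(x)
  df$delta_infestation <- round(df$delta_infestation, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Insecticide-efficacy regression
#'
#' One multiple regression of the sqrt-scale infestation response on the
#' number of insecticide treatments applied in each month December-March.
#' Months with no variation (constant-zero counts) are dropped with a
#' warning to protect the design rank.
#'
#' @param fields Field-record data frame with the four monthly count
#'   columns.
#' @param registry Covariate registry.
#' @return A data frame of class `"insecticide_model"`: `month`,
#'   `estimate`, `se`; the underlying `"weevil_fit"` is attached as
#'   attribute `"fit"`.
#' @export
insecticide_model <- function(fields, registry = covariate_registry()) {
  miss <- setdiff(.INSECTICIDE_MONTHS, names(fields))
  if (length(miss))
    stop_weevil("weevil_validation_error",
                "missing monthly treatment column(s): %s",
                paste(miss, collapse = ", "))
  keep <- vapply(.INSECTICIDE_MONTHS, function(m)
    stats::var(fields[[m]]) > 0, logical(1))
  if (any(!keep))
    warn_weevil("dropping constant treatment column(s): %s",
                paste(.INSECTICIDE_MONTHS[!keep], collapse = ", "))
  vars <- .INSECTICIDE_MONTHS[keep]
  fit <- fit_ols(build_design(fields, vars, registry))
  est <- fit$coefficients[vars]
  se <- fit$se[vars]
  out <- data.frame(month = c("December", "January", "February", "March")[keep],
                    variable = vars, estimate = unname(est),
                    se = unname(se), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("insecticide_model", "data.frame")
  out
}

#' @export
print.insecticide_model <- function(x, digits = 4, ...) {
  cat("Per-treatment effect on sqrt-proportion infested, by month\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  df$se <- round(df$se, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Harvest-adaptation regression
#'
#' Post-hoc simple regression of the harvest day on model-expected
#' infestation: farmers expecting heavier infestations may harvest earlier,
#' masking a protective effect of early harvest in observational records.
#'
#' @param fields Field-record data frame (needs `harvest_day`).
#' @param expected Model-predicted infestations, one per field.
#' @return A list of class `"harvest_adaptation"`: `intercept`, `slope`,
#'   `se_slope`, `df` (n - 2), `p` (two-sided), `se_intercept`.
#' @export
harvest_adaptation <- function(fields, expected) {
  if (is.null(fields$harvest_day))
    stop_weevil("weevil_validation_error", "harvest_day column is required")
  y <- as.numeric(fields$harvest_day)
  if (length(expected) != length(y))
    stop_weevil("weevil_validation_error",
                "expected must have one value per field")
  if (stats::var(expected) <= 0)
    stop_weevil("weevil_validation_error",
                "expected infestations have zero variance")
  X <- cbind(`(Intercept)` = 1, expected = expected)
  fit <- fit_ols(list(X = X, y = y, variables = "expected"))
  df <- fit$n - 2L
  tval <- fit$coefficients[["expected"]] / fit$se[["expected"]]
  p <- if (fit$rss == 0 || !is.finite(tval)) 0 else 2 * stats::pt(-abs(tval), df)
  structure(list(intercept = fit$coefficients[["(Intercept)"]],
                 slope = fit$coefficients[["expected"]],
                 se_slope = fit$se[["expected"]],
                 se_intercept = fit$se[["(Intercept)"]],
                 df = df, p = p),
            class = "harvest_adaptation")
}

#' @export
print.harvest_adaptation <- function(x, ...) {
  cat(sprintf("harvest day = %.2f %+.2f * expected infestation (d.f. = %d, P = %.3g)\n",
              x$intercept, x$slope, x$df, x$p))
  invisible(x)
}
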