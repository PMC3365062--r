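# Forward AIC-guided construction of the global (least parsimonious)
# model, with a tolerance rule: keep adding past the AIC minimum as long as
# the model stays within `tolerance` of the lowest AIC reached.

#' Best next variable by AIC
#'
#' Fits the current model plus each pool candidate and returns the candidate
#' whose addition yields the lowest AIC. Ties break by pool order;
#' candidates making the design rank deficient are skipped with a warning.
#'
#' @param fields Field-record data frame.
#' @param current Character vector of variables already in the model.
#' @param pool Character vector of candidate variables (ordered).
#' @param registry Covariate registry.
#' @param corrected Use AICc.
#' @return A list with `variable` and `aic`.
#' @export
next_best_variable <- function(fields, current, pool,
                               registry = covariate_registry(),
                               corrected = FALSE) {
  if (!length(pool))
    stop_weevil("weevil_no_candidate_error", "candidate pool is empty")
  base <- build_design(fields, current, registry)
  aics <- vapply(pool, function(v) {
    xc <- encode_covariates(fields, v, registry)
    .aic_quick(cbind(base$X, xc), base$y, corrected)
  }, numeric(1))
  if (any(is.na(aics)))
    warn_weevil("skipping rank-deficient candidate(s): %s",
                paste(pool[is.na(aics)], collapse = ", "))
  if (all(is.na(aics)))
    stop_weevil("weevil_no_candidate_error",
                "every candidate yields a rank-deficient design")
  best <- which.min(aics)  # first minimum: pool-order tie-break
  list(variable = pool[best], aic = aics[[best]])
}

#' Build the global model by forward selection with an AIC tolerance
#'
#' Starts from the intercept-only model and repeatedly adds the variable
#' that lowers AIC the most. Additions continue past the AIC minimum: a
#' variable is admitted as long as the resulting model's AIC does not exceed
#' the lowest AIC reached so far by more than `tolerance` (default 2.0, the
#' conventional band of similarly-supported models). With `tolerance = 0`
#' this is classical forward selection stopping at the first AIC increase.
#'
#' @param fields Field-record data frame.
#' @param pool Ordered candidate variables (registry names and/or observer
#'   indicators `observer_2`..`observer_4`).
#' @param tolerance Nonnegative AIC tolerance above the running minimum.
#' @param registry Covariate registry.
#' @param corrected Use AICc.
#' @return A list of class `"step_trajectory"`: `steps` (data frame with
#'   `variable`, `aic`, `cum_delta` — cumulative AIC change from the
#'   intercept-only model), `selected`, `aic_intercept`, `aic_min`.
#' @export
build_global_model <- function(fields, pool, tolerance = 2,
                               registry = covariate_registry(),
                               corrected = FALSE) {
  if (!is.numeric(tolerance) || tolerance < 0)
    stop_weevil("weevil_validation_error", "tolerance must be >= 0")
  d0 <- build_design(fields, character(), registry)
  aic0 <- .aic_quick(d0$X, d0$y, corrected)
  current <- character()
  remaining <- pool
  steps <- data.frame(variable = character(), aic = numeric(),
                      cum_delta = numeric(), stringsAsFactors = FALSE)
  aic_min <- aic0
  skipped <- character()
  while (length(remaining)) {
    cand <- withCallingHandlers(
      tryCatch(
        next_best_variable(fields, current, remaining, registry, corrected),
        weevil_no_candidate_error = function(e) NULL),
      warning = function(w) {
        m <- regmatches(conditionMessage(w),
                        regexpr("(?<=: ).*$", conditionMessage(w), perl = TRUE))
        if (length(m))
          skipped <<- union(skipped, strsplit(m, ", ", fixed = TRUE)[[1]])
        invokeRestart("muffleWarning")
      })
    if (is.null(cand)) break
    if (cand$aic > aic_min + tolerance) break
    current <- c(current, cand$variable)
    remaining <- setdiff(remaining, cand$variable)
    steps <- rbind(steps, data.frame(variable = cand$variable,
                                     aic = cand$aic,
                                     cum_delta = cand$aic - aic0,
                                     stringsAsFactors = FALSE))
    aic_min <- min(aic_min, cand$aic)
  }
  if (length(skipped))
    warn_weevil("skipped rank-deficient candidate(s): %s",
                paste(skipped, collapse = ", "))
  structure(list(steps = steps, selected = current,
                 aic_intercept = aic0, aic_min = aic_min,
                 tolerance = tolerance, corrected = corrected),
            class = "step_trajectory")
}

#' @export
print.step_trajectory <- function(x, ...) {
  cat(sprintf("Forward AIC trajectory: %d variables selected (tolerance %.1f)\n",
              length(x$selected), x$tolerance))
  cat(sprintf("  intercept-only AIC %.2f, minimum reached %.2f (reduction %.2f)\n",
              x$aic_intercept, x$aic_min, x$aic_intercept - x$aic_min))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' @export
plot.step_trajectory <- function(x, ...) {
  if (!nrow(x$steps)) {
    warn_weevil("empty trajectory; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(seq_len(nrow(x$steps)), -x$steps$cum_delta, type = "b",
                 xlab = "variables added", ylab = "cumulative AIC reduction",
                 main = "Forward stepwise global model", ...)
  imin <- which.min(x$steps$aic)
  graphics::abline(v = imin, lty = 2)
  invisible(x)
}
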