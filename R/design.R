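# Design-matrix construction with the analysis encodings: binary variables
# as 0/1 indicators against a fixed reference, observer as three indicator
# columns against obs1, elevation square-root transformed.

# Encode a set of variables (registry covariates and/or observer
# indicators) into a numeric matrix, one column per requested name, in the
# requested order. No intercept.
encode_covariates <- function(fields, variables,
                              registry = covariate_registry(),
                              transforms = NULL) {
  n <- nrow(fields)
  cols <- lapply(variables, function(v) {
    if (v %in% OBSERVER_INDICATORS) {
      lev <- paste0("obs", sub("observer_", "", v))
      return(as.numeric(fields$observer == lev))
    }
    spec <- registry[[v]]
    if (is.null(spec))
      stop_weevil("weevil_config_error", "unknown variable '%s'", v)
    if (is.null(fields[[v]])) {
      stop_weevil("weevil_validation_error",
                  "covariate '%s' missing from the table", v)
    }
    raw <- fields[[v]]
    if (any(is.na(raw))) {
      id <- if (!is.null(fields$field_id))
        as.character(fields$field_id[which(is.na(raw))[1]]) else "?"
      stop_weevil("weevil_validation_error",
                  "missing value for variable '%s' at field_id %s", v, id)
    }
    x <- if (spec$kind == "binary") {
      bad <- setdiff(unique(raw), spec$levels)
      if (length(bad))
        stop_weevil("weevil_validation_error",
                    "binary variable '%s' has unknown level(s): %s",
                    v, paste(bad, collapse = ", "))
      as.numeric(raw == spec$levels[2])
    } else {
      as.numeric(raw)
    }
    tr <- if (!is.null(transforms) && !is.null(transforms[[v]]))
      transforms[[v]] else spec$transform
    if (identical(tr, "sqrt")) {
      if (any(x < 0))
        stop_weevil("weevil_validation_error",
                    "cannot sqrt-transform negative values in '%s'", v)
      x <- sqrt(x)
    }
    x
  })
  X <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  colnames(X) <- variables
  X
}

#' Build a design matrix and response
#'
#' Expands the requested variables into numeric design columns: binary
#' variables become 0/1 indicators (reference level 0), `"observer"` expands
#' to three indicator columns against reference `obs1` (individual
#' indicators `observer_2`, `observer_3`, `observer_4` may also be requested
#' by name), ordinal variables enter as numeric scores, and registry
#' transforms (elevation: square root) are applied unless overridden via
#' `transforms`. An intercept column is prepended and the column order is
#' deterministic (request order).
#'
#' @param fields Field-record data frame.
#' @param variables Character vector of variable names (possibly empty for
#'   an intercept-only design).
#' @param registry Covariate registry.
#' @param transforms Optional named list overriding per-variable transforms
#'   (`"identity"` or `"sqrt"`).
#' @param response Logical; if `TRUE` (default) compute the sqrt-scale
#'   response via [compute_response()].
#' @return A list of class `"weevil_design"` with elements `X` (n x p
#'   matrix, intercept first), `y` (or `NULL`), and `variables` (the
#'   expanded column names, excluding the intercept).
#' @export
build_design <- function(fields, variables = character(),
                         registry = covariate_registry(),
                         transforms = NULL, response = TRUE) {
  expanded <- unlist(lapply(variables, function(v) {
    if (identical(v, "observer")) OBSERVER_INDICATORS else v
  }), use.names = FALSE)
  if (is.null(expanded)) expanded <- character()
  if (anyDuplicated(expanded))
    stop_weevil("weevil_config_error", "duplicated variable(s): %s",
                paste(unique(expanded[duplicated(expanded)]), collapse = ", "))
  Xv <- encode_covariates(fields, expanded, registry, transforms)
  X <- cbind(`(Intercept)` = rep(1, nrow(fields)), Xv)
  y <- if (response) compute_response(fields) else NULL
  structure(list(X = X, y = y, variables = expanded),
            class = "weevil_design")
}

#' @export
print.weevil_design <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows, %d columns (intercept + %d variables)\n",
              nrow(x$X), ncol(x$X), length(x$variables)))
  if (length(x$variables)) cat(" ", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}
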