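# Covariate registry: the field-survey variables, their survey summary
# statistics (used for synthesis), encodings and true effect sizes on the
# sqrt-proportion scale used by the default generator truth.

#' Construct a covariate specification
#'
#' A covariate spec describes one field-record variable: how it is
#' distributed across fields (for synthesis), how it enters design matrices
#' (encoding and optional transform), which predictor class it belongs to,
#' and its default true effect on the square-root infestation scale.
#'
#' @param name Variable name (unique, used as the table column name).
#' @param kind One of `"continuous"`, `"count"`, `"binary"`, `"ordinal"`.
#' @param category Predictor class: `"chemical"`, `"cultural"`,
#'   `"geographic"`, `"host"`, `"soil"` or `"landscape"`.
#' @param mean,sd Marginal mean and SD (continuous), or mean rate (count).
#' @param levels For binary: `c(reference, indicator)` level labels; for
#'   ordinal: numeric levels.
#' @param level_probs Ordinal level probabilities (sum to 1), or for binary
#'   the probability of the indicator level (scalar).
#' @param transform `"identity"` or `"sqrt"` (applied when the variable
#'   enters a design matrix).
#' @param true_beta Default generative effect per unit of the encoded
#'   (possibly transformed) variable; 0 for variables with no supported
#'   effect.
#' @param lower Lower support bound for continuous variables (default 0).
#' @return A list of class `"covariate_spec"`.
#' @export
covariate_spec <- function(name, kind, category,
                           mean = NA_real_, sd = NA_real_,
                           levels = NULL, level_probs = NULL,
                           transform = "identity", true_beta = 0,
                           lower = 0) {
  kind <- match.arg(kind, c("continuous", "count", "binary", "ordinal"))
  category <- match.arg(category, c("chemical", "cultural", "geographic",
                                    "host", "soil", "landscape"))
  transform <- match.arg(transform, c("identity", "sqrt"))
  if (kind == "continuous") {
    if (!is.finite(mean) || !is.finite(sd) || sd < 0)
      stop_weevil("weevil_validation_error",
                  "continuous covariate '%s' needs finite mean and sd >= 0", name)
  }
  if (kind == "count" && (!is.finite(mean) || mean < 0))
    stop_weevil("weevil_validation_error",
                "count covariate '%s' needs a nonnegative rate", name)
  if (kind == "binary") {
    if (is.null(levels) || length(levels) != 2L)
      stop_weevil("weevil_validation_error",
                  "binary covariate '%s' needs levels c(reference, indicator)", name)
    p <- level_probs
    if (is.null(p) || length(p) != 1L || p < 0 || p > 1)
      stop_weevil("weevil_validation_error",
                  "binary covariate '%s' needs an indicator probability in [0,1]", name)
  }
  if (kind == "ordinal") {
    if (is.null(levels) || is.null(level_probs) ||
        length(levels) != length(level_probs))
      stop_weevil("weevil_validation_error",
                  "ordinal covariate '%s' needs matching levels and probabilities", name)
    if (any(level_probs < 0) || abs(sum(level_probs) - 1) > 1e-8)
      stop_weevil("weevil_validation_error",
                  "ordinal probabilities for '%s' must be nonnegative and sum to 1", name)
  }
  spec <- structure(list(name = name, kind = kind, category = category,
                         mean = mean, sd = sd, levels = levels,
                         level_probs = level_probs, transform = transform,
                         true_beta = true_beta, lower = lower),
                    class = "covariate_spec")
  .synth_params(spec)
}

# Moment-matched parameters (mu, sigma) of a normal left-truncated at
# `lower` whose truncated mean/SD equal the targets. A left-truncated
# normal cannot exceed CV 1 relative to the bound, so feasibility is the
# caller's concern (see .synth_params).
.trunc_norm_params <- function(m, s, lower = 0) {
  if ((m - lower) / s > 6) return(c(mu = m, sigma = s))
  moments <- function(mu, sg) {
    a <- (lower - mu) / sg
    lam <- exp(stats::dnorm(a, log = TRUE) -
               stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    mt <- mu + sg * lam
    vt <- sg^2 * (1 + a * lam - lam^2)
    c(mt, sqrt(max(vt, 0)))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo[1] - m)^2 / s^2 + (mo[2] - s)^2 / s^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 10000))
  mo <- moments(fit$par[1], exp(fit$par[2]))
  if (max(abs(mo - c(m, s)) / s) > 1e-4)
    stop_weevil("weevil_validation_error",
                "cannot moment-match a truncated normal to mean %.3g sd %.3g", m, s)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Decide and cache the synthesis distribution for a continuous covariate.
# High-CV nonnegative variables get a moment-matched gamma (a left-truncated
# normal cannot reach CV >= 1); the rest get a moment-matched truncated
# normal so sample moments reproduce the survey table.
.synth_params <- function(spec) {
  if (spec$kind != "continuous") return(spec)
  if (spec$sd >= 0.95 * (spec$mean - spec$lower)) {
    spec$synth_family <- "gamma"
    m <- spec$mean - spec$lower
    spec$gamma_shape <- (m / spec$sd)^2
    spec$gamma_rate <- m / spec$sd^2
  } else {
    spec$synth_family <- "truncnorm"
    pars <- .trunc_norm_params(spec$mean, spec$sd, spec$lower)
    spec$tn_mu <- pars[["mu"]]
    spec$tn_sigma <- pars[["sigma"]]
  }
  spec
}

.registry_cache <- new.env(parent = emptyenv())

#' Default covariate registry
#'
#' The registry of all field-survey covariates: chemical control, cultural
#' management, geographic, host, soil and landscape variables, with their
#' survey means/SDs or modes, design-matrix encodings and the default true
#' effects used by the synthetic generator (zero for variables with no
#' supported effect). Binary variables are stored as text levels and encode
#' to a 0/1 indicator (reference level 0); elevation enters design matrices
#' square-root transformed.
#'
#' @return A list of [covariate_spec()] objects, of class
#'   `"covariate_registry"`.
#' @export
covariate_registry <- function() {
  if (!is.null(.registry_cache$registry)) return(.registry_cache$registry)
  f <- function(...) covariate_spec(...)
  n <- 138
  specs <- list(
    # chemical control
    f("carbofuran", "binary", "chemical", levels = c("no", "yes"),
      level_probs = 32 / n),
    f("insecticide_dec", "count", "chemical", mean = 0.51, true_beta = -0.054),
    f("insecticide_jan", "count", "chemical", mean = 1.12, true_beta = -0.053),
    f("insecticide_feb", "count", "chemical", mean = 0.34),
    f("insecticide_mar", "count", "chemical", mean = 0.02),
    # cultural
    f("ash", "binary", "cultural", levels = c("no", "yes"),
      level_probs = 4 / n),
    f("chem_fert", "continuous", "cultural", mean = 8.13, sd = 7.03,
      true_beta = -0.002),
    f("day_first_hilling", "continuous", "cultural", mean = 104.10, sd = 8.57),
    f("harvest_day", "continuous", "cultural", mean = 201.34, sd = 9.50),
    f("height_first_hilling", "continuous", "cultural", mean = 18.30,
      sd = 3.79, true_beta = -0.006),
    f("height_row_harvest", "continuous", "cultural", mean = 29.02, sd = 5.17,
      true_beta = -0.005),
    f("manure", "continuous", "cultural", mean = 75.87, sd = 21.80),
    f("n_hillings", "ordinal", "cultural", levels = 1:3,
      level_probs = c(5, 131, 2) / n, true_beta = 0.127),
    f("perimeter_area", "continuous", "cultural", mean = 0.26, sd = 0.10,
      true_beta = 0.519, lower = 0.03),
    f("planting_day", "continuous", "cultural", mean = 48.96, sd = 8.39),
    f("plants_per_5m", "continuous", "cultural", mean = 14.81, sd = 1.74),
    f("rotation2006", "binary", "cultural", levels = c("potato", "other"),
      level_probs = 114 / n, true_beta = 0.030),
    f("rotation2007", "binary", "cultural", levels = c("potato", "other"),
      level_probs = 136 / n, true_beta = -0.096),
    f("row_distance", "continuous", "cultural", mean = 95.35, sd = 11.72),
    f("weed_removal", "binary", "cultural", levels = c("no", "yes"),
      level_probs = 75 / n),
    # geographic
    f("elevation", "continuous", "geographic", mean = 3747, sd = 148.40,
      transform = "sqrt", true_beta = -0.031),
    f("slope", "continuous", "geographic", mean = 23.04, sd = 10.79),
    # host
    f("cultivar", "binary", "host", levels = c("yungay", "larga"),
      level_probs = 51 / n),
    # soil
    f("clay", "continuous", "soil", mean = 21.08, sd = 5.71,
      true_beta = 0.005),
    f("loam", "continuous", "soil", mean = 34.01, sd = 8.01),
    f("sand", "continuous", "soil", mean = 44.91, sd = 9.62),
    f("soil_k", "continuous", "soil", mean = 331.58, sd = 201.75),
    f("soil_p", "continuous", "soil", mean = 28.22, sd = 21.94),
    f("organic_matter", "continuous", "soil", mean = 5.87, sd = 2.38,
      true_beta = -0.012),
    f("ph", "continuous", "soil", mean = 4.97, sd = 0.98),
    # landscape
    f("nb_current_potato", "continuous", "landscape", mean = 8.79, sd = 9.71,
      true_beta = -0.004),
    f("nb_previous_potato", "continuous", "landscape", mean = 4.08, sd = 4.32,
      true_beta = 0.007),
    f("storage_units", "count", "landscape", mean = 1.01, true_beta = 0.044)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop_weevil("weevil_validation_error", "registry names must be unique")
  reg <- structure(specs, class = "covariate_registry")
  .registry_cache$registry <- reg
  reg
}

#' @export
print.covariate_registry <- function(x, ...) {
  df <- registry_table(x)
  cat(sprintf("Covariate registry: %d variables\n", nrow(df)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Registry as a data frame
#'
#' @param registry A [covariate_registry()].
#' @return A data frame with one row per covariate.
#' @export
registry_table <- function(registry = covariate_registry()) {
  data.frame(
    name = vapply(registry, `[[`, character(1), "name"),
    kind = vapply(registry, `[[`, character(1), "kind"),
    category = vapply(registry, `[[`, character(1), "category"),
    mean = vapply(registry, function(s) {
      if (s$kind == "binary") s$level_probs
      else if (s$kind == "ordinal") sum(s$levels * s$level_probs)
      else s$mean
    }, numeric(1)),
    sd = vapply(registry, function(s) if (is.na(s$sd)) NA_real_ else s$sd,
                numeric(1)),
    transform = vapply(registry, `[[`, character(1), "transform"),
    true_beta = vapply(registry, `[[`, numeric(1), "true_beta"),
    row.names = NULL
  )
}

# Expected value of each covariate on its encoded (design-matrix) scale.
# Used to derive the default intercept. For sqrt transforms a second-order
# delta correction of E[sqrt(X)] is used.
expected_encoded <- function(registry = covariate_registry()) {
  vapply(registry, function(s) {
    switch(s$kind,
      continuous = if (s$transform == "sqrt")
        sqrt(s$mean) * (1 - s$sd^2 / (8 * s$mean^2)) else s$mean,
      count = s$mean,
      binary = s$level_probs,
      ordinal = sum(s$levels * s$level_probs)
    )
  }, numeric(1))
}
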