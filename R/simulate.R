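# Synthetic field-record generator emulating the observational study design:
# n fields surveyed by a small team of observers across four village
# clusters, with edge/center infestation strata and the full covariate set.

# Village-like cluster centers (meters, planar); max pairwise distance
# ~2.1 km, within the 3 km correlogram design.
.CLUSTER_CENTERS <- matrix(c(0, 0, 1500, 0, 0, 1500, 1500, 1500),
                           ncol = 2, byrow = TRUE)
.CLUSTER_SD <- 300

# Stratum infestation ratios relative to the field mean (edge fields carry
# more damage than centers: study means 25.1% edge, 16.1% center, 18.3%
# overall).
.EDGE_RATIO <- 25.1 / 18.3
.CENTER_RATIO <- 16.1 / 18.3

# Draw one covariate; continuous margins are inverted from a uniform so a
# Gaussian copula can impose cross-covariate correlation when requested.
.draw_covariate <- function(spec, n, u = NULL) {
  switch(spec$kind,
    continuous = {
      if (is.null(u)) u <- stats::runif(n)
      if (spec$synth_family == "gamma") {
        spec$lower + stats::qgamma(u, shape = spec$gamma_shape,
                                   rate = spec$gamma_rate)
      } else {
        # inverse-CDF truncated normal: exact and vectorized
        plo <- stats::pnorm(spec$lower, spec$tn_mu, spec$tn_sigma)
        stats::qnorm(plo + u * (1 - plo), spec$tn_mu, spec$tn_sigma)
      }
    },
    count = stats::rpois(n, spec$mean),
    binary = ifelse(stats::runif(n) < spec$level_probs,
                    spec$levels[2], spec$levels[1]),
    ordinal = sample(spec$levels, n, replace = TRUE, prob = spec$level_probs)
  )
}

# Correlated uniforms for the named continuous covariates via a Gaussian
# copula; identity correlation reproduces independent draws.
.copula_uniforms <- function(correlation, n) {
  nms <- colnames(correlation)
  if (is.null(nms) || !identical(nms, rownames(correlation)))
    stop_weevil("weevil_config_error",
                "correlation must have matching row/column names")
  if (any(abs(correlation - t(correlation)) > 1e-12) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    stop_weevil("weevil_validation_error",
                "correlation must be symmetric with unit diagonal")
  L <- tryCatch(chol(correlation), error = function(e)
    stop_weevil("weevil_validation_error",
                "correlation matrix is not positive definite"))
  Z <- matrix(stats::rnorm(n * ncol(correlation)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- nms
  U
}

# Near-equal observer block sizes: first (n mod k) observers get one extra.
.observer_blocks <- function(n_fields, n_observers) {
  base <- n_fields %/% n_observers
  extra <- n_fields %% n_observers
  sizes <- base + as.integer(seq_len(n_observers) <= extra)
  rep(paste0("obs", seq_len(n_observers)), times = sizes)
}

#' Generate a synthetic field-record table
#'
#' Draws covariates independently from the registry's synthesis
#' distributions, assigns fields to observers in near-equal blocks (one
#' village cluster per observer), and builds the infestation response on the
#' square-root scale as intercept + sum(beta * x) + observer offset +
#' Gaussian(0, sigma), squared into a field-level infested proportion. The
#' field proportion is split into edge and center strata (edges inflated,
#' centers deflated, renormalized to preserve the area-weighted field mean),
#' with areas drawn to match the study's field-size distribution and the
#' edge share tied to the field's perimeter-to-area ratio via the square
#' ring approximation 3r - 2.25 r^2.
#'
#' @param n_fields Number of fields (default 138).
#' @param n_observers Number of observers (default 4; at most `n_fields`).
#' @param truth A [truth_record()]; defaults to [default_truth()].
#' @param registry A [covariate_registry()].
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @param correlation Optional correlation matrix (Gaussian copula) over a
#'   subset of the continuous covariates, with matching row/column names;
#'   the default (`NULL`) draws all covariates independently. The survey
#'   reports only marginal moments, so independence is the default
#'   assumption.
#' @return A data frame with columns `field_id`, `observer`, `x`, `y`,
#'   `edge_area`, `center_area`, `edge_infested`, `center_infested` and one
#'   column per registry covariate. The truth record used is attached as
#'   attribute `"truth"`.
#' @export
simulate_fields <- function(n_fields = 138, n_observers = 4,
                            truth = default_truth(),
                            registry = covariate_registry(), seed = NULL,
                            correlation = NULL) {
  if (!is_count(n_fields) || !is_count(n_observers) || n_fields < n_observers)
    stop_weevil("weevil_validation_error",
                "need n_fields >= n_observers >= 1")
  if (!inherits(truth, "truth_record"))
    stop_weevil("weevil_validation_error", "truth must be a truth_record")
  if (!length(registry))
    stop_weevil("weevil_validation_error", "registry must be non-empty")
  unknown <- setdiff(names(truth$betas), names(registry))
  if (length(unknown))
    stop_weevil("weevil_config_error",
                "truth betas name unknown covariate(s): %s",
                paste(unknown, collapse = ", "))
  if (truth$sigma <= 0)
    stop_weevil("weevil_validation_error", "sigma must be > 0")
  if (!is.null(seed)) set.seed(seed)

  observer <- .observer_blocks(n_fields, n_observers)
  cl <- ((match(observer, paste0("obs", seq_len(n_observers))) - 1) %% 4) + 1
  x <- .CLUSTER_CENTERS[cl, 1] + stats::rnorm(n_fields, 0, .CLUSTER_SD)
  y <- .CLUSTER_CENTERS[cl, 2] + stats::rnorm(n_fields, 0, .CLUSTER_SD)

  U <- NULL
  if (!is.null(correlation)) {
    bad <- setdiff(colnames(correlation), names(registry))
    if (length(bad))
      stop_weevil("weevil_config_error",
                  "correlation names unknown: %s", paste(bad, collapse = ", "))
    kinds <- vapply(registry[colnames(correlation)], `[[`, character(1), "kind")
    if (any(kinds != "continuous"))
      stop_weevil("weevil_config_error",
                  "correlation hook covers continuous covariates only")
    U <- .copula_uniforms(correlation, n_fields)
  }
  cov_cols <- lapply(registry, function(s)
    .draw_covariate(s, n_fields,
                    u = if (!is.null(U) && s$name %in% colnames(U))
                      U[, s$name] else NULL))
  covs <- as.data.frame(cov_cols, stringsAsFactors = FALSE)

  # linear predictor on the sqrt-proportion scale
  lp <- rep(truth$intercept, n_fields)
  if (length(truth$betas)) {
    X <- encode_covariates(covs, names(truth$betas), registry)
    lp <- lp + drop(X %*% truth$betas)
  }
  offs <- truth$observer_effects
  lp <- lp + unname(offs[observer])
  y_sqrt <- lp + stats::rnorm(n_fields, 0, truth$sigma)
  p_field <- pmin(1, pmax(0, y_sqrt))^2

  # field geometry: total area ~ study distribution; edge share from the
  # square-ring approximation given the perimeter/area ratio
  ap <- .trunc_norm_params(424.6, 282.4, lower = 30)
  plo <- stats::pnorm(30, ap[["mu"]], ap[["sigma"]])
  total_area <- stats::qnorm(stats::runif(n_fields, plo, 1),
                             ap[["mu"]], ap[["sigma"]])
  r <- covs$perimeter_area
  edge_frac <- if (is.null(r)) rep(0.5, n_fields) else
    pmin(0.95, pmax(0.05, 3 * r - 2.25 * r^2))
  edge_area <- edge_frac * total_area
  center_area <- total_area - edge_area

  # split field proportion into strata preserving the area-weighted mean
  denom <- (.EDGE_RATIO * edge_area + .CENTER_RATIO * center_area) / total_area
  edge_inf <- pmin(1, p_field * .EDGE_RATIO / denom)
  center_inf <- pmin(1, p_field * .CENTER_RATIO / denom)

  fields <- data.frame(
    field_id = sprintf("F%03d", seq_len(n_fields)),
    observer = observer,
    x = x, y = y,
    edge_area = edge_area, center_area = center_area,
    edge_infested = edge_inf, center_infested = center_inf,
    covs,
    stringsAsFactors = FALSE
  )
  attr(fields, "truth") <- truth
  fields
}

#' Calibrate the generator's residual SD to a target explained-variance band
#'
#' Searches (by bisection on log sigma) for the residual SD at which the
#' median best-model R-squared over `n_reps` simulated datasets falls inside
#' `target_r2_band`. "Best model" is the minimum-AIC model from the
#' all-subsets enumeration of the forward-stepwise global variables — the
#' same quantity the analysis pipeline reports.
#'
#' @param registry Covariate registry.
#' @param truth Truth record supplying betas/intercept/offsets; its sigma is
#'   ignored (the search variable).
#' @param target_r2_band Numeric length-2 interval within (0, 1).
#' @param n_reps Simulated datasets per evaluation (median taken).
#' @param seed Integer seed controlling all replicate simulations.
#' @param n_fields,n_observers Dataset dimensions per replicate.
#' @param tolerance Stepwise AIC tolerance passed to
#'   [build_global_model()].
#' @param max_iter Maximum bisection iterations.
#' @return The calibrated sigma, with attribute `"median_r2"`.
#' @export
calibrate_sigma <- function(registry = covariate_registry(),
                            truth = default_truth(registry = registry),
                            target_r2_band = c(0.402, 0.464),
                            n_reps = 20, seed = 1,
                            n_fields = 138, n_observers = 4,
                            tolerance = 2, max_iter = 12) {
  if (length(target_r2_band) != 2L || any(!is.finite(target_r2_band)) ||
      target_r2_band[1] <= 0 || target_r2_band[2] >= 1 ||
      target_r2_band[1] >= target_r2_band[2])
    stop_weevil("weevil_validation_error",
                "target_r2_band must be an increasing interval within (0,1)")
  if (!is_count(n_reps))
    stop_weevil("weevil_validation_error", "n_reps must be a positive integer")

  pool <- c(names(registry), OBSERVER_INDICATORS[seq_len(n_observers - 1)])
  measure <- function(sigma) {
    tr <- truth
    tr$sigma <- sigma
    r2 <- vapply(seq_len(n_reps), function(r) {
      fields <- simulate_fields(n_fields, n_observers, tr, registry,
                                seed = seed + 7919L * r)
      traj <- build_global_model(fields, pool, tolerance = tolerance,
                                 registry = registry)
      if (!length(traj$selected)) return(0)
      # at extreme noise the stepwise stage can select more variables than
      # the enumeration cap admits; keep the strongest (earliest-added)
      sel <- utils::head(traj$selected, 24L)
      ms <- enumerate_and_fit(fields, sel, registry = registry, force = TRUE)
      best <- which.min(ms$table$aic)
      ms$table$r2[best]
    }, numeric(1))
    stats::median(r2)
  }

  no_signal <- all(truth$betas == 0) && all(truth$observer_effects == 0)
  # signal-variance guess from one large noise-free-ish draw
  tr0 <- truth
  tr0$sigma <- 1e-6
  big <- simulate_fields(max(1000L, n_fields), n_observers, tr0, registry,
                         seed = seed)
  v_signal <- stats::var(compute_response(big))
  if (no_signal || v_signal < 1e-10) {
    med <- measure(0.05)
    if (med >= target_r2_band[1] && med <= target_r2_band[2])
      return(structure(0.05, median_r2 = med))
    stop_weevil("weevil_calibration_error",
                paste0("explained variance does not depend on sigma without ",
                       "signal; achievable median R^2 is about %.3f"), med)
  }
  # start at the analytic guess (R^2 = V / (V + sigma^2) at the band
  # midpoint) and expand the bracket only toward the side that needs it:
  # the explained-variance curve is monotone decreasing in sigma
  mid <- mean(target_r2_band)
  s <- sqrt(v_signal * (1 - mid) / mid)
  med <- measure(s)
  if (med >= target_r2_band[1] && med <= target_r2_band[2])
    return(structure(s, median_r2 = med))
  lo <- hi <- s
  med_lo <- med_hi <- med
  tries <- 0L
  while (med_hi > target_r2_band[2] && tries < 8L) {   # too little noise
    hi <- hi * 1.6
    med_hi <- measure(hi)
    tries <- tries + 1L
  }
  tries <- 0L
  while (med_lo < target_r2_band[1] && tries < 8L) {   # too much noise
    lo <- lo / 1.6
    med_lo <- measure(lo)
    tries <- tries + 1L
  }
  if (med_hi >= target_r2_band[1] && med_hi <= target_r2_band[2])
    return(structure(hi, median_r2 = med_hi))
  if (med_lo >= target_r2_band[1] && med_lo <= target_r2_band[2])
    return(structure(lo, median_r2 = med_lo))
  if (med_lo < target_r2_band[1] || med_hi > target_r2_band[2])
    stop_weevil("weevil_calibration_error",
                "band (%.3f, %.3f) unreachable; achievable median R^2 spans about (%.3f, %.3f)",
                target_r2_band[1], target_r2_band[2], med_hi, med_lo)
  for (i in seq_len(max_iter)) {
    sig <- sqrt(lo * hi)
    med <- measure(sig)
    if (med >= target_r2_band[1] && med <= target_r2_band[2])
      return(structure(sig, median_r2 = med))
    if (med > target_r2_band[2]) lo <- sig else hi <- sig
  }
  stop_weevil("weevil_calibration_error",
              "bisection did not land in the band after %d iterations (last median R^2 %.3f)",
              max_iter, med)
}
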