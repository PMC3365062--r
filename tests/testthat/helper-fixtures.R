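# Fixtures built in code: small registries, hand-made field tables, and a
# quick simulator wrapper. All fixtures are deterministic given a seed.

# A compact registry of continuous covariates x1..xp (mean 0 would break the
# nonnegativity support, so means are comfortably positive).
make_registry <- function(p, means = rep(10, p), sds = rep(2, p),
                          betas = rep(0, p), category = "cultural") {
  specs <- lapply(seq_len(p), function(j)
    covariate_spec(paste0("x", j), "continuous", category,
                   mean = means[j], sd = sds[j], true_beta = betas[j]))
  names(specs) <- paste0("x", seq_len(p))
  structure(specs, class = "covariate_registry")
}

# Hand-made field table around given covariate columns and a target
# sqrt-scale response (stored as equal edge/center proportions so
# compute_response() returns it exactly).
make_fields <- function(covs, y_sqrt, observer = NULL) {
  n <- nrow(covs)
  stopifnot(length(y_sqrt) == n, all(y_sqrt >= 0 & y_sqrt <= 1))
  if (is.null(observer)) observer <- rep(paste0("obs", 1:4), length.out = n)
  data.frame(field_id = sprintf("T%03d", seq_len(n)),
             observer = observer,
             x = seq_len(n) * 100, y = rev(seq_len(n)) * 100,
             edge_area = rep(50, n), center_area = rep(150, n),
             edge_infested = y_sqrt^2, center_infested = y_sqrt^2,
             covs, stringsAsFactors = FALSE)
}

# Simulated table from a small registry with chosen betas and noise. The
# intercept is centered so the mean sqrt-scale response sits at 0.5 (the
# covariates have mean 10), keeping the linear predictor inside [0, 1] and
# the response clear of the clipping bounds.
quick_sim <- function(n = 60, p = 3, betas = rep(0, p), sigma = 0.05,
                      seed = 1, intercept = NULL) {
  reg <- make_registry(p, betas = betas)
  b <- betas
  names(b) <- names(reg)
  if (is.null(intercept)) intercept <- 0.5 - sum(betas) * 10
  truth <- truth_record(betas = b[b != 0], intercept = intercept,
                        sigma = sigma, registry = reg)
  simulate_fields(n_fields = n, n_observers = 4, truth = truth,
                  registry = reg, seed = seed)
}

# Independently coded all-subsets search: QR fits via stats::lm.fit over
# subsets enumerated with utils::combn, scored by the same criterion
# definition written out directly. Returns the best subset (sorted).
brute_force_best <- function(X, y) {
  p <- ncol(X)
  n <- length(y)
  best_aic <- Inf
  best <- NULL
  for (k in seq_len(p)) {
    combos <- utils::combn(p, k)
    for (c_i in seq_len(ncol(combos))) {
      j <- combos[, c_i]
      fit <- stats::lm.fit(cbind(1, X[, j, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      K <- k + 2  # coefficients incl. intercept, + residual variance
      a <- n * log(rss / n) + 2 * K
      if (a < best_aic) {
        best_aic <- a
        best <- sort(j)
      }
    }
  }
  list(best = best, aic = best_aic)
}

# Hand-built confidence set (for averaging arithmetic tests).
make_cset <- function(weights, fits, variables) {
  structure(list(table = data.frame(mask = seq_along(weights),
                                    weight = weights),
                 variables = variables, fits = fits, n = NA_integer_),
            class = c("confidence_set", "model_set"))
}
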