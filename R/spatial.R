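# Moran's I and a binned permutation correlogram of model residuals.

#' Moran's I for a binary neighbor relation
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` over i != j, with
#' `S0` the sum of the weights. The input is centered internally; its
#' expectation under no autocorrelation is `-1 / (n - 1)`.
#'
#' @param z Numeric vector.
#' @param w Symmetric 0/1 neighbor matrix with zero diagonal.
#' @return Moran's I.
#' @export
moran_i <- function(z, w) {
  n <- length(z)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
    stop_weevil("weevil_validation_error", "w must be an n x n matrix")
  if (any(w != t(w)) || any(diag(w) != 0))
    stop_weevil("weevil_validation_error",
                "w must be symmetric with zero diagonal")
  s0 <- sum(w)
  if (s0 <= 0)
    stop_weevil("weevil_undefined_error", "no pairs in the neighbor relation")
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom <= 0)
    stop_weevil("weevil_undefined_error",
                "Moran's I undefined for a constant vector")
  (n / s0) * drop(crossprod(zc, w %*% zc)) / denom
}

#' Permutation Moran's I correlogram
#'
#' Bins all field pairs into contiguous half-open distance bands
#' `(d_low, d_high]` of width `interval` up to `max_dist` (self-pairs
#' excluded), computes Moran's I per band, and attaches a two-sided
#' permutation p-value: residuals are randomly permuted over locations
#' `n_perm` times (the same permutations across bands), and
#' `p = min(1, 2 * min(b_lo + 1, b_hi + 1) / (n_perm + 1))` where `b_hi` /
#' `b_lo` count permuted I at least / at most the observed. Deterministic
#' given `seed`. Empty bands are reported with `n_pairs = 0` and no I.
#'
#' @param residuals Numeric vector (centered internally).
#' @param coords Two-column matrix/data frame of planar coordinates in
#'   meters.
#' @param max_dist Maximum distance (m), default 3000.
#' @param interval Band width (m), default 250.
#' @param n_perm Number of permutations, default 1000.
#' @param seed Optional integer seed.
#' @return A data frame of class `"weevil_correlogram"`: `d_low`, `d_high`,
#'   `n_pairs`, `moran_i`, `p_perm`; attributes `expected` (`-1/(n-1)`) and
#'   `n_perm`.
#' @export
correlogram <- function(residuals, coords, max_dist = 3000, interval = 250,
                        n_perm = 1000, seed = NULL) {
  z <- residuals - mean(residuals)
  n <- length(z)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 2)
    stop_weevil("weevil_validation_error",
                "coords must be a two-column matrix with one row per residual")
  if (sum(z^2) <= 0)
    stop_weevil("weevil_undefined_error",
                "Moran's I undefined for constant residuals")
  if (!is_count(n_perm))
    stop_weevil("weevil_validation_error", "n_perm must be a positive integer")
  if (!is.null(seed)) set.seed(seed)

  d <- as.matrix(stats::dist(coords))
  breaks <- seq(0, max_dist, by = interval)
  n_bins <- length(breaks) - 1L
  ut <- upper.tri(d)
  pair_i <- row(d)[ut]
  pair_j <- col(d)[ut]
  pair_d <- d[ut]
  band <- findInterval(pair_d, breaks, left.open = TRUE)  # (low, high]
  band[pair_d <= 0 | pair_d > max_dist] <- 0L

  denom <- sum(z^2)
  perms <- replicate(n_perm, sample.int(n))
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- band == b
    np <- sum(sel)
    if (np == 0L)
      return(data.frame(d_low = breaks[b], d_high = breaks[b + 1],
                        n_pairs = 0L, moran_i = NA_real_, p_perm = NA_real_))
    ii <- pair_i[sel]
    jj <- pair_j[sel]
    s0 <- 2 * np  # symmetric relation counts both directions
    obs <- (n / s0) * (2 * sum(z[ii] * z[jj])) / denom
    perm_i <- vapply(seq_len(n_perm), function(k) {
      zp <- z[perms[, k]]
      (n / s0) * (2 * sum(zp[ii] * zp[jj])) / sum(zp^2)
    }, numeric(1))
    b_hi <- sum(perm_i >= obs)
    b_lo <- sum(perm_i <= obs)
    p <- min(1, 2 * min(b_hi + 1, b_lo + 1) / (n_perm + 1))
    data.frame(d_low = breaks[b], d_high = breaks[b + 1], n_pairs = np,
               moran_i = obs, p_perm = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "expected") <- -1 / (n - 1)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("weevil_correlogram", "data.frame")
  out
}

#' @export
print.weevil_correlogram <- function(x, digits = 4, ...) {
  cat(sprintf("Moran's I correlogram (%d permutations; null expectation %.4f)\n",
              attr(x, "n_perm"), attr(x, "expected")))
  df <- as.data.frame(x)
  df$moran_i <- round(df$moran_i, digits)
  df$p_perm <- round(df$p_perm, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.weevil_correlogram <- function(x, ...) {
  mid <- (x$d_low + x$d_high) / 2
  graphics::plot(mid, x$moran_i, type = "b", xlab = "distance (m)",
                 ylab = "Moran's I", main = "Residual correlogram", ...)
  graphics::abline(h = attr(x, "expected"), lty = 2)
  sig <- !is.na(x$p_perm) & x$p_perm < 0.05
  if (any(sig)) graphics::points(mid[sig], x$moran_i[sig], pch = 16)
  invisible(x)
}
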