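# Independent oracles used across the suite. These are deliberately naive
# (closed-form normal equations, brute-force loops) and share no code with
# the package internals they check.

# weighted least squares of y on columns of X, weights w; returns
# coefficients and their SEs with the weights treated as known inverse
# variances (no residual rescaling)
oracle_wls_known_var <- function(y, X, w) {
  XtWX <- t(X) %*% (w * X)
  V <- solve(XtWX)
  coef <- as.vector(V %*% t(X) %*% (w * y))
  list(coef = coef, se = unname(sqrt(diag(V))))
}

# IVW as weighted regression through the origin, by explicit sums
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - est * bx)^2)
  list(est = est, se_fixed = se_fixed, Q = Q)
}

# weighted median by brute-force weighted empirical CDF with linear
# interpolation at probability one half
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  cdf <- cumsum(w) - w / 2
  if (0.5 <= cdf[1]) return(r[1])
  for (i in 2:length(r)) {
    if (cdf[i] >= 0.5) {
      lo <- cdf[i - 1]; hi <- cdf[i]
      return(r[i - 1] + (0.5 - lo) / (hi - lo) * (r[i] - r[i - 1]))
    }
  }
  r[length(r)]
}

# exhaustive re-simulation of greedy p-ranked clumping
oracle_clump <- function(ids, p, r2m, p_thresh, r2_thresh) {
  ord <- order(p, ids)
  ids <- ids[ord]; p <- p[ord]
  kept <- character()
  while (length(ids) > 0) {
    if (p[1] >= p_thresh) break
    kept <- c(kept, ids[1])
    drop <- r2m[ids[1], ids] >= r2_thresh
    ids <- ids[!drop]; p <- p[!drop]
  }
  kept
}

# small deterministic cohort for structural tests
tiny_cohort <- function(n = 400, n_snps = 5, seed = 11, ...) {
  generate_cohort(cohort_config(n_individuals = n, n_snps = n_snps,
                                maf = 0.3, beta_g = 0.2, theta = 0,
                                noise_sd = 1, seed = seed, ...))
}
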