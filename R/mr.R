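#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on variant id and aligns the outcome
#' association to the exposure's effect allele. Variants whose alleles are
#' swapped between the tables have their outcome beta negated (and outcome
#' eaf flipped); palindromic variants (A/T or G/C) with effect-allele
#' frequency inside the ambiguity window are dropped, as are variants whose
#' alleles cannot be reconciled at all. Every drop is logged with a reason
#' in the `log` attribute.
#'
#' @param exposure,outcome data.frames with `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`.
#' @param palindromic_window eaf interval treated as strand-ambiguous for
#'   palindromic variants.
#' @return A data.frame of class `mr_input` with `variant_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `status`; attribute
#'   `log` records dropped variants and reasons.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_window = c(0.42, 0.58)) {
  m <- match(exposure$variant_id, outcome$variant_id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no shared variants between the tables", call. = FALSE)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]
  pal <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG")
  status <- character(nrow(ex))
  beta_y <- ou$beta
  eaf_y <- ou$eaf
  log <- list()
  for (i in seq_len(nrow(ex))) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    yea <- ou$effect_allele[i]; yoa <- ou$other_allele[i]
    if (pal(ea, oa)) {
      f <- ex$eaf[i]
      if (is.na(f) || (f >= palindromic_window[1] && f <= palindromic_window[2])) {
        status[i] <- "dropped_palindromic"
        log[[length(log) + 1L]] <- data.frame(
          variant_id = ex$variant_id[i], action = "dropped",
          reason = "palindromic with ambiguous eaf")
        next
      }
    }
    if (ea == yea && oa == yoa) {
      status[i] <- "ok"
    } else if (ea == yoa && oa == yea) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
      status[i] <- "flipped"
      log[[length(log) + 1L]] <- data.frame(
        variant_id = ex$variant_id[i], action = "flipped",
        reason = "effect/other alleles swapped")
    } else {
      status[i] <- "dropped_mismatch"
      log[[length(log) + 1L]] <- data.frame(
        variant_id = ex$variant_id[i], action = "dropped",
        reason = "allele mismatch")
    }
  }
  ok <- !startsWith(status, "dropped")
  out <- data.frame(variant_id = ex$variant_id[ok],
                    beta_x = ex$beta[ok], se_x = ex$se[ok],
                    beta_y = beta_y[ok], se_y = ou$se[ok],
                    eaf_x = ex$eaf[ok], eaf_y = eaf_y[ok],
                    status = status[ok], stringsAsFactors = FALSE)
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(), action = character(),
               reason = character())
  class(out) <- c("mr_input", "data.frame")
  out
}

.mr_result <- function(method, estimate, se, p, n_snp, Q = NA_real_,
                       overdispersion = NA_real_, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_lo = estimate - z * se, ci_hi = estimate + z * se,
                 p = p, n_snp = n_snp, Q = Q,
                 overdispersion = overdispersion),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP%s\n", x$method, x$n_snp,
              if (x$n_snp == 1L) "" else "s"))
  cat(sprintf("  estimate %.4g (SE %.3g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$estimate, x$se, x$ci_lo, x$ci_hi, x$p))
  if (is.finite(x$Q))
    cat(sprintf("  Cochran Q = %.3f, overdispersion = %.3f\n",
                x$Q, x$overdispersion))
  invisible(x)
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$estimate - z * object$se, object$estimate + z * object$se)
  dimnames(m) <- list(object$method, c("lo", "hi"))
  m
}

.as_mr_input <- function(dat) {
  need <- c("beta_x", "beta_y", "se_y")
  if (!all(need %in% names(dat)))
    stop("input must have beta_x, beta_y, se_y", call. = FALSE)
  if (any(dat$se_y <= 0)) stop("all se_y must be > 0", call. = FALSE)
  dat
}

#' Inverse-variance weighted Mendelian randomization estimate
#'
#' Weighted regression of outcome associations on exposure associations
#' through the origin, with weights `1 / se_y^2`:
#' \deqn{\hat\beta = \frac{\sum_j w_j \beta_{x,j} \beta_{y,j}}
#'                        {\sum_j w_j \beta_{x,j}^2}}
#' By convention the exposure standard errors do not enter the point
#' estimate (NO-Measurement-Error assumption). The fixed-effect standard
#' error \eqn{\sqrt{1/\sum_j w_j \beta_{x,j}^2}} is inflated by
#' `max(1, sqrt(Q/(n-1)))` under the default multiplicative random-effects
#' model; `overdispersion = "fixed"` keeps it unscaled. A single variant
#' returns the Wald ratio `beta_y / beta_x` with delta-method SE.
#'
#' @param dat an `mr_input` (or any data.frame with `beta_x`, `beta_y`,
#'   `se_y`).
#' @param overdispersion `"multiplicative"` (default) or `"fixed"`.
#' @param method_label label stored in the result.
#' @return An `mr_result`.
#' @export
mr_ivw <- function(dat, overdispersion = c("multiplicative", "fixed"),
                   method_label = "ivw") {
  dat <- .as_mr_input(dat)
  overdispersion <- match.arg(overdispersion)
  bx <- dat$beta_x; by <- dat$beta_y; sy <- dat$se_y
  n <- length(bx)
  if (n < 1L) stop("no variants", call. = FALSE)
  if (all(bx == 0)) stop("all exposure betas are zero", call. = FALSE)
  if (n == 1L) {
    est <- by / bx
    se <- sy / abs(bx)
    return(.mr_result("wald_ratio", est, se, 2 * stats::pnorm(-abs(est / se)),
                      1L))
  }
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  Q <- sum(w * (by - est * bx)^2)
  phi <- if (overdispersion == "multiplicative") max(1, sqrt(Q / (n - 1))) else 1
  se <- phi * sqrt(1 / sxx)
  .mr_result(method_label, est, se, 2 * stats::pnorm(-abs(est / se)), n,
             Q = Q, overdispersion = phi)
}

#' Modified IVW: age-interaction slopes as the exposure
#'
#' The same estimator as [mr_ivw()] with each variant's meta-regression age
#' slope \eqn{\hat\delta_j} substituted for its exposure association,
#' fitting \eqn{\hat\Gamma_j = \beta \hat\delta_j + u_j}. The estimand is
#' the effect on the outcome of the rate of change of the genetically
#' predicted exposure with age, in log-odds per exposure-unit per year.
#' The slope standard errors are carried in the input for reporting only
#' and do not enter the estimate.
#'
#' @param interactions a [metareg_scan()] result (or data.frame with
#'   `variant_id`, `delta`, `se_delta`).
#' @param outcome outcome summary statistics with `variant_id`, `beta`,
#'   `se`.
#' @param snp_ids optional subset of variant ids to use (e.g. an inclusion
#'   set).
#' @param overdispersion passed to [mr_ivw()].
#' @return An `mr_result` with method `"ivw_modified"`.
#' @export
mr_modified_ivw <- function(interactions, outcome, snp_ids = NULL,
                            overdispersion = c("multiplicative", "fixed")) {
  if (!is.null(snp_ids))
    interactions <- interactions[interactions$variant_id %in% snp_ids, ,
                                 drop = FALSE]
  ok <- is.finite(interactions$delta)
  interactions <- interactions[ok, , drop = FALSE]
  m <- match(interactions$variant_id, outcome$variant_id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no shared variants", call. = FALSE)
  dat <- data.frame(variant_id = interactions$variant_id[keep],
                    beta_x = interactions$delta[keep],
                    se_x = interactions$se_delta[keep],
                    beta_y = outcome$beta[m[keep]],
                    se_y = outcome$se[m[keep]],
                    stringsAsFactors = FALSE)
  if (all(dat$beta_x == 0))
    stop("all age-interaction slopes are zero", call. = FALSE)
  mr_ivw(dat, overdispersion = match.arg(overdispersion),
         method_label = "ivw_modified")
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure associations with an
#' intercept, weights `1 / se_y^2`. A non-zero intercept indicates
#' directional pleiotropy. Because the fit is not invariant to allele
#' recoding, variants are oriented so that all exposure betas are
#' non-negative before fitting. Standard errors use the same multiplicative
#' overdispersion convention as [mr_ivw()] (here with `n - 2` df).
#'
#' @param dat an `mr_input`-like data.frame (>= 3 variants).
#' @param overdispersion `"multiplicative"` or `"fixed"`.
#' @return A list with `slope` and `intercept`, each an `mr_result`.
#' @export
mr_egger <- function(dat, overdispersion = c("multiplicative", "fixed")) {
  dat <- .as_mr_input(dat)
  overdispersion <- match.arg(overdispersion)
  n <- nrow(dat)
  if (n < 3L) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  flip <- sign(dat$beta_x)
  flip[flip == 0] <- 1
  bx <- dat$beta_x * flip
  by <- dat$beta_y * flip
  w <- 1 / dat$se_y^2
  X <- cbind(1, bx)
  V <- solve(crossprod(X, w * X))
  co <- as.vector(V %*% crossprod(X, w * by))
  resid <- by - as.vector(X %*% co)
  Q <- sum(w * resid^2)
  phi <- if (overdispersion == "multiplicative") max(1, sqrt(Q / (n - 2))) else 1
  se <- phi * unname(sqrt(diag(V)))
  zs <- co / se
  list(slope = .mr_result("egger_slope", co[2], se[2],
                          2 * stats::pnorm(-abs(zs[2])), n, Q, phi),
       intercept = .mr_result("egger_intercept", co[1], se[1],
                              2 * stats::pnorm(-abs(zs[1])), n, Q, phi))
}

# weighted median of ratios: linear interpolation of the weighted empirical
# CDF at probability 1/2 (weights normalized to sum 1)
.weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(r[1])
  if (0.5 >= cw[length(cw)]) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median Mendelian randomization estimate
#'
#' Computes per-variant Wald ratios `beta_y / beta_x` with inverse-variance
#' weights `beta_x^2 / se_y^2` (the first-order variance of the ratio),
#' normalized to sum one, and takes the value at which the weighted
#' empirical CDF of the ordered ratios crosses one half (linear
#' interpolation). Consistent when variants contributing at least half the
#' weight are valid instruments. The standard error is obtained by
#' parametric bootstrap: `n_boot` resamples of `(beta_x, beta_y)` from
#' normal distributions with the reported SEs.
#'
#' @param dat an `mr_input`-like data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y` (>= 3 variants, no zero `beta_x`).
#' @param n_boot bootstrap resamples for the SE.
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(dat, n_boot = 2000L, seed = 1L) {
  dat <- .as_mr_input(dat)
  n <- nrow(dat)
  if (n < 3L) stop("weighted median needs at least 3 variants", call. = FALSE)
  if (any(dat$beta_x == 0))
    stop("weighted median is undefined for beta_x = 0", call. = FALSE)
  r <- dat$beta_y / dat$beta_x
  w <- dat$beta_x^2 / dat$se_y^2
  est <- .weighted_median(r, w)
  set.seed(seed)
  boot <- numeric(n_boot)
  sx <- if (is.null(dat$se_x)) rep(0, n) else dat$se_x
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(n, dat$beta_x, sx)
    by <- stats::rnorm(n, dat$beta_y, dat$se_y)
    bx[bx == 0] <- .Machine$double.eps
    boot[b] <- .weighted_median(by / bx, bx^2 / dat$se_y^2)
  }
  se <- stats::sd(boot)
  .mr_result("weighted_median", est, se,
             2 * stats::pnorm(-abs(est / se)), n)
}

#' Age-stratified MR using single-stratum exposure estimates
#'
#' Runs [mr_ivw()] separately with the exposure associations estimated in
#' the chosen age strata (conventionally the youngest and the oldest), for
#' a given variant set. This contrasts the exposure-outcome relationship as
#' proxied by genetic effects measured at different ages.
#'
#' @param stratified stacked stratified association records (long format
#'   with a `stratum` column).
#' @param outcome outcome summary statistics (`variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`).
#' @param strata stratum indices to analyse (default youngest and oldest).
#' @param snp_ids variant ids to instrument with (e.g. the discovery set).
#' @param ... passed to [mr_ivw()].
#' @return A named list of `mr_result`s, one per stratum.
#' @export
age_stratified_mr <- function(stratified, outcome, strata = c(1L, 15L),
                              snp_ids = NULL, ...) {
  out <- list()
  for (s in strata) {
    exp_s <- stratified[stratified$stratum == as.character(s), , drop = FALSE]
    if (!is.null(snp_ids))
      exp_s <- exp_s[exp_s$variant_id %in% snp_ids, , drop = FALSE]
    exp_s <- exp_s[is.finite(exp_s$beta) & is.finite(exp_s$se) & exp_s$se > 0,
                   , drop = FALSE]
    dat <- harmonize(exp_s, outcome)
    out[[paste0("stratum_", s)]] <- mr_ivw(dat, ...)
  }
  out
}

#' Odds-ratio transform of an MR result
#'
#' Exponentiates a log-odds estimate and its confidence interval.
#'
#' @param result an `mr_result` on the log-odds scale.
#' @return A list with `or`, `ci_lo`, `ci_hi`.
#' @export
to_odds_ratio <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  list(or = exp(result$estimate), ci_lo = exp(result$ci_lo),
       ci_hi = exp(result$ci_hi))
}
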