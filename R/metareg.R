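#' Fixed-effects meta-regression of one SNP's stratum estimates on age
#'
#' Fits the weighted least-squares regression of per-stratum effect
#' estimates on mean stratum age with fixed-effect weights `1 / se^2`:
#' \deqn{\hat\pi_{a} = \omega + \delta \bar A_a + \epsilon_a,\qquad
#'       w_a = 1/se_a^2}
#' The slope \eqn{\hat\delta} is the SNP-by-age interaction: the change in
#' the per-allele effect per year of age. Standard errors come from the
#' weighted normal equations with the sampling variances treated as known
#' (no residual-variance rescaling), z-based two-sided p-values, and `QE`
#' is the weighted residual sum of squares (the residual heterogeneity
#' statistic on `n_strata - 2` df).
#'
#' An intercept is included by default; `intercept = FALSE` forces the
#' regression line through the origin of the moderator scale, which is not
#' meaningful for ages 40-69 but is provided for exact replication of the
#' no-intercept display of the model.
#'
#' @param betas per-stratum effect estimates.
#' @param ses per-stratum standard errors (> 0).
#' @param mean_ages per-stratum mean ages in years.
#' @param intercept include an intercept term (default TRUE).
#' @return An object of class `snp_metareg`: list with `intercept`,
#'   `delta`, `se_intercept`, `se_delta`, `z`, `p_int`, `n_strata`, `QE`
#'   and the input `data`.
#' @export
meta_regress_snp <- function(betas, ses, mean_ages, intercept = TRUE) {
  n <- length(betas)
  if (length(ses) != n || length(mean_ages) != n)
    stop("betas, ses and mean_ages must have equal length", call. = FALSE)
  if (n < 3L)
    stop("at least 3 strata are required for a meta-regression", call. = FALSE)
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all ses must be positive and finite", call. = FALSE)
  w <- 1 / ses^2
  X <- if (intercept) cbind(1, mean_ages) else cbind(mean_ages)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * betas)
  V <- solve(XtWX)
  coefs <- as.vector(V %*% XtWy)
  se <- unname(sqrt(diag(V)))
  resid <- betas - as.vector(X %*% coefs)
  QE <- sum(w * resid^2)
  j <- if (intercept) 2L else 1L
  delta <- coefs[j]
  se_delta <- se[j]
  z <- delta / se_delta
  structure(list(intercept = if (intercept) coefs[1L] else NA_real_,
                 delta = delta,
                 se_intercept = if (intercept) se[1L] else NA_real_,
                 se_delta = se_delta, z = z,
                 p_int = 2 * stats::pnorm(-abs(z)),
                 n_strata = n, QE = QE,
                 intercept_included = intercept,
                 data = data.frame(beta = betas, se = ses,
                                   mean_age = mean_ages)),
            class = "snp_metareg")
}

#' @export
print.snp_metareg <- function(x, ...) {
  cat("SNP-by-age fixed-effects meta-regression\n")
  cat(sprintf("  strata: %d   QE: %.3f (df = %d)\n", x$n_strata, x$QE,
              x$n_strata - if (x$intercept_included) 2L else 1L))
  cat(sprintf("  age slope: %.5g (SE %.3g), z = %.3f, p = %.3g\n",
              x$delta, x$se_delta, x$z, x$p_int))
  if (x$intercept_included)
    cat(sprintf("  intercept: %.5g (SE %.3g)\n", x$intercept, x$se_intercept))
  invisible(x)
}

#' @export
coef.snp_metareg <- function(object, ...) {
  if (object$intercept_included)
    c(intercept = object$intercept, delta = object$delta)
  else c(delta = object$delta)
}

#' @export
confint.snp_metareg <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$delta - z * object$se_delta,
             object$delta + z * object$se_delta)
  dimnames(m) <- list("delta", c("lo", "hi"))
  m
}

#' Bubble-style plot of a per-SNP meta-regression
#'
#' Plots the stratum estimates against mean stratum age with point area
#' proportional to the fixed-effect weight, and overlays the fitted line.
#'
#' @param x a `snp_metareg`.
#' @param ... passed to [plot()].
#' @export
plot.snp_metareg <- function(x, ...) {
  d <- x$data
  w <- 1 / d$se^2
  cex <- 0.5 + 2 * sqrt(w / max(w))
  plot(d$mean_age, d$beta, cex = cex, pch = 21, bg = "grey80",
       xlab = "Mean stratum age (years)", ylab = "Per-allele effect", ...)
  ab <- if (x$intercept_included) c(x$intercept, x$delta) else c(0, x$delta)
  graphics::abline(ab[1], ab[2], col = "steelblue", lwd = 2)
  invisible(x)
}

#' Genome-wide meta-regression scan
#'
#' Applies [meta_regress_snp()] to every variant in a stacked set of
#' stratified association records. Variants with incomplete stratum
#' coverage are fitted on the strata available (>= 3) and flagged; variants
#' with fewer than 3 usable strata get an `NA` record flagged
#' `"insufficient"`.
#'
#' @param assoc stacked stratified records from [stratified_scan()] (or a
#'   summary-statistics file read with [read_sumstats()]); must have
#'   `variant_id`, `beta`, `se`, `mean_age`.
#' @param n_strata_expected number of strata a complete variant should
#'   have.
#' @param intercept passed to [meta_regress_snp()].
#' @return A data.frame of class `metareg_scan` with one row per variant:
#'   `variant_id`, `intercept`, `delta`, `se_delta`, `z`, `p_int`,
#'   `n_strata`, `QE`, `flag`.
#' @export
metareg_scan <- function(assoc, n_strata_expected = 15L, intercept = TRUE) {
  need <- c("variant_id", "beta", "se", "mean_age")
  if (!all(need %in% names(assoc)))
    stop("assoc must have variant_id, beta, se, mean_age", call. = FALSE)
  usable <- is.finite(assoc$beta) & is.finite(assoc$se) & assoc$se > 0
  sp <- split(assoc[usable, need], assoc$variant_id[usable])
  ids <- unique(assoc$variant_id)
  res <- lapply(ids, function(id) {
    d <- sp[[id]]
    k <- if (is.null(d)) 0L else nrow(d)
    if (k < 3L)
      return(data.frame(variant_id = id, intercept = NA_real_,
                        delta = NA_real_, se_delta = NA_real_, z = NA_real_,
                        p_int = NA_real_, n_strata = k, QE = NA_real_,
                        flag = "insufficient", stringsAsFactors = FALSE))
    f <- meta_regress_snp(d$beta, d$se, d$mean_age, intercept = intercept)
    data.frame(variant_id = id, intercept = f$intercept, delta = f$delta,
               se_delta = f$se_delta, z = f$z, p_int = f$p_int,
               n_strata = f$n_strata, QE = f$QE,
               flag = if (k < n_strata_expected) "missing_strata" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("metareg_scan", "data.frame")
  out
}

#' @export
print.metareg_scan <- function(x, ...) {
  ok <- if (is.null(x$flag)) sum(!is.na(x$delta)) else
    sum(x$flag != "insufficient")
  cat(sprintf("Meta-regression scan: %d variants (%d fitted)\n", nrow(x), ok))
  if (!is.null(x$p_int))
    cat(sprintf("  age slopes with p < 0.05: %d\n",
                sum(x$p_int < 0.05, na.rm = TRUE)))
  NextMethod()
}

#' Classify variants into the age-interaction inclusion sets
#'
#' Builds the nested variant sets used downstream:
#' \describe{
#'   \item{inclusion1}{discovery variants with meta-regression interaction
#'     p < `p1` (strict).}
#'   \item{inclusion2}{independent variants genome-wide with interaction
#'     p < `p2`, obtained by greedy clumping on the interaction p-value at
#'     `r2_thresh`.}
#'   \item{bonferroni}{discovery variants with interaction
#'     p < 0.05 / n_discovery.}
#'   \item{genomewide_interaction}{inclusion2 variants whose interaction
#'     reaches genome-wide significance (`gw`).}
#' }
#'
#' @param discovery_ids character vector of discovery variant ids.
#' @param records a [metareg_scan()] result (or data.frame with
#'   `variant_id` and `p_int`).
#' @param r2_matrix pairwise r^2 matrix covering all variants in `records`.
#' @param p1 nominal interaction threshold for inclusion 1.
#' @param p2 genome-wide suggestive threshold for inclusion 2.
#' @param r2_thresh clumping independence threshold.
#' @param gw genome-wide significance threshold.
#' @param n_discovery denominator of the Bonferroni threshold (defaults to
#'   `length(discovery_ids)`).
#' @return An object of class `inclusion_sets`: list of id vectors
#'   `discovery`, `inclusion1`, `inclusion2`, `bonferroni`,
#'   `genomewide_interaction` plus the `thresholds` used.
#' @export
classify_inclusion <- function(discovery_ids, records, r2_matrix,
                               p1 = 0.05, p2 = 5e-5, r2_thresh = 0.01,
                               gw = 5e-8, n_discovery = length(discovery_ids)) {
  if (length(discovery_ids) == 0L)
    stop("discovery set is empty", call. = FALSE)
  p <- records$p_int
  ids <- records$variant_id
  disc <- ids %in% discovery_ids
  inclusion1 <- ids[disc & !is.na(p) & p < p1]
  bonf <- ids[disc & !is.na(p) & p < 0.05 / n_discovery]
  inclusion2 <- clump(records, r2_matrix, p_thresh = p2,
                      r2_thresh = r2_thresh, p_col = "p_int")
  gw_ids <- inclusion2[p[match(inclusion2, ids)] < gw]
  structure(list(discovery = discovery_ids,
                 inclusion1 = inclusion1,
                 inclusion2 = inclusion2,
                 bonferroni = bonf,
                 genomewide_interaction = gw_ids,
                 thresholds = list(p1 = p1, p2 = p2, r2 = r2_thresh, gw = gw,
                                   bonferroni = 0.05 / n_discovery)),
            class = "inclusion_sets")
}

#' @export
print.inclusion_sets <- function(x, ...) {
  cat("Age-interaction inclusion sets\n")
  cat(sprintf("  discovery: %d\n", length(x$discovery)))
  cat(sprintf("  inclusion 1 (p < %g): %d (%.1f%% of discovery)\n",
              x$thresholds$p1, length(x$inclusion1),
              100 * length(x$inclusion1) / length(x$discovery)))
  cat(sprintf("  inclusion 2 (p < %g, r2 < %g): %d\n", x$thresholds$p2,
              x$thresholds$r2, length(x$inclusion2)))
  cat(sprintf("  Bonferroni (p < %.3g): %d\n", x$thresholds$bonferroni,
              length(x$bonferroni)))
  cat(sprintf("  genome-wide interaction (p < %g): %d\n", x$thresholds$gw,
              length(x$genomewide_interaction)))
  invisible(x)
}

#' Fraction of variants whose stratum effects change sign
#'
#' For each variant, counts it if its per-stratum effect estimates include
#' both strictly positive and strictly negative values (exact zeros are
#' ignored). Variants selected on an age interaction but not on a main
#' effect often straddle zero across the age range, which shrinks their
#' average full-range effect.
#'
#' @param betas either a matrix (variants x strata) or a long data.frame
#'   with `variant_id` and `beta`.
#' @return The proportion of variants with a sign change.
#' @export
sign_change_fraction <- function(betas) {
  if (is.matrix(betas)) {
    per <- apply(betas, 1L, function(b) any(b > 0, na.rm = TRUE) &&
                   any(b < 0, na.rm = TRUE))
  } else {
    per <- vapply(split(betas$beta, betas$variant_id),
                  function(b) any(b > 0, na.rm = TRUE) &&
                    any(b < 0, na.rm = TRUE), logical(1))
  }
  mean(per)
}

#' Individual-level SNP-by-age interaction scan
#'
#' Sensitivity comparator for the summary-level meta-regression: per SNP,
#' OLS of the trait on dosage, age, dosage x (age - age_ref) and the
#' covariates, returning the genetic main effect (at `age_ref`) and the
#' interaction coefficient. Variants below the minor-allele-frequency
#' filter are skipped with a flag.
#'
#' @param cohort a `cohort`.
#' @param trait trait column name.
#' @param covariates covariate column names (beyond age, which is always in
#'   the model).
#' @param age_ref centring age for the interaction term.
#' @param maf_min minimum minor allele frequency (default 1e-4, i.e. 0.01%).
#' @return A data.frame: `variant_id`, `beta_main`, `se_main`, `p_main`,
#'   `beta_inter`, `se_inter`, `p_inter`, `n`, `flag`.
#' @export
interaction_scan_individual <- function(cohort,
                                        trait = cohort$config$trait_name,
                                        covariates = c("sex", "chip"),
                                        age_ref = cohort$config$age_ref,
                                        maf_min = 1e-4) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  x <- d[[trait]]
  n <- nrow(d)
  C <- cbind(1, d$age)
  for (cv in covariates) {
    v <- d[[cv]]
    if (stats::var(v) > 0) C <- cbind(C, v)
  }
  agec <- d$age - age_ref
  p <- ncol(cohort$dosages)
  out <- data.frame(variant_id = cohort$variants$variant_id,
                    beta_main = NA_real_, se_main = NA_real_,
                    p_main = NA_real_, beta_inter = NA_real_,
                    se_inter = NA_real_, p_inter = NA_real_,
                    n = n, flag = "ok", stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    g <- cohort$dosages[, j]
    eaf <- mean(g) / 2
    maf <- min(eaf, 1 - eaf)
    if (maf < maf_min) {
      out$flag[j] <- "maf_filtered"
      next
    }
    X <- cbind(C, g, g * agec)
    XtX <- crossprod(X)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) {
      out$flag[j] <- "degenerate"
      next
    }
    V <- chol2inv(ch)
    co <- as.vector(V %*% crossprod(X, x))
    df <- n - ncol(X)
    sigma2 <- sum((x - as.vector(X %*% co))^2) / df
    se <- sqrt(sigma2 * diag(V))
    jm <- ncol(X) - 1L
    ji <- ncol(X)
    tmain <- co[jm] / se[jm]; tint <- co[ji] / se[ji]
    out$beta_main[j] <- co[jm]; out$se_main[j] <- se[jm]
    out$p_main[j] <- 2 * stats::pt(-abs(tmain), df)
    out$beta_inter[j] <- co[ji]; out$se_inter[j] <- se[ji]
    out$p_inter[j] <- 2 * stats::pt(-abs(tint), df)
  }
  out
}
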