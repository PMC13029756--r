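#' Per-SNP association scan by ordinary least squares
#'
#' Regresses the trait on each variant's dosage plus the covariates, one
#' variant at a time, and returns classical OLS estimates. Internally the
#' trait and dosages are residualised on the covariate design once
#' (Frisch-Waugh-Lovell), which reproduces the full-model coefficient, its
#' classical standard error and the two-sided t-test exactly while scaling
#' to many variants. Monomorphic variants (or dosages collinear with the
#' covariates) yield a flagged null record rather than an error.
#'
#' @param cohort a `cohort`.
#' @param trait trait column name (defaults to the cohort's trait).
#' @param covariates covariate column names; the intercept is implicit.
#' @param subset optional logical or integer index of individuals to use
#'   (e.g. one age stratum, or the selected subset).
#' @param stratum_label value for the `stratum` column of the output
#'   (an index, or `"discovery"` for a full-range scan).
#' @return A data.frame of association records with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `stratum`, `mean_age`, `flag` (`"ok"` or `"monomorphic"`).
#' @export
assoc_scan <- function(cohort, trait = cohort$config$trait_name,
                       covariates = c("age", "sex", "chip"),
                       subset = NULL, stratum_label = "discovery") {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  G <- cohort$dosages
  if (!is.null(subset)) {
    d <- d[subset, , drop = FALSE]
    G <- G[subset, , drop = FALSE]
  }
  n <- nrow(d)
  x <- d[[trait]]
  if (is.null(x)) stop(sprintf("trait '%s' not found", trait), call. = FALSE)
  C <- cbind(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.null(v)) stop(sprintf("covariate '%s' not found", cv), call. = FALSE)
    if (stats::var(v) > 0) C <- cbind(C, v)  # drop constant covariates
  }
  k <- ncol(C)
  if (n < k + 3L)
    stop("too few individuals for the covariate design", call. = FALSE)
  qrC <- qr(C)
  rx <- qr.resid(qrC, x)
  rG <- qr.resid(qrC, G)
  den <- colSums(rG^2)
  num <- as.vector(crossprod(rG, rx))
  df <- n - k - 1L
  ok <- den > 1e-10 * n
  beta <- ifelse(ok, num / den, NA_real_)
  rss <- sum(rx^2) - ifelse(ok, beta^2 * den, 0)
  se <- ifelse(ok, sqrt(pmax(rss, 0) / df / den), NA_real_)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  eaf <- colMeans(G) / 2
  data.frame(variant_id = cohort$variants$variant_id,
             effect_allele = cohort$variants$effect_allele,
             other_allele = cohort$variants$other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stratum = stratum_label, mean_age = mean(d$age),
             flag = ifelse(ok, "ok", "monomorphic"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Age-stratified association scan
#'
#' Runs [assoc_scan()] within every age stratum of a capped cohort (see
#' [cap_strata()]) and stacks the per-stratum records. The `mean_age`
#' recorded for each stratum is the sample mean age of its included
#' individuals, which is the moderator the meta-regression uses.
#'
#' @param cohort a `cohort` that has been through [cap_strata()].
#' @param trait,covariates passed to [assoc_scan()].
#' @param n_strata number of strata to scan.
#' @return A data.frame of stacked per-stratum association records.
#' @export
stratified_scan <- function(cohort, trait = cohort$config$trait_name,
                            covariates = c("age", "sex", "chip"),
                            n_strata = 15L) {
  if (is.null(cohort$data$stratum))
    stop("cohort has no stratum assignment; run cap_strata() first",
         call. = FALSE)
  out <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    idx <- which(!is.na(cohort$data$stratum) & cohort$data$stratum == s)
    if (length(idx) == 0L) next
    out[[s]] <- assoc_scan(cohort, trait, covariates, subset = idx,
                           stratum_label = as.character(s))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Greedy LD clumping of association records
#'
#' Ranks variants by ascending p-value (ties broken by variant id), keeps
#' the top-ranked remaining variant if its p-value is below `p_thresh`, and
#' removes every variant correlated with it at `r^2 >= r2_thresh`; repeats
#' until no variant remains. All retained pairs therefore satisfy
#' `r^2 < r2_thresh`.
#'
#' @param assoc data.frame with `variant_id` and a p-value column.
#' @param r2_matrix symmetric matrix of pairwise squared dosage
#'   correlations with dimnames matching the variant ids.
#' @param p_thresh significance threshold (strict `<`).
#' @param r2_thresh independence threshold.
#' @param p_col name of the p-value column.
#' @return Character vector of retained variant ids, in selection order.
#' @export
clump <- function(assoc, r2_matrix, p_thresh = 5e-8, r2_thresh = 0.01,
                  p_col = "pval") {
  p <- assoc[[p_col]]
  ids <- assoc$variant_id
  keep_rows <- !is.na(p)
  p <- p[keep_rows]; ids <- ids[keep_rows]
  if (!isTRUE(all.equal(r2_matrix, t(r2_matrix))) ||
      any(r2_matrix < -1e-12 | r2_matrix > 1 + 1e-12))
    stop("r2_matrix must be symmetric with entries in [0, 1]", call. = FALSE)
  ord <- order(p, ids)
  p <- p[ord]; ids <- ids[ord]
  retained <- character(0)
  alive <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    if (p[i] >= p_thresh) break  # sorted: nothing later can pass
    retained <- c(retained, ids[i])
    r2 <- r2_matrix[ids[i], ids]
    alive[alive & r2 >= r2_thresh] <- FALSE
  }
  retained
}

#' Pairwise squared dosage correlation matrix
#'
#' @param cohort a `cohort`.
#' @return Symmetric matrix of squared Pearson correlations between dosage
#'   columns, with variant ids as dimnames.
#' @export
dosage_r2 <- function(cohort) {
  r <- stats::cor(cohort$dosages)
  r2 <- r^2
  r2[r2 > 1] <- 1
  r2
}

#' Stratum-level power projection for discovery signals
#'
#' For each variant, the expected test statistic in a stratum is the
#' discovery effect size divided by the stratum-specific standard error,
#' `E[Z] = beta / se`. Power is the probability that a normal statistic
#' with this mean and unit variance reaches the two-sided significance
#' level `alpha`:
#' \deqn{power = \Phi(-z_\alpha + |E[Z]|) + \Phi(-z_\alpha - |E[Z]|)}
#' and the expected number of detectable loci is the sum of power over
#' variants.
#'
#' @param discovery_betas vector of discovery effect sizes.
#' @param stratum_ses vector of stratum-specific standard errors (> 0).
#' @param alpha two-sided significance level (default genome-wide 5e-8).
#' @return A list with `expected_z`, per-SNP `power` and
#'   `expected_loci = sum(power)`.
#' @export
power_projection <- function(discovery_betas, stratum_ses, alpha = 5e-8) {
  if (any(stratum_ses <= 0)) stop("standard errors must be > 0", call. = FALSE)
  ez <- discovery_betas / stratum_ses
  za <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(-za + abs(ez)) + stats::pnorm(-za - abs(ez))
  list(expected_z = ez, power = pow, expected_loci = sum(pow))
}
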