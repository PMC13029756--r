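make_sumstats <- function(ids, beta, se, ea = "A", oa = "G", eaf = 0.3) {
  data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)
}

test_that("harmonization aligns alleles and logs every drop", {
  exp <- make_sumstats(c("v1", "v2", "v3", "v4"), beta = c(0.1, 0.2, 0.3, 0.4),
                       se = 0.01,
                       ea = c("A", "A", "A", "A"), oa = c("G", "G", "T", "G"))
  out <- make_sumstats(c("v1", "v2", "v3", "v4"), beta = c(1, 2, 3, 4),
                       se = 0.05,
                       ea = c("A", "G", "A", "C"), oa = c("G", "A", "T", "T"))
  exp$eaf <- c(0.3, 0.3, 0.5, 0.3)
  h <- harmonize(exp, out)
  expect_equal(h$beta_y[h$variant_id == "v1"], 1)        # pass-through
  expect_equal(h$beta_y[h$variant_id == "v2"], -2)       # swapped: negated
  expect_false("v3" %in% h$variant_id)                   # palindromic, eaf 0.5
  expect_false("v4" %in% h$variant_id)                   # allele mismatch
  log <- attr(h, "log")
  expect_setequal(log$variant_id[log$action == "dropped"], c("v3", "v4"))
  expect_error(harmonize(make_sumstats("x", 1, 1), make_sumstats("y", 1, 1)),
               "no shared")
})

test_that("IVW reduces to the Wald ratio for one variant", {
  dat <- data.frame(beta_x = 0.1, beta_y = 0.2, se_y = 0.05)
  r <- mr_ivw(dat)
  expect_equal(r$estimate, 2)
  expect_equal(r$method, "wald_ratio")
  expect_equal(r$se, 0.05 / 0.1)
  expect_error(mr_ivw(data.frame(beta_x = 0, beta_y = 1, se_y = 1)), "zero")
})

test_that("IVW equals the weighted-regression-through-origin oracle", {
  set.seed(301)
  n <- 10
  bx <- runif(n, 0.05, 0.3)
  sy <- runif(n, 0.02, 0.08)
  by <- 0.5 * bx + rnorm(n, 0, sy)
  dat <- data.frame(beta_x = bx, beta_y = by, se_y = sy)
  o <- oracle_ivw(bx, by, sy)
  r <- mr_ivw(dat)
  expect_equal(r$estimate, o$est, tolerance = 1e-10)
  expect_equal(r$Q, o$Q, tolerance = 1e-10)
  expect_equal(r$se, o$se_fixed * max(1, sqrt(o$Q / (n - 1))),
               tolerance = 1e-10)
  rf <- mr_ivw(dat, overdispersion = "fixed")
  expect_equal(rf$se, o$se_fixed, tolerance = 1e-10)
  # independent check against unweighted lm with weights
  lmfit <- lm(by ~ bx - 1, weights = 1 / sy^2)
  expect_equal(r$estimate, unname(coef(lmfit)), tolerance = 1e-10)
})

test_that("IVW confidence interval covers the generating slope", {
  set.seed(311)
  n <- 10
  bx <- runif(n, 0.1, 0.4)
  cover <- logical(500)
  for (i in 1:500) {
    sy <- rep(0.05, n)
    by <- 0.5 * bx + rnorm(n, 0, sy)
    r <- mr_ivw(data.frame(beta_x = bx, beta_y = by, se_y = sy))
    cover[i] <- r$ci_lo <= 0.5 && 0.5 <= r$ci_hi
  }
  expect_gte(mean(cover), 0.93)
})

test_that("estimators are invariant to allele recoding and equivariant to scale", {
  set.seed(321)
  n <- 15
  bx <- runif(n, 0.05, 0.3) * sample(c(-1, 1), n, TRUE)
  sy <- runif(n, 0.02, 0.08)
  by <- 0.4 * bx + rnorm(n, 0, sy)
  dat <- data.frame(beta_x = bx, se_x = 0.01, beta_y = by, se_y = sy)
  flip <- sample(c(-1, 1), n, TRUE)
  datf <- transform(dat, beta_x = beta_x * flip, beta_y = beta_y * flip)
  expect_equal(mr_ivw(datf)$estimate, mr_ivw(dat)$estimate, tolerance = 1e-12)
  expect_equal(mr_ivw(datf)$se, mr_ivw(dat)$se, tolerance = 1e-12)
  expect_equal(mr_egger(datf)$slope$estimate, mr_egger(dat)$slope$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(datf, n_boot = 50, seed = 9)$estimate,
               mr_weighted_median(dat, n_boot = 50, seed = 9)$estimate,
               tolerance = 1e-12)
  # scale: multiplying exposure betas by k divides estimates by k
  k <- 3
  datk <- transform(dat, beta_x = beta_x * k)
  expect_equal(mr_ivw(datk)$estimate, mr_ivw(dat)$estimate / k,
               tolerance = 1e-12)
  expect_equal(mr_egger(datk)$slope$estimate,
               mr_egger(dat)$slope$estimate / k, tolerance = 1e-12)
  expect_equal(mr_weighted_median(datk, n_boot = 50, seed = 9)$estimate,
               mr_weighted_median(dat, n_boot = 50, seed = 9)$estimate / k,
               tolerance = 1e-12)
})

test_that("Egger regression separates slope from directional pleiotropy", {
  set.seed(331)
  n <- 12
  bx <- runif(n, 0.1, 0.4)
  sy <- runif(n, 0.02, 0.05)
  # zero pleiotropy, exact proportionality
  dat0 <- data.frame(beta_x = bx, beta_y = 0.7 * bx, se_y = sy)
  e0 <- mr_egger(dat0)
  expect_equal(e0$slope$estimate, 0.7, tolerance = 1e-10)
  expect_equal(e0$intercept$estimate, 0, tolerance = 1e-10)
  # adding a constant to every outcome beta moves only the intercept
  by <- 0.7 * bx + rnorm(n, 0, sy)
  d1 <- data.frame(beta_x = bx, beta_y = by, se_y = sy)
  d2 <- transform(d1, beta_y = beta_y + 0.05)
  e1 <- mr_egger(d1); e2 <- mr_egger(d2)
  expect_equal(e2$slope$estimate, e1$slope$estimate, tolerance = 1e-10)
  expect_equal(e2$intercept$estimate, e1$intercept$estimate + 0.05,
               tolerance = 1e-10)
  # oracle: weighted lm with intercept
  o <- oracle_wls_known_var(by, cbind(1, bx), 1 / sy^2)
  phi <- max(1, sqrt(sum((by - cbind(1, bx) %*% o$coef)^2 / sy^2) / (n - 2)))
  expect_equal(e1$slope$estimate, o$coef[2], tolerance = 1e-10)
  expect_equal(e1$slope$se, phi * o$se[2], tolerance = 1e-10)
  expect_error(mr_egger(d1[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the weighted ratio CDF", {
  dat <- data.frame(beta_x = c(1, 1, 1), se_x = 0,
                    beta_y = c(1, 2, 3), se_y = c(1, 1, 1))
  r <- mr_weighted_median(dat, n_boot = 100, seed = 5)
  expect_equal(r$estimate, 2)
  # all ratios equal: the median is that value whatever the weights
  dat2 <- data.frame(beta_x = c(0.1, 0.2, 0.4), se_x = 0,
                     beta_y = c(0.05, 0.1, 0.2), se_y = c(0.01, 0.05, 0.02))
  expect_equal(mr_weighted_median(dat2, n_boot = 100, seed = 5)$estimate, 0.5)
  # 15 variants, unequal weights: brute-force CDF oracle to 1e-12
  set.seed(341)
  n <- 15
  bx <- runif(n, 0.05, 0.4)
  sy <- runif(n, 0.01, 0.1)
  by <- 0.3 * bx + rnorm(n, 0, sy)
  dat3 <- data.frame(beta_x = bx, se_x = 0.01, beta_y = by, se_y = sy)
  want <- oracle_weighted_median(by / bx, bx^2 / sy^2)
  expect_equal(mr_weighted_median(dat3, n_boot = 100, seed = 5)$estimate,
               want, tolerance = 1e-12)
  # bootstrap SE stable to 5% across seeds at n_boot = 2000
  s1 <- mr_weighted_median(dat3, n_boot = 2000, seed = 1)$se
  s2 <- mr_weighted_median(dat3, n_boot = 2000, seed = 2)$se
  expect_lt(abs(s1 - s2) / s1, 0.05)
  expect_error(mr_weighted_median(dat3[1:2, ]), "at least 3")
  expect_error(mr_weighted_median(transform(dat3, beta_x = 0)), "beta_x = 0")
})

test_that("modified IVW is the substitution identity on the age slopes", {
  set.seed(351)
  n <- 20
  delta <- rnorm(n, 0, 0.01)
  ids <- sprintf("v%02d", 1:n)
  inter <- data.frame(variant_id = ids, delta = delta, se_delta = 0.002)
  outc <- generate_outcome_summary(ids, delta_true = delta,
                                   pi_ref = rep(0.1, n), b_level = 0,
                                   b_rate = 1.5, se_outcome = 0.03, seed = 7)
  got <- mr_modified_ivw(inter, outc)
  direct <- mr_ivw(data.frame(beta_x = delta, beta_y = outc$beta,
                              se_y = outc$se))
  expect_equal(got$estimate, direct$estimate, tolerance = 1e-12)
  expect_equal(got$se, direct$se, tolerance = 1e-12)
  expect_equal(got$method, "ivw_modified")
  expect_error(mr_modified_ivw(transform(inter, delta = 0), outc), "zero")
})

test_that("modified IVW recovers the generating age-effect coefficient", {
  set.seed(361)
  n <- 200
  delta <- rnorm(n, 0, 0.01)
  ids <- sprintf("v%03d", 1:n)
  inter <- data.frame(variant_id = ids, delta = delta, se_delta = 0.002)
  outc <- generate_outcome_summary(ids, delta_true = delta,
                                   pi_ref = rep(0, n), b_level = 0,
                                   b_rate = 0.8, se_outcome = 0.01, seed = 8)
  r <- mr_modified_ivw(inter, outc)
  expect_lt(abs(r$estimate - 0.8), 3 * r$se)
})

test_that("age-stratified MR contrasts young and old exposure estimates", {
  # deterministic construction: old-age effects double the young ones
  ids <- sprintf("v%02d", 1:10)
  young <- make_sumstats(ids, beta = seq(0.1, 0.3, length.out = 10), se = 0.01)
  old <- make_sumstats(ids, beta = 2 * young$beta, se = 0.01)
  young$stratum <- "1"; old$stratum <- "15"
  strat <- rbind(young, old)
  outc <- make_sumstats(ids, beta = 0.5 * old$beta, se = 0.02)
  res <- age_stratified_mr(strat, outc, strata = c(1, 15), snp_ids = ids)
  expect_equal(res$stratum_15$estimate, 0.5, tolerance = 1e-10)
  expect_equal(res$stratum_1$estimate, 1, tolerance = 1e-10)
  expect_gt(res$stratum_1$estimate, res$stratum_15$estimate)
  # single variant reduces to the per-stratum Wald ratio
  res1 <- age_stratified_mr(strat[strat$variant_id == "v01", ], outc,
                            strata = c(1, 15), snp_ids = "v01")
  expect_equal(res1$stratum_1$method, "wald_ratio")
  expect_equal(res1$stratum_1$estimate,
               outc$beta[1] / young$beta[1], tolerance = 1e-12)
})

test_that("stratum estimates agree under a null age interaction", {
  cfg <- cohort_config(n_individuals = 20000, n_snps = 20, maf = 0.3,
                       beta_g = 0.3, theta = 0, noise_sd = 1, seed = 371)
  co <- cap_strata(generate_cohort(cfg), seed = 372)
  strat <- stratified_scan(co)
  outc <- generate_outcome_summary(co$variants$variant_id,
                                   delta_true = co$variants$theta,
                                   pi_ref = co$variants$beta_g,
                                   b_level = 0.5, se_outcome = 0.02,
                                   seed = 373)
  res <- age_stratified_mr(strat, outc, strata = c(1, 15),
                           snp_ids = co$variants$variant_id)
  diff <- abs(res$stratum_1$estimate - res$stratum_15$estimate)
  comb <- sqrt(res$stratum_1$se^2 + res$stratum_15$se^2)
  expect_lt(diff, 2 * comb)
})

test_that("odds-ratio transform is the exponential map", {
  r0 <- mr_ivw(data.frame(beta_x = 1, beta_y = 0, se_y = 0.1))
  expect_equal(to_odds_ratio(r0)$or, 1)
  r2 <- mr_ivw(data.frame(beta_x = 1, beta_y = log(2), se_y = 0.1))
  expect_equal(to_odds_ratio(r2)$or, 2)
  # log/exp round trip at the reported precision of a typical estimate
  r <- structure(list(method = "ivw_modified", estimate = 0.9969,
                      se = NA, ci_lo = 0.7324, ci_hi = 1.2613, p = NA,
                      n_snp = 10, Q = NA, overdispersion = NA),
                 class = "mr_result")
  o <- to_odds_ratio(r)
  expect_equal(round(o$or, 2), 2.71)
  expect_equal(round(o$ci_lo, 2), 2.08)
  expect_equal(round(o$ci_hi, 2), 3.53)
})
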