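test_that("meta-regression recovers exact lines and rejects thin input", {
  expect_error(meta_regress_snp(c(0.1, 0.2), c(0.01, 0.01), c(41, 61)),
               "at least 3")
  expect_error(meta_regress_snp(c(0.1, 0.2, 0.3), c(0.01, 0, 0.01),
                                c(41, 51, 61)), "positive")
  # collinear points: slope exact, no residual heterogeneity
  f <- meta_regress_snp(c(0.10, 0.15, 0.20), rep(0.01, 3), c(41, 51, 61))
  expect_equal(f$delta, 0.005, tolerance = 1e-12)
  expect_equal(f$QE, 0, tolerance = 1e-12)
  # constant effects: slope exactly zero
  f0 <- meta_regress_snp(rep(0.07, 5), rep(0.02, 5), seq(41, 69, 7))
  expect_equal(f0$delta, 0, tolerance = 1e-14)
  expect_equal(coef(f)[["delta"]], f$delta)
})

test_that("meta-regression equals the closed-form WLS oracle", {
  set.seed(201)
  ages <- seq(40.5, 68.5, 2)
  ses <- runif(15, 0.01, 0.08)
  betas <- 0.2 - 0.005 * (ages - 40) + rnorm(15, 0, ses)
  f <- meta_regress_snp(betas, ses, ages)
  o <- oracle_wls_known_var(betas, cbind(1, ages), 1 / ses^2)
  expect_equal(f$delta, o$coef[2], tolerance = 1e-10)
  expect_equal(f$se_delta, o$se[2], tolerance = 1e-10)
  expect_equal(f$intercept, o$coef[1], tolerance = 1e-10)
  expect_equal(f$p_int, 2 * pnorm(-abs(o$coef[2] / o$se[2])),
               tolerance = 1e-10)
  # no-intercept mode: regression through the moderator origin
  fn <- meta_regress_snp(betas, ses, ages, intercept = FALSE)
  on <- oracle_wls_known_var(betas, cbind(ages), 1 / ses^2)
  expect_equal(fn$delta, on$coef[1], tolerance = 1e-10)
})

test_that("meta-regression agrees with an established meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(211)
  ages <- seq(40.5, 68.5, 2)
  ses <- runif(15, 0.02, 0.06)
  betas <- 0.1 + 0.004 * ages + rnorm(15, 0, ses)
  f <- meta_regress_snp(betas, ses, ages)
  m <- metafor::rma(yi = betas, sei = ses, mods = ~ages, method = "FE")
  expect_equal(f$delta, unname(m$beta[2, 1]), tolerance = 1e-8)
  expect_equal(f$se_delta, m$se[2], tolerance = 1e-8)
  expect_equal(f$QE, m$QE, tolerance = 1e-6)
})

test_that("moderator centring shifts the intercept but not the slope", {
  set.seed(221)
  ses <- runif(15, 0.02, 0.06)
  ages <- seq(40.5, 68.5, 2)
  betas <- 0.3 - 0.002 * ages + rnorm(15, 0, ses)
  a <- meta_regress_snp(betas, ses, ages)
  b <- meta_regress_snp(betas, ses, ages - 55)
  expect_equal(a$delta, b$delta, tolerance = 1e-12)
  expect_equal(a$se_delta, b$se_delta, tolerance = 1e-12)
  expect_equal(a$p_int, b$p_int, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$intercept, b$intercept)))
  # allele recoding negates slope and intercept, p unchanged
  c_ <- meta_regress_snp(-betas, ses, ages)
  expect_equal(c_$delta, -a$delta, tolerance = 1e-12)
  expect_equal(c_$intercept, -a$intercept, tolerance = 1e-12)
  expect_equal(c_$p_int, a$p_int, tolerance = 1e-12)
})

test_that("scan flags variants with missing strata and fits the rest", {
  set.seed(231)
  ages <- seq(40.5, 68.5, 2)
  long <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(variant_id = paste0("v", j), beta = rnorm(15, 0, 0.05),
               se = runif(15, 0.02, 0.05), mean_age = ages,
               stratum = as.character(1:15))
  }))
  long <- long[!(long$variant_id == "v2" & long$stratum == "9"), ]
  sc <- metareg_scan(long)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$flag[sc$variant_id == "v2"], "missing_strata")
  expect_equal(sc$n_strata[sc$variant_id == "v2"], 14L)
  expect_equal(sc$flag[sc$variant_id == "v1"], "ok")
  # a variant with almost no strata is not fitted
  long2 <- rbind(long, data.frame(variant_id = "v4", beta = 0.1, se = 0.05,
                                  mean_age = 40.5, stratum = "1"))
  sc2 <- metareg_scan(long2)
  expect_equal(sc2$flag[sc2$variant_id == "v4"], "insufficient")
  expect_true(is.na(sc2$delta[sc2$variant_id == "v4"]))
})

test_that("inclusion sets apply strict thresholds and stay nested", {
  ids <- sprintf("v%03d", 1:100)
  p <- rep(0.5, 100)
  p[1] <- 0.04      # inclusion 1
  p[2] <- 0.05      # exactly at threshold: excluded (strict <)
  p[3] <- 1e-6      # non-discovery, inclusion 2
  p[4] <- 1e-9      # discovery, Bonferroni and genome-wide scale
  records <- data.frame(variant_id = ids, p_int = p)
  r2m <- diag(100); dimnames(r2m) <- list(ids, ids)
  sets <- classify_inclusion(discovery_ids = ids[1:50], records, r2m)
  expect_true("v001" %in% sets$inclusion1)
  expect_false("v002" %in% sets$inclusion1)
  expect_true("v003" %in% sets$inclusion2)
  expect_true("v004" %in% sets$bonferroni)   # 1e-9 < 0.05/50
  expect_true(all(sets$inclusion1 %in% sets$discovery))
  expect_true(all(sets$bonferroni %in% sets$inclusion1))
  expect_true(all(sets$genomewide_interaction %in% sets$inclusion2))
  expect_error(classify_inclusion(character(), records, r2m), "empty")
})

test_that("inclusion counting reproduces printed-fraction arithmetic", {
  # constructed p-value vector: 1150 discovery variants, exactly 119 below 0.05
  ids <- sprintf("d%04d", 1:1150)
  p <- c(runif(119, 0, 0.049), runif(1031, 0.051, 1))
  records <- data.frame(variant_id = ids, p_int = p)
  r2m <- diag(1150); dimnames(r2m) <- list(ids, ids)
  sets <- classify_inclusion(ids, records, r2m)
  expect_length(sets$inclusion1, 119)
  expect_equal(round(100 * length(sets$inclusion1) / length(sets$discovery), 1),
               10.3)
})

test_that("sign-change fraction counts strictly mixed-sign variants", {
  expect_equal(sign_change_fraction(matrix(c(0.1, 0.2, 0.3), 1)), 0)
  expect_equal(sign_change_fraction(matrix(c(-0.1, 0, 0.1), 1)), 1)
  expect_equal(sign_change_fraction(matrix(c(0, 0, 0.1), 1)), 0)  # zeros ignored
  m <- rbind(matrix(rep(c(-1, 1), 97), 97, 2, byrow = TRUE),
             matrix(1, 3, 2))
  expect_equal(sign_change_fraction(m), 0.97)
  # long-format input
  long <- data.frame(variant_id = rep(c("a", "b"), each = 2),
                     beta = c(-1, 1, 1, 2))
  expect_equal(sign_change_fraction(long), 0.5)
})

test_that("individual-level interaction scan equals its OLS oracle", {
  co <- tiny_cohort(n = 400, n_snps = 3, seed = 241)
  res <- interaction_scan_individual(co, age_ref = 55)
  d <- co$data
  for (j in 1:3) {
    g <- co$dosages[, j]
    fit <- lm(d$trait ~ d$age + d$sex + d$chip + g + I(g * (d$age - 55)))
    s <- summary(fit)$coefficients
    expect_equal(res$beta_main[j], s["g", 1], tolerance = 1e-10)
    expect_equal(res$se_main[j], s["g", 2], tolerance = 1e-10)
    expect_equal(res$beta_inter[j], s["I(g * (d$age - 55))", 1],
                 tolerance = 1e-10)
    expect_equal(res$se_inter[j], s["I(g * (d$age - 55))", 2],
                 tolerance = 1e-10)
  }
})

test_that("interaction scan recovers a noiseless interaction and filters rare variants", {
  co <- tiny_cohort(n = 500, n_snps = 2, seed = 251)
  co$data$trait <- (0.2 + 0.01 * (co$data$age - 55)) * co$dosages[, 1]
  res <- interaction_scan_individual(co, covariates = character(),
                                     age_ref = 55)
  expect_equal(res$beta_main[1], 0.2, tolerance = 1e-8)
  expect_equal(res$beta_inter[1], 0.01, tolerance = 1e-8)
  # variant below the MAF filter is skipped with a flag
  co$dosages[, 2] <- c(1L, rep(0L, 499))  # maf 0.1%... still above 0.01%
  res2 <- interaction_scan_individual(co, maf_min = 0.01)
  expect_equal(res2$flag[2], "maf_filtered")
  expect_true(is.na(res2$beta_inter[2]))
})

test_that("summary-level slopes track individual-level interaction estimates", {
  set.seed(261)
  theta <- rnorm(100, 0, 0.01)
  cfg <- cohort_config(n_individuals = 15000, n_snps = 100, maf = 0.3,
                       beta_g = 0.05, theta = theta, beta_age = 0.01,
                       noise_sd = 1, seed = 262)
  co <- generate_cohort(cfg)
  co <- cap_strata(co, seed = 263)
  sc <- metareg_scan(stratified_scan(co))
  ind <- interaction_scan_individual(co)
  m <- match(sc$variant_id, ind$variant_id)
  expect_gt(cor(sc$delta, ind$beta_inter[m]), 0.9)
  # and both track the generating slopes
  vt <- co$variants$theta[match(sc$variant_id, co$variants$variant_id)]
  expect_gt(cor(sc$delta, vt), 0.9)
})
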