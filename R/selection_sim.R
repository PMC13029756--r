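#' Specification of the selection-bias simulation study
#'
#' Describes a factorial grid of selection mechanisms crossed with the
#' presence/absence of a genetic effect. Each replicate generates a cohort
#' under the linear trait model of [cohort_config()] with a single variant,
#' applies rank-based selection on the score
#' \eqn{S = \delta_1 A + \delta_2 A X + \delta_3 X + \delta_4 U + v}
#' (the half of the sample with the highest S set to missing), splits the
#' observed individuals into equal-width age groups and re-estimates the
#' genetic effect in each group by OLS of the trait on genotype and age.
#'
#' The default grids use per-year scales consistent with age generated in
#' years on 40-69: `delta_age` in {0, 0.005}/yr, `delta_inter` in
#' {0, 0.0167}/yr (0.5 spread over the 30-year span), `delta_trait` in
#' {0, 0.5} per trait unit, `delta_u` fixed at 0.2.
#'
#' @param delta_age grid of age coefficients (per year).
#' @param delta_inter grid of age-by-trait coefficients (per year-unit).
#' @param delta_trait grid of trait coefficients (per unit).
#' @param delta_u fixed confounder coefficient.
#' @param beta_g genetic effects to cross with the grid ({0, b}).
#' @param beta_age,beta_u,noise_sd trait-model parameters.
#' @param maf allele frequency of the single variant.
#' @param n individuals per replicate.
#' @param n_age_groups equal-width age groups (default 4).
#' @param n_reps replicates per grid point.
#' @param seed RNG seed.
#' @return An object of class `selection_sim_spec`.
#' @export
selection_sim_spec <- function(delta_age = c(0, 0.005),
                               delta_inter = c(0, 0.0167),
                               delta_trait = c(0, 0.5),
                               delta_u = 0.2,
                               beta_g = c(0, 0.3),
                               beta_age = 0.01, beta_u = 0.5, noise_sd = 1,
                               maf = 0.4, n = 50000L,
                               n_age_groups = 4L, n_reps = 200L, seed = 1L) {
  if (n_age_groups < 2L) stop("n_age_groups must be >= 2", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(delta_age = delta_age, delta_inter = delta_inter,
                 delta_trait = delta_trait, delta_u = delta_u,
                 beta_g = beta_g, beta_age = beta_age, beta_u = beta_u,
                 noise_sd = noise_sd, maf = maf, n = as.integer(n),
                 n_age_groups = as.integer(n_age_groups),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "selection_sim_spec")
}

#' Run the selection-bias simulation study
#'
#' For every grid point of the specification, repeatedly generates a
#' cohort, applies selection, and estimates the per-age-group genetic
#' effect \eqn{\hat\gamma_{1a}} among the observed individuals from the
#' regression \eqn{X = \gamma_0 + \gamma_1 G + \gamma_2 A + \omega}.
#' Reports, per grid point and age group, the mean estimate, bias relative
#' to the generating `beta_g`, and Monte-Carlo SE; per grid point, the
#' average marginal variance in missingness explained by the genotype
#' (`r2_g`) and by age (`r2_a`), each from a single-predictor regression of
#' the missingness indicator over the full pre-selection sample.
#'
#' @param spec a [selection_sim_spec()].
#' @return An object of class `selection_sim`: list with `estimates` (one
#'   row per grid point x age group) and `r2` (one row per grid point),
#'   plus the `spec`.
#' @export
run_selection_sim <- function(spec) {
  stopifnot(inherits(spec, "selection_sim_spec"))
  grid <- expand.grid(delta_age = spec$delta_age,
                      delta_inter = spec$delta_inter,
                      delta_trait = spec$delta_trait,
                      beta_g = spec$beta_g,
                      KEEP.OUT.ATTRS = FALSE)
  ng <- spec$n_age_groups
  breaks <- seq(40, 70, length.out = ng + 1L)
  est_rows <- list()
  r2_rows <- list()
  for (g in seq_len(nrow(grid))) {
    gp <- grid[g, ]
    params <- selection_params(delta_age = gp$delta_age,
                               delta_inter = gp$delta_inter,
                               delta_trait = gp$delta_trait,
                               delta_u = spec$delta_u)
    gam <- matrix(NA_real_, spec$n_reps, ng)
    r2g <- r2a <- numeric(spec$n_reps)
    for (r in seq_len(spec$n_reps)) {
      rep_seed <- derive_seed(spec$seed, (g - 1L) * spec$n_reps + r)
      cfg <- cohort_config(n_individuals = spec$n, n_snps = 1L,
                           maf = spec$maf, beta_g = gp$beta_g, theta = 0,
                           age_ref = 0, beta_age = spec$beta_age,
                           beta_u = spec$beta_u, noise_sd = spec$noise_sd,
                           seed = rep_seed)
      co <- generate_cohort(cfg)
      co <- apply_selection(co, params, seed = rep_seed + 1L)
      d <- co$data
      miss <- as.numeric(!d$selected)
      G <- co$dosages[, 1L]
      r2g[r] <- stats::cor(miss, G)^2
      r2a[r] <- stats::cor(miss, d$age)^2
      grp <- findInterval(d$age, breaks, rightmost.closed = TRUE)
      x <- d$trait
      for (a in seq_len(ng)) {
        i <- d$selected & grp == a
        if (sum(i) >= 10L) {
          f <- stats::lm.fit(cbind(1, G[i], d$age[i]), x[i])
          gam[r, a] <- f$coefficients[2L]
        }
      }
    }
    for (a in seq_len(ng)) {
      v <- gam[, a]
      n_ok <- sum(!is.na(v))
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        delta_age = gp$delta_age, delta_inter = gp$delta_inter,
        delta_trait = gp$delta_trait, beta_g = gp$beta_g,
        age_group = a,
        mean_gamma = mean(v, na.rm = TRUE),
        bias = mean(v, na.rm = TRUE) - gp$beta_g,
        mc_se = stats::sd(v, na.rm = TRUE) / sqrt(max(n_ok, 1L)),
        n_reps = n_ok,
        flag = if (n_ok < spec$n_reps) "some_groups_empty" else "ok",
        stringsAsFactors = FALSE)
    }
    r2_rows[[length(r2_rows) + 1L]] <- data.frame(
      delta_age = gp$delta_age, delta_inter = gp$delta_inter,
      delta_trait = gp$delta_trait, beta_g = gp$beta_g,
      r2_g = mean(r2g), r2_a = mean(r2a), stringsAsFactors = FALSE)
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 r2 = do.call(rbind, r2_rows), spec = spec),
            class = "selection_sim")
}

#' @export
print.selection_sim <- function(x, ...) {
  cat(sprintf(
    "Selection-bias simulation: %d grid points x %d age groups, %d reps\n",
    nrow(x$r2), x$spec$n_age_groups, x$spec$n_reps))
  inter <- x$estimates$delta_inter != 0 & x$estimates$beta_g != 0
  cat(sprintf("  max |bias| with interaction selection: %.4f\n",
              max(abs(x$estimates$bias[inter]), 0)))
  cat(sprintf("  max |bias| with beta_g = 0: %.4f\n",
              max(abs(x$estimates$bias[x$estimates$beta_g == 0]), 0)))
  invisible(x)
}

#' Plot age-group bias panels of a selection simulation
#'
#' Bias in the estimated genetic effect against age group, one panel per
#' selection-parameter combination.
#'
#' @param x a `selection_sim`.
#' @param beta_g which genetic-effect level to display.
#' @param ... ignored.
#' @export
plot.selection_sim <- function(x, beta_g = max(x$spec$beta_g), ...) {
  e <- x$estimates[x$estimates$beta_g == beta_g, ]
  key <- interaction(e$delta_age, e$delta_inter, e$delta_trait, drop = TRUE)
  panels <- levels(key)
  nc <- ceiling(sqrt(length(panels)))
  nr <- ceiling(length(panels) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (pn in panels) {
    d <- e[key == pn, ]
    plot(d$age_group, d$bias, type = "b", pch = 19,
         ylim = range(e$bias) + c(-1, 1) * max(e$mc_se),
         xlab = "Age group", ylab = "Bias",
         main = sprintf("d1=%g d2=%g d3=%g", d$delta_age[1],
                        d$delta_inter[1], d$delta_trait[1]))
    graphics::arrows(d$age_group, d$bias - 2 * d$mc_se,
                     d$age_group, d$bias + 2 * d$mc_se,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Linear-probability attendance curves by age group
#'
#' Fits a linear model of the attendance indicator on the trait, age-group
#' dummies and trait-by-age-group interactions, returning the per-group
#' intercept and trait slope (with SEs) and fitted attendance
#' probabilities over a grid of trait values. Groups with fewer than 10
#' attendees or 10 non-attendees are flagged.
#'
#' @param cohort a `cohort` with an `attended` column.
#' @param trait trait column name.
#' @param n_age_groups number of equal-width age groups (default 5).
#' @param trait_grid trait values at which to evaluate fitted
#'   probabilities (default 25 values spanning the sample range).
#' @return A list with `coefficients` (per-group intercept, slope, SEs,
#'   flag), `fitted` (long data.frame: age_group, trait, prob) and the
#'   underlying `model`.
#' @export
attendance_curves <- function(cohort, trait = cohort$config$trait_name,
                              n_age_groups = 5L, trait_grid = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (is.null(d$attended)) stop("cohort has no attended column", call. = FALSE)
  breaks <- seq(min(d$age), max(d$age) + 1L, length.out = n_age_groups + 1L)
  grp <- factor(findInterval(d$age, breaks, rightmost.closed = TRUE),
                levels = seq_len(n_age_groups))
  x <- d[[trait]]
  fit <- stats::lm(d$attended ~ grp + x:grp - 1)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  flags <- vapply(levels(grp), function(g) {
    att <- d$attended[grp == g]
    if (sum(att == 1) < 10 || sum(att == 0) < 10) "sparse" else "ok"
  }, character(1))
  coefs <- data.frame(age_group = seq_len(n_age_groups),
                      intercept = cf[seq_len(n_age_groups)],
                      slope = cf[n_age_groups + seq_len(n_age_groups)],
                      se_intercept = se[seq_len(n_age_groups)],
                      se_slope = se[n_age_groups + seq_len(n_age_groups)],
                      flag = flags, row.names = NULL,
                      stringsAsFactors = FALSE)
  if (is.null(trait_grid))
    trait_grid <- seq(min(x), max(x), length.out = 25L)
  fitted <- do.call(rbind, lapply(seq_len(n_age_groups), function(g)
    data.frame(age_group = g, trait = trait_grid,
               prob = coefs$intercept[g] + coefs$slope[g] * trait_grid)))
  list(coefficients = coefs, fitted = fitted, model = fit)
}

#' Logistic trait-by-age interaction on attendance
#'
#' Logistic regressions of the attendance indicator on trait, age and
#' their interaction, fitted over the full age range and within each of
#' `age_bins` equal-width bins, by iteratively reweighted least squares
#' (deviance tolerance 1e-8, at most 50 iterations). Non-convergence or
#' separation (runaway coefficients) is flagged, never silently truncated.
#'
#' @param cohort a `cohort` with an `attended` column.
#' @param trait trait column name.
#' @param age_bins number of equal-width age bins (default 5).
#' @return A data.frame: one row per bin plus an `"overall"` row, with the
#'   interaction coefficient, SE, Wald z and p, and a convergence flag.
#' @export
attendance_interaction <- function(cohort, trait = cohort$config$trait_name,
                                   age_bins = 5L) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (is.null(d$attended)) stop("cohort has no attended column", call. = FALSE)
  x <- d[[trait]]
  breaks <- seq(min(d$age), max(d$age) + 1L, length.out = age_bins + 1L)
  grp <- findInterval(d$age, breaks, rightmost.closed = TRUE)
  fit_one <- function(idx, label) {
    fit <- suppressWarnings(stats::glm(
      d$attended[idx] ~ x[idx] * d$age[idx], family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
    co <- summary(fit)$coefficients
    term <- "x[idx]:d$age[idx]"
    if (!term %in% rownames(co))  # aliased (e.g. constant age in the bin)
      return(data.frame(bin = label, estimate = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, flag = "not_estimable",
                        stringsAsFactors = FALSE))
    sep <- !fit$converged || any(abs(stats::coef(fit)) > 20, na.rm = TRUE)
    data.frame(bin = label, estimate = co[term, 1], se = co[term, 2],
               z = co[term, 3], p = co[term, 4],
               flag = if (sep) "separation_or_nonconvergence" else "ok",
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(age_bins), function(g)
    fit_one(grp == g, as.character(g)))
  rows[[age_bins + 1L]] <- fit_one(rep(TRUE, nrow(d)), "overall")
  do.call(rbind, rows)
}

#' Repeat-clinic attendance rate
#'
#' @param n_invited number invited.
#' @param n_attended number who attended.
#' @return Attendance percentage, reported to 2 decimal places.
#' @export
attendance_rate <- function(n_invited, n_attended) {
  if (n_attended > n_invited)
    stop("n_attended cannot exceed n_invited", call. = FALSE)
  round(100 * n_attended / n_invited, 2)
}
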