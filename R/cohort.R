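#' Configuration for a synthetic individual-level cohort
#'
#' Describes the generative model for a cohort of middle-aged adults with a
#' quantitative trait whose per-allele genetic effects change linearly with
#' age at measurement:
#' \deqn{X_i = \beta_0 + \beta_{age} A_i + \sum_j (\beta_{g,j} + \theta_j (A_i - a_{ref})) G_{ij} + \beta_u U_i + u_i}
#' with \eqn{A_i} uniform on the integers \code{age_min:age_max}, dosages
#' \eqn{G_{ij} \sim Binomial(2, maf_j)}, a standard-normal confounder
#' \eqn{U_i} and residual \eqn{u_i \sim N(0, noise\_sd^2)}.
#'
#' @param n_individuals number of individuals.
#' @param n_snps number of independent variants.
#' @param maf allele frequencies in (0, 0.5], recycled to `n_snps`.
#' @param beta_g per-SNP main effects at `age_ref` (trait units per allele),
#'   recycled to `n_snps`.
#' @param theta per-SNP age-interaction slopes (trait units per allele per
#'   year), recycled to `n_snps`.
#' @param age_min,age_max inclusive integer age range in years.
#' @param age_ref age in years at which `beta_g` applies.
#' @param beta_age trait units per year of age.
#' @param beta_u trait units per confounder SD.
#' @param intercept trait units.
#' @param noise_sd residual standard deviation (> 0).
#' @param chip_fraction fraction genotyped on the alternate array.
#' @param trait_name column name for the generated trait.
#' @param seed RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals, n_snps = 1L, maf = 0.4,
                          beta_g = 0, theta = 0,
                          age_min = 40L, age_max = 69L, age_ref = 55,
                          beta_age = 0, beta_u = 0, intercept = 0,
                          noise_sd = 1, chip_fraction = 0.1,
                          trait_name = "trait", seed = 1L) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L || n_individuals < 1)
    stop("n_individuals must be a positive count", call. = FALSE)
  n_snps <- as.integer(n_snps)
  maf <- rep_len(maf, n_snps)
  beta_g <- rep_len(beta_g, n_snps)
  theta <- rep_len(theta, n_snps)
  if (any(maf <= 0 | maf > 0.5))
    stop("all maf must lie in (0, 0.5]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (age_min >= age_max) stop("age_min must be < age_max", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals), n_snps = n_snps,
                 maf = maf, beta_g = beta_g, theta = theta,
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 age_ref = age_ref, beta_age = beta_age, beta_u = beta_u,
                 intercept = intercept, noise_sd = noise_sd,
                 chip_fraction = chip_fraction, trait_name = trait_name,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws individual ages, sex, genotyping-array indicator, confounder,
#' genotype dosages and the quantitative trait under the linear SNP-by-age
#' model described in [cohort_config()]. The same configuration (including
#' its seed) always yields a bit-identical cohort.
#'
#' @param config a [cohort_config()] object.
#' @return An object of class `cohort`: a list with elements
#'   \describe{
#'     \item{data}{data.frame with `id`, `age`, `sex`, `chip`, `confounder`
#'       and the trait column.}
#'     \item{dosages}{integer matrix (individuals x SNPs) of 0/1/2 dosages.}
#'     \item{variants}{data.frame of `variant_id`, `effect_allele`,
#'       `other_allele`, `maf`, `beta_g`, `theta`, `info` (pass-through
#'       imputation-quality field, always 1 for hard calls).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  p <- config$n_snps
  age <- sample(seq.int(config$age_min, config$age_max), n, replace = TRUE)
  sex <- rbinom(n, 1L, 0.5)
  chip <- rbinom(n, 1L, config$chip_fraction)
  confounder <- rnorm(n)
  dos <- matrix(rbinom(n * p, 2L, rep(config$maf, each = n)),
                nrow = n, ncol = p)
  genetic <- dos %*% config$beta_g +
    (dos %*% config$theta) * (age - config$age_ref)
  trait <- config$intercept + config$beta_age * age +
    as.vector(genetic) + config$beta_u * confounder +
    rnorm(n, sd = config$noise_sd)
  dat <- data.frame(id = seq_len(n), age = age, sex = sex, chip = chip,
                    confounder = confounder)
  dat[[config$trait_name]] <- trait
  al <- .assign_alleles(p)
  variants <- data.frame(variant_id = sprintf("snp%04d", seq_len(p)),
                         effect_allele = al$effect, other_allele = al$other,
                         maf = config$maf, beta_g = config$beta_g,
                         theta = config$theta, info = 1,
                         stringsAsFactors = FALSE)
  colnames(dos) <- variants$variant_id
  structure(list(data = dat, dosages = dos, variants = variants,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs, ages %d-%d\n",
              nrow(x$data), ncol(x$dosages),
              x$config$age_min, x$config$age_max))
  cat(sprintf("Trait '%s'; columns: %s\n", x$config$trait_name,
              paste(names(x$data), collapse = ", ")))
  invisible(x)
}

#' Selection-mechanism parameters
#'
#' Parameters of the linear selection score
#' \deqn{S_i = \delta_1 A_i + \delta_2 A_i X_i + \delta_3 X_i + \delta_4 U_i + v_i}
#' with selection noise \eqn{v_i \sim N(0, noise\_sd^2)}. By default the
#' `missing_fraction` of individuals with the highest scores are flagged as
#' missing (`direction = "highest-S-missing"`); the opposite convention
#' (`"highest-S-selected"`) retains them instead.
#'
#' @param delta_age per year.
#' @param delta_inter per year-trait-unit.
#' @param delta_trait per trait unit.
#' @param delta_u per confounder SD.
#' @param missing_fraction proportion removed, in [0, 1).
#' @param direction `"highest-S-missing"` or `"highest-S-selected"`.
#' @param noise_sd SD of the selection noise v (0 gives a deterministic
#'   score, useful for rank-arithmetic checks).
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(delta_age = 0, delta_inter = 0, delta_trait = 0,
                             delta_u = 0, missing_fraction = 0.5,
                             direction = c("highest-S-missing",
                                           "highest-S-selected"),
                             noise_sd = 1) {
  direction <- match.arg(direction)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(delta_age = delta_age, delta_inter = delta_inter,
                 delta_trait = delta_trait, delta_u = delta_u,
                 missing_fraction = missing_fraction, direction = direction,
                 noise_sd = noise_sd),
            class = "selection_params")
}

#' Apply a selection mechanism to a cohort
#'
#' Computes the selection score S for every individual and flags exactly
#' `round(missing_fraction * N)` of them as unselected, by rank of S in the
#' configured direction, ties broken by ascending individual id. Trait and
#' genotype values are never altered; two columns (`selection_score`,
#' `selected`) are added.
#'
#' @param cohort a `cohort`.
#' @param params a [selection_params()] object.
#' @param seed RNG seed for the selection noise.
#' @return The cohort with `selection_score` and logical `selected` columns.
#' @export
apply_selection <- function(cohort, params, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(params, "selection_params"))
  trait <- cohort$config$trait_name
  if (is.null(cohort$data[[trait]]))
    stop("cohort has no trait column; generate the cohort first", call. = FALSE)
  set.seed(seed)
  d <- cohort$data
  x <- d[[trait]]
  v <- if (params$noise_sd > 0) rnorm(nrow(d), sd = params$noise_sd) else 0
  s <- params$delta_age * d$age + params$delta_inter * d$age * x +
    params$delta_trait * x + params$delta_u * d$confounder + v
  n_miss <- round(params$missing_fraction * nrow(d))
  ord <- if (params$direction == "highest-S-missing")
    order(-s, d$id) else order(s, d$id)
  selected <- rep(TRUE, nrow(d))
  if (n_miss > 0) selected[ord[seq_len(n_miss)]] <- FALSE
  cohort$data$selection_score <- s
  cohort$data$selected <- selected
  cohort
}

#' Generate a repeat-assessment attendance indicator
#'
#' Attendance is Bernoulli with probability
#' \eqn{logit^{-1}(\alpha + (b_{trait} + b_{trait\_age}(A - a_{ref})) X)},
#' emulating a trait-by-age interaction in the probability of returning to a
#' repeat assessment clinic.
#'
#' @param cohort a `cohort` with its trait populated.
#' @param alpha logit-scale intercept.
#' @param b_trait per trait unit.
#' @param b_trait_age per trait unit per year.
#' @param age_ref centring age in years (defaults to the cohort's).
#' @param seed RNG seed.
#' @return The cohort with an integer `attended` column.
#' @export
generate_attendance <- function(cohort, alpha, b_trait = 0, b_trait_age = 0,
                                age_ref = cohort$config$age_ref, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  trait <- cohort$config$trait_name
  if (is.null(cohort$data[[trait]]))
    stop("cohort has no trait column", call. = FALSE)
  set.seed(seed)
  d <- cohort$data
  eta <- alpha + (b_trait + b_trait_age * (d$age - age_ref)) * d[[trait]]
  cohort$data$attended <- rbinom(nrow(d), 1L, plogis(eta))
  cohort
}

#' Generate synthetic outcome GWAS summary statistics
#'
#' Draws per-variant log-odds outcome associations
#' \eqn{\hat\Gamma_j \sim N(b_{level} \pi_{ref,j} + b_{rate} \delta_j,
#' se_j^2)}, i.e. the outcome responds both to the level of the genetically
#' predicted exposure at the reference age and to its rate of change with
#' age. The generating parameters are recorded as attributes.
#'
#' @param snp_ids character vector of variant ids.
#' @param delta_true per-SNP age-interaction slopes of the exposure.
#' @param pi_ref per-SNP exposure associations at the reference age.
#' @param b_level log-odds per exposure unit.
#' @param b_rate log-odds per exposure unit per year.
#' @param se_outcome per-SNP outcome standard errors (recycled).
#' @param eaf per-SNP effect-allele frequencies (recycled).
#' @param n_cases,n_controls case/control counts recorded in the table.
#' @param seed RNG seed.
#' @return A data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n_cases`, `n_controls`,
#'   carrying a `generating` attribute.
#' @export
generate_outcome_summary <- function(snp_ids, delta_true, pi_ref,
                                     b_level = 0, b_rate = 0,
                                     se_outcome = 0.05, eaf = 0.3,
                                     n_cases = 10000L, n_controls = 100000L,
                                     seed = 1L) {
  p <- length(snp_ids)
  if (length(delta_true) != p || length(pi_ref) != p)
    stop("snp_ids, delta_true and pi_ref must have equal length", call. = FALSE)
  se_outcome <- rep_len(se_outcome, p)
  if (any(se_outcome < 0)) stop("se_outcome must be >= 0", call. = FALSE)
  eaf <- rep_len(eaf, p)
  set.seed(seed)
  mu <- b_level * pi_ref + b_rate * delta_true
  beta <- mu + ifelse(se_outcome > 0, rnorm(p, sd = se_outcome), 0)
  z <- ifelse(se_outcome > 0, beta / se_outcome, Inf * sign(beta))
  pval <- ifelse(is.finite(z), 2 * pnorm(-abs(z)), ifelse(beta == 0, 1, 0))
  al <- .assign_alleles(p)
  out <- data.frame(variant_id = as.character(snp_ids),
                    effect_allele = al$effect, other_allele = al$other,
                    eaf = eaf, beta = beta,
                    se = se_outcome, pval = pval,
                    n_cases = n_cases, n_controls = n_controls,
                    stringsAsFactors = FALSE)
  attr(out, "generating") <- list(b_level = b_level, b_rate = b_rate,
                                  seed = seed)
  out
}

#' Serialize a cohort to tab-separated text
#'
#' Writes the per-individual table to `path` and, optionally, the dosage
#' matrix variant-major to `dosage_path`.
#'
#' @param cohort a `cohort`.
#' @param path output file for the individual table.
#' @param dosage_path optional output file for the genotype matrix.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, dosage_path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.table(cohort$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dosage_path)) {
    m <- t(cohort$dosages)
    out <- data.frame(variant_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, dosage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
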