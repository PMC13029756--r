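#' End-to-end run configuration
#'
#' Bundles the cohort generator, stratification grid, meta-regression
#' thresholds, outcome generator and MR settings for [run_pipeline()], and
#' validates them up front. Per-stage seeds are derived from the single
#' master seed (see [derive_seed()]), so any stage can be reproduced in
#' isolation.
#'
#' @param cohort a [cohort_config()] for the simulated study population.
#' @param n_strata,width,reference_stratum stratification grid and the
#'   stratum whose size caps the others.
#' @param p1,p2,r2,gw interaction thresholds: nominal (inclusion 1),
#'   suggestive (inclusion 2), clumping r^2, genome-wide.
#' @param discovery_p discovery genome-wide significance threshold.
#' @param b_level,b_rate,se_outcome outcome-generator settings.
#' @param n_boot weighted-median bootstrap resamples.
#' @param overdispersion IVW standard-error convention.
#' @param master_seed master RNG seed recorded in every output.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort,
                       n_strata = 15L, width = 2L, reference_stratum = 7L,
                       p1 = 0.05, p2 = 5e-5, r2 = 0.01, gw = 5e-8,
                       discovery_p = 5e-8,
                       b_level = 0.1, b_rate = 0.5, se_outcome = 0.05,
                       n_boot = 2000L,
                       overdispersion = c("multiplicative", "fixed"),
                       master_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  for (th in list(p1 = p1, p2 = p2, r2 = r2, gw = gw,
                  discovery_p = discovery_p)) {
    if (!is.numeric(th) || th <= 0 || th >= 1)
      stop("all thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(cohort = cohort, n_strata = as.integer(n_strata),
                 width = as.integer(width),
                 reference_stratum = as.integer(reference_stratum),
                 p1 = p1, p2 = p2, r2 = r2, gw = gw,
                 discovery_p = discovery_p,
                 b_level = b_level, b_rate = b_rate,
                 se_outcome = se_outcome, n_boot = as.integer(n_boot),
                 overdispersion = match.arg(overdispersion),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [run_config()], with a `cohort:` block for [cohort_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort)
  y$cohort <- NULL
  do.call(run_config, c(list(cohort = cohort), y))
}

.stage <- function(manifest, name, t0, files = character()) {
  digests <- if (length(files)) as.vector(tools::md5sum(files)) else character()
  manifest$stages[[name]] <- list(
    files = as.list(files),
    md5 = as.list(digests),
    seconds = round(as.numeric(Sys.time()) - t0, 3))
  manifest
}

#' Run the full age-stratified interaction and MR pipeline
#'
#' Executes, in order: cohort simulation; full-range discovery scan with
#' LD clumping; stratification with size capping and per-stratum scans;
#' per-SNP meta-regression; inclusion-set classification; synthetic
#' outcome generation; standard IVW MR per variant set and modified IVW
#' with the age slopes as exposures; and the stratum-level power
#' projection. All tabular outputs are written to `out_dir` and listed,
#' with content digests, in the returned manifest (also written as JSON).
#' Identical configurations produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return An object of class `run_manifest` (invisibly written to
#'   `manifest.json`): stage names, output files and digests, parameter
#'   echo, package version and wall times.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(stages = list(),
                   parameters = config[setdiff(names(config), "cohort")],
                   cohort = unclass(config$cohort),
                   version = as.character(utils::packageVersion("agevarmr")),
                   master_seed = config$master_seed)
  ms <- config$master_seed

  t0 <- as.numeric(Sys.time())
  say("stage simulate: generating cohort")
  cfg <- config$cohort
  cfg$seed <- derive_seed(ms, 1L)
  cohort <- generate_cohort(cfg)
  f_cohort <- file.path(out_dir, "cohort.tsv")
  write_cohort(cohort, f_cohort)
  manifest <- .stage(manifest, "simulate", t0, f_cohort)

  t0 <- as.numeric(Sys.time())
  say("stage discovery: full-range association scan")
  disc <- assoc_scan(cohort)
  f_disc <- file.path(out_dir, "discovery.tsv")
  write_sumstats(disc, f_disc)
  r2m <- dosage_r2(cohort)
  discovery_ids <- clump(disc, r2m, p_thresh = config$discovery_p,
                         r2_thresh = config$r2)
  manifest <- .stage(manifest, "discovery", t0, f_disc)

  t0 <- as.numeric(Sys.time())
  say("stage stratify: capping and per-stratum scans")
  cohort <- cap_strata(cohort, reference_stratum = config$reference_stratum,
                       seed = derive_seed(ms, 2L),
                       age_min = cfg$age_min, n_strata = config$n_strata,
                       width = config$width)
  strat <- stratified_scan(cohort, n_strata = config$n_strata)
  f_strat <- file.path(out_dir, "stratified.tsv")
  write_sumstats(strat, f_strat)
  manifest <- .stage(manifest, "stratify", t0, f_strat)

  t0 <- as.numeric(Sys.time())
  say("stage metareg: per-SNP meta-regression")
  scan <- metareg_scan(strat, n_strata_expected = config$n_strata)
  f_scan <- file.path(out_dir, "metareg.tsv")
  utils::write.table(scan, f_scan, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  manifest <- .stage(manifest, "metareg", t0, f_scan)

  t0 <- as.numeric(Sys.time())
  say("stage include: inclusion-set classification")
  sets <- if (length(discovery_ids)) {
    classify_inclusion(discovery_ids, scan, r2m, p1 = config$p1,
                       p2 = config$p2, r2_thresh = config$r2, gw = config$gw)
  } else NULL
  inc_files <- character()
  if (!is.null(sets))
    inc_files <- write_inclusion_sets(sets, file.path(out_dir, "inclusion"))
  manifest <- .stage(manifest, "include", t0, inc_files)

  t0 <- as.numeric(Sys.time())
  say("stage outcome: synthetic outcome summary statistics")
  outc <- generate_outcome_summary(cohort$variants$variant_id,
                                   delta_true = cohort$variants$theta,
                                   pi_ref = cohort$variants$beta_g,
                                   b_level = config$b_level,
                                   b_rate = config$b_rate,
                                   se_outcome = config$se_outcome,
                                   eaf = cohort$variants$maf,
                                   seed = derive_seed(ms, 3L))
  f_outc <- file.path(out_dir, "outcome.tsv")
  write_sumstats(outc, f_outc)
  manifest <- .stage(manifest, "outcome", t0, f_outc)

  t0 <- as.numeric(Sys.time())
  say("stage mr: standard and modified IVW")
  mr_rows <- list()
  add_mr <- function(res, set_name) {
    mr_rows[[length(mr_rows) + 1L]] <<- data.frame(
      set = set_name, method = res$method, estimate = res$estimate,
      se = res$se, ci_lo = res$ci_lo, ci_hi = res$ci_hi, p = res$p,
      n_snp = res$n_snp, Q = res$Q, overdispersion = res$overdispersion,
      stringsAsFactors = FALSE)
  }
  set_list <- if (is.null(sets)) list() else
    list(discovery = sets$discovery, inclusion1 = sets$inclusion1,
         inclusion2 = sets$inclusion2)
  for (nm in names(set_list)) {
    ids <- set_list[[nm]]
    if (length(ids) == 0L) next
    expd <- disc[disc$variant_id %in% ids & is.finite(disc$beta), ]
    if (nrow(expd) >= 1L) {
      h <- harmonize(expd, outc)
      add_mr(mr_ivw(h, overdispersion = config$overdispersion), nm)
    }
    inter <- scan[scan$variant_id %in% ids & is.finite(scan$delta) &
                    scan$delta != 0, ]
    if (nrow(inter) >= 1L)
      add_mr(mr_modified_ivw(inter, outc,
                             overdispersion = config$overdispersion), nm)
  }
  f_mr <- file.path(out_dir, "mr_results.tsv")
  mr_tab <- if (length(mr_rows)) do.call(rbind, mr_rows) else
    data.frame(set = character(), method = character())
  utils::write.table(mr_tab, f_mr, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  manifest <- .stage(manifest, "mr", t0, f_mr)

  t0 <- as.numeric(Sys.time())
  say("stage power: stratum-level power projection")
  pow_files <- character()
  if (length(discovery_ids)) {
    dd <- disc[match(discovery_ids, disc$variant_id), ]
    strat_sizes <- table(factor(strat$stratum,
                                levels = as.character(seq_len(config$n_strata))))
    small <- names(which.min(strat_sizes))
    ses <- strat$se[strat$stratum == small][
      match(discovery_ids, strat$variant_id[strat$stratum == small])]
    okp <- is.finite(dd$beta) & is.finite(ses) & ses > 0
    if (any(okp)) {
      pow <- power_projection(dd$beta[okp], ses[okp])
      f_pow <- file.path(out_dir, "power.json")
      jsonlite::write_json(list(stratum = small,
                                expected_loci = pow$expected_loci,
                                n_snps = sum(okp)),
                           f_pow, auto_unbox = TRUE, digits = NA)
      pow_files <- f_pow
    }
  }
  manifest <- .stage(manifest, "power", t0, pow_files)

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  class(manifest) <- "run_manifest"
  say("pipeline complete: %d stages", length(manifest$stages))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline manifest (seed %d, version %s)\n", x$master_seed,
              x$version))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %d file(s), %.2fs\n", nm,
                length(x$stages[[nm]]$files), x$stages[[nm]]$seconds))
  invisible(x)
}
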