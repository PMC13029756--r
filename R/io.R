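#' Write association records as a summary-statistics TSV
#'
#' Tab-separated, one-line header, `.` for missing values. Columns:
#' `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n`, and — for stratified files — `stratum` and `mean_age`.
#'
#' @param assoc association records (from [assoc_scan()] /
#'   [stratified_scan()], or any data.frame with the columns above).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(assoc, path) {
  cols <- intersect(c("variant_id", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pval", "n", "stratum", "mean_age"),
                    names(assoc))
  out <- assoc[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a summary-statistics TSV
#'
#' @param path file written by [write_sumstats()] (or in the same dialect).
#' @return A data.frame with numeric columns parsed and `.` as `NA`.
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = ".", stringsAsFactors = FALSE,
                         colClasses = NA)
  for (cl in intersect(c("eaf", "beta", "se", "pval", "mean_age"), names(d)))
    d[[cl]] <- as.numeric(d[[cl]])
  if ("stratum" %in% names(d)) d$stratum <- as.character(d$stratum)
  d
}

#' Validate a summary-statistics file
#'
#' Checks the header, column types, `se > 0`, `pval` in (0, 1], allele
#' characters in {A, C, G, T}, and — when `stratified` — the presence of
#' `stratum` and `mean_age` columns. Returns a row-level report of every
#' problem found; an empty report means the file is valid.
#'
#' @param path file to validate.
#' @param stratified whether the file must carry stratum columns.
#' @return A data.frame of class `sumstats_report` with columns `row`
#'   (`NA` for file-level problems), `column`, `problem`; attribute
#'   `valid` is TRUE iff no problems were found.
#' @export
validate_sumstats <- function(path, stratified = FALSE) {
  problems <- list()
  note <- function(row, column, problem)
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem, stringsAsFactors = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "eaf",
                "beta", "se", "pval", "n")
  if (stratified) required <- c(required, "stratum", "mean_age")
  d <- tryCatch(read_sumstats(path), error = function(e) NULL)
  if (is.null(d)) {
    note(NA_integer_, NA_character_, "file could not be parsed")
  } else {
    miss <- setdiff(required, names(d))
    for (mcol in miss)
      note(NA_integer_, mcol,
           if (mcol %in% c("stratum", "mean_age"))
             "missing column (stratified dialect)" else "missing column")
    if (!length(miss) || !any(c("se", "pval", "effect_allele") %in% miss)) {
      if ("se" %in% names(d))
        for (i in which(!is.na(d$se) & d$se <= 0))
          note(i, "se", "se must be > 0")
      if ("pval" %in% names(d))
        for (i in which(!is.na(d$pval) & (d$pval <= 0 | d$pval > 1)))
          note(i, "pval", "pval must lie in (0, 1]")
      for (acol in intersect(c("effect_allele", "other_allele"), names(d)))
        for (i in which(!d[[acol]] %in% c("A", "C", "G", "T")))
          note(i, acol, "allele must be one of A, C, G, T")
    }
  }
  report <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), column = character(), problem = character(),
               stringsAsFactors = FALSE)
  attr(report, "valid") <- nrow(report) == 0L
  class(report) <- c("sumstats_report", "data.frame")
  report
}

#' @export
print.sumstats_report <- function(x, ...) {
  if (attr(x, "valid")) cat("Summary-statistics file is valid.\n")
  else cat(sprintf("Summary-statistics file has %d problem(s):\n", nrow(x)))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Write inclusion sets to disk
#'
#' Each set goes to a newline-delimited id list; the thresholds used go to
#' a JSON manifest alongside.
#'
#' @param sets an `inclusion_sets` object.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_inclusion_sets <- function(sets, dir) {
  stopifnot(inherits(sets, "inclusion_sets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("discovery", "inclusion1", "inclusion2", "bonferroni",
               "genomewide_interaction")) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(sets[[nm]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "thresholds.json")
  jsonlite::write_json(sets$thresholds, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
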