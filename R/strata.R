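#' Assign individuals to two-year age strata
#'
#' Age `a` maps to stratum `floor((a - age_min) / width) + 1`; with the
#' defaults this yields 15 mutually exclusive two-year strata covering ages
#' 40-69. Ages outside the covered range are not an error: they receive
#' `NA` (excluded), mirroring the exclusion of participants outside the
#' recruitment age window.
#'
#' @param ages integer ages in years.
#' @param age_min lower bound of stratum 1.
#' @param n_strata number of strata.
#' @param width stratum width in years.
#' @return Integer stratum indices (1..n_strata), `NA` for excluded ages.
#' @export
assign_strata <- function(ages, age_min = 40L, n_strata = 15L, width = 2L) {
  idx <- floor((ages - age_min) / width) + 1L
  idx[idx < 1L | idx > n_strata] <- NA_integer_
  as.integer(idx)
}

#' Cap stratum sample sizes at a reference stratum's size
#'
#' Participant age in volunteer cohorts is typically skewed towards the
#' upper range, giving unequal stratum sizes. To equalise precision, strata
#' larger than the reference stratum are downsampled uniformly at random
#' (without replacement) to exactly its size; smaller strata are unchanged.
#'
#' @param cohort a `cohort`.
#' @param reference_stratum index of the stratum supplying the cap.
#' @param seed RNG seed for the downsampling.
#' @param age_min,n_strata,width stratification grid, see [assign_strata()].
#' @return The cohort with a logical `in_strata` column (TRUE for retained
#'   individuals) and an integer `stratum` column (`NA` when excluded by age
#'   or by capping).
#' @export
cap_strata <- function(cohort, reference_stratum = 7L, seed = 1L,
                       age_min = 40L, n_strata = 15L, width = 2L) {
  stopifnot(inherits(cohort, "cohort"))
  stratum <- assign_strata(cohort$data$age, age_min, n_strata, width)
  sizes <- tabulate(stratum, nbins = n_strata)
  cap <- sizes[reference_stratum]
  if (is.na(cap) || cap == 0L)
    stop("reference stratum is empty", call. = FALSE)
  set.seed(seed)
  keep <- !is.na(stratum)
  for (s in seq_len(n_strata)) {
    idx <- which(!is.na(stratum) & stratum == s)
    if (length(idx) > cap) {
      drop <- sample(idx, length(idx) - cap)
      keep[drop] <- FALSE
    }
  }
  cohort$data$stratum <- ifelse(keep, stratum, NA_integer_)
  cohort$data$in_strata <- keep
  cohort
}
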