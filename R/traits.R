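#' Pulse pressure from systolic and diastolic blood pressure
#'
#' Pulse pressure (PP), a proxy for arterial stiffness, is the difference
#' between systolic and diastolic blood pressure.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @return PP in mmHg (`sbp - dbp`).
#' @export
derive_pp <- function(sbp, dbp) {
  if (!all(is.finite(sbp)) || !all(is.finite(dbp)))
    stop("sbp and dbp must be finite", call. = FALSE)
  sbp - dbp
}

#' Adjust blood pressure for anti-hypertensive medication use
#'
#' Adds 15 mmHg to SBP and 10 mmHg to DBP for individuals who report use of
#' anti-hypertensive medication, the standard constant adjustment. Applying
#' the adjustment twice adds the constants twice; idempotence is not
#' assumed, so adjust once.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @param med_flag 0/1 indicator of self-reported medication use.
#' @return A list with adjusted `sbp` and `dbp` vectors.
#' @export
adjust_medication <- function(sbp, dbp, med_flag) {
  med <- as.numeric(med_flag)
  if (any(is.na(med)) || any(!med %in% c(0, 1)))
    stop("med_flag must be binary", call. = FALSE)
  list(sbp = sbp + 15 * med, dbp = dbp + 10 * med)
}
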