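#' Derive a per-stage RNG seed from a master seed
#'
#' Stages of [run_pipeline()] draw their seeds from the master seed by a
#' fixed affine counter scheme so that any stage can be rerun in isolation
#' and still reproduce its output. The result is kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 1)
  as.integer((abs(as.numeric(master)) * 1009 + 97 * as.numeric(stage)) %% 2147483647)
}

# non-palindromic allele pairs used for synthetic variants; keeps harmonize()
# from dropping variants as strand-ambiguous unless a test asks for it
.allele_pairs <- matrix(c("A", "G",
                          "A", "C",
                          "T", "G",
                          "T", "C",
                          "G", "A",
                          "C", "A",
                          "G", "T",
                          "C", "T"), ncol = 2, byrow = TRUE)

.assign_alleles <- function(n_snps) {
  idx <- ((seq_len(n_snps) - 1L) %% nrow(.allele_pairs)) + 1L
  list(effect = .allele_pairs[idx, 1L], other = .allele_pairs[idx, 2L])
}

.check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
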