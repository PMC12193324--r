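#' Published pooled RSCU values for three Medicago mitochondrial genomes
#'
#' The per-codon RSCU values of the ENC-decile high- and low-expression gene
#' pools, as published for the mitochondrial genomes of *Medicago
#' polymorpha*, *M. sativa* and *M. truncatula*, together with the printed
#' dRSCU column and the codons the published analysis reported as optimal.
#' This table lets the optimal-codon arithmetic ([call_optimal()],
#' [shared_optimal()]) be exercised and audited without access to the
#' underlying genome records.
#'
#' Two known quirks of the published table are preserved verbatim rather
#' than corrected: for *M. polymorpha* the printed dRSCU of the Lys rows
#' (AAA/AAG) and Gln rows (CAA/CAG) does not equal RSCU-H minus RSCU-L of
#' the same rows (the printed values match the *M. sativa* column instead),
#' and applying the stated optimality criteria (RSCU-H > 1, dRSCU >= 0.08)
#' marks more codons than the `reported_optimal` flags (e.g. CCU, GUU, CGU).
#' Compare `reported_optimal` with [call_optimal()] output to see the
#' discrepancy.
#'
#' @param species optionally restrict to one of `"M. polymorpha"`,
#'   `"M. sativa"`, `"M. truncatula"`.
#' @return data.frame with columns `species`, `amino_acid`, `codon` (RNA
#'   spelling as printed), `rscu_high`, `rscu_low`, `delta_printed`,
#'   `reported_optimal`.
#' @export
medicago_pool_rscu <- function(species = NULL) {
  path <- system.file("extdata", "medicago_mito_pool_rscu.tsv",
                      package = "mitocub", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$reported_optimal <- as.logical(df$reported_optimal)
  if (!is.null(species)) {
    stopifnot(all(species %in% df$species))
    df <- df[df$species %in% species, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
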