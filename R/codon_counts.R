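#' Count codons in a coding sequence
#'
#' Splits an in-frame coding sequence into consecutive non-overlapping
#' triplets and tabulates them over the 64-codon universe.
#'
#' @param x a single nucleotide sequence: character scalar,
#'   [Biostrings::DNAString], or a `coding_sequence` row as produced by the
#'   screening functions. `U` is accepted and treated as `T`.
#' @param include_stop logical; count stop codons? Default `FALSE`, matching
#'   the convention that downstream indices are computed on sense codons.
#' @param code a [genetic_code()] object (controls which codons are stops).
#' @param source optional label (gene or pool name) carried in the result.
#' @return An object of class `codon_counts`: a named integer vector over all
#'   64 codons (zeros included) with attributes `source` and `code_id`.
#' @examples
#' count_codons("ATGAAACGATAA")                      # stop not counted
#' count_codons("ATGAAACGATAA", include_stop = TRUE) # TAA counted
#' @export
count_codons <- function(x, include_stop = FALSE, code = genetic_code(),
                         source = NA_character_) {
  s <- normalize_codons(as.character(x))
  stopifnot(length(s) == 1L)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, " nt) is not a multiple of 3: not in frame")
  }
  codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  bad <- !codons %in% names(code$codon_to_aa)
  if (any(bad)) {
    stop("sequence contains non-ACGT codons: ",
         paste(unique(codons[bad]), collapse = ", "))
  }
  if (!include_stop) codons <- codons[!codons %in% code$stop_codons]
  counts <- stats::setNames(rep(0L, 64L), names(code$codon_to_aa))
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, source = source, code_id = code$id,
            class = c("codon_counts", "integer"))
}

#' Sum codon counts across genes
#'
#' Pools several `codon_counts` vectors (e.g. the members of an expression
#' pool) by elementwise addition.
#'
#' @param counts_list list of `codon_counts` objects over the same code.
#' @param source label for the pooled counts.
#' @return A `codon_counts` object.
#' @export
sum_codon_counts <- function(counts_list, source = "pool") {
  stopifnot(length(counts_list) >= 1L)
  out <- Reduce(`+`, lapply(counts_list, unclass))
  structure(as.integer(out), names = names(counts_list[[1]]),
            source = source, code_id = attr(counts_list[[1]], "code_id"),
            class = c("codon_counts", "integer"))
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts (", sum(x), " codons",
      if (!is.na(attr(x, "source"))) paste0(", source: ", attr(x, "source")),
      ")\n", sep = "")
  nz <- x[x > 0L]
  print(stats::setNames(as.integer(nz), names(nz)))
  invisible(x)
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon \eqn{c} in a family of \eqn{n} synonymous codons is the
#' observed count divided by the family mean, \eqn{x_c / (\sum x / n)}. A
#' value of 1 means the codon is used exactly as often as expected under
#' uniform synonymous usage; values above 1 mark preferred codons. Within
#' every family with a nonzero total the RSCU values sum to the family size.
#'
#' @param counts a [count_codons()] result (or any named numeric vector of
#'   codon counts).
#' @param code a [genetic_code()] object.
#' @return An object of class `rscu_table`: a data.frame with columns
#'   `amino_acid`, `codon` (DNA spelling), `codon_rna`, `count`, `rscu`.
#'   Families with zero total count are absent, not zero-filled. Stop codons
#'   are never included.
#' @examples
#' cc <- count_codons("ATGAGAAGAAGAAGGTAA")
#' rscu(cc)   # Arg: AGA used 3x, AGG 1x -> RSCU 4.5 and 1.5
#' @export
rscu <- function(counts, code = genetic_code()) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  rows <- lapply(names(code$families), function(a) {
    cods <- sort(code$families[[a]])
    x <- as.numeric(counts[cods])
    x[is.na(x)] <- 0
    tot <- sum(x)
    if (tot == 0) return(NULL)
    data.frame(amino_acid = a, codon = cods,
               count = x, rscu = x / (tot / length(cods)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(amino_acid = character(), codon = character(),
                      count = numeric(), rscu = numeric())
  }
  out <- out[order(out$amino_acid, out$codon), , drop = FALSE]
  out$codon_rna <- as_rna_codon(out$codon)
  rownames(out) <- NULL
  structure(out[, c("amino_acid", "codon", "codon_rna", "count", "rscu")],
            source = attr(counts, "source"),
            class = c("rscu_table", "data.frame"))
}

#' Extract a named RSCU vector over the synonymous codon universe
#'
#' Convenience accessor used by the clustering and optimal-codon stages:
#' returns RSCU keyed by codon over all synonymously variable codons of the
#' code, filling codons from unobserved families with `NA` (or 0 on request).
#'
#' @param x an `rscu_table`.
#' @param code a [genetic_code()] object.
#' @param fill value for codons of unobserved families (`NA` or `0`).
#' @return Named numeric vector over [synonymous_codons()] (DNA spelling).
#' @export
rscu_vector <- function(x, code = genetic_code(), fill = NA_real_) {
  stopifnot(inherits(x, "rscu_table"))
  cods <- sort(synonymous_codons(code))
  v <- stats::setNames(rep(fill, length(cods)), cods)
  keep <- x$codon %in% cods
  v[x$codon[keep]] <- x$rscu[keep]
  v
}

#' @export
print.rscu_table <- function(x, digits = 4, ...) {
  cat("RSCU over", nrow(x), "codons in", length(unique(x$amino_acid)),
      "amino-acid families\n")
  y <- as.data.frame(x)
  y$rscu <- round(y$rscu, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
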