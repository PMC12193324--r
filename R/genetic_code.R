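#' Genetic code tables for codon usage analysis
#'
#' Builds the codon/amino-acid machinery used throughout the package: the
#' codon-to-amino-acid map, synonymous families, and degeneracy classes.
#' Plant mitochondria translate with the standard code, which is therefore
#' the default; any NCBI translation table supported by
#' [Biostrings::getGeneticCode()] can be requested by id.
#'
#' @param id NCBI genetic code table id as a character scalar (`"1"` is the
#'   standard code).
#' @return An object of class `genetic_code`: a list with elements
#'   \describe{
#'     \item{id}{the table id}
#'     \item{codon_to_aa}{named character vector, 64 DNA codons to one-letter
#'       amino acids (`*` for stop)}
#'     \item{families}{named list, amino acid to its synonymous DNA codons}
#'     \item{degeneracy}{named integer vector, codon to its family size
#'       (stop codons get `NA`)}
#'     \item{stop_codons}{character vector of stop codons}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]   # "M"
#' length(gc$families$L)     # leucine is six-fold degenerate
#' @export
genetic_code <- function(id = "1") {
  map <- Biostrings::getGeneticCode(id)
  stopifnot(length(map) == 64L)
  aa <- map[map != "*"]
  fams <- split(names(aa), aa)
  deg <- stats::setNames(rep(NA_integer_, 64L), names(map))
  for (a in names(fams)) deg[fams[[a]]] <- length(fams[[a]])
  structure(
    list(
      id = id,
      codon_to_aa = map,
      families = fams,
      degeneracy = deg,
      stop_codons = names(map)[map == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  sizes <- table(vapply(x$families, length, integer(1)))
  cat("Genetic code table", x$id, "-", length(x$families), "amino acids,",
      length(x$stop_codons), "stop codons\n")
  cat("Family sizes:",
      paste(sprintf("%s-fold x%s", names(sizes), sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Synonymously variable codons of a genetic code
#'
#' Codons belonging to families with two or more members, i.e. those that
#' carry information about synonymous codon choice. Single-codon families
#' (Met and Trp in the standard code) and stop codons are excluded; this is
#' the codon universe over which GC3s, A3s/T3s/C3s/G3s, CAI, CBI and Fop are
#' defined.
#'
#' @param code a [genetic_code()] object.
#' @return Character vector of DNA codons (59 for the standard code).
#' @export
synonymous_codons <- function(code = genetic_code()) {
  unlist(code$families[vapply(code$families, length, integer(1)) > 1L],
         use.names = FALSE)
}

# normalize codon spellings: RNA -> DNA, uppercase
normalize_codons <- function(x) chartr("Uu", "Tt", toupper(x))

#' Convert DNA codons to the RNA spelling used in reports
#'
#' @param x character vector of codons.
#' @return The same codons with `T` replaced by `U`.
#' @export
as_rna_codon <- function(x) chartr("T", "U", toupper(x))
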