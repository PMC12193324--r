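#' Generate synthetic coding sequences with known ground truth
#'
#' Produces a set of clean CDSs (ATG start, TAA stop, no internal stops,
#' in-frame) whose codon usage follows one of two regimes, so that every
#' downstream stage — screening, indices, neutrality/ENC/PR2 diagnostics,
#' optimal-codon calling — can be validated against a known answer:
#'
#' \describe{
#'   \item{mutation}{each gene draws a composition parameter theta uniformly
#'     from `gc3_range` and samples the G+C probability of *all three* codon
#'     positions from theta. GC12 then tracks GC3 across genes, so the
#'     neutrality regression slope is close to 1 (attenuated only by
#'     within-gene sampling noise).}
#'   \item{selection}{the amino-acid sequence is random with frequencies
#'     common to all genes (uniform by default), and each codon is chosen as
#'     the family's preferred codon with probability `selection_strength`,
#'     otherwise uniformly among synonyms. Third-position composition is
#'     therefore decoupled from the first two positions and the neutrality
#'     slope is close to 0, while ENC drops below the composition-only
#'     expectation. Setting `aa_concentration` to a finite value draws
#'     per-gene amino-acid frequencies from a symmetric Dirichlet instead;
#'     note that this re-couples GC3 to GC12 through amino-acid identity
#'     (non-synonymous codons such as AUG and UGG have fixed, GC-ending
#'     third positions), pulling the slope below 0.}
#' }
#'
#' `regime = "mixed"` alternates the two gene by gene. The generator is fully
#' deterministic given `seed` (the caller's RNG state is saved and restored).
#'
#' @param n_genes number of genes (>= 2); default 21, the size of a typical
#'   shared mitochondrial CDS set.
#' @param codons_per_gene integer range (min, max) of total codons per gene
#'   including start and stop; default c(101, 500), i.e. roughly 300-1500 bp.
#' @param gc3_range composition-parameter range for the mutation regime;
#'   default c(0.28, 0.58), the span observed in plant mitochondrial CDS
#'   sets.
#' @param regime `"mutation"`, `"selection"` or `"mixed"`.
#' @param preferred_codons codons favoured under selection (DNA or RNA
#'   spelling); default [default_preferred_codons()], one A/U-ending codon
#'   per family.
#' @param selection_strength mixing weight in [0, 1]; 0 reduces the selection
#'   regime to uniform synonymous usage, 1 uses only preferred codons.
#' @param aa_concentration symmetric Dirichlet concentration for per-gene
#'   amino-acid frequencies in the selection regime; `Inf` (default) means
#'   identical uniform frequencies for every gene, which is what keeps the
#'   third position decoupled from the first two.
#' @param gene_prefix gene name prefix.
#' @param species species label for the generated set.
#' @param seed integer seed; required for reproducibility.
#' @param code a [genetic_code()] object.
#' @return A `cds_set` data.frame (as from [screen_cds()]) with attribute
#'   `truth` (see [synthetic_truth()]): per-gene regime, theta, realized
#'   GC3, plus the preferred set and the expected neutrality slope.
#' @export
generate_cds_set <- function(n_genes = 21L,
                             codons_per_gene = c(101L, 500L),
                             gc3_range = c(0.28, 0.58),
                             regime = c("mutation", "selection", "mixed"),
                             preferred_codons = default_preferred_codons(code),
                             selection_strength = 0.5,
                             aa_concentration = Inf,
                             gene_prefix = "gene",
                             species = "synthetic",
                             seed = 1L,
                             code = genetic_code()) {
  regime <- match.arg(regime)
  stopifnot(n_genes >= 2L, length(codons_per_gene) == 2L,
            codons_per_gene[[1]] >= 4L,
            length(gc3_range) == 2L,
            all(gc3_range > 0 & gc3_range < 1),
            selection_strength >= 0, selection_strength <= 1)
  preferred_codons <- normalize_codons(preferred_codons)
  if (regime %in% c("selection", "mixed") && !length(preferred_codons)) {
    stop("selection regime requires a non-empty preferred codon set")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  gene_regime <- switch(regime,
    mutation = rep("mutation", n_genes),
    selection = rep("selection", n_genes),
    mixed = rep(c("mutation", "selection"), length.out = n_genes))
  lens <- sample(seq(codons_per_gene[[1]], codons_per_gene[[2]]), n_genes,
                 replace = TRUE)
  theta <- ifelse(gene_regime == "mutation",
                  stats::runif(n_genes, gc3_range[[1]], gc3_range[[2]]),
                  NA_real_)

  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    body <- if (gene_regime[[i]] == "mutation") {
      sample_codons_composition(lens[[i]] - 2L, theta[[i]], code)
    } else {
      sample_codons_selection(lens[[i]] - 2L, preferred_codons,
                              selection_strength, aa_concentration, code)
    }
    seqs[[i]] <- paste0("ATG", paste(body, collapse = ""), "TAA")
  }

  width <- nchar(as.character(n_genes))
  genes <- sprintf("%s%0*d", gene_prefix, width, seq_len(n_genes))
  out <- new_cds_set(data.frame(
    gene = genes, species = species, nucleotides = seqs,
    length_bp = nchar(seqs), stringsAsFactors = FALSE))
  gc3_real <- vapply(seqs, function(s) {
    composition(count_codons(s, code = code), code = code)$gc3 / 100
  }, numeric(1), USE.NAMES = FALSE)
  attr(out, "truth") <- structure(list(
    genes = data.frame(gene = genes, regime = gene_regime, theta = theta,
                       n_codons = lens, gc3 = gc3_real,
                       stringsAsFactors = FALSE),
    regime = regime,
    preferred_codons = preferred_codons,
    selection_strength = selection_strength,
    expected_slope = switch(regime, mutation = 1, selection = 0,
                            mixed = NA_real_),
    seed = seed
  ), class = "synthetic_truth")
  out
}

# n codons, all three positions with P(G or C) = theta, stops rejected
sample_codons_composition <- function(n, theta, code) {
  if (n <= 0L) return(character(0))
  draw <- function(k) {
    gc <- matrix(stats::runif(3L * k) < theta, ncol = 3L)
    strong <- matrix(sample(c("G", "C"), 3L * k, replace = TRUE), ncol = 3L)
    weak <- matrix(sample(c("A", "T"), 3L * k, replace = TRUE), ncol = 3L)
    b <- ifelse(gc, strong, weak)
    paste0(b[, 1L], b[, 2L], b[, 3L])
  }
  out <- draw(n)
  bad <- which(out %in% code$stop_codons)
  while (length(bad)) {
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] %in% code$stop_codons]
  }
  out
}

# n codons: random amino acids, preferred-vs-uniform synonym mixture
sample_codons_selection <- function(n, preferred, strength, concentration,
                                    code) {
  if (n <= 0L) return(character(0))
  aas <- names(code$families)
  k <- length(aas)
  w <- if (is.finite(concentration)) {
    g <- stats::rgamma(k, shape = concentration / k, rate = 1)
    g / sum(g)
  } else {
    rep(1 / k, k)
  }
  aa_seq <- sample(aas, n, replace = TRUE, prob = w)
  vapply(aa_seq, function(a) {
    cods <- code$families[[a]]
    pref <- intersect(cods, preferred)
    if (length(pref) && stats::runif(1) < strength) {
      sample(pref, 1L)
    } else {
      sample(cods, 1L)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Default preferred codon set for the selection regime
#'
#' One codon per multi-codon family, preferring a U-ending codon, then an
#' A-ending one, mirroring the A/U-ending optimal codons typical of plant
#' mitochondrial genomes. Deterministic.
#'
#' @param code a [genetic_code()] object.
#' @return Character vector of DNA codons, one per family with >= 2 members.
#' @export
default_preferred_codons <- function(code = genetic_code()) {
  vapply(code$families[vapply(code$families, length, integer(1)) > 1L],
         function(cods) {
           cods <- sort(cods)
           b3 <- substr(cods, 3L, 3L)
           if (any(b3 == "T")) cods[b3 == "T"][[1]]
           else if (any(b3 == "A")) cods[b3 == "A"][[1]]
           else cods[[1]]
         }, character(1), USE.NAMES = FALSE)
}

#' Ground truth of a synthetic CDS set
#'
#' @param x a `cds_set` from [generate_cds_set()].
#' @return The `synthetic_truth` object stored by the generator: list with
#'   `genes` (per-gene regime, theta, length, realized GC3), `regime`,
#'   `preferred_codons`, `selection_strength`, `expected_slope`, `seed`.
#' @export
synthetic_truth <- function(x) attr(x, "truth")

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$genes), "genes, regime:", x$regime,
      "(seed", paste0(x$seed, ")"), "\n")
  if (!is.na(x$expected_slope)) {
    cat("  expected neutrality slope ~", x$expected_slope, "\n")
  }
  invisible(x)
}

#' Write a synthetic set as FASTA plus a truth table
#'
#' @param x a `cds_set` from [generate_cds_set()].
#' @param fasta,truth_tsv output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_synthetic <- function(x, fasta, truth_tsv) {
  write_cds_fasta(x, fasta)
  utils::write.table(synthetic_truth(x)$genes, truth_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, truth_tsv = truth_tsv))
}

#' Tiny worked fixture with hand-computed statistics
#'
#' A three-gene miniature CDS set whose codon counts, RSCU values and
#' positional GC contents were computed by hand from the definitions, for use
#' as an independent oracle in examples and tests. The conventions applied:
#' stop codons are excluded from counting, RSCU is count over family mean,
#' GC percentages are over counted (non-stop) codons, and GC3s is over
#' synonymously variable codons only.
#'
#' @return List with `cds` (a `cds_set` of genes F1-F3) and `expected`, a
#'   data.frame of frozen hand-computed values (`gene`, `quantity`, `value`):
#'   \itemize{
#'     \item F1 = ATG AAA AAG CGA CGA CGA TAA: RSCU(AAA) = RSCU(AAG) = 1,
#'       RSCU(CGA) = 6 (3 counts / family mean 0.5), GC1 = GC2 = 50,
#'       GC3 = 100/3, GC3s = 20, A3s = 0.8.
#'     \item F2 = ATG GGA GGC GGG GGT TTT TTC TAA: uniform usage in both
#'       observed families, all RSCU = 1.
#'     \item F3 = ATG GGG TAA: GC3 of the non-stop codons = 100 (third bases
#'       G, G), GC1 = GC2 = 50, GC3s = 100 (GGG only).
#'   }
#' @export
worked_fixture <- function() {
  cds <- new_cds_set(data.frame(
    gene = c("F1", "F2", "F3"),
    species = "fixture",
    nucleotides = c("ATGAAAAAGCGACGACGATAA",
                    "ATGGGAGGCGGGGGTTTTTTCTAA",
                    "ATGGGGTAA"),
    length_bp = c(21L, 24L, 9L),
    stringsAsFactors = FALSE))
  expected <- rbind(
    data.frame(gene = "F1",
               quantity = c("rscu_AAA", "rscu_AAG", "rscu_CGA", "rscu_CGC",
                            "gc1", "gc2", "gc3", "gc12", "gc3s", "a3s"),
               value = c(1, 1, 6, 0, 50, 50, 100 / 3, 50, 20, 0.8)),
    data.frame(gene = "F2",
               quantity = c("rscu_GGA", "rscu_GGC", "rscu_GGG", "rscu_GGT",
                            "rscu_TTT", "rscu_TTC"),
               value = c(1, 1, 1, 1, 1, 1)),
    data.frame(gene = "F3",
               quantity = c("gc1", "gc2", "gc3", "gc3s"),
               value = c(50, 50, 100, 100))
  )
  list(cds = cds, expected = expected)
}
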