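#' ENC-ranked expression pools
#'
#' Ranks genes by ENC and forms the two pools used for optimal-codon calling:
#' the lowest-ENC decile (strongest codon usage bias, taken as the putative
#' high-expression pool) and the highest-ENC decile (low-expression pool).
#' Pool size is `ceiling(fraction * n)`, at least 1; ENC ties are broken by
#' gene name so the pools are deterministic.
#'
#' @param profiles a `gene_profiles` data.frame (columns `gene`, `enc`).
#' @param fraction pool fraction in (0, 0.5]; default 0.10.
#' @return Object of class `expression_pools`: list with `high_pool`,
#'   `low_pool` (gene-name vectors), `fraction`, `pool_size`.
#' @export
build_pools <- function(profiles, fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 0.5)) {
    stop("fraction must lie in (0, 0.5]")
  }
  df <- as.data.frame(profiles)
  stopifnot(all(c("gene", "enc") %in% names(df)))
  df <- df[!is.na(df$enc), , drop = FALSE]
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 genes with ENC to build pools")
  k <- max(1L, as.integer(ceiling(fraction * n)))
  if (2L * k > n) stop("pools would overlap: fraction too large for ", n,
                       " genes")
  ord <- df[order(df$enc, df$gene), , drop = FALSE]
  structure(list(
    high_pool = ord$gene[seq_len(k)],
    low_pool = ord$gene[seq(n - k + 1L, n)],
    fraction = fraction, pool_size = k
  ), class = "expression_pools")
}

#' @export
print.expression_pools <- function(x, ...) {
  cat("Expression pools (fraction ", x$fraction, ", size ", x$pool_size,
      ")\n", sep = "")
  cat("  high (low ENC): ", paste(x$high_pool, collapse = ", "), "\n")
  cat("  low (high ENC): ", paste(x$low_pool, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled RSCU of a gene pool
#'
#' Sums codon counts across the pool members and computes RSCU on the pooled
#' counts (not a per-gene average).
#'
#' @param counts_list list of `codon_counts`, e.g. `profile_counts(profiles)`
#'   subset to a pool.
#' @param source label for the pool.
#' @param code a [genetic_code()] object.
#' @return An `rscu_table` (see [rscu()]).
#' @export
pooled_rscu <- function(counts_list, source = "pool", code = genetic_code()) {
  rscu(sum_codon_counts(counts_list, source = source), code = code)
}

#' Call optimal codons from high- and low-pool RSCU
#'
#' Classifies a codon as optimal when it is high-frequency in the
#' high-expression pool (RSCU-H > 1) and enriched there relative to the
#' low-expression pool (dRSCU = RSCU-H - RSCU-L >= `delta_threshold`).
#' Single-codon families (Met, Trp) have RSCU pinned at 1 and dRSCU at 0 and
#' are never callable.
#'
#' @param rscu_high,rscu_low `rscu_table`s of the two pools (or data.frames
#'   with columns `codon` and `rscu`). Codons missing from one table are
#'   treated as RSCU 0 with a warning.
#' @param delta_threshold minimal dRSCU; default 0.08.
#' @param code a [genetic_code()] object.
#' @return Object of class `optimal_codon_report`: data.frame with
#'   `amino_acid`, `codon`, `codon_rna`, `rscu_high`, `rscu_low`, `delta`,
#'   `high_frequency` (RSCU-H > 1), `optimal`; the called set is available
#'   via [optimal_set()].
#' @export
call_optimal <- function(rscu_high, rscu_low, delta_threshold = 0.08,
                         code = genetic_code()) {
  hi <- as.data.frame(rscu_high)
  lo <- as.data.frame(rscu_low)
  stopifnot(all(c("codon", "rscu") %in% names(hi)),
            all(c(
              "codon", "rscu") %in% names(lo)))
  hi$codon <- normalize_codons(hi$codon)
  lo$codon <- normalize_codons(lo$codon)
  universe <- sort(union(hi$codon, lo$codon))
  missing_h <- setdiff(universe, hi$codon)
  missing_l <- setdiff(universe, lo$codon)
  if (length(missing_h) || length(missing_l)) {
    warning("codons absent from one pool treated as RSCU 0: ",
            paste(union(missing_h, missing_l), collapse = ", "),
            call. = FALSE)
  }
  h <- stats::setNames(rep(0, length(universe)), universe)
  l <- h
  h[hi$codon] <- hi$rscu
  l[lo$codon] <- lo$rscu
  aa <- unname(code$codon_to_aa[universe])
  deg <- unname(code$degeneracy[universe])
  out <- data.frame(
    amino_acid = aa, codon = universe, codon_rna = as_rna_codon(universe),
    rscu_high = unname(h), rscu_low = unname(l),
    delta = unname(h - l),
    stringsAsFactors = FALSE)
  out$high_frequency <- out$rscu_high > 1
  out$optimal <- out$high_frequency & out$delta >= delta_threshold &
    !is.na(deg) & deg > 1L
  out <- out[order(out$amino_acid, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, delta_threshold = delta_threshold,
            class = c("optimal_codon_report", "data.frame"))
}

#' @export
print.optimal_codon_report <- function(x, digits = 4, ...) {
  opt <- optimal_set(x)
  cat("Optimal codon report (dRSCU >= ", attr(x, "delta_threshold"),
      "): ", length(opt), " optimal of ", nrow(x), " codons\n", sep = "")
  cat("  optimal:", paste(as_rna_codon(opt), collapse = ", "), "\n")
  y <- as.data.frame(x)
  for (f in c("rscu_high", "rscu_low", "delta")) y[[f]] <- round(y[[f]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Extract the called optimal set from a report
#'
#' @param x an `optimal_codon_report`.
#' @param rna return RNA spelling? Default DNA.
#' @return Character vector of codons.
#' @export
optimal_set <- function(x, rna = FALSE) {
  out <- x$codon[x$optimal]
  if (rna) as_rna_codon(out) else out
}

#' Codons shared across per-species optimal sets
#'
#' Exact intersection of two or more optimal-codon sets, with a tally of
#' A/U-ending versus G/C-ending codons.
#'
#' @param sets list of character vectors of codons (DNA or RNA spelling),
#'   or of `optimal_codon_report`s.
#' @return Object of class `shared_optimal`: list with `codons` (DNA
#'   spelling, sorted), `codons_rna`, `n`, `ending` (named counts for
#'   A, T, G, C third bases).
#' @export
shared_optimal <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  sets <- lapply(sets, function(s) {
    if (inherits(s, "optimal_codon_report")) s <- optimal_set(s)
    normalize_codons(s)
  })
  shared <- sort(Reduce(intersect, sets))
  b3 <- substr(shared, 3L, 3L)
  ending <- vapply(c("A", "T", "G", "C"), function(b) sum(b3 == b),
                   integer(1))
  structure(list(codons = shared, codons_rna = as_rna_codon(shared),
                 n = length(shared), ending = ending),
            class = "shared_optimal")
}

#' @export
print.shared_optimal <- function(x, ...) {
  cat("Shared optimal codons:", x$n, "\n")
  if (x$n) {
    cat("  ", paste(x$codons_rna, collapse = ", "), "\n")
    cat("  ending A/U:", x$ending[["A"]] + x$ending[["T"]],
        " G:", x$ending[["G"]], " C:", x$ending[["C"]], "\n")
  }
  invisible(x)
}
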