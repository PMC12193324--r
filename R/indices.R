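#' Positional base composition of a coding sequence
#'
#' Computes GC content at each codon position (GC1, GC2, GC3, in percent),
#' their overall mean (GCall) and the mean of the first two positions (GC12),
#' plus the third-position statistics restricted to synonymously variable
#' codons (families with two or more members; Met, Trp and stop codons are
#' excluded): GC3s in percent and the base frequencies A3s/T3s/C3s/G3s as
#' fractions. Raw third-position base counts A3/T3/C3/G3 over all counted
#' codons are also returned.
#'
#' @param x a nucleotide sequence, a [count_codons()] result, or any named
#'   numeric vector of codon counts. When a sequence is given it is counted
#'   with `include_stop` as requested; when counts are given they are used
#'   as-is (so whether stops contribute is decided at counting time).
#' @param include_stop logical, only used when `x` is a sequence.
#' @param code a [genetic_code()] object.
#' @return Named list of class `codon_composition` with elements `n_codons`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `gc_all` (percent), `a3`, `t3`, `c3`, `g3`
#'   (counts), `n_syn`, `gc3s` (percent), `a3s`, `t3s`, `c3s`, `g3s`
#'   (fractions). Synonymous-only fields are `NA` when no synonymously
#'   variable codon is present.
#' @examples
#' composition("GGCGGC")$gc_all  # 100
#' composition("ATGTGG")$gc3s    # NA: Met + Trp only
#' @export
composition <- function(x, include_stop = FALSE, code = genetic_code()) {
  counts <- if (inherits(x, "codon_counts") ||
                (is.numeric(x) && !is.null(names(x)))) {
    x
  } else {
    count_codons(x, include_stop = include_stop, code = code)
  }
  cods <- names(counts)
  n <- as.numeric(counts)
  ntot <- sum(n)
  if (ntot == 0) stop("no codons to analyse")
  base_at <- function(pos) substr(cods, pos, pos)
  gc_at <- function(pos) {
    100 * sum(n[base_at(pos) %in% c("G", "C")]) / ntot
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  b3 <- base_at(3L)
  cnt3 <- function(b) sum(n[b3 == b])

  syn <- cods %in% synonymous_codons(code)
  nsyn <- sum(n[syn])
  if (nsyn > 0) {
    b3s <- b3[syn]; ns <- n[syn]
    f3s <- function(b) sum(ns[b3s == b]) / nsyn
    gc3s <- 100 * (f3s("G") + f3s("C"))
    a3s <- f3s("A"); t3s <- f3s("T"); c3s <- f3s("C"); g3s <- f3s("G")
  } else {
    gc3s <- a3s <- t3s <- c3s <- g3s <- NA_real_
  }
  structure(list(
    n_codons = ntot,
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2, gc_all = (gc1 + gc2 + gc3) / 3,
    a3 = cnt3("A"), t3 = cnt3("T"), c3 = cnt3("C"), g3 = cnt3("G"),
    n_syn = nsyn, gc3s = gc3s,
    a3s = a3s, t3s = t3s, c3s = c3s, g3s = g3s
  ), class = "codon_composition")
}

#' Wright's effective number of codons (ENC)
#'
#' Estimates how far a gene departs from uniform synonymous codon usage.
#' For each amino-acid family the codon homozygosity is estimated as
#' \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)} where \eqn{n} is the number
#' of codons counted for that family and \eqn{\hat p_i} the within-family
#' codon frequencies. Homozygosities are averaged within degeneracy classes
#' and combined as \eqn{ENC = 2 + N_2/\bar F_2 + N_3/\bar F_3 + N_4/\bar F_4
#' + N_6/\bar F_6} (standard code: \eqn{N} = 9, 1, 5, 3). The result is
#' clipped to [20, 61].
#'
#' Families with fewer than 2 counted codons are excluded from their class
#' average. A missing three-fold class (Ile unobserved) is imputed as the
#' mean of the two-fold and four-fold class homozygosities; any other missing
#' class is dropped and the remaining class contributions rescaled in
#' proportion to the number of families each class contributes.
#'
#' @param counts a [count_codons()] result.
#' @param code a [genetic_code()] object.
#' @return ENC value in [20, 61], or `NA` if no family is computable.
#' @export
enc_wright <- function(counts, code = genetic_code()) {
  fam_F <- family_homozygosity(counts, code)
  if (!nrow(fam_F)) return(NA_real_)
  classes <- sort(unique(code$degeneracy[!is.na(code$degeneracy)]))
  classes <- classes[classes > 1L]
  n_fam <- vapply(classes, function(d) {
    sum(vapply(code$families, length, integer(1)) == d)
  }, numeric(1))
  names(n_fam) <- classes

  Fbar <- vapply(classes, function(d) {
    f <- fam_F$F[fam_F$deg == d]
    if (length(f)) mean(f) else NA_real_
  }, numeric(1))
  names(Fbar) <- classes

  # Wright's imputation for a missing 3-fold class
  if ("3" %in% names(Fbar) && is.na(Fbar[["3"]]) &&
      !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  usable <- !is.na(Fbar)
  if (!any(usable)) return(NA_real_)
  # a class at zero homozygosity implies unbounded codon diversity: clip high
  if (any(Fbar[usable] == 0)) return(61)
  contrib <- sum(n_fam[usable] / Fbar[usable])
  if (!all(usable)) {
    contrib <- contrib * sum(n_fam) / sum(n_fam[usable])
  }
  enc <- 2 + contrib
  min(max(enc, 20), 61)
}

# per-family homozygosity F-hat for families with >= 2 counted codons
family_homozygosity <- function(counts, code) {
  rows <- lapply(names(code$families), function(a) {
    cods <- code$families[[a]]
    if (length(cods) < 2L) return(NULL)
    x <- as.numeric(counts[cods])
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) return(NULL)
    p <- x / n
    data.frame(amino_acid = a, deg = length(cods), n = n,
               F = (n * sum(p^2) - 1) / (n - 1))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(amino_acid = character(), deg = integer(),
                      n = numeric(), F = numeric())
  }
  out
}

#' Reference sets for CAI, CBI and Fop
#'
#' CAI, CBI and Fop are defined relative to a reference: per-codon relative
#' adaptiveness weights for CAI, and a set of "optimal" codons for CBI and
#' Fop. `reference_set()` builds one from explicit inputs;
#' `reference_from_counts()` derives one from the codon usage of a reference
#' gene pool (typically the putatively highly expressed, low-ENC pool):
#' weights are each codon's count divided by the count of the most-used codon
#' in its family (Sharp–Li relative adaptiveness), and the optimal set holds
#' the most-used codon(s) of each family.
#'
#' @param cai_weights named numeric vector over codons, each in [0, 1], with
#'   at least one codon per family at weight 1 (weights are rescaled by the
#'   family maximum if needed).
#' @param optimal_codons character vector of codons (DNA or RNA spelling);
#'   stop codons and single-codon families are dropped.
#' @param name label recorded in the object.
#' @param code a [genetic_code()] object.
#' @return Object of class `reference_set`: list with `name`,
#'   `optimal_codons` (DNA spelling), `cai_weights`.
#' @export
reference_set <- function(optimal_codons, cai_weights, name = "custom",
                          code = genetic_code()) {
  opt <- normalize_codons(optimal_codons)
  syn <- synonymous_codons(code)
  opt <- unique(opt[opt %in% syn])
  w <- cai_weights
  names(w) <- normalize_codons(names(w))
  stopifnot(all(w >= 0))
  # rescale so each family's best codon has weight 1
  for (a in names(code$families)) {
    cods <- intersect(code$families[[a]], names(w))
    if (length(cods) && max(w[cods]) > 0) w[cods] <- w[cods] / max(w[cods])
  }
  structure(list(name = name, optimal_codons = opt, cai_weights = w),
            class = "reference_set")
}

#' @rdname reference_set
#' @param counts pooled [count_codons()] of the reference gene pool.
#' @export
reference_from_counts <- function(counts, name = "self",
                                  code = genetic_code()) {
  syn <- synonymous_codons(code)
  w <- numeric(0)
  opt <- character(0)
  for (a in names(code$families)) {
    cods <- code$families[[a]]
    if (length(cods) < 2L) next
    x <- as.numeric(counts[cods])
    x[is.na(x)] <- 0
    if (max(x) > 0) {
      w <- c(w, stats::setNames(x / max(x), cods))
      opt <- c(opt, cods[x == max(x)])
    } else {
      # unobserved family: uninformative, all weights 1, no optimal call
      w <- c(w, stats::setNames(rep(1, length(cods)), cods))
    }
  }
  structure(list(name = name, optimal_codons = sort(opt),
                 cai_weights = w[names(w) %in% syn]),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set '", x$name, "': ", length(x$optimal_codons),
      " optimal codons, ", length(x$cai_weights), " CAI weights\n", sep = "")
  invisible(x)
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptiveness weights over the synonymously
#' variable codons of a gene: \eqn{CAI = \exp(\sum x_c \ln w_c / \sum x_c)}.
#' Met, Trp and stop codons are excluded. Observed codons with weight 0 (or
#' missing from the reference) are floored at 1e-4 with a warning.
#'
#' @param counts a [count_codons()] result.
#' @param ref a [reference_set()].
#' @param code a [genetic_code()] object.
#' @return CAI in (0, 1], or `NA` if no synonymously variable codon observed.
#' @export
cai <- function(counts, ref, code = genetic_code()) {
  syn <- synonymous_codons(code)
  x <- as.numeric(counts[syn])
  x[is.na(x)] <- 0
  keep <- x > 0
  if (!any(keep)) return(NA_real_)
  w <- ref$cai_weights[syn[keep]]
  if (anyNA(w) || any(w <= 0)) {
    warning("observed codon(s) with zero/missing CAI weight floored at 1e-4",
            call. = FALSE)
    w[is.na(w) | w <= 0] <- 1e-4
  }
  exp(sum(x[keep] * log(w)) / sum(x[keep]))
}

#' Codon bias index (CBI)
#'
#' Bennetzen–Hall index: \eqn{(N_{opt} - N_{ran})/(N_{tot} - N_{ran})},
#' where \eqn{N_{opt}} is the number of optimal codons used, \eqn{N_{tot}}
#' the number of synonymous codons in families containing an optimal codon,
#' and \eqn{N_{ran}} the count of optimal codons expected under uniform
#' synonymous usage. Ranges from -1 (only non-optimal codons) through 0
#' (uniform usage) to 1 (only optimal codons).
#'
#' @inheritParams cai
#' @return CBI in [-1, 1], `NA` when degenerate (`N_tot == N_ran`).
#' @export
cbi <- function(counts, ref, code = genetic_code()) {
  opt <- ref$optimal_codons
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (a in names(code$families)) {
    cods <- code$families[[a]]
    if (length(cods) < 2L) next
    fam_opt <- intersect(cods, opt)
    if (!length(fam_opt)) next
    x <- as.numeric(counts[cods])
    x[is.na(x)] <- 0
    n_tot <- n_tot + sum(x)
    n_opt <- n_opt + sum(x[cods %in% fam_opt])
    n_ran <- n_ran + sum(x) * length(fam_opt) / length(cods)
  }
  if (n_tot == 0 || abs(n_tot - n_ran) < .Machine$double.eps^0.5) {
    return(NA_real_)
  }
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Frequency of optimal codons (Fop)
#'
#' Fraction of a gene's synonymously variable codons that belong to the
#' reference optimal set (Ikemura).
#'
#' @inheritParams cai
#' @return Fop in [0, 1], `NA` when no synonymously variable codon observed.
#' @export
fop <- function(counts, ref, code = genetic_code()) {
  syn <- synonymous_codons(code)
  x <- as.numeric(counts[syn])
  x[is.na(x)] <- 0
  n_syn <- sum(x)
  if (n_syn == 0) return(NA_real_)
  sum(x[syn %in% ref$optimal_codons]) / n_syn
}

#' Per-gene codon usage bias profiles
#'
#' Computes, for every gene in a screened CDS set, the full panel of codon
#' usage statistics: codon count, positional GC (GC1/GC2/GC3/GC12/GCall,
#' percent), synonymous third-position statistics (GC3s percent,
#' A3s/T3s/C3s/G3s fractions, raw A3/T3/C3/G3 counts), Wright's ENC, and —
#' given a reference set — CAI, CBI and Fop.
#'
#' With `reference = "self"` the reference is derived from the data: genes
#' are ranked by ENC, the lowest-ENC decile (strongest bias, putatively
#' highest expression) is pooled, and [reference_from_counts()] of that pool
#' supplies the weights and optimal set. Pass a [reference_set()] to use an
#' external reference, or `NULL` to skip CAI/CBI/Fop.
#'
#' @param cds a `cds_set` data.frame (see [screen_cds()]).
#' @param reference `"self"`, a [reference_set()], or `NULL`.
#' @param pool_fraction pool fraction used when `reference = "self"`.
#' @param code a [genetic_code()] object.
#' @return Object of class `gene_profiles`: a data.frame with one row per
#'   gene and the columns above, carrying the per-gene `codon_counts` list as
#'   attribute `counts` and the reference used as attribute `reference`.
#' @export
codon_profiles <- function(cds, reference = "self", pool_fraction = 0.10,
                           code = genetic_code()) {
  df <- as.data.frame(cds)
  stopifnot(nrow(df) >= 1L, all(c("gene", "nucleotides") %in% names(df)))
  counts <- lapply(seq_len(nrow(df)), function(i) {
    count_codons(df$nucleotides[[i]], include_stop = FALSE, code = code,
                 source = df$gene[[i]])
  })
  names(counts) <- make.unique(df$gene)
  comp <- lapply(counts, composition, code = code)
  enc <- vapply(counts, enc_wright, numeric(1), code = code)

  prof <- data.frame(
    gene = df$gene,
    species = if ("species" %in% names(df)) df$species else NA_character_,
    n_codons = vapply(comp, `[[`, numeric(1), "n_codons"),
    enc = enc,
    stringsAsFactors = FALSE
  )
  for (f in c("gc1", "gc2", "gc3", "gc12", "gc_all", "gc3s",
              "a3s", "t3s", "c3s", "g3s", "a3", "t3", "c3", "g3")) {
    prof[[f]] <- vapply(comp, `[[`, numeric(1), f)
  }

  ref <- reference
  if (identical(reference, "self")) {
    pools <- build_pools(prof, fraction = pool_fraction)
    ref <- reference_from_counts(
      sum_codon_counts(counts[pools$high_pool], source = "high_pool"),
      name = "self")
  }
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "reference_set"))
    prof$cai <- vapply(counts, cai, numeric(1), ref = ref, code = code)
    prof$cbi <- vapply(counts, cbi, numeric(1), ref = ref, code = code)
    prof$fop <- vapply(counts, fop, numeric(1), ref = ref, code = code)
  }
  rownames(prof) <- NULL
  structure(prof, counts = counts, reference = ref, code_id = code$id,
            class = c("gene_profiles", "data.frame"))
}

#' @export
print.gene_profiles <- function(x, digits = 3, ...) {
  ref <- attr(x, "reference")
  cat("Codon usage profiles for", nrow(x), "genes",
      if (!is.null(ref)) paste0("(reference: ", ref$name, ")"), "\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-gene codon counts stored in a profile table
#'
#' @param x a `gene_profiles` object.
#' @return Named list of `codon_counts`, one per gene row.
#' @export
profile_counts <- function(x) attr(x, "counts")
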