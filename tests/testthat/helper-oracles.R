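# Independent oracles, deliberately written from first principles and kept
# free of the package's internal helpers.

# Wright's ENC by direct enumeration: per-family homozygosity, class means,
# 2 + sum N_c / Fbar_c, clipped to [20, 61]. Assumes every degeneracy class
# has at least one family with >= 2 counted codons (fixtures are built so).
enc_oracle <- function(counts) {
  gc <- Biostrings::GENETIC_CODE
  aa_of <- gc[gc != "*"]
  classes <- list()
  for (a in unique(aa_of)) {
    codons <- names(aa_of)[aa_of == a]
    k <- length(codons)
    if (k < 2) next
    n <- 0
    sum_sq <- 0
    for (cod in codons) {
      x <- if (cod %in% names(counts)) counts[[cod]] else 0
      n <- n + x
    }
    if (n < 2) next
    for (cod in codons) {
      x <- if (cod %in% names(counts)) counts[[cod]] else 0
      sum_sq <- sum_sq + (x / n)^2
    }
    Fhat <- (n * sum_sq - 1) / (n - 1)
    classes[[as.character(k)]] <- c(classes[[as.character(k)]], Fhat)
  }
  n_families <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  enc <- 2
  for (k in names(n_families)) {
    Fbar <- mean(classes[[k]])
    enc <- enc + n_families[[k]] / Fbar
  }
  min(max(enc, 20), 61)
}

# random 64-codon count table guaranteed to make every degeneracy class
# computable (one family per class is topped up to >= 2 counts)
random_count_table <- function(lambda = 3) {
  gc <- Biostrings::GENETIC_CODE
  counts <- stats::setNames(stats::rpois(64, lambda), names(gc))
  counts[names(gc)[gc == "*"]] <- 0L
  for (fam in list(c("AAA", "AAG"),            # Lys, 2-fold
                   c("ATT", "ATC", "ATA"),     # Ile, 3-fold
                   c("GTT", "GTC"),            # Val, 4-fold
                   c("CGT", "AGA"))) {         # Arg, 6-fold
    if (sum(counts[fam]) < 2) counts[fam[1]] <- counts[fam[1]] + 2L
  }
  counts
}

# OLS slope/intercept by the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# minimal GenBank flat file for parser tests; features is a list of lists
# with elements `location` and optional `gene`
write_genbank_fixture <- function(path, sequence, features,
                                  accession = "TEST0001",
                                  organism = "Testus syntheticus") {
  n <- nchar(sequence)
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     circular PLN 01-JAN-2024",
            accession, n),
    "DEFINITION  synthetic fixture record.",
    sprintf("ACCESSION   %s", accession),
    "SOURCE      synthetic construct",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  for (f in features) {
    lines <- c(lines, sprintf("     CDS             %s", f$location))
    if (!is.null(f$gene)) {
      lines <- c(lines, sprintf('                     /gene="%s"', f$gene))
    }
    if (!is.null(f$locus_tag)) {
      lines <- c(lines, sprintf('                     /locus_tag="%s"',
                                f$locus_tag))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(sequence)
  for (i in seq(1, n, by = 60)) {
    chunk <- substr(s, i, min(i + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), by = 10),
                        pmin(seq(10, nchar(chunk) + 9, by = 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

# valid toy CDS: ATG + body + TAA (body must contain no in-frame stop)
make_cds <- function(body) paste0("ATG", body, "TAA")

# random in-frame stop-free body of n codons under a fixed alphabet
random_body <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all64 <- names(Biostrings::GENETIC_CODE)
  paste(sample(setdiff(all64, stops), n_codons, replace = TRUE),
        collapse = "")
}
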