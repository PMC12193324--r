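test_that("count_codons reads off non-overlapping triplets", {
  cc <- count_codons("ATGAAACGATAA")
  expect_equal(sum(cc), 3)
  expect_equal(unname(cc[c("ATG", "AAA", "CGA")]), c(1L, 1L, 1L))
  expect_equal(cc[["TAA"]], 0L)
  with_stop <- count_codons("ATGAAACGATAA", include_stop = TRUE)
  expect_equal(with_stop[["TAA"]], 1L)
  expect_error(count_codons("ATGAAAC"), "frame")
})

test_that("RSCU matches hand-computed values and definitions", {
  # uniform usage in a four-fold family -> all RSCU 1
  uni <- rscu(count_codons(paste0("ATG", "GCA", "GCC", "GCG", "GCT", "TAA")))
  expect_equal(uni$rscu[uni$amino_acid == "A"], rep(1, 4))

  # Arg AGA=3, AGG=1 within the six-fold family
  arg <- rscu(count_codons("ATGAGAAGAAGAAGGTAA"))
  expect_equal(arg$rscu[arg$codon == "AGA"], 4.5)
  expect_equal(arg$rscu[arg$codon == "AGG"], 1.5)
  expect_equal(arg$rscu[arg$codon == "CGA"], 0)

  # unobserved families are absent, not zero-filled
  expect_false("GGT" %in% arg$codon)
})

test_that("RSCU family sums equal family size (property, random tables)", {
  gc <- genetic_code()
  set.seed(11)
  for (i in 1:50) {
    counts <- random_count_table(lambda = runif(1, 0.5, 8))
    tab <- rscu(counts)
    sums <- tapply(tab$rscu, tab$amino_acid, sum)
    sizes <- vapply(names(sums), function(a) length(gc$families[[a]]),
                    numeric(1))
    expect_equal(as.numeric(sums), as.numeric(sizes), tolerance = 1e-12)
  }
})

test_that("positional composition matches direct counting", {
  all_gc <- composition("GGCGGC")
  expect_equal(all_gc$gc1, 100)
  expect_equal(all_gc$gc2, 100)
  expect_equal(all_gc$gc3, 100)
  expect_equal(all_gc$gc_all, 100)

  met_trp <- composition("ATGTGG")
  expect_true(is.na(met_trp$gc3s))
  expect_true(is.na(met_trp$a3s))

  # GC12 is the arithmetic mean of GC1 and GC2: GAA,CAT -> GC1 100, GC2 0
  x <- composition("GAACAT")
  expect_equal(x$gc1, 100)
  expect_equal(x$gc2, 0)
  expect_equal(x$gc12, 50)
})

test_that("composition conserves third-position counts and GCall identity", {
  set.seed(12)
  for (i in 1:20) {
    cds <- make_cds(random_body(sample(50:200, 1)))
    comp <- composition(count_codons(cds))
    expect_equal(comp$a3 + comp$t3 + comp$c3 + comp$g3, comp$n_codons)
    expect_equal(comp$gc_all, (comp$gc1 + comp$gc2 + comp$gc3) / 3,
                 tolerance = 1e-12)
    expect_true(comp$gc_all >= min(comp$gc1, comp$gc2, comp$gc3) - 1e-12)
    expect_true(comp$gc_all <= max(comp$gc1, comp$gc2, comp$gc3) + 1e-12)
  }
})

test_that("ENC hits its theoretical limits", {
  gc <- genetic_code()
  # one codon per family, large counts -> ENC = 20
  one_per_family <- stats::setNames(rep(0L, 64), names(gc$codon_to_aa))
  for (a in names(gc$families)) {
    one_per_family[[gc$families[[a]][1]]] <- 100L
  }
  expect_equal(enc_wright(one_per_family), 20)

  # exactly uniform usage with large counts -> ENC -> 61 (clipped)
  uniform <- stats::setNames(rep(0L, 64), names(gc$codon_to_aa))
  for (a in names(gc$families)) uniform[gc$families[[a]]] <- 1000L
  expect_equal(enc_wright(uniform), 61)
})

test_that("ENC agrees with the brute-force oracle on random tables", {
  set.seed(13)
  for (i in 1:200) {
    counts <- random_count_table(lambda = runif(1, 0.5, 10))
    expect_equal(enc_wright(counts), enc_oracle(counts), tolerance = 1e-9)
  }
})

test_that("concentrating a family's counts never increases ENC", {
  set.seed(14)
  for (i in 1:25) {
    counts <- random_count_table(lambda = 6)
    fam <- sample(c("GCT", "GCC", "GCA", "GCG"), 4)  # Ala
    base <- enc_wright(counts)
    conc <- counts
    conc[fam[1]] <- sum(conc[fam])
    conc[fam[-1]] <- 0L
    expect_lte(enc_wright(conc), base + 1e-9)
  }
})

test_that("CAI follows the geometric-mean definition", {
  ref <- reference_set(
    optimal_codons = c("AAA", "GAA"),
    cai_weights = c(AAA = 1, AAG = 0.25, GAA = 1, GAG = 0.5))
  # only weight-1 codons -> CAI = 1
  expect_equal(cai(count_codons("ATGAAAGAATAA"), ref), 1)
  # one AAA (w=1) and one AAG (w=0.25) -> geometric mean 0.5
  expect_equal(cai(count_codons("ATGAAAAAGTAA"), ref), 0.5)
  # scale invariance: repeating the gene leaves CAI unchanged
  g <- "ATGAAAAAGGAAGAGTAA"
  expect_equal(cai(count_codons(g, source = "g"), ref),
               cai(count_codons(strrep(substr(g, 4, nchar(g) - 3), 5)), ref))
  # zero-weight codon floors with warning
  ref0 <- reference_set("AAA", c(AAA = 1, AAG = 0))
  expect_warning(v <- cai(count_codons("ATGAAGTAA"), ref0), "floored")
  expect_equal(v, 1e-4)
})

test_that("CBI matches the Bennetzen-Hall formula", {
  ref <- reference_set(c("AAA"), c(AAA = 1, AAG = 0.1))
  # only optimal codons
  expect_equal(cbi(count_codons("ATGAAAAAATAA"), ref), 1)
  # all counts on the non-optimal codon of a 2-fold family: (0-2)/(4-2) = -1
  expect_equal(cbi(count_codons(paste0("ATG", strrep("AAG", 4), "TAA")), ref),
               -1)
  # exactly uniform usage -> 0
  ref2 <- reference_set(c("AAA", "GGT"),
                        c(AAA = 1, AAG = 0.2, GGT = 1, GGA = 0.5,
                          GGC = 0.5, GGG = 0.5))
  uni <- count_codons(paste0("ATG", "AAAAAG", "GGTGGAGGCGGG", "TAA"))
  expect_equal(cbi(uni, ref2), 0)
})

test_that("Fop is the optimal fraction of synonymous codons", {
  ref <- reference_set(c("AAA", "GCT"),
                       c(AAA = 1, AAG = 0.5, GCT = 1, GCA = 0.5,
                         GCC = 0.5, GCG = 0.5))
  expect_equal(fop(count_codons("ATGAAAGCTTAA"), ref), 1)
  expect_equal(fop(count_codons("ATGAAGGCATAA"), ref), 0)
  # 3 optimal of 8 synonymous
  seqs <- paste0("ATG", "AAA", "AAA", "GCT", "AAG", "GCA", "GCC", "GCG",
                 "GCG", "TAA")
  expect_equal(fop(count_codons(seqs), ref), 3 / 8)
})

test_that("self reference derives weights and optimal codons from the pool", {
  counts <- count_codons(paste0("ATG", strrep("AAA", 3), "AAG",
                                strrep("GCT", 2), "GCA", "TAA"))
  ref <- reference_from_counts(counts)
  expect_equal(unname(ref$cai_weights[c("AAA", "AAG")]), c(1, 1 / 3))
  expect_true(all(c("AAA", "GCT") %in% ref$optimal_codons))
  expect_false("GCA" %in% ref$optimal_codons)
})

test_that("worked fixture statistics match the frozen hand computation", {
  wf <- worked_fixture()
  for (g in unique(wf$expected$gene)) {
    cc <- count_codons(wf$cds$nucleotides[wf$cds$gene == g])
    tab <- rscu(cc)
    comp <- composition(cc)
    exp_g <- wf$expected[wf$expected$gene == g, ]
    for (k in seq_len(nrow(exp_g))) {
      q <- exp_g$quantity[k]
      got <- if (startsWith(q, "rscu_")) {
        cod <- sub("rscu_", "", q)
        if (cod %in% tab$codon) tab$rscu[tab$codon == cod] else NA_real_
      } else {
        comp[[q]]
      }
      expect_equal(got, exp_g$value[k], tolerance = 1e-12,
                   label = paste(g, q))
    }
  }
})

test_that("gene profiles assemble all indices with a self reference", {
  cds <- generate_cds_set(n_genes = 12, codons_per_gene = c(101, 200),
                          seed = 21)
  # small self-reference pools leave some codons at weight 0, which CAI
  # floors with a warning by design
  prof <- suppressWarnings(codon_profiles(cds))
  expect_s3_class(prof, "gene_profiles")
  expect_equal(nrow(prof), 12)
  expect_true(all(prof$enc >= 20 & prof$enc <= 61))
  expect_true(all(prof$cai > 0 & prof$cai <= 1))
  expect_true(all(prof$cbi >= -1 & prof$cbi <= 1))
  expect_true(all(prof$fop >= 0 & prof$fop <= 1))
  expect_equal(prof$gc12, (prof$gc1 + prof$gc2) / 2, tolerance = 1e-12)
  expect_length(profile_counts(prof), 12)
})
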