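test_that("GenBank parsing extracts forward, reverse and joined CDSs", {
  set.seed(42)
  fwd <- make_cds(random_body(99))            # 303 bp at position 101
  rev_cds <- make_cds(random_body(99))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  exon1 <- substr(fwd, 1, 150)
  exon2 <- substr(fwd, 151, 303)
  genome <- paste0(pad(100), fwd, pad(50),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(rev_cds))), pad(40),
                   exon1, pad(30), exon2, pad(20))
  rc_start <- 100 + 303 + 50 + 1
  j1_start <- rc_start + 303 + 40
  j2_start <- j1_start + 150 + 30
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(path, genome, list(
    list(location = "101..403", gene = "fwd1"),
    list(location = sprintf("complement(%d..%d)", rc_start, rc_start + 302),
         gene = "rev1"),
    list(location = sprintf("join(%d..%d,%d..%d)",
                            j1_start, j1_start + 149,
                            j2_start, j2_start + 152), gene = "join1")
  ))

  rec <- read_genbank(path)
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$accession, "TEST0001")
  expect_equal(rec$sequence_length, nchar(genome))
  expect_equal(nrow(rec$cds), 3)
  expect_equal(rec$cds$nucleotides[rec$cds$gene == "fwd1"], fwd)
  expect_equal(rec$cds$nucleotides[rec$cds$gene == "rev1"], rev_cds)
  expect_equal(rec$cds$nucleotides[rec$cds$gene == "join1"], fwd)
})

test_that("CDS without a gene qualifier falls back to locus_tag with warning", {
  seq <- paste0(strrep("A", 10), make_cds(random_body(99)), strrep("T", 10))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(path, seq, list(
    list(location = "11..313", locus_tag = "LT_007")))
  expect_warning(rec <- read_genbank(path), "locus_tag")
  expect_equal(rec$cds$gene, "LT_007")
})

test_that("unreadable input raises a format error", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines("not a genbank file", path)
  expect_error(read_genbank(path), "LOCUS")
})

test_that("screen_cds enforces all four screening criteria", {
  set.seed(7)
  good <- make_cds(random_body(100))               # 309 bp
  cases <- data.frame(
    gene = c("ok", "short", "badstart", "badstop", "frame", "ambig",
             "internal"),
    nucleotides = c(
      good,
      make_cds(random_body(80)),                       # 249 bp, too short
      sub("^ATG", "GTG", make_cds(random_body(100))),  # GTG start
      sub("TAA$", "CCC", make_cds(random_body(100))),  # no stop
      paste0(make_cds(random_body(100)), "A"),         # not /3
      sub("^(ATG...)", "\\1NNN", make_cds(random_body(100))),
      paste0("ATG", random_body(50), "TAA", random_body(49), "TAA")),
    stringsAsFactors = FALSE)
  expect_warning(kept <- screen_cds(cases), "internal stop")
  expect_equal(kept$gene, "ok")
  log <- screen_log(kept)
  expect_setequal(
    log$outcome[match(c("short", "badstart", "badstop", "frame", "ambig",
                        "internal"), log$gene)],
    c("too_short", "no_atg_start", "no_stop_end", "out_of_frame",
      "ambiguity_codes", "internal_stop"))
  # every survivor satisfies the criteria by direct assertion
  expect_true(all(kept$length_bp > 300))
  expect_true(all(kept$length_bp %% 3 == 0))
  expect_true(all(substr(kept$nucleotides, 1, 3) == "ATG"))
  expect_true(all(substr(kept$nucleotides, kept$length_bp - 2,
                         kept$length_bp) %in% c("TGA", "TAA", "TAG")))
})

test_that("duplicate gene copies keep only the longest, names normalized", {
  set.seed(8)
  short <- make_cds(random_body(110))
  long <- make_cds(random_body(200))
  df <- data.frame(gene = c("nad5-1", "NAD5"),
                   nucleotides = c(short, long), stringsAsFactors = FALSE)
  kept <- screen_cds(df)
  expect_equal(kept$gene, "nad5")
  expect_equal(kept$nucleotides, long)
})

test_that("shared_cds is exact gene-set intersection", {
  set.seed(9)
  mk <- function(genes) {
    screen_cds(data.frame(
      gene = genes,
      nucleotides = vapply(genes, function(g) make_cds(random_body(101)),
                           character(1)),
      stringsAsFactors = FALSE))
  }
  a <- mk(c("atp1", "cob", "nad2"))
  b <- mk(c("cob", "nad2", "rps4"))
  c3 <- mk(c("cob", "nad2", "matr"))
  out <- shared_cds(list(A = a, B = b, C = c3))
  expect_setequal(unique(out$gene), intersect(intersect(
    a$gene, b$gene), c3$gene))
  expect_equal(nrow(out), 2 * 3)

  # identity and empty-intersection behavior
  same <- shared_cds(list(X = a, Y = a))
  expect_setequal(unique(same$gene), a$gene)
  expect_warning(none <- shared_cds(list(A = mk("atp1"), B = mk("rps4"))),
                 "no genes shared")
  expect_equal(nrow(none), 0)

  # property: random gene subsets, 25 draws
  pool <- c("atp1", "atp4", "cob", "cox1", "nad2", "nad5", "rps4", "matr")
  for (i in 1:25) {
    g1 <- sample(pool, sample(2:8, 1))
    g2 <- sample(pool, sample(2:8, 1))
    s1 <- mk(g1); s2 <- mk(g2)
    res <- suppressWarnings(shared_cds(list(s1, s2)))
    expect_setequal(unique(res$gene), intersect(g1, g2))
  }
})

test_that("FASTA round trip is lossless for screened sequences", {
  set.seed(10)
  cds <- generate_cds_set(n_genes = 4, codons_per_gene = c(101, 150),
                          seed = 44)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(cds, path)
  back <- read_cds_fasta(path, species = "synthetic")
  expect_equal(back$gene, cds$gene)
  expect_equal(back$nucleotides, cds$nucleotides)
})
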