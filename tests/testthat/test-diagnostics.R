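test_that("neutrality regression recovers exact linear relationships", {
  df <- data.frame(gene = paste0("g", 1:6),
                   gc3 = c(30, 35, 40, 45, 50, 55))
  # identity line (cor.test warns about the exact fit; that is fine)
  df$gc12 <- df$gc3
  fit <- suppressWarnings(neutrality_fit(df))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  # constant response
  df$gc12 <- 45
  expect_equal(suppressWarnings(neutrality_fit(df))$slope, 0,
               tolerance = 1e-12)
  # degenerate regressor
  df$gc3 <- 40
  df$gc12 <- c(38, 40, 42, 44, 46, 48)
  expect_error(neutrality_fit(df), "zero variance")
})

test_that("neutrality slope matches the normal-equations oracle", {
  set.seed(15)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- runif(n, 25, 60)
    y <- 0.2 * x + 40 + rnorm(n, sd = 2)
    fit <- neutrality_fit(data.frame(gc3 = x, gc12 = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-9)
  }
})

test_that("neutrality_fit behaves as a model object", {
  set.seed(16)
  df <- data.frame(gene = paste0("g", 1:10), gc3 = runif(10, 28, 58))
  df$gc12 <- 0.15 * df$gc3 + 40 + rnorm(10, sd = 0.5)
  fit <- neutrality_fit(df)
  expect_named(coef(fit), c("(Intercept)", "gc3"))
  expect_equal(unname(predict(fit, c(40))),
               fit$intercept + fit$slope * 40, tolerance = 1e-12)
  expect_length(residuals(fit), 10)
  expect_s3_class(summary(fit), "summary.lm")
  expect_output(print(fit), "slope")
})

test_that("enc_expected evaluates the closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "0, 1")
  # maximum sits near gc3 = 0.5 and exceeds 60
  grid <- seq(0.01, 0.99, by = 0.001)
  vals <- enc_expected(grid)
  expect_gt(max(vals), 60)
  expect_lt(abs(grid[which.max(vals)] - 0.5), 0.05)
})

test_that("ENC plot deviations are observed minus expected", {
  prof <- data.frame(gene = c("a", "b"), enc = c(60.5, 45),
                     gc3s = c(50, 50), gc3 = c(50, 50))
  ep <- enc_plot_data(prof)
  expect_equal(ep$deviation, c(0, -15.5))
  expect_equal(unname(attr(ep, "summary")), c(1, 0))
  # uniform-usage synthetic gene near gc3 0.5: ENC 61, deviation ~ +0.5
  gc <- genetic_code()
  uniform <- stats::setNames(rep(0L, 64), names(gc$codon_to_aa))
  for (a in names(gc$families)) uniform[gc$families[[a]]] <- 500L
  comp <- composition(uniform)
  # uniform usage sits at GC3s = 29/59 = 49.15%, so the deviation is ~0.53
  expect_lt(abs(enc_wright(uniform) - enc_expected(comp$gc3s / 100) - 0.5),
            0.1)
})

test_that("selection-regime genes fall mostly below the expected ENC curve", {
  cds <- generate_cds_set(n_genes = 40, codons_per_gene = c(200, 400),
                          regime = "selection", seed = 31)
  ep <- enc_plot_data(codon_profiles(cds, reference = NULL))
  expect_gt(mean(ep$deviation < 0), 0.5)
})

test_that("PR2 coordinates and quadrants follow the definitions", {
  # balanced third positions -> center
  bal <- count_codons(paste0("ATG", "GCA", "GCT", "GCG", "GCC", "TAA"))
  p <- pr2_points(bal)
  expect_equal(p$x, 0.5)
  expect_equal(p$y, 0.5)
  expect_true(is.na(p$quadrant))

  # G3=3, C3=1, A3=1, T3=3 within four-fold families -> (0.75, 0.25)
  cc <- count_codons(paste0("ATG", "GCG", "GCG", "GTG", "CCC",
                            "GGA", "ACT", "CCT", "GTT", "TAA"))
  p2 <- pr2_points(cc)
  expect_equal(p2$x, 0.75)
  expect_equal(p2$y, 0.25)
  expect_equal(p2$quadrant, "IV")

  # all third positions T -> y = 0 (x undefined, flagged)
  allt <- count_codons(paste0("ATG", "GCT", "GGT", "CCT", "TAA"))
  expect_warning(pallt <- pr2_points(allt), "undefined")
  expect_equal(pallt$y, 0)

  # zero denominator flagged
  expect_warning(pna <- pr2_points(count_codons("ATGGCTTAA")), "undefined")
  expect_true(is.na(pna$x))
})

test_that("PR2 scope restricts to four-fold families by default", {
  # Lys AAA is 2-fold: invisible under fourfold scope, visible under all
  cc <- count_codons(paste0("ATG", "AAA", "GCC", "GCG", "TAA"))
  expect_warning(strict <- pr2_points(cc), "undefined")
  loose <- pr2_points(cc, scope = "all")
  expect_equal(strict$y, NA_real_)  # no A or T at 4-fold third positions
  expect_equal(loose$y, 1)          # AAA contributes the only A3/T3
})

test_that("correlation matrix is symmetric with exact special cases", {
  set.seed(17)
  df <- data.frame(gene = paste0("g", 1:12),
                   gc3 = runif(12, 28, 58))
  df$gc_all <- -df$gc3          # exact anticorrelation
  df$enc <- runif(12, 45, 61)
  cm <- correlation_matrix(df, variables = c("gc3", "gc_all", "enc"))
  expect_equal(diag(cm$r), c(gc3 = 1, gc_all = 1, enc = 1))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["gc3", "gc_all"], -1, tolerance = 1e-12)
  expect_equal(cm$stars["gc3", "gc_all"], "**")
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
  # constant variable reported missing
  df$fop <- 0.3
  cm2 <- correlation_matrix(df, variables = c("gc3", "fop"))
  expect_true(is.na(cm2$r["gc3", "fop"]))
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(18)
  n <- 8
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.6)
  cm <- correlation_matrix(data.frame(gc3 = x, enc = y, gene = seq_len(n)),
                           variables = c("gc3", "enc"))
  r_obs <- cm$r["gc3", "enc"]
  perm <- replicate(4000, abs(stats::cor(x, sample(y))) >= abs(r_obs) - 1e-12)
  p_perm <- mean(perm)
  # Monte-Carlo agreement: binomial error ~ 3 sd
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(cm$p["gc3", "enc"] - p_perm), 3 * se + 0.02)
})

test_that("RSCU clustering distances and topology behave", {
  set.seed(19)
  base <- runif(59)
  m <- rbind(A = base, B = base, C = sample(base))
  colnames(m) <- sort(synonymous_codons())
  cl <- rscu_cluster(m)
  # identical rows merge first at height ~0
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  # ((A,B),C) topology: A and B merge before C joins
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first, c("A", "B"))
  # anticorrelated rows: distance 2
  m2 <- rbind(up = seq(0, 2, length.out = 59),
              down = seq(2, 0, length.out = 59))
  cl2 <- rscu_cluster(m2)
  expect_equal(as.numeric(cl2$dist), 2, tolerance = 1e-12)
  # merge heights non-decreasing; newick parses to the right leaves
  cds <- lapply(1:4, function(i) {
    generate_cds_set(n_genes = 6, codons_per_gene = c(101, 150), seed = i)
  })
  tabs <- lapply(cds, function(s) {
    pooled_rscu(profile_counts(codon_profiles(s, reference = NULL)))
  })
  names(tabs) <- paste0("sp", 1:4)
  cl3 <- rscu_cluster(tabs)
  expect_true(all(diff(cl3$hclust$height) >= -1e-12))
  tree <- ape::read.tree(text = cl3$newick)
  expect_setequal(tree$tip.label, paste0("sp", 1:4))
  # zero-variance row is named in the error
  bad <- rbind(ok = base, flat = rep(1, 59))
  expect_error(rscu_cluster(bad), "flat")
})
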