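#' Neutrality regression of GC12 on GC3
#'
#' Fits the neutrality plot model: ordinary least squares of GC12 (mean GC
#' content of the first two codon positions) on GC3, one point per gene. A
#' slope near 1 indicates mutation pressure dominating codon usage (all three
#' positions drift together); a slope near 0 indicates selection holding the
#' first two positions while the third varies.
#'
#' @param profiles a `gene_profiles` data.frame (needs columns `gc3`, `gc12`,
#'   in percent), or any data.frame with those columns.
#' @param x,y column names for the regressor and response (defaults `"gc3"`,
#'   `"gc12"`; use `"gc3s"` to regress on synonymous GC3).
#' @return Object of class `neutrality_fit`: list with `slope`, `intercept`,
#'   `pearson_r`, `p_value` (two-sided t-test on the slope), `n`, `points`
#'   (data.frame `gene`, `gc3`, `gc12`) and the underlying `lm` fit. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @export
neutrality_fit <- function(profiles, x = "gc3", y = "gc12") {
  df <- as.data.frame(profiles)
  stopifnot(all(c(x, y) %in% names(df)))
  pts <- data.frame(
    gene = if ("gene" %in% names(df)) df$gene else seq_len(nrow(df)),
    gc3 = df[[x]], gc12 = df[[y]], stringsAsFactors = FALSE)
  pts <- pts[stats::complete.cases(pts[c("gc3", "gc12")]), , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 genes with defined GC3 and GC12")
  if (stats::var(pts$gc3) == 0) {
    stop("GC3 has zero variance across genes; slope undefined")
  }
  fit <- stats::lm(gc12 ~ gc3, data = pts)
  sm <- summary(fit)
  ct <- stats::cor.test(pts$gc3, pts$gc12, method = "pearson")
  structure(list(
    slope = unname(stats::coef(fit)[["gc3"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    pearson_r = unname(ct$estimate),
    p_value = sm$coefficients["gc3", "Pr(>|t|)"],
    n = nrow(pts), points = pts, lm = fit,
    x_var = x, y_var = y
  ), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, digits = 4, ...) {
  cat("Neutrality regression:", x$y_var, "~", x$x_var,
      "over", x$n, "genes\n")
  cat(sprintf("  slope = %.*f, intercept = %.*f, r = %.*f, p = %.*f\n",
              digits, x$slope, digits, x$intercept,
              digits, x$pearson_r, digits, x$p_value))
  cat("  interpretation:", neutrality_interpretation(x$slope), "\n")
  invisible(x)
}

# slope-based reading; thresholds are the conventional halves of the 0-1 range
neutrality_interpretation <- function(slope) {
  if (slope >= 0.5) {
    "mutation pressure is the dominant force (slope >= 0.5)"
  } else {
    "natural selection is the dominant force (slope < 0.5)"
  }
}

#' @export
summary.neutrality_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.neutrality_fit <- function(object, ...) stats::coef(object$lm)

#' @export
predict.neutrality_fit <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata) && !is.data.frame(newdata)) {
    newdata <- data.frame(gc3 = newdata)
  }
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.neutrality_fit <- function(object, ...) {
  stats::residuals(object$lm, ...)
}

#' @export
plot.neutrality_fit <- function(x, ...) {
  graphics::plot(x$points$gc3, x$points$gc12,
                 xlab = paste0(toupper(x$x_var), " (%)"),
                 ylab = paste0(toupper(x$y_var), " (%)"),
                 main = "Neutrality plot", pch = 19, ...)
  graphics::abline(x$lm, lty = 2)
  graphics::abline(0, 1, col = "grey60")
  invisible(x)
}

#' Expected ENC under composition-only bias
#'
#' The null ENC expected when codon usage is driven solely by third-position
#' base composition: \eqn{ENC = 2 + s + 29/(s^2 + (1-s)^2)} with \eqn{s} the
#' GC3 fraction.
#'
#' @param gc3 GC3 as a fraction in [0, 1] (vectorised).
#' @return Expected ENC values.
#' @examples
#' enc_expected(0.5)  # 60.5
#' enc_expected(0)    # 31
#' @export
enc_expected <- function(gc3) {
  if (any(gc3 < 0 | gc3 > 1, na.rm = TRUE)) {
    stop("gc3 must lie in [0, 1] (fraction, not percent)")
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' ENC plot data: observed ENC against the composition-only expectation
#'
#' For each gene, compares the observed ENC with [enc_expected()] evaluated
#' at its third-position GC content. Genes lying on or near the curve are
#' compatible with pure compositional (mutational) bias; genes falling below
#' it use fewer codons than composition alone explains, implicating
#' selection.
#'
#' @param profiles a `gene_profiles` data.frame.
#' @param x which GC3 variant to use on the x-axis: `"gc3s"` (synonymous
#'   third positions, the classic choice, default) or `"gc3"` (all third
#'   positions).
#' @return Object of class `enc_plot`: data.frame with `gene`, `gc3`
#'   (fraction), `enc`, `enc_expected`, `deviation` (observed - expected),
#'   plus attributes `x_var` and `summary` (genes below/above the curve).
#' @export
enc_plot_data <- function(profiles, x = c("gc3s", "gc3")) {
  x <- match.arg(x)
  df <- as.data.frame(profiles)
  stopifnot(all(c(x, "enc") %in% names(df)))
  gc3 <- df[[x]] / 100
  out <- data.frame(
    gene = if ("gene" %in% names(df)) df$gene else seq_len(nrow(df)),
    gc3 = gc3, enc = df$enc,
    enc_expected = enc_expected(gc3),
    stringsAsFactors = FALSE)
  out$deviation <- out$enc - out$enc_expected
  structure(out,
            x_var = x,
            summary = c(below = sum(out$deviation < 0, na.rm = TRUE),
                        above = sum(out$deviation > 0, na.rm = TRUE)),
            class = c("enc_plot", "data.frame"))
}

#' @export
print.enc_plot <- function(x, digits = 2, ...) {
  s <- attr(x, "summary")
  cat("ENC plot (x =", attr(x, "x_var"), "):", nrow(x), "genes,",
      s[["below"]], "below /", s[["above"]], "above the expected curve\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.enc_plot <- function(x, ...) {
  graphics::plot(x$gc3, x$enc, xlim = c(0, 1), ylim = c(20, 62),
                 xlab = paste0(toupper(attr(x, "x_var")), " (fraction)"),
                 ylab = "ENC", main = "ENC plot", pch = 19, ...)
  s <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(s, enc_expected(s), lty = 2)
  invisible(x)
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Third-position base balance of a gene: x = G3/(G3+C3) against
#' y = A3/(A3+T3). Under strand-symmetric mutation with no selection both
#' ratios sit at 0.5 (A = T and G = C at the third position); displacement
#' from the centre indicates directional mutation or selection. The classic
#' formulation restricts third positions to the four-fold degenerate
#' families, where the third base is free of amino-acid constraint
#' (`scope = "fourfold"`, default); `scope = "all"` uses all synonymously
#' variable codons.
#'
#' @param profiles a `gene_profiles` object (per-gene codon counts are taken
#'   from it), or a single `codon_counts` object.
#' @param scope `"fourfold"` or `"all"`.
#' @param code a [genetic_code()] object.
#' @return Object of class `pr2_points`: data.frame with `gene`, `x`, `y`,
#'   `quadrant` (I: A&G excess, II: G&T, III: T&C, IV: C&A; `NA` on the
#'   axes or when a denominator is zero).
#' @export
pr2_points <- function(profiles, scope = c("fourfold", "all"),
                       code = genetic_code()) {
  scope <- match.arg(scope)
  counts_list <- if (inherits(profiles, "codon_counts")) {
    stats::setNames(list(profiles),
                    attr(profiles, "source") %||% "gene")
  } else {
    profile_counts(profiles)
  }
  deg <- vapply(code$families, length, integer(1))
  fams <- if (scope == "fourfold") {
    names(deg)[deg == 4L]
  } else {
    names(deg)[deg > 1L]
  }
  cods <- unlist(code$families[fams], use.names = FALSE)
  b3 <- substr(cods, 3L, 3L)

  rows <- lapply(names(counts_list), function(g) {
    n <- as.numeric(counts_list[[g]][cods])
    n[is.na(n)] <- 0
    cnt <- function(b) sum(n[b3 == b])
    gc_den <- cnt("G") + cnt("C")
    at_den <- cnt("A") + cnt("T")
    x <- if (gc_den > 0) cnt("G") / gc_den else NA_real_
    y <- if (at_den > 0) cnt("A") / at_den else NA_real_
    data.frame(gene = g, x = x, y = y,
               quadrant = pr2_quadrant(x, y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$x) || anyNA(out$y)) {
    warning("PR2 undefined for ", sum(is.na(out$x) | is.na(out$y)),
            " gene(s): zero third-position denominator", call. = FALSE)
  }
  structure(out, scope = scope, class = c("pr2_points", "data.frame"))
}

pr2_quadrant <- function(x, y) {
  if (is.na(x) || is.na(y) || x == 0.5 || y == 0.5) return(NA_character_)
  if (y > 0.5) {
    if (x > 0.5) "I" else "II"
  } else {
    if (x > 0.5) "IV" else "III"
  }
}

#' @export
plot.pr2_points <- function(x, ...) {
  graphics::plot(x$x, x$y, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
                 main = paste0("PR2 plot (", attr(x, "scope"), ")"),
                 pch = 19, ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey60")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Pearson correlation matrix of codon usage indices
#'
#' Pairwise Pearson correlations (with two-sided p-values from the t
#' distribution, no multiple-testing correction) across the per-gene indices:
#' codon count, GC1, GC2, GC3, GCall, GC3s, CAI, CBI, Fop and ENC — the
#' variables present in the profile table are used.
#'
#' @param profiles a `gene_profiles` data.frame (>= 3 genes).
#' @param variables columns to correlate; defaults to the standard panel,
#'   restricted to those present.
#' @return Object of class `cub_correlation`: list with matrices `r`, `p`,
#'   `stars` (`**` p < 0.01, `*` p < 0.05) and `n`. Variables that are
#'   constant across genes yield `NA` entries.
#' @export
correlation_matrix <- function(profiles,
                               variables = c("n_codons", "gc1", "gc2", "gc3",
                                             "gc_all", "gc3s", "cai", "cbi",
                                             "fop", "enc")) {
  df <- as.data.frame(profiles)
  vars <- intersect(variables, names(df))
  stopifnot(length(vars) >= 2L, nrow(df) >= 3L)
  m <- as.matrix(df[vars])
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      xi <- m[, i]; xj <- m[, j]
      cc <- stats::complete.cases(xi, xj)
      if (sum(cc) >= 3L && stats::var(xi[cc]) > 0 && stats::var(xj[cc]) > 0) {
        ct <- stats::cor.test(xi[cc], xj[cc], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nrow(df)),
            class = "cub_correlation")
}

#' @export
print.cub_correlation <- function(x, digits = 2, ...) {
  cat("Pearson correlations over", x$n, "genes",
      "(*: p < 0.05, **: p < 0.01; uncorrected)\n")
  disp <- matrix(paste0(ifelse(is.na(x$r), "NA",
                               formatC(x$r, digits = digits, format = "f")),
                        x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Hierarchical clustering of RSCU profiles
#'
#' Clusters genomes (or genes) by their RSCU vectors using one minus the
#' Pearson correlation as the dissimilarity, with agglomerative average
#' linkage by default. Identical usage patterns have distance 0; perfectly
#' anticorrelated patterns have distance 2.
#'
#' @param rscu_rows numeric matrix, one row per genome/species, columns =
#'   codons (e.g. stacked [rscu_vector()] results), or a named list of
#'   `rscu_table`s.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param code a [genetic_code()] object (used when a list of tables is
#'   given).
#' @return Object of class `rscu_dendrogram`: list with the `hclust` fit,
#'   `dist` (the 1 - r matrix), `newick` (serialised tree with branch
#'   lengths) and `labels`.
#' @export
rscu_cluster <- function(rscu_rows, linkage = "average",
                         code = genetic_code()) {
  if (is.list(rscu_rows) && !is.matrix(rscu_rows) &&
      !is.data.frame(rscu_rows)) {
    m <- do.call(rbind, lapply(rscu_rows, rscu_vector, code = code, fill = 0))
    rownames(m) <- names(rscu_rows)
  } else {
    m <- as.matrix(rscu_rows)
  }
  stopifnot(nrow(m) >= 2L)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  sds <- apply(m, 1L, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stop("zero-variance RSCU row(s): ",
         paste(rownames(m)[sds == 0 | is.na(sds)], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(m), use = "pairwise.complete.obs"))
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, dist = d,
                 newick = ape::write.tree(phy), labels = rownames(m)),
            class = "rscu_dendrogram")
}

#' @export
print.rscu_dendrogram <- function(x, ...) {
  cat("RSCU dendrogram over", length(x$labels), "rows",
      "(1 - Pearson r,", x$hclust$method, "linkage)\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.rscu_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "RSCU clustering (1 - Pearson r)", ...)
  invisible(x)
}

#' Write an RSCU dendrogram to a Newick file
#'
#' @param x an `rscu_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  writeLines(x$newick, path)
  invisible(path)
}
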