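#' Run the full codon usage bias analysis pipeline
#'
#' Orchestrates the end-to-end analysis over one or more genomes: CDS
#' screening, cross-species shared gene set, per-gene codon usage profiles,
#' pooled RSCU, neutrality / ENC-plot / PR2 diagnostics, correlation
#' matrices, optimal-codon calling from ENC-decile pools, the cross-species
#' shared optimal set, and RSCU-based hierarchical clustering. All tabular
#' results are written as TSV under `outdir`, the dendrogram as Newick, and a
#' machine-readable run report as JSON. Re-running with identical inputs and
#' configuration reproduces identical tables.
#'
#' @param inputs named list of inputs, one per species. Each element may be a
#'   path to a GenBank flat file (`.gb`/`.gbk`), a path to a CDS FASTA, a
#'   `genome_record`, or a `cds_set`. Names are the species labels.
#' @param outdir output directory (created if missing).
#' @param min_length CDS length screening threshold in bp, exclusive
#'   (default 300).
#' @param pool_fraction ENC-decile pool fraction (default 0.10).
#' @param delta_threshold dRSCU threshold for optimal codons (default 0.08).
#' @param reference `"self"` or a [reference_set()] for CAI/CBI/Fop.
#' @param enc_x x-axis variant for the ENC plot: `"gc3s"` or `"gc3"`.
#' @param pr2_scope `"fourfold"` or `"all"` third-position scope for PR2.
#' @param linkage clustering linkage for [rscu_cluster()].
#' @param code_id NCBI genetic code table id (default `"1"`, standard code;
#'   plant mitochondria use the standard code).
#' @param make_plots write PNG figures alongside the tables?
#' @return Object of class `cub_report`: list with `files` (manifest of
#'   written files), `species`, `shared_genes`, `profiles` (per-species
#'   `gene_profiles`), `neutrality`, `enc_plot`, `pr2`, `correlations`,
#'   `optimal` (per-species `optimal_codon_report`s), `shared_optimal`,
#'   `dendrogram`, `warnings`, and `config`.
#' @export
run_pipeline <- function(inputs, outdir,
                         min_length = 300L,
                         pool_fraction = 0.10,
                         delta_threshold = 0.08,
                         reference = "self",
                         enc_x = c("gc3s", "gc3"),
                         pr2_scope = c("fourfold", "all"),
                         linkage = "average",
                         code_id = "1",
                         make_plots = FALSE) {
  enc_x <- match.arg(enc_x)
  pr2_scope <- match.arg(pr2_scope)
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("every element of `inputs` must be named with a species label")
  }
  if (anyDuplicated(names(inputs))) stop("species labels must be unique")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  code <- genetic_code(code_id)
  files <- character(0)
  warns <- character(0)
  note <- function(msg) {
    warns <<- c(warns, msg)
    warning(msg, call. = FALSE)
  }
  emit <- function(df, name, digits = NULL) {
    path <- file.path(outdir, name)
    if (!is.null(digits)) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                     format = "f"))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # -- stage 1: read + screen per species -----------------------------------
  screened <- list()
  for (sp in names(inputs)) {
    x <- inputs[[sp]]
    if (is.character(x) && length(x) == 1L) {
      x <- if (grepl("\\.(gb|gbk|genbank)$", x, ignore.case = TRUE)) {
        read_genbank(x)
      } else {
        read_cds_fasta(x, species = sp)
      }
    }
    scr <- if (inherits(x, "cds_set") || is.data.frame(x)) {
      if (inherits(x, "cds_set") && !is.null(attr(x, "screen_log"))) x
      else screen_cds(x, min_length = min_length, species = sp)
    } else {
      screen_cds(x, min_length = min_length, species = sp)
    }
    scr$species <- sp
    screened[[sp]] <- scr
    tag <- gsub("[^A-Za-z0-9._-]", "_", sp)
    p <- file.path(outdir, paste0(tag, "_screened_cds.fasta"))
    write_cds_fasta(scr, p)
    files <- c(files, p)
    if (!is.null(screen_log(scr))) {
      emit(screen_log(scr), paste0(tag, "_screen_manifest.tsv"))
    }
  }

  # -- stage 2: shared gene set ---------------------------------------------
  if (length(screened) >= 2L) {
    shared <- shared_cds(screened)
    shared_genes <- unique(shared$gene)
    if (!length(shared_genes)) stop("no CDSs shared across all species")
    analysed <- split(as.data.frame(shared), shared$species)
    analysed <- lapply(analysed, new_cds_set)
    emit(as.data.frame(shared)[c("gene", "species", "length_bp")],
         "shared_cds_manifest.tsv")
  } else {
    note("single species input: cross-species stages skipped")
    shared_genes <- unique(screened[[1]]$gene)
    analysed <- screened
  }

  # -- stage 3: per-species profiles, diagnostics, optimal codons -----------
  profiles <- list(); neut <- list(); encp <- list(); pr2s <- list()
  cors <- list(); optimal <- list(); species_rscu <- list()
  for (sp in names(analysed)) {
    tag <- gsub("[^A-Za-z0-9._-]", "_", sp)
    prof <- codon_profiles(analysed[[sp]], reference = reference,
                           pool_fraction = pool_fraction, code = code)
    profiles[[sp]] <- prof
    tab3 <- as.data.frame(prof)[c("gene", "cai", "cbi", "fop", "enc")]
    tab3[-1] <- lapply(tab3[-1], round, 3)
    compcols <- c("gene", "n_codons", "gc1", "gc2", "gc3", "gc12", "gc_all",
                  "gc3s", "a3s", "t3s", "c3s", "g3s")
    comp <- as.data.frame(prof)[compcols]
    comp[-(1:2)] <- lapply(comp[-(1:2)], round, 2)
    emit(cbind(tab3, comp[-1]), paste0(tag, "_gene_indices.tsv"))

    counts <- profile_counts(prof)
    sp_rscu <- pooled_rscu(counts, source = sp, code = code)
    species_rscu[[sp]] <- sp_rscu
    rt <- as.data.frame(sp_rscu)
    rt$rscu <- round(rt$rscu, 4)
    emit(rt, paste0(tag, "_rscu.tsv"))

    nf <- neutrality_fit(prof)
    neut[[sp]] <- nf
    emit(data.frame(species = sp, n = nf$n, slope = round(nf$slope, 4),
                    intercept = round(nf$intercept, 4),
                    pearson_r = round(nf$pearson_r, 4),
                    p_value = round(nf$p_value, 4),
                    interpretation = neutrality_interpretation(nf$slope)),
         paste0(tag, "_neutrality.tsv"))

    ep <- enc_plot_data(prof, x = enc_x)
    encp[[sp]] <- ep
    et <- as.data.frame(ep)
    et[-1] <- lapply(et[-1], round, 4)
    emit(et, paste0(tag, "_enc_plot.tsv"))

    pp <- pr2_points(prof, scope = pr2_scope, code = code)
    pr2s[[sp]] <- pp
    pt <- as.data.frame(pp)
    pt[c("x", "y")] <- lapply(pt[c("x", "y")], round, 4)
    emit(pt, paste0(tag, "_pr2.tsv"))

    cm <- correlation_matrix(prof)
    cors[[sp]] <- cm
    emit(data.frame(variable = rownames(cm$r),
                    matrix(paste0(formatC(cm$r, digits = 2, format = "f"),
                                  cm$stars),
                           nrow(cm$r), dimnames = list(NULL,
                                                       colnames(cm$r)))),
         paste0(tag, "_correlation.tsv"))

    pools <- build_pools(prof, fraction = pool_fraction)
    hi <- pooled_rscu(counts[pools$high_pool], source = "high", code = code)
    lo <- pooled_rscu(counts[pools$low_pool], source = "low", code = code)
    rep4 <- call_optimal(hi, lo, delta_threshold = delta_threshold,
                         code = code)
    optimal[[sp]] <- rep4
    ot <- as.data.frame(rep4)
    ot[c("rscu_high", "rscu_low")] <-
      lapply(ot[c("rscu_high", "rscu_low")], round, 4)
    # printed delta equals printed H - L exactly, so the emitted table is
    # internally consistent at its own precision
    ot$delta <- round(ot$rscu_high - ot$rscu_low, 4)
    emit(ot, paste0(tag, "_optimal_codons.tsv"))

    if (make_plots) {
      for (what in c("neutrality", "enc", "pr2")) {
        p <- file.path(outdir, paste0(tag, "_", what, ".png"))
        grDevices::png(p, width = 900, height = 900, res = 150)
        switch(what, neutrality = plot(nf), enc = plot(ep), pr2 = plot(pp))
        grDevices::dev.off()
        files <- c(files, p)
      }
    }
  }

  # -- stage 4: cross-species summaries -------------------------------------
  shared_opt <- NULL
  dendro <- NULL
  if (length(analysed) >= 2L) {
    shared_opt <- shared_optimal(optimal)
    emit(data.frame(codon = shared_opt$codons_rna,
                    third_base = substr(shared_opt$codons_rna, 3L, 3L)),
         "shared_optimal_codons.tsv")
    dendro <- rscu_cluster(species_rscu, linkage = linkage, code = code)
    p <- file.path(outdir, "rscu_dendrogram.nwk")
    write_newick(dendro, p)
    files <- c(files, p)
  }

  config <- list(min_length = min_length, pool_fraction = pool_fraction,
                 delta_threshold = delta_threshold,
                 reference = if (is.character(reference)) reference
                             else reference$name,
                 enc_x = enc_x, pr2_scope = pr2_scope, linkage = linkage,
                 code_id = code_id)
  report <- structure(list(
    files = files, species = names(analysed), shared_genes = shared_genes,
    profiles = profiles, neutrality = neut, enc_plot = encp, pr2 = pr2s,
    correlations = cors, optimal = optimal, shared_optimal = shared_opt,
    dendrogram = dendro, warnings = warns, config = config
  ), class = "cub_report")

  rp <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report_summary(report), rp, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  report$files <- c(files, rp)
  report
}

# plain-data summary of a cub_report, for JSON serialization
report_summary <- function(x) {
  list(
    species = x$species,
    n_shared_genes = length(x$shared_genes),
    shared_genes = x$shared_genes,
    neutrality = lapply(x$neutrality, function(nf) {
      list(slope = nf$slope, intercept = nf$intercept,
           pearson_r = nf$pearson_r, p_value = nf$p_value, n = nf$n)
    }),
    enc_deviation_negative = lapply(x$enc_plot, function(ep) {
      unname(attr(ep, "summary")[["below"]])
    }),
    optimal_codons = lapply(x$optimal, function(o) {
      as_rna_codon(optimal_set(o))
    }),
    shared_optimal = if (!is.null(x$shared_optimal)) {
      list(n = x$shared_optimal$n,
           codons = x$shared_optimal$codons_rna,
           ending_au = unname(x$shared_optimal$ending[["A"]] +
                              x$shared_optimal$ending[["T"]]),
           ending_g = unname(x$shared_optimal$ending[["G"]]),
           ending_c = unname(x$shared_optimal$ending[["C"]]))
    },
    newick = if (!is.null(x$dendrogram)) x$dendrogram$newick,
    warnings = x$warnings,
    config = x$config,
    files = basename(x$files)
  )
}

#' @export
print.cub_report <- function(x, ...) {
  cat("Codon usage bias pipeline report\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  shared genes:", length(x$shared_genes), "\n")
  for (sp in names(x$neutrality)) {
    nf <- x$neutrality[[sp]]
    cat(sprintf("  %s: neutrality slope %.4f (p = %.3f), %d/%d genes below ENC curve, %d optimal codons\n",
                sp, nf$slope, nf$p_value,
                attr(x$enc_plot[[sp]], "summary")[["below"]],
                nrow(x$enc_plot[[sp]]),
                length(optimal_set(x$optimal[[sp]]))))
  }
  if (!is.null(x$shared_optimal)) {
    cat("  shared optimal codons:", x$shared_optimal$n, "\n")
  }
  if (length(x$warnings)) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  cat("  files written:", length(x$files), "\n")
  invisible(x)
}
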