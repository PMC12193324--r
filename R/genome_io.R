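#' Read a GenBank flat file and extract CDS features
#'
#' Minimal reader for GenBank flat files (.gb/.gbk) sufficient for organelle
#' genome records: it parses the LOCUS length, ACCESSION, ORGANISM, the
#' ORIGIN sequence, and every CDS feature with its location and `gene` (or
#' fallback `locus_tag`) qualifier. Joined (multi-exon) locations are spliced
#' in coding order and `complement(...)` segments are reverse-complemented,
#' so each extracted feature is the mRNA-sense coding sequence. GenBank
#' coordinates are 1-based inclusive as written in the file.
#'
#' @param path path to a GenBank flat file.
#' @return An object of class `genome_record`: list with `accession`,
#'   `species`, `sequence` (character), `sequence_length`, and `cds` — a
#'   data.frame with columns `gene`, `location`, `nucleotides`, `length_bp`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[[1]])) {
    stop("not a GenBank flat file (missing LOCUS line): ", path)
  }
  locus <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  accession <- locus[[2]]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    accession <- strsplit(trimws(acc_line[[1]]), "\\s+")[[1]][2]
  }
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  species <- if (length(org_line)) {
    trimws(sub("^\\s*ORGANISM\\s+", "", org_line[[1]]))
  } else NA_character_

  # ORIGIN block: strip coordinates and whitespace
  o <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(o)) {
    end <- grep("^//", lines)
    end <- if (length(end)) min(end[end > o[[1]]]) else length(lines) + 1L
    block <- lines[seq(o[[1]] + 1L, end - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
  }

  cds <- parse_genbank_cds(lines, seq)
  structure(
    list(accession = accession, species = species, sequence = seq,
         sequence_length = nchar(seq), cds = cds),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("GenBank record", x$accession,
      if (!is.na(x$species)) paste0("(", x$species, ")"), "-",
      format(x$sequence_length, big.mark = ","), "bp,",
      nrow(x$cds), "CDS features\n")
  invisible(x)
}

# -- internal GenBank feature machinery --------------------------------------

parse_genbank_cds <- function(lines, seq) {
  f0 <- grep("^FEATURES", lines)
  empty <- data.frame(gene = character(), location = character(),
                      nucleotides = character(), length_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!length(f0)) return(empty)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend[fend > f0[[1]]])) min(fend[fend > f0[[1]]]) else length(lines) + 1L
  feat <- lines[seq(f0[[1]] + 1L, fend - 1L)]
  if (!length(feat)) return(empty)

  # feature starts: a key in column 6, qualifiers/continuations indented deeper
  is_key <- grepl("^ {5}\\S", feat)
  idx <- which(is_key)
  keys <- sub("^\\s*(\\S+).*$", "\\1", feat[idx])
  starts <- idx[keys == "CDS"]
  if (!length(starts)) return(empty)
  bounds <- c(idx, length(feat) + 1L)

  rows <- lapply(starts, function(i) {
    j <- min(bounds[bounds > i]) - 1L
    chunk <- feat[i:j]
    # location may wrap over lines until the first qualifier line
    qual_at <- grep("^\\s+/", chunk)
    loc_end <- if (length(qual_at)) qual_at[[1]] - 1L else length(chunk)
    loc <- gsub("\\s+", "", paste(
      c(sub("^\\s*CDS\\s+", "", chunk[[1]]),
        if (loc_end >= 2L) trimws(chunk[2:loc_end])), collapse = ""))
    gene <- genbank_qualifier(chunk, "gene")
    if (is.na(gene)) {
      gene <- genbank_qualifier(chunk, "locus_tag")
      if (!is.na(gene)) {
        warning("CDS at ", loc, " has no gene qualifier; using locus_tag ",
                gene, call. = FALSE)
      } else {
        gene <- paste0("CDS_", loc)
        warning("CDS at ", loc, " has no gene or locus_tag qualifier",
                call. = FALSE)
      }
    }
    nt <- extract_location(loc, seq)
    data.frame(gene = gene, location = loc, nucleotides = nt,
               length_bp = nchar(nt), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

genbank_qualifier <- function(chunk, name) {
  hit <- grep(paste0("^\\s+/", name, "="), chunk, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^[^=]*="?|"?$', "", hit[[1]])
}

# Recursive descent over join()/complement()/a..b location strings.
# Returns the spliced coding-strand sequence.
extract_location <- function(loc, seq) {
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(revcomp(extract_location(inner, seq)))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- split_toplevel(inner)
    return(paste(vapply(parts, extract_location, character(1), seq = seq),
                 collapse = ""))
  }
  if (grepl("^order\\(", loc)) {
    inner <- sub("^order\\((.*)\\)$", "\\1", loc)
    parts <- split_toplevel(inner)
    return(paste(vapply(parts, extract_location, character(1), seq = seq),
                 collapse = ""))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    return(substr(seq, ab[[1]], ab[[2]]))
  }
  if (grepl("^[0-9]+$", loc)) {
    return(substr(seq, as.integer(loc), as.integer(loc)))
  }
  stop("unsupported GenBank location: ", loc)
}

# split "a,b,c" at top-level commas (not inside parentheses)
split_toplevel <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  cut <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[[k]] == "(") depth <- depth + 1L
    if (chars[[k]] == ")") depth <- depth - 1L
    if (chars[[k]] == "," && depth == 0L) cut <- c(cut, k)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(i) {
    paste(chars[starts[[i]]:ends[[i]]], collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read coding sequences from a multi-FASTA file
#'
#' Alternative input path when CDSs are already extracted. The gene name is
#' taken as the first whitespace-delimited token of each FASTA header.
#'
#' @param path FASTA file of nucleotide CDSs.
#' @param species species label attached to every sequence.
#' @return A `cds_set` data.frame (columns `gene`, `species`, `nucleotides`,
#'   `length_bp`) — unscreened; pass through [screen_cds()] before analysis.
#' @export
read_cds_fasta <- function(path, species = NA_character_) {
  ss <- Biostrings::readDNAStringSet(path)
  genes <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  new_cds_set(data.frame(
    gene = genes, species = species,
    nucleotides = as.character(ss),
    length_bp = Biostrings::width(ss),
    stringsAsFactors = FALSE
  ))
}

#' Write a set of coding sequences to FASTA
#'
#' @param cds a `cds_set` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  ss <- Biostrings::DNAStringSet(cds$nucleotides)
  names(ss) <- if (all(is.na(cds$species))) cds$gene else {
    paste(cds$gene, cds$species)
  }
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

new_cds_set <- function(df, log = NULL) {
  rownames(df) <- NULL
  structure(df, screen_log = log, class = c("cds_set", "data.frame"))
}

#' Screen CDS features by the coding-sequence quality rules
#'
#' Keeps only features that look like complete, translatable coding
#' sequences: length strictly greater than `min_length` bp (the stop codon
#' counts towards the length), length divisible by 3, ATG start codon, a
#' canonical stop codon (TGA/TAA/TAG) at the end, no ambiguity codes, and no
#' in-frame internal stop. When several copies of the same gene survive, only
#' the longest is retained; gene names are matched case-insensitively with
#' trailing copy suffixes stripped (`nad5-1` and `nad5` are the same gene).
#' Output is sorted by gene name.
#'
#' @param x a `genome_record` from [read_genbank()], or a `cds_set` /
#'   data.frame with columns `gene` and `nucleotides` (e.g. from
#'   [read_cds_fasta()]).
#' @param min_length minimal length in bp, exclusive (default 300).
#' @param species species label; defaults to the record's organism.
#' @return A `cds_set` data.frame of the retained sequences, with a
#'   `screen_log` attribute (accessible via [screen_log()]) recording every
#'   input feature and its filter outcome.
#' @export
screen_cds <- function(x, min_length = 300L, species = NULL) {
  if (inherits(x, "genome_record")) {
    df <- x$cds
    if (is.null(species)) species <- x$species
  } else {
    df <- as.data.frame(x)
    if (is.null(species)) {
      species <- if ("species" %in% names(df)) df$species else NA_character_
    }
  }
  if (length(species) == 1L) species <- rep(species, nrow(df))
  if (nrow(df) == 0L) {
    return(new_cds_set(
      data.frame(gene = character(), species = character(),
                 nucleotides = character(), length_bp = integer()),
      log = data.frame(gene = character(), length_bp = integer(),
                       outcome = character())))
  }

  nt <- normalize_codons(df$nucleotides)
  len <- nchar(nt)
  outcome <- rep("kept", nrow(df))
  outcome[len <= min_length] <- "too_short"
  outcome[outcome == "kept" & len %% 3L != 0L] <- "out_of_frame"
  ok <- outcome == "kept"
  outcome[ok & substr(nt, 1L, 3L) != "ATG"] <- "no_atg_start"
  ok <- outcome == "kept"
  last <- substr(nt, len - 2L, len)
  outcome[ok & !last %in% c("TGA", "TAA", "TAG")] <- "no_stop_end"
  ok <- outcome == "kept"
  outcome[ok & grepl("[^ACGT]", nt)] <- "ambiguity_codes"
  ok <- which(outcome == "kept")
  for (i in ok) {
    if (has_internal_stop(nt[[i]])) outcome[[i]] <- "internal_stop"
  }

  norm <- normalize_gene_name(df$gene)
  keep <- which(outcome == "kept")
  # longest copy per normalized gene name; ties broken by first occurrence
  if (length(keep)) {
    ord <- keep[order(norm[keep], -len[keep])]
    dup <- duplicated(norm[ord])
    outcome[ord[dup]] <- "shorter_duplicate"
    keep <- ord[!dup]
    keep <- keep[order(norm[keep])]
  }

  log <- data.frame(gene = df$gene, gene_normalized = norm,
                    length_bp = len, outcome = outcome,
                    stringsAsFactors = FALSE)
  if (any(outcome == "internal_stop")) {
    warning(sum(outcome == "internal_stop"),
            " CDS feature(s) excluded for internal stop codons", call. = FALSE)
  }
  new_cds_set(
    data.frame(gene = norm[keep], species = species[keep],
               nucleotides = nt[keep], length_bp = len[keep],
               stringsAsFactors = FALSE),
    log = log
  )
}

has_internal_stop <- function(nt, code = genetic_code()) {
  n <- nchar(nt)
  if (n < 6L) return(FALSE)
  cods <- substring(nt, seq(1L, n - 3L, by = 3L), seq(3L, n - 3L, by = 3L))
  any(cods %in% code$stop_codons)
}

normalize_gene_name <- function(x) {
  x <- tolower(trimws(x))
  sub("[-_.][0-9]+$", "", x)
}

#' Filter outcomes from the last screening
#'
#' @param x a `cds_set` returned by [screen_cds()].
#' @return data.frame with one row per input feature: `gene`,
#'   `gene_normalized`, `length_bp`, `outcome`.
#' @export
screen_log <- function(x) attr(x, "screen_log")

#' @export
print.cds_set <- function(x, ...) {
  cat("CDS set:", nrow(x), "sequences",
      if (length(unique(x$species[!is.na(x$species)])))
        paste0("from ", length(unique(x$species)), " species"), "\n")
  print(as.data.frame(x[, setdiff(names(x), "nucleotides")]),
        row.names = FALSE)
  invisible(x)
}

#' Cross-species shared CDS table
#'
#' Intersects the gene names of several screened CDS sets (one per species)
#' and returns, for each shared gene, one coding sequence per species.
#'
#' @param per_species list of `cds_set` objects (length >= 2). Species labels
#'   are taken from each set's `species` column, or from `names(per_species)`.
#' @return A `cds_set` data.frame restricted to shared genes, ordered by gene
#'   then species. Zero rows (with a warning) when the intersection is empty.
#' @export
shared_cds <- function(per_species) {
  stopifnot(is.list(per_species), length(per_species) >= 2L)
  labs <- names(per_species)
  sets <- lapply(seq_along(per_species), function(i) {
    df <- as.data.frame(per_species[[i]])
    if (!is.null(labs) && nzchar(labs[[i]])) df$species <- labs[[i]]
    if (all(is.na(df$species))) df$species <- paste0("species", i)
    df
  })
  shared <- Reduce(intersect, lapply(sets, function(d) unique(d$gene)))
  if (!length(shared)) {
    warning("no genes shared across all species", call. = FALSE)
  }
  out <- do.call(rbind, lapply(sets, function(d) d[d$gene %in% shared, ]))
  out <- out[order(out$gene, out$species), , drop = FALSE]
  new_cds_set(out)
}
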