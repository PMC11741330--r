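# Genome model: sequence, annotation, masks, numt track, effective size.
#
# Coordinates are 1-based inclusive everywhere at the interface, matching the
# convention of organelle genome papers and GFF3. Genomes are circular by
# default; position arithmetic wraps modulo the length.

#' Construct a genome specification
#'
#' Bundles a (by default circular) organelle genome sequence with its gene
#' annotation, interval masks and numt copy-number track, and computes the
#' effective genome size `G` used for mutation-rate estimation: the sequence
#' length minus the total length of masked large-repeat copies (one copy of
#' each large repeat pair is excluded from variant calling so that variants in
#' interconverting repeats are not double-counted).
#'
#' @param name Genome name (used as the chromosome name in tables).
#' @param sequence Nucleotide sequence as a single character string (A/C/G/T).
#' @param kind `"mito"` or `"plastid"`; controls numt handling and
#'   homoplasmy thresholds downstream.
#' @param circular Logical; circular genomes wrap position arithmetic.
#' @param features `NULL` or a data frame of gene features with columns
#'   `gene`, `kind` (`CDS`, `intron`, `rRNA`, `tRNA`), `start`, `end`,
#'   `strand` (`+`/`-`). Multi-interval CDS are given as multiple rows sharing
#'   `gene`; the joined CDS length must be divisible by 3.
#' @param repeat_mask `NULL` or a data frame with `start`, `end`: one copy of
#'   each large repeat pair, excluded from calling and from `G`.
#' @param numt_track `NULL` or a data frame with `start`, `end`, `copies`:
#'   regions of the mitochondrial genome present in the nuclear genome, with
#'   their nuclear copy number.
#' @param artefact_mask `NULL` or a data frame with `start`, `end`: zones
#'   excluded as structural-rearrangement/numt artefacts.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(name, sequence, kind = c("mito", "plastid"),
                        circular = TRUE, features = NULL, repeat_mask = NULL,
                        numt_track = NULL, artefact_mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence contains characters other than A/C/G/T")
  }
  len <- nchar(sequence)

  repeat_mask <- validate_intervals(repeat_mask, len, "repeat_mask",
                                    require_disjoint = TRUE)
  artefact_mask <- validate_intervals(artefact_mask, len, "artefact_mask")
  numt_track <- validate_intervals(numt_track, len, "numt_track",
                                   extra_cols = "copies")
  if (!is.null(numt_track) && any(numt_track$copies < 0)) {
    stop("numt copy numbers must be >= 0")
  }
  features <- validate_features(features, len)

  g_eff <- len - masked_length(repeat_mask)

  structure(list(
    name = name, sequence = sequence, kind = kind, circular = circular,
    length = len, features = features, repeat_mask = repeat_mask,
    numt_track = numt_track, artefact_mask = artefact_mask,
    effective_size_G = g_eff
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec '%s' (%s, %s): %d bp, effective G = %d bp\n",
              x$name, x$kind, if (x$circular) "circular" else "linear",
              x$length, x$effective_size_G))
  cat(sprintf("  features: %d  repeat mask: %d bp  artefact mask: %d bp  numt track: %d interval(s)\n",
              if (is.null(x$features)) 0L else nrow(x$features),
              masked_length(x$repeat_mask), masked_length(x$artefact_mask),
              if (is.null(x$numt_track)) 0L else nrow(x$numt_track)))
  invisible(x)
}

masked_length <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(0L)
  sum(mask$end - mask$start + 1L)
}

validate_intervals <- function(x, len, what, require_disjoint = FALSE,
                               extra_cols = character(0)) {
  if (is.null(x)) return(NULL)
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(NULL)
  need <- c("start", "end", extra_cols)
  if (!all(need %in% names(x))) {
    stop(sprintf("%s must have columns %s", what, paste(need, collapse = ", ")))
  }
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$start < 1L) || any(x$end > len) || any(x$start > x$end)) {
    stop(sprintf("%s intervals must lie within [1, %d] with start <= end",
                 what, len))
  }
  x <- x[order(x$start), , drop = FALSE]
  if (require_disjoint && nrow(x) > 1L &&
      any(x$start[-1L] <= x$end[-nrow(x)])) {
    stop(sprintf("%s intervals must be disjoint", what))
  }
  rownames(x) <- NULL
  x
}

FEATURE_KINDS <- c("CDS", "intron", "rRNA", "tRNA")

validate_features <- function(features, len) {
  if (is.null(features)) return(NULL)
  features <- as.data.frame(features)
  if (nrow(features) == 0L) return(NULL)
  need <- c("gene", "kind", "start", "end", "strand")
  if (!all(need %in% names(features))) {
    stop("features must have columns gene, kind, start, end, strand")
  }
  if (!all(features$kind %in% FEATURE_KINDS)) {
    stop("feature kinds must be one of ", paste(FEATURE_KINDS, collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1L) || any(features$end > len) ||
      any(features$start > features$end)) {
    stop("feature intervals must lie within the genome with start <= end")
  }
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cds_len <- tapply(cds$end - cds$start + 1L, cds$gene, sum)
    bad <- names(cds_len)[cds_len %% 3L != 0L]
    if (length(bad)) {
      stop("CDS length not divisible by 3 for gene(s): ",
           paste(bad, collapse = ", "))
    }
    check_cds_frames(cds, len)
  }
  rownames(features) <- NULL
  features
}

# Overlapping CDS of different genes on the same strand must agree in reading
# frame at every shared position; inconsistent frames are rejected at load.
check_cds_frames <- function(cds, len) {
  for (str in c("+", "-")) {
    sub <- cds[cds$strand == str, , drop = FALSE]
    genes <- unique(sub$gene)
    if (length(genes) < 2L) next
    phase <- rep(NA_integer_, len)
    for (g in genes) {
      iv <- sub[sub$gene == g, , drop = FALSE]
      iv <- iv[order(iv$start, decreasing = (str == "-")), , drop = FALSE]
      pos <- unlist(lapply(seq_len(nrow(iv)), function(i) {
        p <- iv$start[i]:iv$end[i]
        if (str == "-") rev(p) else p
      }), use.names = FALSE)
      ph <- (seq_along(pos) - 1L) %% 3L
      prev <- phase[pos]
      clash <- !is.na(prev) & prev != ph
      if (any(clash)) {
        stop("overlapping CDS on the same strand with inconsistent frames ",
             "near position ", pos[which(clash)[1L]])
      }
      phase[pos] <- ph
    }
  }
  invisible(TRUE)
}

#' Load a genome from standard files
#'
#' Reads a single-record FASTA, an optional GFF3 gene annotation and optional
#' BED masks, and assembles a [genome_spec()]. The numt BED carries the
#' nuclear copy number in its score column. Note that reproducing the
#' published effective sizes of the *A. thaliana* organelle genomes
#' (357,025 bp mitochondrial, 128,214 bp plastid) requires the real reference
#' sequences together with user-supplied repeat-mask coordinates; the package
#' ships only synthetic fixtures.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param gff3_path Optional GFF3 with features of type CDS/intron/rRNA/tRNA.
#' @param masks_bed_path Optional BED of excluded large-repeat copies.
#' @param numt_bed_path Optional BED of numt intervals (copy number in score).
#' @param artefact_bed_path Optional BED of artefact exclusion zones.
#' @param kind,circular,name Passed to [genome_spec()]; `name` defaults to
#'   the FASTA record name.
#' @return A `genome_spec`.
#' @export
load_genome <- function(fasta_path, gff3_path = NULL, masks_bed_path = NULL,
                        numt_bed_path = NULL, artefact_bed_path = NULL,
                        kind = c("mito", "plastid"), circular = TRUE,
                        name = NULL) {
  kind <- match.arg(kind)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("FASTA must contain exactly one record")
  if (is.null(name)) name <- sub("\\s.*$", "", names(dna)[1L])
  sequence <- as.character(dna[[1L]])

  features <- if (!is.null(gff3_path)) read_gff3_features(gff3_path) else NULL
  repeat_mask <- if (!is.null(masks_bed_path)) read_bed_df(masks_bed_path) else NULL
  artefact_mask <- if (!is.null(artefact_bed_path)) read_bed_df(artefact_bed_path) else NULL
  numt_track <- NULL
  if (!is.null(numt_bed_path)) {
    numt_track <- read_bed_df(numt_bed_path, score_as = "copies")
  }

  genome_spec(name = name, sequence = sequence, kind = kind,
              circular = circular, features = features,
              repeat_mask = repeat_mask, numt_track = numt_track,
              artefact_mask = artefact_mask)
}

read_bed_df <- function(path, score_as = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(start = BiocGenerics::start(gr),
                    end = BiocGenerics::end(gr))
  if (!is.null(score_as)) {
    sc <- gr$score
    if (is.null(sc)) stop("BED file ", path, " lacks the score column")
    out[[score_as]] <- as.integer(sc)
  }
  out
}

read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  keep <- as.character(gr$type) %in% FEATURE_KINDS
  gr <- gr[keep]
  if (length(gr) == 0L) return(NULL)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  parents <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  gene <- ifelse(!is.na(parents), parents, ids)
  gene[is.na(gene)] <- sprintf("feature_%d", which(is.na(gene)))
  data.frame(gene = gene,
             kind = as.character(gr$type),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a genome specification to standard files
#'
#' Writes the FASTA sequence, GFF3 annotation and BED masks of a
#' [genome_spec()] into a directory, using the genome name as the file stem.
#' The inverse of [load_genome()]; used by the simulator so that synthetic
#' experiments round-trip through the same readers as real data.
#'
#' @param genome A `genome_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, genome$name)
  paths <- c(fasta = paste0(stem, ".fasta"))
  dna <- Biostrings::DNAStringSet(structure(genome$sequence,
                                            names = genome$name))
  Biostrings::writeXStringSet(dna, paths[["fasta"]])

  if (!is.null(genome$features)) {
    paths[["gff3"]] <- paste0(stem, ".gff3")
    f <- genome$features
    gr <- GenomicRanges::GRanges(
      seqnames = genome$name,
      ranges = IRanges::IRanges(f$start, f$end),
      strand = f$strand, type = f$kind, ID = f$gene,
      phase = cds_phases(f))
    rtracklayer::export(gr, paths[["gff3"]], format = "GFF3")
  }
  if (!is.null(genome$repeat_mask)) {
    paths[["masks_bed"]] <- paste0(stem, ".repeat_mask.bed")
    write_bed_df(genome$repeat_mask, genome$name, paths[["masks_bed"]])
  }
  if (!is.null(genome$artefact_mask)) {
    paths[["artefact_bed"]] <- paste0(stem, ".artefact_mask.bed")
    write_bed_df(genome$artefact_mask, genome$name, paths[["artefact_bed"]])
  }
  if (!is.null(genome$numt_track)) {
    paths[["numt_bed"]] <- paste0(stem, ".numt.bed")
    write_bed_df(genome$numt_track, genome$name, paths[["numt_bed"]],
                 score_col = "copies")
  }
  invisible(paths)
}

# GFF3 phase column for CDS rows: offset to the next codon start, from the
# cumulative joined CDS length upstream of each interval in strand order
cds_phases <- function(f) {
  phase <- rep(NA_integer_, nrow(f))
  for (g in unique(f$gene[f$kind == "CDS"])) {
    idx <- which(f$gene == g & f$kind == "CDS")
    idx <- idx[order(f$start[idx], decreasing = (f$strand[idx[1L]] == "-"))]
    before <- cumsum(c(0L, (f$end[idx] - f$start[idx] + 1L)))
    phase[idx] <- (3L - before[seq_along(idx)] %% 3L) %% 3L
  }
  phase
}

write_bed_df <- function(df, chrom, path, score_col = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end))
  gr$name <- sprintf("iv%d", seq_len(nrow(df)))
  gr$score <- if (is.null(score_col)) 0L else as.numeric(df[[score_col]])
  rtracklayer::export(gr, path, format = "BED")
}

# positions (1-based) covered by an interval data frame, as a logical mask
interval_mask_vector <- function(mask, len) {
  v <- logical(len)
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) v[mask$start[i]:mask$end[i]] <- TRUE
  }
  v
}

pos_in_intervals <- function(pos, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(mask))) {
    out <- out | (pos >= mask$start[i] & pos <= mask$end[i])
  }
  out
}

#' Base composition of the unmasked genome
#'
#' Counts A/C/G/T over the sequence, excluding positions inside the repeat
#' mask (the same exclusion used for the effective genome size), and reports
#' the AT and GC base-pair totals used to normalize mutation spectra.
#'
#' @param genome A `genome_spec`.
#' @param exclude_masked Drop positions inside `repeat_mask` (default TRUE).
#' @return A list with `base_counts` (named A/C/G/T), `at_bp`, `gc_bp`,
#'   and `gc_fraction`.
#' @export
base_composition <- function(genome, exclude_masked = TRUE) {
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  if (exclude_masked) {
    keep <- !interval_mask_vector(genome$repeat_mask, genome$length)
    chars <- chars[keep]
  }
  counts <- vapply(DNA_BASES, function(b) sum(chars == b), integer(1))
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  list(base_counts = counts, at_bp = at, gc_bp = gc,
       gc_fraction = gc / (at + gc))
}
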