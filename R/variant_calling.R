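# Variant filtering chain: candidates -> background -> masks -> homology ->
# numt frequency correction -> homoplasmy classification -> MNV merging.
#
# Filters accumulate flags in the `filters` column (";"-separated, "" = PASS)
# rather than dropping rows, so the chain is order-independent and every
# candidate stays auditable. A call "passes" iff `filters` is empty.

add_flag <- function(filters, flag, which) {
  ifelse(which,
         ifelse(filters == "", flag, paste(filters, flag, sep = ";")),
         filters)
}

#' Passing calls
#'
#' @param calls A variant-call data frame.
#' @return The subset with an empty `filters` field.
#' @export
passing_calls <- function(calls) {
  calls[calls$filters == "", , drop = FALSE]
}

#' Extract candidate variant calls from site counts
#'
#' Emits one candidate per (sample, position, non-reference allele) with a
#' raw frequency of allele count / depth. Candidates below the detection
#' thresholds are retained but flagged `low_freq` / `low_depth`. The default
#' thresholds -- frequency >= 20% and depth >= 50x, both boundaries
#' inclusive -- are deliberately strict: a high frequency cutoff avoids
#' mistaking low-frequency somatic variants and homopolymer sequencing noise
#' for germline mutations.
#'
#' @param counts Site-count data frame (see [read_site_counts()]).
#' @param min_freq Minimum raw allele frequency, in (0, 1].
#' @param min_depth Minimum read depth, >= 1.
#' @param min_alt_count Drop alleles with fewer supporting reads (default 1
#'   keeps every observed allele).
#' @return A variant-call data frame with columns `line`, `genome`, `pos`,
#'   `ref`, `alt`, `var_type`, `depth`, `alt_count`, `raw_frequency`,
#'   `corrected_frequency` (initialized to raw), `homoplasmy`, `filters`.
#' @export
call_candidates <- function(counts, min_freq = 0.20, min_depth = 50L,
                            min_alt_count = 1L) {
  stopifnot(min_freq > 0, min_freq <= 1, min_depth >= 1)
  pieces <- list()
  for (b in DNA_BASES) {
    keep <- counts[[b]] >= min_alt_count & counts$ref != b
    if (!any(keep)) next
    sub <- counts[keep, , drop = FALSE]
    pieces[[b]] <- data.frame(
      line = sub$sample, genome = sub$chrom, pos = sub$pos, ref = sub$ref,
      alt = b, var_type = "SNV", depth = sub$depth, alt_count = sub[[b]],
      allele = b, stringsAsFactors = FALSE)
  }
  keep <- counts$ins >= min_alt_count & nzchar(counts$ins_seq)
  if (any(keep)) {
    sub <- counts[keep, , drop = FALSE]
    pieces[["ins"]] <- data.frame(
      line = sub$sample, genome = sub$chrom, pos = sub$pos, ref = sub$ref,
      alt = sub$ins_seq, var_type = "insertion", depth = sub$depth,
      alt_count = sub$ins, allele = "ins", stringsAsFactors = FALSE)
  }
  keep <- counts$del >= min_alt_count & nzchar(counts$del_seq)
  if (any(keep)) {
    sub <- counts[keep, , drop = FALSE]
    pieces[["del"]] <- data.frame(
      line = sub$sample, genome = sub$chrom, pos = sub$pos, ref = sub$ref,
      alt = sub$del_seq, var_type = "deletion", depth = sub$depth,
      alt_count = sub$del, allele = "del", stringsAsFactors = FALSE)
  }
  calls <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(line = character(0), genome = character(0), pos = integer(0),
               ref = character(0), alt = character(0), var_type = character(0),
               depth = integer(0), alt_count = integer(0),
               allele = character(0), stringsAsFactors = FALSE)
  calls$raw_frequency <- ifelse(calls$depth > 0, calls$alt_count / calls$depth, 0)
  calls$corrected_frequency <- calls$raw_frequency
  calls$homoplasmy <- "unclassified"
  calls$filters <- ""
  calls$filters <- add_flag(calls$filters, "low_freq",
                            calls$raw_frequency < min_freq)
  calls$filters <- add_flag(calls$filters, "low_depth",
                            calls$depth < min_depth)
  calls <- calls[order(calls$line, calls$genome, calls$pos, calls$allele), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Wild-type background rule for a single call
#'
#' A call passes the background filter when its frequency is at least
#' `fold` times the mean frequency of the same allele across all wild-type
#' lines (absent alleles contribute 0), or when that mean is exactly 0.
#' Long homopolymers and other low-complexity regions inflate apparent
#' variant frequencies in every sample; requiring a three-fold excess over
#' the WT panel removes this shared error background.
#'
#' @param freq Raw frequency of the focal call.
#' @param wt_freqs Numeric vector with one frequency per WT line.
#' @param fold Required fold excess (default 3, boundary inclusive).
#' @return `TRUE` when the call should be flagged as background.
#' @export
background_flag <- function(freq, wt_freqs, fold = 3) {
  if (length(wt_freqs) == 0L) {
    stop("background filter is undefined without WT lines")
  }
  m <- mean(wt_freqs)
  # boundary inclusive: a call at exactly fold * mean passes
  m > 0 & (fold * m - freq) > 1e-9
}

#' Apply the wild-type background filter to a call table
#'
#' Computes, per (genome, position, allele), the mean frequency across the
#' wild-type samples in `counts` (0 for absent alleles, every WT line in the
#' denominator) and flags calls that are not at least `fold` times above it.
#'
#' @param calls Variant-call data frame from [call_candidates()].
#' @param counts The site-count table the calls came from.
#' @param wt_samples Character vector of WT sample ids.
#' @param fold Required fold excess.
#' @return `calls` with the `background` flag added where appropriate.
#' @export
background_filter <- function(calls, counts, wt_samples, fold = 3) {
  if (length(wt_samples) == 0L) {
    stop("background filter is undefined without WT lines")
  }
  wt <- counts[counts$sample %in% wt_samples, , drop = FALSE]
  n_wt <- length(unique(wt_samples))
  if (nrow(calls) == 0L) return(calls)
  wt_mean <- numeric(nrow(calls))
  key_chrom_pos <- function(chrom, pos) paste(chrom, pos, sep = "\r")
  wt_key <- key_chrom_pos(wt$chrom, wt$pos)
  call_key <- key_chrom_pos(calls$genome, calls$pos)
  for (al in unique(calls$allele)) {
    rows <- calls$allele == al
    f <- ifelse(wt$depth > 0, wt[[al]] / wt$depth, 0)
    sums <- tapply(f, wt_key, sum)
    hit <- sums[call_key[rows]]
    hit[is.na(hit)] <- 0
    wt_mean[rows] <- hit / n_wt
  }
  flag <- wt_mean > 0 & (fold * wt_mean - calls$raw_frequency) > 1e-9
  calls$filters <- add_flag(calls$filters, "background", flag)
  calls
}

#' Flag calls inside repeat-copy and artefact masks
#'
#' Calls at positions inside the genome's `repeat_mask` (the excluded copy
#' of each large repeat pair) get the `repeat_copy` flag; calls inside the
#' `artefact_mask` (structural-rearrangement / numt artefact zones) get the
#' `artefact` flag. Boundaries are inclusive; a call 1 bp outside a mask
#' passes.
#'
#' @param calls Variant-call data frame.
#' @param genome The matching [genome_spec()].
#' @return `calls` with flags added.
#' @export
apply_masks <- function(calls, genome) {
  if (nrow(calls) == 0L) return(calls)
  rows <- calls$genome == genome$name
  in_rep <- rows & pos_in_intervals(calls$pos, genome$repeat_mask)
  in_art <- rows & pos_in_intervals(calls$pos, genome$artefact_mask)
  calls$filters <- add_flag(calls$filters, "repeat_copy", in_rep)
  calls$filters <- add_flag(calls$filters, "artefact", in_art)
  calls
}

#' Exact-flank homology check for rearrangement artefacts
#'
#' Recombination between dispersed repeats relocates pre-existing sequence;
#' mapped against the reference, such rearranged reads masquerade as de novo
#' variants. This check rebuilds the variant-containing k-mer (`flank_k`
#' reference bases on each side with the alternate allele applied) and
#' searches for an exact occurrence anywhere in the supplied genome set, on
#' either strand. A hit means the "variant" sequence already exists
#' elsewhere and the call is flagged as an artefact.
#'
#' @param genomes A `genome_spec` or list of them (the search space).
#' @param genome_name Name of the genome carrying the variant.
#' @param pos 1-based variant position.
#' @param ref,alt Reference and alternate alleles. For insertions `alt` is
#'   the inserted sequence (placed after `pos`); for deletions `alt` is the
#'   deleted sequence (starting at `pos`).
#' @param var_type `"SNV"`, `"insertion"` or `"deletion"`.
#' @param flank_k Flank length in bp (>= 10; default 30, i.e. a 61-mer for
#'   an SNV).
#' @return `TRUE` when the variant k-mer occurs in the genome set.
#' @export
flank_homology_check <- function(genomes, genome_name, pos, ref, alt,
                                 var_type = "SNV", flank_k = 30L) {
  stopifnot(flank_k >= 10L)
  if (inherits(genomes, "genome_spec")) genomes <- list(genomes)
  focal <- NULL
  for (g in genomes) if (g$name == genome_name) focal <- g
  if (is.null(focal)) stop("genome ", genome_name, " not in genome set")
  if (var_type == "SNV" && ref == alt) stop("alt allele equals ref: not a variant")

  kmer <- variant_kmer(focal, pos, alt, var_type, flank_k)
  for (g in genomes) {
    subject <- g$sequence
    if (g$circular) {
      pad <- substr(subject, 1L, min(nchar(kmer) - 1L, g$length))
      subject <- paste0(subject, pad)
    }
    if (count_fixed(kmer, subject) > 0L) return(TRUE)
    if (count_fixed(kmer, revcomp(subject)) > 0L) return(TRUE)
  }
  FALSE
}

count_fixed <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (length(hits) == 1L && hits[1L] == -1L) 0L else length(hits)
}

# variant-containing k-mer with the alternate allele substituted in
variant_kmer <- function(genome, pos, alt, var_type, flank_k) {
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  len <- genome$length
  take <- function(idx) {
    if (genome$circular) {
      chars[((idx - 1L) %% len) + 1L]
    } else {
      ok <- idx >= 1L & idx <= len
      if (!all(ok)) {
        warning("flank truncated at the end of linear genome ", genome$name)
      }
      chars[idx[ok]]
    }
  }
  if (var_type == "SNV") {
    left <- take((pos - flank_k):(pos - 1L))
    right <- take((pos + 1L):(pos + flank_k))
    core <- alt
  } else if (var_type == "insertion") {
    left <- take((pos - flank_k):pos)
    right <- take((pos + 1L):(pos + flank_k))
    core <- alt
  } else if (var_type == "deletion") {
    dlen <- nchar(alt)
    left <- take((pos - flank_k):(pos - 1L))
    right <- take((pos + dlen):(pos + dlen + flank_k - 1L))
    core <- ""
  } else stop("unknown var_type: ", var_type)
  paste0(paste(left, collapse = ""), core, paste(right, collapse = ""))
}

apply_flank_check <- function(calls, genomes, flank_k = 30L,
                              only_clean = TRUE) {
  if (nrow(calls) == 0L) return(calls)
  idx <- which(if (only_clean) calls$filters == "" else rep(TRUE, nrow(calls)))
  if (!length(idx)) return(calls)
  flagged <- vapply(idx, function(i) {
    flank_homology_check(genomes, calls$genome[i], calls$pos[i],
                         calls$ref[i], calls$alt[i], calls$var_type[i],
                         flank_k = flank_k)
  }, logical(1))
  which_flag <- rep(FALSE, nrow(calls))
  which_flag[idx[flagged]] <- TRUE
  calls$filters <- add_flag(calls$filters, "homology", which_flag)
  calls
}

#' Estimate mean nuclear genome coverage
#'
#' Total-cellular DNA libraries are dominated by organelle reads; the
#' leftover fraction estimates nuclear depth, which in turn scales the
#' expected numt read contamination at mitochondrial sites:
#' `(total_reads - organelle_mapped_reads) * read_length_bp /
#' nuclear_genome_size_bp`.
#'
#' @param total_reads,organelle_mapped_reads Read totals (mapped <= total).
#' @param read_length_bp Read length in bp.
#' @param nuclear_genome_size_bp Nuclear genome size in bp (> 0).
#' @return Mean nuclear depth in x.
#' @export
estimate_nuclear_coverage <- function(total_reads, organelle_mapped_reads,
                                      read_length_bp, nuclear_genome_size_bp) {
  if (any(nuclear_genome_size_bp <= 0)) stop("nuclear genome size must be > 0")
  if (any(read_length_bp <= 0)) stop("read length must be > 0")
  if (any(organelle_mapped_reads > total_reads)) {
    stop("organelle-mapped reads cannot exceed total reads")
  }
  (total_reads - organelle_mapped_reads) * read_length_bp /
    nuclear_genome_size_bp
}

#' numt correction of a mitochondrial allele frequency
#'
#' The nuclear genome carries a large insertion of mitochondrial DNA (numt)
#' nearly identical to the mitochondrial reference, so even a homoplasmic
#' mitochondrial variant keeps receiving reference-matching reads from the
#' nucleus. The correction subtracts the expected number of nuclear-derived
#' reads (`nuclear_cov * numt_copies_at_site`) from the reference allele
#' count and the total coverage, then recomputes the frequency:
#' `alt_count / max(depth - expected_nuclear, alt_count)`. The corrected
#' reference count is clamped at 0 (equivalently the frequency at 1); the
#' correction is approximate by construction.
#'
#' @param alt_count Alternate-allele read count.
#' @param depth Total depth at the site.
#' @param nuclear_cov Mean nuclear coverage (x).
#' @param numt_copies_at_site Nuclear copy number of this region (>= 0).
#' @return Corrected allele frequency in \[0, 1\]. Vectorized.
#' @export
numt_correct_frequency <- function(alt_count, depth, nuclear_cov,
                                   numt_copies_at_site) {
  stopifnot(all(numt_copies_at_site >= 0))
  expected_nuclear <- nuclear_cov * numt_copies_at_site
  eff_depth <- pmax(depth - expected_nuclear, alt_count)
  ifelse(alt_count > 0, alt_count / eff_depth,
         ifelse(depth > 0, 0, 0))
}

#' Apply the numt frequency correction to a call table
#'
#' Sets `corrected_frequency` for calls on a mitochondrial genome using the
#' genome's numt track (copy number 0 outside numt intervals leaves the raw
#' frequency untouched). Raw frequencies are retained.
#'
#' @param calls Variant-call data frame.
#' @param genome A mitochondrial [genome_spec()] with a `numt_track`.
#' @param nuclear_cov Either a single mean nuclear coverage or a named
#'   vector keyed by sample/line id.
#' @return `calls` with `corrected_frequency` updated.
#' @export
apply_numt_correction <- function(calls, genome, nuclear_cov) {
  if (nrow(calls) == 0L || is.null(genome$numt_track)) return(calls)
  rows <- which(calls$genome == genome$name)
  if (!length(rows)) return(calls)
  copies <- numt_copies_at(genome, calls$pos[rows])
  cov <- if (!is.null(names(nuclear_cov))) {
    unname(nuclear_cov[calls$line[rows]])
  } else rep(nuclear_cov, length(rows))
  cov[is.na(cov)] <- 0
  calls$corrected_frequency[rows] <- numt_correct_frequency(
    calls$alt_count[rows], calls$depth[rows], cov, copies)
  calls
}

numt_copies_at <- function(genome, pos) {
  copies <- rep(0L, length(pos))
  nt <- genome$numt_track
  if (is.null(nt)) return(copies)
  for (i in seq_len(nrow(nt))) {
    hit <- pos >= nt$start[i] & pos <= nt$end[i]
    copies[hit] <- pmax(copies[hit], nt$copies[i])
  }
  copies
}

#' Classify calls as homoplasmic or heteroplasmic
#'
#' Plastid SNVs at a frequency of at least 98% are considered fixed
#' (homoplasmic); mitochondrial SNVs require a numt-corrected frequency
#' strictly above 90% because the correction is approximate. Indels are left
#' `unclassified`: homopolymer sequencing error makes their frequencies
#' unreliable.
#'
#' @param calls Variant-call data frame with `corrected_frequency` set.
#' @param genome_kind `"mito"` or `"plastid"`.
#' @return `calls` with the `homoplasmy` column filled in.
#' @export
classify_homoplasmy <- function(calls, genome_kind = c("mito", "plastid")) {
  genome_kind <- match.arg(genome_kind)
  if (nrow(calls) == 0L) return(calls)
  is_snv <- calls$var_type %in% c("SNV", "MNV")
  f <- calls$corrected_frequency
  state <- if (genome_kind == "plastid") {
    ifelse(f >= 0.98, "homoplasmic", "heteroplasmic")
  } else {
    ifelse(f > 0.90, "homoplasmic", "heteroplasmic")
  }
  calls$homoplasmy <- ifelse(is_snv, state, "unclassified")
  calls
}

#' Merge adjacent SNVs into multinucleotide variants
#'
#' Within one line and genome, SNV calls at consecutive positions whose
#' frequencies differ by at most `max_freq_diff` are merged into a single
#' MNV (counted as one variant downstream). Only unflagged SNVs are merged.
#'
#' @param calls Variant-call data frame.
#' @param max_freq_diff Maximum frequency difference between neighbours.
#' @return `calls` with merged rows replaced by MNV rows.
#' @export
merge_mnv <- function(calls, max_freq_diff = 0.1) {
  if (nrow(calls) == 0L) return(calls)
  snv <- calls$var_type == "SNV" & calls$filters == ""
  rest <- calls[!snv, , drop = FALSE]
  sub <- calls[snv, , drop = FALSE]
  if (nrow(sub) < 2L) return(calls)
  sub <- sub[order(sub$line, sub$genome, sub$pos), , drop = FALSE]
  new_grp <- c(TRUE, !(sub$line[-1L] == sub$line[-nrow(sub)] &
                       sub$genome[-1L] == sub$genome[-nrow(sub)] &
                       sub$pos[-1L] == sub$pos[-nrow(sub)] + 1L &
                       abs(sub$raw_frequency[-1L] -
                           sub$raw_frequency[-nrow(sub)]) <= max_freq_diff))
  grp <- cumsum(new_grp)
  merged <- lapply(split(seq_len(nrow(sub)), grp), function(ii) {
    if (length(ii) == 1L) return(sub[ii, , drop = FALSE])
    block <- sub[ii, , drop = FALSE]
    out <- block[1L, , drop = FALSE]
    out$ref <- paste(block$ref, collapse = "")
    out$alt <- paste(block$alt, collapse = "")
    out$var_type <- "MNV"
    out$depth <- min(block$depth)
    out$alt_count <- as.integer(round(mean(block$alt_count)))
    out$raw_frequency <- mean(block$raw_frequency)
    out$corrected_frequency <- mean(block$corrected_frequency)
    out
  })
  out <- rbind(do.call(rbind, merged), rest)
  out <- out[order(out$line, out$genome, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full variant-filtering chain on one genome
#'
#' Candidates are extracted from the count table, then flagged by the
#' wild-type background filter, repeat-copy/artefact masks and the
#' exact-flank homology check; mitochondrial frequencies are numt-corrected,
#' homoplasmy is classified, and adjacent SNVs are merged into MNVs.
#'
#' @param counts Site-count table covering all samples for this genome.
#' @param genome The [genome_spec()].
#' @param meta Line metadata: data frame with `line`, `genotype`
#'   (`"WT"`/`"msh1"`), `generations` (and optionally `founder`).
#' @param genome_set Genomes searched by the homology check (defaults to
#'   the focal genome alone).
#' @param min_freq,min_depth,background_fold,flank_k Filter thresholds.
#' @param nuclear_cov Scalar or per-sample named vector of nuclear coverage
#'   (used only for `kind = "mito"` genomes with a numt track).
#' @param merge_mnvs Merge adjacent same-frequency SNVs (default TRUE).
#' @param min_alt_count Candidate support threshold (see [call_candidates()]).
#' @return A variant-call data frame (all candidates, flags accumulated).
#' @export
call_variants <- function(counts, genome, meta, genome_set = list(genome),
                          min_freq = 0.20, min_depth = 50L,
                          background_fold = 3, flank_k = 30L,
                          nuclear_cov = NULL, merge_mnvs = TRUE,
                          min_alt_count = 1L) {
  counts <- counts[counts$chrom == genome$name, , drop = FALSE]
  calls <- call_candidates(counts, min_freq = min_freq,
                           min_depth = min_depth,
                           min_alt_count = min_alt_count)
  wt_samples <- meta$line[meta$genotype == "WT"]
  calls <- background_filter(calls, counts, wt_samples,
                             fold = background_fold)
  calls <- apply_masks(calls, genome)
  calls <- apply_flank_check(calls, genome_set, flank_k = flank_k)
  if (genome$kind == "mito" && !is.null(nuclear_cov)) {
    calls <- apply_numt_correction(calls, genome, nuclear_cov)
  }
  calls <- classify_homoplasmy(calls, genome$kind)
  if (merge_mnvs) calls <- merge_mnv(calls)
  calls
}

#' Write variant calls as VCF and TSV
#'
#' Writes a minimal VCFv4.2 file (one genome per file) with INFO fields for
#' variant type, raw and corrected frequency and homoplasmy state, plus a
#' flat TSV mirror of the call table. Indels follow VCF anchor-base
#' conventions.
#'
#' @param calls Variant-call data frame for one genome.
#' @param genome The matching [genome_spec()] (for anchor bases).
#' @param vcf_path,tsv_path Output paths (`NULL` to skip either).
#' @param passing_only Write only passing calls to the VCF (default TRUE;
#'   the TSV always contains everything).
#' @return Invisibly, the paths written.
#' @export
write_variant_calls <- function(calls, genome, vcf_path = NULL,
                                tsv_path = NULL, passing_only = TRUE) {
  if (!is.null(tsv_path)) {
    write.table(calls, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    sub <- if (passing_only) passing_calls(calls) else calls
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
    lines_out <- c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
      "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
      "##INFO=<ID=RF,Number=1,Type=Float,Description=\"Raw allele frequency\">",
      "##INFO=<ID=CF,Number=1,Type=Float,Description=\"numt-corrected allele frequency\">",
      "##INFO=<ID=HP,Number=1,Type=String,Description=\"Homoplasmy state\">",
      "##INFO=<ID=LINE,Number=1,Type=String,Description=\"MA line\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    if (nrow(sub)) {
      rows <- vapply(seq_len(nrow(sub)), function(i) {
        pos <- sub$pos[i]; ref <- sub$ref[i]; alt <- sub$alt[i]
        vt <- sub$var_type[i]
        if (vt == "insertion") {
          anchor <- chars[pos]
          ref <- anchor; alt <- paste0(anchor, alt)
        } else if (vt == "deletion") {
          anchor_pos <- if (pos > 1L) pos - 1L else genome$length
          anchor <- chars[anchor_pos]
          ref <- paste0(anchor, alt); alt <- anchor
          pos <- anchor_pos
        }
        sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tTYPE=%s;RF=%.6g;CF=%.6g;HP=%s;LINE=%s",
                genome$name, pos, ref, alt,
                if (sub$filters[i] == "") "PASS" else
                  gsub(";", ",", sub$filters[i]),
                vt, sub$raw_frequency[i], sub$corrected_frequency[i],
                sub$homoplasmy[i], sub$line[i])
      }, character(1))
      lines_out <- c(lines_out, rows)
    }
    writeLines(lines_out, vcf_path)
  }
  invisible(c(vcf = vcf_path, tsv = tsv_path))
}
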