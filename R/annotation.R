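# Functional annotation: assign each variant a location class
# (CDS > rRNA > tRNA > intron > intergenic, in that priority on overlap)
# and, for SNVs in protein-coding sequence, a synonymous/nonsynonymous
# effect under the standard genetic code (plant organelles use it).

# Spliced CDS model for one gene: genomic position and coding-strand base
# for each CDS index (1..CDS length), in translation order.
gene_cds_map <- function(genome, gene) {
  f <- genome$features
  iv <- f[f$gene == gene & f$kind == "CDS", , drop = FALSE]
  if (nrow(iv) == 0L) return(NULL)
  str <- iv$strand[1L]
  iv <- iv[order(iv$start, decreasing = (str == "-")), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    p <- iv$start[i]:iv$end[i]
    if (str == "-") rev(p) else p
  }), use.names = FALSE)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  base <- chars[gpos]
  if (str == "-") base <- comp_base(base)
  list(gene = gene, strand = str, gpos = gpos, base = base)
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# location class at each position with the documented priority
location_class_at <- function(genome, pos) {
  f <- genome$features
  out <- rep("intergenic", length(pos))
  gene <- rep(NA_character_, length(pos))
  if (is.null(f)) return(data.frame(location = out, gene = gene))
  for (kind in c("intron", "tRNA", "rRNA", "CDS")) {  # ascending priority
    iv <- f[f$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      hit <- pos >= iv$start[i] & pos <= iv$end[i]
      out[hit] <- kind
      gene[hit] <- iv$gene[i]
    }
  }
  data.frame(location = out, gene = gene, stringsAsFactors = FALSE)
}

#' Annotate variants with location and coding effect
#'
#' Adds `location` (`CDS`, `rRNA`, `tRNA`, `intron` or `intergenic`; ties on
#' overlapping features resolved in that priority order) and, for SNVs in
#' CDS, `effect` (`synonymous`/`nonsynonymous`; `NA` otherwise) by
#' translating the reference and alternate codons.
#'
#' @param calls Variant-call data frame.
#' @param genome The matching [genome_spec()] with gene features.
#' @return `calls` with `location`, `gene` and `effect` columns added.
#' @export
annotate_variants <- function(calls, genome) {
  loc <- location_class_at(genome, calls$pos)
  calls$location <- loc$location
  calls$gene <- loc$gene
  calls$effect <- NA_character_
  idx <- which(calls$location == "CDS" & calls$var_type == "SNV" &
               calls$genome == genome$name)
  if (length(idx)) {
    maps <- list()
    for (i in idx) {
      g <- calls$gene[i]
      if (is.null(maps[[g]])) maps[[g]] <- gene_cds_map(genome, g)
      m <- maps[[g]]
      ci <- match(calls$pos[i], m$gpos)
      if (is.na(ci)) next
      codon_i <- (ci - 1L) %/% 3L
      off <- (ci - 1L) %% 3L
      codon <- m$base[codon_i * 3L + 1:3]
      alt_coding <- if (m$strand == "-") comp_base(calls$alt[i]) else calls$alt[i]
      alt_codon <- codon
      alt_codon[off + 1L] <- alt_coding
      same <- translate_codon(paste(codon, collapse = "")) ==
        translate_codon(paste(alt_codon, collapse = ""))
      calls$effect[i] <- if (same) "synonymous" else "nonsynonymous"
    }
  }
  calls
}

#' Tabulate variant locations (Table-1-style)
#'
#' @param annotated Output of [annotate_variants()] (passing SNV/MNV rows
#'   are counted).
#' @param var_types Variant types to include (default SNVs only).
#' @return Named integer vector over `CDS`, `rRNA`, `tRNA`, `intron`,
#'   `intergenic`, plus `synonymous` (within CDS) and `total`.
#' @export
location_summary <- function(annotated, var_types = "SNV") {
  ok <- passing_calls(annotated)
  ok <- ok[ok$var_type %in% var_types, , drop = FALSE]
  classes <- c("CDS", "rRNA", "tRNA", "intron", "intergenic")
  out <- vapply(classes, function(k) sum(ok$location == k), integer(1))
  c(out,
    synonymous = sum(ok$effect == "synonymous", na.rm = TRUE),
    total = nrow(ok))
}

#' Genic fraction of variant locations
#'
#' The fraction of variants in gene sequences. With
#' `include_introns = FALSE` (default) this is the fraction in
#' protein-coding, rRNA or tRNA sequence -- the quantity compared against
#' the genic fraction of the genome to assess whether MA propagation
#' suppressed selection.
#'
#' @param counts Named vector as returned by [location_summary()], or any
#'   vector with `CDS`, `rRNA`, `tRNA`, `intron`, `intergenic` entries.
#' @param include_introns Count intronic variants as genic.
#' @return Fraction in `[0, 1]`.
#' @export
genic_fraction <- function(counts, include_introns = FALSE) {
  genic <- counts[["CDS"]] + counts[["rRNA"]] + counts[["tRNA"]] +
    if (include_introns) counts[["intron"]] else 0
  total <- counts[["CDS"]] + counts[["rRNA"]] + counts[["tRNA"]] +
    counts[["intron"]] + counts[["intergenic"]]
  if (total == 0) return(NaN)
  genic / total
}

# Synonymous-outcome lookup for all CDS positions of a genome: for each CDS
# position (unique; CDS-priority on overlap) and each alternate base,
# whether the substitution is synonymous. Used by the permutation test.
cds_site_inventory <- function(genome) {
  f <- genome$features
  if (is.null(f)) stop("genome has no annotation")
  cds_genes <- unique(f$gene[f$kind == "CDS"])
  if (!length(cds_genes)) stop("genome has no CDS features")
  seen <- integer(0)
  rows <- list()
  for (g in cds_genes) {
    m <- gene_cds_map(genome, g)
    keep <- !(m$gpos %in% seen)
    if (!any(keep)) next
    n_codon <- length(m$base) %/% 3L
    codons <- matrix(m$base, nrow = 3L)
    aa_ref <- translate_codon(apply(codons, 2L, paste, collapse = ""))
    syn <- matrix(NA, nrow = length(m$gpos), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
    for (off in 0:2) {
      idx <- seq_len(n_codon) * 3L - 2L + off
      for (b in DNA_BASES) {
        alt_codons <- codons
        alt_codons[off + 1L, ] <- b
        aa_alt <- translate_codon(apply(alt_codons, 2L, paste, collapse = ""))
        syn[idx, b] <- aa_alt == aa_ref
      }
    }
    rows[[g]] <- data.frame(gpos = m$gpos[keep],
                            base = m$base[keep],
                            strand = m$strand,
                            syn[keep, , drop = FALSE],
                            stringsAsFactors = FALSE)
    seen <- c(seen, m$gpos[keep])
  }
  inv <- do.call(rbind, rows)
  rownames(inv) <- NULL
  inv
}
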