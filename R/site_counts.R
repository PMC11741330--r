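# Per-site allele-count tables ("pileup counter" output).
#
# Column schema (TSV, header required):
#   sample  chrom  pos  ref  depth  A  C  G  T  ins  del  [ins_seq  del_seq]
#
# `depth` is the read depth at the position; A/C/G/T are read counts
# supporting each base; `ins`/`del` are counts of reads carrying an
# insertion/deletion anchored at the position, with the representative
# inserted/deleted sequence in `ins_seq`/`del_seq` ("." or "" when absent).
# depth >= sum(counts) is NOT required (clipped and ambiguous reads), but
# every individual count must be <= depth.

COUNT_COLS <- c("A", "C", "G", "T", "ins", "del")

#' Read a per-site allele-count table
#'
#' Reads and validates a TSV of per-sample, per-position allele counts.
#' Malformed rows (unknown reference token, negative counts, a count larger
#' than the depth, non-positive position) are dropped with a warning that
#' reports their line numbers; the rejected rows are attached as the
#' `"rejected"` attribute of the result.
#'
#' @param path TSV file path.
#' @return A validated data frame of site counts (see the schema in the
#'   package source); rejected rows in `attr(, "rejected")`.
#' @export
read_site_counts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_site_counts(x, source = path)
}

#' @rdname read_site_counts
#' @param counts A data frame already in the site-count schema.
#' @param source Label used in diagnostics.
#' @export
validate_site_counts <- function(counts, source = "site counts") {
  need <- c("sample", "chrom", "pos", "ref", "depth", COUNT_COLS)
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop(source, ": missing columns ", paste(missing, collapse = ", "))
  }
  if (!"ins_seq" %in% names(counts)) counts$ins_seq <- ""
  if (!"del_seq" %in% names(counts)) counts$del_seq <- ""
  counts$ins_seq[counts$ins_seq == "."] <- ""
  counts$del_seq[counts$del_seq == "."] <- ""
  counts$pos <- as.integer(counts$pos)
  counts$depth <- as.integer(counts$depth)
  for (cc in COUNT_COLS) counts[[cc]] <- as.integer(counts[[cc]])

  cnt <- as.matrix(counts[COUNT_COLS])
  bad_ref <- !(counts$ref %in% c(DNA_BASES, "N"))
  bad_pos <- is.na(counts$pos) | counts$pos < 1L
  bad_cnt <- apply(is.na(cnt) | cnt < 0L | cnt > counts$depth, 1L, any) |
    is.na(counts$depth) | counts$depth < 0L
  bad <- bad_ref | bad_pos | bad_cnt
  if (any(bad)) {
    warning(sprintf("%s: rejected %d malformed row(s) at line(s) %s",
                    source, sum(bad),
                    paste(utils::head(which(bad) + 1L, 20L), collapse = ", ")))
    rejected <- counts[bad, , drop = FALSE]
    counts <- counts[!bad, , drop = FALSE]
    rownames(counts) <- NULL
    attr(counts, "rejected") <- rejected
  }
  counts
}

#' Write a per-site allele-count table
#'
#' @param counts Data frame in the site-count schema.
#' @param path Output TSV path.
#' @export
write_site_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
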