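# Simple-repeat catalogues: homopolymers and tandem dinucleotide arrays.
#
# Replication slippage at these loci dominates the small-indel spectrum of
# msh1 mutants, so the catalogues are the backbone of the indel analysis.
# Records are maximal (extending a run one base either side breaks it) and
# runs spanning the origin of a circular genome are merged, reported with
# start in [1, length] and a length that may wrap past the end.

#' Find homopolymer runs
#'
#' Returns all maximal single-nucleotide runs of at least `min_len` bases
#' (default 5 bp, the threshold at which organelle homopolymers become indel
#' hotspots). Runs that lie entirely inside the genome's repeat mask are
#' excluded, so the catalogue matches the copy-deduplicated view used for
#' variant calling and mutation rates. On circular genomes a run spanning the
#' origin is merged and reported once.
#'
#' @param genome A [genome_spec()] or a plain character sequence (treated as
#'   linear unless `circular = TRUE`).
#' @param min_len Minimum run length in bp (>= 2).
#' @param circular Only used when `genome` is a character string.
#' @return A data frame with columns `start`, `length`, `unit`, `unit_count`,
#'   `base_class` (`AT` or `GC`). `end = start + length - 1` may exceed the
#'   genome length for an origin-spanning run.
#' @export
find_homopolymers <- function(genome, min_len = 5L, circular = NULL) {
  stopifnot(min_len >= 2L)
  if (inherits(genome, "genome_spec")) {
    seq <- genome$sequence
    circ <- genome$circular
    mask <- genome$repeat_mask
  } else {
    seq <- toupper(genome)
    circ <- isTRUE(circular)
    mask <- NULL
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  r <- rle(chars)
  n <- length(r$lengths)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  df <- data.frame(start = starts, length = r$lengths, unit = r$values,
                   stringsAsFactors = FALSE)
  if (circ && n > 1L && r$values[1L] == r$values[n]) {
    # merge the origin-spanning run; anchored at the tail run's start
    df$length[n] <- df$length[n] + df$length[1L]
    df <- df[-1L, , drop = FALSE]
  }
  if (circ && n == 1L) df$length <- min(df$length, len)
  df <- df[df$length >= min_len & df$unit %in% DNA_BASES, , drop = FALSE]
  if (!is.null(mask) && nrow(df)) {
    inside <- run_fully_masked(df$start, df$start + df$length - 1L, mask, len)
    df <- df[!inside, , drop = FALSE]
  }
  df$unit_count <- df$length
  df$base_class <- ifelse(df$unit %in% c("A", "T"), "AT", "GC")
  rownames(df) <- NULL
  df
}

run_fully_masked <- function(start, end, mask, len) {
  # wrapped runs (end > len) cannot be inside a non-wrapping mask interval
  out <- rep(FALSE, length(start))
  if (is.null(mask) || nrow(mask) == 0L) return(out)
  for (i in seq_len(nrow(mask))) {
    out <- out | (start >= mask$start[i] & end <= mask$end[i])
  }
  out & (end <= len)
}

#' Find tandem dinucleotide repeats
#'
#' Returns maximal tandem arrays of a two-base unit with at least `min_units`
#' repetitions. Units with two identical bases are homopolymers and are
#' excluded here. The default of 3 units (6 bp) is a configurable choice:
#' two units cannot be distinguished from chance dinucleotide adjacency.
#'
#' @inheritParams find_homopolymers
#' @param min_units Minimum number of unit repetitions (>= 2).
#' @return A data frame with columns `start`, `length`, `unit`, `unit_count`,
#'   `base_class` (`NA` for dinucleotide units).
#' @export
find_dinucleotide_repeats <- function(genome, min_units = 3L, circular = NULL) {
  stopifnot(min_units >= 2L)
  if (inherits(genome, "genome_spec")) {
    seq <- genome$sequence
    circ <- genome$circular
    mask <- genome$repeat_mask
  } else {
    seq <- toupper(genome)
    circ <- isTRUE(circular)
    mask <- NULL
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  scan_chars <- if (circ) c(chars, chars) else chars
  segs <- period2_segments(scan_chars)
  out <- list()
  for (k in seq_len(nrow(segs))) {
    a <- segs$start[k]; b <- segs$end[k]
    if (scan_chars[a] == scan_chars[a + 1L]) next  # homopolymer unit
    n_units <- (b - a + 1L) %/% 2L
    if (n_units < min_units) next
    if (circ && a > len) next    # duplicate of an array already seen
    out[[length(out) + 1L]] <- data.frame(
      start = a, seg_end = b,
      length = 2L * min(n_units, if (circ) len %/% 2L else n_units),
      unit = paste0(scan_chars[a], scan_chars[a + 1L]),
      unit_count = min(n_units, if (circ) len %/% 2L else n_units),
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), seg_end = integer(0), length = integer(0),
               unit = character(0), unit_count = integer(0),
               stringsAsFactors = FALSE)
  if (circ && nrow(df) > 1L) {
    # a maximal array that begins at position 1 of the doubled scan is the
    # head fragment of an origin-spanning array and is already reported there
    wrapped_cover <- any(df$start > 1L & df$seg_end > len)
    if (wrapped_cover) df <- df[df$start != 1L, , drop = FALSE]
  }
  df$seg_end <- NULL
  if (!is.null(mask) && nrow(df)) {
    inside <- run_fully_masked(df$start, df$start + df$length - 1L, mask, len)
    df <- df[!inside, , drop = FALSE]
  }
  df$base_class <- rep(NA_character_, nrow(df))
  rownames(df) <- NULL
  df
}

# maximal segments where x[i] == x[i+2] holds throughout; a segment
# [a, b] in base coordinates covers a period-2 array from a to b.
period2_segments <- function(x) {
  n <- length(x)
  if (n < 4L) return(data.frame(start = integer(0), end = integer(0)))
  m <- x[seq_len(n - 2L)] == x[3L:n]
  r <- rle(m)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  keep <- r$values
  data.frame(start = starts[keep], end = starts[keep] + r$lengths[keep] + 1L)
}

#' Homopolymer counts by base class and length
#'
#' Tabulates the homopolymer catalogue per (`base_class`, `length`) and
#' reports the AT:GC ratio of homopolymer counts. In the real organelle
#' genomes this ratio separates the AT-dominated plastid repeat landscape
#' (about 12.3-fold more A/T than G/C homopolymers) from the more balanced
#' mitochondrial one (about 2.8-fold).
#'
#' @inheritParams find_homopolymers
#' @return A list with `counts` (data frame `base_class`, `length`, `count`),
#'   `n_at`, `n_gc` and `at_gc_ratio` (`Inf` when no G/C homopolymers exist).
#' @export
homopolymer_class_counts <- function(genome, min_len = 5L) {
  reps <- find_homopolymers(genome, min_len = min_len)
  if (nrow(reps) == 0L) {
    return(list(counts = data.frame(base_class = character(0),
                                    length = integer(0), count = integer(0)),
                n_at = 0L, n_gc = 0L, at_gc_ratio = NaN))
  }
  counts <- aggregate(list(count = rep(1L, nrow(reps))),
                      by = list(base_class = reps$base_class,
                                length = reps$length), FUN = sum)
  counts <- counts[order(counts$base_class, counts$length), , drop = FALSE]
  rownames(counts) <- NULL
  n_at <- sum(reps$base_class == "AT")
  n_gc <- sum(reps$base_class == "GC")
  list(counts = counts, n_at = n_at, n_gc = n_gc,
       at_gc_ratio = if (n_gc == 0L) Inf else n_at / n_gc)
}

#' Write a repeat catalogue to TSV
#'
#' @param repeats Data frame from [find_homopolymers()] or
#'   [find_dinucleotide_repeats()].
#' @param path Output file.
#' @export
write_repeat_catalogue <- function(repeats, path) {
  write.table(repeats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
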