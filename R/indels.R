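# Homopolymer-centric indel analysis: assign each small indel to the simple
# repeat it expands or contracts, then tabulate insertion/deletion bias per
# repeat class and genome, and report loci mutated in several lines.

is_repetition_of <- function(seq, unit) {
  n <- nchar(seq); u <- nchar(unit)
  if (n == 0L || n %% u != 0L) return(FALSE)
  # accept any rotation of the unit (a deletion of "TA" inside an (AT)n
  # array is the same event as a deletion of "AT")
  rotations <- vapply(seq_len(u), function(k) {
    paste0(substr(unit, k, u), substr(unit, 1L, k - 1L))
  }, character(1))
  any(vapply(rotations, function(r) {
    seq == paste(rep(r, n %/% u), collapse = "")
  }, logical(1)))
}

#' Assign small indels to simple-repeat loci
#'
#' Each indel (left-aligned, anchored at `pos`, with the inserted/deleted
#' sequence in `alt`) is assigned to the homopolymer whose interval contains
#' the anchor and whose unit base the indel sequence repeats; failing that,
#' to a matching dinucleotide array; otherwise it is `non-repetitive`. An
#' indel longer than the containing run that still consists of the run's
#' base counts as an expansion/contraction of that run.
#'
#' @param indel_calls Variant-call data frame (insertion/deletion rows are
#'   used; flagged calls are dropped).
#' @param homopolymers Catalogue from [find_homopolymers()].
#' @param dinucleotides Catalogue from [find_dinucleotide_repeats()].
#' @param max_indel_bp "Small indel" ceiling in bp (default 10); longer
#'   events are dropped with a message.
#' @return A data frame of assignments: `line`, `genome`, `pos`,
#'   `indel_seq`, `length_change` (+insertion/-deletion), `context`
#'   (`homopolymer-AT`, `homopolymer-GC`, `dinucleotide`,
#'   `non-repetitive`), `locus_start`, `locus_length`, `unit`.
#' @export
assign_indels <- function(indel_calls, homopolymers,
                          dinucleotides = NULL, max_indel_bp = 10L) {
  ok <- passing_calls(indel_calls)
  ok <- ok[ok$var_type %in% c("insertion", "deletion"), , drop = FALSE]
  too_big <- nchar(ok$alt) > max_indel_bp
  if (any(too_big)) {
    message(sum(too_big), " indel(s) over ", max_indel_bp, " bp dropped")
    ok <- ok[!too_big, , drop = FALSE]
  }
  n <- nrow(ok)
  out <- data.frame(
    line = ok$line, genome = ok$genome, pos = ok$pos,
    indel_seq = ok$alt,
    length_change = ifelse(ok$var_type == "insertion", 1L, -1L) *
      nchar(ok$alt),
    context = rep("non-repetitive", n),
    locus_start = rep(NA_integer_, n), locus_length = rep(NA_integer_, n),
    unit = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  hp <- homopolymers
  dn <- dinucleotides
  for (i in seq_len(n)) {
    p <- out$pos[i]; s <- out$indel_seq[i]
    if (!is.null(hp) && nrow(hp)) {
      hit <- which(p >= hp$start & p <= hp$start + hp$length - 1L &
                   vapply(hp$unit, function(u) is_repetition_of(s, u),
                          logical(1)))
      if (length(hit)) {
        h <- hit[1L]
        out$context[i] <- paste0("homopolymer-", hp$base_class[h])
        out$locus_start[i] <- hp$start[h]
        out$locus_length[i] <- hp$length[h]
        out$unit[i] <- hp$unit[h]
        next
      }
    }
    if (!is.null(dn) && nrow(dn)) {
      hit <- which(p >= dn$start & p <= dn$start + dn$length - 1L &
                   vapply(dn$unit, function(u) is_repetition_of(s, u),
                          logical(1)))
      if (length(hit)) {
        h <- hit[1L]
        out$context[i] <- "dinucleotide"
        out$locus_start[i] <- dn$start[h]
        out$locus_length[i] <- dn$length[h]
        out$unit[i] <- dn$unit[h]
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Insertion/deletion bias table
#'
#' Counts insertions and deletions per (genome, repeat context), with a
#' histogram of absolute length changes. The study-scale signature is a
#' deletion bias at A/T homopolymers and an insertion bias at G/C
#' homopolymers in both organelle genomes.
#'
#' @param assignments Output of [assign_indels()].
#' @return A data frame with one row per (genome, context): `insertions`,
#'   `deletions`, `len_1`, `len_2`, `len_3`, `len_gt3`.
#' @export
bias_table <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(genome = character(0), context = character(0),
                      insertions = integer(0), deletions = integer(0),
                      len_1 = integer(0), len_2 = integer(0),
                      len_3 = integer(0), len_gt3 = integer(0)))
  }
  key <- interaction(assignments$genome, assignments$context, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- assignments[key == k, , drop = FALSE]
    alen <- abs(sub$length_change)
    data.frame(genome = sub$genome[1L], context = sub$context[1L],
               insertions = sum(sub$length_change > 0L),
               deletions = sum(sub$length_change < 0L),
               len_1 = sum(alen == 1L), len_2 = sum(alen == 2L),
               len_3 = sum(alen == 3L), len_gt3 = sum(alen > 3L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genome, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overall indel summary per genome
#'
#' @param assignments Output of [assign_indels()].
#' @return A list with `per_genome` (data frame of insertion/deletion
#'   totals), `n_total`, `n_homopolymer`, `n_dinucleotide`,
#'   `n_non_repetitive` and `homopolymer_fraction`.
#' @export
indel_summary <- function(assignments) {
  per_genome <- lapply(unique(assignments$genome), function(g) {
    sub <- assignments[assignments$genome == g, , drop = FALSE]
    data.frame(genome = g,
               insertions = sum(sub$length_change > 0L),
               deletions = sum(sub$length_change < 0L),
               total = nrow(sub), stringsAsFactors = FALSE)
  })
  n_hp <- sum(startsWith(assignments$context, "homopolymer"))
  list(per_genome = do.call(rbind, per_genome),
       n_total = nrow(assignments),
       n_homopolymer = n_hp,
       n_dinucleotide = sum(assignments$context == "dinucleotide"),
       n_non_repetitive = sum(assignments$context == "non-repetitive"),
       homopolymer_fraction = if (nrow(assignments)) {
         n_hp / nrow(assignments)
       } else NaN)
}

#' Report repeat loci mutated in multiple lines
#'
#' Groups assignments by repeat locus and reports loci hit in two or more
#' lines, whether the observed indel lengths differ between lines (evidence
#' for independent mutational hits rather than shared inheritance), and --
#' when line metadata with a `founder` column is supplied -- whether all
#' lines share a founder family.
#'
#' @param assignments Output of [assign_indels()].
#' @param meta Optional line metadata with `line` and `founder`.
#' @return A data frame with one row per recurrent locus: `genome`,
#'   `locus_start`, `context`, `n_lines`, `lines`, `length_changes`,
#'   `lengths_differ`, `shared_founder`.
#' @export
recurrence_report <- function(assignments, meta = NULL) {
  rep_rows <- assignments[assignments$context != "non-repetitive", ,
                          drop = FALSE]
  empty <- data.frame(genome = character(0), locus_start = integer(0),
                      context = character(0), n_lines = integer(0),
                      lines = character(0), length_changes = character(0),
                      lengths_differ = logical(0),
                      shared_founder = logical(0))
  if (nrow(rep_rows) == 0L) return(empty)
  key <- paste(rep_rows$genome, rep_rows$locus_start, sep = ":")
  rows <- lapply(unique(key), function(k) {
    sub <- rep_rows[key == k, , drop = FALSE]
    lines <- unique(sub$line)
    if (length(lines) < 2L) return(NULL)
    shared <- NA
    if (!is.null(meta) && "founder" %in% names(meta)) {
      fam <- meta$founder[match(lines, meta$line)]
      shared <- length(unique(fam)) == 1L
    }
    per_line_lens <- tapply(sub$length_change, sub$line,
                            function(v) paste(sort(v), collapse = ","))
    data.frame(genome = sub$genome[1L], locus_start = sub$locus_start[1L],
               context = sub$context[1L], n_lines = length(lines),
               lines = paste(sort(lines), collapse = ","),
               length_changes = paste(per_line_lens[sort(lines)],
                                      collapse = ";"),
               lengths_differ = length(unique(sub$length_change)) > 1L,
               shared_founder = shared, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$genome, out$locus_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
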