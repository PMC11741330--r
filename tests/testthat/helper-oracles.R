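# Independent brute-force oracles used to check the package scanners, plus
# small builders shared across test files.

# regex-based homopolymer finder (linear sequences only)
oracle_homopolymers <- function(seq, min_len = 5L) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_len), seq)[[1L]]
    if (m[1L] == -1L) next
    out[[b]] <- data.frame(start = as.integer(m),
                           length = attr(m, "match.length"), unit = b,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), length = integer(0),
                      unit = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# position-by-position maximal tandem dinucleotide scan (linear)
oracle_dinucs <- function(seq, min_units = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    a <- chars[i]; b <- chars[i + 1L]
    if (a == b) next
    # maximal: the alternating pattern must not extend one base left
    if (i > 1L && chars[i - 1L] == chars[i + 1L]) next
    j <- i + 1L
    while (j < n && chars[j + 1L] == chars[j - 1L]) j <- j + 1L
    units <- (j - i + 1L) %/% 2L
    if (units >= min_units) {
      out[[length(out) + 1L]] <- data.frame(
        start = i, length = 2L * units, unit = paste0(a, b),
        unit_count = units, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), length = integer(0),
                      unit = character(0), unit_count = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one site-count row in the schema used throughout the tests
count_row <- function(sample, chrom, pos, ref, depth, A = 0L, C = 0L,
                      G = 0L, T = 0L, ins = 0L, del = 0L, ins_seq = "",
                      del_seq = "") {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             depth = depth, A = A, C = C, G = G, T = T, ins = ins,
             del = del, ins_seq = ins_seq, del_seq = del_seq,
             stringsAsFactors = FALSE)
}

# fixed toy gene used by annotation/permutation tests:
# ATG GCT AAA TGC GGA TAA ("M A K C G *")
toy_seq <- function(flank5 = "TTGACC", flank3 = "CAGTTG") {
  paste0(flank5, "ATGGCTAAATGCGGATAA", flank3)
}

# a small annotated genome used by annotation/permutation tests: a single
# forward-strand CDS of `n_codons` codons starting at `cds_start`
toy_cds_genome <- function(seq, cds_start, n_codons, name = "toy",
                           strand = "+", kind = "mito") {
  genome_spec(
    name = name, sequence = seq, kind = kind, circular = FALSE,
    features = data.frame(
      gene = "g1", kind = "CDS", start = cds_start,
      end = cds_start + 3L * n_codons - 1L, strand = strand,
      stringsAsFactors = FALSE))
}

# standard-code translation used as the oracle side in annotation tests
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

scaled_sim_config <- function(seed, rates = list(), sequencing = list(),
                              heteroplasmy = list(), lines = list()) {
  sim_config(
    seed = seed,
    mito = list(length = 5000L, repeat_pair_len = 600L, numt_len = 700L,
                numt_copies = 1L, n_at_homopolymers = 12L,
                n_gc_homopolymers = 5L, n_dinucleotides = 4L,
                n_genes = 2L, cds_codons = 40L),
    plastid = list(length = 1500L, repeat_pair_len = 200L,
                   n_at_homopolymers = 6L, n_gc_homopolymers = 2L,
                   n_dinucleotides = 2L, n_genes = 1L, cds_codons = 30L),
    lines = utils::modifyList(
      list(n_mut = 6L, n_wt = 4L, mut_generations = rep(4L, 6L),
           wt_generations = 4L), lines),
    heteroplasmy = utils::modifyList(list(mode = "fixation"), heteroplasmy),
    sequencing = utils::modifyList(
      list(mean_depth = 80, nuclear_cov = 30, error_rate = 0.003),
      sequencing),
    rates = rates)
}
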