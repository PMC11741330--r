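# Synthetic reconstructions of the study's supplementary variant tables.
#
# The per-variant supplementary tables (SD1: SNVs/MNVs, SD2: indels) are
# not redistributed with this package. These constructors rebuild tables of
# the same shape from the *published marginal counts* -- the per-genome SNV
# totals and spectrum-class counts, and the indel totals with their
# insertion/deletion and repeat-context breakdowns -- so that the summary
# statistics recomputed from them reproduce the printed values. They are
# synthetic stand-ins: positions and line assignments are arbitrary, and
# per-variant frequencies are set to the uniform value implied by each
# genome's published frequency-weighted rate (V = mu * G * N spread evenly
# over the variants). Use them to exercise the analysis code, not as data.

#' Published study constants
#'
#' Effective genome sizes, generation totals and headline counts used by
#' the worked examples and the acceptance checks: `G` (357,025 bp
#' mitochondrial, 128,214 bp plastid), `N_msh1 = 150` (18 lines x 7 + 4 x
#' 6 homozygous generations), `N_wt = 2835` (2,675 + 160 wild-type
#' generations including the reanalysed 107-line experiment), SNV rates
#' 6.1e-7 / 3.2e-6, and indel counts 258 / 410.
#'
#' @return A named list of constants.
#' @export
study_constants <- function() {
  list(
    G = c(mito = 357025, plastid = 128214),
    N_msh1 = 150,
    N_wt = 2835,
    snv_rate = c(mito = 6.1e-7, plastid = 3.2e-6),
    n_snv = c(mito = 49, plastid = 75),
    n_indel = c(mito = 258, plastid = 410),
    spectrum_counts = list(
      mito = c("AT>GC" = 23, "GC>AT" = 21, "AT>CG" = 2,
               "GC>TA" = 1, "AT>TA" = 1, "GC>CG" = 1),
      plastid = c("AT>GC" = 62, "GC>AT" = 6, "AT>CG" = 2,
                  "GC>TA" = 2, "AT>TA" = 2, "GC>CG" = 1)),
    location_counts = list(
      mito = c(CDS = 6, rRNA = 1, tRNA = 0, intron = 7, intergenic = 35),
      plastid = c(CDS = 35, rRNA = 7, tRNA = 3, intron = 8,
                  intergenic = 22)),
    indel_insertions = c(mito = 144, plastid = 140),
    indel_deletions = c(mito = 114, plastid = 270),
    indel_contexts = list(
      mito = c(homopolymer = 253, dinucleotide = 4, non_repetitive = 1),
      plastid = c(homopolymer = 402, dinucleotide = 6, non_repetitive = 2)))
}

# cycle variants over the 22 msh1 line ids of the study design
msh1_line_name <- function(i) {
  j <- ((i - 1L) %% 22L) + 1L
  sprintf("M%d_%d", ((j - 1L) %% 3L) + 1L, ((j - 1L) %/% 3L) + 1L)
}

class_example_alleles <- function(class, i) {
  subst <- CLASS_SUBST[[class]]
  refs <- names(subst)
  j <- ((i - 1L) %% length(refs)) + 1L
  c(ref = refs[j], alt = unname(subst[refs[j]]))
}

#' Synthetic SD1-style SNV table
#'
#' A variant-call table with the published per-genome SNV totals and
#' spectrum-class counts (49 mitochondrial, 75 plastid; 23/21 and 62/6
#' AT>GC / GC>AT). Frequencies are the uniform per-genome values implied by
#' the published frequency-weighted rates. Positions and line assignments
#' are synthetic.
#'
#' @return A variant-call data frame compatible with
#'   [estimate_mutation_rate()] and [spectrum_table()].
#' @export
synthetic_sd1_snvs <- function() {
  k <- study_constants()
  rows <- list()
  for (g in c("mito", "plastid")) {
    counts <- k$spectrum_counts[[g]]
    n <- sum(counts)
    freq <- k$snv_rate[[g]] * k$G[[g]] * k$N_msh1 / n
    i <- 0L
    for (cl in names(counts)) {
      for (j in seq_len(counts[[cl]])) {
        i <- i + 1L
        al <- class_example_alleles(cl, j)
        rows[[length(rows) + 1L]] <- data.frame(
          line = msh1_line_name(i),
          genome = g, pos = 1000L + 50L * i, ref = al[["ref"]],
          alt = al[["alt"]], var_type = "SNV", depth = 100L,
          alt_count = as.integer(round(100 * freq)),
          raw_frequency = freq, corrected_frequency = freq,
          homoplasmy = "unclassified", filters = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic SD2-style indel assignment table
#'
#' An indel-assignment table (shape of [assign_indels()] output) with the
#' published totals: 258 mitochondrial (144 insertions / 114 deletions) and
#' 410 plastid indels (140 / 270), of which 655 sit in homopolymers, 10 in
#' dinucleotide repeats and 3 in non-repetitive sequence. Loci are
#' synthetic.
#'
#' @return A data frame compatible with [bias_table()] and
#'   [indel_summary()].
#' @export
synthetic_sd2_indels <- function() {
  k <- study_constants()
  rows <- list()
  for (g in c("mito", "plastid")) {
    ctx <- k$indel_contexts[[g]]
    n_ins <- k$indel_insertions[[g]]
    n_tot <- sum(ctx)
    contexts <- c(rep("homopolymer-AT", round(ctx[["homopolymer"]] * 0.7)),
                  rep("homopolymer-GC",
                      ctx[["homopolymer"]] - round(ctx[["homopolymer"]] * 0.7)),
                  rep("dinucleotide", ctx[["dinucleotide"]]),
                  rep("non-repetitive", ctx[["non_repetitive"]]))
    sign <- rep(-1L, n_tot)
    sign[seq_len(n_ins)] <- 1L
    unit <- ifelse(startsWith(contexts, "homopolymer-AT"), "A",
                   ifelse(startsWith(contexts, "homopolymer-GC"), "G", "AT"))
    i <- seq_len(n_tot)
    rows[[g]] <- data.frame(
      line = msh1_line_name(i),
      genome = g, pos = 500L + 20L * i, indel_seq = unit,
      length_change = sign * 1L, context = contexts,
      locus_start = ifelse(contexts == "non-repetitive", NA_integer_,
                           500L + 20L * i),
      locus_length = ifelse(contexts == "non-repetitive", NA_integer_, 7L),
      unit = ifelse(contexts == "non-repetitive", NA_character_, unit),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic line metadata matching the study design
#'
#' 22 msh1 lines (18 at 7 homozygous generations, 4 at 6; N = 150) and 20
#' wild-type lines at 8 generations (N = 160), in 3 founder families.
#'
#' @return A line-metadata data frame.
#' @export
study_line_plan <- function() {
  line_plan(sim_config())
}
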