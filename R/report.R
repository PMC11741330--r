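# Analysis front end: run the whole chain on a dataset (typically a
# simulated experiment) and assemble one report object, written as JSON
# plus a Markdown summary. Every number in the report is computed by the
# stage functions; the reporter only collects.

#' Run the full MA analysis on a dataset
#'
#' Calls variants per genome, estimates SNV (frequency-weighted) and indel
#' (unscaled) mutation rates for the mutant lines, tabulates the mutation
#' spectrum and variant locations, assigns indels to repeat loci, and runs
#' the synonymous permutation test when CDS SNVs are present. Wild-type
#' passing-call counts are reported alongside the Poisson upper bound that
#' a zero-variant WT panel implies.
#'
#' @param counts Site-count table covering all samples and genomes.
#' @param genomes Named list of [genome_spec()] objects.
#' @param meta Line metadata (`line`, `genotype`, `generations`, optional
#'   `founder`).
#' @param sample_info Optional per-sample read totals (see
#'   [render_counts()]) used to estimate nuclear coverage for the numt
#'   correction.
#' @param min_freq,min_depth,background_fold,flank_k Filter thresholds.
#' @param n_perms,seed Permutation-test settings.
#' @return A nested list (class `ma_report`) with one entry per genome plus
#'   the permutation result.
#' @export
run_ma_analysis <- function(counts, genomes, meta, sample_info = NULL,
                            min_freq = 0.20, min_depth = 50L,
                            background_fold = 3, flank_k = 30L,
                            n_perms = 10000L, seed = 1L) {
  nuclear_cov <- NULL
  if (!is.null(sample_info)) {
    nuclear_cov <- setNames(
      estimate_nuclear_coverage(sample_info$total_reads,
                                sample_info$organelle_mapped_reads,
                                sample_info$read_length,
                                sample_info$nuclear_genome_size),
      sample_info$sample)
  }
  mut_lines <- meta[meta$genotype == "msh1", , drop = FALSE]
  wt_lines <- meta[meta$genotype == "WT", , drop = FALSE]
  report <- list(genomes = list(), thresholds = list(
    min_freq = min_freq, min_depth = min_depth,
    background_fold = background_fold, flank_k = flank_k))
  all_cds_snvs <- NULL

  for (g in genomes) {
    calls <- call_variants(counts, g, meta, genome_set = genomes,
                           min_freq = min_freq, min_depth = min_depth,
                           background_fold = background_fold,
                           flank_k = flank_k, nuclear_cov = nuclear_cov)
    ann <- annotate_variants(calls, g)
    ok <- passing_calls(ann)
    ok_mut <- ok[ok$line %in% mut_lines$line, , drop = FALSE]
    ok_wt <- ok[ok$line %in% wt_lines$line, , drop = FALSE]

    snv_rate <- estimate_mutation_rate(ann, mut_lines, g$effective_size_G,
                                       "SNV", weight_by_frequency = TRUE)
    indel_rate <- estimate_mutation_rate(ann, mut_lines, g$effective_size_G,
                                         "indel")
    hp <- find_homopolymers(g)
    dn <- find_dinucleotide_repeats(g)
    assignments <- assign_indels(ok_mut, hp, dn)

    wt_N <- sum(wt_lines$generations)
    report$genomes[[g$name]] <- list(
      kind = g$kind, effective_size_G = g$effective_size_G,
      calls = ann,
      n_passing_mut = nrow(ok_mut), n_passing_wt = nrow(ok_wt),
      snv_rate = snv_rate, indel_rate = indel_rate,
      wt_upper_bound = if (wt_N > 0) {
        poisson_upper_bound(g$effective_size_G, wt_N)
      } else NA_real_,
      spectrum = spectrum_table(ann, g, mut_lines),
      locations = location_summary(ann[ann$line %in% mut_lines$line, ,
                                       drop = FALSE]),
      indel_bias = bias_table(assignments),
      indel_summary = indel_summary(assignments),
      recurrence = recurrence_report(assignments, meta))

    cds <- ok_mut[ok_mut$var_type == "SNV" & ok_mut$location == "CDS", ,
                  drop = FALSE]
    if (nrow(cds)) {
      all_cds_snvs <- rbind(all_cds_snvs,
                            cds[, c("genome", "pos", "ref", "alt")])
    }
  }
  report$permutation <- if (!is.null(all_cds_snvs)) {
    permutation_test_synonymous(all_cds_snvs, genomes, n_perms = n_perms,
                                seed = seed)
  } else NULL
  class(report) <- "ma_report"
  report
}

#' Write an analysis report
#'
#' Writes `report.json` (full precision) and `report.md` (3 significant
#' figures) summarizing rates, bounds, spectra, location counts, indel bias
#' and the permutation P-value.
#'
#' @param report Output of [run_ma_analysis()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_ma_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list()
  md <- c("# Organelle MA analysis report", "")
  for (gname in names(report$genomes)) {
    r <- report$genomes[[gname]]
    json[[gname]] <- list(
      kind = r$kind, effective_size_G = r$effective_size_G,
      snv_rate = r$snv_rate$mu, snv_weighted_V = r$snv_rate$V,
      indel_rate = r$indel_rate$mu, indel_count = r$indel_rate$V,
      wt_upper_bound = r$wt_upper_bound,
      n_passing_mut = r$n_passing_mut, n_passing_wt = r$n_passing_wt,
      spectrum = r$spectrum[, c("class", "count", "weighted", "rate")],
      locations = as.list(r$locations),
      indel_summary = r$indel_summary[c("n_total", "n_homopolymer",
                                        "n_dinucleotide",
                                        "homopolymer_fraction")])
    md <- c(md, sprintf("## %s (%s)", gname, r$kind),
            sprintf("- effective genome size G: %d bp", r$effective_size_G),
            sprintf("- SNV rate (frequency-weighted): %.3g per bp per generation (V = %.3g)",
                    r$snv_rate$mu, r$snv_rate$V),
            sprintf("- indel rate (unscaled): %.3g per bp per generation (V = %d)",
                    r$indel_rate$mu, as.integer(r$indel_rate$V)),
            sprintf("- WT passing calls: %d (upper bound %.3g)",
                    r$n_passing_wt, r$wt_upper_bound),
            sprintf("- homopolymer indel fraction: %.3g",
                    r$indel_summary$homopolymer_fraction), "")
  }
  if (!is.null(report$permutation)) {
    json$permutation <- report$permutation[c("n_perms", "n_variants",
                                             "observed_synonymous",
                                             "p_value", "null_mean")]
    md <- c(md, "## Synonymous permutation test",
            sprintf("- observed synonymous: %d; one-tailed P = %.3g (%d permutations)",
                    report$permutation$observed_synonymous,
                    report$permutation$p_value,
                    report$permutation$n_perms))
  }
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path))
}
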