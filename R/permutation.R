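# Permutation null for synonymous-variant counts: keep the number and
# strand-collapsed class of the observed CDS SNVs fixed per genome, but
# randomize each variant's position uniformly over the CDS sites whose
# reference base is consistent with its class (an AT>GC variant lands on an
# A or T in coding sequence). The one-tailed P-value is the fraction of
# permutations with at least as many synonymous outcomes as observed.
#
# Because the spectrum classes are strand-collapsed, eligibility and the
# substituted base can be evaluated on the coding strand directly: a site's
# membership in the A/T or G/C pair is the same on both strands.

# per-class synonymous-outcome vectors over the eligible CDS sites
class_syn_vectors <- function(inventory) {
  out <- list()
  for (cl in SPECTRUM_CLASSES) {
    subst <- CLASS_SUBST[[cl]]
    rows <- inventory$base %in% names(subst)
    if (!any(rows)) {
      out[[cl]] <- logical(0)
      next
    }
    sub <- inventory[rows, , drop = FALSE]
    alt <- unname(subst[sub$base])
    out[[cl]] <- vapply(seq_len(nrow(sub)),
                        function(i) sub[[alt[i]]][i], logical(1))
  }
  out
}

#' Permutation test for synonymous-variant enrichment
#'
#' Tests whether the observed number of synonymous substitutions among CDS
#' SNVs exceeds what random placement would produce, holding the number and
#' substitution class of variants fixed per genome. For each of `n_perms`
#' permutations, every variant is dropped (with replacement) onto a uniform
#' CDS position whose reference base matches the variant's class source
#' pair, the class substitution is applied, and synonymous outcomes are
#' counted. The one-tailed P-value is the plain proportion of permutations
#' with a synonymous count greater than or equal to the observed count (no
#' +1 smoothing).
#'
#' @param cds_snvs Data frame of observed CDS SNVs with columns `genome`,
#'   `pos`, `ref`, `alt` (passing SNV rows; the function annotates them to
#'   count observed synonymous outcomes).
#' @param genomes Named list of [genome_spec()] objects covering every
#'   genome in `cds_snvs`.
#' @param n_perms Number of permutations (default 10,000).
#' @param seed Optional integer seed for the permutation stream.
#' @param observed_synonymous Override for the observed synonymous count
#'   (computed from `cds_snvs` by annotation when `NULL`).
#' @return A list with `n_perms`, `n_variants`, `observed_synonymous`,
#'   `p_value`, `null_mean` and `null_quantiles`.
#' @export
permutation_test_synonymous <- function(cds_snvs, genomes, n_perms = 10000L,
                                        seed = NULL,
                                        observed_synonymous = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(genomes, "genome_spec")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")

  n_var <- nrow(cds_snvs)
  if (n_var == 0L) {
    return(list(n_perms = n_perms, n_variants = 0L,
                observed_synonymous = 0L, p_value = 1.0,
                null_mean = 0, null_quantiles = stats::setNames(
                  rep(0, 5L), c("0%", "25%", "50%", "75%", "100%"))))
  }
  if (is.null(observed_synonymous)) {
    obs <- 0L
    for (gname in unique(cds_snvs$genome)) {
      sub <- cds_snvs[cds_snvs$genome == gname, , drop = FALSE]
      sub$var_type <- "SNV"; sub$filters <- ""
      ann <- annotate_variants(sub, genomes[[gname]])
      if (any(ann$location != "CDS")) {
        stop("all observed variants must lie in CDS")
      }
      obs <- obs + sum(ann$effect == "synonymous", na.rm = TRUE)
    }
    observed_synonymous <- obs
  }

  null_counts <- integer(n_perms)
  for (gname in unique(cds_snvs$genome)) {
    sub <- cds_snvs[cds_snvs$genome == gname, , drop = FALSE]
    classes <- classify_snv_class(sub$ref, sub$alt)
    inv <- cds_site_inventory(genomes[[gname]])
    syn_vec <- class_syn_vectors(inv)
    for (cl in unique(classes)) {
      v <- syn_vec[[cl]]
      if (length(v) == 0L) {
        stop("no eligible CDS positions for class ", cl,
             " in genome ", gname)
      }
      m <- sum(classes == cl)
      draws <- matrix(sample(v, m * n_perms, replace = TRUE), nrow = m)
      null_counts <- null_counts + colSums(draws)
    }
  }
  p <- mean(null_counts >= observed_synonymous)
  list(n_perms = n_perms, n_variants = n_var,
       observed_synonymous = observed_synonymous,
       p_value = p, null_mean = mean(null_counts),
       null_quantiles = quantile(null_counts))
}
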