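# Strand-collapsed mutation spectrum: each substitution is pooled with its
# reverse complement into one of six classes (AT>GC, GC>AT, AT>CG, GC>TA,
# AT>TA, GC>CG), weighted by heteroplasmic frequency and normalized to the
# number of AT or GC base pairs so that genomes of different composition are
# comparable.

# (source base -> alt base) for each class, on the A/G representative strand
CLASS_SUBST <- list(
  "AT>GC" = c(A = "G", T = "C"),
  "GC>AT" = c(G = "A", C = "T"),
  "AT>CG" = c(A = "C", T = "G"),
  "GC>TA" = c(G = "T", C = "A"),
  "AT>TA" = c(A = "T", T = "A"),
  "GC>CG" = c(G = "C", C = "G")
)

#' Strand-collapsed substitution class
#'
#' Maps a substitution to one of the six strand-collapsed classes; a change
#' and its reverse complement share a class (A>G and T>C are both `AT>GC`).
#' `AT>GC` and `GC>AT` are the transitions.
#'
#' @param ref,alt Reference and alternate bases (vectors of A/C/G/T).
#' @return Character vector of classes (see `spectrum_classes()`).
#' @export
classify_snv_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES)) {
    stop("ref and alt must be single nucleotides A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  # collapse onto the A/G representative strand
  flip <- ref %in% c("T", "C")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  key <- paste0(r, a)
  map <- c(AG = "AT>GC", GA = "GC>AT", AC = "AT>CG",
           GT = "GC>TA", AT = "AT>TA", GC = "GC>CG")
  unname(map[key])
}

#' @rdname classify_snv_class
#' @export
spectrum_classes <- function() SPECTRUM_CLASSES

#' @rdname classify_snv_class
#' @param class A spectrum class string.
#' @return For `is_transition()`, logical.
#' @export
is_transition <- function(class) class %in% c("AT>GC", "GC>AT")

#' Mutation spectrum table
#'
#' Tabulates passing SNVs by strand-collapsed class with raw counts,
#' frequency-weighted counts and normalized per-bp per-generation rates.
#' `AT>*` classes are normalized by the number of A/T base pairs and `GC>*`
#' classes by G/C base pairs of the unmasked genome, then divided by the
#' total generations `N`.
#'
#' @param snvs Variant-call data frame (SNV rows with single-base
#'   `ref`/`alt` are used; flagged calls are dropped).
#' @param genome The [genome_spec()] (for base composition).
#' @param lines Line metadata restricted to the genotype under study.
#' @param weight_by_frequency Weight each SNV by `corrected_frequency`
#'   (default TRUE).
#' @return A data frame with one row per class: `class`, `count`,
#'   `weighted`, `count_fraction`, `rate`, `transition`.
#' @export
spectrum_table <- function(snvs, genome, lines, weight_by_frequency = TRUE) {
  ok <- passing_calls(snvs)
  ok <- ok[ok$var_type == "SNV" & ok$line %in% lines$line, , drop = FALSE]
  N <- sum(lines$generations)
  comp <- base_composition(genome, exclude_masked = TRUE)
  cls <- if (nrow(ok)) classify_snv_class(ok$ref, ok$alt) else character(0)
  w <- if (weight_by_frequency) ok$corrected_frequency else rep(1, nrow(ok))
  out <- data.frame(class = SPECTRUM_CLASSES, stringsAsFactors = FALSE)
  out$count <- vapply(SPECTRUM_CLASSES, function(k) sum(cls == k), numeric(1))
  out$weighted <- vapply(SPECTRUM_CLASSES, function(k) sum(w[cls == k]),
                         numeric(1))
  total <- sum(out$count)
  out$count_fraction <- if (total > 0) out$count / total else rep(0, 6L)
  class_bp <- ifelse(startsWith(out$class, "AT"), comp$at_bp, comp$gc_bp)
  out$rate <- ifelse(class_bp > 0 & N > 0, out$weighted / (class_bp * N), 0)
  out$transition <- is_transition(out$class)
  rownames(out) <- NULL
  out
}
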