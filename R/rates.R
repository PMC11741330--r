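# Mutation-rate estimation: mu = V / (G * N), where V is the (optionally
# frequency-weighted) variant count, G the effective genome size in bp and
# N the total number of generations summed across the MA lines.

#' Mutation rate from a variant count
#'
#' `mu = V / (G * N)`. For SNVs, `V` is usually the sum of heteroplasmic
#' frequencies (each variant scaled by its frequency); for indels it is the
#' unscaled count, because frequency estimates at homopolymers are dominated
#' by sequencing error.
#'
#' @param V Variant count (possibly frequency-weighted, so not necessarily
#'   an integer).
#' @param G Effective genome size in bp (> 0).
#' @param N Total generations summed across lines (> 0).
#' @param variant_class Label stored with the estimate (`"SNV"`/`"indel"`).
#' @param genome Optional genome name stored with the estimate.
#' @return A `rate_estimate`: list with `mu`, `V`, `G`, `N`,
#'   `variant_class`, `genome`.
#' @examples
#' mutation_rate(258, G = 357025, N = 150)$mu   # 4.8e-6
#' mutation_rate(410, G = 128214, N = 150)$mu   # 2.1e-5
#' @export
mutation_rate <- function(V, G, N, variant_class = "SNV", genome = NA) {
  if (N <= 0) stop("N must be > 0")
  if (G <= 0) stop("G must be > 0")
  if (V < 0) stop("V must be >= 0")
  structure(list(mu = V / (G * N), V = V, G = G, N = N,
                 variant_class = variant_class, genome = genome),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s mutation rate%s: mu = %.3g per bp per generation (V = %.4g, G = %d bp, N = %d)\n",
              x$variant_class,
              if (is.na(x$genome)) "" else paste0(" [", x$genome, "]"),
              x$mu, x$V, as.integer(x$G), as.integer(x$N)))
  invisible(x)
}

#' Mutation rate from a filtered call table
#'
#' Computes `V` from passing calls and `N` from the line metadata (the
#' caller restricts `lines` to the genotype under study) and delegates to
#' [mutation_rate()]. MNVs are excluded from the SNV count by default,
#' mirroring their separate reporting.
#'
#' @param calls Variant-call data frame (flagged calls are dropped).
#' @param lines Line metadata restricted to the genotype under study
#'   (columns `line`, `generations`).
#' @param G Effective genome size in bp.
#' @param variant_class `"SNV"` (uses SNV rows) or `"indel"` (insertion and
#'   deletion rows).
#' @param weight_by_frequency Sum corrected frequencies instead of counting
#'   (default TRUE for SNVs; ignored meaningfully for indels, which the
#'   study counts unscaled).
#' @param include_mnv Count MNVs together with SNVs (default FALSE).
#' @return A `rate_estimate`.
#' @export
estimate_mutation_rate <- function(calls, lines, G,
                                   variant_class = c("SNV", "indel"),
                                   weight_by_frequency = variant_class == "SNV",
                                   include_mnv = FALSE) {
  variant_class <- match.arg(variant_class)
  if (any(lines$generations < 1)) stop("generations must be >= 1")
  N <- sum(lines$generations)
  if (N == 0) stop("N must be > 0")
  ok <- passing_calls(calls)
  ok <- ok[ok$line %in% lines$line, , drop = FALSE]
  types <- if (variant_class == "SNV") {
    if (include_mnv) c("SNV", "MNV") else "SNV"
  } else c("insertion", "deletion")
  ok <- ok[ok$var_type %in% types, , drop = FALSE]
  V <- if (isTRUE(weight_by_frequency)) {
    sum(ok$corrected_frequency)
  } else nrow(ok)
  g_name <- if (nrow(ok)) ok$genome[1L] else NA
  mutation_rate(V, G, N, variant_class = variant_class, genome = g_name)
}

#' Poisson upper bound on an undetected mutation rate
#'
#' When no variant is observed, the mutation count is modeled as Poisson
#' with mean `mu * G * N`; the probability of observing zero is
#' `exp(-mu*G*N)`. Setting it to `alpha` and solving gives the smallest rate
#' that would have been detected with probability `1 - alpha`:
#' `mu_upper = ln(1/alpha) / (G * N)`.
#'
#' @param G Effective genome size in bp (> 0).
#' @param N Total generations (> 0).
#' @param alpha Zero-observation probability, in (0, 1); default 0.05.
#' @return The upper-bound rate per bp per generation.
#' @examples
#' signif(poisson_upper_bound(357025, 2835), 1)  # ~3e-9 (mitochondrial)
#' signif(poisson_upper_bound(128214, 2835), 1)  # ~8e-9 (plastid)
#' @export
poisson_upper_bound <- function(G, N, alpha = 0.05) {
  if (G <= 0 || N <= 0) stop("G and N must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  log(1 / alpha) / (G * N)
}

#' Rate implied by a single observed variant
#'
#' `1 / (G * N)`: the rate estimate a single (homoplasmic) variant would
#' have produced in a sample of `N` total generations. A useful sensitivity
#' floor when zero variants were observed.
#'
#' @inheritParams poisson_upper_bound
#' @return Rate per bp per generation.
#' @export
single_variant_rate <- function(G, N) {
  if (G <= 0 || N <= 0) stop("G and N must be > 0")
  1 / (G * N)
}

#' Fold ratio of two rates
#'
#' @param rate_a Numerator rate.
#' @param rate_b Denominator rate (> 0).
#' @return `rate_a / rate_b`.
#' @export
fold_ratio <- function(rate_a, rate_b) {
  if (any(rate_b <= 0)) stop("denominator rate must be > 0")
  rate_a / rate_b
}
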