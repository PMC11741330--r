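# Forward simulator of organelle MA experiments.
#
# Generates a pair of circular genomes of contrasting GC content with
# planted homopolymers, dinucleotide arrays, a duplicated large-repeat pair
# and (for the "mitochondrial" genome) a numt interval; propagates MA lines
# by single-seed descent with per-generation Poisson mutation input and a
# heteroplasmic drift model; and renders per-site allele-count tables with
# sequencing error, homopolymer slippage noise and numt read bleed-through.
# Every stage is driven by one root seed through named substreams, so
# genomes, line histories and read counts are independently reproducible.
#
# The background sequence is generated with no single-base run of 5 bp or
# more, so the homopolymer catalogue of a simulated genome is exactly the
# planted truth set; random dinucleotide arrays, by contrast, do arise by
# chance and truth assertions on them are one-sided.

derive_seed <- function(seed, label) {
  (as.integer(seed) %% 94906249L) * 19L +
    (sum(utf8ToInt(label)) %% 7919L)
}

#' Simulation configuration
#'
#' Builds the full configuration for [simulate_ma_experiment()]. Defaults
#' mirror the study conditions: a 50 kb, 45% GC "mitochondrial" genome with
#' a balanced homopolymer landscape and a numt copy, a 30 kb, 35% GC
#' "plastid" genome dominated by A/T homopolymers; 22 mutant lines (18 at 7
#' homozygous generations, 4 at 6) and 20 wild-type lines at 8 generations
#' in 3 founder families; SNV rates of 6.1e-7 and 3.2e-6 per bp per
#' generation with the observed strand-collapsed spectra; slippage-driven
#' indel rates increasing with run length; and a beta-perturbation
#' heteroplasmy drift model with faster sorting in the plastid.
#'
#' Any element can be overridden via the arguments, which are merged into
#' the defaults with [utils::modifyList()] semantics (partial lists fine).
#'
#' @param seed Integer root seed.
#' @param mito,plastid Per-genome settings (length, gc, planted repeat
#'   counts, repeat-pair/numt geometry, gene layout).
#' @param lines Line plan (`n_mut`, `n_wt`, `mut_generations`,
#'   `wt_generations`, `n_founders`).
#' @param rates Mutation input (`snv` per-genome rates, `spectrum` class
#'   probabilities, `indel_per_locus_unit` slippage rate per excess run
#'   base per generation, `indel_size_probs`, `at_deletion_prob`,
#'   `gc_deletion_prob`).
#' @param heteroplasmy `mode` (`"drift"` or `"fixation"`), initial
#'   frequency `f0`, per-genome `concentration` of the beta perturbation,
#'   absorption tolerance `absorb_tol`.
#' @param sequencing Depth and error model (`mean_depth`, `error_rate`,
#'   `hp_slip_q0`, `nuclear_cov`, `read_length`, `nuclear_genome_size`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 101L, mito = list(), plastid = list(),
                       lines = list(), rates = list(),
                       heteroplasmy = list(), sequencing = list()) {
  cfg <- list(
    seed = as.integer(seed),
    mito = list(
      name = "mito_sim", kind = "mito", length = 50000L, gc = 0.45,
      n_at_homopolymers = 60L, n_gc_homopolymers = 22L, hp_len_mean = 7,
      n_dinucleotides = 10L, dinuc_min_units = 3L,
      repeat_pair_len = 2000L, numt_len = 4000L, numt_copies = 1L,
      n_genes = 6L, cds_codons = 80L, intron_len = 100L),
    plastid = list(
      name = "plastid_sim", kind = "plastid", length = 30000L, gc = 0.35,
      n_at_homopolymers = 86L, n_gc_homopolymers = 7L, hp_len_mean = 8,
      n_dinucleotides = 10L, dinuc_min_units = 3L,
      repeat_pair_len = 3000L, numt_len = 0L, numt_copies = 0L,
      n_genes = 8L, cds_codons = 80L, intron_len = 100L),
    lines = list(
      n_mut = 22L, n_wt = 20L,
      mut_generations = c(rep(7L, 18L), rep(6L, 4L)),
      wt_generations = 8L, n_founders = 3L),
    rates = list(
      snv = c(mito = 6.1e-7, plastid = 3.2e-6),
      spectrum = list(
        mito = c("AT>GC" = 23, "GC>AT" = 21, "AT>CG" = 2,
                 "GC>TA" = 1, "AT>TA" = 1, "GC>CG" = 1) / 49,
        plastid = c("AT>GC" = 62, "GC>AT" = 6, "AT>CG" = 2,
                    "GC>TA" = 2, "AT>TA" = 2, "GC>CG" = 1) / 75),
      indel_per_locus_unit = 1.5e-3,
      indel_size_probs = c("1" = 0.90, "2" = 0.08, "3" = 0.02),
      at_deletion_prob = 0.65, gc_deletion_prob = 0.40),
    heteroplasmy = list(
      mode = "drift", f0 = 0.5,
      concentration = c(mito = 40, plastid = 8), absorb_tol = 1e-3),
    sequencing = list(
      mean_depth = 200, error_rate = 0.003, hp_slip_q0 = 0.01,
      nuclear_cov = 30, read_length = 150, nuclear_genome_size = 1.2e8))
  cfg$mito <- utils::modifyList(cfg$mito, mito)
  cfg$plastid <- utils::modifyList(cfg$plastid, plastid)
  cfg$lines <- utils::modifyList(cfg$lines, lines)
  cfg$rates <- utils::modifyList(cfg$rates, rates)
  cfg$heteroplasmy <- utils::modifyList(cfg$heteroplasmy, heteroplasmy)
  cfg$sequencing <- utils::modifyList(cfg$sequencing, sequencing)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (g in c("mito", "plastid")) {
    gc <- cfg[[g]]$gc
    if (gc < 0 || gc > 1) stop(g, ": gc must be in [0, 1]")
    if (cfg[[g]]$length < 1000L) stop(g, ": genome length must be >= 1 kb")
  }
  for (p in list(cfg$rates$spectrum$mito, cfg$rates$spectrum$plastid)) {
    if (abs(sum(p) - 1) > 1e-8) stop("spectrum probabilities must sum to 1")
  }
  if (any(cfg$rates$snv < 0)) stop("SNV rates must be >= 0")
  if (cfg$sequencing$mean_depth <= 0) stop("mean depth must be > 0")
  invisible(cfg)
}

# background sequence at a target GC with every run kept below `max_run`
random_background <- function(len, gc, max_run = 4L) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(DNA_BASES, len, replace = TRUE, prob = probs)
  break_long_runs(chars, max_run = max_run, protected = logical(len))
}

# mutate one unprotected base inside every run longer than max_run (and the
# circular junction run) until none remain
break_long_runs <- function(chars, max_run = 4L, protected = NULL,
                            circular = TRUE) {
  len <- length(chars)
  if (is.null(protected)) protected <- logical(len)
  for (iter in 1:50) {
    r <- rle(chars)
    n <- length(r$lengths)
    starts <- cumsum(c(1L, head(r$lengths, -1L)))
    bad <- which(r$lengths > max_run)
    junction <- circular && n > 1L && r$values[1L] == r$values[n] &&
      (r$lengths[1L] + r$lengths[n]) > max_run
    if (!length(bad) && !junction) break
    fix_positions <- integer(0)
    for (b in bad) {
      run_pos <- starts[b]:(starts[b] + r$lengths[b] - 1L)
      cand <- run_pos[!protected[run_pos]]
      if (!length(cand)) next
      fix_positions <- c(fix_positions, cand[ceiling(length(cand) / 2)])
    }
    if (junction) {
      run_pos <- c((len - r$lengths[n] + 1L):len, 1L:r$lengths[1L])
      cand <- run_pos[!protected[run_pos]]
      if (length(cand)) fix_positions <- c(fix_positions, cand[1L])
    }
    if (!length(fix_positions)) break
    for (p in fix_positions) {
      left <- chars[if (p == 1L) len else p - 1L]
      right <- chars[if (p == len) 1L else p + 1L]
      choices <- setdiff(DNA_BASES, c(chars[p], left, right))
      if (!length(choices)) choices <- setdiff(DNA_BASES, chars[p])
      chars[p] <- sample(choices, 1L)
    }
  }
  chars
}

# non-overlapping interval placement with a safety buffer
make_placer <- function(len, buffer = 2L, edge = 5L) {
  occupied <- matrix(numeric(0), ncol = 2L)
  place <- function(width) {
    for (try in 1:500) {
      s <- sample.int(len - width - 2L * edge, 1L) + edge
      e <- s + width - 1L
      if (nrow(occupied) == 0L ||
          all(e + buffer < occupied[, 1L] | s - buffer > occupied[, 2L])) {
        occupied <<- rbind(occupied, c(s, e))
        return(c(s, e))
      }
    }
    stop("could not place an interval of width ", width,
         "; genome too crowded")
  }
  place
}

generate_one_genome <- function(gcfg, seed) {
  set.seed(derive_seed(seed, paste0("genome_", gcfg$name)))
  len <- gcfg$length
  chars <- random_background(len, gcfg$gc)
  place <- make_placer(len)

  # large repeat pair: dst is overwritten with a verbatim copy of src and
  # masked as the excluded repeat copy
  repeat_pair <- NULL
  if (gcfg$repeat_pair_len > 0L) {
    src <- place(gcfg$repeat_pair_len)
    dst <- place(gcfg$repeat_pair_len)
    repeat_pair <- list(src_start = src[1L], dst_start = dst[1L],
                        length = gcfg$repeat_pair_len)
  }
  numt <- NULL
  if (gcfg$numt_len > 0L && gcfg$numt_copies > 0L) {
    iv <- place(gcfg$numt_len)
    numt <- data.frame(start = iv[1L], end = iv[2L],
                       copies = gcfg$numt_copies)
  }

  # toy genes: alternate single-exon CDS and two-exon CDS with an intron
  features <- NULL
  if (gcfg$n_genes > 0L) {
    feats <- list()
    for (i in seq_len(gcfg$n_genes)) {
      gname <- sprintf("%s_g%02d", gcfg$name, i)
      strand <- if (i %% 2L == 0L) "-" else "+"
      cds_len <- 3L * gcfg$cds_codons
      if (i %% 3L == 0L && gcfg$intron_len > 0L) {
        span <- cds_len + gcfg$intron_len
        iv <- place(span)
        ex1 <- cds_len %/% 2L
        ex1 <- ex1 - (ex1 %% 3L) + 3L  # keep a codon boundary tidy
        feats[[length(feats) + 1L]] <- data.frame(
          gene = gname, kind = c("CDS", "intron", "CDS"),
          start = c(iv[1L], iv[1L] + ex1, iv[1L] + ex1 + gcfg$intron_len),
          end = c(iv[1L] + ex1 - 1L, iv[1L] + ex1 + gcfg$intron_len - 1L,
                  iv[2L]),
          strand = strand, stringsAsFactors = FALSE)
      } else {
        iv <- place(cds_len)
        feats[[length(feats) + 1L]] <- data.frame(
          gene = gname, kind = "CDS", start = iv[1L], end = iv[2L],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    # a couple of structural RNAs for the location classes
    rr <- place(300L)
    tr <- place(80L)
    feats[[length(feats) + 1L]] <- data.frame(
      gene = c(sprintf("%s_rrn", gcfg$name), sprintf("%s_trn", gcfg$name)),
      kind = c("rRNA", "tRNA"), start = c(rr[1L], tr[1L]),
      end = c(rr[2L], tr[2L]), strand = "+", stringsAsFactors = FALSE)
    features <- do.call(rbind, feats)
  }

  # planted homopolymers
  n_hp <- gcfg$n_at_homopolymers + gcfg$n_gc_homopolymers
  hp_units <- c(sample(c("A", "T"), gcfg$n_at_homopolymers, replace = TRUE),
                sample(c("G", "C"), gcfg$n_gc_homopolymers, replace = TRUE))
  hp_rows <- list()
  for (i in seq_len(n_hp)) {
    hlen <- 5L + rgeom(1L, prob = 1 / (1 + max(gcfg$hp_len_mean - 5, 0.1)))
    iv <- place(hlen)
    s <- iv[1L]; e <- iv[2L]
    chars[s:e] <- hp_units[i]
    for (edge_pos in c(s - 1L, e + 1L)) {
      nb <- chars[c(max(edge_pos - 1L, 1L), min(edge_pos + 1L, len))]
      choices <- setdiff(DNA_BASES, c(hp_units[i], nb))
      if (!length(choices)) choices <- setdiff(DNA_BASES, hp_units[i])
      chars[edge_pos] <- sample(choices, 1L)
    }
    hp_rows[[i]] <- data.frame(start = s, length = hlen, unit = hp_units[i],
                               stringsAsFactors = FALSE)
  }
  hp_truth <- if (n_hp) do.call(rbind, hp_rows) else
    data.frame(start = integer(0), length = integer(0), unit = character(0))
  hp_truth$unit_count <- hp_truth$length
  hp_truth$base_class <- ifelse(hp_truth$unit %in% c("A", "T"), "AT", "GC")

  # planted dinucleotide arrays
  dn_rows <- list()
  for (i in seq_len(gcfg$n_dinucleotides)) {
    pair <- sample(DNA_BASES, 2L, replace = FALSE)
    units <- gcfg$dinuc_min_units + rgeom(1L, 0.5)
    width <- 2L * units
    iv <- place(width)
    s <- iv[1L]
    chars[s:(s + width - 1L)] <- rep(pair, units)
    # break period-2 extension on both sides
    lpos <- s - 1L
    choices <- setdiff(DNA_BASES, c(chars[s + 1L], chars[lpos - 1L]))
    chars[lpos] <- sample(choices, 1L)
    rpos <- s + width
    choices <- setdiff(DNA_BASES, c(chars[rpos - 2L], chars[rpos + 1L]))
    chars[rpos] <- sample(choices, 1L)
    dn_rows[[i]] <- data.frame(start = s, length = width,
                               unit = paste(pair, collapse = ""),
                               unit_count = units, stringsAsFactors = FALSE)
  }
  dn_truth <- if (length(dn_rows)) do.call(rbind, dn_rows) else
    data.frame(start = integer(0), length = integer(0), unit = character(0),
               unit_count = integer(0))

  repeat_mask <- NULL
  if (!is.null(repeat_pair)) {
    chars[repeat_pair$dst_start:(repeat_pair$dst_start + repeat_pair$length - 1L)] <-
      chars[repeat_pair$src_start:(repeat_pair$src_start + repeat_pair$length - 1L)]
    repeat_mask <- data.frame(
      start = repeat_pair$dst_start,
      end = repeat_pair$dst_start + repeat_pair$length - 1L)
  }

  # final pass: planted runs are protected, anything else >= 5 bp (junction
  # effects of the verbatim copy) is broken so the catalogue equals truth
  protected <- logical(len)
  for (i in seq_len(nrow(hp_truth))) {
    protected[hp_truth$start[i]:(hp_truth$start[i] + hp_truth$length[i] - 1L)] <- TRUE
  }
  if (!is.null(repeat_mask)) {
    protected[repeat_mask$start:repeat_mask$end] <- TRUE
    protected[repeat_pair$src_start:(repeat_pair$src_start + repeat_pair$length - 1L)] <- TRUE
  }
  chars <- break_long_runs(chars, max_run = 4L, protected = protected)

  genome <- genome_spec(
    name = gcfg$name, sequence = paste(chars, collapse = ""),
    kind = gcfg$kind, circular = TRUE, features = features,
    repeat_mask = repeat_mask, numt_track = numt, artefact_mask = NULL)
  list(genome = genome,
       truth = list(homopolymers = hp_truth, dinucleotides = dn_truth,
                    repeat_pair = repeat_pair, numt = numt))
}

#' Generate a synthetic genome pair
#'
#' Builds the "mitochondrial" and "plastid" [genome_spec()] objects of a
#' simulated MA experiment, with planted simple repeats at recorded
#' coordinates, a duplicated-and-masked large repeat pair per genome and an
#' optional numt interval. The same seed always yields the same genomes.
#'
#' @param config A [sim_config()].
#' @return A list with `genomes` (named list of `genome_spec`) and `truth`
#'   (planted repeat coordinates per genome).
#' @export
generate_genomes <- function(config) {
  mito <- generate_one_genome(config$mito, config$seed)
  plastid <- generate_one_genome(config$plastid, config$seed)
  list(genomes = list(mito = mito$genome, plastid = plastid$genome),
       truth = list(mito = mito$truth, plastid = plastid$truth))
}

#' Line metadata for a simulated experiment
#'
#' @param config A [sim_config()].
#' @return Data frame with `line`, `genotype`, `generations`, `founder`.
#' @export
line_plan <- function(config) {
  lc <- config$lines
  gens <- rep_len(lc$mut_generations, lc$n_mut)
  founder_of <- function(prefix, i) {
    sprintf("%s%d", prefix, ((i - 1L) %% lc$n_founders) + 1L)
  }
  mut <- data.frame(
    line = sprintf("M%d_%d", ((seq_len(lc$n_mut) - 1L) %% lc$n_founders) + 1L,
                   ((seq_len(lc$n_mut) - 1L) %/% lc$n_founders) + 1L),
    genotype = "msh1", generations = gens,
    founder = founder_of("M", seq_len(lc$n_mut)), stringsAsFactors = FALSE)
  wt <- if (lc$n_wt > 0L) data.frame(
    line = sprintf("W%d_%d", ((seq_len(lc$n_wt) - 1L) %% lc$n_founders) + 1L,
                   ((seq_len(lc$n_wt) - 1L) %/% lc$n_founders) + 1L),
    genotype = "WT", generations = lc$wt_generations,
    founder = founder_of("W", seq_len(lc$n_wt)), stringsAsFactors = FALSE)
  else NULL
  rbind(mut, wt)
}

drift_frequency <- function(f0, n_gens, concentration, absorb_tol) {
  f <- f0
  if (n_gens <= 0L) return(f)
  for (g in seq_len(n_gens)) {
    if (f <= absorb_tol) return(0)
    if (f >= 1 - absorb_tol) return(1)
    f <- rbeta(1L, concentration * f, concentration * (1 - f))
  }
  if (f <= absorb_tol) 0 else if (f >= 1 - absorb_tol) 1 else f
}

#' Simulate germline mutations along MA lines
#'
#' For each mutant line and generation, draws Poisson numbers of new SNVs
#' per spectrum class over the unmasked genome and slippage indels per
#' homopolymer locus (rate proportional to run length minus 4). New
#' variants start at the configured heteroplasmic frequency and evolve by
#' per-generation beta-perturbation drift with absorption at 0 and 1
#' (`mode = "fixation"` transmits every mutation homoplasmic instead).
#' Wild-type lines receive no mutations.
#'
#' @param genomes Output of [generate_genomes()].
#' @param config A [sim_config()].
#' @return A list with `meta` (line plan) and `variants` (truth data
#'   frame: line, genome, pos, ref, alt, type, class, origin_gen,
#'   frequency, locus_start, locus_length). Variants lost to drift
#'   (frequency 0) are dropped.
#' @export
simulate_lines <- function(genomes, config) {
  set.seed(derive_seed(config$seed, "lines"))
  meta <- line_plan(config)
  het <- config$heteroplasmy
  rows <- list()

  for (gname in names(genomes$genomes)) {
    g <- genomes$genomes[[gname]]
    chars <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
    unmasked <- !interval_mask_vector(g$repeat_mask, g$length)
    at_pos <- which(unmasked & chars %in% c("A", "T"))
    gc_pos <- which(unmasked & chars %in% c("G", "C"))
    mu <- config$rates$snv[[g$kind]]
    spectrum <- config$rates$spectrum[[g$kind]]
    g_eff <- g$effective_size_G
    hp <- genomes$truth[[gname]]$homopolymers
    hp_lambda <- config$rates$indel_per_locus_unit * pmax(hp$length - 4L, 0L)
    conc <- het$concentration[[g$kind]]

    for (li in which(meta$genotype == "msh1")) {
      line <- meta$line[li]
      n_gens <- meta$generations[li]
      hit_loci <- integer(0)
      for (gen in seq_len(n_gens)) {
        n_new <- rpois(1L, mu * g_eff)
        if (n_new > 0L) {
          cls <- sample(names(spectrum), n_new, replace = TRUE,
                        prob = spectrum)
          for (k in seq_len(n_new)) {
            pool <- if (startsWith(cls[k], "AT")) at_pos else gc_pos
            if (!length(pool)) next
            pos <- pool[sample.int(length(pool), 1L)]
            ref <- chars[pos]
            alt <- unname(CLASS_SUBST[[cls[k]]][ref])
            f <- if (het$mode == "fixation") 1 else
              drift_frequency(het$f0, n_gens - gen, conc, het$absorb_tol)
            rows[[length(rows) + 1L]] <- data.frame(
              line = line, genome = g$name, pos = pos, ref = ref,
              alt = alt, type = "SNV", class = cls[k], origin_gen = gen,
              frequency = f, locus_start = NA_integer_,
              locus_length = NA_integer_, stringsAsFactors = FALSE)
          }
        }
        if (nrow(hp) > 0L && any(hp_lambda > 0)) {
          events <- which(rpois(nrow(hp), hp_lambda) > 0L)
          events <- setdiff(events, hit_loci)
          for (h in events) {
            hit_loci <- c(hit_loci, h)
            size <- as.integer(sample(names(config$rates$indel_size_probs),
                                      1L,
                                      prob = config$rates$indel_size_probs))
            p_del <- if (hp$base_class[h] == "AT") {
              config$rates$at_deletion_prob
            } else config$rates$gc_deletion_prob
            type <- if (runif(1L) < p_del) "deletion" else "insertion"
            f <- if (het$mode == "fixation") 1 else
              drift_frequency(het$f0, n_gens - gen, conc, het$absorb_tol)
            rows[[length(rows) + 1L]] <- data.frame(
              line = line, genome = g$name, pos = hp$start[h],
              ref = chars[hp$start[h]],
              alt = paste(rep(hp$unit[h], size), collapse = ""),
              type = type, class = paste0("homopolymer-", hp$base_class[h]),
              origin_gen = gen, frequency = f,
              locus_start = hp$start[h], locus_length = hp$length[h],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line = character(0), genome = character(0), pos = integer(0),
               ref = character(0), alt = character(0), type = character(0),
               class = character(0), origin_gen = integer(0),
               frequency = numeric(0), locus_start = integer(0),
               locus_length = integer(0), stringsAsFactors = FALSE)
  variants <- variants[variants$frequency > 0, , drop = FALSE]
  # a site mutated twice in one line keeps only the latest event
  key <- paste(variants$line, variants$genome, variants$pos)
  variants <- variants[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  rownames(variants) <- NULL
  list(meta = meta, variants = variants)
}

#' Render per-site allele-count tables
#'
#' Simulates the sequencing layer: per-position depth is Poisson around the
#' configured mean; true variant reads are binomial in the heteroplasmic
#' frequency; every non-reference base receives uniform error reads;
#' homopolymer anchors receive slippage indel reads with probability
#' `q0 * (L - 4)` per read for a run of length `L >= 5`; and mitochondrial
#' positions inside the numt interval receive additional reference-matching
#' reads at `nuclear_cov * copies` (Poisson), emulating numt bleed-through.
#'
#' @param genomes Output of [generate_genomes()].
#' @param truth Output of [simulate_lines()] (uses `meta` and `variants`).
#' @param config A [sim_config()].
#' @param samples Optional subset of sample ids to render.
#' @return A list with `counts` (site-count data frame across all samples
#'   and genomes, in the [read_site_counts()] schema) and `sample_info`
#'   (per-sample read totals from which nuclear coverage can be
#'   re-estimated with [estimate_nuclear_coverage()]).
#' @export
render_counts <- function(genomes, truth, config, samples = NULL) {
  set.seed(derive_seed(config$seed, "reads"))
  sq <- config$sequencing
  meta <- truth$meta
  if (is.null(samples)) samples <- meta$line
  variants <- truth$variants

  out <- vector("list", length(samples) * length(genomes$genomes))
  oi <- 0L
  for (s in samples) {
    for (gname in names(genomes$genomes)) {
      g <- genomes$genomes[[gname]]
      len <- g$length
      chars <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
      depth <- rpois(len, sq$mean_depth)
      cnt <- matrix(0L, nrow = len, ncol = 4L,
                    dimnames = list(NULL, DNA_BASES))
      er3 <- sq$error_rate / 3
      for (b in DNA_BASES) {
        e <- rbinom(len, depth, er3)
        e[chars == b] <- 0L
        cnt[, b] <- e
      }
      ins <- integer(len); del <- integer(len)
      ins_seq <- character(len); del_seq <- character(len)
      hp <- genomes$truth[[gname]]$homopolymers
      if (nrow(hp) > 0L && sq$hp_slip_q0 > 0) {
        q <- pmin(sq$hp_slip_q0 * pmax(hp$length - 4L, 0L), 0.4)
        a <- hp$start
        ins[a] <- ins[a] + rbinom(nrow(hp), depth[a], q / 2)
        del[a] <- del[a] + rbinom(nrow(hp), depth[a], q / 2)
        ins_seq[a] <- hp$unit
        del_seq[a] <- hp$unit
      }
      tv <- variants[variants$line == s & variants$genome == g$name, ,
                     drop = FALSE]
      for (k in seq_len(nrow(tv))) {
        p <- tv$pos[k]
        reads <- rbinom(1L, depth[p], tv$frequency[k])
        if (tv$type[k] == "SNV") {
          cnt[p, tv$alt[k]] <- cnt[p, tv$alt[k]] + reads
        } else if (tv$type[k] == "insertion") {
          ins[p] <- ins[p] + reads
          ins_seq[p] <- tv$alt[k]
        } else {
          del[p] <- del[p] + reads
          del_seq[p] <- tv$alt[k]
        }
      }
      if (g$kind == "mito" && !is.null(g$numt_track) &&
          sq$nuclear_cov > 0) {
        nt <- g$numt_track
        for (i in seq_len(nrow(nt))) {
          idx <- nt$start[i]:nt$end[i]
          extra <- rpois(length(idx), sq$nuclear_cov * nt$copies[i])
          depth[idx] <- depth[idx] + extra
        }
      }
      alt_total <- rowSums(cnt) + del
      ref_count <- pmax(depth - alt_total, 0L)
      ridx <- match(chars, DNA_BASES)
      cnt[cbind(seq_len(len), ridx)] <- ref_count
      # clamp: no allele count may exceed depth
      cnt <- pmin(cnt, depth)
      storage.mode(cnt) <- "integer"
      ins <- pmin(ins, depth)
      del <- pmin(del, depth)
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        sample = s, chrom = g$name, pos = seq_len(len), ref = chars,
        depth = depth, A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
        T = cnt[, "T"], ins = ins, del = del, ins_seq = ins_seq,
        del_seq = del_seq, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, out[seq_len(oi)])
  rownames(counts) <- NULL

  org_len <- sum(vapply(genomes$genomes, `[[`, integer(1), "length"))
  org_reads <- round(sq$mean_depth * org_len / sq$read_length)
  nuc_reads <- round(sq$nuclear_cov * sq$nuclear_genome_size /
                     sq$read_length)
  sample_info <- data.frame(
    sample = samples,
    genotype = meta$genotype[match(samples, meta$line)],
    total_reads = org_reads + nuc_reads,
    organelle_mapped_reads = org_reads,
    read_length = sq$read_length,
    nuclear_genome_size = sq$nuclear_genome_size,
    stringsAsFactors = FALSE)
  list(counts = counts, sample_info = sample_info)
}

#' Simulate a complete MA experiment
#'
#' Runs [generate_genomes()], [simulate_lines()] and [render_counts()] from
#' one configuration and returns every layer, including the truth set, so
#' the analysis chain can be validated end to end.
#'
#' @param config A [sim_config()].
#' @param render Set `FALSE` to skip the (comparatively expensive)
#'   count-rendering stage.
#' @return A list with `config`, `genomes`, `truth` (planted repeats and
#'   variants), `meta`, and (when rendered) `counts` and `sample_info`.
#' @export
simulate_ma_experiment <- function(config = sim_config(), render = TRUE) {
  gen <- generate_genomes(config)
  sim <- simulate_lines(gen, config)
  out <- list(config = config, genomes = gen$genomes,
              truth = list(repeats = gen$truth, variants = sim$variants),
              meta = sim$meta)
  if (render) {
    rc <- render_counts(gen, sim, config)
    out$counts <- rc$counts
    out$sample_info <- rc$sample_info
  }
  out
}

#' Write a simulated experiment to disk
#'
#' Writes the genome files (FASTA/GFF3/BED), line metadata, per-sample
#' site-count TSVs and the truth variant table, so a simulated experiment
#' can be re-analysed through the file-based interface.
#'
#' @param sim Output of [simulate_ma_experiment()] (rendered).
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) write_genome_files(g, file.path(dir, "genomes"))
  write.table(sim$meta, file.path(dir, "lines.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$variants, file.path(dir, "truth_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$counts)) {
    for (s in unique(sim$counts$sample)) {
      write_site_counts(sim$counts[sim$counts$sample == s, , drop = FALSE],
                        file.path(dir, sprintf("counts_%s.tsv", s)))
    }
    write.table(sim$sample_info, file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
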