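test_that("genome generation is deterministic and respects the GC target", {
  cfg <- scaled_sim_config(seed = 9)
  g1 <- generate_genomes(cfg)
  g2 <- generate_genomes(cfg)
  expect_identical(g1$genomes$mito$sequence, g2$genomes$mito$sequence)
  expect_identical(g1$genomes$plastid$sequence, g2$genomes$plastid$sequence)
  expect_identical(g1$truth$mito$homopolymers, g2$truth$mito$homopolymers)

  # GC fidelity at the full study-condition genome sizes
  full <- generate_genomes(sim_config(seed = 9))
  comp <- base_composition(full$genomes$mito, exclude_masked = FALSE)
  expect_lt(abs(comp$gc_fraction - 0.45), 0.02)
  comp_p <- base_composition(full$genomes$plastid, exclude_masked = FALSE)
  expect_lt(abs(comp_p$gc_fraction - 0.35), 0.02)
})

test_that("the homopolymer catalogue of a generated genome equals the planted truth", {
  for (seed in c(3, 14, 27)) {
    gen <- generate_genomes(scaled_sim_config(seed = seed))
    for (gname in c("mito", "plastid")) {
      truth <- gen$truth[[gname]]$homopolymers
      found <- find_homopolymers(gen$genomes[[gname]])
      expect_identical(nrow(found), nrow(truth), info = paste(seed, gname))
      key <- function(df) sort(paste(df$start, df$unit, df$length))
      expect_identical(key(found), key(truth), info = paste(seed, gname))
    }
  }
})

test_that("planted dinucleotide arrays are present in the catalogue", {
  gen <- generate_genomes(scaled_sim_config(seed = 5))
  truth <- gen$truth$mito$dinucleotides
  found <- find_dinucleotide_repeats(gen$genomes$mito, min_units = 3)
  expect_true(all(paste(truth$start, truth$unit_count) %in%
                  paste(found$start, found$unit_count)))
})

test_that("the duplicated repeat copy is verbatim and masked", {
  gen <- generate_genomes(scaled_sim_config(seed = 8))
  g <- gen$genomes$mito
  rp <- gen$truth$mito$repeat_pair
  src <- substr(g$sequence, rp$src_start, rp$src_start + rp$length - 1L)
  dst <- substr(g$sequence, rp$dst_start, rp$dst_start + rp$length - 1L)
  expect_identical(src, dst)
  expect_identical(g$repeat_mask$start, rp$dst_start)
  expect_identical(g$effective_size_G, g$length - rp$length)
})

test_that("zero mutation rate yields an empty truth set; fixation fixes frequencies", {
  cfg <- scaled_sim_config(seed = 4, rates = list(
    snv = c(mito = 0, plastid = 0), indel_per_locus_unit = 0))
  gen <- generate_genomes(cfg)
  sim <- simulate_lines(gen, cfg)
  expect_identical(nrow(sim$variants), 0L)

  cfg2 <- scaled_sim_config(seed = 4, rates = list(
    snv = c(mito = 2e-4, plastid = 2e-4)))
  sim2 <- simulate_lines(generate_genomes(cfg2), cfg2)
  expect_gt(nrow(sim2$variants), 0L)
  expect_true(all(sim2$variants$frequency == 1))
  expect_true(all(sim2$variants$line %in%
                  sim2$meta$line[sim2$meta$genotype == "msh1"]))
})

test_that("SNV input matches the Poisson expectation over replicates", {
  cfg <- scaled_sim_config(seed = 1, rates = list(
    snv = c(mito = 1e-4, plastid = 0), indel_per_locus_unit = 0))
  gen <- generate_genomes(cfg)
  lam <- 1e-4 * gen$genomes$mito$effective_size_G *
    sum(cfg$lines$mut_generations[seq_len(cfg$lines$n_mut)])
  counts <- integer(120)
  for (r in seq_along(counts)) {
    cfg_r <- scaled_sim_config(seed = 1000 + r, rates = list(
      snv = c(mito = 1e-4, plastid = 0), indel_per_locus_unit = 0))
    counts[r] <- nrow(simulate_lines(gen, cfg_r)$variants)
  }
  se <- sqrt(lam / length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
})

test_that("heteroplasmic drift is absorbing at 0 and 1", {
  set.seed(77)
  f <- vapply(1:300, function(i) {
    organelleMA:::drift_frequency(0.5, 60L, concentration = 8,
                                  absorb_tol = 1e-3)
  }, numeric(1))
  expect_true(all(f %in% c(0, 1)))
  expect_gt(mean(f), 0.3)  # roughly balanced absorption from f0 = 0.5
  expect_lt(mean(f), 0.7)
})

test_that("rendered counts are deterministic and reflect truth and numt bleed", {
  cfg <- scaled_sim_config(seed = 6, rates = list(
    snv = c(mito = 5e-5, plastid = 0)),
    sequencing = list(mean_depth = 80, nuclear_cov = 80, error_rate = 0,
                      hp_slip_q0 = 0))
  gen <- generate_genomes(cfg)
  # plant two homoplasmic mito variants: one inside the numt, one outside
  numt <- gen$truth$mito$numt
  chars <- strsplit(gen$genomes$mito$sequence, "", fixed = TRUE)[[1]]
  pos_in <- numt$start + 50L
  pos_out <- if (numt$end + 200L <= cfg$mito$length) numt$end + 200L else 50L
  mk <- function(pos) data.frame(
    line = "M1_1", genome = "mito_sim", pos = pos, ref = chars[pos],
    alt = setdiff(c("A", "C", "G", "T"), chars[pos])[1], type = "SNV",
    class = "AT>GC", origin_gen = 1L, frequency = 1,
    locus_start = NA_integer_, locus_length = NA_integer_,
    stringsAsFactors = FALSE)
  truth <- list(meta = line_plan(cfg), variants = rbind(mk(pos_in), mk(pos_out)))
  rc1 <- render_counts(gen, truth, cfg, samples = "M1_1")
  rc2 <- render_counts(gen, truth, cfg, samples = "M1_1")
  expect_identical(rc1$counts, rc2$counts)

  m <- rc1$counts[rc1$counts$chrom == "mito_sim", ]
  row_out <- m[m$pos == pos_out, ]
  alt_out <- row_out[[truth$variants$alt[2]]]
  # no error, no numt at this site: every read supports the alt allele
  expect_identical(alt_out, row_out$depth)
  row_in <- m[m$pos == pos_in, ]
  alt_in <- row_in[[truth$variants$alt[1]]]
  # inside the numt with nuclear_cov == organelle depth the raw frequency
  # of a homoplasmic variant sits near 1/2
  expect_lt(abs(alt_in / row_in$depth - 0.5), 0.15)

  # nuclear coverage is recoverable from the sample read totals
  si <- rc1$sample_info
  est <- estimate_nuclear_coverage(si$total_reads,
                                   si$organelle_mapped_reads,
                                   si$read_length, si$nuclear_genome_size)
  expect_lt(abs(est - 80) / 80, 0.01)
})

test_that("a simulated experiment round-trips through the file interface", {
  cfg <- scaled_sim_config(seed = 13, rates = list(
    snv = c(mito = 1e-4, plastid = 1e-4)))
  sim <- simulate_ma_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "genomes", "mito_sim.fasta")))
  g <- load_genome(file.path(dir, "genomes", "mito_sim.fasta"),
                   file.path(dir, "genomes", "mito_sim.gff3"),
                   file.path(dir, "genomes", "mito_sim.repeat_mask.bed"),
                   file.path(dir, "genomes", "mito_sim.numt.bed"),
                   kind = "mito")
  expect_identical(g$sequence, sim$genomes$mito$sequence)
  expect_identical(g$effective_size_G, sim$genomes$mito$effective_size_G)
  s1 <- sim$meta$line[1]
  counts <- read_site_counts(file.path(dir, sprintf("counts_%s.tsv", s1)))
  sub <- sim$counts[sim$counts$sample == s1, ]
  expect_identical(nrow(counts), nrow(sub))
  expect_identical(counts$depth, sub$depth)
})
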