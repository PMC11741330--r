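test_that("site-count reader validates rows and reports rejects", {
  tab <- rbind(
    count_row("s1", "m", 1, "A", 100, G = 10),
    count_row("s1", "m", 2, "C", 0),                 # depth 0: retained
    count_row("s1", "m", 3, "G", 50, T = 60),        # count > depth: reject
    count_row("s1", "m", 4, "X", 50))                # unknown ref: reject
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_counts(tab, path)
  expect_warning(got <- read_site_counts(path), "rejected 2")
  expect_identical(nrow(got), 2L)
  expect_identical(attr(got, "rejected")$pos, c(3L, 4L))
  expect_true(2L %in% got$pos)
})

test_that("candidate thresholds are boundary-inclusive", {
  tab <- rbind(
    count_row("s1", "m", 10, "A", 100, G = 20),  # exactly 20%: passes
    count_row("s1", "m", 11, "A", 49, G = 25),   # depth 49: low_depth
    count_row("s1", "m", 12, "A", 100, G = 19))  # 19%: low_freq
  calls <- call_candidates(tab)
  expect_identical(calls$filters[calls$pos == 10], "")
  expect_equal(calls$raw_frequency[calls$pos == 10], 0.20)
  expect_match(calls$filters[calls$pos == 11], "low_depth")
  expect_false(grepl("low_freq", calls$filters[calls$pos == 11]))
  expect_match(calls$filters[calls$pos == 12], "low_freq")
})

test_that("candidates cover SNVs and indel alleles with correct frequencies", {
  tab <- count_row("s1", "m", 5, "A", 200, C = 60, ins = 50, del = 40,
                   ins_seq = "T", del_seq = "A")
  calls <- call_candidates(tab)
  expect_setequal(calls$var_type, c("SNV", "insertion", "deletion"))
  expect_equal(calls$raw_frequency[calls$var_type == "SNV"], 0.30)
  expect_equal(calls$raw_frequency[calls$var_type == "insertion"], 0.25)
  expect_identical(calls$alt[calls$var_type == "deletion"], "A")
})

test_that("background filter applies the fold rule against the WT mean", {
  expect_true(background_flag(0.30, c(0.12, 0.12)))        # 0.30 < 0.36
  expect_false(background_flag(0.30, c(0, 0)))             # zero background
  expect_false(background_flag(0.60, c(0.20, 0.20)))       # exactly 3-fold
  expect_error(background_flag(0.5, numeric(0)), "WT")

  # table version: WT mean computed per position/allele over all WT lines,
  # with absent alleles contributing zero
  counts <- rbind(
    count_row("mut", "m", 7, "A", 100, G = 30),
    count_row("wt1", "m", 7, "A", 100, G = 24),
    count_row("wt2", "m", 7, "A", 100, G = 0),
    count_row("mut", "m", 8, "A", 100, G = 30),
    count_row("wt1", "m", 8, "A", 100),
    count_row("wt2", "m", 8, "A", 100))
  calls <- call_candidates(counts[counts$sample == "mut", ])
  calls <- background_filter(calls, counts, c("wt1", "wt2"))
  # pos 7: WT mean = 0.12, 0.30 < 0.36 -> background
  expect_match(calls$filters[calls$pos == 7], "background")
  # pos 8: WT mean = 0 -> passes
  expect_false(grepl("background", calls$filters[calls$pos == 8]))
  expect_error(background_filter(calls, counts, character(0)), "WT")
})

test_that("mask flags respect interval boundaries", {
  set.seed(20)
  g <- genome_spec("m", random_dna(1000),
                   repeat_mask = data.frame(start = 101, end = 200),
                   artefact_mask = data.frame(start = 501, end = 510))
  calls <- call_candidates(rbind(
    count_row("s1", "m", 100, "A", 100, G = 50),
    count_row("s1", "m", 101, "A", 100, G = 50),
    count_row("s1", "m", 200, "A", 100, G = 50),
    count_row("s1", "m", 201, "A", 100, G = 50),
    count_row("s1", "m", 505, "A", 100, G = 50)))
  calls <- apply_masks(calls, g)
  flags <- setNames(calls$filters, calls$pos)
  expect_identical(unname(flags[c("100", "201")]), c("", ""))
  expect_match(flags[["101"]], "repeat_copy")
  expect_match(flags[["200"]], "repeat_copy")
  expect_match(flags[["505"]], "artefact")
  expect_identical(nrow(passing_calls(calls)), 2L)
})

test_that("flank homology check flags relocatable variant k-mers", {
  set.seed(21)
  base <- random_dna(3000)
  # plant at a second locus the exact 61-mer that a C>T variant at position
  # 1500 would create
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  chars[1500] <- "C"
  var_kmer <- c(chars[1470:1499], "T", chars[1501:1530])
  chars[2200:2260] <- var_kmer
  g <- genome_spec("m", paste(chars, collapse = ""), circular = FALSE)
  expect_true(flank_homology_check(g, "m", 1500, "C", "T"))
  # a different alt at the same site is not explainable by relocation
  expect_false(flank_homology_check(g, "m", 1500, "C", "G"))
  expect_error(flank_homology_check(g, "m", 1500, "C", "C"), "not a variant")

  # random alt in non-repetitive sequence is never flagged
  g2 <- genome_spec("m", random_dna(3000), circular = FALSE)
  chars2 <- strsplit(g2$sequence, "", fixed = TRUE)[[1]]
  for (pos in c(500, 1500, 2500)) {
    alt <- setdiff(c("A", "C", "G", "T"), chars2[pos])[1]
    expect_false(flank_homology_check(g2, "m", pos, chars2[pos], alt))
  }
  # near a linear end the flank is truncated with a warning
  expect_warning(flank_homology_check(g2, "m", 5, chars2[5],
                                      setdiff(c("A", "C", "G", "T"),
                                              chars2[5])[1]),
                 "truncated")
})

test_that("nuclear coverage estimate follows the unmapped-read arithmetic", {
  est <- estimate_nuclear_coverage(1e8, 2e7, 150, 1.2e8)
  expect_equal(est, 100)
  expect_equal(estimate_nuclear_coverage(5e7, 5e7, 150, 1.2e8), 0)
  expect_equal(estimate_nuclear_coverage(0, 0, 150, 1.2e8), 0)
  expect_error(estimate_nuclear_coverage(10, 20, 150, 1.2e8), "exceed")
  expect_error(estimate_nuclear_coverage(10, 5, 150, 0), "> 0")
})

test_that("numt correction recomputes frequency after subtracting nuclear reads", {
  # depth 100, alt 40, nuclear 20x * 1 copy: 40 / (100 - 20) = 0.5
  expect_equal(numt_correct_frequency(40, 100, 20, 1), 0.5)
  expect_equal(numt_correct_frequency(40, 100, 20, 0), 0.4)    # identity
  expect_equal(numt_correct_frequency(40, 100, 80, 1), 1.0)    # clamp
  expect_equal(numt_correct_frequency(0, 100, 20, 1), 0)

  # monotone in copies and coverage, equal to raw at zero copies
  f <- vapply(0:5, function(k) numt_correct_frequency(30, 100, 15, k),
              numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_equal(f[1], 0.30)
  g <- vapply(seq(0, 60, by = 10),
              function(cv) numt_correct_frequency(30, 100, cv, 1),
              numeric(1))
  expect_true(all(diff(g) >= 0))
})

test_that("homoplasmy classification uses organelle-specific thresholds", {
  calls <- data.frame(
    line = "l", genome = "g", pos = 1:4, ref = "A", alt = "G",
    var_type = c("SNV", "SNV", "SNV", "insertion"),
    depth = 100L, alt_count = 90L,
    raw_frequency = c(0.98, 0.97, 0.90, 0.99),
    corrected_frequency = c(0.98, 0.97, 0.90, 0.99),
    homoplasmy = "unclassified", filters = "", stringsAsFactors = FALSE)
  pl <- classify_homoplasmy(calls, "plastid")
  expect_identical(pl$homoplasmy[1:2], c("homoplasmic", "heteroplasmic"))
  mt <- classify_homoplasmy(calls, "mito")
  expect_identical(mt$homoplasmy[3], "heteroplasmic")  # strict > 0.90
  mt2 <- calls; mt2$corrected_frequency[3] <- 0.901
  expect_identical(classify_homoplasmy(mt2, "mito")$homoplasmy[3],
                   "homoplasmic")
  expect_identical(pl$homoplasmy[4], "unclassified")   # indel
})

test_that("adjacent same-frequency SNVs merge into one MNV", {
  mk <- function(line, pos, freq) data.frame(
    line = line, genome = "g", pos = pos, ref = "A", alt = "G",
    var_type = "SNV", depth = 100L, alt_count = as.integer(100 * freq),
    raw_frequency = freq, corrected_frequency = freq,
    homoplasmy = "unclassified", filters = "", stringsAsFactors = FALSE)
  merged <- merge_mnv(rbind(mk("l1", 100, 0.95), mk("l1", 101, 0.93)))
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$var_type, "MNV")
  expect_identical(merged$ref, "AA")
  expect_equal(merged$raw_frequency, 0.94)

  # non-adjacent positions stay separate
  expect_identical(nrow(merge_mnv(rbind(mk("l1", 100, 0.95),
                                        mk("l1", 102, 0.95)))), 2L)
  # different lines stay separate
  expect_identical(nrow(merge_mnv(rbind(mk("l1", 100, 0.95),
                                        mk("l2", 101, 0.95)))), 2L)
  # frequency gap above the tolerance stays separate
  expect_identical(nrow(merge_mnv(rbind(mk("l1", 100, 0.95),
                                        mk("l1", 101, 0.80)))), 2L)
})

test_that("filter flags accumulate order-independently", {
  set.seed(22)
  g <- genome_spec("m", random_dna(2000),
                   repeat_mask = data.frame(start = 501, end = 600))
  counts <- rbind(
    count_row("mut", "m", 550, "A", 100, G = 90),
    count_row("mut", "m", 700, "A", 100, G = 15),
    count_row("mut", "m", 900, "A", 100, G = 80),
    count_row("wt1", "m", 900, "A", 100, G = 40),
    count_row("wt1", "m", 550, "A", 100),
    count_row("wt1", "m", 700, "A", 100))
  base <- call_candidates(counts[counts$sample == "mut", ])
  a <- background_filter(apply_masks(base, g), counts, "wt1")
  b <- apply_masks(background_filter(base, counts, "wt1"), g)
  key <- function(df) {
    df <- df[order(df$pos), ]
    paste(df$pos, vapply(strsplit(df$filters, ";"),
                         function(f) paste(sort(f), collapse = ";"),
                         character(1)))
  }
  expect_identical(key(a), key(b))
  expect_identical(passing_calls(a)$pos, passing_calls(b)$pos)
})
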