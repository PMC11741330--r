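mk_indel <- function(line, pos, alt, type, genome = "m") data.frame(
  line = line, genome = genome, pos = pos, ref = "A", alt = alt,
  var_type = type, depth = 100L, alt_count = 60L, raw_frequency = 0.6,
  corrected_frequency = 0.6, homoplasmy = "unclassified", filters = "",
  stringsAsFactors = FALSE)

hp_cat <- data.frame(start = c(100L, 300L), length = c(7L, 6L),
                     unit = c("A", "G"), unit_count = c(7L, 6L),
                     base_class = c("AT", "GC"), stringsAsFactors = FALSE)
dn_cat <- data.frame(start = 500L, length = 8L, unit = "AT",
                     unit_count = 4L, base_class = NA_character_,
                     stringsAsFactors = FALSE)

test_that("indels are assigned to matching repeat loci", {
  calls <- rbind(
    mk_indel("l1", 103L, "A", "insertion"),    # +1 A inside the A7 run
    mk_indel("l1", 502L, "AT", "deletion"),    # -2 AT inside (AT)4
    mk_indel("l1", 504L, "TA", "deletion"),    # rotation of the unit
    mk_indel("l1", 800L, "G", "deletion"),     # non-repetitive context
    mk_indel("l1", 102L, "G", "insertion"))    # wrong base at the A-run
  a <- assign_indels(calls, hp_cat, dn_cat)
  expect_identical(a$context[1], "homopolymer-AT")
  expect_identical(a$length_change[1], 1L)
  expect_identical(a$locus_start[1], 100L)
  expect_identical(a$context[2], "dinucleotide")
  expect_identical(a$length_change[2], -2L)
  expect_identical(a$context[3], "dinucleotide")
  expect_identical(a$context[4], "non-repetitive")
  expect_identical(a$context[5], "non-repetitive")
})

test_that("assignment is invariant to the anchor position within the run", {
  # the same event reported at any position of the locus (e.g. a
  # right-shifted representation) maps to the same locus
  for (p in 100:106) {
    a <- assign_indels(mk_indel("l1", p, "A", "deletion"), hp_cat, dn_cat)
    expect_identical(a$locus_start, 100L)
    expect_identical(a$context, "homopolymer-AT")
  }
})

test_that("multi-unit steps and long runs of the unit count as expansions", {
  a <- assign_indels(mk_indel("l1", 100L, "AAAAAA", "insertion"),
                     hp_cat, dn_cat)
  expect_identical(a$context, "homopolymer-AT")
  expect_identical(a$length_change, 6L)
  # over the small-indel ceiling: dropped
  expect_message(
    b <- assign_indels(mk_indel("l1", 100L, strrep("A", 11), "insertion"),
                       hp_cat, dn_cat),
    "dropped")
  expect_identical(nrow(b), 0L)
})

test_that("bias table counts insertions/deletions per context and conserves totals", {
  calls <- rbind(
    mk_indel("l1", 100L, "A", "insertion"),
    mk_indel("l2", 101L, "A", "deletion"),
    mk_indel("l3", 102L, "AA", "deletion"),
    mk_indel("l1", 300L, "G", "insertion"),
    mk_indel("l2", 800L, "C", "deletion"))
  a <- assign_indels(calls, hp_cat, dn_cat)
  tab <- bias_table(a)
  expect_identical(sum(tab$insertions) + sum(tab$deletions), nrow(a))
  at <- tab[tab$context == "homopolymer-AT", ]
  expect_identical(at$insertions, 1L)
  expect_identical(at$deletions, 2L)
  expect_identical(at$len_1, 2L)
  expect_identical(at$len_2, 1L)
  s <- indel_summary(a)
  expect_identical(s$n_total, 5L)
  expect_identical(s$n_homopolymer, 4L)
  expect_equal(s$homopolymer_fraction, 0.8)
  expect_identical(nrow(bias_table(a[0, ])), 0L)
})

test_that("recurrence report finds loci mutated in multiple lines", {
  meta <- data.frame(line = c("l1", "l2", "l3"),
                     founder = c("F1", "F1", "F2"),
                     stringsAsFactors = FALSE)
  calls <- rbind(
    mk_indel("l1", 100L, "A", "insertion"),
    mk_indel("l2", 103L, "A", "deletion"),   # same locus, other line
    mk_indel("l3", 300L, "G", "insertion"))  # unique locus
  a <- assign_indels(calls, hp_cat, dn_cat)
  rep1 <- recurrence_report(a, meta)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$locus_start, 100L)
  expect_identical(rep1$n_lines, 2L)
  expect_true(rep1$lengths_differ)          # +1 vs -1
  expect_true(rep1$shared_founder)          # l1, l2 both F1

  # all-unique loci: empty report
  uniq <- assign_indels(rbind(mk_indel("l1", 100L, "A", "insertion"),
                              mk_indel("l2", 300L, "G", "insertion")),
                        hp_cat, dn_cat)
  expect_identical(nrow(recurrence_report(uniq, meta)), 0L)
})

test_that("planted recurrent loci are recovered exactly from simulated truth", {
  set.seed(55)
  # five loci hit in >= 2 lines, three hit once
  cat5 <- data.frame(start = seq(100L, 800L, by = 100L), length = 7L,
                     unit = "A", unit_count = 7L, base_class = "AT",
                     stringsAsFactors = FALSE)
  calls <- NULL
  for (i in 1:5) {
    calls <- rbind(calls,
                   mk_indel("l1", cat5$start[i], "A", "insertion"),
                   mk_indel("l2", cat5$start[i] + 2L, "A", "deletion"))
  }
  for (i in 6:8) calls <- rbind(calls, mk_indel("l1", cat5$start[i], "A",
                                                "deletion"))
  a <- assign_indels(calls, cat5, NULL)
  expect_identical(nrow(recurrence_report(a)), 5L)
})
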