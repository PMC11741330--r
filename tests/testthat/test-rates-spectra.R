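test_that("mutation rate follows V/(G*N) and scales linearly", {
  expect_equal(mutation_rate(0, 1e5, 100)$mu, 0)
  expect_error(mutation_rate(10, 1e5, 0), "N")
  r <- mutation_rate(37, 123456, 77)
  expect_equal(r$mu, 37 / (123456 * 77))
  # linear in V, inverse in G and N
  expect_equal(mutation_rate(2 * 37, 123456, 77)$mu, 2 * r$mu)
  expect_equal(mutation_rate(37, 2 * 123456, 77)$mu, r$mu / 2)
  expect_equal(mutation_rate(37, 123456, 2 * 77)$mu, r$mu / 2)
})

test_that("rate estimation from calls weights SNVs and counts indels", {
  lines <- data.frame(line = c("l1", "l2"), generations = c(7L, 6L))
  calls <- data.frame(
    line = c("l1", "l1", "l2", "l2", "l1"),
    genome = "m", pos = c(10L, 20L, 30L, 40L, 50L),
    ref = "A", alt = c("G", "G", "G", "A", "AA"),
    var_type = c("SNV", "SNV", "SNV", "insertion", "deletion"),
    depth = 100L, alt_count = 50L,
    raw_frequency = c(1, 0.5, 0.25, 1, 1),
    corrected_frequency = c(1, 0.5, 0.25, 1, 1),
    homoplasmy = "unclassified",
    filters = c("", "", "", "", "background"), stringsAsFactors = FALSE)
  snv <- estimate_mutation_rate(calls, lines, G = 1000,
                                variant_class = "SNV")
  expect_equal(snv$V, 1.75)          # frequency-weighted, flagged excluded
  expect_equal(snv$N, 13)
  expect_equal(snv$mu, 1.75 / (1000 * 13))
  unw <- estimate_mutation_rate(calls, lines, G = 1000, "SNV",
                                weight_by_frequency = FALSE)
  expect_equal(unw$V, 3)             # weighted V <= unweighted count
  expect_true(snv$V <= unw$V)
  ind <- estimate_mutation_rate(calls, lines, G = 1000, "indel")
  expect_equal(ind$V, 1)             # the flagged deletion is excluded
})

test_that("published rate arithmetic reproduces from printed inputs", {
  expect_equal(signif(mutation_rate(258, 357025, 150)$mu, 2), 4.8e-6)
  expect_equal(signif(mutation_rate(410, 128214, 150)$mu, 2), 2.1e-5)
})

test_that("Poisson upper bound and single-variant rate are consistent", {
  expect_equal(poisson_upper_bound(1, 1, alpha = exp(-1)), 1)
  expect_error(poisson_upper_bound(1e5, 100, alpha = 1), "alpha")
  expect_error(poisson_upper_bound(1e5, 100, alpha = 0), "alpha")
  expect_equal(single_variant_rate(1, 1), 1)
  # closed form: bound / single-variant rate = ln(20) at alpha = 0.05
  for (G in c(357025, 128214, 5e4)) {
    for (N in c(150, 2835)) {
      expect_equal(poisson_upper_bound(G, N) / single_variant_rate(G, N),
                   log(20))
    }
  }
})

test_that("fold ratio is a plain quotient with a guarded denominator", {
  expect_equal(fold_ratio(6, 3), 2)
  expect_equal(fold_ratio(5e-7, 5e-7), 1)
  expect_error(fold_ratio(1, 0), "denominator")
})

test_that("substitution classes collapse reverse complements", {
  expect_identical(classify_snv_class("A", "G"), "AT>GC")
  expect_identical(classify_snv_class("T", "C"), "AT>GC")
  expect_identical(classify_snv_class("G", "T"), "GC>TA")
  expect_identical(classify_snv_class("C", "A"), "GC>TA")
  expect_identical(classify_snv_class("A", "T"), "AT>TA")
  expect_identical(classify_snv_class("G", "C"), "GC>CG")
  expect_true(is_transition("AT>GC"))
  expect_true(is_transition("GC>AT"))
  expect_false(any(is_transition(c("AT>CG", "GC>TA", "AT>TA", "GC>CG"))))
  expect_error(classify_snv_class("A", "A"), "differ")
  expect_error(classify_snv_class("A", "N"), "nucleotide")
  # every substitution maps to the same class as its reverse complement
  for (r in c("A", "C", "G", "T")) {
    for (a in setdiff(c("A", "C", "G", "T"), r)) {
      expect_identical(classify_snv_class(r, a),
                       classify_snv_class(chartr("ACGT", "TGCA", r),
                                          chartr("ACGT", "TGCA", a)))
    }
  }
})

test_that("spectrum table normalizes by class base counts and generations", {
  seq <- paste0(strrep("AT", 25), strrep("GC", 25))  # 50 AT bp, 50 GC bp
  g <- genome_spec("m", seq)
  lines <- data.frame(line = "l1", generations = 10L)
  calls <- data.frame(
    line = "l1", genome = "m", pos = c(1L, 3L), ref = c("A", "A"),
    alt = c("G", "G"), var_type = "SNV", depth = 100L, alt_count = 50L,
    raw_frequency = c(1, 0.5), corrected_frequency = c(1, 0.5),
    homoplasmy = "unclassified", filters = "", stringsAsFactors = FALSE)
  tab <- spectrum_table(calls, g, lines)
  expect_identical(sum(tab$count), 2)
  row <- tab[tab$class == "AT>GC", ]
  expect_equal(row$count, 2)
  expect_equal(row$weighted, 1.5)
  expect_equal(row$rate, 1.5 / (50 * 10))
  expect_true(all(tab$rate[tab$class != "AT>GC"] == 0))

  # reverse-complementing genome and calls leaves class counts unchanged
  rc_calls <- calls
  rc_calls$ref <- chartr("ACGT", "TGCA", calls$ref)
  rc_calls$alt <- chartr("ACGT", "TGCA", calls$alt)
  g_rc <- genome_spec("m", paste(rev(strsplit(chartr("ACGT", "TGCA", seq),
                                              "")[[1]]), collapse = ""))
  tab_rc <- spectrum_table(rc_calls, g_rc, lines)
  expect_identical(tab_rc$count, tab$count)
  expect_identical(tab_rc$rate, tab$rate)
})
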