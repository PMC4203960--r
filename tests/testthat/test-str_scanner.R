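test_that("canonicalisation folds phase and strand variants to one family", {
  expect_equal(canonicalize_motif("GT"), "AC")
  expect_equal(canonicalize_motif("AC"), "AC")
  # frozen by brute-force rotation/revcomp enumeration
  expect_equal(canonicalize_motif("GGGGT"), "ACCCC")
  expect_equal(canonicalize_motif("GGGGT"), oracle_canonical("GGGGT"))
  expect_error(canonicalize_motif("AA"), "primitive")
  expect_error(canonicalize_motif("ACAC"), "primitive")
  expect_error(canonicalize_motif("A"))
})

test_that("canonicalisation is idempotent and rotation/revcomp invariant", {
  withr::local_seed(21)
  units <- unique(replicate(60, {
    repeat {
      u <- random_dna(sample(2:6, 1))
      if (oracle_is_primitive(u)) return(u)
    }
  }))
  for (u in units) {
    canon <- canonicalize_motif(u)
    expect_equal(canonicalize_motif(canon), canon)
    rot <- paste0(substring(u, 2), substring(u, 1, 1))
    if (oracle_is_primitive(rot)) {
      expect_equal(canonicalize_motif(rot), canon)
    }
    expect_equal(canonicalize_motif(revcomp(u)), canon)
    expect_equal(canon, oracle_canonical(u))
  }
})

test_that("the reference table motif labels are fixed points of canonicalisation", {
  tab <- reference_frequency_table("chicken")
  expect_equal(canonicalize_motif(tab$motif), tab$motif)
  expect_equal(nrow(tab), 20L)
})

test_that("STR scanner handles the worked pentanucleotide example", {
  p <- make_promoters(dlx3 = strrep("GGGGT", 6))
  calls <- scan_strs(p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$period, 5L)
  expect_equal(calls$units, 6L)
  expect_equal(calls$canonical_motif, "ACCCC")
  expect_equal(calls$start, 1L)
  expect_equal(calls$end, 30L)
})

test_that("runs below six units and mononucleotide runs are not called", {
  # 5.5 units of AC in a non-extending context
  p <- make_promoters(x = paste0("TTGTT", strrep("AC", 5), "A", "GTCCA"))
  expect_equal(nrow(scan_strs(p)), 0L)
  # poly-G is never an STR (primitive-unit rule kills GG, GGG, ...)
  expect_equal(nrow(scan_strs(make_promoters(g = strrep("G", 40)))), 0L)
  # exactly six units is called
  p6 <- make_promoters(y = paste0("TTGTT", strrep("AC", 6), "TTGTT"))
  expect_equal(scan_strs(p6)$units, 6L)
})

test_that("a run is reported once, at its primitive period", {
  # (AG)12 must be a single period-2 call, never a period-4 (AGAG)6 call
  p <- make_promoters(x = paste0("CCTCC", strrep("AG", 12), "CCTCC"))
  calls <- scan_strs(p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$period, 2L)
  expect_equal(calls$units, 12L)
})

test_that("N breaks runs and never sits inside a call", {
  s <- paste0(strrep("AC", 7), "N", strrep("AC", 7))
  p <- make_promoters(x = paste0("GTTTG", s, "GTTTG"))
  calls <- scan_strs(p)
  expect_equal(nrow(calls), 2L)
  for (i in seq_len(nrow(calls))) {
    expect_false(grepl("N", substr(p$seq, calls$start[i], calls$end[i])))
  }
})

test_that("reported intervals are perfect repeats of the observed unit", {
  withr::local_seed(33)
  for (rep_i in 1:20) {
    s <- random_dna(500, c(A = .3, C = .2, G = .2, T = .3))
    s <- with_planted(s, strrep("ACGT", 8), 100)
    s <- with_planted(s, strrep("AAT", 7), 300)
    calls <- scan_strs(promoter_set(c(x = s)))
    for (i in seq_len(nrow(calls))) {
      span <- substr(s, calls$start[i], calls$end[i])
      expect_equal(span, strrep(calls$observed_motif[i], calls$units[i]))
      expect_equal(nchar(span), calls$period[i] * calls$units[i])
      expect_true(oracle_is_primitive(calls$observed_motif[i]))
      expect_equal(canonicalize_motif(calls$observed_motif[i]),
                   calls$canonical_motif[i])
    }
  }
})

test_that("scanner matches the brute-force oracle on random sequences", {
  withr::local_seed(77)
  for (rep_i in 1:40) {
    probs <- c(A = .3, C = .2, G = .2, T = .3)
    s <- random_dna(600, probs)
    # enrich with planted repeats of varied periods to exercise the paths
    s <- with_planted(s, strrep("AC", 10), 50)
    s <- with_planted(s, strrep("AGG", 6), 150)
    s <- with_planted(s, strrep("GGGGT", 6), 280)
    s <- with_planted(s, strrep("AAATT", 6), 400)
    got <- scan_strs(promoter_set(c(x = s)))
    want <- oracle_scan_strs(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$period, want$period)
    expect_equal(got$units, want$units)
    expect_equal(got$canonical_motif, want$canonical_motif)
  }
})

test_that("trinucleotide GC classes follow the unit base composition", {
  expect_equal(as.character(trinucleotide_gc_class(c("AAT", "AGC", "CCG",
                                                     "ACT"))),
               c("0%GC", "67%GC", "100%GC", "33%GC"))
  p <- make_promoters(x = paste0("TT", strrep("CCG", 6), "TT"))
  calls <- scan_strs(p)
  expect_equal(as.character(calls$gc_class), "100%GC")
  expect_true(is.na(scan_strs(make_promoters(y = paste0("TTG",
    strrep("AC", 8), "GTT")))$gc_class[1]))
})

test_that("frequency tables count, rank and normalise canonical motifs", {
  calls <- data.frame(canonical_motif = c(rep("AC", 5), rep("AT", 5)))
  tab <- str_frequency_table(calls, n_promoters = 20L)
  expect_equal(tab$freq_percent, c(50, 50))
  expect_equal(attr(tab, "str_per_seq"), 0.5)
  one <- str_frequency_table(data.frame(canonical_motif = "AAG"), 10L)
  expect_equal(one$freq_percent, 100)
  empty <- str_frequency_table(scan_strs(make_promoters(x = strrep("T", 50))),
                               5L)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "str_per_seq"), 0)
})

test_that("bundled reference tables are internally consistent", {
  # the percent column is relative to the full motif census (the tables list
  # the 20 most frequent families only), so counts and percents must agree
  # through one implied census total
  for (sp in c("chicken", "duck")) {
    tab <- reference_frequency_table(sp)
    implied_total <- sum(tab$count) * 100 / sum(tab$freq_percent)
    expect_true(all(abs(100 * tab$count / implied_total - tab$freq_percent)
                    <= 0.1))
    expect_true(all(diff(tab$count[tab$motif %in% c("AC", "AT", "AG")]) < 0))
  }
})

test_that("frequency tables round-trip through TSV", {
  calls <- data.frame(canonical_motif = c(rep("AC", 7), rep("AAT", 2), "CG"))
  tab <- str_frequency_table(calls, 50L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(tab, f)
  back <- read_frequency_table(f)
  expect_equal(back$motif, tab$motif)
  expect_equal(back$count, tab$count)
  expect_equal(attr(back, "str_per_seq"), attr(tab, "str_per_seq"),
               tolerance = 1e-6)
})

test_that("unit-count summary separates period classes and flags empties", {
  calls <- data.frame(period = c(2L, 2L, 2L, 4L, 6L),
                      units = c(6L, 6L, 8L, 7L, 6L))
  sm <- unit_count_summary(calls)
  expect_equal(sm$per_period$mean_units[sm$per_period$period == 2], 20 / 3)
  expect_true(is.na(sm$per_period$mean_units[sm$per_period$period == 5]))
  expect_equal(sm$di_units, c(6L, 6L, 8L))
  expect_equal(sort(sm$tetra_plus_units), c(6L, 7L))
})
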