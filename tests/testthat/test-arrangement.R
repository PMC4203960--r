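test_that("GC profile is exact on degenerate input and tracks a gradient", {
  p <- promoter_set(c(a = strrep("G", 500), b = strrep("C", 500)))
  prof <- gc_profile(p)
  expect_true(all(prof$profile$mean_gc == 1))
  expect_equal(prof$overall_mean_gc, 1)
  expect_equal(nrow(prof$profile), 500L)
  expect_equal(prof$profile$position, -500:-1)
  # an AT-rich patch planted at -31..-23 in every promoter dips the profile
  withr::local_seed(501)
  seqs <- replicate(60, random_dna(2000, c(A = .2, C = .3, G = .3, T = .2)))
  seqs <- vapply(seqs, function(s) with_planted(s, strrep("TA", 5), 1970),
                 character(1))
  gp <- gc_profile(promoter_set(stats::setNames(seqs, paste0("g", 1:60))))
  dip <- mean(gp$profile$mean_gc[gp$profile$position %in% -31:-23])
  flank <- mean(gp$profile$mean_gc[gp$profile$position %in% -200:-100])
  expect_lt(dip, flank - 0.2)
})

test_that("binning conserves counts and places anchors correctly", {
  p <- promoter_set(c(g = strrep("A", 2000)))
  calls <- data.frame(gene_id = "g",
                      start = c(6L, 10L, 1996L),
                      end = c(6L, 10L, 1996L))
  prof <- bin_positions(calls, p, 10L, anchor = "start")
  expect_equal(sum(prof$count), 3L)
  expect_equal(prof$count[prof$bin_start_tss == -2000], 2L)
  expect_equal(prof$count[prof$bin_start_tss == -10], 1L)
  expect_equal(sum(bin_positions(calls[0, ], p, 10L)$count), 0L)
  # conservation on random call sets, midpoint anchor
  withr::local_seed(502)
  for (i in 1:5) {
    s <- sample.int(1900, 40)
    calls <- data.frame(gene_id = "g", start = s, end = s + sample.int(50, 40))
    expect_equal(sum(bin_positions(calls, p, 100L)$count), 40L)
  }
})

test_that("region partition is exhaustive with half-open boundaries", {
  pos <- -2000:-1
  reg <- promoter_region(pos)
  expect_false(any(is.na(reg)))
  expect_equal(as.integer(table(reg)), c(1500L, 400L, 100L))
  expect_equal(as.character(promoter_region(c(-2000L, -501L, -500L, -101L,
                                              -100L, -1L))),
               c("distal", "distal", "proximal", "proximal", "core", "core"))
})

test_that("motif-vs-CGI classification covers all five labels exclusively", {
  # one CGI at [1501, 1800]
  expect_equal(classify_vs_cgi(100L, 120L, 1501L, 1800L), "upstream")
  expect_equal(classify_vs_cgi(1900L, 1950L, 1501L, 1800L), "downstream")
  expect_equal(classify_vs_cgi(1800L, 1820L, 1501L, 1800L), "overlapped")
  expect_equal(classify_vs_cgi(100L, 120L, integer(0), integer(0)), "no_cgi")
  # flanked by two CGIs without overlap
  expect_equal(classify_vs_cgi(900L, 950L, c(100L, 1501L), c(400L, 1800L)),
               "intervened")
  # exhaustive & mutually exclusive over random configurations
  withr::local_seed(503)
  for (i in 1:200) {
    ncgi <- sample(0:3, 1)
    cs <- sort(sample.int(1900, ncgi))
    ce <- cs + 50L
    ms <- sample.int(1950, 1)
    lab <- classify_vs_cgi(ms, ms + 30L, cs, ce)
    expect_true(lab %in% c("upstream", "downstream", "overlapped",
                           "intervened", "no_cgi"))
    expect_equal(lab == "no_cgi", ncgi == 0L)
    if (lab == "overlapped") {
      expect_true(any(cs <= ms + 30L & ce >= ms))
    }
  }
})

test_that("arrangement table separates planted location biases", {
  # di-STRs planted outside islands, tri-STRs inside: association must show
  withr::local_seed(504)
  n <- 60
  seqs <- character(n)
  for (i in 1:n) {
    s <- at_background(2000)
    # irregular CpG-rich island (not itself a tandem repeat) at [1001, 1300]
    island <- random_dna(300, c(A = .15, C = .35, G = .35, T = .15))
    s <- with_planted(s, island, 1001)
    if (i %% 2 == 0) {
      s <- with_planted(s, strrep("AT", 8), 201)            # di outside CGI
    } else {
      s <- with_planted(s, paste0("T", strrep("ACG", 7), "T"), 1101) # tri inside
    }
    seqs[i] <- s
  }
  p <- promoter_set(stats::setNames(seqs, sprintf("g%02d", 1:n)))
  strs <- scan_strs(p)
  cgis <- scan_cgis(p)
  arr <- arrangement_table(strs, scan_pqs(p), cgis, p)
  tab <- arr$table
  expect_gt(tab["di-STR", "upstream"], 0)
  expect_gt(tab["tri-STR", "overlapped"], 0)
  expect_equal(tab["di-STR", "overlapped"], 0L)
  expect_lt(arr$fisher_p, 0.01)
})

test_that("degenerate arrangement tables are skipped with a message", {
  p <- promoter_set(c(g = at_background(600, seed = 505)))
  arr <- arrangement_table(scan_strs(p), scan_pqs(p), scan_cgis(p), p)
  expect_true(is.na(arr$fisher_p))
})

test_that("trinucleotide GC-class profiles key on unit composition", {
  bg <- at_background(2000, seed = 506)
  s <- with_planted(bg, paste0("G", strrep("CCG", 6), "A"), 1921) # 100%GC at core
  s <- with_planted(s, paste0("G", strrep("AAT", 6), "G"), 101)   # 0%GC distal
  p <- promoter_set(c(g = s))
  tri <- scan_strs(p)
  tri <- tri[tri$period == 3L, ]
  prof <- trinucleotide_gc_positions(tri, p)
  expect_equal(sum(prof$count[prof$gc_class == "100%GC" &
                                prof$bin_start_tss == -100]), 1L)
  expect_equal(sum(prof$count[prof$gc_class == "0%GC"]), 1L)
  expect_error(trinucleotide_gc_positions(
    data.frame(gene_id = "g", start = 1L, end = 12L, period = 2L,
               gc_class = NA), p))
})

test_that("co-occurrence tables band counts and test independence", {
  withr::local_seed(507)
  n <- 400
  # planted positive coupling: PQS presence doubles high CGI counts
  pqs <- rbinom(n, 1, 0.4)
  cgi <- rpois(n, ifelse(pqs == 1, 2.0, 0.5))
  counts <- data.frame(gene_id = sprintf("g%03d", 1:n),
                       CGI = cgi, STR = rbinom(n, 2, 0.1), PQS = pqs)
  res <- cooccurrence_table(counts)
  row <- res[res$presence_of == "PQS" & res$counts_of == "CGI", ]
  expect_lt(row$p_two_sided, 0.01)
  tabs <- attr(res, "tables")
  expect_equal(sum(tabs[["PQS_vs_CGI"]]), n)
  # degenerate: all genes identical counts -> skipped
  same <- data.frame(gene_id = c("a", "b"), CGI = c(1L, 1L), PQS = c(1L, 1L))
  res2 <- cooccurrence_table(same)
  expect_true(all(is.na(res2$p_two_sided)))
})
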