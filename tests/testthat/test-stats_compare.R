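test_that("minor-motif pruning drops the bottom decile and aligns tables", {
  ref <- data.frame(motif = sprintf("M%02d", 1:20), count = 20:1)
  out <- prune_minor_motifs(ref)
  expect_equal(length(out$motifs), 18L)   # floor(0.10 * 20) = 2 removed
  expect_equal(out$motifs[1], "M01")
  nine <- prune_minor_motifs(data.frame(motif = letters[1:9], count = 9:1))
  expect_equal(length(nine$motifs), 9L)   # floor(0.10 * 9) = 0 removed
  # alignment zero-fills motifs absent from the other table
  chicken <- reference_frequency_table("chicken")
  duck <- reference_frequency_table("duck")
  al <- prune_minor_motifs(chicken, list(duck = duck))
  expect_equal(unname(al$duck[c("CG", "ACGGC")]), c(0L, 0L))
  expect_equal(unname(al$duck["AC"]), 433L)
  expect_error(prune_minor_motifs(ref, prune = 1))
})

test_that("tau-b equals pair enumeration on small tied vectors", {
  expect_equal(kendall_tau_b(1:5, c(10, 20, 30, 40, 50))$tau, 1)
  expect_equal(kendall_tau_b(1:5, 5:1)$tau, -1)
  withr::local_seed(601)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y)$tau, oracle_tau_b(x, y))
  }
})

test_that("tau-b agrees with the reference implementation", {
  withr::local_seed(602)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    got <- kendall_tau_b(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(got$tau, unname(ct$estimate), tolerance = 1e-12)
  }
  # tie-free exact p agrees with the reference exact test
  for (i in 1:10) {
    x <- sample(1:7)
    y <- sample(1:7)
    got <- kendall_tau_b(x, y)
    ct <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(got$p_two_sided, ct$p.value, tolerance = 1e-9)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  withr::local_seed(603)
  x <- rexp(15); y <- rexp(15)
  f <- function(v) log(v + 1) * 3
  expect_equal(kendall_tau_b(x, y)$tau, kendall_tau_b(f(x), f(y))$tau)
  a <- rexp(10); b <- rexp(12)
  expect_equal(mann_whitney_z(a, b)$z, mann_whitney_z(f(a), f(b))$z)
})

test_that("correlation handles both flavours and flags zero variance", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_r(x, 2 * x), 1)
  expect_warning(r <- correlation_r(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(r))
  withr::local_seed(604)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(correlation_r(x, y)), 0.05)
  # spearman equals pearson on ranks for tie-free input
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(correlation_r(x, y, "spearman"),
               correlation_r(rank(x), rank(y), "pearson"))
})

test_that("Mann-Whitney matches exact enumeration and the reference test", {
  r <- mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_one_sided, 0.05)  # 1 / choose(6, 3)
  expect_equal(mann_whitney_z(c(5, 7), c(5, 7))$z, 0)
  withr::local_seed(605)
  for (i in 1:15) {
    a <- rnorm(8); b <- rnorm(8)
    got <- mann_whitney_z(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_two_sided, wt$p.value, tolerance = 1e-9)
    # exact and normal approximation agree closely at n = m = 8
    approx_p <- 2 * stats::pnorm(-abs(got$z))
    expect_lt(abs(got$p_two_sided - approx_p), 0.02)
  }
})

test_that("2x2 Fisher matches hypergeometric enumeration on random tables", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_two_sided, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_two_sided, 1)
  withr::local_seed(606)
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    got <- fisher_exact_2x2(tab)
    ft <- stats::fisher.test(tab)
    expect_equal(got$p_two_sided, ft$p.value, tolerance = 1e-7)
    ft1 <- stats::fisher.test(tab, alternative = "greater")
    expect_equal(got$p_one_sided, ft1$p.value, tolerance = 1e-7)
  }
})

test_that("r x c Fisher reduces to 2x2 and detects planted association", {
  tab <- matrix(c(8, 2, 1, 9), 2)
  expect_equal(fisher_exact_rxc(tab)$p_two_sided,
               fisher_exact_2x2(tab)$p_two_sided, tolerance = 1e-7)
  strong <- rbind(c(40, 5, 3, 2), c(4, 6, 20, 30))
  expect_lt(fisher_exact_rxc(strong)$p_two_sided, 0.001)
  expect_error(fisher_exact_rxc(matrix(1:3, 1)), "degenerate")
  # large tables fall back to seeded Monte Carlo with a reported SE
  big <- rbind(c(300, 200, 250, 260), c(250, 260, 300, 200))
  mc <- fisher_exact_rxc(big, B = 2e4)
  expect_equal(mc$method, "monte-carlo")
  expect_false(is.na(mc$mc_se))
  mc2 <- fisher_exact_rxc(big, B = 2e4)
  expect_equal(mc$p_two_sided, mc2$p_two_sided)  # seeded: reproducible
})

test_that("frequency-table comparison pipeline is deterministic", {
  chicken <- reference_frequency_table("chicken")
  duck <- reference_frequency_table("duck")
  c1 <- compare_frequency_tables(chicken, duck)
  c2 <- compare_frequency_tables(chicken, duck)
  expect_identical(c1, c2)
  expect_equal(c1$n_motifs_used, 18L)
  expect_gt(c1$r, 0.9)       # closely related avian tables
  expect_gt(c1$tau, 0.4)
  expect_lt(c1$p_two_sided, 0.01)
})

test_that("GO enrichment flags a planted term and respects edge cases", {
  withr::local_seed(607)
  genes <- sprintf("g%04d", 1:2000)
  group <- sample(genes, 200)
  terms <- sprintf("T%02d", 1:20)
  ann <- list()
  for (tm in terms) {
    p <- rep(0.10, 2000)
    if (tm == "T01") p[genes %in% group] <- 5 * (0.1 / 0.9) /
        (1 + 5 * (0.1 / 0.9))
    has <- runif(2000) < p
    ann[[tm]] <- data.frame(gene_id = genes[has], term = tm)
  }
  ann <- do.call(rbind, ann)
  res <- go_enrichment(list(grp = group), ann, genes)
  rec <- res$records
  expect_true(rec$significant[rec$term == "T01"])
  expect_lt(mean(rec$significant[rec$term != "T01"]), 0.2)
  expect_true(all(rec$p >= 0 & rec$p <= 1))
  expect_true(all(rec$k <= pmin(rec$K, rec$n)))
  # group == background -> every p = 1
  res2 <- go_enrichment(list(all = genes), ann, genes)
  expect_true(all(res2$records$p == 1))
  # k = 0 -> p = 1
  res3 <- go_enrichment(list(none = setdiff(genes, ann$gene_id)[1:10]),
                        ann, genes)
  expect_true(all(res3$records$p == 1))
  # heat-map matrix mirrors the records
  expect_equal(unname(res$matrix["grp", "T01"]),
               -log10(rec$p[rec$term == "T01"]))
})

test_that("motif groups follow the STR-over-PQS assignment rule", {
  str_calls <- data.frame(gene_id = c("a", "b"), start = c(10L, 100L),
                          end = c(40L, 130L))
  pqs_calls <- data.frame(gene_id = c("a", "c"), start = c(20L, 50L),
                          end = c(45L, 70L))
  cls <- data.frame(gene_id = c("a", "b", "c", "d"),
                    label = c("other", "LCGI", "NCGI", "NCGI"))
  grp <- assign_motif_groups(str_calls, pqs_calls, cls)
  # gene a's PQS overlaps its STR -> sorted into STR, not PQS
  expect_false("a" %in% grp$PQS)
  expect_true("c" %in% grp$PQS)
  expect_equal(sort(grp$STR), c("a", "b"))
  expect_equal(grp$LCGI, "b")
  expect_equal(sort(grp$NCGI), c("c", "d"))
})
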