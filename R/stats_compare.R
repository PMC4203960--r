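#' Prune minor motifs and align frequency tables
#'
#' Ranks motifs by the reference table's counts (descending, ties broken
#' alphabetically for determinism), removes the bottom `floor(prune * m)`
#' motifs, and aligns every other table onto the retained motifs (motifs
#' absent from a table contribute count 0).
#'
#' @param ref Reference frequency table (`motif`, `count`).
#' @param others Named list of frequency tables to align.
#' @param prune Fraction of minor motifs to drop (default 0.10).
#' @return List: `motifs` — retained motifs in rank order; `ref` — reference
#'   count vector; one aligned count vector per element of `others`.
#' @export
prune_minor_motifs <- function(ref, others = list(), prune = 0.10) {
  stopifnot(nrow(ref) > 0L)
  ord <- order(-ref$count, ref$motif)
  m <- nrow(ref)
  k <- floor(prune * m)
  if (m - k < 1L) stop("all motifs pruned")
  keep <- ref$motif[ord][seq_len(m - k)]
  align <- function(tab) {
    v <- stats::setNames(tab$count, tab$motif)[keep]
    v[is.na(v)] <- 0L
    stats::setNames(as.integer(v), keep)
  }
  c(list(motifs = keep, ref = align(ref)), lapply(others, align))
}

#' Kendall tau-b rank correlation with tie correction
#'
#' Tau-b: `(C - D) / sqrt((n0 - n1)(n0 - n2))` over all pairs, with the
#' standard tie corrections in the denominator and in the normal-approximation
#' variance of the two-sided test. When `n <= 8` and neither vector has ties,
#' the null distribution is evaluated exactly by enumerating all permutations.
#' The Kendall distance `D = (1 - tau) n (n - 1) / 4` is returned as a
#' derived convenience.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `tau`, `p_two_sided`, `n`, `method`
#'   (`"exact"`/`"normal"`), `kendall_distance`. Zero variance in either
#'   vector yields `tau = NA` with a message attribute.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(tau = NA_real_, p_two_sided = NA_real_, n = n,
                method = "undefined: zero variance",
                kendall_distance = NA_real_))
  }
  sgn <- function(v) sign(outer(v, v, "-"))
  sx <- sgn(x); sy <- sgn(y)
  S <- sum(sx * sy * upper.tri(sx))
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (n <= 8L && !has_ties) {
    perms <- permutations_of(n)
    r <- rank(y)
    sxu <- sx * upper.tri(sx)
    stats_all <- apply(perms, 1L, function(p) sum(sxu * sgn(r[p])))
    p <- mean(abs(stats_all) >= abs(S) - 1e-9)
    method <- "exact"
  } else {
    # tie-corrected variance of S (normal approximation)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(tau = tau, p_two_sided = min(1, p), n = n, method = method,
       kendall_distance = (1 - tau) * n * (n - 1) / 4)
}

## All permutations of 1..n as a matrix (n! rows); n <= 8 in practice.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(sub + (sub >= i), i)
  }
  out
}

#' Correlation coefficient between two count vectors
#'
#' Product-moment (Pearson, default — matching the conventional symbol `r`)
#' or rank (Spearman) correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in `[-1, 1]`; `NA` with zero variance.
#' @export
correlation_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Compare two motif frequency tables
#'
#' The full cross-species comparison: prune the bottom fraction of minor
#' motifs by the reference table, align, then compute the correlation `r`,
#' Kendall tau-b and its two-sided p on the aligned count vectors.
#'
#' @param ref,other Frequency tables (`motif`, `count`).
#' @param prune Minor-motif fraction to drop (default 0.10).
#' @param method Correlation flavour for `r`.
#' @return `data.frame` with `r`, `tau`, `p_two_sided`, `n_motifs_used`.
#' @export
compare_frequency_tables <- function(ref, other, prune = 0.10,
                                     method = "pearson") {
  al <- prune_minor_motifs(ref, list(other = other), prune)
  kt <- kendall_tau_b(as.numeric(al$ref), as.numeric(al$other))
  data.frame(r = correlation_r(as.numeric(al$ref), as.numeric(al$other),
                               method),
             tau = kt$tau, p_two_sided = kt$p_two_sided,
             n_motifs_used = length(al$motifs))
}

#' Mann-Whitney U test with normal approximation and exact enumeration
#'
#' Returns the U statistic for sample `a`, the z score under the normal
#' approximation with tie correction and 0.5 continuity correction, and the
#' two-sided p. When both samples have at most `exact_max` observations the
#' two-sided p is computed exactly by enumerating all labelings
#' (`choose(n + m, n)` group assignments); `p_one_sided` is the exact/
#' approximate probability of a U as small as observed for sample `a`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest per-sample size for exact enumeration (default 8).
#' @return List with `U`, `z`, `p_two_sided`, `p_one_sided`, `method`.
#' @export
mann_whitney_z <- function(a, b, exact_max = 8L) {
  n <- length(a); m <- length(b)
  stopifnot(n >= 1L, m >= 1L)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sig2 <- n * m / 12 * ((n + m + 1) - tiecor)
  if (sig2 == 0) {
    return(list(U = U, z = 0, p_two_sided = 1, p_one_sided = 1,
                method = "degenerate"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  if (U == mu) z <- 0
  if (n <= exact_max && m <= exact_max) {
    idx <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p_two <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    p_one <- mean(Us <= U + 1e-9)
    method <- "exact"
  } else {
    p_two <- 2 * stats::pnorm(-abs(z))
    p_one <- stats::pnorm((U - mu + 0.5) / sqrt(sig2))
    method <- "normal"
  }
  list(U = U, z = z, p_two_sided = min(1, p_two), p_one_sided = min(1, p_one),
       method = method)
}

#' Fisher's exact test on a 2x2 table
#'
#' Direct hypergeometric computation: the one-sided p sums the tail of the
#' hypergeometric distribution toward larger `table[1,1]` (over-representation
#' of the top-left cell); the two-sided p sums all tables with fixed margins
#' whose probability does not exceed the observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts, positive total.
#' @return List with `p_one_sided`, `p_two_sided`, `odds_ratio` (sample).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            sum(table) > 0)
  a <- table[1, 1]
  K <- a + table[1, 2]          # row 1 margin
  nn <- a + table[2, 1]         # col 1 margin
  N <- sum(table)
  if (K == 0 || nn == 0 || K == N || nn == N) {
    return(list(p_one_sided = 1, p_two_sided = 1, odds_ratio = NA_real_))
  }
  support <- max(0, K + nn - N):min(K, nn)
  dens <- stats::dhyper(support, nn, N - nn, K)
  obs <- stats::dhyper(a, nn, N - nn, K)
  p_one <- sum(dens[support >= a])
  p_two <- sum(dens[dens <= obs * (1 + 1e-7)])
  orat <- if (table[1, 2] * table[2, 1] == 0) Inf else
    (a * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p_one_sided = min(1, p_one), p_two_sided = min(1, p_two),
       odds_ratio = orat)
}

#' Fisher's exact test on an r x c table
#'
#' Exact (network algorithm) for tables of moderate size; falls back to a
#' seeded Monte-Carlo p over the margin-preserving null with `B` permutations
#' (standard error reported) when the exact computation is infeasible. A 2x2
#' input reduces to [fisher_exact_2x2()] semantics.
#'
#' @param table Integer matrix of nonnegative counts, at least 2 rows and 2
#'   columns after dropping empty margins (degenerate input is an error; use
#'   the calling helpers to skip).
#' @param B Monte-Carlo replicates (default 1e5).
#' @param mc_cells Total count above which Monte Carlo is used (default 500).
#' @param seed Seed for the Monte-Carlo draw (default 1).
#' @return List with `p_two_sided`, `method` (`"exact"`/`"monte-carlo"`),
#'   `mc_se` (`NA` for exact).
#' @export
fisher_exact_rxc <- function(table, B = 1e5, mc_cells = 500L, seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("degenerate table: need at least 2 rows and 2 columns")
  }
  if (sum(table) <= mc_cells) {
    ft <- try(stats::fisher.test(table, workspace = 2e7), silent = TRUE)
    if (!inherits(ft, "try-error")) {
      return(list(p_two_sided = ft$p.value, method = "exact", mc_se = NA_real_))
    }
  }
  p <- withr::with_seed(seed,
    stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  list(p_two_sided = p, method = "monte-carlo",
       mc_se = sqrt(p * (1 - p) / B))
}

#' Gene-ontology over-representation by Fisher's exact test
#'
#' For each gene group and each GO term, tests over-representation of the
#' term among the group's genes against the background with a one-sided
#' Fisher exact test on `[[k, n-k], [K-k, N-n-(K-k)]]`. Raw p-values with a
#' fixed cutoff are the primary readout; Benjamini-Hochberg q-values are
#' emitted as an optional extra column (`q_bh`), clearly an extension of the
#' raw-p protocol. With `ease = TRUE` the more conservative EASE variant
#' (one success removed from `k`) is used instead.
#'
#' @param groups Named list of gene-id character vectors (e.g. `PQS`, `STR`,
#'   `LCGI`, `NCGI`); each must be a subset of `background`.
#' @param annotations `data.frame` with columns `gene_id`, `term`.
#' @param background Character vector of all genes under consideration.
#' @param cutoff Significance cutoff on the raw one-sided p (default 0.01).
#' @param ease Use the EASE score variant (default `FALSE`).
#' @return List: `records` — `data.frame` with `group`, `term`, `k`, `K`,
#'   `n`, `N`, `p`, `q_bh`, `significant`; `matrix` — group x term matrix of
#'   `-log10(p)` for heat-map export.
#' @export
go_enrichment <- function(groups, annotations, background, cutoff = 0.01,
                          ease = FALSE) {
  stopifnot(length(groups) >= 1L, nrow(annotations) > 0L)
  background <- unique(background)
  N <- length(background)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  dropped <- setdiff(unique(annotations$term), unique(ann$term))
  if (length(dropped)) {
    message(length(dropped), " term(s) absent from background skipped")
  }
  genes_by_term <- split(ann$gene_id, ann$term)
  terms <- names(genes_by_term)
  recs <- list()
  for (g in names(groups)) {
    gset <- unique(groups[[g]])
    if (!all(gset %in% background)) stop("group ", g, " not within background")
    n <- length(gset)
    for (tm in terms) {
      tgenes <- unique(genes_by_term[[tm]])
      K <- length(tgenes)
      k <- length(intersect(gset, tgenes))
      keff <- if (ease) max(0L, k - 1L) else k
      p <- if (keff == 0L) 1 else
        stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
      recs[[length(recs) + 1L]] <-
        data.frame(group = g, term = tm, k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < cutoff
  mat <- matrix(0, nrow = length(groups), ncol = length(terms),
                dimnames = list(names(groups), terms))
  for (i in seq_len(nrow(out))) {
    mat[out$group[i], out$term[i]] <- -log10(max(out$p[i], 1e-300))
  }
  list(records = out, matrix = mat)
}

#' Assign genes to motif-defined groups for enrichment analysis
#'
#' Builds the four promoter subgroups: genes with at least one STR call,
#' genes with at least one PQS call, LCGI genes and NCGI genes. Membership
#' is non-exclusive across groups except for one rule at the motif level:
#' a locus called by both the STR and the PQS scanner counts as an STR, so a
#' gene enters the PQS group only through a PQS call that does not overlap
#' any of its STR calls.
#'
#' @param str_calls,pqs_calls Call `data.frame`s.
#' @param cgi_classes Output of [classify_cgi_promoters()].
#' @return Named list of gene-id vectors: `PQS`, `STR`, `LCGI`, `NCGI`.
#' @export
assign_motif_groups <- function(str_calls, pqs_calls, cgi_classes) {
  str_genes <- unique(str_calls$gene_id)
  pqs_only <- vapply(seq_len(nrow(pqs_calls)), function(i) {
    g <- pqs_calls$gene_id[i]
    s <- str_calls[str_calls$gene_id == g, , drop = FALSE]
    !any(s$start <= pqs_calls$end[i] & s$end >= pqs_calls$start[i])
  }, logical(1))
  list(PQS = unique(pqs_calls$gene_id[pqs_only]),
       STR = str_genes,
       LCGI = cgi_classes$gene_id[cgi_classes$label == "LCGI"],
       NCGI = cgi_classes$gene_id[cgi_classes$label == "NCGI"])
}
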