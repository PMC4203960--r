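#' Observed/expected CpG ratio of a sequence window
#'
#' `O/E = N(CpG) * L / (N(C) * N(G))` with `L` the window length (including
#' `N` bases, which contribute to no count). Returns 0 when the window has no
#' `C` or no `G`.
#'
#' @param seq_window A single sequence string, length >= 2.
#' @return Nonnegative ratio.
#' @export
cpg_oe <- function(seq_window) {
  L <- nchar(seq_window)
  if (L < 2L) stop("window must be at least 2 bp")
  b <- strsplit(seq_window, "", fixed = TRUE)[[1]]
  nc <- sum(b == "C")
  ng <- sum(b == "G")
  if (nc == 0L || ng == 0L) return(0)
  ncg <- sum(b[-L] == "C" & b[-1L] == "G")
  ncg * L / (nc * ng)
}

#' GC fraction of a sequence (N-aware)
#'
#' `(N(G)+N(C)) / length`; `N` bases count toward the length but not toward
#' the GC count.
#'
#' @param seq A single sequence string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  nchar(gsub("[^GC]", "", seq)) / nchar(seq)
}

## Criteria evaluated on a span [s, e] (1-based closed) given cumulative
## counts; strict inequalities throughout ("exceeded 50%", "more than 0.6").
span_passes <- function(cumC, cumG, cumCG, s, e, gc_min, oe_min) {
  L <- e - s + 1L
  nc <- cumC[e + 1L] - cumC[s]
  ng <- cumG[e + 1L] - cumG[s]
  gc_ok <- (nc + ng) / L > gc_min
  if (!gc_ok) return(FALSE)
  if (nc == 0L || ng == 0L) return(FALSE)
  ncg <- cumCG[e] - cumCG[s]            # CpG starts in s..e-1
  ncg * L / (nc * ng) > oe_min
}

#' Call CpG islands in promoter sequences
#'
#' Identifies CpG islands (CGIs) under the three traditional
#' Gardiner-Garden-Frommer criteria: GC content above `gc_min` in a sliding
#' window of `window` bp, observed/expected CpG ratio above `oe_min`, and a
#' minimum length of `min_len` bp. Qualifying windows are merged into
#' candidate regions, each candidate is trimmed until all criteria hold on
#' its whole reported span, and candidates shorter than `min_len` after
#' trimming are discarded. Islands whose right edge reaches the promoter end
#' (the TSS) are emitted as-is with `truncated_at_tss = TRUE` — no attempt is
#' made to follow the island past the TSS.
#'
#' All thresholds are strict inequalities: boundary values fail. `N` bases
#' count toward length but not toward any base or dinucleotide count.
#'
#' @param promoters Promoter `data.frame`.
#' @param window Sliding-window width in bp (default 100).
#' @param min_len Minimum island length in bp (default 200).
#' @param gc_min Minimum GC fraction, exclusive (default 0.5).
#' @param oe_min Minimum CpG O/E ratio, exclusive (default 0.6).
#' @return `data.frame` with `gene_id`, `start`, `end` (1-based closed),
#'   `length`, `gc_fraction`, `cpg_oe`, `truncated_at_tss`, `name`; calls are
#'   pairwise disjoint and sorted. Promoters shorter than `window` yield no
#'   calls plus a warning.
#' @export
scan_cgis <- function(promoters, window = 100L, min_len = 200L,
                      gc_min = 0.5, oe_min = 0.6) {
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    calls <- scan_cgis_one(promoters$seq[i], window, min_len, gc_min, oe_min)
    if (nrow(calls) == 0L) return(NULL)
    calls$gene_id <- promoters$gene_id[i]
    calls
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), cpg_oe = numeric(),
                      truncated_at_tss = logical(), gene_id = character(),
                      stringsAsFactors = FALSE)
  }
  res$name <- sprintf("CGI:%d", res$length)
  rownames(res) <- NULL
  res[, c("gene_id", "start", "end", "length", "gc_fraction", "cpg_oe",
          "truncated_at_tss", "name")]
}

scan_cgis_one <- function(seq, window = 100L, min_len = 200L,
                          gc_min = 0.5, oe_min = 0.6) {
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), cpg_oe = numeric(),
                      truncated_at_tss = logical(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < window) {
    warning("promoter shorter than the CGI window (", window, " bp); no calls")
    return(empty)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  isC <- b == "C"
  isG <- b == "G"
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  isCG <- c(isC[-n] & isG[-1L], FALSE)
  cumCG <- c(0L, cumsum(isCG))
  ws <- seq_len(n - window + 1L)             # window starts
  we <- ws + window - 1L
  nc <- cumC[we + 1L] - cumC[ws]
  ng <- cumG[we + 1L] - cumG[ws]
  ncg <- cumCG[we] - cumCG[ws]
  gc_ok <- (nc + ng) / window > gc_min
  oe <- ifelse(nc == 0L | ng == 0L, 0, ncg * window / (nc * ng))
  qual <- gc_ok & oe > oe_min
  if (!any(qual)) return(empty)
  # merge overlapping/adjacent qualifying windows into candidate regions:
  # windows starting <= `window` bp apart share bases or abut
  qs <- which(qual)
  grp <- cumsum(c(1L, diff(qs) > window))
  out <- list()
  for (k in unique(grp)) {
    s <- qs[grp == k][1L]
    e <- qs[grp == k][sum(grp == k)] + window - 1L
    tr <- trim_candidate(isCG, cumC, cumG, cumCG, s, e, n,
                         min_len, gc_min, oe_min)
    if (is.null(tr)) next
    s <- tr[1L]; e <- tr[2L]
    L <- e - s + 1L
    ncs <- cumC[e + 1L] - cumC[s]
    ngs <- cumG[e + 1L] - cumG[s]
    ncgs <- cumCG[e] - cumCG[s]
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, length = L,
      gc_fraction = (ncs + ngs) / L,
      cpg_oe = if (ncs == 0L || ngs == 0L) 0 else ncgs * L / (ncs * ngs),
      truncated_at_tss = (e == n), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

## Trim a candidate region so every criterion holds on the reported span.
## Two deterministic moves alternate until stable: (a) ends are pulled in so
## the island starts at the C of a CpG and ends at the G of a CpG (the
## standard end adjustment of island callers; skipped at the right edge when
## the candidate reaches the promoter end, where the island is cut by the
## TSS); (b) while GC or O/E fail on the whole span, one bp is removed from
## whichever end sits in the weaker local 10-bp context (fewer C/G inward
## from that end; ties trim the 5' end). Returns c(start, end) or NULL when
## the span falls below min_len first.
trim_candidate <- function(isCG, cumC, cumG, cumCG, s, e, n,
                           min_len, gc_min, oe_min) {
  repeat {
    if (e - s + 1L < min_len) return(NULL)
    # (a) snap ends to CpG
    first_cg <- s
    while (first_cg <= e - 1L && !isCG[first_cg]) first_cg <- first_cg + 1L
    if (first_cg > e - 1L) return(NULL)      # no CpG in span
    s <- first_cg
    if (e < n) {
      last_cg <- e - 1L
      while (last_cg >= s && !isCG[last_cg]) last_cg <- last_cg - 1L
      if (last_cg < s) return(NULL)
      e <- last_cg + 1L
    }
    if (e - s + 1L < min_len) return(NULL)
    if (span_passes(cumC, cumG, cumCG, s, e, gc_min, oe_min)) return(c(s, e))
    # (b) one step of weaker-end trimming, then re-snap
    le <- min(e, s + 9L)
    left_gc <- (cumC[le + 1L] - cumC[s]) + (cumG[le + 1L] - cumG[s])
    rs <- max(s, e - 9L)
    right_gc <- (cumC[e + 1L] - cumC[rs]) + (cumG[e + 1L] - cumG[rs])
    if (left_gc <= right_gc) s <- s + 1L else e <- e - 1L
  }
}

#' Classify promoters by total CpG-island length
#'
#' Labels each promoter `NCGI` (no island), `LCGI` (total island length
#' strictly greater than `lcgi_threshold`, default 800 bp — the top-decile cut
#' used for chicken promoters) or `other`. Also reports the empirical quantile
#' of the threshold among CGI-bearing promoters so a top-10% style cut can be
#' re-derived on other datasets.
#'
#' @param promoters Promoter `data.frame`.
#' @param cgi_calls CGI call `data.frame` from [scan_cgis()].
#' @param lcgi_threshold LCGI total-length threshold in bp (strict; default 800).
#' @return `data.frame` with `gene_id`, `total_cgi_length`, `n_cgi`, `label`;
#'   attribute `"threshold_quantile"` gives the fraction of CGI-bearing genes
#'   with total length <= threshold.
#' @export
classify_cgi_promoters <- function(promoters, cgi_calls, lcgi_threshold = 800L) {
  tot <- tapply(cgi_calls$length, cgi_calls$gene_id, sum)
  cnt <- tapply(cgi_calls$length, cgi_calls$gene_id, length)
  out <- data.frame(gene_id = promoters$gene_id, stringsAsFactors = FALSE)
  out$total_cgi_length <- ifelse(out$gene_id %in% names(tot),
                                 as.integer(tot[out$gene_id]), 0L)
  out$n_cgi <- ifelse(out$gene_id %in% names(cnt),
                      as.integer(cnt[out$gene_id]), 0L)
  out$label <- ifelse(out$n_cgi == 0L, "NCGI",
                      ifelse(out$total_cgi_length > lcgi_threshold,
                             "LCGI", "other"))
  withcgi <- out$total_cgi_length[out$n_cgi > 0L]
  attr(out, "threshold_quantile") <-
    if (length(withcgi)) mean(withcgi <= lcgi_threshold) else NA_real_
  out
}
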