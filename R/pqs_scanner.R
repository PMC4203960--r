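#' Enumerate potential G-quadruplex candidates
#'
#' Enumerates every placement of four guanine tracts of equal used length
#' `t >= min_tetrad` (QGRS-style equal G-groups; `t` is the number of stacked
#' tetrads) with inter-tract loops of length `>= min_loop` and a total span of
#' at most `max_len` bp. A longer physical G-run may contribute a used tract
#' at any offset within it. Candidates whose entire span consists of
#' undisrupted poly-G are removed — this includes every candidate whose three
#' loops are all zero.
#'
#' @param seq A single normalised sequence string.
#' @param max_len Maximum candidate span in bp (default 30).
#' @param min_tetrad Minimum G-tract length / tetrad count (default 4).
#' @param min_loop Minimum loop length in bp (default 0).
#' @return `data.frame` with one row per candidate: `start`, `end` (1-based
#'   closed), `tetrad`, `run1`..`run4` (tract start positions), `loop1`..
#'   `loop3` (loop lengths).
#' @export
enumerate_pqs_candidates <- function(seq, max_len = 30L, min_tetrad = 4L,
                                     min_loop = 0L) {
  n <- nchar(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  isG <- b == "G"
  # glen[i] = length of the G run starting at i (0 if b[i] != G)
  glen <- integer(n)
  run <- 0L
  for (i in n:1) {
    run <- if (isG[i]) run + 1L else 0L
    glen[i] <- run
  }
  out <- list()
  for (t in seq.int(min_tetrad, max(min_tetrad, max_len %/% 4L))) {
    if (4L * t + 3L * min_loop > max_len) break
    pos <- which(glen >= t)                  # usable tract starts
    if (length(pos) < 4L) next
    for (a1 in pos) {
      if (a1 + 4L * t + 3L * min_loop - 1L > n) next   # minimal span must fit
      last_end <- a1 + max_len - 1L
      p2 <- pos[pos >= a1 + t + min_loop & pos + t - 1L <= last_end]
      for (a2 in p2) {
        p3 <- pos[pos >= a2 + t + min_loop & pos + t - 1L <= last_end]
        for (a3 in p3) {
          p4 <- pos[pos >= a3 + t + min_loop & pos + t - 1L <= last_end]
          for (a4 in p4) {
            e <- a4 + t - 1L
            if (all(isG[a1:e])) next         # undisrupted poly-G span
            out[[length(out) + 1L]] <-
              c(a1, e, t, a1, a2, a3, a4,
                a2 - (a1 + t), a3 - (a2 + t), a4 - (a3 + t))
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), tetrad = integer(),
                      run1 = integer(), run2 = integer(), run3 = integer(),
                      run4 = integer(), loop1 = integer(), loop2 = integer(),
                      loop3 = integer()))
  }
  m <- as.data.frame(do.call(rbind, out))
  names(m) <- c("start", "end", "tetrad", "run1", "run2", "run3", "run4",
                "loop1", "loop2", "loop3")
  m
}

#' Resolve overlapping G-quadruplex candidates into disjoint calls
#'
#' Greedy selection over candidates ranked by (1) larger tetrad count,
#' (2) smaller loop-length variance, (3) smaller total span, (4) leftmost
#' start; a candidate is kept iff it shares no base with an already-kept
#' call. This deterministic rank stands in for scanner-specific scores, which
#' the analysis never uses — only presence and position matter.
#'
#' @param candidates Candidate `data.frame` from [enumerate_pqs_candidates()],
#'   all from one promoter.
#' @return Disjoint calls sorted by `start`.
#' @export
resolve_pqs_overlaps <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  loopvar <- apply(as.matrix(candidates[, c("loop1", "loop2", "loop3")]), 1L,
                   stats::var)
  span <- candidates$end - candidates$start + 1L
  ord <- order(-candidates$tetrad, loopvar, span, candidates$start)
  kept <- logical(nrow(candidates))
  covered_end <- integer(0)
  covered_start <- integer(0)
  for (i in ord) {
    s <- candidates$start[i]; e <- candidates$end[i]
    if (!any(covered_start <= e & covered_end >= s)) {
      kept[i] <- TRUE
      covered_start <- c(covered_start, s)
      covered_end <- c(covered_end, e)
    }
  }
  out <- candidates[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan promoters for potential G-quadruplex sequences
#'
#' Runs [enumerate_pqs_candidates()] and [resolve_pqs_overlaps()] on each
#' promoter. Default constraints: span at most 30 bp, at least four stacked
#' tetrads (G-tracts of at least 4 G), minimum loop length 0, undisrupted
#' poly-G excluded. Only the given strand is scanned unless
#' `both_strands = TRUE` (minus-strand calls are reported on forward
#' coordinates).
#'
#' @param promoters Promoter `data.frame`.
#' @param max_len,min_tetrad,min_loop See [enumerate_pqs_candidates()].
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return `data.frame` with `gene_id`, `start`, `end`, `tetrad`,
#'   `loop1`..`loop3`, `strand`, `name` (`"PQS:<tetrad>"`).
#' @export
scan_pqs <- function(promoters, max_len = 30L, min_tetrad = 4L, min_loop = 0L,
                     both_strands = FALSE) {
  scan_one <- function(seq, gene_id) {
    cand <- enumerate_pqs_candidates(seq, max_len, min_tetrad, min_loop)
    calls <- resolve_pqs_overlaps(cand)
    if (nrow(calls) == 0L) return(NULL)
    calls$strand <- "+"
    if (both_strands) {
      n <- nchar(seq)
      rcand <- enumerate_pqs_candidates(revcomp(seq), max_len, min_tetrad,
                                        min_loop)
      rcalls <- resolve_pqs_overlaps(rcand)
      if (nrow(rcalls) > 0L) {
        tmp <- rcalls$start
        rcalls$start <- n - rcalls$end + 1L
        rcalls$end <- n - tmp + 1L
        rcalls$strand <- "-"
        calls <- rbind(calls, rcalls)
      }
    }
    calls$gene_id <- gene_id
    calls
  }
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    scan_one(promoters$seq[i], promoters$gene_id[i])
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), tetrad = integer(), loop1 = integer(),
                      loop2 = integer(), loop3 = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  res$name <- sprintf("PQS:%d", res$tetrad)
  rownames(res) <- NULL
  res[order(res$gene_id, res$start),
      c("gene_id", "start", "end", "tetrad", "loop1", "loop2", "loop3",
        "strand", "name")]
}

#' Per-gene G-quadruplex presence and counts
#'
#' @param pqs_calls PQS call `data.frame` from [scan_pqs()].
#' @param gene_ids All gene ids in the promoter set (genes without calls get
#'   count 0).
#' @return `data.frame` with `gene_id`, `n_pqs`, `present`.
#' @export
pqs_presence <- function(pqs_calls, gene_ids) {
  cnt <- table(factor(pqs_calls$gene_id, levels = gene_ids))
  data.frame(gene_id = gene_ids, n_pqs = as.integer(cnt),
             present = as.integer(cnt) > 0L, stringsAsFactors = FALSE)
}
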