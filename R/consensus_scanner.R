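IUPAC_CODES <- "ACGTRYSWKMBDHVN"

#' Scan promoters for a degenerate IUPAC consensus pattern
#'
#' Reports every match position of an IUPAC pattern (e.g. `"CWGCWSWG"`, the
#' distal C[A/T]GC[A/T][C/G][A/T]G consensus, or `"TATAWAW"`, the TATA box)
#' on the given strand and, optionally, its reverse complement. Minus-strand
#' hits are reported on forward coordinates. Overlapping hits are allowed;
#' `N` bases in the promoter never match.
#'
#' @param promoters Promoter `data.frame`.
#' @param pattern IUPAC pattern string (non-empty).
#' @param pattern_id Label stored with each hit (default: the pattern).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return `data.frame` with `gene_id`, `pattern_id`, `start`, `end`
#'   (1-based closed), `strand`, `name`.
#' @export
scan_iupac <- function(promoters, pattern, pattern_id = pattern,
                       both_strands = TRUE) {
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  bad <- setdiff(strsplit(toupper(pattern), "")[[1]],
                 strsplit(IUPAC_CODES, "")[[1]])
  if (length(bad)) {
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  }
  pattern <- toupper(pattern)
  subj <- Biostrings::DNAStringSet(promoters$seq)
  names(subj) <- promoters$gene_id
  hits_of <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    st <- Biostrings::startIndex(m)
    k <- lengths(st)
    if (sum(k) == 0L) return(NULL)
    data.frame(gene_id = rep(promoters$gene_id, k),
               pattern_id = pattern_id,
               start = unlist(st, use.names = FALSE),
               end = unlist(st, use.names = FALSE) + nchar(pat) - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- hits_of(pattern, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    if (rc != pattern) out <- rbind(out, hits_of(rc, "-"))
  }
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), pattern_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
  out$name <- sprintf("%s:%s", out$pattern_id, out$strand)
  rownames(out) <- NULL
  out
}

#' Scan promoters for polypurine runs (poly-A / poly-G)
#'
#' One hit per maximal run of the base with length at least `min_run`.
#' The default `min_run = 10` is chosen to exceed background run lengths in
#' near-equiprobable sequence while staying below typical discovered motif
#' widths; sensitivity to this choice should be reported, not hidden.
#'
#' @param promoters Promoter `data.frame`.
#' @param base `"A"` or `"G"`.
#' @param min_run Minimum run length (default 10, must be >= 2).
#' @return `data.frame` with `gene_id`, `pattern_id` (`"polyA"`/`"polyG"`),
#'   `start`, `end`, `length`, `strand` (`"+"`), `name`.
#' @export
scan_polypurine <- function(promoters, base = c("A", "G"), min_run = 10L) {
  base <- match.arg(base)
  stopifnot(min_run >= 2L)
  pid <- paste0("poly", base)
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    b <- strsplit(promoters$seq[i], "", fixed = TRUE)[[1]]
    r <- rle(b == base)
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    e <- ends[keep]
    s <- e - r$lengths[keep] + 1L
    data.frame(gene_id = promoters$gene_id[i], pattern_id = pid,
               start = s, end = e, length = e - s + 1L, strand = "+",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), pattern_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  res$name <- sprintf("%s:%d", res$pattern_id, res$length)
  rownames(res) <- NULL
  res
}

#' Positional profile of consensus hits relative to the TSS
#'
#' Histogram of hit start positions in TSS-relative coordinates
#' (`start - 1 - promoter_length`, so a hit whose first base lies 31 bp
#' upstream of the TSS sits at -31), at 1-bp resolution. Used e.g. to locate
#' the preferred TATA-box sites.
#'
#' @param hits Hit `data.frame` from [scan_iupac()].
#' @param promoters Promoter `data.frame` (for per-gene lengths).
#' @return `data.frame` with `position` (TSS-relative start) and `count`,
#'   sorted by position; zero-row for no hits.
#' @export
tata_positional_profile <- function(hits, promoters) {
  if (nrow(hits) == 0L) {
    return(data.frame(position = integer(), count = integer()))
  }
  len <- stats::setNames(promoters$length, promoters$gene_id)[hits$gene_id]
  if (anyNA(len)) stop("hits reference unknown promoters")
  pos <- hits$start - 1L - unname(len)
  tab <- table(pos)
  data.frame(position = as.integer(names(tab)), count = as.integer(tab))
}
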