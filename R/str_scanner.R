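#' Reverse complement of a DNA string
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Smallest period of a repeat unit
#'
#' The length of the shortest prefix whose repetition reconstructs the unit;
#' a primitive unit has `primitive_period(m) == nchar(m)` and a mononucleotide
#' run has primitive period 1.
#'
#' @param motif A single unit string.
#' @return Integer period.
#' @keywords internal
primitive_period <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n)) {
    if (n %% d == 0L && strrep(substr(motif, 1L, d), n %/% d) == motif) {
      return(d)
    }
  }
  n
}

#' Canonical representative of a repeat-motif family
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of the unit and all cyclic rotations of its reverse complement, so that one
#' label stands for every phase and strand variant of a tandem-repeat family
#' (e.g. `AC` = AC/CA/GT/TG, and `GGGGT` canonicalises to `ACCCC`).
#' Idempotent.
#'
#' @param motif Character vector of primitive repeat units, length 2-6,
#'   over `{A,C,G,T}`.
#' @return Character vector of canonical unit strings.
#' @export
canonicalize_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n < 2L || n > 6L || grepl("[^ACGT]", m)) {
      stop("motif must be a 2-6 bp string over A,C,G,T: ", m)
    }
    if (primitive_period(m) < n) {
      stop("motif is not primitive (mononucleotide runs and repeated units ",
           "are not motif families): ", m)
    }
    variants <- character(2L * n)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]), collapse = ""))
    for (i in seq_len(n)) {
      variants[i] <- paste0(substr(m, i, n), substr(m, 1L, i - 1L))
      variants[n + i] <- paste0(substr(rc, i, n), substr(rc, 1L, i - 1L))
    }
    min(variants)
  }, character(1), USE.NAMES = FALSE)
}

#' GC class of a trinucleotide repeat unit
#'
#' Classifies a 3-bp unit by its count of G or C bases into
#' `0%GC` / `33%GC` / `67%GC` / `100%GC`. Rotation- and strand-invariant
#' (depends only on the base multiset).
#'
#' @param unit Character vector of 3-bp units.
#' @return Factor with levels `0%GC`, `33%GC`, `67%GC`, `100%GC`.
#' @export
trinucleotide_gc_class <- function(unit) {
  stopifnot(all(nchar(unit) == 3L))
  ngc <- nchar(gsub("[^GC]", "", unit))
  factor(c("0%GC", "33%GC", "67%GC", "100%GC")[ngc + 1L],
         levels = c("0%GC", "33%GC", "67%GC", "100%GC"))
}

## Scan one normalized sequence for perfect tandem repeats.
## Strategy: for each period p, the lag-p self-match vector marks every
## position i with seq[i] == seq[i+p] (N never matches); a maximal TRUE run of
## length L is a maximal perfect repeat region of length L + p. Complete units
## only; a run is reported once, at its primitive period, anchored at its
## leftmost full unit. Overlaps between runs of different motifs are resolved
## greedily left-first: the right run restarts after the left call's end and
## is kept only if it still has >= min_units complete units (its observed unit
## becomes a rotation; the canonical motif is unchanged).
scan_strs_one <- function(seq, min_units = 6L, periods = 2:6) {
  n <- nchar(seq)
  b <- utf8ToInt(seq)
  isN <- b == utf8ToInt("N")
  cand <- list()
  for (p in sort(as.integer(periods))) {
    if (n < p * min_units) next
    i1 <- seq_len(n - p)
    eq <- (b[i1] == b[i1 + p]) & !isN[i1] & !isN[i1 + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= p * (min_units - 1L)
    for (k in which(keep)) {
      i <- starts[k]
      region_len <- r$lengths[k] + p
      units <- region_len %/% p
      if (units < min_units) next
      unit <- substr(seq, i, i + p - 1L)
      if (primitive_period(unit) != p) next  # reported at the primitive period only
      cand[[length(cand) + 1L]] <-
        c(start = i, period = p, region_end = i + region_len - 1L)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      units = integer(), observed_motif = character(),
                      canonical_motif = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, cand)
  m <- m[order(m[, "start"], m[, "period"]), , drop = FALSE]
  out <- vector("list", nrow(m))
  last_end <- 0L
  for (j in seq_len(nrow(m))) {
    s <- m[j, "start"]
    p <- m[j, "period"]
    if (s <= last_end) s <- last_end + 1L
    units <- (m[j, "region_end"] - s + 1L) %/% p
    if (units < min_units) next
    e <- s + units * p - 1L
    out[[j]] <- data.frame(start = s, end = e, period = p, units = units,
                           observed_motif = substr(seq, s, s + p - 1L),
                           stringsAsFactors = FALSE)
    last_end <- max(last_end, e)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      units = integer(), observed_motif = character(),
                      canonical_motif = character(), stringsAsFactors = FALSE))
  }
  out$canonical_motif <- canonicalize_motif(out$observed_motif)
  out[order(out$start), , drop = FALSE]
}

#' Scan promoters for perfect short tandem repeats
#'
#' Detects every maximal perfect tandem run of a primitive 2-6 bp unit with at
#' least `min_units` complete repeat units. Mononucleotide repeats are never
#' reported (the primitive-unit rule also suppresses e.g. `GG` calls inside
#' poly-G), a run is reported exactly once at its primitive period, runs
#' containing `N` are broken at the `N`, trailing partial units are excluded,
#' and directly adjacent runs of different motifs are reported as separate
#' calls with the left run extended greedily first.
#'
#' @param promoters Promoter `data.frame` (see [read_promoter_fasta()]).
#' @param min_units Minimum number of complete repeat units (default 6).
#' @param periods Repeat periods to scan (default 2:6).
#' @return `data.frame` with one row per call: `gene_id`, `start`, `end`
#'   (1-based closed), `period`, `units`, `observed_motif`, `canonical_motif`,
#'   `gc_class` (trinucleotide GC class, `NA` unless `period == 3`), and a BED
#'   `name` label `"STR:<canonical>:<units>"`; sorted by gene then start.
#' @export
scan_strs <- function(promoters, min_units = 6L, periods = 2:6) {
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    calls <- scan_strs_one(promoters$seq[i], min_units, periods)
    if (nrow(calls) == 0L) return(NULL)
    calls$gene_id <- promoters$gene_id[i]
    calls
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(), period = integer(),
                      units = integer(), observed_motif = character(),
                      canonical_motif = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  }
  res$gc_class <- factor(rep(NA_character_, nrow(res)),
                         levels = c("0%GC", "33%GC", "67%GC", "100%GC"))
  if (any(res$period == 3L)) {
    res$gc_class[res$period == 3L] <-
      trinucleotide_gc_class(res$observed_motif[res$period == 3L])
  }
  res$name <- sprintf("STR:%s:%d", res$canonical_motif, res$units)
  rownames(res) <- NULL
  res[, c("gene_id", "start", "end", "period", "units", "observed_motif",
          "canonical_motif", "gc_class", "name")]
}

#' Frequency table of canonical STR motifs
#'
#' Tabulates canonical motifs across a promoter set: per-motif count and
#' percent of all calls, plus the per-sequence call density
#' (`str_per_seq = total calls / n_promoters`), the unit of cross-species
#' comparison.
#'
#' @param calls STR call `data.frame` from [scan_strs()].
#' @param n_promoters Number of promoter sequences scanned.
#' @return `data.frame` with columns `motif`, `count`, `freq_percent`, sorted
#'   by decreasing count (ties alphabetical); the call density is attached as
#'   attribute `"str_per_seq"`.
#' @export
str_frequency_table <- function(calls, n_promoters) {
  stopifnot(n_promoters >= 1L)
  if (nrow(calls) == 0L) {
    out <- data.frame(motif = character(), count = integer(),
                      freq_percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "str_per_seq") <- 0
    return(out)
  }
  tab <- table(calls$canonical_motif)
  out <- data.frame(motif = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$motif), , drop = FALSE]
  out$freq_percent <- 100 * out$count / sum(out$count)
  rownames(out) <- NULL
  attr(out, "str_per_seq") <- sum(out$count) / n_promoters
  out
}

#' Write / read a motif frequency table as TSV
#'
#' Columns `motif`, `count`, `freq_percent`; the per-sequence density, when
#' known, travels in a `# str_per_seq=` header comment.
#'
#' @param tab Frequency table from [str_frequency_table()].
#' @param path TSV path.
#' @return `path` invisibly (write) / the table (read).
#' @export
write_frequency_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sps <- attr(tab, "str_per_seq")
  if (!is.null(sps)) writeLines(sprintf("# str_per_seq=%.6g", sps), con)
  writeLines("motif\tcount\tfreq_percent", con)
  if (nrow(tab) > 0L) {
    writeLines(sprintf("%s\t%d\t%.4f", tab$motif, tab$count, tab$freq_percent),
               con)
  }
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  first <- readLines(path, n = 1L)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#",
                           colClasses = c("character", "integer", "numeric"))
  if (startsWith(first, "# str_per_seq=")) {
    attr(tab, "str_per_seq") <- as.numeric(sub("# str_per_seq=", "", first))
  }
  tab
}

#' Per-period repeat-unit summary and the di- vs tetranucleotide contrast
#'
#' Summarises unit counts per repeat period and returns the two samples for
#' the dinucleotide versus "tetranucleotide" (tetra- + penta- + hexa-)
#' comparison, ready for [mann_whitney_z()]. A period with zero calls has its
#' mean flagged as `NA` (undefined), never reported as 0.
#'
#' @param calls STR call `data.frame` from [scan_strs()].
#' @return List with `per_period` (`period`, `n_calls`, `mean_units`),
#'   `di_units` (unit counts of period-2 calls) and `tetra_plus_units`
#'   (unit counts of period 4-6 calls).
#' @export
unit_count_summary <- function(calls) {
  per_period <- data.frame(period = 2:6)
  per_period$n_calls <- vapply(per_period$period,
                               function(p) sum(calls$period == p), integer(1))
  per_period$mean_units <- vapply(per_period$period, function(p) {
    u <- calls$units[calls$period == p]
    if (length(u) == 0L) NA_real_ else mean(u)
  }, numeric(1))
  list(per_period = per_period,
       di_units = calls$units[calls$period == 2L],
       tetra_plus_units = calls$units[calls$period %in% 4:6])
}
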