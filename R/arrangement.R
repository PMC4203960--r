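#' Average GC profile of a promoter set
#'
#' At each promoter position, the mean over promoters of the GC fraction in a
#' centred window (clipped at the promoter edges). All promoters must share
#' one length. `N` counts toward window length but not GC.
#'
#' @param promoters Promoter `data.frame` with equal-length sequences.
#' @param window Smoothing window in bp (default 10).
#' @return List: `profile` — `data.frame` with `position` (TSS-relative,
#'   `-length`..`-1`) and `mean_gc`; `overall_mean_gc` — mean per-promoter GC
#'   fraction; `gc_range` — range of per-promoter GC fractions.
#' @export
gc_profile <- function(promoters, window = 10L) {
  stopifnot(nrow(promoters) >= 1L)
  len <- unique(promoters$length)
  if (length(len) != 1L) stop("gc_profile requires equal-length promoters")
  acc <- numeric(len)       # per-position count of G/C across promoters
  valid <- numeric(len)     # per-position count of non-N across promoters
  per_prom_gc <- numeric(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    b <- strsplit(promoters$seq[i], "", fixed = TRUE)[[1]]
    g <- as.numeric(b == "G" | b == "C")
    acc <- acc + g
    valid <- valid + 1
    per_prom_gc[i] <- sum(g) / len
  }
  p <- acc / valid          # per-position GC indicator mean
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cp <- c(0, cumsum(p))
  lo <- pmax(seq_len(len) - half_lo, 1L)
  hi <- pmin(seq_len(len) + half_hi, len)
  smooth <- (cp[hi + 1L] - cp[lo]) / (hi - lo + 1L)
  list(profile = data.frame(position = seq_len(len) - 1L - len,
                            mean_gc = smooth),
       overall_mean_gc = mean(per_prom_gc),
       gc_range = range(per_prom_gc))
}

#' Bin motif calls along the promoter
#'
#' Histogram of call anchor positions in fixed-width bins tiling
#' `[-length, 0)` in TSS-relative coordinates. The total count is conserved.
#'
#' @param calls Call `data.frame` with `gene_id`, `start`, `end`.
#' @param promoters Promoter `data.frame` (for per-gene lengths).
#' @param bin_width Bin width in bp (10 for fine profiles, 100 for region
#'   summaries).
#' @param anchor `"midpoint"` (default; avoids edge bias for long calls) or
#'   `"start"` (the call's most distal base).
#' @param promoter_length Length of the tiled frame (default: the common
#'   promoter length).
#' @return `data.frame` with `bin_start_tss`, `bin_end_tss` (half-open) and
#'   `count`.
#' @export
bin_positions <- function(calls, promoters, bin_width,
                          anchor = c("midpoint", "start"),
                          promoter_length = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(promoter_length)) {
    promoter_length <- max(promoters$length)
  }
  nb <- ceiling(promoter_length / bin_width)
  bin_start <- -as.integer(promoter_length) + (seq_len(nb) - 1L) * bin_width
  out <- data.frame(bin_start_tss = bin_start,
                    bin_end_tss = bin_start + bin_width,
                    count = 0L)
  if (nrow(calls) == 0L) return(out)
  len <- stats::setNames(promoters$length, promoters$gene_id)[calls$gene_id]
  if (anyNA(len)) stop("calls reference unknown promoters")
  pos <- if (anchor == "midpoint") {
    tss_midpoint(calls$start, calls$end, unname(len))
  } else {
    calls$start - 1L - unname(len)
  }
  if (any(pos < -promoter_length | pos >= 0L)) {
    stop("call anchor outside the promoter frame")
  }
  idx <- (pos + promoter_length) %/% bin_width + 1L
  tab <- tabulate(idx, nbins = nb)
  out$count <- as.integer(tab)
  out
}

#' Distal / proximal / core region of a TSS-relative position
#'
#' The promoter is partitioned into distal `[-2000, -500)`, proximal
#' `[-500, -100)` and core `[-100, 0)` regions (half-open, so -500 is
#' proximal and -100 is core).
#'
#' @param tss_pos Integer vector of TSS-relative positions in `[-2000, -1]`.
#' @return Factor with levels `distal`, `proximal`, `core`.
#' @export
promoter_region <- function(tss_pos) {
  stopifnot(all(tss_pos < 0L))
  out <- ifelse(tss_pos >= -100L, "core",
                ifelse(tss_pos >= -500L, "proximal", "distal"))
  factor(out, levels = c("distal", "proximal", "core"))
}

#' Classify a motif's position relative to a promoter's CpG islands
#'
#' Labels: `overlapped` when the motif shares at least one base with any CGI;
#' else `intervened` when at least one CGI lies wholly 5' of the motif and at
#' least one wholly 3' (flanked by two or more CGIs); else `upstream` when
#' the motif lies 5' (more distal) of every CGI; else `downstream`;
#' `no_cgi` when the promoter has no CGI. Exhaustive and mutually exclusive.
#'
#' @param motif_start,motif_end 1-based closed motif interval.
#' @param cgi_starts,cgi_ends Integer vectors of the promoter's CGI intervals
#'   (possibly empty).
#' @return One of `"upstream"`, `"downstream"`, `"overlapped"`,
#'   `"intervened"`, `"no_cgi"`.
#' @export
classify_vs_cgi <- function(motif_start, motif_end, cgi_starts, cgi_ends) {
  if (length(cgi_starts) == 0L) return("no_cgi")
  if (any(cgi_starts <= motif_end & cgi_ends >= motif_start)) {
    return("overlapped")
  }
  left <- any(cgi_ends < motif_start)    # CGI wholly 5' (more distal)
  right <- any(cgi_starts > motif_end)   # CGI wholly 3' (TSS side)
  if (left && right) return("intervened")
  if (right) return("upstream")          # motif 5' of every CGI
  "downstream"
}

#' Arrangement records for a set of motif calls
#'
#' One record per call: its CGI relation ([classify_vs_cgi()]) and its
#' promoter region (midpoint anchor).
#'
#' @param calls Call `data.frame` (`gene_id`, `start`, `end`).
#' @param cgi_calls CGI call `data.frame`.
#' @param promoters Promoter `data.frame`.
#' @param motif_class Label attached to every record (e.g. `"di-STR"`).
#' @return `data.frame` with `gene_id`, `start`, `end`, `motif_class`,
#'   `cgi_relation`, `region`.
#' @export
arrangement_records <- function(calls, cgi_calls, promoters,
                                motif_class = "motif") {
  if (nrow(calls) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), motif_class = character(),
                      cgi_relation = character(), region = character(),
                      stringsAsFactors = FALSE))
  }
  len <- stats::setNames(promoters$length, promoters$gene_id)[calls$gene_id]
  cgi_by_gene <- split(cgi_calls[, c("start", "end")], cgi_calls$gene_id)
  rel <- vapply(seq_len(nrow(calls)), function(i) {
    cg <- cgi_by_gene[[calls$gene_id[i]]]
    if (is.null(cg)) cg <- data.frame(start = integer(), end = integer())
    classify_vs_cgi(calls$start[i], calls$end[i], cg$start, cg$end)
  }, character(1))
  data.frame(gene_id = calls$gene_id, start = calls$start, end = calls$end,
             motif_class = motif_class, cgi_relation = rel,
             region = as.character(
               promoter_region(tss_midpoint(calls$start, calls$end,
                                            unname(len)))),
             stringsAsFactors = FALSE)
}

#' Contingency table of CGI relation by motif class
#'
#' Builds the relation-by-class table (rows = motif classes such as di-STR /
#' tri-STR / PQS; columns = upstream / downstream / overlapped / intervened)
#' feeding the Fisher exact comparison of motif locations. Calls on
#' promoters without any CGI (`no_cgi`) carry no location information and
#' are excluded.
#'
#' @param str_calls STR call `data.frame` (split into di-/tri-STR by period).
#' @param pqs_calls PQS call `data.frame`.
#' @param cgi_calls CGI call `data.frame`.
#' @param promoters Promoter `data.frame`.
#' @return List: `table` — class x relation integer matrix; `records` — the
#'   underlying arrangement records; `fisher_p` — two-sided r x c Fisher
#'   exact p (`NA` with a message attribute when the table is degenerate).
#' @export
arrangement_table <- function(str_calls, pqs_calls, cgi_calls, promoters) {
  recs <- rbind(
    arrangement_records(str_calls[str_calls$period == 2L, , drop = FALSE],
                        cgi_calls, promoters, "di-STR"),
    arrangement_records(str_calls[str_calls$period == 3L, , drop = FALSE],
                        cgi_calls, promoters, "tri-STR"),
    arrangement_records(pqs_calls, cgi_calls, promoters, "PQS"))
  located <- recs[recs$cgi_relation != "no_cgi", , drop = FALSE]
  rels <- c("upstream", "downstream", "overlapped", "intervened")
  tab <- table(factor(located$motif_class,
                      levels = c("di-STR", "tri-STR", "PQS")),
               factor(located$cgi_relation, levels = rels))
  tab <- unclass(tab)
  used <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
  p <- if (nrow(used) < 2L || ncol(used) < 2L) {
    structure(NA_real_, message = "degenerate table, test skipped")
  } else {
    fisher_exact_rxc(used)$p_two_sided
  }
  list(table = tab, records = recs, fisher_p = p)
}

#' Positional profiles of trinucleotide repeats by GC class
#'
#' 100-bp-bin positional profiles of period-3 STR calls, one per GC class
#' (0/33/67/100%GC by the number of G or C in the repeat unit).
#'
#' @param tri_calls STR calls, all with `period == 3` (contract error
#'   otherwise).
#' @param promoters Promoter `data.frame`.
#' @param bin_width Bin width (default 100).
#' @return `data.frame` with `gc_class`, `bin_start_tss`, `bin_end_tss`,
#'   `count` (all four classes present, zero-filled).
#' @export
trinucleotide_gc_positions <- function(tri_calls, promoters, bin_width = 100L) {
  if (nrow(tri_calls) > 0L && any(tri_calls$period != 3L)) {
    stop("trinucleotide_gc_positions requires period-3 calls only")
  }
  classes <- c("0%GC", "33%GC", "67%GC", "100%GC")
  out <- lapply(classes, function(cl) {
    sub <- tri_calls[!is.na(tri_calls$gc_class) & tri_calls$gc_class == cl, ,
                     drop = FALSE]
    prof <- bin_positions(sub, promoters, bin_width)
    prof$gc_class <- cl
    prof
  })
  out <- do.call(rbind, out)
  out[, c("gc_class", "bin_start_tss", "bin_end_tss", "count")]
}

#' Pairwise co-occurrence tables of motif counts per promoter
#'
#' For each ordered pair of motif kinds, cross-tabulates presence/absence of
#' kind A against banded counts of kind B (bands 0 / 1 / >= 2 by default,
#' keeping expected cell counts usable at moderate sample sizes), with a
#' two-sided Fisher exact p per pair. Degenerate tables are skipped with a
#' message.
#'
#' @param counts `data.frame` with `gene_id` and one integer count column per
#'   motif kind (e.g. `CGI`, `STR`, `PQS`).
#' @param kinds Count columns to compare (default: all but `gene_id`).
#' @param bands Band upper edges for the count axis; default `c(0, 1)` gives
#'   bands 0, 1, >= 2.
#' @return `data.frame` with `presence_of`, `counts_of`, `p_two_sided`,
#'   `method`, `note`; the tables themselves in attribute `"tables"`.
#' @export
cooccurrence_table <- function(counts, kinds = setdiff(names(counts), "gene_id"),
                               bands = c(0L, 1L)) {
  band_of <- function(x) {
    labs <- c(as.character(bands), paste0(">=", bands[length(bands)] + 1L))
    cut(x, breaks = c(-Inf, bands, Inf), labels = labs)
  }
  res <- list()
  tabs <- list()
  for (a in kinds) for (b in setdiff(kinds, a)) {
    tab <- table(presence = factor(counts[[a]] > 0L, levels = c(FALSE, TRUE)),
                 band = band_of(counts[[b]]))
    tab <- unclass(tab)
    used <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
    key <- paste0(a, "_vs_", b)
    tabs[[key]] <- tab
    if (nrow(used) < 2L || ncol(used) < 2L) {
      res[[key]] <- data.frame(presence_of = a, counts_of = b,
                               p_two_sided = NA_real_, method = "none",
                               note = "degenerate table, test skipped",
                               stringsAsFactors = FALSE)
    } else {
      ft <- fisher_exact_rxc(used)
      res[[key]] <- data.frame(presence_of = a, counts_of = b,
                               p_two_sided = ft$p_two_sided,
                               method = ft$method, note = "",
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "tables") <- tabs
  out
}
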