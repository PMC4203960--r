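#' Read promoter sequences from a FASTA file
#'
#' Reads one promoter record per gene from a FASTA file and normalises the
#' sequences: uppercased, `U` mapped to `T`, and any character outside
#' `{A,C,G,T}` mapped to `N`. By convention each record is the 2 kb
#' immediately upstream of the transcription start site (TSS), written
#' 5'->3' on the gene's strand so that the last base is the base at TSS-relative
#' position -1.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species tag attached to every record.
#' @return A `data.frame` with columns `gene_id`, `species`, `seq`, `length`,
#'   one row per FASTA record, in file order. `gene_id` is the first
#'   whitespace-delimited token of the header.
#' @details Sequences shorter than 2,000 bp are accepted and analysed as-is
#'   (upstream extracts can be truncated at contig edges); a warning is issued.
#'   Duplicate gene ids are an error.
#' @export
read_promoter_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("no records in FASTA file: ", path)
  }
  ids <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_promoter_seq(as.character(recs))
  lens <- nchar(seqs)
  if (any(lens < 2000L)) {
    warning(sum(lens < 2000L), " promoter(s) shorter than 2000 bp; analysed as-is")
  }
  data.frame(gene_id = ids, species = species, seq = unname(seqs),
             length = lens, stringsAsFactors = FALSE)
}

#' Normalise a promoter sequence
#'
#' Uppercases, maps `U` to `T`, and maps every character outside `{A,C,G,T}`
#' (ambiguity codes, gaps, soft-masked leftovers) to `N`.
#'
#' @param seq Character vector of sequences.
#' @return Character vector over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_promoter_seq <- function(seq) {
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  gsub("[^ACGT]", "N", s)
}

#' Construct an in-memory promoter set
#'
#' Convenience constructor used by the synthetic generator and in tests:
#' builds the same `data.frame` that [read_promoter_fasta()] returns.
#'
#' @param seqs Named character vector (names = gene ids) or unnamed vector.
#' @param species Species tag.
#' @return Promoter `data.frame` (`gene_id`, `species`, `seq`, `length`).
#' @export
promoter_set <- function(seqs, species = NA_character_) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_along(seqs))
  seqs <- normalize_promoter_seq(unname(seqs))
  data.frame(gene_id = ids, species = species, seq = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a promoter set to FASTA
#'
#' @param promoters Promoter `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  lines <- character(2L * nrow(promoters))
  lines[c(TRUE, FALSE)] <- paste0(">", promoters$gene_id)
  lines[c(FALSE, TRUE)] <- promoters$seq
  writeLines(lines, path)
  invisible(path)
}

#' Convert promoter-relative coordinates to TSS-relative coordinates
#'
#' Intervals are held 1-based and closed (the usual R convention); this
#' converts them to TSS-relative, 0-based half-open positions in which the
#' TSS-adjacent base occupies `[-1, 0)` and the most distal base of a 2-kb
#' promoter occupies `[-2000, -1999)`. A 1-based closed interval
#' `[1970, 1978]` on a 2,000-bp promoter therefore maps to `(-31, -22)`,
#' i.e. it covers TSS-relative bases -31..-23 — the canonical TATA zone.
#'
#' @param start,end Integer vectors, 1-based closed interval bounds.
#' @param promoter_length Promoter length(s) in bp.
#' @return A `data.frame` with columns `tss_start`, `tss_end` (half-open).
#' @export
to_tss_coords <- function(start, end, promoter_length) {
  stopifnot(all(start >= 1L), all(end >= start), all(end <= promoter_length))
  data.frame(tss_start = start - 1L - promoter_length,
             tss_end = end - promoter_length)
}

#' Convert TSS-relative coordinates back to promoter-relative
#'
#' Exact inverse of [to_tss_coords()].
#'
#' @param tss_start,tss_end Half-open TSS-relative bounds.
#' @param promoter_length Promoter length(s) in bp.
#' @return A `data.frame` with 1-based closed columns `start`, `end`.
#' @export
from_tss_coords <- function(tss_start, tss_end, promoter_length) {
  start <- tss_start + promoter_length + 1L
  end <- tss_end + promoter_length
  stopifnot(all(start >= 1L), all(end >= start), all(end <= promoter_length))
  data.frame(start = start, end = end)
}

#' TSS-relative midpoint anchor of calls
#'
#' Midpoint base index (left-of-centre for even lengths) expressed as a
#' TSS-relative position in `[-length, -1]`.
#'
#' @param start,end 1-based closed bounds.
#' @param promoter_length Promoter length(s).
#' @return Integer vector of TSS-relative anchor positions.
#' @keywords internal
tss_midpoint <- function(start, end, promoter_length) {
  mid <- start + (end - start) %/% 2L
  mid - 1L - promoter_length
}

#' Write motif calls as BED6
#'
#' Emits one BED6 line per call: `chrom` = gene id, 0-based half-open
#' coordinates, `name` = scanner label (e.g. `"STR:AC:6"`), `score` = scanner
#' score (0 when none), `strand`. In `"tss"` mode both coordinates are shifted
#' by minus the promoter length so that the TSS sits at 0.
#'
#' @param calls A call `data.frame` with at least `gene_id`, `start`, `end`
#'   (1-based closed) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @param mode `"promoter"` (default) or `"tss"`.
#' @param promoter_lengths Named vector gene_id -> promoter length; required
#'   for `"tss"` mode.
#' @return `path`, invisibly. The file starts with a `#` header comment.
#' @export
write_bed <- function(calls, path, mode = c("promoter", "tss"),
                      promoter_lengths = NULL) {
  mode <- match.arg(mode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand", con)
  if (nrow(calls) == 0L) return(invisible(path))
  name <- if ("name" %in% names(calls)) calls$name else "."
  score <- if ("score" %in% names(calls)) calls$score else 0
  strand <- if ("strand" %in% names(calls)) calls$strand else "+"
  cs <- calls$start - 1L
  ce <- calls$end
  if (mode == "tss") {
    if (is.null(promoter_lengths)) stop("tss mode requires promoter_lengths")
    len <- unname(promoter_lengths[calls$gene_id])
    if (anyNA(len)) stop("calls reference unknown promoters")
    stopifnot(all(cs >= 0L), all(ce <= len))
    cs <- cs - len
    ce <- ce - len
  }
  ord <- order(calls$gene_id, cs, name)
  writeLines(paste(calls$gene_id, cs, ce, name, score, strand,
                   sep = "\t")[ord], con)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path BED path.
#' @return `data.frame` with `gene_id`, `start`, `end` (1-based closed),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("gene_id", "chromStart", "chromEnd",
                                       "name", "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character"))
  data.frame(gene_id = x$gene_id, start = x$chromStart + 1L, end = x$chromEnd,
             name = x$name, score = x$score, strand = x$strand,
             stringsAsFactors = FALSE)
}
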