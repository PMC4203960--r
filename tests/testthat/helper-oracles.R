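# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the package's vectorised code paths: character-by-
# character stepping, substring equality and exhaustive enumeration only.

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Lexicographic minimum over rotations of the unit and of its reverse
# complement, built by explicit string surgery.
oracle_canonical <- function(unit) {
  rots <- function(u) {
    n <- nchar(u)
    vapply(seq_len(n), function(i) {
      paste0(substring(u, i, n), substring(u, 1, i - 1))
    }, character(1))
  }
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", unit), "")[[1]]),
              collapse = "")
  min(c(rots(unit), rots(rc)))
}

oracle_is_primitive <- function(unit) {
  n <- nchar(unit)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && strrep(substr(unit, 1, d), n / d) == unit) return(FALSE)
  }
  TRUE
}

# Brute-force perfect-tandem-repeat scan: for every (start, period), step
# base-by-base to find the maximal perfect extension, keep left-maximal runs
# of primitive units with >= min_units complete units, then apply the
# greedy-left overlap policy.
oracle_scan_strs <- function(seq, min_units = 6, periods = 2:6) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cand <- list()
  for (p in periods) {
    for (i in seq_len(max(0, n - 2 * p + 1))) {
      # left-maximality in the lag-p sense
      if (i > 1 && ch[i - 1] == ch[i - 1 + p] && ch[i - 1] != "N") next
      t <- p
      while (i + t <= n && ch[i + t] == ch[i + t - p] && ch[i + t] != "N") {
        t <- t + 1
      }
      units <- t %/% p
      if (units < min_units) next
      unit <- paste(ch[i:(i + p - 1)], collapse = "")
      if (grepl("N", unit, fixed = TRUE)) next
      if (!oracle_is_primitive(unit)) next
      cand[[length(cand) + 1]] <- list(start = i, period = p,
                                       region_end = i + t - 1)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      units = integer(), canonical_motif = character(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(vapply(cand, `[[`, 1, "start"), vapply(cand, `[[`, 1, "period"))
  cand <- cand[ord]
  out <- list()
  last_end <- 0
  for (cc in cand) {
    s <- max(cc$start, last_end + 1)
    units <- (cc$region_end - s + 1) %/% cc$period
    if (units < min_units) next
    e <- s + units * cc$period - 1
    out[[length(out) + 1]] <- data.frame(
      start = s, end = e, period = cc$period, units = units,
      canonical_motif = oracle_canonical(paste(ch[s:(s + cc$period - 1)],
                                               collapse = "")),
      stringsAsFactors = FALSE)
    last_end <- max(last_end, e)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# Exhaustive G-quadruplex candidate search on short sequences: all equal-
# length tract quadruples checked by substring inspection.
oracle_pqs_candidates <- function(seq, max_len = 30, min_tetrad = 4,
                                  min_loop = 0) {
  n <- nchar(seq)
  out <- list()
  for (t in min_tetrad:max(min_tetrad, max_len %/% 4)) {
    if (4 * t + 3 * min_loop > max_len) break
    ok <- vapply(seq_len(max(0, n - t + 1)), function(i) {
      substr(seq, i, i + t - 1) == strrep("G", t)
    }, logical(1))
    starts <- which(ok)
    for (a1 in starts) for (a2 in starts) for (a3 in starts)
      for (a4 in starts) {
        if (a2 < a1 + t + min_loop || a3 < a2 + t + min_loop ||
            a4 < a3 + t + min_loop) next
        e <- a4 + t - 1
        if (e - a1 + 1 > max_len) next
        if (gsub("G", "", substr(seq, a1, e)) == "") next  # undisrupted poly-G
        out[[length(out) + 1]] <- c(a1, e, t, a1, a2, a3, a4)
      }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 7))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3], m[, 5], m[, 6], m[, 7]), , drop = FALSE]
}

# Kendall tau-b by explicit pair enumeration.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

make_promoters <- function(...) promoter_set(c(...))

# Plant a substring into AT background at a fixed position.
with_planted <- function(bg, insert, at) {
  substr(bg, at, at + nchar(insert) - 1) <- insert
  bg
}

at_background <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  random_dna(n, c(A = 0.5, C = 0, G = 0, T = 0.5))
}
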