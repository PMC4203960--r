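#' Bundled reference STR motif frequency tables
#'
#' Loads one of the avian promoter STR frequency tables shipped with the
#' package (canonical motif, call count, percent, per-sequence density).
#' The chicken table is also the default motif distribution of the synthetic
#' generator, so simulated frequency tables rank-correlate with it by
#' construction — useful to exercise, not to validate, the comparison code.
#'
#' @param species `"chicken"` or `"duck"`.
#' @return Frequency table `data.frame` (`motif`, `count`, `freq_percent`)
#'   with attribute `"str_per_seq"`.
#' @export
reference_frequency_table <- function(species = c("chicken", "duck")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_promoter_strs.tsv"),
                      package = "promoscan", mustWork = TRUE)
  read_frequency_table(path)
}

#' Configuration for the synthetic promoter generator
#'
#' Defaults describe a chicken-like promoter set: 2,000-bp promoters with a
#' linear background GC gradient rising toward the TSS (0.48 -> 0.57, overall
#' mean about 0.525), a TATA box planted at TSS-relative -31 in 10% of
#' promoters, STRs planted at 0.114 per promoter with motifs drawn from the
#' bundled chicken frequency table, CpG islands in half of the promoters,
#' and potential G-quadruplexes in 8%. Unit-count ranges follow the avian
#' pattern (tetra-/penta-/hexanucleotide repeats carry more units than
#' dinucleotide repeats).
#'
#' @param n_promoters Number of promoters.
#' @param length Promoter length in bp (default 2000).
#' @param seed Integer seed; one global stream drives every draw.
#' @param gc_start,gc_end Background GC fraction at the distal end / at the
#'   TSS (defaults 0.48, 0.57).
#' @param tata_rate Fraction of promoters with a planted TATA box (0.10).
#' @param tata_position TSS-relative start of the planted TATA box (-31).
#' @param str_rate Expected planted STRs per promoter (0.114).
#' @param str_motif_distribution Named probability vector canonical motif ->
#'   probability (default: bundled chicken table frequencies, renormalised).
#' @param str_unit_range Named list of `c(min, max)` unit counts per period
#'   class: `di`, `tri`, `tetra_plus`.
#' @param cgi_rate Fraction of promoters with a planted CpG island (0.5).
#' @param cgi_length_range `c(min, max)` planted island length (250-1000 bp;
#'   the upper tail populates the long-island LCGI class).
#' @param cpg_depletion Fraction of background CpG dinucleotides removed by a
#'   composition-preserving CG->GC swap (default 0.7, giving background
#'   O/E around 0.3 as in vertebrate DNA; 0 disables depletion).
#' @param cgi_cpg_prob Probability of emitting a CpG dinucleotide while
#'   building island sequence (0.2; the rest of the island is drawn with GC
#'   0.6, giving island GC ~0.7 and CpG O/E ~1.4-1.8).
#' @param pqs_rate Fraction of promoters with a planted G-quadruplex (0.08).
#' @param pqs_tetrad Planted G-tract length (4).
#' @param pqs_loop_range Planted loop length range (`c(1, 3)`).
#' @param n_go_terms Number of GO terms in the synthetic annotation (50).
#' @param term_prevalence Baseline term probability per gene (0.10).
#' @param planted_odds_ratio Odds multiplier tying one term to each planted
#'   motif kind (5).
#' @return Validated config list of class `"promoscan_sim_config"`.
#' @export
generator_config <- function(n_promoters = 1000L, length = 2000L, seed = 1L,
                             gc_start = 0.48, gc_end = 0.57,
                             tata_rate = 0.10, tata_position = -31L,
                             str_rate = 0.114,
                             str_motif_distribution = NULL,
                             str_unit_range = list(di = c(6L, 8L),
                                                   tri = c(6L, 7L),
                                                   tetra_plus = c(6L, 12L)),
                             cgi_rate = 0.5,
                             cgi_length_range = c(250L, 1000L),
                             cgi_cpg_prob = 0.2,
                             cpg_depletion = 0.7,
                             pqs_rate = 0.08, pqs_tetrad = 4L,
                             pqs_loop_range = c(1L, 3L),
                             n_go_terms = 50L, term_prevalence = 0.10,
                             planted_odds_ratio = 5) {
  if (is.null(str_motif_distribution)) {
    tab <- reference_frequency_table("chicken")
    str_motif_distribution <- stats::setNames(tab$count / sum(tab$count),
                                              tab$motif)
  }
  cfg <- list(n_promoters = as.integer(n_promoters),
              length = as.integer(length), seed = as.integer(seed),
              gc_start = gc_start, gc_end = gc_end,
              tata_rate = tata_rate, tata_position = as.integer(tata_position),
              str_rate = str_rate,
              str_motif_distribution = str_motif_distribution,
              str_unit_range = str_unit_range,
              cgi_rate = cgi_rate,
              cgi_length_range = as.integer(cgi_length_range),
              cgi_cpg_prob = cgi_cpg_prob,
              cpg_depletion = cpg_depletion,
              pqs_rate = pqs_rate, pqs_tetrad = as.integer(pqs_tetrad),
              pqs_loop_range = as.integer(pqs_loop_range),
              n_go_terms = as.integer(n_go_terms),
              term_prevalence = term_prevalence,
              planted_odds_ratio = planted_odds_ratio)
  rates <- c(cfg$tata_rate, cfg$str_rate, cfg$cgi_rate, cfg$pqs_rate,
             cfg$term_prevalence)
  stopifnot(all(rates >= 0), all(rates <= 1),
            abs(sum(cfg$str_motif_distribution) - 1) < 1e-8,
            cfg$gc_start > 0, cfg$gc_start < 1, cfg$gc_end > 0, cfg$gc_end < 1,
            cfg$length >= 200L, cfg$n_promoters >= 1L)
  class(cfg) <- "promoscan_sim_config"
  cfg
}

## Draw one background sequence with position-wise GC interpolated
## gc_start -> gc_end (distal -> TSS). Vertebrate background DNA is strongly
## CpG-depleted (O/E ~0.2-0.4) — the very fact the island criteria rely on —
## so a fraction of the CpG dinucleotides arising by chance is removed by
## swapping "CG" -> "GC", which preserves base composition (and hence the GC
## gradient) exactly.
draw_background <- function(len, gc_start, gc_end, cpg_depletion = 0.7) {
  gc <- gc_start + (gc_end - gc_start) * (seq_len(len) - 1) / (len - 1)
  is_gc <- stats::runif(len) < gc
  pick <- stats::runif(len) < 0.5
  b <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
  if (cpg_depletion > 0) {
    # a swap can recreate a CpG with its neighbours ("CCG" -> "CGC"), so the
    # pass is repeated until the CpG density reaches the depletion target
    n_cg0 <- sum(b[-len] == "C" & b[-1L] == "G")
    for (pass in 1:6) {
      cg <- which(b[-len] == "C" & b[-1L] == "G")
      if (length(cg) <= (1 - cpg_depletion) * n_cg0) break
      swap <- cg[stats::runif(length(cg)) < cpg_depletion]
      b[swap] <- "G"
      b[swap + 1L] <- "C"
    }
  }
  paste(b, collapse = "")
}

## Island sequence: with prob cpg_prob emit "CG", else one base at GC 0.6.
## Gives GC ~0.7 and CpG O/E ~1.5, comfortably above the calling criteria.
## Consecutive CpG emissions are capped at 3: real islands are CpG-dense but
## not perfect (CG)n tandem arrays, and uncapped runs would plant spurious
## dinucleotide repeats that belong to the STR scanner's domain.
draw_island_seq <- function(len, cpg_prob = 0.2) {
  is_cpg <- stats::runif(len) < cpg_prob
  pos_in_run <- stats::ave(as.integer(is_cpg), cumsum(!is_cpg), FUN = cumsum)
  is_cpg[is_cpg & pos_in_run > 3L] <- FALSE
  singles <- sample(c("G", "C", "A", "T"), len, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2))
  tok <- ifelse(is_cpg, "CG", singles)
  w <- cumsum(nchar(tok))
  k <- which(w >= len)[1L]
  s <- substr(paste(tok[seq_len(k)], collapse = ""), 1L, len)
  # break any incidental STR-grade tandem array (>= 6 units): islands are
  # CpG-dense, not perfect repeat arrays, and such runs would contaminate
  # the planted-STR ground truth
  for (attempt in 1:25) {
    runs <- scan_strs_one(s, min_units = 6L)
    if (nrow(runs) == 0L) break
    mid <- runs$start[1L] + (runs$end[1L] - runs$start[1L]) %/% 2L
    cur <- substr(s, mid, mid)
    substr(s, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  s
}

## Planted G4: four G-tracts separated by loops of non-G bases.
draw_pqs_seq <- function(tetrad, loop_range) {
  loops <- sample(seq.int(loop_range[1], loop_range[2]), 3L, replace = TRUE)
  loopseq <- vapply(loops, function(l) {
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(strrep("G", tetrad), loopseq[1], strrep("G", tetrad), loopseq[2],
         strrep("G", tetrad), loopseq[3], strrep("G", tetrad))
}

## Place an element of width w uniformly at random without overlapping any
## interval in `occupied` (matrix with columns start, end). NULL on failure.
place_element <- function(w, len, occupied, max_tries = 200L) {
  for (. in seq_len(max_tries)) {
    s <- sample.int(len - w + 1L, 1L)
    e <- s + w - 1L
    if (nrow(occupied) == 0L ||
        !any(occupied[, 1L] <= e & occupied[, 2L] >= s)) {
      return(c(s, e))
    }
  }
  NULL
}

#' Generate a synthetic promoter set with ground truth
#'
#' Draws `n_promoters` background sequences with the configured GC gradient,
#' plants TATA boxes, STRs, CpG islands and G-quadruplexes at the configured
#' rates (planting replaces background bases so every promoter keeps its
#' fixed length and coordinates stay comparable), and draws a synthetic
#' gene-to-GO-term annotation in which one term per motif kind is enriched at
#' the configured odds ratio among the genes bearing that kind. Fully
#' reproducible: one seed drives a single random stream.
#'
#' @param config A [generator_config()].
#' @return List with `promoters` (promoter `data.frame`), `truth`
#'   (`data.frame`: `gene_id`, `kind`, `start`, `end`, `detail`),
#'   `annotations` (`data.frame`: `gene_id`, `term`), `planted_terms`
#'   (named vector kind -> enriched term id) and `config`.
#' @export
generate_promoters <- function(config) {
  stopifnot(inherits(config, "promoscan_sim_config"))
  cfg <- config
  withr::local_seed(cfg$seed)
  len <- cfg$length
  seqs <- character(cfg$n_promoters)
  truth <- list()
  ids <- sprintf("g%05d", seq_len(cfg$n_promoters))
  motifs <- names(cfg$str_motif_distribution)
  for (i in seq_len(cfg$n_promoters)) {
    s <- draw_background(len, cfg$gc_start, cfg$gc_end, cfg$cpg_depletion)
    occupied <- matrix(integer(0), ncol = 2L)
    add <- function(kind, st, en, detail) {
      truth[[length(truth) + 1L]] <<-
        data.frame(gene_id = ids[i], kind = kind, start = st, end = en,
                   detail = detail, stringsAsFactors = FALSE)
      occupied <<- rbind(occupied, c(st, en))
    }
    if (stats::runif(1) < cfg$tata_rate) {
      tata <- "TATAAAA"
      st <- len + cfg$tata_position + 1L
      substr(s, st, st + nchar(tata) - 1L) <- tata
      add("TATA", st, st + nchar(tata) - 1L, tata)
    }
    if (stats::runif(1) < cfg$cgi_rate) {
      w <- sample.int(cfg$cgi_length_range[2] - cfg$cgi_length_range[1] + 1L,
                      1L) + cfg$cgi_length_range[1] - 1L
      isl <- draw_island_seq(w, cfg$cgi_cpg_prob)
      pos <- place_element(w, len, occupied)
      if (is.null(pos)) stop("cannot place planted CGI; lower the rates")
      substr(s, pos[1], pos[2]) <- isl
      add("CGI", pos[1], pos[2], sprintf("len=%d", w))
    }
    if (stats::runif(1) < cfg$str_rate) {
      m <- sample(motifs, 1L, prob = cfg$str_motif_distribution)
      p <- nchar(m)
      ur <- cfg$str_unit_range[[if (p == 2L) "di" else if (p == 3L) "tri"
                                else "tetra_plus"]]
      units <- sample(seq.int(ur[1], ur[2]), 1L)
      rep_seq <- strrep(m, units)
      pos <- place_element(nchar(rep_seq), len, occupied)
      if (is.null(pos)) stop("cannot place planted STR; lower the rates")
      substr(s, pos[1], pos[2]) <- rep_seq
      add("STR", pos[1], pos[2], sprintf("%s:%d", m, units))
    }
    if (stats::runif(1) < cfg$pqs_rate) {
      g4 <- draw_pqs_seq(cfg$pqs_tetrad, cfg$pqs_loop_range)
      pos <- place_element(nchar(g4), len, occupied)
      if (is.null(pos)) stop("cannot place planted PQS; lower the rates")
      substr(s, pos[1], pos[2]) <- g4
      add("PQS", pos[1], pos[2], sprintf("tetrad=%d", cfg$pqs_tetrad))
    }
    seqs[i] <- s
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), kind = character(), start = integer(),
               end = integer(), detail = character(), stringsAsFactors = FALSE)
  promoters <- data.frame(gene_id = ids, species = "synthetic", seq = seqs,
                          length = len, stringsAsFactors = FALSE)
  # synthetic GO annotation with one planted term per motif kind
  kinds <- c("STR", "PQS", "CGI", "TATA")
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  planted_terms <- stats::setNames(terms[seq_along(kinds)], kinds)
  p0 <- cfg$term_prevalence
  odds0 <- p0 / (1 - p0)
  p1 <- odds0 * cfg$planted_odds_ratio /
    (1 + odds0 * cfg$planted_odds_ratio)
  bearers <- lapply(kinds, function(k) unique(truth$gene_id[truth$kind == k]))
  names(bearers) <- kinds
  ann <- list()
  for (tm in terms) {
    prob <- rep(p0, cfg$n_promoters)
    k <- kinds[match(tm, planted_terms)]
    if (!is.na(k)) prob[ids %in% bearers[[k]]] <- p1
    has <- stats::runif(cfg$n_promoters) < prob
    if (any(has)) {
      ann[[length(ann) + 1L]] <- data.frame(gene_id = ids[has], term = tm,
                                            stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann)
  list(promoters = promoters, truth = truth, annotations = annotations,
       planted_terms = planted_terms, config = cfg)
}

#' Per-scanner background call rates of the generator
#'
#' Runs the generator with every planting rate set to zero and reports, per
#' scanner, the mean number of calls per promoter and an exact binomial
#' confidence interval on the fraction of promoters with at least one call.
#' Random background sequence spawns spurious calls (especially at high GC);
#' recovery analyses subtract these rates rather than suppressing them.
#'
#' @param config A [generator_config()]; its plant rates are zeroed here.
#' @param conf_level Confidence level (default 0.95).
#' @return `data.frame` with `scanner`, `mean_calls_per_promoter`,
#'   `presence_fraction`, `ci_lo`, `ci_hi`.
#' @export
background_rates <- function(config, conf_level = 0.95) {
  cfg <- config
  cfg$tata_rate <- 0; cfg$str_rate <- 0; cfg$cgi_rate <- 0; cfg$pqs_rate <- 0
  sim <- generate_promoters(cfg)
  n <- nrow(sim$promoters)
  count_of <- function(calls) table(factor(calls$gene_id,
                                           levels = sim$promoters$gene_id))
  scans <- list(STR = scan_strs(sim$promoters),
                CGI = scan_cgis(sim$promoters),
                PQS = scan_pqs(sim$promoters))
  out <- lapply(names(scans), function(nm) {
    cnt <- as.integer(count_of(scans[[nm]]))
    ci <- stats::binom.test(sum(cnt > 0L), n,
                            conf.level = conf_level)$conf.int
    data.frame(scanner = nm, mean_calls_per_promoter = mean(cnt),
               presence_fraction = mean(cnt > 0L),
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
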