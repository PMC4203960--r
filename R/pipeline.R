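#' Build a validated end-to-end run configuration
#'
#' Defaults are the conventional scan parameters: STRs with at least 6 units
#' at periods 2-6; CpG islands at window 100 / minimum length 200 / GC > 0.5
#' / O/E > 0.6 with an 800-bp LCGI cut; G-quadruplexes at span <= 30, tetrad
#' >= 4, loop >= 0; enrichment cutoff p < 0.01. Exactly one of `input_fasta`
#' or `simulate` must be given. Unknown keys in any parameter block are
#' rejected.
#'
#' @param input_fasta Path to a promoter FASTA, or `NULL` to simulate.
#' @param simulate Named list of [generator_config()] arguments, or `NULL`.
#' @param out_dir Output directory (created if missing), or `NULL` for an
#'   in-memory run.
#' @param seed Integer seed for every stochastic stage.
#' @param str,cgi,pqs,consensus,compare,enrichment Named lists overriding the
#'   per-stage defaults (see Details in the package vignette).
#' @return Config list of class `"promoscan_config"`.
#' @export
promoscan_config <- function(input_fasta = NULL, simulate = NULL,
                             out_dir = NULL, seed = 1L,
                             str = list(), cgi = list(), pqs = list(),
                             consensus = list(), compare = list(),
                             enrichment = list()) {
  if (is.null(input_fasta) == is.null(simulate)) {
    stop("give exactly one of input_fasta or simulate")
  }
  merge_block <- function(defaults, user, block) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      stop("unknown key(s) in ", block, " block: ", paste(bad, collapse = ", "))
    }
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    input_fasta = input_fasta, simulate = simulate, out_dir = out_dir,
    seed = as.integer(seed),
    str = merge_block(list(min_units = 6L, periods = 2:6), str, "str"),
    cgi = merge_block(list(window = 100L, min_len = 200L, gc_min = 0.5,
                           oe_min = 0.6, lcgi_threshold = 800L), cgi, "cgi"),
    pqs = merge_block(list(max_len = 30L, min_tetrad = 4L, min_loop = 0L),
                      pqs, "pqs"),
    consensus = merge_block(list(tata_pattern = "TATAWAW",
                                 distal_pattern = "CWGCWSWG",
                                 polypurine_min_run = 10L),
                            consensus, "consensus"),
    compare = merge_block(list(ref_tables = list(), prune = 0.10),
                          compare, "compare"),
    enrichment = merge_block(list(annotations = NULL, cutoff = 0.01,
                                  ease = FALSE),
                             enrichment, "enrichment"))
  stopifnot(cfg$str$min_units >= 2L, cfg$cgi$window > 0L,
            cfg$cgi$min_len > 0L, cfg$pqs$max_len > 0L,
            cfg$pqs$min_tetrad > 0L, cfg$enrichment$cutoff > 0)
  class(cfg) <- "promoscan_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [promoscan_config()]
#'   arguments.
#' @return A `"promoscan_config"`.
#' @export
promoscan_config_from_yaml <- function(path) {
  do.call(promoscan_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full promoter-motif analysis
#'
#' Orchestrates scan -> arrange -> compare -> enrich: scans the input (or
#' simulated) promoters for STRs, CpG islands, G-quadruplexes, TATA boxes,
#' the distal consensus and polypurine runs; builds the frequency table, GC
#' profile and 10-/100-bp positional bin profiles; classifies LCGI/NCGI
#' promoters, motif-vs-CGI arrangement and co-occurrence (with Fisher exact
#' tests); compares the frequency table against any supplied reference
#' tables; and, when an annotation table is configured, runs GO enrichment
#' on the four motif-defined gene groups. When `out_dir` is set, every table
#' is written as TSV (calls also as BED6) together with a machine-readable
#' JSON manifest (package version, parameters, seed, input checksum, output
#' checksums). Identical inputs and config give identical outputs.
#'
#' @param config A [promoscan_config()].
#' @return The result bundle (named list), invisibly when writing to disk.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "promoscan_config"))
  cfg <- config
  bundle <- list(config = cfg)
  input_md5 <- NULL
  if (!is.null(cfg$input_fasta)) {
    promoters <- stage("read", read_promoter_fasta(cfg$input_fasta))
    input_md5 <- unname(tools::md5sum(cfg$input_fasta))
  } else {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- stage("simulate", generate_promoters(do.call(generator_config,
                                                        sim_args)))
    promoters <- sim$promoters
    bundle$truth <- sim$truth
    bundle$sim_annotations <- sim$annotations
    bundle$planted_terms <- sim$planted_terms
  }
  bundle$promoters <- promoters
  n <- nrow(promoters)

  bundle$str_calls <- stage("scan-str",
    scan_strs(promoters, cfg$str$min_units, cfg$str$periods))
  bundle$cgi_calls <- stage("scan-cgi",
    scan_cgis(promoters, cfg$cgi$window, cfg$cgi$min_len, cfg$cgi$gc_min,
              cfg$cgi$oe_min))
  bundle$pqs_calls <- stage("scan-pqs",
    scan_pqs(promoters, cfg$pqs$max_len, cfg$pqs$min_tetrad,
             cfg$pqs$min_loop))
  bundle$tata_hits <- stage("scan-consensus",
    scan_iupac(promoters, cfg$consensus$tata_pattern, "TATA",
               both_strands = FALSE))
  bundle$distal_hits <- stage("scan-consensus",
    scan_iupac(promoters, cfg$consensus$distal_pattern, "distal_consensus"))
  bundle$polyA <- stage("scan-consensus",
    scan_polypurine(promoters, "A", cfg$consensus$polypurine_min_run))
  bundle$polyG <- stage("scan-consensus",
    scan_polypurine(promoters, "G", cfg$consensus$polypurine_min_run))

  bundle$frequency_table <- stage("frequency",
    str_frequency_table(bundle$str_calls, n))
  bundle$gc <- stage("gc-profile", gc_profile(promoters))
  bundle$str_bins10 <- stage("bins",
    bin_positions(bundle$str_calls, promoters, 10L))
  bundle$pqs_bins10 <- stage("bins",
    bin_positions(bundle$pqs_calls, promoters, 10L))
  bundle$tata_profile <- stage("bins",
    tata_positional_profile(bundle$tata_hits, promoters))
  bundle$cgi_classes <- stage("cgi-classes",
    classify_cgi_promoters(promoters, bundle$cgi_calls,
                           cfg$cgi$lcgi_threshold))
  bundle$arrangement <- stage("arrange",
    arrangement_table(bundle$str_calls, bundle$pqs_calls, bundle$cgi_calls,
                      promoters))
  bundle$tri_gc_bins <- stage("arrange",
    trinucleotide_gc_positions(
      bundle$str_calls[bundle$str_calls$period == 3L, , drop = FALSE],
      promoters))
  counts <- data.frame(
    gene_id = promoters$gene_id,
    CGI = as.integer(table(factor(bundle$cgi_calls$gene_id,
                                  levels = promoters$gene_id))),
    STR = as.integer(table(factor(bundle$str_calls$gene_id,
                                  levels = promoters$gene_id))),
    PQS = as.integer(table(factor(bundle$pqs_calls$gene_id,
                                  levels = promoters$gene_id))),
    stringsAsFactors = FALSE)
  bundle$motif_counts <- counts
  bundle$cooccurrence <- stage("cooccurrence", cooccurrence_table(counts))

  if (length(cfg$compare$ref_tables)) {
    bundle$comparisons <- stage("compare", {
      do.call(rbind, lapply(names(cfg$compare$ref_tables), function(nm) {
        ref <- cfg$compare$ref_tables[[nm]]
        if (is.character(ref)) ref <- read_frequency_table(ref)
        cmp <- compare_frequency_tables(ref, bundle$frequency_table,
                                        cfg$compare$prune)
        cbind(data.frame(reference = nm, stringsAsFactors = FALSE), cmp)
      }))
    })
  }

  ann <- cfg$enrichment$annotations
  if (is.null(ann) && !is.null(bundle$sim_annotations)) {
    ann <- bundle$sim_annotations
  }
  if (!is.null(ann)) {
    bundle$enrichment <- stage("enrich", {
      if (is.character(ann)) {
        ann <- utils::read.table(ann, sep = "\t", header = TRUE,
                                 colClasses = "character")
      }
      groups <- assign_motif_groups(bundle$str_calls, bundle$pqs_calls,
                                    bundle$cgi_classes)
      groups <- groups[lengths(groups) > 0L]
      go_enrichment(groups, ann, promoters$gene_id,
                    cutoff = cfg$enrichment$cutoff, ease = cfg$enrichment$ease)
    })
  }

  if (!is.null(cfg$out_dir)) {
    write_bundle(bundle, cfg$out_dir, input_md5)
    return(invisible(bundle))
  }
  bundle
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## Write every bundle table plus a deterministic JSON manifest.
write_bundle <- function(bundle, out_dir, input_md5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  lens <- stats::setNames(bundle$promoters$length, bundle$promoters$gene_id)
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    paths <<- c(paths, p)
  }
  emit(bundle$str_calls, "str_calls.tsv")
  write_bed(bundle$str_calls, file.path(out_dir, "str_calls.bed"))
  emit(bundle$cgi_calls, "cgi_calls.tsv")
  write_bed(bundle$cgi_calls, file.path(out_dir, "cgi_calls.bed"))
  emit(bundle$pqs_calls, "pqs_calls.tsv")
  write_bed(bundle$pqs_calls, file.path(out_dir, "pqs_calls.bed"))
  emit(bundle$tata_hits, "tata_hits.tsv")
  emit(bundle$distal_hits, "distal_consensus_hits.tsv")
  emit(bundle$polyA, "polyA_runs.tsv")
  emit(bundle$polyG, "polyG_runs.tsv")
  ft <- bundle$frequency_table
  write_frequency_table(ft, file.path(out_dir, "str_frequency_table.tsv"))
  paths <- c(paths, file.path(out_dir, "str_frequency_table.tsv"),
             file.path(out_dir, "str_calls.bed"),
             file.path(out_dir, "cgi_calls.bed"),
             file.path(out_dir, "pqs_calls.bed"))
  emit(bundle$gc$profile, "gc_profile.tsv")
  emit(bundle$str_bins10, "str_bins_10bp.tsv")
  emit(bundle$pqs_bins10, "pqs_bins_10bp.tsv")
  emit(bundle$tata_profile, "tata_positions.tsv")
  emit(bundle$cgi_classes, "cgi_promoter_classes.tsv")
  emit(as.data.frame(bundle$arrangement$table), "arrangement_table.tsv")
  emit(bundle$arrangement$records, "arrangement_records.tsv")
  emit(bundle$tri_gc_bins, "trinucleotide_gc_bins.tsv")
  emit(bundle$motif_counts, "motif_counts.tsv")
  emit(bundle$cooccurrence, "cooccurrence_tests.tsv")
  if (!is.null(bundle$comparisons)) emit(bundle$comparisons, "comparisons.tsv")
  if (!is.null(bundle$enrichment)) {
    emit(bundle$enrichment$records, "enrichment_records.tsv")
    emit(as.data.frame(bundle$enrichment$matrix), "enrichment_matrix.tsv")
  }
  if (!is.null(bundle$truth)) emit(bundle$truth, "truth.tsv")
  manifest <- list(
    tool = "promoscan",
    version = as.character(utils::packageVersion("promoscan")),
    seed = cfg$seed,
    parameters = cfg[c("str", "cgi", "pqs", "consensus", "compare",
                       "enrichment")],
    n_promoters = nrow(bundle$promoters),
    input_md5 = input_md5,
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(paths))),
                                      basename(sort(paths)))))
  manifest$parameters$compare$ref_tables <-
    names(cfg$compare$ref_tables)
  manifest$parameters$enrichment$annotations <-
    if (is.character(cfg$enrichment$annotations))
      cfg$enrichment$annotations else NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Human-readable summary of a pipeline result bundle
#'
#' A pure function of the bundle: two renders of the same bundle are
#' byte-identical.
#'
#' @param bundle Result of [run_all()].
#' @return Character vector of report lines, invisibly; also printed with
#'   `cat` when `print = TRUE`.
#' @param print Print the report to the console (default `TRUE`).
#' @export
report_bundle <- function(bundle, print = TRUE) {
  n <- nrow(bundle$promoters)
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  genes_with <- function(calls) length(unique(calls$gene_id))
  cls <- bundle$cgi_classes
  top_arr <- sort(table(bundle$arrangement$records$cgi_relation),
                  decreasing = TRUE)
  lines <- c(
    "promoscan run summary",
    sprintf("promoters: %d (mean GC %s)", n,
            pct(bundle$gc$overall_mean_gc)),
    sprintf("STR calls: %d (%s of genes with >=1 STR; %.3f per sequence)",
            nrow(bundle$str_calls), pct(genes_with(bundle$str_calls) / n),
            attr(bundle$frequency_table, "str_per_seq")),
    sprintf("CGI calls: %d (%s of genes with CGI; LCGI %d, NCGI %d)",
            nrow(bundle$cgi_calls), pct(genes_with(bundle$cgi_calls) / n),
            sum(cls$label == "LCGI"), sum(cls$label == "NCGI")),
    sprintf("PQS calls: %d (%s of genes)", nrow(bundle$pqs_calls),
            pct(genes_with(bundle$pqs_calls) / n)),
    sprintf("TATA hits: %d (%s of genes)", nrow(bundle$tata_hits),
            pct(genes_with(bundle$tata_hits) / n)),
    if (length(top_arr)) {
      sprintf("arrangement classes (motifs vs CGI): %s",
              paste(sprintf("%s=%d", names(top_arr), as.integer(top_arr)),
                    collapse = ", "))
    },
    if (!is.null(bundle$enrichment)) {
      sig <- bundle$enrichment$records
      sprintf("significant GO terms (p < cutoff): %d across %d group(s)",
              sum(sig$significant), length(unique(sig$group[sig$significant])))
    })
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
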