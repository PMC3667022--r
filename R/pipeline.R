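# umbrella pipeline: simulate -> count -> rpkm -> dge -> enrich -> ssr -> orf

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Defaults are the
#' standard analysis cutoffs: FDR 0.001 with |log2 ratio| >= 1 for
#' differential expression, alpha 0.05 for enrichment, microsatellites of at
#' least 5 repetitions of 2-6 bp units, coding at CDS > 300 bp, and read
#' assignment with at most 2 mismatches. When no input FASTA is supplied the
#' pipeline simulates its own ground-truthed inputs at desk scale.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @param fasta optional unigene FASTA; `NULL` simulates instead.
#' @param reads1,reads2 optional FASTA/FASTQ read files for the two libraries.
#' @param term_map optional term-map TSV/GMT path.
#' @param sim named list overriding [synthetic_spec()] arguments, plus
#'   `n_reads_per_lib`, `read_length`, `error_rate` for read emission.
#' @param ... scalar overrides for analysis parameters: `k`, `max_mismatch`,
#'   `fdr`, `lfc`, `alpha`, `correction`, `ssr_min_repeats`, `min_cds_bp`,
#'   `min_flank_bp`, `min_product_bp`.
#' @return a named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, fasta = NULL, reads1 = NULL,
                            reads2 = NULL, term_map = NULL, sim = list(),
                            ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), fasta = fasta,
              reads1 = reads1, reads2 = reads2, term_map = term_map,
              sim = modifyList(list(n_unigenes = 150L,
                                    library_sizes = c(8000, 8000),
                                    n_reads_per_lib = 8000L,
                                    read_length = 75L, error_rate = 0.005),
                               sim),
              k = 21L, max_mismatch = 2L, fdr = 0.001, lfc = 1,
              alpha = 0.05, correction = "bonferroni",
              ssr_min_repeats = 5L, min_cds_bp = 300L,
              min_flank_bp = 50L, min_product_bp = 150L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, dots)
  for (p in c("fasta", "reads1", "reads2", "term_map")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input path does not exist: ", cfg[[p]], " (", p, ")")
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML or key=value file
#'
#' @param path configuration file; YAML, or plain `key=value` lines.
#' @param out_dir fallback output directory when the file does not set one.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = "txmine_out") {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(f) utils::type.convert(trimws(f[2]),
                                                       as.is = TRUE))
    setNames(vals, vapply(kv, function(f) trimws(f[1]), character(1)))
  }
  raw$out_dir <- raw$out_dir %||% out_dir
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no FASTA is supplied), read counting, RPKM,
#' two-library differential expression, term enrichment, microsatellite
#' detection/selection and ORF triage, writing one TSV per stage plus a JSON
#' manifest (file paths, md5 checksums, parameter echo, seed and per-stage
#' row counts). Reruns with an identical configuration reproduce the outputs
#' byte for byte.
#'
#' @param config a [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  rowcounts <- list()
  truth <- NULL

  if (is.null(config$fasta)) {
    sim_args <- config$sim
    sim_args$n_reads_per_lib <- NULL
    sim_args$read_length <- NULL
    sim_args$error_rate <- NULL
    spec <- stage("simulate", do.call(synthetic_spec,
                                      c(sim_args, list(seed = config$seed))))
    sim <- stage("simulate", generate_unigenes(spec))
    unigenes <- sim$unigenes
    truth <- sim$truth
    write_fasta(unigenes, out("unigenes.fasta"))
    write_tsv(truth$genes, out("truth_genes.tsv"))
    files <- c(files, unigenes = out("unigenes.fasta"),
               truth_genes = out("truth_genes.tsv"))
    g <- truth$genes
    reads1 <- stage("simulate", generate_reads(
      unigenes, config$sim$n_reads_per_lib, config$sim$read_length,
      config$sim$error_rate, weights = g$length * g$expr1,
      seed = config$seed + 11L))
    reads2 <- stage("simulate", generate_reads(
      unigenes, config$sim$n_reads_per_lib, config$sim$read_length,
      config$sim$error_rate, weights = g$length * g$expr2,
      seed = config$seed + 12L))
    write_fastq(setNames(reads1$seq, reads1$read_id), out("reads_lib1.fastq"))
    write_fastq(setNames(reads2$seq, reads2$read_id), out("reads_lib2.fastq"))
    files <- c(files, reads1 = out("reads_lib1.fastq"),
               reads2 = out("reads_lib2.fastq"))
    term_map <- stage("simulate", generate_term_map(spec, sim))
    write_tsv(term_map, out("term_map.tsv"))
    files <- c(files, term_map = out("term_map.tsv"))
  } else {
    unigenes <- stage("load", read_fasta(config$fasta))
    reads1 <- data.frame(read_id = character(0), seq = character(0))
    reads2 <- reads1
    if (!is.null(config$reads1)) {
      r1 <- stage("load", read_reads(config$reads1))
      reads1 <- data.frame(read_id = names(r1), seq = unname(r1))
    }
    if (!is.null(config$reads2)) {
      r2 <- stage("load", read_reads(config$reads2))
      reads2 <- data.frame(read_id = names(r2), seq = unname(r2))
    }
    term_map <- if (!is.null(config$term_map)) {
      stage("load", read_term_map(config$term_map))
    } else NULL
  }

  dge <- NULL
  have_reads <- nrow(reads1) > 0 && nrow(reads2) > 0
  if (have_reads) {
    index <- stage("count", build_kmer_index(unigenes, k = config$k))
    c1 <- stage("count", count_reads(reads1, index,
                                     max_mismatch = config$max_mismatch))
    c2 <- stage("count", count_reads(reads2, index,
                                     max_mismatch = config$max_mismatch))
    write_counts_tsv(c1, out("counts_lib1.tsv"))
    write_counts_tsv(c2, out("counts_lib2.tsv"))
    files <- c(files, counts1 = out("counts_lib1.tsv"),
               counts2 = out("counts_lib2.tsv"))

    r1 <- stage("rpkm", rpkm_table(c1, unigenes))
    r2 <- stage("rpkm", rpkm_table(c2, unigenes))
    write_tsv(r1, out("rpkm_lib1.tsv"))
    write_tsv(r2, out("rpkm_lib2.tsv"))
    files <- c(files, rpkm1 = out("rpkm_lib1.tsv"),
               rpkm2 = out("rpkm_lib2.tsv"))

    dge <- stage("dge", dge_table(c1, c2, unigenes, fdr_cutoff = config$fdr,
                                  lfc_cutoff = config$lfc))
    write_tsv(dge$table, out("dge.tsv"))
    files <- c(files, dge = out("dge.tsv"))
    rowcounts$dge_significant <- unname(dge$summary["total"])
  }

  if (!is.null(dge) && !is.null(term_map) && nrow(term_map)) {
    de_ids <- dge$table$unigene_id[dge$table$direction != "not_significant"]
    de_ids <- intersect(de_ids, term_map$unigene_id)
    enr <- stage("enrich", enrich(de_ids, term_map,
                                  correction = config$correction,
                                  alpha = config$alpha))
    write_tsv(enr, out("enrichment.tsv"))
    files <- c(files, enrichment = out("enrichment.tsv"))
    rowcounts$enriched_terms <- sum(enr$significant)
  }

  loci <- stage("ssr", detect_ssrs(unigenes,
                                   min_repeats = config$ssr_min_repeats))
  write_tsv(loci, out("ssr_loci.tsv"))
  markers <- stage("ssr", select_marker_loci(
    loci, unigenes, min_flank_bp = config$min_flank_bp,
    min_product_bp = config$min_product_bp))
  write_tsv(markers, out("ssr_markers.tsv"))
  non_ambig <- sum(nchar(gsub("[^ACGT]", "", unigenes)))
  summ <- stage("ssr", summarize_ssrs(loci, non_ambig))
  write_tsv(summ, out("ssr_summary.tsv"))
  files <- c(files, ssr_loci = out("ssr_loci.tsv"),
             ssr_markers = out("ssr_markers.tsv"),
             ssr_summary = out("ssr_summary.tsv"))
  rowcounts$ssr_loci <- nrow(loci)

  orfs <- stage("orf", classify_coding(unigenes,
                                       min_cds_bp = config$min_cds_bp))
  write_tsv(orfs, out("orf_calls.tsv"))
  files <- c(files, orfs = out("orf_calls.tsv"))
  rowcounts$coding_unigenes <- sum(orfs$coding)

  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("out_dir", "fasta", "reads1", "reads2",
                                  "term_map"))],
    files = as.list(files),
    md5 = as.list(tools::md5sum(unname(files))),
    rows = rowcounts,
    n_unigenes = length(unigenes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message("pipeline complete: ", length(files), " outputs in ", config$out_dir)
  invisible(manifest)
}
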