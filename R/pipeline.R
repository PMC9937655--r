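#' Run the full target-identification pipeline
#'
#' Orchestrates the analysis end to end: obtain counts (simulated or read
#' from TSV), FPKM-normalize, fit the four pairwise contrasts, call DETs,
#' classify genes by CHX resistance, scan direct-target promoters for the
#' DR4 element, build the consensus motif, and (when an annotation is
#' supplied) run over-representation analysis. All intermediates are
#' persisted as TSV so any stage can be re-entered with external data, and
#' a JSON summary records every parameter and headline count.
#'
#' The configuration is a named list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{synth}{arguments to \code{\link{sim_config}} — used when no
#'     \code{inputs} block is given.}
#'   \item{inputs}{paths \code{counts}, \code{conditions}, \code{lengths},
#'     and optionally \code{promoters} (FASTA) and \code{annotation} (TSV
#'     with term_id, gene_id).}
#'   \item{thresholds}{\code{lfc} (default 1), \code{padj} (default 0.05),
#'     \code{budget} (default 4), \code{window} (default 5000),
#'     \code{strands} ("both").}
#' }
#'
#' @param config named list or YAML file path.
#' @param outdir output directory for artifacts.
#' @param seed optional master seed overriding the config's.
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json} in \code{outdir}).
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  th <- config$thresholds
  lfc_min <- th$lfc %||% 1
  padj_max <- th$padj %||% 0.05
  budget <- th$budget %||% 4
  window <- th$window %||% 5000
  strands <- th$strands %||% "both"
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logf, append = TRUE)
  log_line("thresholds: lfc", lfc_min, "padj", padj_max,
           "budget", budget, "window", window, "strands", strands)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL; promoters <- NULL; annotation <- NULL
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    cm <- stage("ingest", read_count_matrix(inp$counts, inp$conditions,
                                            inp$lengths))
    if (!is.null(inp$promoters)) promoters <- read_fasta(inp$promoters)
    if (!is.null(inp$annotation))
      annotation <- utils::read.table(inp$annotation, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
    master_seed <- seed %||% 0L
  } else {
    sargs <- config$synth %||% list()
    if (!is.null(seed)) sargs$seed <- seed
    scfg <- stage("synth", do.call(sim_config, sargs))
    master_seed <- scfg$seed
    sim <- stage("synth", simulate_experiment(scfg))
    cm <- sim$matrix; truth <- sim$truth; promoters <- sim$promoters
    write_simulation(sim, outdir)
  }
  log_line("counts:", nrow(cm$counts), "genes x", ncol(cm$counts), "samples,",
           "seed", master_seed)

  fp <- stage("fpkm", fpkm(cm))
  utils::write.table(data.frame(gene_id = rownames(fp), fp,
                                check.names = FALSE),
                     file.path(outdir, "fpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  contrasts <- list(
    TH_vs_control = c("control", "TH"),
    TH_CHX_vs_CHX = c("CHX", "TH_CHX"),
    CHX_vs_control = c("control", "CHX"),
    TH_CHX_vs_control = c("control", "TH_CHX"))
  results <- lapply(names(contrasts), function(nm) {
    cr <- stage(nm, fit_contrast(cm, contrasts[[nm]][1], contrasts[[nm]][2]))
    utils::write.table(cr, file.path(outdir, paste0("contrast_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cr
  })
  names(results) <- names(contrasts)

  dets <- lapply(results, call_dets, lfc_min = lfc_min, padj_max = padj_max)
  for (nm in names(dets))
    utils::write.table(dets[[nm]], file.path(outdir, paste0("dets_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  cls <- stage("classify", classify_targets(
    dets$TH_vs_control, dets$TH_CHX_vs_CHX, dets$CHX_vs_control))
  utils::write.table(cls, file.path(outdir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_by_label <- label_counts(cls)
  venn <- overlap_counts(dets$TH_vs_control, dets$TH_CHX_vs_CHX)
  report <- direct_target_report(cls, results$TH_vs_control,
                                 results$TH_CHX_vs_CHX)
  utils::write.table(report, file.path(outdir, "direct_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  consensus <- NULL; n_hits <- 0L
  direct_ids <- cls$gene_id[cls$label %in% c("direct_up", "direct_down")]
  if (!is.null(promoters) && length(direct_ids) > 0) {
    scfg2 <- scan_config(max_mismatch = budget, window_bp = window,
                         strands = strands)
    hits <- stage("tre_scan", scan_set(
      promoters[names(promoters) %in% direct_ids], scfg2,
      mode = "best_per_gene"))
    write_hits_bed(hits, file.path(outdir, "tre_hits.bed"))
    n_hits <- nrow(hits)
    clean <- hits$matched_seq[!grepl("N", hits$matched_seq)]
    if (length(clean) > 0) {
      motif <- stage("motif", build_motif(clean))
      write_motif_matrix(motif, file.path(outdir, "motif_counts.tsv"))
      consensus <- motif$consensus
    }
  } else {
    log_line("TRE/consensus stage skipped:",
             if (is.null(promoters)) "no promoters" else "no direct genes")
  }

  enrichment_terms <- NULL
  if (!is.null(annotation)) {
    universe <- results$TH_vs_control$gene_id[
      !is.na(results$TH_vs_control$padj)]
    enr <- stage("enrich", ora(dets$TH_vs_control$gene_id, annotation,
                               universe, q_max = padj_max))
    utils::write.table(enr, file.path(outdir, "enrichment_TH_vs_control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enrichment_terms <- sum(enr$significant)
  }

  summary <- list(
    seed = master_seed,
    parameters = list(lfc_min = lfc_min, padj_max = padj_max,
                      budget = budget, window = window, strands = strands),
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    dets_per_contrast = lapply(dets, nrow),
    label_counts = as.list(counts_by_label),
    venn_focal = venn,
    n_tre_hits = n_hits,
    consensus = consensus,
    n_significant_terms = enrichment_terms)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  log_line("done")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
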