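#' Simulation configuration for the four-condition TH/CHX design
#'
#' Defines a synthetic experiment mirroring the study design this package
#' targets: four treatment groups (control, TH, CHX, TH_CHX) with replicate
#' tadpole pools, gene classes with known regulatory behaviour, and promoter
#' sequences carrying planted DR4 thyroid response elements.
#'
#' Gene classes and their planted expression rules:
#' \itemize{
#'   \item \code{direct_up} / \code{direct_down}: respond to TH by
#'     \code{+/- effect_lfc} (log2) both with and without CHX, i.e. in
#'     TH-vs-control and in TH_CHX-vs-CHX. These carry a planted TRE.
#'   \item \code{late}: respond to TH only when translation is permitted
#'     (TH-vs-control only); blocked by CHX.
#'   \item \code{chx_response}: shifted by \code{+effect_lfc} in every
#'     CHX-containing condition, mimicking the rapid transcriptional
#'     upregulation cycloheximide itself induces.
#'   \item \code{null}: constant across all four conditions.
#' }
#'
#' @param n_genes number of genes.
#' @param n_reps_per_condition replicates per condition (study design: 4).
#' @param class_fractions named numeric vector with entries \code{direct_up},
#'   \code{direct_down}, \code{late}, \code{chx_response}, each in [0,1],
#'   summing to at most 1; the remainder are null genes.
#' @param effect_lfc magnitude of the planted log2 fold change.
#' @param dispersion negative-binomial dispersion alpha, with
#'   \code{var = mu + alpha * mu^2} (shared across genes).
#' @param mean_log_range length-2 numeric: natural-log bounds of the
#'   log-uniform baseline mean distribution.
#' @param gene_length_range length-2 integer: uniform bounds of transcript
#'   lengths in bp.
#' @param promoter_length promoter window length in bp (default 5000,
#'   the upstream window used for TRE scanning).
#' @param planted_mismatches number of mismatches (0-4) introduced into each
#'   planted TRE, only at the 12 half-site positions.
#' @param seed master integer seed; counts and promoters draw from separate
#'   streams derived from it, so changing one output does not perturb the other.
#' @return An object of class \code{SimConfig}.
#' @export
sim_config <- function(n_genes = 1000,
                       n_reps_per_condition = 4,
                       class_fractions = c(direct_up = 0.02, direct_down = 0.01,
                                           late = 0.05, chx_response = 0.10),
                       effect_lfc = 3,
                       dispersion = 0.1,
                       mean_log_range = c(log(20), log(2000)),
                       gene_length_range = c(500L, 6000L),
                       promoter_length = 5000L,
                       planted_mismatches = 0L,
                       seed = 1L) {
  class_fractions <- unlist(class_fractions)
  mean_log_range <- unlist(mean_log_range)
  gene_length_range <- unlist(gene_length_range)
  needed <- c("direct_up", "direct_down", "late", "chx_response")
  if (!all(needed %in% names(class_fractions)))
    stop("class_fractions must name: ", paste(needed, collapse = ", "))
  class_fractions <- class_fractions[needed]
  if (any(class_fractions < 0) || sum(class_fractions) > 1)
    stop("class fractions must be non-negative and sum to at most 1")
  if (n_genes < 1 || n_reps_per_condition < 1)
    stop("n_genes and n_reps_per_condition must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (mean_log_range[1] > mean_log_range[2] ||
      gene_length_range[1] > gene_length_range[2])
    stop("ranges must satisfy low <= high")
  if (promoter_length < 16) stop("promoter_length must be at least 16 bp")
  if (planted_mismatches < 0 || planted_mismatches > 4)
    stop("planted_mismatches must be in 0..4")
  structure(
    list(n_genes = as.integer(n_genes),
         n_reps_per_condition = as.integer(n_reps_per_condition),
         class_fractions = class_fractions,
         effect_lfc = effect_lfc,
         dispersion = dispersion,
         mean_log_range = mean_log_range,
         gene_length_range = as.integer(gene_length_range),
         promoter_length = as.integer(promoter_length),
         planted_mismatches = as.integer(planted_mismatches),
         seed = as.integer(seed)),
    class = "SimConfig"
  )
}

# Deterministic class assignment: exact counts by rounding down fractions,
# genes assigned in order so fraction arithmetic is auditable.
sim_class_labels <- function(config) {
  n <- config$n_genes
  k <- floor(config$class_fractions * n)
  rep(c(names(k), "null"), times = c(k, n - sum(k)))
}

#' Simulate counts for the four-condition design
#'
#' Draws a negative-binomial count matrix (\code{var = mu + alpha mu^2})
#' around condition means determined by each gene's class (see
#' \code{\link{sim_config}}) and returns it together with the ground truth.
#'
#' @param config a \code{SimConfig}.
#' @return A list with elements \code{matrix} (a \code{\link{count_matrix}}
#'   with conditions control, TH, CHX, TH_CHX) and \code{truth}, a data frame
#'   with one row per gene: \code{gene_id}, \code{class}, true log2 fold
#'   changes for the three informative contrasts, and (after
#'   \code{\link{generate_promoters}}) the planted TRE position, strand and
#'   sequence.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  nr <- config$n_reps_per_condition
  classes <- sim_class_labels(config)
  gene_id <- sprintf("gene%05d", seq_len(n))
  mu0 <- exp(stats::runif(n, config$mean_log_range[1], config$mean_log_range[2]))
  gene_length <- as.integer(round(stats::runif(
    n, config$gene_length_range[1], config$gene_length_range[2])))

  L <- config$effect_lfc
  # per-contrast true log2 fold changes by class
  lfc_th <- ifelse(classes == "direct_up", L,
            ifelse(classes == "direct_down", -L,
            ifelse(classes == "late", L, 0)))
  lfc_thchx <- ifelse(classes == "direct_up", L,
               ifelse(classes == "direct_down", -L, 0))
  lfc_chx <- ifelse(classes == "chx_response", L, 0)

  # condition means; TH_CHX mean = CHX baseline times the CHX-resistant effect
  mu_ctrl <- mu0
  mu_th <- mu0 * 2^lfc_th
  mu_chx <- mu0 * 2^lfc_chx
  mu_thchx <- mu_chx * 2^lfc_thchx

  conds <- c("control", "TH", "CHX", "TH_CHX")
  mu_mat <- cbind(mu_ctrl, mu_th, mu_chx, mu_thchx)
  size <- 1 / config$dispersion
  counts <- matrix(0L, n, 4 * nr)
  for (ci in seq_along(conds)) {
    for (r in seq_len(nr)) {
      counts[, (ci - 1) * nr + r] <-
        stats::rnbinom(n, mu = mu_mat[, ci], size = size)
    }
  }
  colnames(counts) <- paste0(rep(conds, each = nr), "_", seq_len(nr))
  rownames(counts) <- gene_id
  cm <- count_matrix(counts, rep(conds, each = nr), gene_length)
  truth <- data.frame(
    gene_id = gene_id, class = classes,
    lfc_th_vs_ctrl = lfc_th, lfc_thchx_vs_chx = lfc_thchx,
    lfc_chx_vs_ctrl = lfc_chx,
    tre_pos = NA_integer_, tre_strand = NA_character_,
    tre_seq = NA_character_,
    stringsAsFactors = FALSE)
  list(matrix = cm, truth = truth)
}

# one planted DR4 element: pattern with `n_mm` substitutions confined to the
# 12 half-site positions; spacer (N) positions drawn uniformly.
plant_tre <- function(pattern_chars, n_mm) {
  bases <- c("A", "C", "G", "T")
  el <- pattern_chars
  n_pos <- which(el == "N")
  el[n_pos] <- sample(bases, length(n_pos), replace = TRUE)
  if (n_mm > 0) {
    half <- which(pattern_chars != "N")
    mm_at <- sample(half, n_mm)
    for (i in mm_at) el[i] <- sample(setdiff(bases, el[i]), 1)
  }
  paste(el, collapse = "")
}

#' Simulate promoter sequences with planted TREs
#'
#' Generates one uniform-random promoter per gene; promoters of direct-target
#' genes receive exactly one planted 16-mer matching the DR4 pattern at no
#' more than \code{planted_mismatches} mismatches (introduced only at the 12
#' half-site positions), on a randomly chosen strand. Planted positions are
#' 0-based on the forward coordinate system.
#'
#' @param truth ground-truth data frame from \code{\link{generate_counts}}.
#' @param config the same \code{SimConfig}.
#' @param pattern degenerate element to plant (default the DR4 TRE).
#' @return A list: \code{promoters}, a named \code{Biostrings::DNAStringSet}
#'   (one record per gene), and \code{truth}, the input truth with
#'   \code{tre_pos}, \code{tre_strand}, \code{tre_seq} filled for direct genes.
#' @export
generate_promoters <- function(truth, config, pattern = "AGGTCANNNNAGGTCA") {
  stopifnot(inherits(config, "SimConfig"))
  if (config$promoter_length < nchar(pattern))
    stop("promoter_length shorter than the planted element")
  # separate stream from the count stream
  set.seed(config$seed + 1L)
  bases <- c("A", "C", "G", "T")
  plen <- config$promoter_length
  k <- nchar(pattern)
  pat_chars <- strsplit(pattern, "")[[1]]
  n <- nrow(truth)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, plen, replace = TRUE), collapse = ""), "")
  direct <- which(truth$class %in% c("direct_up", "direct_down"))
  for (i in direct) {
    el <- plant_tre(pat_chars, config$planted_mismatches)
    strand <- sample(c("+", "-"), 1)
    pos <- if (plen == k) 0L else sample.int(plen - k + 1L, 1) - 1L
    ins <- if (strand == "+") el else revcomp_str(el)
    s <- seqs[i]
    seqs[i] <- paste0(substr(s, 1, pos), ins, substr(s, pos + k + 1, plen))
    truth$tre_pos[i] <- pos
    truth$tre_strand[i] <- strand
    truth$tre_seq[i] <- el
  }
  proms <- Biostrings::DNAStringSet(seqs)
  names(proms) <- truth$gene_id
  list(promoters = proms, truth = truth)
}

#' Run the full simulator
#'
#' Convenience wrapper: counts, ground truth and promoters from one config.
#'
#' @param config a \code{SimConfig}.
#' @return list with \code{matrix}, \code{truth}, \code{promoters}.
#' @export
simulate_experiment <- function(config) {
  cg <- generate_counts(config)
  pg <- generate_promoters(cg$truth, config)
  list(matrix = cg$matrix, truth = pg$truth, promoters = pg$promoters)
}

#' Write simulated data to a directory
#'
#' Persists counts/conditions/lengths TSVs, promoters FASTA and the
#' ground-truth TSV.
#'
#' @param sim output of \code{\link{simulate_experiment}}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(sim$matrix, dir)
  Biostrings::writeXStringSet(sim$promoters, file.path(dir, "promoters.fasta"))
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
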