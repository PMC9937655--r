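#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-sample fold changes of a target gene relative to a reference
#' (internal control) gene, calibrated against a calibrator group:
#' \deqn{\Delta Ct_s = Ct_{target,s} - Ct_{ref,s}}
#' \deqn{\Delta\Delta Ct_s = \Delta Ct_s - \mathrm{mean}(\Delta Ct
#'   \mathrm{\ over\ calibrator\ samples})}
#' \deqn{fold_s = 2^{-\Delta\Delta Ct_s}}
#' Calibrator ddCt is centered on the arithmetic mean of the calibrator
#' samples' dCt (a geometric mean on the linear scale), so the calibrator
#' group's geometric-mean fold change is 1 by construction.
#'
#' @param records data frame with columns \code{sample_id}, \code{group},
#'   \code{gene_id}, \code{ct}; one row per (sample, gene).
#' @param target target gene id.
#' @param reference reference (internal control) gene id, measured in every
#'   sample.
#' @param calibrator_group group label used as calibrator (e.g. "control").
#' @return A list: \code{samples}, a data frame (\code{sample_id},
#'   \code{group}, \code{dct}, \code{ddct}, \code{fold}); and \code{groups},
#'   per-group mean fold change with SEM.
#' @export
ddct_fold_change <- function(records, target, reference, calibrator_group) {
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  if (any(records$ct <= 0)) stop("Ct values must be positive")
  if (anyDuplicated(records[records$gene_id %in% c(target, reference),
                            c("sample_id", "gene_id")]))
    stop("each (sample, gene) pair may appear only once")
  tgt <- records[records$gene_id == target, ]
  ref <- records[records$gene_id == reference, ]
  if (nrow(tgt) == 0) stop("target gene not found: ", target)
  i <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(i))
    stop("reference gene missing for sample(s): ",
         paste(tgt$sample_id[is.na(i)], collapse = ", "))
  dct <- tgt$ct - ref$ct[i]
  cal <- tgt$group == calibrator_group
  if (!any(cal)) stop("calibrator group is empty: ", calibrator_group)
  ddct <- dct - mean(dct[cal])
  fold <- 2^(-ddct)
  samples <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                        dct = dct, ddct = ddct, fold = fold,
                        stringsAsFactors = FALSE, row.names = NULL)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(g)
    data.frame(group = g$group[1], n = nrow(g), mean_fold = mean(g$fold),
               sem_fold = sem(g$fold), stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  list(samples = samples, groups = groups)
}

#' One-way ANOVA on per-sample fold changes
#'
#' Routine group-significance companion to \code{\link{ddct_fold_change}};
#' delegates to \code{stats::aov}.
#'
#' @param samples the \code{samples} data frame from
#'   \code{\link{ddct_fold_change}}.
#' @return The ANOVA p-value for a group effect on fold change.
#' @export
qpcr_anova <- function(samples) {
  fit <- stats::aov(fold ~ group, data = samples)
  summary(fit)[[1]][["Pr(>F)"]][1]
}
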