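#' Classify genes by cycloheximide resistance of their TH response
#'
#' The core inference: a gene whose TH response survives translation
#' blockade needs no intermediate protein synthesis and is a direct
#' TR target. Combining the DET sets of the two focal contrasts
#' (TH vs control; TH_CHX vs CHX) and the CHX-vs-control contrast:
#' \itemize{
#'   \item \code{direct_up}: up in both focal sets;
#'   \item \code{direct_down}: down in both focal sets;
#'   \item \code{late}: in TH-vs-control but absent from TH_CHX-vs-CHX
#'     (TH-responsive only when translation is permitted);
#'   \item \code{chx_response}: in CHX-vs-control but not in TH-vs-control;
#'   \item \code{null}: everything else.
#' }
#' A gene present in both focal sets with opposite directions is not
#' direct; it keeps its fall-through label and is flagged
#' \code{discordant}. Direction concordance is required because genes
#' "commonly upregulated"/"commonly downregulated" across the two
#' comparisons are what defines the direct class.
#'
#' @param th_vs_ctrl \code{DETSet} for TH vs control.
#' @param thchx_vs_chx \code{DETSet} for TH_CHX vs CHX.
#' @param chx_vs_ctrl optional \code{DETSet} for CHX vs control; when NULL
#'   no gene is labeled \code{chx_response}.
#' @return A \code{TargetClassification} data frame, one row per universe
#'   gene: \code{gene_id}, \code{label}, membership flags \code{in_th},
#'   \code{in_thchx}, \code{in_chx}, directions \code{dir_th},
#'   \code{dir_thchx}, and \code{discordant}.
#' @export
classify_targets <- function(th_vs_ctrl, thchx_vs_chx, chx_vs_ctrl = NULL) {
  u1 <- sort(attr(th_vs_ctrl, "universe"))
  u2 <- sort(attr(thchx_vs_chx, "universe"))
  if (!identical(u1, u2)) stop("DET sets come from different gene universes")
  if (!is.null(chx_vs_ctrl) &&
      !identical(sort(attr(chx_vs_ctrl, "universe")), u1))
    stop("DET sets come from different gene universes")
  universe <- u1

  dir_th <- th_vs_ctrl$direction[match(universe, th_vs_ctrl$gene_id)]
  dir_thchx <- thchx_vs_chx$direction[match(universe, thchx_vs_chx$gene_id)]
  in_th <- !is.na(dir_th)
  in_thchx <- !is.na(dir_thchx)
  in_chx <- if (is.null(chx_vs_ctrl)) rep(FALSE, length(universe))
            else universe %in% chx_vs_ctrl$gene_id

  concordant <- in_th & in_thchx & dir_th == dir_thchx
  discordant <- in_th & in_thchx & dir_th != dir_thchx

  label <- rep("null", length(universe))
  label[in_chx & !in_th] <- "chx_response"
  label[in_th & !in_thchx] <- "late"
  label[concordant & dir_th == "up"] <- "direct_up"
  label[concordant & dir_th == "down"] <- "direct_down"

  res <- data.frame(
    gene_id = universe, label = label,
    in_th = in_th, in_thchx = in_thchx, in_chx = in_chx,
    dir_th = dir_th, dir_thchx = dir_thchx,
    discordant = discordant,
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("TargetClassification", "data.frame")
  res
}

#' Direction-aware overlap of two DET sets
#'
#' Counts for the Venn comparison of two contrasts. Shared membership
#' requires direction agreement; genes present in both sets with opposite
#' directions are counted in both "only" tallies and reported separately.
#'
#' @param a,b \code{DETSet}s over the same universe.
#' @return A list: \code{n_a_only}, \code{n_shared_same_direction},
#'   \code{n_b_only}, \code{n_discordant}.
#' @export
overlap_counts <- function(a, b) {
  genes <- union(a$gene_id, b$gene_id)
  dir_a <- a$direction[match(genes, a$gene_id)]
  dir_b <- b$direction[match(genes, b$gene_id)]
  in_a <- !is.na(dir_a); in_b <- !is.na(dir_b)
  shared <- in_a & in_b & dir_a == dir_b
  disc <- in_a & in_b & dir_a != dir_b
  list(n_a_only = sum(in_a & (!in_b | disc)),
       n_shared_same_direction = sum(shared),
       n_b_only = sum(in_b & (!in_a | disc)),
       n_discordant = sum(disc))
}

#' Tabulate classification labels
#'
#' @param classification a \code{TargetClassification}.
#' @return Named integer vector of label counts over
#'   \{direct_up, direct_down, late, chx_response, null\}.
#' @export
label_counts <- function(classification) {
  lv <- c("direct_up", "direct_down", "late", "chx_response", "null")
  tab <- table(factor(classification$label, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Report direct targets with their statistics in both focal contrasts
#'
#' Builds the publication-style table of direct targets: one row per gene
#' labeled direct, with log2 fold change and adjusted p-value from each
#' focal contrast and optional annotation pass-through.
#'
#' @param classification a \code{TargetClassification}.
#' @param th_result,thchx_result the two focal \code{ContrastResult}s.
#' @param annotation optional data frame with \code{gene_id} plus columns to
#'   carry through (e.g. symbol, description).
#' @return Data frame sorted with upregulated genes first.
#' @export
direct_target_report <- function(classification, th_result, thchx_result,
                                 annotation = NULL) {
  d <- classification[classification$label %in% c("direct_up", "direct_down"), ]
  i1 <- match(d$gene_id, th_result$gene_id)
  i2 <- match(d$gene_id, thchx_result$gene_id)
  out <- data.frame(
    gene_id = d$gene_id, label = d$label,
    log2fc_th_vs_ctrl = th_result$log2fc[i1],
    q_th_vs_ctrl = th_result$padj[i1],
    log2fc_thchx_vs_chx = thchx_result$log2fc[i2],
    q_thchx_vs_chx = thchx_result$padj[i2],
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation))
    out <- merge(out, annotation, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[order(out$label == "direct_down", out$gene_id), ]
}
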