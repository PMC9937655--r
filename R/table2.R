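#' Load the published direct-target table
#'
#' The package ships the published list of 45 TH direct response genes
#' (39 upregulated, 6 downregulated) with their log2 fold change and
#' adjusted p-value in the two focal contrasts (TH vs control and TH_CHX vs
#' CHX). It serves as the worked example for the classification chain: the
#' printed statistics, pushed through \code{\link{call_dets}} and
#' \code{\link{classify_targets}}, reproduce the published class counts.
#'
#' @return Data frame: \code{gene_id}, \code{annotation}, \code{symbol},
#'   \code{log2fc_th_vs_ctrl}, \code{q_th_vs_ctrl},
#'   \code{log2fc_thchx_vs_chx}, \code{q_thchx_vs_chx}.
#' @export
th_direct_table <- function() {
  path <- system.file("extdata", "table2_direct_targets.tsv",
                      package = "thtargets", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' The worked-example contrasts from the published direct-target table
#'
#' Splits \code{\link{th_direct_table}} into the two focal
#' \code{ContrastResult}-shaped tables (gene_id, log2fc, padj) ready for
#' \code{\link{call_dets}}.
#'
#' @return list with elements \code{th_vs_ctrl} and \code{thchx_vs_chx}.
#' @export
th_direct_contrasts <- function() {
  t2 <- th_direct_table()
  mk <- function(lfc, q, name) {
    r <- data.frame(gene_id = t2$gene_id, log2fc = lfc, padj = q,
                    stringsAsFactors = FALSE)
    attr(r, "contrast") <- name
    r
  }
  list(th_vs_ctrl = mk(t2$log2fc_th_vs_ctrl, t2$q_th_vs_ctrl, "TH_vs_control"),
       thchx_vs_chx = mk(t2$log2fc_thchx_vs_chx, t2$q_thchx_vs_chx,
                         "TH_CHX_vs_CHX"))
}
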