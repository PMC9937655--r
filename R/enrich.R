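#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a DE gene set in a
#' gene universe. With universe size N, DE total K, term size n (after
#' intersecting the term's genes with the universe) and overlap k, the
#' p-value is the upper-tail hypergeometric probability P(X >= k), adjusted
#' across all tested terms by Benjamini-Hochberg.
#'
#' @param de_genes character vector of DE gene ids (must lie in the universe).
#' @param annotation data frame with columns \code{term_id}, \code{gene_id}
#'   and optionally \code{term_name}.
#' @param universe character vector: the gene universe (typically all genes
#'   with a defined adjusted p-value in the focal contrast).
#' @param q_max significance cutoff on the BH-adjusted value (default 0.05).
#' @param weights optional per-gene weights (reserved hook for length-bias
#'   correction; currently ignored with a warning if supplied).
#' @return Data frame, one row per term with at least one universe gene:
#'   \code{term_id}, \code{term_name} (if given), \code{term_size},
#'   \code{overlap}, \code{universe_size}, \code{de_total}, \code{pvalue},
#'   \code{qvalue}, \code{significant}; sorted by ascending qvalue then
#'   pvalue then term_id.
#' @export
ora <- function(de_genes, annotation, universe, q_max = 0.05, weights = NULL) {
  if (!all(c("term_id", "gene_id") %in% names(annotation)))
    stop("annotation needs columns term_id and gene_id")
  missing <- setdiff(de_genes, universe)
  if (length(missing))
    stop("DE genes absent from universe: ", paste(missing, collapse = ", "))
  if (!is.null(weights))
    warning("per-gene weights are accepted but not yet used; ",
            "running the unweighted hypergeometric test")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, intersect(c("term_id", "gene_id"), names(ann))])
  if (nrow(ann) == 0)
    return(data.frame(term_id = character(0), term_size = integer(0),
                      overlap = integer(0), universe_size = integer(0),
                      de_total = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), significant = logical(0)))
  N <- length(unique(universe))
  K <- length(unique(de_genes))
  term_genes <- split(ann$gene_id, ann$term_id)
  n <- vapply(term_genes, length, 0L)
  k <- vapply(term_genes, function(g) sum(g %in% de_genes), 0L)
  pvalue <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  qvalue <- bh_adjust(pvalue)
  out <- data.frame(term_id = names(term_genes), term_size = n,
                    overlap = k, universe_size = N, de_total = K,
                    pvalue = pvalue, qvalue = qvalue,
                    significant = qvalue < q_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("term_name" %in% names(annotation)) {
    nm <- annotation$term_name[match(out$term_id, annotation$term_id)]
    out <- cbind(out[, "term_id", drop = FALSE], term_name = nm,
                 out[, -1, drop = FALSE])
  }
  out[order(out$qvalue, out$pvalue, out$term_id), ]
}
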