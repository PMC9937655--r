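#' Negative-binomial Wald test between two conditions
#'
#' Differential expression for one pairwise contrast under the
#' negative-binomial model \code{var = mu + alpha mu^2}. The procedure:
#' \enumerate{
#'   \item median-of-ratios size factors over the samples of the two
#'     conditions (geometric-mean reference over genes observed in every
#'     sample);
#'   \item per-gene dispersion by method of moments on normalized counts
#'     pooled within conditions, floored at 1e-8;
#'   \item dispersion sharing: a parametric trend
#'     \code{alpha(mu) = a0 + a1/mu} is fitted across genes and each gene
#'     uses the maximum of its own and the trended dispersion — the sharing
#'     rule classical NB differential-expression tools apply so that the
#'     noisy per-gene moment estimate at small replicate numbers does not
#'     make the test anti-conservative;
#'   \item \code{log2fc = log2((mean_b + 0.5)/(mean_a + 0.5))} on the
#'     normalized scale (pseudo-count 0.5 keeps zero-mean genes finite);
#'   \item Wald statistic \code{log2fc / SE} with the delta-method standard
#'     error from the NB variance, two-sided normal p-value;
#'   \item Benjamini-Hochberg adjustment over genes with defined p-values.
#' }
#' Genes with zero counts in every sample of both conditions get
#' \code{log2fc = 0} and missing p-values, and are excluded from the
#' Benjamini-Hochberg denominator.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param cond_a reference condition label (denominator of the fold change).
#' @param cond_b test condition label (numerator).
#' @return A \code{ContrastResult} data frame: \code{gene_id},
#'   \code{base_mean} (mean normalized count over both conditions),
#'   \code{log2fc}, \code{pvalue}, \code{padj}; attribute \code{contrast}
#'   is \code{"<cond_b>_vs_<cond_a>"}.
#' @export
fit_contrast <- function(x, cond_a, cond_b) {
  stopifnot(inherits(x, "CountMatrix"))
  for (cc in c(cond_a, cond_b))
    if (!cc %in% x$condition) stop("unknown condition: ", cc)
  sel <- x$condition %in% c(cond_a, cond_b)
  counts <- x$counts[, sel, drop = FALSE]
  cond <- x$condition[sel]
  na <- sum(cond == cond_a); nb <- sum(cond == cond_b)
  if (na < 2 || nb < 2)
    stop("each condition needs at least 2 replicates to estimate dispersion")

  k <- sweep(counts, 2, size_factors(counts), "/")
  a <- cond == cond_a; b <- cond == cond_b
  mA <- rowMeans(k[, a, drop = FALSE]); mB <- rowMeans(k[, b, drop = FALSE])
  vA <- apply(k[, a, drop = FALSE], 1, stats::var)
  vB <- apply(k[, b, drop = FALSE], 1, stats::var)
  vpool <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
  mpool <- (na * mA + nb * mB) / (na + nb)
  alpha <- ifelse(mpool > 0, pmax((vpool - mpool) / mpool^2, 1e-8), 1e-8)

  # share dispersion through a parametric trend; per-gene max keeps the test
  # honest where the 6-df moment estimate happens to undershoot
  use <- mpool > 0 & alpha > 1e-8
  if (sum(use) >= 10) {
    fit <- tryCatch(stats::lm(alpha[use] ~ I(1 / mpool[use])),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      alpha <- pmax(alpha, pmax(co[1] + co[2] / mpool, 1e-8), na.rm = TRUE)
    }
  }

  c0 <- 0.5
  log2fc <- log2((mB + c0) / (mA + c0))
  varA <- (mA + alpha * mA^2) / na
  varB <- (mB + alpha * mB^2) / nb
  se <- sqrt(varA / (mA + c0)^2 + varB / (mB + c0)^2) / log(2)
  z <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(z))

  allzero <- rowSums(counts) == 0
  log2fc[allzero] <- 0
  pvalue[allzero] <- NA_real_
  pvalue[!allzero & se == 0] <- 1  # constant non-zero gene: no evidence

  res <- data.frame(
    gene_id = rownames(counts),
    base_mean = mpool,
    log2fc = log2fc,
    pvalue = pvalue,
    padj = bh_adjust(pvalue),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- paste0(cond_b, "_vs_", cond_a)
  res
}

# median-of-ratios size factors (geometric-mean reference over genes with
# counts in every sample); falls back to depth ratios on degenerate input
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  gm <- exp(rowMeans(lg))
  ok <- is.finite(gm) & gm > 0 & !apply(counts == 0, 1, any)
  if (sum(ok) >= 1) {
    sf <- apply(counts[ok, , drop = FALSE], 2,
                function(cj) stats::median(cj / gm[ok]))
    if (all(is.finite(sf)) && all(sf > 0)) return(sf)
  }
  cs <- colSums(counts)
  cs / exp(mean(log(cs)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Missing values pass through untouched and do not
#' count toward the number of tests.
#'
#' @param pvalues numeric vector in [0,1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  fin <- pvalues[!is.na(pvalues)]
  if (any(fin < 0 | fin > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed transcripts
#'
#' Applies the DET filter: a gene is called iff \code{|log2fc| >= lfc_min}
#' (inclusive) and \code{padj < padj_max} (strict) and \code{padj} is
#' defined. Direction is the sign of \code{log2fc}.
#'
#' @param result a \code{ContrastResult} (or any data frame with
#'   \code{gene_id}, \code{log2fc}, \code{padj}).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param padj_max adjusted-p cutoff, strict (default 0.05).
#' @return A \code{DETSet}: data frame \code{gene_id}, \code{direction}
#'   ("up"/"down"), with attributes \code{universe} (all gene ids tested,
#'   i.e. with defined padj) and \code{contrast}.
#' @export
call_dets <- function(result, lfc_min = 1, padj_max = 0.05) {
  if (lfc_min <= 0 || padj_max <= 0) stop("thresholds must be positive")
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(result)))
    stop("result must have columns: ", paste(need, collapse = ", "))
  keep <- !is.na(result$padj) &
    abs(result$log2fc) >= lfc_min & result$padj < padj_max
  det <- data.frame(
    gene_id = result$gene_id[keep],
    direction = ifelse(result$log2fc[keep] > 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(det, "universe") <- result$gene_id[!is.na(result$padj)]
  attr(det, "contrast") <- attr(result, "contrast")
  class(det) <- c("DETSet", "data.frame")
  det
}

#' Construct a DETSet directly
#'
#' Used when DE calls come from an external table rather than
#' \code{\link{call_dets}}.
#'
#' @param gene_id character vector of called genes.
#' @param direction "up"/"down" per gene.
#' @param universe full gene universe the calls were made in.
#' @param contrast optional contrast name.
#' @return A \code{DETSet}.
#' @export
det_set <- function(gene_id, direction, universe, contrast = NA_character_) {
  if (anyDuplicated(gene_id)) stop("a gene may appear at most once")
  if (!all(direction %in% c("up", "down"))) stop("direction must be up/down")
  if (!all(gene_id %in% universe)) stop("called genes must lie in the universe")
  det <- data.frame(gene_id = gene_id, direction = direction,
                    stringsAsFactors = FALSE)
  attr(det, "universe") <- universe
  attr(det, "contrast") <- contrast
  class(det) <- c("DETSet", "data.frame")
  det
}
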