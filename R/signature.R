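# Disease-signature construction: TPM, an internal differential-expression
# stand-in, DEG filtering at the |log2FC| > 2 / padj < 0.05 thresholds,
# log2FC-descending ranking, hypergeometric over-representation and BH
# adjustment.

#' Compute transcripts per million (TPM)
#'
#' Per sample: \code{rate_g = count_g / (length_g / 1000)};
#' \code{TPM_g = rate_g / sum(rate) * 1e6}. Each column sums to one
#' million unless the sample has no counts at all.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param lengths Per-gene transcript/feature length in bp (> 0), in row
#'   order or named by gene.
#' @return Matrix of TPM values, same dimensions as \code{counts}.
#' @examples
#' compute_tpm(matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'             c(a = 1000, b = 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("'lengths' must match the number of genes", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1  # leaves the column all-zero
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Internal two-group differential expression
#'
#' A lightweight stand-in for a full negative-binomial GLM fit: library
#' sizes are normalized by median-of-ratios size factors, the log2 fold
#' change is computed from group means of normalized counts with a 0.5
#' pseudocount, and the p-value comes from a Welch (unequal-variance)
#' t-test on log2(normalized + 1). Adjusted p-values are Benjamini-
#' Hochberg. This is an approximation adequate for signature ranking, not
#' a DESeq2 clone; supply an external DE table via \code{\link{read_de_csv}}
#' when a shrinkage-based fit is wanted.
#'
#' Genes with zero counts in every sample are reported with
#' \code{log2fc = 0, p = 1} and are excluded from multiple-testing
#' (\code{tested = FALSE}).
#'
#' @param counts Gene x sample count matrix.
#' @param groups Character vector (or named vector aligned to columns) with
#'   exactly two levels.
#' @param disease Label of the group treated as numerator of the fold
#'   change; default is the second level in sorted order (so
#'   "control"/"disease" works out of the box).
#' @return A \code{data.frame} with columns \code{gene, log2fc, p, padj,
#'   base_mean, tested}.
#' @export
internal_de <- function(counts, groups, disease = NULL) {
  if (!is.null(names(groups)) && !is.null(colnames(counts))) {
    groups <- groups[colnames(counts)]
  }
  if (length(groups) != ncol(counts)) {
    stop("'groups' must label every sample", call. = FALSE)
  }
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  disease <- disease %||% lv[2]
  control <- setdiff(lv, disease)
  if (min(table(groups)) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  if (any(counts != round(counts))) warning("non-integer counts supplied")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  d <- groups == disease
  m_dis <- rowMeans(norm[, d, drop = FALSE])
  m_ctl <- rowMeans(norm[, !d, drop = FALSE])
  log2fc <- log2((m_dis + 0.5) / (m_ctl + 0.5))

  lg <- log2(norm + 1)
  p <- welch_p(lg[, d, drop = FALSE], lg[, !d, drop = FALSE])
  tested <- rowSums(counts) > 0
  log2fc[!tested] <- 0
  p[!tested] <- 1
  padj <- rep(1, length(p))
  padj[tested] <- bh_adjust(p[tested])
  data.frame(gene = rownames(counts), log2fc = log2fc, p = p, padj = padj,
             base_mean = rowMeans(norm), tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Median-of-ratios size factors (reference = geometric mean over samples of
# genes expressed everywhere). Falls back to library-size scaling when no
# gene is all-positive.
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    warning("no gene expressed in all samples; using library-size factors")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  apply(counts[ok, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - loggeo[ok]))
  })
}

# Vectorized Welch two-sample t-test p-values over matrix rows.
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  # zero variance in both groups: identical -> 1, separated -> ~0
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Filter differentially expressed genes
#'
#' DEG calls use strict thresholds: upregulated when
#' \code{log2fc > lfc_thresh} and \code{padj < alpha}; downregulated when
#' \code{log2fc < -lfc_thresh} and \code{padj < alpha}.
#'
#' @param records DE table (\code{gene, log2fc, padj}).
#' @param lfc_thresh Positive log2 fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with \code{up} and \code{down} \code{\link{gene_set}}s
#'   (NULL when empty).
#' @export
filter_degs <- function(records, lfc_thresh = 2, alpha = 0.05) {
  stopifnot(lfc_thresh > 0, alpha > 0)
  up <- records$gene[records$log2fc > lfc_thresh & records$padj < alpha]
  down <- records$gene[records$log2fc < -lfc_thresh & records$padj < alpha]
  list(up = if (length(up)) gene_set("up_degs", up) else NULL,
       down = if (length(down)) gene_set("down_degs", down) else NULL)
}

new_ranked_signature <- function(gene, score) {
  if (anyDuplicated(gene)) stop("duplicate gene ids", call. = FALSE)
  ord <- order(-score, gene, method = "radix")
  structure(data.frame(gene = gene[ord], score = score[ord],
                       direction = ifelse(score[ord] >= 0, "up", "down"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ranked_signature", "data.frame"))
}

#' Rank genes into a disease signature
#'
#' Orders genes by log2 fold change, descending; ties are broken
#' lexicographically by gene id so the ranking is reproducible regardless
#' of input order.
#'
#' @param records DE table (\code{gene, log2fc}; optionally \code{tested}).
#' @param expressed_only Drop genes never observed (\code{tested == FALSE});
#'   default TRUE.
#' @return A \code{ranked_signature} data frame with columns
#'   \code{gene, score, direction}.
#' @export
rank_signature <- function(records, expressed_only = TRUE) {
  if (expressed_only && "tested" %in% names(records)) {
    records <- records[records$tested, , drop = FALSE]
  }
  new_ranked_signature(records$gene, records$log2fc)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a query gene set and an annotation set within a finite
#' universe — the standard over-representation analysis behind GO-term
#' enrichment of a DEG list.
#'
#' @param query Query \code{gene_set} (e.g. upregulated DEGs); must be
#'   contained in \code{universe}.
#' @param annotation Annotation \code{gene_set} (e.g. one GO term).
#' @param universe Character vector of all considered gene ids.
#' @return List with \code{overlap} and \code{p} =
#'   P(X >= overlap | Hypergeom(|universe|, |annotation ∩ universe|,
#'   |query|)).
#' @export
ora_hypergeometric <- function(query, annotation, universe) {
  q <- as_members(query)
  a <- intersect(as_members(annotation), universe)
  universe <- unique(as.character(universe))
  if (!all(q %in% universe)) {
    stop("query must be contained in the universe", call. = FALSE)
  }
  if (length(a) == 0L) {
    stop("annotation does not intersect the universe", call. = FALSE)
  }
  k <- length(intersect(q, a))
  p <- stats::phyper(k - 1, length(a), length(universe) - length(a),
                     length(q), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; input order preserved.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
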