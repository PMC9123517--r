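# Cell-type enrichment from bulk expression: a single-sample gene-set
# enrichment (ssGSEA-style) score per cell-type signature per sample, with
# exact Mann-Whitney comparison of scores between disease groups. The
# signatures are user-supplied GMT sets; no fixed signature compendium,
# cross-type calibration or spillover correction is applied, so scores are
# pure per-sample rank statistics.

#' Single-sample gene-set enrichment score
#'
#' Genes are ranked by expression, descending (ties broken
#' lexicographically by gene id). The score is the sum over all rank
#' positions of \eqn{P_{hit}(i) - P_{miss}(i)}, where \eqn{P_{hit}}
#' accumulates member weights \eqn{(N - i + 1)^\alpha} (normalized over
#' members) and \eqn{P_{miss}} is the uniform ECDF of non-members. The
#' statistic depends only on expression ranks, so any monotone transform
#' of the input leaves it unchanged.
#'
#' @param expression Named numeric vector, one sample's expression (TPM).
#' @param members A \code{gene_set} or character vector (the cell-type
#'   signature); must intersect the genes and leave a non-empty complement.
#' @param alpha Rank-weight exponent (default 0.25, the usual ssGSEA
#'   convention; 0 gives unweighted ECDF differences).
#' @return Numeric enrichment score.
#' @examples
#' ssgsea_score(c(a = 9, b = 5, c = 1), "a", alpha = 0)  # 1.5
#' @export
ssgsea_score <- function(expression, members, alpha = 0.25) {
  genes <- names(expression)
  if (is.null(genes)) stop("'expression' must be named by gene", call. = FALSE)
  ord <- order(-expression, genes, method = "radix")
  hit <- genes[ord] %in% as_members(members)
  N <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop("no member among the expressed genes", call. = FALSE)
  if (nh == N) stop("members cover all genes; miss ECDF undefined",
                    call. = FALSE)
  w <- (N - seq_len(N) + 1)^alpha
  p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  p_miss <- cumsum(!hit) / (N - nh)
  sum(p_hit - p_miss)
}

#' Score all cell-type signatures across samples
#'
#' Applies \code{\link{ssgsea_score}} to every (signature, sample) pair.
#' Signatures without any expressed member are dropped with a warning.
#'
#' @param tpm Gene x sample expression matrix (TPM; see
#'   \code{\link{compute_tpm}}).
#' @param signatures List of \code{gene_set}s (e.g. from
#'   \code{\link{read_gmt}}).
#' @param alpha Rank-weight exponent passed through.
#' @return Cell-type x sample score matrix.
#' @export
score_all <- function(tpm, signatures, alpha = 0.25) {
  usable <- vapply(signatures, function(s) {
    n <- sum(rownames(tpm) %in% as_members(s))
    n >= 1 && n < nrow(tpm)
  }, logical(1))
  if (!any(usable)) stop("no signature intersects the gene universe",
                         call. = FALSE)
  if (any(!usable)) {
    warning("signature(s) without scorable overlap dropped: ",
            paste(vapply(signatures[!usable], function(s) s$name,
                         character(1)), collapse = ", "))
  }
  signatures <- signatures[usable]
  scores <- vapply(seq_len(ncol(tpm)), function(j) {
    x <- stats::setNames(tpm[, j], rownames(tpm))
    vapply(signatures, function(s) ssgsea_score(x, s, alpha), numeric(1))
  }, numeric(length(signatures)))
  scores <- matrix(scores, nrow = length(signatures),
                   dimnames = list(vapply(signatures, function(s) s$name,
                                          character(1)),
                                   colnames(tpm)))
  scores
}

#' Mann-Whitney U test
#'
#' U counts pairs where an \code{x} value exceeds a \code{y} value (ties
#' count 1/2). For small groups (both sizes <= \code{exact_max}) the
#' two-sided p-value is computed by complete enumeration of all group
#' assignments of the pooled values (exact even under ties); larger groups
#' use the normal approximation with tie-corrected variance.
#'
#' @param x,y Numeric score vectors for the two groups (each length >= 2).
#' @param exact_max Largest group size for the exact branch (default 8).
#' @return List with \code{U} (for \code{x}), \code{p} (two-sided) and
#'   \code{method} ("exact" or "normal").
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_of(x, y)
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    list(U = u, p = p, method = "exact")
  } else {
    n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' Compare cell-type scores between two groups
#'
#' Two-sided Mann-Whitney U test on one cell type's per-sample scores.
#'
#' @param scores Cell-type x sample score matrix (from
#'   \code{\link{score_all}}).
#' @param groups Named character vector of group labels per sample.
#' @param cell_type Row name of the cell type to test.
#' @param group_a,group_b The two group labels (need >= 2 samples each).
#' @return List with \code{U} and two-sided \code{p}.
#' @export
compare_groups <- function(scores, groups, cell_type, group_a, group_b) {
  if (!cell_type %in% rownames(scores)) {
    stop("unknown cell type: ", cell_type, call. = FALSE)
  }
  groups <- groups[colnames(scores)]
  a <- scores[cell_type, groups == group_a]
  b <- scores[cell_type, groups == group_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  mw <- mann_whitney_u(a, b)
  list(U = mw$U, p = mw$p)
}

#' Compare all cell types between two groups
#'
#' Runs \code{\link{compare_groups}} over every cell type and adjusts the
#' p-values across cell types by Benjamini-Hochberg.
#'
#' @inheritParams compare_groups
#' @return \code{data.frame} with \code{cell_type, U, p, padj}, ordered by
#'   p ascending (ties by name).
#' @export
compare_all_celltypes <- function(scores, groups, group_a, group_b) {
  res <- lapply(rownames(scores), function(ct) {
    cg <- compare_groups(scores, groups, ct, group_a, group_b)
    data.frame(cell_type = ct, U = cg$U, p = cg$p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$padj <- bh_adjust(df$p)
  df <- df[order(df$p, df$cell_type, method = "radix"), ]
  rownames(df) <- NULL
  df
}
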