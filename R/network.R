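# STRING-style interaction handling: load a scored edge list and retain
# signature genes that interact with at least one other signature gene.

new_interaction_network <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1000)) {
    stop("combined_score must be within [0, 1000]", call. = FALSE)
  }
  # canonical unordered representation, no self-loops, no duplicates
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  structure(data.frame(gene_a = a[keep], gene_b = b[keep],
                       combined_score = edges$combined_score[keep],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("interaction_network", "data.frame"))
}

#' Load a STRING-style edge list
#'
#' Reads a TSV with columns \code{gene_a, gene_b, combined_score} (header
#' optional, auto-detected), keeps edges at or above the confidence
#' threshold, collapses symmetric duplicates and drops self-loops with a
#' warning. The default threshold 400 corresponds to STRING's "medium
#' confidence".
#'
#' @param path Path to the TSV edge list.
#' @param score_threshold Minimum combined score retained (default 400).
#' @return An \code{interaction_network} data frame.
#' @export
load_string_edges <- function(path, score_threshold = 400) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][3])))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs >= 3 columns", call. = FALSE)
  names(df)[1:3] <- c("gene_a", "gene_b", "combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score))) stop("non-numeric combined_score", call. = FALSE)
  df$combined_score <- score
  df <- df[score >= score_threshold, 1:3, drop = FALSE]
  n_loops <- sum(df$gene_a == df$gene_b)
  if (n_loops > 0) warning(n_loops, " self-loop(s) dropped")
  new_interaction_network(df)
}

#' Retain signature genes with known interactions
#'
#' Keeps the genes whose degree within the subgraph induced on the input
#' gene set reaches \code{min_degree} — i.e. genes interacting with at
#' least one other gene of the signature. Degree is counted within the
#' signature, not against the whole proteome, because the screen asks
#' which disease genes form an interacting core.
#'
#' @param genes A \code{gene_set} or character vector.
#' @param network An \code{interaction_network}.
#' @param min_degree Minimum within-signature degree (default 1).
#' @return A \code{gene_set} of retained genes (NULL when none survive).
#' @export
filter_by_interaction <- function(genes, network, min_degree = 1) {
  stopifnot(min_degree >= 1)
  g <- as_members(genes)
  inside <- network$gene_a %in% g & network$gene_b %in% g
  deg <- table(c(network$gene_a[inside], network$gene_b[inside]))
  keep <- g[g %in% names(deg)[deg >= min_degree]]
  if (length(keep) == 0L) return(NULL)
  gene_set(if (inherits(genes, "gene_set")) genes$name else "interacting",
           keep)
}
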