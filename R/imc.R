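# Imaging-mass-cytometry single-cell phenotyping: per-marker 99th-
# percentile normalization, PhenoGraph-style clustering (k-nearest-
# neighbour graph reweighted by neighbourhood Jaccard overlap, modularity
# community detection), cluster marker profiles and per-entity
# composition, and threshold gating for co-expression percentages.

#' Normalize marker intensities to a high percentile
#'
#' Divides each marker by its \code{q}-quantile across all cells and clips
#' to [0, 1] — the usual preparation of IMC intensities before graph
#' clustering, robust to the heavy right tail of mean pixel intensities.
#' Markers whose \code{q}-quantile is zero map to all-zero with a warning.
#'
#' @param cells A \code{cell_matrix} (see \code{\link{read_cell_csv}}) or
#'   bare cells x markers matrix.
#' @param q Quantile used as the scale, in (0, 1]; default 0.99.
#' @return Object of the same type with intensities in [0, 1].
#' @export
normalize_percentile <- function(cells, q = 0.99) {
  if (q <= 0 || q > 1) stop("'q' must be in (0, 1]", call. = FALSE)
  m <- if (inherits(cells, "cell_matrix")) cells$intensities else cells
  if (length(m) == 0L) stop("empty matrix", call. = FALSE)
  scale <- apply(m, 2, stats::quantile, probs = q, names = FALSE)
  zero <- scale == 0
  if (any(zero)) {
    warning("marker(s) with zero ", q, "-quantile left all-zero: ",
            paste(colnames(m)[zero], collapse = ", "))
    scale[zero] <- 1
  }
  norm <- pmin(sweep(m, 2, scale, "/"), 1)
  if (inherits(cells, "cell_matrix")) {
    cells$intensities <- norm
    cells
  } else {
    norm
  }
}

#' Cluster cells on a Jaccard-weighted nearest-neighbour graph
#'
#' Builds each cell's k-nearest-neighbour set (Euclidean distance on the
#' normalized marker intensities, the cell itself included), connects
#' every pair of cells whose neighbourhood Jaccard overlap reaches the
#' pruning threshold with that overlap as edge weight, and partitions the
#' graph with seeded modularity-maximizing (Louvain) community detection.
#' This is the shared-nearest-neighbour formulation of the kNN/Jaccard
#' graph used by cytometry and single-cell clustering tools: scoring the
#' overlap of all neighbourhood pairs (rather than only kNN edges) makes
#' homogeneous populations near-complete subgraphs, so modularity at
#' resolution 1 does not shatter them into spurious sub-communities.
#' Neighbour ties at equal distance are broken by a seeded shuffle of cell
#' indices, so the assignment is a pure function of (data, k, seed).
#' Cluster ids are relabelled 1..K by decreasing cluster size.
#'
#' @param cells A \code{cell_matrix} with normalized intensities (see
#'   \code{\link{normalize_percentile}}) or a bare matrix.
#' @param k Number of nearest neighbours (default 15).
#' @param seed Integer seed (required; community detection and tie
#'   handling are seeded).
#' @param resolution Modularity resolution parameter (default 1).
#' @param prune Minimum Jaccard overlap kept as an edge (default 1/15).
#' @return A \code{cluster_assignment}: list with \code{cluster} (per-cell
#'   integer ids, contiguous from 1), \code{k}, \code{seed}.
#' @export
cluster_cells <- function(cells, k = 15, seed, resolution = 1,
                          prune = 1 / 15) {
  m <- if (inherits(cells, "cell_matrix")) cells$intensities else cells
  n <- nrow(m)
  if (n <= k) stop("need more cells than neighbours (n > k)", call. = FALSE)
  with_seed(seed, {
    tie_rank <- sample.int(n)
    d <- as.matrix(stats::dist(m))
    # k nearest neighbours per cell (plus self), ties by seeded shuffle
    nbr <- diag(n) > 0
    for (i in seq_len(n)) {
      ord <- order(d[i, ], tie_rank, method = "radix")
      ord <- ord[ord != i]
      nbr[i, ord[seq_len(k)]] <- TRUE
    }
    inter <- tcrossprod(nbr * 1)             # shared-neighbour counts
    jac <- inter / (2 * (k + 1) - inter)     # all neighbourhoods size k+1
    jac[lower.tri(jac, diag = TRUE)] <- 0
    idx <- which(jac >= prune, arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(idx, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comm <- igraph::cluster_louvain(g, weights = jac[idx],
                                    resolution = resolution)
    member <- igraph::membership(comm)
    # relabel by decreasing size for stable, figure-friendly ids
    sizes <- sort(table(member), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes), names(sizes))
    structure(list(cluster = as.integer(relab[as.character(member)]),
                   k = k, seed = seed),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$cluster), " cells in ",
      max(x$cluster), " clusters (k=", x$k, ", seed=", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Cluster marker profiles
#'
#' Mean intensity per (cluster, marker), plus a z-score per marker across
#' cluster means (each marker column standardized to mean 0, sd 1 across
#' clusters — the deviation of a cluster from the marker's average
#' expression in standard-deviation units, as shown in cluster heatmaps).
#' With a single cluster, or a marker constant across clusters, the
#' z-score is defined as 0.
#'
#' @param cells A \code{cell_matrix} (or bare matrix).
#' @param assignment A \code{cluster_assignment} matching the cells.
#' @return List with \code{mean} and \code{z}, both cluster x marker
#'   matrices.
#' @export
cluster_profile <- function(cells, assignment) {
  m <- if (inherits(cells, "cell_matrix")) cells$intensities else cells
  cl <- assignment$cluster
  stopifnot(length(cl) == nrow(m))
  means <- do.call(rbind, lapply(sort(unique(cl)), function(c) {
    colMeans(m[cl == c, , drop = FALSE])
  }))
  rownames(means) <- sort(unique(cl))
  z <- apply(means, 2, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  z <- matrix(z, nrow = nrow(means), dimnames = dimnames(means))
  list(mean = means, z = z)
}

#' Cluster composition per entity
#'
#' Raw cell counts per (cluster, entity), mean counts per sample within
#' each entity, and an entity attribution per cluster: a cluster is
#' attributed to an entity when at least \code{attribution_fraction} of
#' its cells carry that label, otherwise it is "shared".
#'
#' @param cells A \code{cell_matrix} (provides entity and sample labels).
#' @param assignment A \code{cluster_assignment}.
#' @param attribution_fraction Fraction of cells required to attribute a
#'   cluster to one entity (default 0.80).
#' @return List with \code{counts} (cluster x entity matrix),
#'   \code{mean_per_sample} (counts divided by the number of samples of
#'   each entity) and \code{attribution} (named character per cluster).
#' @export
cluster_composition <- function(cells, assignment,
                                attribution_fraction = 0.80) {
  cl <- assignment$cluster
  stopifnot(length(cl) == length(cells$entity))
  counts <- table(cluster = cl, entity = cells$entity)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  n_samples <- vapply(colnames(counts), function(e) {
    length(unique(cells$sample[cells$entity == e]))
  }, numeric(1))
  frac <- counts / rowSums(counts)
  attribution <- apply(frac, 1, function(f) {
    j <- which.max(f)
    if (f[j] >= attribution_fraction) colnames(counts)[j] else "shared"
  })
  list(counts = counts,
       mean_per_sample = sweep(counts, 2, n_samples, "/"),
       attribution = attribution)
}

#' Gated co-expression percentages
#'
#' Gates the cells whose normalized gate-marker intensity exceeds the
#' threshold, then reports the percentage of gated cells positive for each
#' co-marker. A co-marker entry may be a boolean combination:
#' \code{"CD45&HLA-DR"} requires all listed markers positive,
#' \code{"CD8|CD44"} any of them (one operator type per entry). For every
#' co-marker, positive% + negative% = 100.
#'
#' @param cells A normalized \code{cell_matrix} (or bare matrix in [0,1]).
#' @param gate_marker Marker defining the gated population (e.g. "aSMA").
#' @param co_markers Character vector of markers or \code{&}/\code{|}
#'   combinations.
#' @param threshold Positivity threshold on the normalized scale, in
#'   (0, 1); default 0.5. The gating rule behind published co-expression
#'   percentages is rarely stated, so the threshold is a required, logged
#'   parameter of any analysis.
#' @return A \code{gate_result}: list with \code{gate_marker, threshold,
#'   n_gated, percent} (named, per co-marker), \code{empty} flag.
#' @export
gate_coexpression <- function(cells, gate_marker, co_markers,
                              threshold = 0.5) {
  m <- if (inherits(cells, "cell_matrix")) cells$intensities else cells
  if (threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  }
  positive <- function(spec, rows) {
    op <- if (grepl("|", spec, fixed = TRUE)) "|" else "&"
    mk <- trimws(strsplit(spec, op, fixed = TRUE)[[1]])
    miss <- setdiff(mk, colnames(m))
    if (length(miss)) stop("unknown marker(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    pos <- m[rows, mk, drop = FALSE] > threshold
    if (op == "&") rowSums(pos) == length(mk) else rowSums(pos) > 0
  }
  if (!gate_marker %in% colnames(m)) {
    stop("unknown gate marker: ", gate_marker, call. = FALSE)
  }
  gated <- which(m[, gate_marker] > threshold)
  if (length(gated) == 0L) {
    warning("no cell passes the ", gate_marker, " gate")
    return(structure(list(gate_marker = gate_marker, threshold = threshold,
                          n_gated = 0L, percent = NULL, empty = TRUE),
                     class = "gate_result"))
  }
  pct <- vapply(co_markers, function(cm) {
    100 * sum(positive(cm, gated)) / length(gated)
  }, numeric(1))
  structure(list(gate_marker = gate_marker, threshold = threshold,
                 n_gated = length(gated),
                 percent = stats::setNames(pct, co_markers), empty = FALSE),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result> ", x$gate_marker, "+ cells: ", x$n_gated, "\n",
      sep = "")
  if (!x$empty) {
    for (nm in names(x$percent)) {
      cat(sprintf("  %s positive: %.1f%%\n", nm, x$percent[nm]))
    }
  }
  invisible(x)
}
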