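# Synthetic-data generators. Every pipeline input (bulk counts, drug
# catalog with perturbation down-sets, interaction network, single-cell
# intensities) can be produced with known ground truth, so each downstream
# stage is scorable: DEG recall against planted effects, rank of the
# planted drug, adjusted Rand index of the clustering.

#' Simulate a two-group bulk RNA-seq count matrix
#'
#' Draws negative-binomial counts for a disease-vs-control design with a
#' chosen fraction of genes carrying a planted log2 fold-change effect.
#' The NB is parameterized by (mean, dispersion) with
#' \eqn{Var = \mu + \alpha \mu^2}; baseline means are sampled log-uniformly
#' on [1, 1e4], the usual dynamic range of RNA-seq simulations. Planted
#' genes have their disease-group mean multiplied by \code{2^effect}.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_per_group Samples per group (>= 2).
#' @param de_fraction Fraction of genes with a planted effect, in [0, 1].
#' @param effect_log2fc Planted log2 fold change (disease vs control).
#'   May be a vector, recycled over planted genes, e.g. \code{c(3, -3)} for
#'   a mix of up- and downregulation; every value must be nonzero.
#' @param dispersion NB dispersion \eqn{\alpha > 0}, shared across genes.
#' @param seed Integer seed; identical (args, seed) give identical output.
#' @return List with \code{counts} (genes x samples integer matrix),
#'   \code{groups} (named character vector, "control"/"disease"),
#'   \code{lengths} (per-gene transcript length in bp, for TPM), and
#'   \code{truth} (list: \code{de_genes}, \code{effect_log2fc} named per
#'   planted gene, \code{baseline_mean}).
#' @examples
#' sim <- simulate_bulk_counts(200, 4, de_fraction = 0.1,
#'                             effect_log2fc = 3, dispersion = 0.1, seed = 1)
#' dim(sim$counts)
#' @export
simulate_bulk_counts <- function(n_genes, n_per_group, de_fraction,
                                 effect_log2fc, dispersion, seed) {
  stopifnot(n_genes >= 10, n_per_group >= 2)
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (any(effect_log2fc == 0) && de_fraction > 0) {
    stop("planted effects must be nonzero", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    samples <- c(sprintf("ctrl%02d", seq_len(n_per_group)),
                 sprintf("dis%02d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("control", "disease"), each = n_per_group),
                              samples)
    base_mu <- exp(stats::runif(n_genes, log(1), log(1e4)))
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    effects <- stats::setNames(rep_len(effect_log2fc, n_de), genes[de_idx])
    mu <- matrix(base_mu, n_genes, 2 * n_per_group)
    dis_cols <- n_per_group + seq_len(n_per_group)
    if (n_de > 0) {
      mu[de_idx, dis_cols] <- mu[de_idx, dis_cols] * 2^effects
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, 2 * n_per_group,
                     dimnames = list(genes, samples))
    lengths <- stats::setNames(
      round(exp(stats::runif(n_genes, log(300), log(1e4)))), genes)
    list(counts = counts, groups = groups, lengths = lengths,
         truth = list(de_genes = genes[de_idx], effect_log2fc = effects,
                      baseline_mean = stats::setNames(base_mu, genes)))
  })
}

#' Simulate a drug catalog with one planted inverse-signature drug
#'
#' Emulates a perturbation-reference screen: one planted drug whose
#' downregulated gene set overlaps the top of the disease signature (the
#' inverse-match the connectivity step should detect), plus decoy drugs
#' with uniformly random down-sets. Catalog attributes are assigned so the
#' planted drug always survives the organism/known-action/approved filters;
#' optional extra decoys are generated to fail them.
#'
#' @param disease_signature A \code{ranked_signature} (see
#'   \code{\link{rank_signature}}).
#' @param n_decoys Number of filter-passing decoy drugs.
#' @param planted_overlap Number of planted-drug down-genes drawn from the
#'   signature top (<= \code{set_size}).
#' @param set_size Size of every drug's down-set (<= signature length).
#' @param seed Integer seed.
#' @param top_n Size of the "top of the signature" window the planted
#'   overlap is sampled from (default 50).
#' @param n_filter_fail Additional decoys built to fail the catalog filter
#'   (wrong organism, unknown action, or not approved), for exercising
#'   \code{\link{filter_catalog}}.
#' @param n_targets Catalog targets per drug, sampled from its down-set.
#' @return List with \code{drugs} (list of \code{\link{drug_profile}}) and
#'   \code{truth} (list with \code{planted_drug}).
#' @export
simulate_drug_catalog <- function(disease_signature, n_decoys,
                                  planted_overlap, set_size, seed,
                                  top_n = 50, n_filter_fail = 0,
                                  n_targets = 3) {
  genes <- disease_signature$gene
  if (planted_overlap > set_size) {
    stop("'planted_overlap' must be <= 'set_size'", call. = FALSE)
  }
  stopifnot(set_size <= length(genes), top_n <= length(genes),
            planted_overlap <= top_n)
  with_seed(seed, {
    top <- genes[seq_len(top_n)]
    planted_down <- sample(top, planted_overlap)
    if (set_size > planted_overlap) {
      planted_down <- c(planted_down,
                        sample(setdiff(genes, top), set_size - planted_overlap))
    }
    passing <- list(organism = "Humans", known_action = "yes",
                    groups = "approved")
    # targets live in the signature-top window (the screen's therapeutic
    # targets), so every catalog drug is a genuine mapping candidate
    make_drug <- function(id, down, attrs) {
      pool <- intersect(down, top)     # prefer targets the drug downregulates
      if (length(pool) > n_targets) pool <- sample(pool, n_targets)
      if (length(pool) < n_targets) {
        pool <- c(pool, sample(setdiff(top, pool), n_targets - length(pool)))
      }
      drug_profile(drug_id = id, name = id, targets = pool,
                   organism = attrs$organism,
                   known_action = attrs$known_action,
                   groups = attrs$groups,
                   down_genes = gene_set(id, down))
    }
    planted <- make_drug("planted_drug", planted_down, passing)
    decoys <- lapply(seq_len(n_decoys), function(i) {
      make_drug(sprintf("decoy%02d", i), sample(genes, set_size), passing)
    })
    fail_attrs <- list(
      list(organism = "Rat", known_action = "yes", groups = "approved"),
      list(organism = "Humans", known_action = "no", groups = "approved"),
      list(organism = "Humans", known_action = "yes",
           groups = c("investigational", "withdrawn")))
    failing <- lapply(seq_len(n_filter_fail), function(i) {
      make_drug(sprintf("faildecoy%02d", i), sample(genes, set_size),
                fail_attrs[[((i - 1) %% 3) + 1]])
    })
    list(drugs = c(list(planted), decoys, failing),
         truth = list(planted_drug = "planted_drug"))
  })
}

#' Simulate a STRING-like interaction network
#'
#' Erdős–Rényi edges among non-orphan genes; designated orphan genes get
#' degree zero, emulating signature genes without any known interaction.
#'
#' @param genes Character vector of gene ids.
#' @param edge_prob Probability of an edge between any two non-orphan
#'   genes, in [0, 1].
#' @param orphans Subset of \code{genes} forced to have no edges.
#' @param seed Integer seed.
#' @param score_range Range the uniform combined scores are drawn from
#'   (STRING scale, 0-1000).
#' @return An \code{interaction_network} (see
#'   \code{\link{load_string_edges}}).
#' @export
simulate_network <- function(genes, edge_prob, orphans = character(0), seed,
                             score_range = c(400, 1000)) {
  if (edge_prob < 0 || edge_prob > 1) {
    stop("'edge_prob' must be in [0, 1]", call. = FALSE)
  }
  if (!all(orphans %in% genes)) {
    stop("'orphans' must be a subset of 'genes'", call. = FALSE)
  }
  with_seed(seed, {
    connectable <- setdiff(genes, orphans)
    if (length(connectable) < 2 || edge_prob == 0) {
      return(new_interaction_network(
        data.frame(gene_a = character(0), gene_b = character(0),
                   combined_score = numeric(0), stringsAsFactors = FALSE)))
    }
    pairs <- utils::combn(sort(connectable), 2)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    edges <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                        combined_score = round(stats::runif(sum(keep),
                                                            score_range[1],
                                                            score_range[2])),
                        stringsAsFactors = FALSE)
    new_interaction_network(edges)
  })
}

# Internal constructor for the cell x marker container used throughout the
# IMC module; validates the invariants (non-negative, labelled, unique
# marker names).
new_cell_matrix <- function(intensities, sample, entity) {
  stopifnot(is.matrix(intensities), nrow(intensities) == length(sample),
            nrow(intensities) == length(entity))
  if (any(intensities < 0)) stop("negative intensities", call. = FALSE)
  if (anyDuplicated(colnames(intensities))) {
    stop("duplicate marker names", call. = FALSE)
  }
  structure(list(intensities = intensities,
                 sample = as.character(sample),
                 entity = as.character(entity)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$intensities), " cells x ",
      ncol(x$intensities), " markers; entities: ",
      paste(unique(x$entity), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a single-cell marker-intensity matrix
#'
#' Cells are drawn from a small number of populations, each with its own
#' marker mean vector; Gaussian noise is added and intensities are
#' truncated at zero (marker intensities are non-negative). Emulates the
#' per-cell mean pixel intensities extracted from segmented IMC images.
#'
#' @param populations List of populations, each a list with \code{n_cells},
#'   \code{means} (named numeric vector over markers, shared names), and
#'   optionally \code{entity} and \code{sample} labels.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with \code{cells} (a \code{cell_matrix}) and \code{truth}
#'   (list: \code{cell_labels}, the per-cell population index).
#' @examples
#' pops <- list(list(n_cells = 50, means = c(aSMA = 5, CD45 = 0.5)),
#'              list(n_cells = 50, means = c(aSMA = 0.5, CD45 = 5)))
#' sim <- simulate_cell_matrix(pops, noise_sd = 0.2, seed = 7)
#' @export
simulate_cell_matrix <- function(populations, noise_sd, seed) {
  if (length(populations) == 0L) stop("no populations given", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  markers <- names(populations[[1]]$means)
  for (p in populations) {
    if (!identical(names(p$means), markers)) {
      stop("all population mean vectors must share marker names", call. = FALSE)
    }
  }
  with_seed(seed, {
    blocks <- lapply(seq_along(populations), function(i) {
      p <- populations[[i]]
      n <- p$n_cells
      m <- matrix(rep(p$means, each = n), n, length(markers),
                  dimnames = list(NULL, markers))
      m <- m + matrix(stats::rnorm(n * length(markers), sd = noise_sd),
                      n, length(markers))
      pmax(m, 0)
    })
    labels <- rep(seq_along(populations),
                  vapply(populations, function(p) p$n_cells, numeric(1)))
    entity <- unlist(lapply(populations, function(p) {
      rep(p$entity %||% "PVR", p$n_cells)
    }))
    samp <- unlist(lapply(populations, function(p) {
      rep(p$sample %||% "s1", p$n_cells)
    }))
    cells <- new_cell_matrix(do.call(rbind, blocks), sample = samp,
                             entity = entity)
    list(cells = cells, truth = list(cell_labels = labels))
  })
}
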