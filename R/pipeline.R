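# End-to-end drug-repurposing screen: counts -> DE -> DEG filter ->
# interaction retention -> catalog filter/target mapping -> connectivity
# scoring -> ranked candidate table.

#' Run the transcriptome-based drug-repurposing screen
#'
#' The four-step screen: (1) differential expression (internal stand-in,
#' or a precomputed DE table) and selection of significantly upregulated
#' disease genes; (2) retention of upregulated genes with at least one
#' known interaction among themselves in the network; (3) catalog
#' filtering (humans / known action / approved) and mapping of drug
#' targets into the retained genes; (4) enrichment scoring of each
#' candidate's downregulated gene set against the full log2FC-ranked
#' disease signature, with permutation NES, BH-adjusted p-values and final
#' ranking. A high positive NES marks a drug whose induced profile opposes
#' the disease profile.
#'
#' @param counts Gene x sample count matrix (with \code{groups}), or NULL
#'   when \code{de} is supplied.
#' @param groups Named group labels per sample (two groups).
#' @param network An \code{interaction_network}.
#' @param drugs List of \code{\link{drug_profile}}s; down-sets may already
#'   be attached, otherwise supply \code{profiles}.
#' @param de Optional precomputed DE table (\code{gene, log2fc, p, padj});
#'   overrides \code{counts}/\code{groups}.
#' @param profiles Optional named list of down-gene \code{gene_set}s (GMT)
#'   to attach to the catalog.
#' @param lfc_thresh,alpha DEG thresholds (defaults 2 and 0.05).
#' @param min_degree Interaction-retention degree (default 1).
#' @param n_perm,weight_exponent,seed Connectivity-scoring parameters (see
#'   \code{\link{score_drugs}}).
#' @param disease Disease group label passed to \code{\link{internal_de}}.
#' @return List with \code{de}, \code{degs} (up/down gene sets),
#'   \code{retained} (interacting upregulated genes), \code{candidates}
#'   (drugs surviving catalog filter and target mapping), \code{ranked}
#'   (the signature) and \code{drug_table} (the final ranked results).
#' @export
run_repurposing_screen <- function(counts = NULL, groups = NULL, network,
                                   drugs, de = NULL, profiles = NULL,
                                   lfc_thresh = 2, alpha = 0.05,
                                   min_degree = 1, n_perm = 1000,
                                   weight_exponent = 1, seed,
                                   disease = NULL) {
  if (is.null(de)) {
    if (is.null(counts) || is.null(groups)) {
      stop("supply either 'de' or 'counts' + 'groups'", call. = FALSE)
    }
    de <- internal_de(counts, groups, disease)
  }
  degs <- filter_degs(de, lfc_thresh, alpha)
  if (is.null(degs$up)) {
    stop("no significantly upregulated genes at the chosen thresholds",
         call. = FALSE)
  }
  retained <- filter_by_interaction(degs$up, network, min_degree)
  if (is.null(retained)) {
    stop("no upregulated gene has a known interaction", call. = FALSE)
  }
  candidates <- filter_catalog(drugs)
  candidates <- map_targets(candidates, retained)
  if (!is.null(profiles)) {
    candidates <- attach_profiles(candidates, profiles)
  } else {
    has_prof <- vapply(candidates, function(d) !is.null(d$down_genes),
                       logical(1))
    if (any(!has_prof)) {
      warning(sum(!has_prof), " candidate(s) without perturbation ",
              "profile dropped")
      candidates <- candidates[has_prof]
    }
  }
  if (length(candidates) == 0L) {
    stop("no candidate drug survives filtering", call. = FALSE)
  }
  ranked <- rank_signature(de)
  results <- score_drugs(ranked, candidates, n_perm, weight_exponent, seed)
  list(de = de, degs = degs, retained = retained, candidates = candidates,
       ranked = ranked, drug_table = rank_drugs(results))
}
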