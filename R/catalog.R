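# DrugBank-like catalog handling: construct drug profiles, apply the
# organism / known-action / approved filter, map targets into the disease
# signature and attach perturbation-reference down-sets from GMT.

#' Construct a drug profile
#'
#' @param drug_id Unique drug identifier.
#' @param name Drug name (defaults to \code{drug_id}).
#' @param targets Character vector of target gene ids.
#' @param organism Target organism attribute (e.g. "Humans").
#' @param known_action Whether the pharmacological action is known
#'   ("yes"/"no"/"unknown").
#' @param groups Character vector of approval groups (e.g. "approved").
#' @param down_genes Optional \code{\link{gene_set}} of genes the drug
#'   downregulates (attached later via \code{\link{attach_profiles}} when
#'   read from GMT).
#' @return An object of class \code{drug_profile}.
#' @export
drug_profile <- function(drug_id, name = drug_id, targets = character(0),
                         organism = NA_character_,
                         known_action = NA_character_,
                         groups = character(0), down_genes = NULL) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L, nzchar(drug_id))
  structure(list(drug_id = drug_id, name = name,
                 targets = unique(as.character(targets)),
                 organism = organism, known_action = known_action,
                 groups = as.character(groups), down_genes = down_genes),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("<drug_profile> ", x$drug_id, " (", length(x$targets), " targets, ",
      if (is.null(x$down_genes)) "no" else length(x$down_genes$members),
      " down-genes)\n", sep = "")
  invisible(x)
}

#' Read a drug catalog from CSV
#'
#' One row per drug-target pair; columns \code{drug_id, name, target_gene,
#' organism, known_action, groups} (groups semicolon-separated). Rows are
#' aggregated into one \code{\link{drug_profile}} per drug.
#'
#' @param path Path to the catalog CSV.
#' @return List of \code{drug_profile} objects.
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "name", "target_gene", "organism", "known_action",
            "groups")
  if (!all(need %in% names(df))) {
    stop("catalog CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$drug_id), function(d) {
    drug_profile(drug_id = d$drug_id[1], name = d$name[1],
                 targets = d$target_gene,
                 organism = d$organism[1], known_action = d$known_action[1],
                 groups = strsplit(d$groups[1], ";", fixed = TRUE)[[1]])
  })
}

#' Write a drug catalog to CSV
#'
#' @param drugs List of \code{drug_profile} objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_catalog_csv <- function(drugs, path) {
  rows <- do.call(rbind, lapply(drugs, function(d) {
    tg <- if (length(d$targets)) d$targets else NA_character_
    data.frame(drug_id = d$drug_id, name = d$name, target_gene = tg,
               organism = d$organism, known_action = d$known_action,
               groups = paste(d$groups, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a drug catalog by the repurposing criteria
#'
#' Keeps drugs with target organism "humans" (case-insensitive), known
#' pharmacological action "yes", and "approved" among their groups. Drugs
#' with a missing attribute are excluded with a warning.
#'
#' @param drugs List of \code{drug_profile} objects.
#' @return Filtered list.
#' @export
filter_catalog <- function(drugs) {
  ok <- vapply(drugs, function(d) {
    if (is.na(d$organism) || is.na(d$known_action) ||
        length(d$groups) == 0L) {
      warning("drug '", d$drug_id, "' has missing attributes; excluded")
      return(FALSE)
    }
    tolower(trimws(d$organism)) == "humans" &&
      tolower(trimws(d$known_action)) == "yes" &&
      "approved" %in% tolower(trimws(d$groups))
  }, logical(1))
  drugs[ok]
}

#' Map drugs to targets inside the disease signature
#'
#' Retains drugs with at least one target among the signature genes and
#' annotates each retained drug with its in-signature targets.
#'
#' @param drugs List of \code{drug_profile} objects.
#' @param signature_genes A \code{gene_set} or character vector of
#'   signature gene ids.
#' @return Filtered list, each drug's \code{targets} reduced to the
#'   in-signature ones.
#' @export
map_targets <- function(drugs, signature_genes) {
  sig <- as_members(signature_genes)
  out <- lapply(drugs, function(d) {
    hit <- intersect(d$targets, sig)
    if (length(hit) == 0L) return(NULL)
    d$targets <- hit
    d
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Attach perturbation down-sets to catalog drugs
#'
#' Matches GMT set names to drug ids or names case-insensitively (after
#' whitespace trimming; no fuzzy matching). Drugs without a profile are
#' dropped with a warning; GMT entries without a catalog drug are ignored.
#'
#' @param drugs List of \code{drug_profile} objects.
#' @param profiles Named list of \code{gene_set}s (from
#'   \code{\link{read_gmt}}) of drug-downregulated genes.
#' @return List of drugs, each with non-empty \code{down_genes}.
#' @export
attach_profiles <- function(drugs, profiles) {
  if (length(profiles) == 0L) stop("empty profile collection", call. = FALSE)
  key <- function(x) tolower(trimws(x))
  idx <- stats::setNames(seq_along(profiles), key(names(profiles)))
  out <- lapply(drugs, function(d) {
    i <- idx[key(d$drug_id)]
    if (is.na(i)) i <- idx[key(d$name)]
    if (is.na(i)) {
      warning("no perturbation profile for drug '", d$drug_id, "'; dropped")
      return(NULL)
    }
    d$down_genes <- profiles[[i]]
    d
  })
  out[!vapply(out, is.null, logical(1))]
}
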