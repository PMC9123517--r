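# Plain-text readers and writers for every pipeline input/output format:
# counts TSV, group CSV, GMT, STRING-style edge TSV, drug catalog CSV,
# cell x marker CSV, ranked-signature TSV, DE table CSV.

#' Read a GMT gene-set file
#'
#' Each line is \code{name <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#'
#' @param path Path to a GMT file.
#' @return Named list of \code{\link{gene_set}} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line (need >= 3 fields): ", ln, call. = FALSE)
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of \code{gene_set} objects (or character vectors; list
#'   names are used as set names).
#' @param path Output path.
#' @param description Description field written in column 2.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    nm <- if (inherits(s, "gene_set")) s$name else names(sets)[i]
    paste(c(nm, description, as_members(s)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Genes as rows (first column = gene id), header row of sample ids.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample matrix to TSV
#'
#' @param mat Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @param id_col Name of the first (gene id) column.
#' @return Invisibly, \code{path}.
#' @export
write_counts_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write sample group labels
#'
#' CSV with columns \code{sample,group}.
#'
#' @param path File path.
#' @return \code{read_groups_csv}: named character vector of group labels,
#'   names are sample ids.
#' @export
read_groups_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' @rdname read_groups_csv
#' @param groups Named character vector (names = sample ids).
#' @export
write_groups_csv <- function(groups, path) {
  utils::write.csv(data.frame(sample = names(groups), group = unname(groups),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression table from CSV
#'
#' Expected columns: \code{gene, log2fc, p, padj} (extra columns kept).
#' Use this to feed an externally computed DE result (e.g. from an NB GLM
#' fit) into the signature and drug-screen steps.
#'
#' @param path Path to the CSV file.
#' @return A \code{data.frame} of DE records.
#' @export
read_de_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p", "padj")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a ranked signature to TSV (gene TAB score)
#'
#' @param signature A \code{ranked_signature} (see \code{\link{rank_signature}}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_signature_tsv <- function(signature, path) {
  utils::write.table(signature[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked signature from TSV
#'
#' @param path Path to a two-column TSV (gene, score).
#' @return A \code{ranked_signature} data frame (re-sorted to enforce the
#'   descending-score, lexicographic-tie-break ordering).
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "score")
  new_ranked_signature(df$gene, df$score)
}

#' Read a cell-by-marker intensity matrix from CSV
#'
#' Columns: \code{sample}, \code{entity}, then one column per marker.
#'
#' @param path Path to the CSV file.
#' @return A \code{cell_matrix}: list with \code{intensities} (cells x
#'   markers matrix), \code{sample} and \code{entity} per-cell labels.
#' @export
read_cell_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample", "entity")
  if (!all(meta %in% names(df))) {
    stop("cell CSV needs 'sample' and 'entity' columns", call. = FALSE)
  }
  markers <- setdiff(names(df), meta)
  m <- as.matrix(df[, markers, drop = FALSE])
  storage.mode(m) <- "double"
  new_cell_matrix(m, sample = df$sample, entity = df$entity)
}

#' @rdname read_cell_csv
#' @param cells A \code{cell_matrix}.
#' @export
write_cell_csv <- function(cells, path) {
  df <- data.frame(sample = cells$sample, entity = cells$entity,
                   cells$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
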