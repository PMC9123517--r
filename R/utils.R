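#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the random number generator seeded at \code{seed}
#' and restores the caller's RNG state afterwards, so seeded operations are
#' reproducible without clobbering the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a gene set
#'
#' A gene set is a named collection of unique gene identifiers, the common
#' currency of over-representation analysis, drug down-sets and cell-type
#' signatures.
#'
#' @param name Character scalar, the set name.
#' @param members Character vector of gene ids; duplicates are collapsed.
#' @return An object of class \code{gene_set} with fields \code{name} and
#'   \code{members}.
#' @examples
#' gene_set("ECM", c("FN1", "SPARC", "COL1A1"))
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) {
    stop("gene set '", name, "' has no members", call. = FALSE)
  }
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

# Accept either a gene_set or a bare character vector of ids.
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
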