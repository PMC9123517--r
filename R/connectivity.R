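# Inverse-signature connectivity scoring. Each candidate drug's
# downregulated gene set is tested for enrichment at the top of the
# disease-ranked gene list with the weighted Kolmogorov-Smirnov-like
# running-sum statistic of GSEA; significance and normalization come from
# a gene-permutation null (random sets of the same size drawn from the
# ranking), the natural scheme when a single fixed ranking is screened.

# Running-sum extremum computed from hit positions only. The sum increases
# by w_i at hit i and decreases linearly by 1/(N - nh) per miss, so its
# maximum occurs at a hit and its minimum just before a hit (or at the
# boundary, where the deviation is 0). O(set size) per evaluation.
es_stat <- function(pos, w_raw, N) {
  nh <- length(pos)
  tot <- sum(w_raw)
  w <- if (tot > 0) w_raw / tot else rep(1 / nh, nh)
  d <- 1 / (N - nh)
  cw <- cumsum(w)
  miss_before <- pos - seq_len(nh)
  v_at <- cw - miss_before * d
  v_before <- c(0, cw[-nh]) - miss_before * d
  jmax <- which.max(v_at)
  jmin <- which.min(v_before)
  if (v_at[jmax] >= -v_before[jmin]) {
    list(es = v_at[jmax], extreme_hit = jmax, positive = TRUE)
  } else {
    list(es = v_before[jmin], extreme_hit = jmin, positive = FALSE)
  }
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list top to bottom: at a member ("hit") the sum
#' increases by \eqn{|s_i|^p / \sum_{hits} |s|^p}, at a non-member it
#' decreases by \eqn{1/(N - n_{hits})}. The enrichment score is the signed
#' extremum of maximal absolute deviation; the leading edge contains the
#' members at or before a positive extremum (at or after a negative one).
#' With \code{weight_exponent = 0} the statistic reduces to the classical
#' two-sample Kolmogorov-Smirnov form; if every member score is zero the
#' hit weights likewise fall back to uniform.
#'
#' @param ranked A \code{ranked_signature}.
#' @param members A \code{gene_set} or character vector; must intersect the
#'   ranking and leave a non-empty complement. Members absent from the
#'   ranking are ignored.
#' @param weight_exponent Exponent p on |score| hit weights (default 1,
#'   classic weighted GSEA; 0 for unweighted).
#' @param keep_running_sum Also return the full running-sum vector over
#'   ranks (for enrichment-curve plots).
#' @return List with \code{es}, \code{leading_edge} (gene ids) and
#'   \code{running_sum} (NULL unless requested).
#' @examples
#' rs <- rank_signature(data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                                 log2fc = c(4, 3, 2, 1)))
#' enrichment_score(rs, c("g1", "g3"))$es  # 2/3
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1,
                             keep_running_sum = FALSE) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% as_members(members)
  nh <- sum(hit)
  if (nh == 0L) stop("no member present in the ranking", call. = FALSE)
  if (nh == N) stop("members cover the entire ranking", call. = FALSE)
  pos <- which(hit)
  w_raw <- abs(ranked$score[pos])^weight_exponent
  st <- es_stat(pos, w_raw, N)
  leading <- if (st$positive) {
    ranked$gene[pos[seq_len(st$extreme_hit)]]
  } else {
    ranked$gene[pos[seq(st$extreme_hit, nh)]]
  }
  rs <- NULL
  if (keep_running_sum) {
    incr <- rep(-1 / (N - nh), N)
    tot <- sum(w_raw)
    incr[pos] <- if (tot > 0) w_raw / tot else 1 / nh
    rs <- cumsum(incr)
  }
  list(es = st$es, leading_edge = leading, running_sum = rs)
}

#' Permutation null distribution of the enrichment score
#'
#' Enrichment scores of \code{n_perm} uniformly random gene sets of the
#' given size drawn without replacement from the ranking — the calibration
#' reference for p-values and NES.
#'
#' @param ranked A \code{ranked_signature}.
#' @param set_size Size of the random sets (1 <= set_size < N).
#' @param n_perm Number of permutations (default 1000).
#' @param weight_exponent Hit-weight exponent, as in
#'   \code{\link{enrichment_score}}.
#' @param seed Integer seed.
#' @return Numeric vector of \code{n_perm} null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000,
                             weight_exponent = 1, seed) {
  N <- nrow(ranked)
  if (set_size < 1 || set_size >= N) {
    stop("'set_size' must be in [1, N)", call. = FALSE)
  }
  stopifnot(n_perm >= 1)
  spow <- abs(ranked$score)^weight_exponent
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, set_size))
      es_stat(pos, spow[pos], N)$es
    }, numeric(1))
  })
}

# Sign-split calibration shared by score_drug/score_drugs: one-sided
# permutation p with the +1 correction, NES = es / mean(|null| of the same
# sign).
calibrate_es <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  list(p = p, nes = nes)
}

#' Score one drug against the disease signature
#'
#' Computes the enrichment score of the drug's downregulated gene set on
#' the disease ranking, a one-sided permutation p-value (sign-matched null,
#' with the +1 correction so p >= 1/(n_perm + 1)) and the normalized
#' enrichment score NES = ES / mean(|null ES| of the same sign). Down-set
#' genes absent from the ranking are silently dropped; \code{set_size}
#' records the intersection actually scored. A positive NES means the
#' drug's down-genes sit atop the disease ranking, i.e. the drug profile
#' opposes the disease profile.
#'
#' @param ranked A \code{ranked_signature}.
#' @param drug A \code{\link{drug_profile}} with non-NULL \code{down_genes}.
#' @param n_perm Permutations for the null (default 1000).
#' @param weight_exponent Hit-weight exponent (default 1).
#' @param seed Integer seed.
#' @param null_es Optional precomputed null vector (from
#'   \code{\link{permutation_null}} at the matching set size), e.g. to
#'   share one null across drugs with equal set sizes.
#' @return An \code{enrichment_result}: list with \code{set_name, es, nes,
#'   p, padj} (NA until \code{\link{rank_drugs}}), \code{set_size,
#'   leading_edge, scorable}.
#' @export
score_drug <- function(ranked, drug, n_perm = 1000, weight_exponent = 1,
                       seed, null_es = NULL) {
  if (is.null(drug$down_genes)) {
    stop("drug '", drug$drug_id, "' has no down-regulated gene set",
         call. = FALSE)
  }
  members <- intersect(drug$down_genes$members, ranked$gene)
  if (length(members) == 0L || length(members) == nrow(ranked)) {
    warning("drug '", drug$drug_id, "' has no scorable overlap with the ",
            "ranking; flagged unscorable")
    return(structure(list(set_name = drug$name, es = NA_real_,
                          nes = NA_real_, p = NA_real_, padj = NA_real_,
                          set_size = length(members),
                          leading_edge = character(0), scorable = FALSE),
                     class = "enrichment_result"))
  }
  esr <- enrichment_score(ranked, members, weight_exponent)
  if (is.null(null_es)) {
    null_es <- permutation_null(ranked, length(members), n_perm,
                                weight_exponent, seed)
  }
  cal <- calibrate_es(esr$es, null_es)
  structure(list(set_name = drug$name, es = esr$es, nes = cal$nes,
                 p = cal$p, padj = NA_real_, set_size = length(members),
                 leading_edge = esr$leading_edge, scorable = TRUE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: ES=%.3f NES=%.3f p=%.4g (n=%d)\n",
              x$set_name, x$es, x$nes, x$p, x$set_size))
  invisible(x)
}

#' Score a batch of drugs with shared permutation nulls
#'
#' Convenience wrapper around \code{\link{score_drug}} that computes one
#' permutation null per distinct (intersection) set size and reuses it
#' across drugs, which makes screens over many candidates with equal-sized
#' down-sets much cheaper. Nulls are generated deterministically from
#' \code{seed}.
#'
#' @inheritParams score_drug
#' @param drugs List of \code{drug_profile}s with down-sets attached.
#' @return List of \code{enrichment_result}s (unscorable drugs included,
#'   flagged).
#' @export
score_drugs <- function(ranked, drugs, n_perm = 1000, weight_exponent = 1,
                        seed) {
  sizes <- vapply(drugs, function(d) {
    length(intersect(d$down_genes$members, ranked$gene))
  }, numeric(1))
  valid <- sizes > 0 & sizes < nrow(ranked)
  nulls <- list()
  with_seed(seed, {
    spow <- abs(ranked$score)^weight_exponent
    N <- nrow(ranked)
    for (s in sort(unique(sizes[valid]))) {
      nulls[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
        pos <- sort.int(sample.int(N, s))
        es_stat(pos, spow[pos], N)$es
      }, numeric(1))
    }
  })
  lapply(seq_along(drugs), function(i) {
    score_drug(ranked, drugs[[i]], n_perm, weight_exponent, seed,
               null_es = if (valid[i]) nulls[[as.character(sizes[i])]])
  })
}

#' Rank scored drugs and adjust p-values
#'
#' Benjamini-Hochberg adjustment across all scorable drugs, then ordering
#' by NES descending, ties by adjusted p ascending, then name.
#'
#' @param results List of \code{enrichment_result}s.
#' @return \code{data.frame} with columns \code{drug, es, nes, p, padj,
#'   set_size, leading_edge} (semicolon-joined), best candidate first.
#' @export
rank_drugs <- function(results) {
  results <- Filter(function(r) isTRUE(r$scorable), results)
  if (length(results) == 0L) stop("no scorable results", call. = FALSE)
  df <- data.frame(
    drug = vapply(results, `[[`, character(1), "set_name"),
    es = vapply(results, `[[`, numeric(1), "es"),
    nes = vapply(results, `[[`, numeric(1), "nes"),
    p = vapply(results, `[[`, numeric(1), "p"),
    set_size = vapply(results, function(r) as.integer(r$set_size),
                      integer(1)),
    leading_edge = vapply(results, function(r) {
      paste(r$leading_edge, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  df$padj <- bh_adjust(df$p)
  df <- df[order(-df$nes, df$padj, df$drug, method = "radix"), ]
  rownames(df) <- NULL
  df[, c("drug", "es", "nes", "p", "padj", "set_size", "leading_edge")]
}
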