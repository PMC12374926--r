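# Per-cell gene-set scoring.
#
# The AUC score ranks each cell's genes by decreasing count and measures
# the area under the gene-set recovery curve within the top max_rank
# genes, normalized by the maximum achievable area; it depends only on the
# ranking, so it is invariant under any strictly monotone transform of
# expression. ssGSEA is the rank-weighted ECDF-difference running-sum
# statistic.

#' Scoring configuration
#'
#' @param max_rank_fraction Fraction of the gene universe forming the AUC
#'   recovery window (default 0.05, the cited AUC method's documented
#'   default; the window is \code{ceil(fraction * n_genes)}).
#' @param top_cell_percent Percentile cut used downstream for nomination.
#' @param tie_policy "stable_index" (ties by ascending original gene index;
#'   bitwise reproducible) or "seeded_random" (seeded shuffle among ties).
#' @param seed RNG seed for the seeded_random tie policy.
#' @param ssgsea_alpha Rank-weight exponent for ssGSEA (default 0.25).
#' @param min_geneset_coverage Minimum fraction of a set found in the
#'   universe before a coverage warning is recorded.
#' @return A \code{scoring_config}.
#' @export
scoring_config <- function(max_rank_fraction = 0.05, top_cell_percent = 5,
                           tie_policy = c("stable_index", "seeded_random"),
                           seed = 1L, ssgsea_alpha = 0.25,
                           min_geneset_coverage = 0.8) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(max_rank_fraction > 0, max_rank_fraction <= 1,
            top_cell_percent > 0, top_cell_percent < 100)
  structure(list(max_rank_fraction = max_rank_fraction,
                 top_cell_percent = top_cell_percent,
                 tie_policy = tie_policy, seed = as.integer(seed),
                 ssgsea_alpha = ssgsea_alpha,
                 min_geneset_coverage = min_geneset_coverage),
            class = "scoring_config")
}

#' Rank a cell's genes by decreasing count
#'
#' Zero-count genes participate (below all detected genes) so the recovery
#' window is stable across cells.
#'
#' @param x Numeric expression vector (one cell, all genes).
#' @param config A \code{scoring_config} (tie policy and seed).
#' @return Integer permutation: position r holds the index of the rank-r
#'   gene.
#' @export
rank_genes <- function(x, config = scoring_config()) {
  if (config$tie_policy == "stable_index") {
    order(-x, seq_along(x), method = "radix")
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
    key <- sample.int(length(x))
    order(-x, key, method = "radix")
  }
}

# ranks of the effective set members given a permutation
member_ranks <- function(ranking, members_idx) {
  inv <- integer(length(ranking))
  inv[ranking] <- seq_along(ranking)
  inv[members_idx]
}

auc_from_ranks <- function(ranks, n_set, max_rank) {
  hits <- ranks[ranks <= max_rank]
  raw <- sum(max_rank - hits + 1)
  h <- min(n_set, max_rank)
  max_area <- h * (h + 1) / 2 + (max_rank - h) * h
  raw / max_area
}

#' AUC recovery-curve score for one cell
#'
#' With y(x) = number of set members among the top x ranked genes, the raw
#' area is sum of y(x) over x = 1..max_rank and the score is the raw area
#' divided by the maximum achievable area (all min(|G|, max_rank) members
#' occupying the top ranks). Scores lie in [0, 1].
#'
#' @param ranking Permutation from \code{\link{rank_genes}}.
#' @param gene_set A \code{gene_set}.
#' @param universe Character vector of the gene universe in matrix order.
#' @param config A \code{scoring_config}.
#' @return Score in [0, 1], or NA when the effective set is empty.
#' @export
auc_score <- function(ranking, gene_set, universe,
                      config = scoring_config()) {
  members_idx <- which(universe %in% gene_set$genes)
  if (!length(members_idx)) return(NA_real_)
  max_rank <- ceiling(config$max_rank_fraction * length(universe))
  auc_from_ranks(member_ranks(ranking, members_idx), length(members_idx),
                 max_rank)
}

#' ssGSEA score for one cell
#'
#' Genes are ranked by decreasing expression; the in-set empirical CDF is
#' weighted by (N - position + 1)^alpha while the out-set ECDF is
#' unweighted; the score is the sum over positions of their difference.
#' With alpha = 0 this reduces to the unweighted Kolmogorov-style running
#' sum. Depends only on the ranking, hence monotone-transform invariant.
#'
#' @param x Numeric expression vector (one cell, all genes).
#' @param gene_set A \code{gene_set}.
#' @param universe Character vector of gene symbols, one per entry of x.
#' @param config A \code{scoring_config} (\code{ssgsea_alpha}, tie policy).
#' @return Numeric score, or NA when the effective set is empty or covers
#'   the whole universe.
#' @export
ssgsea_score <- function(x, gene_set, universe,
                         config = scoring_config()) {
  in_set <- universe %in% gene_set$genes
  n <- length(universe)
  if (!any(in_set) || all(in_set)) return(NA_real_)
  ranking <- rank_genes(x, config)
  in_ord <- in_set[ranking]
  w <- ifelse(in_ord, (n - seq_len(n) + 1)^config$ssgsea_alpha, 0)
  ecdf_in <- cumsum(w) / sum(w)
  ecdf_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(ecdf_in - ecdf_out)
}

#' Score every cell against a collection of gene sets
#'
#' @param matrix An \code{expression_matrix}.
#' @param gene_sets List of \code{gene_set} objects.
#' @param method "auc" or "ssgsea".
#' @param config A \code{scoring_config}.
#' @return A \code{score_table}: list with \code{scores} (cells x
#'   signatures numeric matrix, barcodes as rownames), \code{metadata}
#'   (per-signature set size, genes found, coverage, recovery window,
#'   warnings) and the config used. Signatures with no gene in the
#'   universe yield all-NA columns.
#' @export
score_matrix <- function(matrix, gene_sets,
                         method = c("auc", "ssgsea"),
                         config = scoring_config()) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expression_matrix"))
  universe <- matrix$genes
  n_cells <- length(matrix$barcodes)
  max_rank <- ceiling(config$max_rank_fraction * length(universe))
  set_names <- vapply(gene_sets, `[[`, character(1), "name")

  meta <- data.frame(
    signature = set_names,
    n_genes = vapply(gene_sets, function(s) length(s$genes), integer(1)),
    n_found = vapply(gene_sets, function(s) sum(s$genes %in% universe),
                     integer(1)),
    stringsAsFactors = FALSE
  )
  meta$coverage <- ifelse(meta$n_genes > 0, meta$n_found / meta$n_genes, 0)
  meta$max_rank <- if (method == "auc") max_rank else NA_integer_
  meta$low_coverage <- meta$coverage < config$min_geneset_coverage
  for (i in which(meta$low_coverage)) {
    warning("gene set '", meta$signature[i], "' coverage ",
            signif(meta$coverage[i], 3), " below ",
            config$min_geneset_coverage, call. = FALSE)
  }

  dense <- as.matrix(matrix$counts)
  scores <- base::matrix(NA_real_, nrow = n_cells, ncol = length(gene_sets),
                         dimnames = list(matrix$barcodes, set_names))
  members <- lapply(gene_sets, function(s) which(universe %in% s$genes))
  for (j in seq_len(n_cells)) {
    x <- dense[, j]
    ranking <- rank_genes(x, config)
    if (method == "auc") {
      inv <- integer(length(ranking))
      inv[ranking] <- seq_along(ranking)
      for (k in seq_along(gene_sets)) {
        idx <- members[[k]]
        if (length(idx)) {
          scores[j, k] <- auc_from_ranks(inv[idx], length(idx), max_rank)
        }
      }
    } else {
      for (k in seq_along(gene_sets)) {
        if (length(members[[k]])) {
          scores[j, k] <- ssgsea_score(x, gene_sets[[k]], universe, config)
        }
      }
    }
  }
  structure(list(scores = scores, metadata = meta, method = method,
                 config = unclass(config)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s: %d cells x %d signatures\n", x$method,
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Write a score table (long + wide TSV)
#' @param x A \code{score_table}.
#' @param prefix Writes \code{<prefix>_long.tsv}, \code{<prefix>_wide.tsv}
#'   and \code{<prefix>_meta.tsv}.
#' @export
write_score_table <- function(x, prefix) {
  wide <- data.frame(barcode = rownames(x$scores), x$scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
  long <- data.frame(
    barcode = rep(rownames(x$scores), times = ncol(x$scores)),
    signature = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores), stringsAsFactors = FALSE
  )
  utils::write.table(wide, paste0(prefix, "_wide.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(long, paste0(prefix, "_long.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(x$metadata, paste0(prefix, "_meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
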