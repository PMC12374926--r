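# Two-group differential expression: per-gene two-sided Wilcoxon rank-sum
# on CPM-normalized values, exact enumeration of the rank-sum distribution
# when both groups have <= 8 cells, tie-corrected normal approximation
# otherwise; log2 fold changes on CPM means with a pseudocount;
# Benjamini-Hochberg adjustment over the tested genes.

# exact two-sided p for the observed rank sum of group A, enumerating all
# C(nA+nB, nA) assignments of the observed (possibly tied) ranks
rank_sum_exact_p <- function(ranks_a, ranks_all) {
  n_a <- length(ranks_a)
  w_obs <- sum(ranks_a)
  combs <- utils::combn(length(ranks_all), n_a)
  w_all <- colSums(matrix(ranks_all[combs], nrow = n_a))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# tie-corrected normal approximation with continuity correction
rank_sum_normal_p <- function(ranks_a, ranks_all) {
  n_a <- length(ranks_a)
  n_b <- length(ranks_all) - n_a
  n <- n_a + n_b
  w <- sum(ranks_a)
  mu <- n_a * (n + 1) / 2
  ties <- table(ranks_all)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-max(z, 0))
}

#' Wilcoxon rank-sum differential expression
#'
#' @param matrix An \code{expression_matrix} containing both groups.
#' @param group_a,group_b Disjoint barcode vectors, each >= 2 cells.
#' @param pseudocount Added to CPM means inside the log2 fold change.
#' @param min_cells Genes detected (count > 0) in fewer than this many
#'   cells across both groups are not tested (NA p-values); BH adjustment
#'   runs over the tested genes.
#' @return Data frame of class \code{dge_table}: gene, mean_a, mean_b (CPM),
#'   log2fc (A over B), p_value, p_adj, significant (|log2fc| > 0.5 and
#'   p_adj < 0.05, both strict).
#' @export
wilcoxon_dge <- function(matrix, group_a, group_b, pseudocount = 1,
                         min_cells = 3L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(intersect(group_a, group_b))) {
    stop("validation error: groups overlap", call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 cells", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), matrix$barcodes)
  if (length(missing)) {
    stop("validation error: barcodes not in matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  m <- matrix$counts[, c(group_a, group_b), drop = FALSE]
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1
  cpm <- as.matrix(m) %*% diag(1e6 / totals, length(totals))
  colnames(cpm) <- c(group_a, group_b)
  ia <- seq_along(group_a)
  ib <- seq_along(group_b) + length(group_a)

  detected <- Matrix::rowSums(m > 0)
  test_gene <- detected >= min_cells
  exact <- length(group_a) <= 8L && length(group_b) <= 8L

  n_genes <- nrow(m)
  p <- rep(NA_real_, n_genes)
  for (g in which(test_gene)) {
    r <- rank(cpm[g, ])
    p[g] <- if (exact) rank_sum_exact_p(r[ia], r) else
      rank_sum_normal_p(r[ia], r)
  }
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  p_adj <- rep(NA_real_, n_genes)
  p_adj[test_gene] <- stats::p.adjust(p[test_gene], method = "BH")
  out <- data.frame(gene = matrix$genes, mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p_value = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adj) & abs(out$log2fc) > 0.5 &
    out$p_adj < 0.05
  rownames(out) <- NULL
  class(out) <- c("dge_table", "data.frame")
  out
}

#' Filter differentially expressed genes
#'
#' Strict inequalities per the thresholds' wording: a gene with
#' |log2FC| exactly at \code{lfc_min} is excluded.
#'
#' @param table A \code{dge_table}.
#' @param lfc_min Minimum absolute log2 fold change (exclusive).
#' @param padj_max Maximum adjusted p-value (exclusive).
#' @return List with \code{up} and \code{down} gene vectors.
#' @export
deg_filter <- function(table, lfc_min = 0.5, padj_max = 0.05) {
  keep <- !is.na(table$p_adj) & abs(table$log2fc) > lfc_min &
    table$p_adj < padj_max
  list(up = table$gene[keep & table$log2fc > 0],
       down = table$gene[keep & table$log2fc < 0])
}

#' Write a DGE table as TSV
#' @param table A \code{dge_table}.
#' @param path Output TSV path.
#' @export
write_dge_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
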