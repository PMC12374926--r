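# Replicate-concordance statistics: cell-type proportion correlation,
# pseudobulk expression correlation, and repertoire Jaccard overlap.
# Pseudobulk is sum-per-gene -> counts-per-million -> log1p, so replicates
# of different cell numbers are comparable and the profile is invariant to
# global library-size scaling.

#' Cell-type proportions of one sample
#'
#' Proportions over the global cell-type vocabulary (all types observed
#' anywhere in the study), so vectors are commensurate across samples;
#' absent types are exactly 0 and the vector sums to 1.
#'
#' @param cells A \code{cell_table}.
#' @param sample_id Sample to profile.
#' @param vocabulary Optional character vector fixing the type vocabulary;
#'   defaults to all types in \code{cells}.
#' @return Named numeric vector over the vocabulary.
#' @export
celltype_proportions <- function(cells, sample_id,
                                 vocabulary = sort(unique(cells$cell_type))) {
  stopifnot(inherits(cells, "cell_table"))
  sub <- cells[cells$sample_id == sample_id, , drop = FALSE]
  if (!nrow(sub)) stop("empty sample '", sample_id, "'", call. = FALSE)
  tab <- table(factor(sub$cell_type, levels = vocabulary))
  stats::setNames(as.numeric(tab) / nrow(sub), vocabulary)
}

#' Pseudobulk expression profile of a sample
#'
#' Per-gene sum of counts across the sample's cells, scaled to counts per
#' million, then log(1 + x).
#'
#' @param matrix The sample's \code{expression_matrix} (>= 1 cell).
#' @return Named numeric vector over genes.
#' @export
pseudobulk <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(matrix$barcodes) == 0L) {
    stop("empty sample '", matrix$sample_id, "'", call. = FALSE)
  }
  sums <- Matrix::rowSums(matrix$counts)
  total <- sum(sums)
  if (total == 0) stop("all-zero sample '", matrix$sample_id, "'",
                       call. = FALSE)
  log1p(sums / total * 1e6)
}

pairwise_cor_matrix <- function(vectors, method) {
  ids <- names(vectors)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- stats::cor(vectors[[i]], vectors[[j]], method = method)
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Replicate-concordance report
#'
#' Three pairwise sample x sample matrices, each computed once per
#' unordered pair (hence exactly symmetric, unit diagonal): Pearson (or
#' Spearman) correlation of cell-type proportion vectors, correlation of
#' log-CPM pseudobulk profiles, and repertoire Jaccard overlap.
#'
#' @param cells A \code{cell_table} covering all samples.
#' @param matrices Named list of \code{expression_matrix} per sample.
#' @param repertoires Named list of \code{repertoire} per sample.
#' @param method Correlation coefficient: "pearson" (default) or
#'   "spearman".
#' @return A \code{concordance_report}: proportion_corr, pseudobulk_corr,
#'   repertoire_jaccard matrices plus method metadata.
#' @export
concordance_report <- function(cells, matrices, repertoires,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  sample_ids <- sort(unique(cells$sample_id))
  mat_ids <- sort(unname(vapply(matrices, `[[`, character(1), "sample_id")))
  rep_ids <- sort(unname(vapply(repertoires, `[[`, character(1),
                                "sample_id")))
  if (!identical(sample_ids, mat_ids) || !identical(sample_ids, rep_ids)) {
    stop("validation error: sample sets of cells, matrices and ",
         "repertoires do not match", call. = FALSE)
  }
  names(matrices) <- vapply(matrices, `[[`, character(1), "sample_id")
  names(repertoires) <- vapply(repertoires, `[[`, character(1), "sample_id")
  matrices <- matrices[sample_ids]
  repertoires <- repertoires[sample_ids]

  vocab <- sort(unique(cells$cell_type))
  props <- lapply(sample_ids, function(s) celltype_proportions(cells, s, vocab))
  names(props) <- sample_ids
  genes <- matrices[[1]]$genes
  pb <- lapply(matrices, function(m) {
    stopifnot(identical(m$genes, genes))
    pseudobulk(m)
  })

  structure(list(
    proportion_corr = pairwise_cor_matrix(props, method),
    pseudobulk_corr = pairwise_cor_matrix(pb, method),
    repertoire_jaccard = jaccard_matrix(repertoires),
    metadata = list(correlation = method, transform = "log1p(CPM)",
                    pseudocount = 1, aggregation = "sum")
  ), class = "concordance_report")
}

#' Write a concordance report (JSON + three TSV matrices)
#' @param report A \code{concordance_report}.
#' @param prefix Output path prefix.
#' @export
write_concordance_report <- function(report, prefix) {
  for (nm in c("proportion_corr", "pseudobulk_corr", "repertoire_jaccard")) {
    utils::write.table(report[[nm]], paste0(prefix, "_", nm, ".tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  jsonlite::write_json(
    list(metadata = report$metadata,
         samples = rownames(report$proportion_corr)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
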