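# Cell-level inclusion gates. "Total reads" is interpreted as total UMI
# counts of the cell in the matrix (the per-cell total available after
# counting); boundary values are KEPT because exclusions are stated as
# strict inequalities ("fewer than 500", "greater than 25,000").

#' QC thresholds
#'
#' Default gates: keep PTPRC-expressing cells with total counts in
#' [500, 25000], detected features in [300, 6000] and mitochondrial
#' fraction <= 15 percent.
#'
#' @param min_total_reads,max_total_reads Closed interval for per-cell total
#'   counts.
#' @param min_features,max_features Closed interval for detected genes
#'   (count > 0).
#' @param max_mito_pct Maximum mitochondrial percentage (inclusive).
#' @param require_ptprc Require PTPRC (CD45) count > 0.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_total_reads = 500L, min_features = 300L,
                          max_total_reads = 25000L, max_features = 6000L,
                          max_mito_pct = 15, require_ptprc = TRUE,
                          mito_prefix = "MT-") {
  stopifnot(min_total_reads < max_total_reads,
            min_features < max_features,
            max_mito_pct >= 0, max_mito_pct <= 100)
  structure(list(min_total_reads = min_total_reads,
                 min_features = min_features,
                 max_total_reads = max_total_reads,
                 max_features = max_features,
                 max_mito_pct = max_mito_pct,
                 require_ptprc = require_ptprc,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Apply cell-level QC gates
#'
#' A cell is kept iff (when required) its PTPRC count is > 0, its total
#' count lies in [min_total_reads, max_total_reads], its number of detected
#' features lies in [min_features, max_features], and its mitochondrial
#' fraction is <= max_mito_pct / 100. A failing cell is counted under every
#' criterion it violates; boundary values pass.
#'
#' @param matrix An \code{expression_matrix}.
#' @param thresholds A \code{qc_thresholds}.
#' @return List with \code{matrix} (the filtered \code{expression_matrix})
#'   and \code{report} (class \code{qc_report}: cells_in, cells_out,
#'   excluded_by named counts, kept_barcodes, thresholds).
#' @export
apply_qc <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- matrix$counts
  totals <- Matrix::colSums(m)
  features <- Matrix::colSums(m > 0)
  mito_genes <- startsWith(matrix$genes, thresholds$mito_prefix)
  mito_frac <- if (any(mito_genes)) {
    mito <- Matrix::colSums(m[mito_genes, , drop = FALSE])
    ifelse(totals > 0, mito / totals, 0)
  } else {
    rep(0, length(totals))
  }

  fail <- list(
    low_total_reads = totals < thresholds$min_total_reads,
    high_total_reads = totals > thresholds$max_total_reads,
    low_features = features < thresholds$min_features,
    high_features = features > thresholds$max_features,
    high_mito = mito_frac > thresholds$max_mito_pct / 100
  )
  if (isTRUE(thresholds$require_ptprc)) {
    if (!"PTPRC" %in% matrix$genes) {
      stop("configuration error: require_ptprc = TRUE but PTPRC absent ",
           "from gene list", call. = FALSE)
    }
    fail$ptprc <- m["PTPRC", ] <= 0
  }

  keep <- !Reduce(`|`, fail)
  kept_barcodes <- matrix$barcodes[keep]
  report <- structure(list(
    cells_in = length(matrix$barcodes),
    cells_out = sum(keep),
    excluded_by = vapply(fail, sum, numeric(1)),
    kept_barcodes = kept_barcodes,
    thresholds = unclass(thresholds)
  ), class = "qc_report")

  filtered <- expression_matrix(m[, keep, drop = FALSE], matrix$sample_id)
  list(matrix = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d cells in, %d kept (boundaries inclusive)\n",
              x$cells_in, x$cells_out))
  for (nm in names(x$excluded_by)) {
    cat(sprintf("  excluded by %-12s %d\n", paste0(nm, ":"),
                x$excluded_by[[nm]]))
  }
  invisible(x)
}

#' Write a QC report as JSON
#' @param report A \code{qc_report}.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
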