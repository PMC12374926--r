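# Paired-CDR3 clonotype assembly and clonal-expansion binning.
# Clonotype identity is the pair of CDR3 alpha/beta NUCLEOTIDE sequences;
# amino-acid sequences are carried as metadata (used only for viral
# annotation, which matches on amino acids).

clone_key <- function(cdr3a_nt, cdr3b_nt) paste(cdr3a_nt, cdr3b_nt, sep = "|")

# Per barcode and locus, pick the dominant chain: highest UMI count, ties
# by higher read count, then lexicographically smallest cdr3_nt. The result
# is invariant to contig row order.
select_dominant_chain <- function(df) {
  ord <- order(df$barcode, -df$umis, -df$reads, df$cdr3_nt,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df[!duplicated(df$barcode), , drop = FALSE]
}

#' Assemble per-cell paired clonotypes from a contig table
#'
#' Only productive, high-confidence TRA/TRB contigs are considered. Per
#' barcode and locus the UMI-dominant chain is selected (ties broken by
#' read count, then lexicographically smallest CDR3 nucleotide sequence).
#' By default a barcode needs both a selected TRA and TRB to receive a
#' clonotype; barcodes lacking either locus are dropped.
#'
#' @param contigs A \code{contig_table}.
#' @param beta_only If TRUE, define clonotypes on the beta chain alone
#'   (sensitivity-analysis mode; the alpha fields are then empty strings).
#' @return Data frame of class \code{cell_clonotypes} with one row per
#'   clonotype-bearing barcode: barcode, cdr3a_nt, cdr3b_nt, cdr3a_aa,
#'   cdr3b_aa, clone_id.
#' @export
assemble_clonotypes <- function(contigs, beta_only = FALSE) {
  stopifnot(inherits(contigs, "contig_table"))
  df <- as.data.frame(contigs)
  df <- df[df$productive & df$high_confidence & df$chain %in% c("TRA", "TRB"), ,
           drop = FALSE]
  empty <- data.frame(barcode = character(), cdr3a_nt = character(),
                      cdr3b_nt = character(), cdr3a_aa = character(),
                      cdr3b_aa = character(), clone_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(df)) {
    class(empty) <- c("cell_clonotypes", "data.frame")
    return(empty)
  }
  tra <- select_dominant_chain(df[df$chain == "TRA", , drop = FALSE])
  trb <- select_dominant_chain(df[df$chain == "TRB", , drop = FALSE])
  if (beta_only) {
    out <- data.frame(barcode = trb$barcode,
                      cdr3a_nt = "", cdr3b_nt = trb$cdr3_nt,
                      cdr3a_aa = "", cdr3b_aa = trb$cdr3,
                      stringsAsFactors = FALSE)
  } else {
    shared <- intersect(tra$barcode, trb$barcode)
    if (!length(shared)) {
      class(empty) <- c("cell_clonotypes", "data.frame")
      return(empty)
    }
    a <- tra[match(shared, tra$barcode), ]
    b <- trb[match(shared, trb$barcode), ]
    out <- data.frame(barcode = shared,
                      cdr3a_nt = a$cdr3_nt, cdr3b_nt = b$cdr3_nt,
                      cdr3a_aa = a$cdr3, cdr3b_aa = b$cdr3,
                      stringsAsFactors = FALSE)
  }
  out$clone_id <- clone_key(out$cdr3a_nt, out$cdr3b_nt)
  rownames(out) <- NULL
  class(out) <- c("cell_clonotypes", "data.frame")
  out
}

#' Build a per-sample repertoire (the "TCR pool")
#'
#' Tallies clonotype-bearing cells of one sample into clone counts. The
#' pool size is the number of clonotype-bearing cells, the denominator for
#' all clone frequencies.
#'
#' @param cell_clonotypes Output of \code{\link{assemble_clonotypes}}.
#' @param cells A \code{cell_table} giving sample membership of barcodes.
#' @param sample_id Which sample to tally.
#' @return A \code{repertoire}: list with sample_id, clones (data frame
#'   clone_id, cdr3a_nt, cdr3b_nt, cdr3a_aa, cdr3b_aa, count) and pool_size.
#' @export
build_repertoire <- function(cell_clonotypes, cells, sample_id) {
  stopifnot(inherits(cells, "cell_table"))
  if (!sample_id %in% cells$sample_id) {
    stop("lookup error: unknown sample_id '", sample_id, "'", call. = FALSE)
  }
  bcs <- cells$barcode[cells$sample_id == sample_id]
  cc <- cell_clonotypes[cell_clonotypes$barcode %in% bcs, , drop = FALSE]
  if (nrow(cc)) {
    counts <- table(cc$clone_id)
    first <- cc[!duplicated(cc$clone_id), , drop = FALSE]
    first <- first[order(first$clone_id, method = "radix"), , drop = FALSE]
    clones <- data.frame(
      clone_id = first$clone_id,
      cdr3a_nt = first$cdr3a_nt, cdr3b_nt = first$cdr3b_nt,
      cdr3a_aa = first$cdr3a_aa, cdr3b_aa = first$cdr3b_aa,
      count = as.integer(counts[first$clone_id]),
      stringsAsFactors = FALSE
    )
    rownames(clones) <- NULL
  } else {
    clones <- data.frame(clone_id = character(), cdr3a_nt = character(),
                         cdr3b_nt = character(), cdr3a_aa = character(),
                         cdr3b_aa = character(), count = integer(),
                         stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, clones = clones,
                 pool_size = sum(clones$count)),
            class = "repertoire")
}

#' Build a repertoire directly from a clone-count table
#'
#' Convenience constructor for tests and simulations.
#'
#' @param sample_id Sample name.
#' @param counts Named integer vector: clone_id -> cell count.
#' @param meta Optional data frame with clone_id and the four CDR3 columns.
#' @return A \code{repertoire}.
#' @export
repertoire_from_counts <- function(sample_id, counts, meta = NULL) {
  stopifnot(all(counts >= 1))
  ids <- names(counts)
  if (is.null(ids) && length(counts)) {
    stop("counts must be named by clone_id", call. = FALSE)
  }
  ord <- order(ids, method = "radix")
  n <- length(ids)
  clones <- data.frame(clone_id = ids[ord],
                       cdr3a_nt = character(n), cdr3b_nt = character(n),
                       cdr3a_aa = character(n), cdr3b_aa = character(n),
                       count = as.integer(counts[ord]),
                       stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    i <- match(clones$clone_id, meta$clone_id)
    for (col in c("cdr3a_nt", "cdr3b_nt", "cdr3a_aa", "cdr3b_aa")) {
      if (col %in% names(meta)) clones[[col]] <- ifelse(is.na(i), "", meta[[col]][i])
    }
  }
  structure(list(sample_id = sample_id, clones = clones,
                 pool_size = sum(clones$count)),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> sample '%s': %d clones, pool size %d\n",
              x$sample_id, nrow(x$clones), x$pool_size))
  invisible(x)
}

#' Expansion bin boundaries
#'
#' Six ordered bins: unique (exactly one cell, checked before any frequency
#' rule), then by clone frequency f: rare f < 0.001, small 0.001 <= f < 0.01,
#' medium 0.01 <= f < 0.02, large 0.02 <= f < 0.05, hyperexpanded f >= 0.05.
#' Every boundary is half-open with the upper bin taking the boundary value.
#'
#' @param boundaries Strictly increasing frequency boundaries separating
#'   rare/small/medium/large/hyperexpanded.
#' @return An \code{expansion_binning} object.
#' @export
expansion_binning <- function(boundaries = c(0.001, 0.01, 0.02, 0.05)) {
  stopifnot(length(boundaries) == 4L, all(diff(boundaries) > 0),
            all(boundaries > 0), all(boundaries < 1))
  structure(list(boundaries = boundaries,
                 bins = c("unique", "rare", "small", "medium", "large",
                          "hyperexpanded")),
            class = "expansion_binning")
}

#' Classify clonal expansion
#'
#' @param rep A non-empty \code{repertoire}.
#' @param binning An \code{expansion_binning}.
#' @return Data frame clone_id, count, frequency, bin (ordered factor
#'   unique < rare < small < medium < large < hyperexpanded).
#' @export
bin_expansion <- function(rep, binning = expansion_binning()) {
  stopifnot(inherits(rep, "repertoire"))
  if (rep$pool_size < 1L) stop("empty repertoire", call. = FALSE)
  b <- binning$boundaries
  f <- rep$clones$count / rep$pool_size
  bin <- ifelse(rep$clones$count == 1L, "unique",
         ifelse(f < b[1], "rare",
         ifelse(f < b[2], "small",
         ifelse(f < b[3], "medium",
         ifelse(f < b[4], "large", "hyperexpanded")))))
  data.frame(clone_id = rep$clones$clone_id, count = rep$clones$count,
             frequency = f,
             bin = factor(bin, levels = binning$bins, ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Cell-type composition of expanded clones
#'
#' Fractions of cell-type labels among the cells belonging to expanded
#' clones (any bin other than unique, i.e. clone count > 1) of one sample.
#'
#' @param rep The sample's \code{repertoire}.
#' @param cells A \code{cell_table}.
#' @param cell_clonotypes Output of \code{\link{assemble_clonotypes}}.
#' @return Named numeric vector of fractions summing to 1 (empty when the
#'   sample has no expanded clone).
#' @export
expanded_composition <- function(rep, cells, cell_clonotypes) {
  stopifnot(inherits(rep, "repertoire"), inherits(cells, "cell_table"))
  expanded <- rep$clones$clone_id[rep$clones$count > 1L]
  if (!length(expanded)) return(stats::setNames(numeric(0), character(0)))
  sub <- cells[cells$sample_id == rep$sample_id, , drop = FALSE]
  cc <- cell_clonotypes[cell_clonotypes$barcode %in% sub$barcode &
                          cell_clonotypes$clone_id %in% expanded, ,
                        drop = FALSE]
  labels <- sub$cell_type[match(cc$barcode, sub$barcode)]
  tab <- table(labels)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Write a binned repertoire as TSV
#' @param rep A \code{repertoire}.
#' @param path Output TSV path.
#' @param binning Binning used for the bin column.
#' @export
write_repertoire <- function(rep, path, binning = expansion_binning()) {
  tab <- bin_expansion(rep, binning)
  tab$sample_id <- rep$sample_id
  i <- match(tab$clone_id, rep$clones$clone_id)
  for (col in c("cdr3a_nt", "cdr3b_nt", "cdr3a_aa", "cdr3b_aa")) {
    tab[[col]] <- rep$clones[[col]][i]
  }
  utils::write.table(tab[c("sample_id", "clone_id", "cdr3a_nt", "cdr3b_nt",
                           "cdr3a_aa", "cdr3b_aa", "count", "frequency",
                           "bin")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a repertoire written by \code{write_repertoire}
#' @param path TSV path.
#' @return A \code{repertoire}.
#' @export
read_repertoire_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty repertoire file: ", path, call. = FALSE)
  repertoire_from_counts(df$sample_id[1],
                         stats::setNames(df$count, df$clone_id),
                         meta = df)
}
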