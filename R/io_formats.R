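# Readers/writers for every external format the pipeline touches.
# All downstream modules operate only on the in-memory types built here.

#' Construct a validated expression matrix
#'
#' Wraps a sparse genes x cells count matrix together with its sample
#' identifier. Gene identity is the symbol string, case-sensitive; barcode
#' identity is the literal string including any "-1" suffix.
#'
#' @param counts A matrix coercible to \code{\link[Matrix]{dgCMatrix-class}}
#'   with gene symbols as rownames and cell barcodes as colnames.
#' @param sample_id Single string naming the sample.
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{counts} (sparse dgCMatrix), \code{genes}, \code{barcodes},
#'   \code{sample_id}.
#' @export
expression_matrix <- function(counts, sample_id) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop("sample_id must be a single string", call. = FALSE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- rownames(counts)
  barcodes <- colnames(counts)
  if (is.null(genes) || length(genes) == 0L) {
    stop("gene list must be non-empty (rownames required)", call. = FALSE)
  }
  if (is.null(barcodes)) {
    # Matrix drops colnames when subsetting to zero columns
    if (ncol(counts) == 0L) {
      barcodes <- character(0)
      colnames(counts) <- barcodes
    } else {
      stop("barcodes required as colnames", call. = FALSE)
    }
  }
  if (anyDuplicated(barcodes)) {
    stop("validation error: duplicate barcodes within sample '", sample_id, "'",
         call. = FALSE)
  }
  if (any(counts@x < 0)) {
    stop("validation error: negative counts in sample '", sample_id, "'",
         call. = FALSE)
  }
  structure(
    list(counts = counts, genes = genes, barcodes = barcodes,
         sample_id = sample_id),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> sample '%s': %d genes x %d cells, total %g\n",
              x$sample_id, length(x$genes), length(x$barcodes),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

# Open plain or gzip text transparently (10x convention).
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_lines_any <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a 10x-style Matrix Market triplet
#'
#' Reads a sparse count matrix from a Matrix Market coordinate file plus
#' one-entry-per-line feature and barcode files (plain or gzip). Feature
#' files may be 10x-style TSV (id, symbol, type); the second column is used
#' as the gene symbol when present.
#'
#' @param matrix_path Path to the .mtx (or .mtx.gz) file.
#' @param features_path Path to the features/genes file.
#' @param barcodes_path Path to the barcode file.
#' @param sample_id Sample identifier attached to the result.
#' @return An \code{expression_matrix}.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             sample_id) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    stop("format error in '", matrix_path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  feat_lines <- read_lines_any(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  feat_fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  genes <- vapply(feat_fields, function(f) if (length(f) >= 2L) f[[2L]] else f[[1L]],
                  character(1))
  barcodes <- read_lines_any(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(genes)) {
    stop("format error: matrix '", matrix_path, "' has ", nrow(m),
         " rows but features file '", features_path, "' has ", length(genes),
         " entries", call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("format error: matrix '", matrix_path, "' has ", ncol(m),
         " columns but barcodes file '", barcodes_path, "' has ",
         length(barcodes), " entries", call. = FALSE)
  }
  dimnames(m) <- list(genes, barcodes)
  expression_matrix(m, sample_id)
}

#' Write an expression matrix as a Matrix Market triplet
#'
#' Inverse of \code{\link{read_mtx_triplet}}; the round trip is the identity.
#'
#' @param x An \code{expression_matrix}.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix, default the sample id.
#' @return Invisibly, a named list of the three paths written.
#' @export
write_mtx_triplet <- function(x, dir, prefix = x$sample_id) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, paste0(prefix, "_matrix.mtx")),
    features = file.path(dir, paste0(prefix, "_features.tsv")),
    barcodes = file.path(dir, paste0(prefix, "_barcodes.tsv"))
  )
  Matrix::writeMM(x$counts, paths$matrix)
  writeLines(x$genes, paths$features)
  writeLines(x$barcodes, paths$barcodes)
  invisible(paths)
}

normalize_bool <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

contig_required_cols <- c("barcode", "chain", "cdr3", "cdr3_nt", "umis",
                          "productive")

#' Read a CellRanger-VDJ-style filtered contig table
#'
#' Parses the \code{filtered_contig_annotations.csv} dialect. Boolean-like
#' fields ("True"/"true"/"TRUE") are normalized to logical; any other value
#' (including "None") becomes \code{FALSE}. Row order is preserved.
#'
#' @param path CSV path (plain or gzip).
#' @return A \code{data.frame} of class \code{contig_table} with columns
#'   barcode, chain, cdr3, cdr3_nt, v_gene, j_gene, umis, reads, productive,
#'   high_confidence.
#' @export
read_contig_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(contig_required_cols, names(df))
  if (length(missing)) {
    stop("format error in '", path, "': missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contig_table(data.frame(
    barcode = df$barcode,
    chain = df$chain,
    cdr3 = df$cdr3,
    cdr3_nt = df$cdr3_nt,
    v_gene = if ("v_gene" %in% names(df)) df$v_gene else "",
    j_gene = if ("j_gene" %in% names(df)) df$j_gene else "",
    umis = as.integer(df$umis),
    reads = if ("reads" %in% names(df)) as.integer(df$reads) else 0L,
    productive = normalize_bool(df$productive),
    high_confidence = if ("high_confidence" %in% names(df)) {
      normalize_bool(df$high_confidence)
    } else TRUE,
    stringsAsFactors = FALSE
  ))
}

#' Construct/validate a contig table
#' @param df Data frame with the contig columns.
#' @return The validated \code{contig_table}.
#' @export
contig_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene",
            "umis", "reads", "productive", "high_confidence")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("contig table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$umis < 0, na.rm = TRUE)) {
    stop("validation error: negative UMI counts", call. = FALSE)
  }
  bad <- df$productive & (!nzchar(df$cdr3_nt) |
                            grepl("[^ACGT]", df$cdr3_nt))
  if (any(bad)) {
    stop("validation error: productive contig with invalid cdr3_nt at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("contig_table", "data.frame")
  df
}

#' Write a contig table as CSV
#' @param x A \code{contig_table}.
#' @param path Output CSV path.
#' @export
write_contig_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cell_tissues <- c("blood", "liver", "tumor")
cell_lineages <- c("CD4", "CD8", "NK", "myeloid", "B", "other")

#' Construct/validate a per-cell annotation table
#'
#' @param df Data frame with columns barcode, sample_id, patient_id, tissue
#'   (one of blood/liver/tumor), replicate (integer >= 1), cell_type,
#'   lineage (CD4/CD8/NK/myeloid/B/other).
#' @return The validated \code{cell_table}.
#' @export
cell_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("barcode", "sample_id", "patient_id", "tissue", "replicate",
            "cell_type", "lineage")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cell table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$tissue %in% cell_tissues)) {
    stop("validation error: tissue values outside {",
         paste(cell_tissues, collapse = ", "), "}", call. = FALSE)
  }
  if (!all(df$lineage %in% cell_lineages)) {
    stop("validation error: lineage values outside {",
         paste(cell_lineages, collapse = ", "), "}", call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L)) {
    stop("validation error: replicate index must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(df[c("barcode", "sample_id")])) {
    stop("validation error: duplicate (barcode, sample_id) pairs",
         call. = FALSE)
  }
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a per-cell annotation TSV
#' @param path TSV path (plain or gzip).
#' @return A \code{cell_table}.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cell_table(df)
}

#' Write a cell table as TSV
#' @param x A \code{cell_table}.
#' @param path Output TSV path.
#' @export
write_cell_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a gene set
#' @param name Set name.
#' @param genes Character vector of gene symbols; deduplicated case-sensitively.
#' @param source Free-text provenance.
#' @return A \code{gene_set} (list with name, genes, source).
#' @export
gene_set <- function(name, genes, source = "") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!nzchar(name) || length(genes) == 0L) {
    stop("gene set must have a name and at least one gene", call. = FALSE)
  }
  structure(list(name = name, genes = genes, source = source),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line, set name, description, then tab-separated gene
#' symbols. Duplicate genes within a line are dropped with a warning.
#'
#' @param path GMT path (plain or gzip).
#' @return Named list of \code{gene_set} objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- read_lines_any(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("format error in '", path, "' line ", i,
           ": GMT lines need name, description and at least one gene",
           call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[[1]], "' contains duplicate genes; deduplicated",
              call. = FALSE)
    }
    sets[[fields[[1]]]] <- gene_set(fields[[1]], genes, source = fields[[2]])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of \code{gene_set} objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$source)) s$source else "na", s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VDJdb-style viral CDR3 reference table
#'
#' TSV with CDR3 amino-acid sequence, chain, epitope and species columns.
#' Column names are configurable via \code{col_map} so both native and
#' VDJdb-dialect headers parse identically; chain values are normalized to
#' TRA/TRB. Duplicate (cdr3_aa, chain, epitope) rows collapse to one.
#'
#' @param path TSV path.
#' @param col_map Named character vector mapping required names
#'   (cdr3_aa, chain, epitope, species) to the file's column names.
#' @return Data frame of class \code{viral_reference} with columns cdr3_aa,
#'   chain, epitope, species, source.
#' @export
read_viral_reference <- function(path,
                                 col_map = c(cdr3_aa = "cdr3_aa",
                                             chain = "chain",
                                             epitope = "epitope",
                                             species = "species")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cdr3_aa", "chain", "epitope", "species")
  missing <- need[!col_map[need] %in% names(df)]
  if (length(missing)) {
    stop("format error in '", path, "': cannot find column(s) ",
         paste(col_map[missing], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    cdr3_aa = df[[col_map[["cdr3_aa"]]]],
    chain = df[[col_map[["chain"]]]],
    epitope = df[[col_map[["epitope"]]]],
    species = df[[col_map[["species"]]]],
    source = if ("source" %in% names(df)) df$source else rep("", nrow(df)),
    stringsAsFactors = FALSE
  )
  viral_reference(out)
}

#' Construct/validate a viral reference table
#' @param df Data frame with cdr3_aa, chain, epitope, species (and optional
#'   source) columns.
#' @return The validated, deduplicated \code{viral_reference}.
#' @export
viral_reference <- function(df) {
  if (!"source" %in% names(df)) df$source <- rep("", nrow(df))
  chain_map <- c(TRA = "TRA", TRB = "TRB", A = "TRA", B = "TRB",
                 alpha = "TRA", beta = "TRB")
  mapped <- chain_map[as.character(df$chain)]
  if (nrow(df) && anyNA(mapped)) {
    stop("validation error: unmappable chain value(s): ",
         paste(unique(df$chain[is.na(mapped)]), collapse = ", "),
         call. = FALSE)
  }
  df$chain <- unname(mapped)
  if (nrow(df) && any(!nzchar(df$cdr3_aa))) {
    stop("validation error: empty cdr3_aa in viral reference", call. = FALSE)
  }
  df <- df[!duplicated(df[c("cdr3_aa", "chain", "epitope")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("viral_reference", "data.frame")
  df
}

#' Write a viral reference table as TSV
#' @param x A \code{viral_reference}.
#' @param path Output TSV path.
#' @export
write_viral_reference <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
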