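# Tumor-reactivity nomination: filter eligible TILs, take the top
# percentile of each signature's score distribution, intersect per lineage
# into a consensus list, and track consensus clonotypes across sites.
#
# Tregs, MAIT, gamma-delta and cycling T cells are excluded up front:
# Tregs/gd/cycling by the user's cell-type labels (annotation is upstream
# curation), MAIT mechanically by a productive TRAV1-2 alpha chain.

#' Nomination configuration
#'
#' @param top_cell_percent Top percentile of eligible-cell scores nominated
#'   per signature (default 5).
#' @param treg_labels,gd_labels,cycling_labels Cell-type label sets marking
#'   regulatory, gamma-delta and proliferating/cycling T cells.
#' @param mait_v_gene V-gene identifying the semi-invariant MAIT alpha
#'   chain (allele suffixes after "*" are ignored).
#' @param min_cells_warn Below this many eligible cells a signature gets a
#'   small-pool fallback: nominate the top max(1, round(p/100 * n)) cells.
#' @return A \code{nomination_config}.
#' @export
nomination_config <- function(top_cell_percent = 5,
                              treg_labels = c("Treg", "Tregs"),
                              gd_labels = c("gdT", "gamma-delta T"),
                              cycling_labels = c("cycling T",
                                                 "proliferating T"),
                              mait_v_gene = "TRAV1-2",
                              min_cells_warn = 20L) {
  stopifnot(top_cell_percent > 0, top_cell_percent < 100)
  structure(list(top_cell_percent = top_cell_percent,
                 treg_labels = treg_labels, gd_labels = gd_labels,
                 cycling_labels = cycling_labels,
                 mait_v_gene = mait_v_gene,
                 min_cells_warn = as.integer(min_cells_warn)),
            class = "nomination_config")
}

strip_allele <- function(v) sub("\\*.*$", "", v)

#' Filter eligible tumor-infiltrating T cells
#'
#' Keeps tumor-tissue alpha-beta T cells (lineage CD4 or CD8) carrying an
#' assembled paired clonotype, then excludes Tregs, MAIT cells (productive
#' TRAV1-2 alpha contig), gamma-delta labels, and cycling labels. Every
#' non-eligible cell is logged with exactly one primary reason, in the
#' order: non_tumor_tissue, non_t_cell, gamma_delta, no_paired_tcr, treg,
#' mait, cycling.
#'
#' @param cells A \code{cell_table}.
#' @param cell_clonotypes Output of \code{\link{assemble_clonotypes}} (all
#'   samples combined).
#' @param contigs A \code{contig_table} (all samples; used for the MAIT
#'   rule).
#' @param config A \code{nomination_config}.
#' @return List with \code{eligible} (character barcodes) and
#'   \code{exclusion_log} (data frame barcode, reason).
#' @export
filter_tils <- function(cells, cell_clonotypes, contigs,
                        config = nomination_config()) {
  stopifnot(inherits(cells, "cell_table"))
  mait_bcs <- unique(contigs$barcode[
    contigs$productive & contigs$chain == "TRA" &
      strip_allele(contigs$v_gene) == config$mait_v_gene])
  has_pair <- cells$barcode %in% cell_clonotypes$barcode
  is_t <- cells$lineage %in% c("CD4", "CD8")
  reason <- rep(NA_character_, nrow(cells))
  reason[cells$tissue != "tumor"] <- "non_tumor_tissue"
  pick <- function(cond, r) {
    sel <- is.na(reason) & cond
    reason[sel] <<- r
  }
  pick(!is_t & !(cells$cell_type %in% config$gd_labels), "non_t_cell")
  pick(cells$cell_type %in% config$gd_labels, "gamma_delta")
  pick(!has_pair, "no_paired_tcr")
  pick(cells$cell_type %in% config$treg_labels, "treg")
  pick(cells$barcode %in% mait_bcs, "mait")
  pick(cells$cell_type %in% config$cycling_labels, "cycling")
  eligible <- cells$barcode[is.na(reason)]
  log <- data.frame(barcode = cells$barcode[!is.na(reason)],
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  list(eligible = eligible, exclusion_log = log)
}

# top-percentile threshold by nearest rank: the k = ceil(p/100 * n)
# highest score; cells at or above it are nominated, so with n distinct
# scores exactly k cells pass and threshold ties only ever enlarge the set
nearest_rank_threshold <- function(scores, top_percent) {
  n <- length(scores)
  k <- min(n, max(1L, ceiling(top_percent / 100 * n)))
  sort(scores, decreasing = TRUE)[k]
}

#' Nominate top-scoring cells per signature
#'
#' For each signature, ranking is restricted to eligible cells of the
#' signature's declared lineage with a non-missing score. Cells scoring at
#' or above the nearest-rank (100 - p)th percentile are nominated; ties at
#' the threshold are all included, so a set may exceed p percent. Pools
#' smaller than \code{min_cells_warn} fall back (with a warning) to the
#' top \code{max(1, round(p/100 * n))} cells.
#'
#' @param score_table A \code{score_table} over the eligible cells' matrix.
#' @param eligible Character vector of eligible barcodes
#'   (\code{\link{filter_tils}}).
#' @param lineage_map Named character vector signature -> "CD4"/"CD8".
#' @param cells A \code{cell_table} (lineage lookup).
#' @param config A \code{nomination_config}.
#' @return Named list per signature: barcodes, scores, threshold,
#'   n_eligible, lineage.
#' @export
nominate <- function(score_table, eligible, lineage_map, cells,
                     config = nomination_config()) {
  stopifnot(inherits(score_table, "score_table"))
  missing_sig <- setdiff(names(lineage_map), colnames(score_table$scores))
  if (length(missing_sig)) {
    stop("configuration error: signature(s) missing from score table: ",
         paste(missing_sig, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (sig in names(lineage_map)) {
    lin <- lineage_map[[sig]]
    pool_bcs <- intersect(eligible,
                          cells$barcode[cells$lineage == lin])
    pool_bcs <- intersect(pool_bcs, rownames(score_table$scores))
    sm <- score_table$scores[pool_bcs, sig, drop = FALSE]
    s <- stats::setNames(sm[, 1L], rownames(sm))
    s <- s[!is.na(s)]
    n <- length(s)
    if (n == 0L) {
      out[[sig]] <- list(barcodes = character(), scores = numeric(),
                         threshold = NA_real_, n_eligible = 0L,
                         lineage = lin)
      next
    }
    if (n < config$min_cells_warn) {
      warning("signature '", sig, "': only ", n,
              " eligible cells; nominating top max(1, round(",
              config$top_cell_percent, "% of n))", call. = FALSE)
      k <- max(1L, round(config$top_cell_percent / 100 * n))
      ord <- order(-s, names(s), method = "radix")
      sel <- names(s)[ord[seq_len(k)]]
      thr <- min(s[sel])
    } else {
      thr <- nearest_rank_threshold(s, config$top_cell_percent)
      sel <- names(s)[s >= thr]
      if (length(unique(s)) == 1L) {
        warning("signature '", sig,
                "': all scores equal; every eligible cell nominated",
                call. = FALSE)
      }
    }
    out[[sig]] <- list(barcodes = sel, scores = s[sel], threshold = thr,
                       n_eligible = n, lineage = lin)
  }
  out
}

#' Consensus nomination per lineage
#'
#' Consensus barcodes are the intersection of the nominated sets of each
#' lineage's signatures (default two per lineage; generalizes to any
#' number). Consensus clonotypes are the clonotypes of consensus barcodes,
#' deduplicated and ranked by (number of nominating signatures descending,
#' mean AUC over the lineage's signatures descending, clone key).
#'
#' @param nominations Output of \code{\link{nominate}}.
#' @param pairing Named list lineage -> character vector of signatures,
#'   e.g. \code{list(CD8 = c("NeoTCR8", "TR30"), CD4 = c("NeoTCR4",
#'   "ExReCD4"))}.
#' @param cell_clonotypes Output of \code{\link{assemble_clonotypes}}.
#' @param score_table The \code{score_table} used for nomination.
#' @return A \code{nomination_result}: per-lineage list with
#'   \code{barcodes} and \code{clonotypes} (ranked data frame), plus the
#'   per-signature nominations.
#' @export
consensus <- function(nominations, pairing, cell_clonotypes, score_table) {
  missing_sig <- setdiff(unlist(pairing), names(nominations))
  if (length(missing_sig)) {
    stop("configuration error: no nomination for signature(s): ",
         paste(missing_sig, collapse = ", "), call. = FALSE)
  }
  res <- list()
  for (lin in names(pairing)) {
    sigs <- pairing[[lin]]
    sets <- lapply(nominations[sigs], `[[`, "barcodes")
    cons <- Reduce(intersect, sets)
    if (!length(cons)) {
      res[[lin]] <- list(barcodes = character(),
                         clonotypes = data.frame(
                           clone_id = character(), n_signatures = integer(),
                           mean_auc = numeric(), n_cells = integer(),
                           stringsAsFactors = FALSE),
                         note = "empty consensus")
      next
    }
    cc <- cell_clonotypes[match(cons, cell_clonotypes$barcode), ,
                          drop = FALSE]
    per_clone <- split(seq_along(cons), cc$clone_id)
    rows <- lapply(names(per_clone), function(cid) {
      idx <- per_clone[[cid]]
      bcs <- cons[idx]
      n_sig <- sum(vapply(sets, function(s) any(bcs %in% s), logical(1)))
      sc <- score_table$scores[bcs, sigs, drop = FALSE]
      data.frame(clone_id = cid, n_signatures = n_sig,
                 mean_auc = mean(sc, na.rm = TRUE),
                 n_cells = length(bcs), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$n_signatures, -tab$mean_auc, tab$clone_id,
                     method = "radix"), , drop = FALSE]
    rownames(tab) <- NULL
    res[[lin]] <- list(barcodes = cons, clonotypes = tab)
  }
  structure(list(lineages = res, per_signature = nominations),
            class = "nomination_result")
}

#' Track consensus clonotypes across blood/liver repertoires
#'
#' @param result A \code{nomination_result}.
#' @param site_repertoires Named list of \code{repertoire}s (blood, liver
#'   replicates).
#' @return Long data frame lineage, clone_id, sample_id, count, frequency
#'   (0 where absent; empty when the consensus is empty).
#' @export
track_consensus <- function(result, site_repertoires) {
  stopifnot(inherits(result, "nomination_result"))
  rows <- lapply(names(result$lineages), function(lin) {
    tab <- result$lineages[[lin]]$clonotypes
    if (!nrow(tab)) return(NULL)
    tr <- track_clones(tab, site_repertoires)
    tr$lineage <- lin
    tr
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(clone_id = character(), sample_id = character(),
                      count = integer(), frequency = numeric(),
                      lineage = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a nomination result (JSON + ranked clonotype TSV)
#' @param result A \code{nomination_result}.
#' @param prefix Writes \code{<prefix>.json} and
#'   \code{<prefix>_clonotypes.tsv}.
#' @export
write_nomination_result <- function(result, prefix) {
  js <- list(
    per_signature = lapply(result$per_signature, function(x) {
      list(barcodes = x$barcodes, threshold = x$threshold,
           n_eligible = x$n_eligible, lineage = x$lineage)
    }),
    consensus = lapply(result$lineages, function(x) {
      list(barcodes = x$barcodes, clonotypes = x$clonotypes)
    })
  )
  jsonlite::write_json(js, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tabs <- lapply(names(result$lineages), function(lin) {
    tab <- result$lineages[[lin]]$clonotypes
    if (nrow(tab)) cbind(lineage = lin, tab) else NULL
  })
  tabs <- Filter(Negate(is.null), tabs)
  full <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(lineage = character(), clone_id = character(),
               n_signatures = integer(), mean_auc = numeric(),
               n_cells = integer())
  utils::write.table(full, paste0(prefix, "_clonotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
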