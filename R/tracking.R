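# Cross-site clone tracking and viral bystander annotation.
# Tracking matches clones on nucleotide CDR3 identity (the clonotype
# definition); viral annotation matches on amino acids, because public
# CDR3-epitope references store amino-acid sequences. Without patient HLA
# types a viral hit is only a PUTATIVE bystander flag.

#' Top expanded clones of a repertoire
#'
#' Clones sorted by descending cell count, ties broken by lexicographic
#' clone key; returns the first \code{min(n, distinct clones)}.
#'
#' @param rep A non-empty \code{repertoire}.
#' @param n Number of clones to return (default 20).
#' @return Data frame of clone rows (clone_id, CDR3 columns, count) in rank
#'   order.
#' @export
top_expanded <- function(rep, n = 20L) {
  stopifnot(inherits(rep, "repertoire"), n >= 1L)
  if (rep$pool_size < 1L) stop("empty repertoire", call. = FALSE)
  cl <- rep$clones
  ord <- order(-cl$count, cl$clone_id, method = "radix")
  out <- cl[ord[seq_len(min(n, nrow(cl)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track clones across repertoires
#'
#' For each clone and repertoire reports frequency = count / pool_size, and
#' exactly 0 where the clone is absent.
#'
#' @param clones Data frame with at least a clone_id column (e.g. output of
#'   \code{\link{top_expanded}}).
#' @param repertoires Non-empty named list of \code{repertoire} objects.
#' @return Long data frame: clone_id, sample_id, count, frequency.
#' @export
track_clones <- function(clones, repertoires) {
  if (!length(repertoires)) stop("repertoires must be non-empty", call. = FALSE)
  if (!nrow(clones)) {
    return(data.frame(clone_id = character(), sample_id = character(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(repertoires, function(rep) {
    i <- match(clones$clone_id, rep$clones$clone_id)
    count <- ifelse(is.na(i), 0L, rep$clones$count[i])
    data.frame(clone_id = clones$clone_id,
               sample_id = rep$sample_id,
               count = as.integer(count),
               frequency = if (rep$pool_size > 0) count / rep$pool_size else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate clonotypes against a viral CDR3 reference
#'
#' Default mode \code{beta_aa}: a clone matches iff its CDR3 beta amino-acid
#' sequence equals a TRB reference entry exactly. \code{alpha_or_beta_aa}
#' accepts a hit on either chain; \code{paired_aa} requires both chains to
#' hit. When several reference rows hit, all are counted and the first by
#' (species, epitope) order is reported as primary, so the annotation does
#' not depend on reference row order.
#'
#' @param clones Data frame with clone_id, cdr3a_aa, cdr3b_aa columns.
#' @param ref A \code{viral_reference}.
#' @param mode One of "beta_aa", "alpha_or_beta_aa", "paired_aa".
#' @return Data frame clone_id, viral_match (logical), epitope, species
#'   (NA when unmatched), n_hits.
#' @export
annotate_viral <- function(clones, ref,
                           mode = c("beta_aa", "alpha_or_beta_aa",
                                    "paired_aa")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "viral_reference"))
  ref <- as.data.frame(ref)
  ref <- ref[order(ref$species, ref$epitope, method = "radix"), , drop = FALSE]
  ref_a <- ref[ref$chain == "TRA", , drop = FALSE]
  ref_b <- ref[ref$chain == "TRB", , drop = FALSE]
  hit_rows <- function(aa, tab) which(tab$cdr3_aa == aa)
  res <- lapply(seq_len(nrow(clones)), function(i) {
    hb <- hit_rows(clones$cdr3b_aa[i], ref_b)
    ha <- hit_rows(clones$cdr3a_aa[i], ref_a)
    hits <- switch(mode,
      beta_aa = ref_b[hb, , drop = FALSE],
      alpha_or_beta_aa = rbind(ref_b[hb, , drop = FALSE],
                               ref_a[ha, , drop = FALSE]),
      paired_aa = if (length(hb) && length(ha)) {
        rbind(ref_b[hb, , drop = FALSE], ref_a[ha, , drop = FALSE])
      } else ref_b[integer(0), , drop = FALSE]
    )
    if (nrow(hits)) {
      hits <- hits[order(hits$species, hits$epitope, method = "radix"), ,
                   drop = FALSE]
      data.frame(viral_match = TRUE, epitope = hits$epitope[1],
                 species = hits$species[1], n_hits = nrow(hits),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(viral_match = FALSE, epitope = NA_character_,
                 species = NA_character_, n_hits = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- cbind(data.frame(clone_id = clones$clone_id,
                          stringsAsFactors = FALSE),
               do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Build a cross-site tracking report for one patient's top tumor clones
#'
#' Combines \code{\link{top_expanded}}, \code{\link{track_clones}} and
#' \code{\link{annotate_viral}}: tumor clone frequencies, per-site
#' frequencies (0 where absent), putative viral bystander flags, and a
#' per-site sharedness summary (how many of the top clones are detected).
#'
#' @param tumor_rep The tumor \code{repertoire}.
#' @param site_repertoires Named list of blood/liver \code{repertoire}s.
#' @param viral_ref Optional \code{viral_reference}.
#' @param n Number of top tumor clones (default 20).
#' @param patient_id Carried into the report rows.
#' @param mode Viral matching mode, see \code{\link{annotate_viral}}.
#' @return List of class \code{tracking_report}: \code{clones} (wide data
#'   frame: one row per clone with tumor_frequency, one frequency column
#'   per site, viral annotation, bystander flag), \code{tracking} (the long
#'   table), \code{sharedness} (named count of top clones detected per
#'   site).
#' @export
tracking_report <- function(tumor_rep, site_repertoires, viral_ref = NULL,
                            n = 20L, patient_id = NA_character_,
                            mode = "beta_aa") {
  top <- top_expanded(tumor_rep, n)
  long <- track_clones(top, site_repertoires)
  wide <- data.frame(patient_id = patient_id, clone_id = top$clone_id,
                     cdr3b_aa = top$cdr3b_aa,
                     tumor_frequency = top$count / tumor_rep$pool_size,
                     stringsAsFactors = FALSE)
  for (rep in site_repertoires) {
    i <- match(top$clone_id, rep$clones$clone_id)
    freq <- ifelse(is.na(i), 0,
                   rep$clones$count[i] / max(rep$pool_size, 1L))
    freq[is.na(freq)] <- 0
    wide[[paste0("freq_", rep$sample_id)]] <- freq
  }
  if (!is.null(viral_ref)) {
    ann <- annotate_viral(top, viral_ref, mode)
    wide$viral_match <- ann$viral_match
    wide$epitope <- ann$epitope
    wide$species <- ann$species
  } else {
    wide$viral_match <- FALSE
    wide$epitope <- NA_character_
    wide$species <- NA_character_
  }
  wide$putative_bystander <- wide$viral_match
  shared <- vapply(site_repertoires, function(rep) {
    sum(top$clone_id %in% rep$clones$clone_id)
  }, integer(1))
  names(shared) <- vapply(site_repertoires, `[[`, character(1), "sample_id")
  structure(list(clones = wide, tracking = long, sharedness = shared),
            class = "tracking_report")
}

#' Write a tracking report (TSV + JSON)
#' @param report A \code{tracking_report}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @export
write_tracking_report <- function(report, prefix) {
  utils::write.table(report$clones, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(clones = report$clones,
                            sharedness = as.list(report$sharedness)),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}
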