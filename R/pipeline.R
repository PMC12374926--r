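# End-to-end pipeline: qc -> clonotypes/repertoire -> diversity ->
# tracking -> scoring -> nomination -> concordance, driven by a single
# manifest. All stage outputs land under the output directory; the run log
# materializes every configuration value (and no wall-clock timestamps) so
# a rerun with the same manifest is byte-identical.

#' Validate a pipeline manifest
#'
#' A manifest is a list (or JSON file) with \code{samples} (each:
#' sample_id, matrix, features, barcodes, contigs paths), \code{cells},
#' \code{gene_sets} (GMT), \code{viral_reference} paths, and optional
#' \code{config} overrides (qc thresholds, scoring, nomination, pairing,
#' top_n).
#'
#' @param manifest List or path to a JSON manifest.
#' @return The validated manifest list (defaults materialized).
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  }
  for (field in c("samples", "cells", "gene_sets", "viral_reference")) {
    if (is.null(manifest[[field]])) {
      stop("manifest validation: missing field '", field, "'",
           call. = FALSE)
    }
  }
  ids <- vapply(manifest$samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("manifest validation: duplicate sample ids", call. = FALSE)
  }
  for (s in manifest$samples) {
    for (f in c("matrix", "features", "barcodes", "contigs")) {
      if (is.null(s[[f]]) || !file.exists(s[[f]])) {
        stop("manifest validation: sample '", s$sample_id,
             "' missing or nonexistent path for '", f, "'", call. = FALSE)
      }
    }
  }
  for (f in c("cells", "gene_sets", "viral_reference")) {
    if (!file.exists(manifest[[f]])) {
      stop("manifest validation: path does not exist: ", manifest[[f]],
           call. = FALSE)
    }
  }
  cfg <- manifest$config
  if (is.null(cfg)) cfg <- list()
  if (is.null(cfg$qc)) cfg$qc <- unclass(qc_thresholds())
  if (is.null(cfg$scoring)) cfg$scoring <- unclass(scoring_config())
  if (is.null(cfg$nomination)) cfg$nomination <- unclass(nomination_config())
  if (is.null(cfg$pairing)) {
    cfg$pairing <- list(CD8 = c("NeoTCR8", "TR30"),
                        CD4 = c("NeoTCR4", "ExReCD4"))
  }
  if (is.null(cfg$top_n)) cfg$top_n <- 20L
  if (is.null(cfg$seed)) cfg$seed <- 1L
  manifest$config <- cfg
  manifest
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

cbind_expression <- function(matrices, sample_id) {
  genes <- matrices[[1]]$genes
  for (m in matrices) stopifnot(identical(m$genes, genes))
  expression_matrix(do.call(cbind, lapply(matrices, `[[`, "counts")),
                    sample_id)
}

#' Run the full pipeline from a manifest
#'
#' @param manifest Manifest list or JSON path (see
#'   \code{\link{validate_manifest}}).
#' @param out_dir Output directory for all stage reports.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(manifest, out_dir) {
  manifest <- validate_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- manifest$config
  qc_thr <- do.call(qc_thresholds, cfg$qc)
  sc_cfg <- do.call(scoring_config, cfg$scoring)
  nom_cfg <- do.call(nomination_config, cfg$nomination)
  log <- list(package_version = as.character(utils::packageVersion("immunosite")),
              config = cfg,
              samples = vapply(manifest$samples, `[[`, character(1),
                               "sample_id"))

  # io + qc
  cells_all <- stage("io", read_cell_table(manifest$cells))
  gene_sets <- stage("io", read_gmt(manifest$gene_sets))
  viral_ref <- stage("io", read_viral_reference(manifest$viral_reference))
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  matrices <- list()
  contigs_list <- list()
  counts_log <- list()
  for (s in manifest$samples) {
    sid <- s$sample_id
    m <- stage("io", read_mtx_triplet(s$matrix, s$features, s$barcodes, sid))
    res <- stage("qc", apply_qc(m, qc_thr))
    matrices[[sid]] <- res$matrix
    write_qc_report(res$report, file.path(qc_dir, paste0(sid, "_qc.json")))
    contigs_list[[sid]] <- stage("io", read_contig_table(s$contigs))
    counts_log[[sid]] <- c(cells_in = res$report$cells_in,
                           cells_out = res$report$cells_out)
  }
  contigs <- contig_table(do.call(rbind, lapply(contigs_list,
                                                as.data.frame)))
  kept <- unlist(lapply(matrices, `[[`, "barcodes"), use.names = FALSE)
  cells <- cell_table(as.data.frame(cells_all)[cells_all$barcode %in% kept, ,
                                               drop = FALSE])

  # repertoire
  rep_dir <- file.path(out_dir, "repertoire")
  dir.create(rep_dir, showWarnings = FALSE)
  cc <- stage("repertoire", assemble_clonotypes(contigs))
  cc <- cc[cc$barcode %in% kept, , drop = FALSE]
  repertoires <- list()
  for (sid in names(matrices)) {
    rep <- stage("repertoire", build_repertoire(cc, cells, sid))
    repertoires[[sid]] <- rep
    if (rep$pool_size > 0) {
      write_repertoire(rep, file.path(rep_dir, paste0(sid, "_clones.tsv")))
    }
  }

  # diversity
  div_dir <- file.path(out_dir, "diversity")
  dir.create(div_dir, showWarnings = FALSE)
  d50_tab <- do.call(rbind, lapply(repertoires, function(rep) {
    if (rep$pool_size < 1) return(NULL)
    d <- d50(rep)
    data.frame(sample_id = rep$sample_id, d50_k = d$k, d50_index = d$index,
               pool_size = rep$pool_size, n_clones = nrow(rep$clones))
  }))
  utils::write.table(d50_tab, file.path(div_dir, "d50.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  curves <- do.call(rbind, lapply(repertoires, function(rep) {
    if (rep$pool_size < 1) return(NULL)
    cv <- rarefaction(rep)
    cbind(sample_id = rep$sample_id, as.data.frame(cv))
  }))
  utils::write.table(curves, file.path(div_dir, "rarefaction.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(jaccard_matrix(repertoires),
                     file.path(div_dir, "jaccard.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  # tracking per patient
  trk_dir <- file.path(out_dir, "tracking")
  dir.create(trk_dir, showWarnings = FALSE)
  tracking <- list()
  for (pat in sort(unique(cells$patient_id))) {
    pat_samples <- unique(cells$sample_id[cells$patient_id == pat])
    tumor_sid <- pat_samples[vapply(pat_samples, function(s) {
      any(cells$tissue[cells$sample_id == s] == "tumor")
    }, logical(1))]
    if (!length(tumor_sid)) next
    sites <- repertoires[setdiff(pat_samples, tumor_sid)]
    tr <- stage("tracking",
                tracking_report(repertoires[[tumor_sid[1]]], sites,
                                viral_ref, n = cfg$top_n, patient_id = pat))
    tracking[[pat]] <- tr
    write_tracking_report(tr, file.path(trk_dir, paste0(pat, "_tracking")))
  }

  # scoring over tumor cells
  score_dir <- file.path(out_dir, "scores")
  dir.create(score_dir, showWarnings = FALSE)
  tumor_sids <- unique(cells$sample_id[cells$tissue == "tumor"])
  scores <- NULL
  if (length(tumor_sids)) {
    tumor_mat <- cbind_expression(matrices[tumor_sids], "tumor_combined")
    scores <- stage("scoring",
                    score_matrix(tumor_mat, gene_sets, method = "auc",
                                 config = sc_cfg))
    write_score_table(scores, file.path(score_dir, "tumor_auc"))
  }

  # nomination
  nom_dir <- file.path(out_dir, "nomination")
  dir.create(nom_dir, showWarnings = FALSE)
  nomination <- NULL
  if (!is.null(scores)) {
    til <- stage("nomination", filter_tils(cells, cc, contigs, nom_cfg))
    pairing <- lapply(cfg$pairing, unlist)
    lineage_map <- stats::setNames(
      rep(names(pairing), vapply(pairing, length, integer(1))),
      unlist(pairing))
    lineage_map <- as.list(lineage_map)
    noms <- stage("nomination",
                  nominate(scores, til$eligible,
                           lineage_map, cells, nom_cfg))
    nomination <- stage("nomination", consensus(noms, pairing, cc, scores))
    write_nomination_result(nomination, file.path(nom_dir, "nomination"))
    site_reps <- repertoires[setdiff(names(repertoires), tumor_sids)]
    cons_track <- stage("nomination",
                        track_consensus(nomination, site_reps))
    utils::write.table(cons_track,
                       file.path(nom_dir, "consensus_tracking.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(til$exclusion_log,
                       file.path(nom_dir, "exclusion_log.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  # concordance
  conc <- stage("concordance",
                concordance_report(cells, matrices, repertoires))
  write_concordance_report(conc, file.path(out_dir, "concordance"))

  log$counts <- counts_log
  log$pool_sizes <- vapply(repertoires, `[[`, numeric(1), "pool_size")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(matrices = matrices, cells = cells,
                 repertoires = repertoires, tracking = tracking,
                 scores = scores, nomination = nomination,
                 concordance = conc, log = log))
}

#' Build a manifest for a fixture written by \code{simulate_multisite}
#'
#' @param fixture_dir Directory written by
#'   \code{\link{simulate_multisite}}.
#' @param config Optional config overrides (the synthetic world's QC
#'   gates are filled in from the fixture's ground truth).
#' @return A manifest list.
#' @export
fixture_manifest <- function(fixture_dir, config = NULL) {
  gt <- jsonlite::read_json(file.path(fixture_dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  sids <- gt$samples$sample_id
  samples <- lapply(sids, function(sid) {
    list(sample_id = sid,
         matrix = file.path(fixture_dir, paste0(sid, "_matrix.mtx")),
         features = file.path(fixture_dir, paste0(sid, "_features.tsv")),
         barcodes = file.path(fixture_dir, paste0(sid, "_barcodes.tsv")),
         contigs = file.path(fixture_dir, paste0(sid, "_contigs.csv")))
  })
  if (is.null(config)) config <- list()
  if (is.null(config$qc)) {
    config$qc <- gt$config$qc[c("min_total_reads", "min_features",
                                "max_total_reads", "max_features",
                                "max_mito_pct", "require_ptprc",
                                "mito_prefix")]
  }
  list(samples = samples,
       cells = file.path(fixture_dir, "cells.tsv"),
       gene_sets = file.path(fixture_dir, "signatures.gmt"),
       viral_reference = file.path(fixture_dir, "viral_reference.tsv"),
       config = config)
}
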