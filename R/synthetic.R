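# Seeded generator of a complete multisite fixture with recorded ground
# truth: 3 patients x {blood, tumor, 3 liver replicates}, negative-binomial
# counts organized into cell-type expression programs, power-law clone-size
# repertoires, planted cross-site shared clones, planted viral-matching
# bystander clones (highly expanded but transcriptionally unremarkable, the
# bystander confound by construction), planted signature-high reactive
# cells whose clones also seed a liver replicate, and QC-violating decoy
# cells with known labels.

celltype_catalog <- function() {
  data.frame(
    code = c("nCD4", "TREG", "cCD8", "emCD8", "MAIT", "GDT", "CYCT",
             "NK", "B", "MACRO"),
    label = c("naive CD4 T", "Treg", "cytotoxic CD8 T",
              "effector memory CD8 T", "MAIT", "gdT", "cycling T",
              "NK", "B cell", "macrophage"),
    lineage = c("CD4", "CD4", "CD8", "CD8", "CD8", "other", "CD8",
                "NK", "B", "myeloid"),
    has_tcr = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                FALSE),
    stringsAsFactors = FALSE
  )
}

# Fixed synthetic gene universe: PTPRC, 10 mitochondrial genes, 100
# housekeeping genes, a 30-gene program per cell type, four reactivity
# signatures and the M1/M2 polarization sets. 611 genes total.
gene_universe <- function() {
  cat_codes <- celltype_catalog()$code
  programs <- stats::setNames(
    lapply(cat_codes, function(cc) sprintf("PRG-%s-%02d", cc, 1:30)),
    cat_codes)
  sigs <- list(
    NeoTCR8 = sprintf("NEO8-%02d", 1:40),
    TR30 = sprintf("TR30-%02d", 1:30),
    NeoTCR4 = sprintf("NEO4-%02d", 1:40),
    ExReCD4 = sprintf("EXRE-%02d", 1:40),
    M1 = sprintf("M1SIG-%02d", 1:25),
    M2 = sprintf("M2SIG-%02d", 1:25)
  )
  mito <- c("MT-CO1", "MT-CO2", "MT-CO3", paste0("MT-ND", 1:6), "MT-CYB")
  hk <- sprintf("HK%03d", 1:100)
  genes <- c("PTPRC", mito, hk, unlist(programs, use.names = FALSE),
             unlist(sigs, use.names = FALSE))
  list(genes = genes, mito = mito, hk = hk, programs = programs,
       signatures = sigs)
}

#' Simulation configuration
#'
#' Defaults define the generator's stated world: 3 patients, one blood and
#' tumor sample plus 3 liver replicates each; negative-binomial counts
#' (dispersion size 2) with 30-gene cell-type programs; truncated
#' power-law clone sizes (exponent 2.5, support 1..15); per patient 8
#' planted expanded tumor clones shared into liver/blood (two of them
#' viral-matching bystanders), signature-boosted reactive clones (8 CD8 +
#' 2 CD4 cells, ~5 percent of the eligible TIL pool), and per-sample QC
#' decoys. QC gates are scaled to the synthetic expression depth and
#' carried in \code{$qc}.
#'
#' @param seed Mandatory RNG seed.
#' @param n_patients Number of patients.
#' @param blood_size,liver_size Cells per blood/liver sample (drawn
#'   multinomially over types with a patient-specific composition effect).
#' @param tumor_counts Named integer vector of fixed per-type tumor cell
#'   counts (fixed so the eligible-TIL pool size is deterministic).
#' @param alpha,s_max Truncated power-law clone-size exponent and support.
#' @param boost_factor Multiplier on signature-gene means in reactive
#'   cells.
#' @param baseline_mean,hk_mean,program_mean,mito_mean NB means.
#' @param nb_size NB dispersion (size) parameter.
#' @param patient_gene_sd,patient_comp_sd Log-normal sd of per-patient
#'   gene-expression and liver-composition effects.
#' @param n_shared_liver Patient-level liver-only clones shared across the
#'   three replicates.
#' @return A \code{simulation_config}.
#' @export
simulation_config <- function(seed,
                              n_patients = 3L,
                              blood_size = 400L,
                              liver_size = 260L,
                              tumor_counts = c(nCD4 = 40L, TREG = 30L,
                                               cCD8 = 90L, emCD8 = 80L,
                                               MAIT = 10L, GDT = 10L,
                                               CYCT = 10L, NK = 20L,
                                               B = 10L, MACRO = 20L),
                              alpha = 2.5, s_max = 15L,
                              boost_factor = 15,
                              baseline_mean = 0.3, hk_mean = 1.5,
                              program_mean = 4, mito_mean = 2,
                              nb_size = 2,
                              patient_gene_sd = 0.3,
                              patient_comp_sd = 0.35,
                              n_shared_liver = 12L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    blood_size = as.integer(blood_size),
    liver_size = as.integer(liver_size),
    tumor_counts = tumor_counts, alpha = alpha, s_max = as.integer(s_max),
    boost_factor = boost_factor, baseline_mean = baseline_mean,
    hk_mean = hk_mean, program_mean = program_mean, mito_mean = mito_mean,
    nb_size = nb_size, patient_gene_sd = patient_gene_sd,
    patient_comp_sd = patient_comp_sd,
    n_shared_liver = as.integer(n_shared_liver),
    # tumor plantings: 8 shared/top clones (2 viral), 2 reactive CD8
    # clones (5 + 3 cells), 1 reactive CD4 clone (2 cells)
    tumor_shared_sizes = c(28L, 20L, 16L, 14L, 12L, 10L, 9L, 8L),
    viral_shared_index = c(2L, 5L),
    reactive_cd8_sizes = c(5L, 3L),
    reactive_cd4_sizes = 2L,
    qc = qc_thresholds(min_total_reads = 250L, min_features = 120L,
                       max_total_reads = 2500L, max_features = 500L,
                       max_mito_pct = 15)
  ), class = "simulation_config")
}

rand_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

make_clones <- function(n, tag) {
  nts <- c("A", "C", "G", "T")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  df <- data.frame(
    cdr3a_nt = rand_seq(n, 36, nts),
    cdr3b_nt = rand_seq(n, 39, nts),
    cdr3a_aa = paste0("CA", rand_seq(n, 9, aas), "F"),
    cdr3b_aa = paste0("CASS", rand_seq(n, 8, aas), "F"),
    stringsAsFactors = FALSE
  )
  df$clone_id <- clone_key(df$cdr3a_nt, df$cdr3b_nt)
  df
}

# iid truncated power-law clone sizes filling exactly n_cells
power_law_sizes <- function(n_cells, alpha, s_max) {
  if (n_cells <= 0L) return(integer(0))
  support <- seq_len(s_max)
  pmf <- support^(-alpha)
  pmf <- pmf / sum(pmf)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, sample(support, max(16L, n_cells), replace = TRUE,
                             prob = pmf))
    over <- cumsum(sizes) >= n_cells
    if (any(over)) sizes <- sizes[seq_len(which(over)[1])]
  }
  excess <- sum(sizes) - n_cells
  if (excess > 0L) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes[sizes > 0L]
}

#' Generate the multisite synthetic fixture
#'
#' Deterministic given the config's seed. Optionally writes all external
#' formats (Matrix Market triplets, contig CSVs, cell TSV, viral reference
#' TSV, signature GMT, ground-truth JSON) under \code{out_dir}.
#'
#' @param config A \code{simulation_config}.
#' @param out_dir Optional output directory.
#' @return List with \code{matrices} (named list of
#'   \code{expression_matrix}), \code{contigs} (combined
#'   \code{contig_table}), \code{cells} (\code{cell_table}),
#'   \code{gene_sets}, \code{viral_ref}, \code{ground_truth} and, when
#'   written, \code{paths}.
#' @export
simulate_multisite <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  uni <- gene_universe()
  genes <- uni$genes
  n_genes <- length(genes)
  cat <- celltype_catalog()
  patients <- paste0("P", seq_len(config$n_patients))

  # per-patient expression and liver-composition effects
  pat_gene_factor <- matrix(
    exp(stats::rnorm(n_genes * length(patients), 0, config$patient_gene_sd)),
    nrow = n_genes, dimnames = list(genes, patients))
  base_liver <- c(nCD4 = 40, TREG = 20, cCD8 = 70, emCD8 = 60, MAIT = 10,
                  GDT = 10, CYCT = 5, NK = 20, B = 5, MACRO = 20)
  base_blood <- c(nCD4 = 120, TREG = 20, cCD8 = 100, emCD8 = 80, MAIT = 10,
                  GDT = 5, CYCT = 5, NK = 30, B = 20, MACRO = 10)
  liver_probs <- sapply(patients, function(p) {
    w <- base_liver * exp(stats::rnorm(length(base_liver), 0,
                                       config$patient_comp_sd))
    w / sum(w)
  })
  rownames(liver_probs) <- names(base_liver)

  # viral reference: two planted TRB entries per patient plus decoys
  epi_pool <- data.frame(
    epitope = c("NLVPMVATV", "GILGFVFTL", "GLCTLVAML", "TPRVTGGGAM",
                "KLGGALQAK", "AVFDRKSDAK"),
    species = c("CMV", "InfluenzaA", "EBV", "CMV", "CMV", "EBV"),
    stringsAsFactors = FALSE
  )
  n_viral_per_pat <- length(config$viral_shared_index)

  sample_meta <- list()
  matrices <- list()
  contig_rows <- list()
  cell_rows <- list()
  gt_rep <- list()
  gt_assign <- list()
  clone_meta_all <- list()
  gt_track <- list()
  gt_viral <- list()
  gt_react <- list()
  gt_liver_res <- list()
  gt_decoy <- list()
  gt_macro <- list()
  viral_rows <- list()
  planted_ids_all <- list()

  # base NB mean vector for a cell of a given type code
  base_mu <- function(code) {
    mu <- rep(config$baseline_mean, n_genes)
    names(mu) <- genes
    mu[uni$hk] <- config$hk_mean
    mu[uni$mito] <- config$mito_mean
    mu[uni$programs[[code]]] <- config$program_mean
    mu
  }

  draw_counts <- function(mu_matrix) {
    cnt <- matrix(stats::rnbinom(length(mu_matrix), size = config$nb_size,
                                 mu = mu_matrix),
                  nrow = nrow(mu_matrix), dimnames = dimnames(mu_matrix))
    cnt
  }

  for (p_i in seq_along(patients)) {
    pat <- patients[p_i]
    # planted clone identities for this patient
    shared_tumor <- make_clones(length(config$tumor_shared_sizes), pat)
    viral_aa <- paste0("CASS", rand_seq(n_viral_per_pat, 8,
                                        strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                 "")[[1]]), "F")
    for (k in seq_len(n_viral_per_pat)) {
      idx <- config$viral_shared_index[k]
      shared_tumor$cdr3b_aa[idx] <- viral_aa[k]
      epi <- epi_pool[((p_i - 1) * n_viral_per_pat + k - 1) %%
                        nrow(epi_pool) + 1, ]
      viral_rows[[paste(pat, k)]] <- data.frame(
        cdr3_aa = viral_aa[k], chain = "TRB", epitope = epi$epitope,
        species = epi$species, source = "synthetic", stringsAsFactors = FALSE)
      gt_viral[[paste(pat, k)]] <- data.frame(
        patient_id = pat, clone_id = shared_tumor$clone_id[idx],
        cdr3b_aa = viral_aa[k], epitope = epi$epitope,
        species = epi$species, stringsAsFactors = FALSE)
    }
    react_cd8 <- make_clones(length(config$reactive_cd8_sizes), pat)
    react_cd4 <- make_clones(length(config$reactive_cd4_sizes), pat)
    shared_liver <- make_clones(config$n_shared_liver, pat)
    clone_meta_all[[pat]] <- rbind(shared_tumor, react_cd8, react_cd4,
                                   shared_liver)
    planted_ids_all[[pat]] <- clone_meta_all[[pat]]$clone_id

    samples <- c(paste0(pat, "_blood"), paste0(pat, "_tumor"),
                 paste0(pat, "_liver", 1:3))
    tissues <- c("blood", "tumor", rep("liver", 3))
    replicates <- c(1L, 1L, 1L, 2L, 3L)

    for (s_i in seq_along(samples)) {
      sid <- samples[s_i]
      tissue <- tissues[s_i]

      # ---- composition ----
      if (tissue == "tumor") {
        comp <- config$tumor_counts
      } else if (tissue == "blood") {
        pr <- base_blood / sum(base_blood)
        comp <- stats::setNames(
          as.integer(stats::rmultinom(1, config$blood_size, pr)),
          names(base_blood))
      } else {
        comp <- stats::setNames(
          as.integer(stats::rmultinom(1, config$liver_size,
                                      liver_probs[, pat])),
          rownames(liver_probs))
      }
      type_codes <- rep(names(comp), comp)
      n_real <- length(type_codes)
      barcodes <- sprintf("%s_c%04d-1", sid, seq_len(n_real))

      # ---- clone assignment ----
      lab <- cat$label[match(type_codes, cat$code)]
      lin <- cat$lineage[match(type_codes, cat$code)]
      has_tcr <- cat$has_tcr[match(type_codes, cat$code)]
      assign <- rep(NA_character_, n_real)
      new_clone_pool <- function(n) make_clones(n, pat)

      plant <- function(order_idx, planted, cursor_env) {
        # planted: data.frame(clone_id, size); consumes cells in order
        for (r in seq_len(nrow(planted))) {
          take <- order_idx[seq(cursor_env$cur,
                                cursor_env$cur + planted$size[r] - 1L)]
          assign[take] <<- planted$clone_id[r]
          cursor_env$cur <- cursor_env$cur + planted$size[r]
        }
      }

      baseline_clones <- list()
      fill_power_law <- function(idx_left) {
        if (!length(idx_left)) return(invisible(NULL))
        sizes <- power_law_sizes(length(idx_left), config$alpha,
                                 config$s_max)
        fresh <- new_clone_pool(length(sizes))
        baseline_clones[[length(baseline_clones) + 1L]] <<- fresh
        assign[idx_left] <<- rep(fresh$clone_id, sizes)
        invisible(NULL)
      }

      if (tissue == "tumor") {
        elig_cd8 <- which(type_codes %in% c("cCD8", "emCD8"))
        rest_cd8 <- which(type_codes %in% c("MAIT", "CYCT"))
        cd8_order <- c(sample(elig_cd8), sample(rest_cd8))
        planted_cd8 <- data.frame(
          clone_id = c(shared_tumor$clone_id, react_cd8$clone_id),
          size = c(config$tumor_shared_sizes, config$reactive_cd8_sizes),
          stringsAsFactors = FALSE)
        if (sum(planted_cd8$size) > length(elig_cd8)) {
          stop("configuration error: planted tumor CD8 clones exceed ",
               "eligible CD8 pool", call. = FALSE)
        }
        env <- new.env(); env$cur <- 1L
        plant(cd8_order, planted_cd8, env)
        fill_power_law(cd8_order[seq(env$cur, length(cd8_order))])

        elig_cd4 <- which(type_codes == "nCD4")
        rest_cd4 <- which(type_codes == "TREG")
        cd4_order <- c(sample(elig_cd4), sample(rest_cd4))
        planted_cd4 <- data.frame(clone_id = react_cd4$clone_id,
                                  size = config$reactive_cd4_sizes,
                                  stringsAsFactors = FALSE)
        env <- new.env(); env$cur <- 1L
        plant(cd4_order, planted_cd4, env)
        fill_power_law(cd4_order[seq(env$cur, length(cd4_order))])

        react_bcs_cd8 <- barcodes[!is.na(assign) &
                                    assign %in% react_cd8$clone_id]
        react_bcs_cd4 <- barcodes[!is.na(assign) &
                                    assign %in% react_cd4$clone_id]
        gt_react[[sid]] <- rbind(
          data.frame(barcode = react_bcs_cd8, sample_id = sid,
                     lineage = "CD8",
                     clone_id = assign[match(react_bcs_cd8, barcodes)],
                     stringsAsFactors = FALSE),
          data.frame(barcode = react_bcs_cd4, sample_id = sid,
                     lineage = "CD4",
                     clone_id = assign[match(react_bcs_cd4, barcodes)],
                     stringsAsFactors = FALSE))
      } else {
        tpool <- which(has_tcr)
        t_order <- sample(tpool)
        if (tissue == "liver") {
          tumor_idx <- c(setdiff(1:6, config$viral_shared_index),
                         config$viral_shared_index)
          sizes_t <- stats::setNames(sample(2:8, length(tumor_idx),
                                            replace = TRUE),
                                     shared_tumor$clone_id[tumor_idx])
          sizes_t[shared_tumor$clone_id[config$viral_shared_index[1]]] <- 9L
          sizes_t[shared_tumor$clone_id[config$viral_shared_index[2]]] <- 3L
          planted <- data.frame(clone_id = names(sizes_t),
                                size = as.integer(sizes_t),
                                stringsAsFactors = FALSE)
          sizes_s <- sample(1:6, config$n_shared_liver, replace = TRUE)
          planted <- rbind(planted,
                           data.frame(clone_id = shared_liver$clone_id,
                                      size = sizes_s,
                                      stringsAsFactors = FALSE))
          if (replicates[s_i] == 1L) {
            planted <- rbind(planted,
                             data.frame(clone_id = react_cd8$clone_id[1],
                                        size = 3L, stringsAsFactors = FALSE))
          }
        } else {
          planted <- data.frame(
            clone_id = shared_tumor$clone_id[c(1:4,
                                               config$viral_shared_index[2])],
            size = c(6L, 5L, 3L, 2L, 2L), stringsAsFactors = FALSE)
          # index 2 of 1:4 is the first viral clone when
          # viral_shared_index[1] <= 4
        }
        if (sum(planted$size) > length(t_order)) {
          stop("configuration error: planted clones exceed T cell pool in ",
               sid, call. = FALSE)
        }
        env <- new.env(); env$cur <- 1L
        plant(t_order, planted, env)
        fill_power_law(t_order[seq(env$cur, length(t_order))])
        if (tissue == "liver" && replicates[s_i] == 1L) {
          gt_liver_res[[sid]] <- data.frame(
            patient_id = pat, clone_id = react_cd8$clone_id[1],
            sample_id = sid, count = 3L, stringsAsFactors = FALSE)
        }
      }

      # cells without TCR stay NA (gdT, NK, B, macrophage)
      rep_counts <- table(assign[!is.na(assign)])
      gt_rep[[sid]] <- stats::setNames(as.integer(rep_counts),
                                       names(rep_counts))
      gt_assign[[sid]] <- data.frame(
        barcode = barcodes[!is.na(assign)], sample_id = sid,
        clone_id = assign[!is.na(assign)], stringsAsFactors = FALSE)
      if (length(baseline_clones)) {
        clone_meta_all[[paste(sid, "baseline")]] <-
          do.call(rbind, baseline_clones)
      }

      # planted cross-site bookkeeping (counts as realized)
      planted_ids <- c(shared_tumor$clone_id, react_cd8$clone_id,
                       react_cd4$clone_id)
      present <- intersect(planted_ids, names(gt_rep[[sid]]))
      if (length(present)) {
        gt_track[[sid]] <- data.frame(
          patient_id = pat, clone_id = present, sample_id = sid,
          count = as.integer(gt_rep[[sid]][present]),
          pool_size = sum(gt_rep[[sid]]), stringsAsFactors = FALSE)
      }

      # ---- macrophage polarization subtypes ----
      macro_idx <- which(type_codes == "MACRO")
      m1_idx <- macro_idx[seq_len(floor(length(macro_idx) / 2))]
      m2_idx <- setdiff(macro_idx, m1_idx)
      if (length(macro_idx)) {
        gt_macro[[sid]] <- data.frame(
          barcode = barcodes[macro_idx], sample_id = sid,
          subtype = ifelse(macro_idx %in% m1_idx, "M1", "M2"),
          stringsAsFactors = FALSE)
      }

      # ---- expression ----
      mu_mat <- matrix(0, nrow = n_genes, ncol = n_real,
                       dimnames = list(genes, barcodes))
      for (code in unique(type_codes)) {
        mu_mat[, type_codes == code] <- base_mu(code)
      }
      mu_mat[uni$signatures$M1, m1_idx] <- config$program_mean
      mu_mat[uni$signatures$M2, m2_idx] <- config$program_mean
      # signature boost for reactive cells
      if (tissue == "tumor") {
        boost_genes_cd8 <- c(uni$signatures$NeoTCR8, uni$signatures$TR30)
        boost_genes_cd4 <- c(uni$signatures$NeoTCR4, uni$signatures$ExReCD4)
        i8 <- which(barcodes %in% gt_react[[sid]]$barcode[
          gt_react[[sid]]$lineage == "CD8"])
        i4 <- which(barcodes %in% gt_react[[sid]]$barcode[
          gt_react[[sid]]$lineage == "CD4"])
        mu_mat[boost_genes_cd8, i8] <-
          mu_mat[boost_genes_cd8, i8] * config$boost_factor
        mu_mat[boost_genes_cd4, i4] <-
          mu_mat[boost_genes_cd4, i4] * config$boost_factor
      }
      mu_mat <- mu_mat * pat_gene_factor[, pat]

      # ---- QC decoys ----
      decoy_kinds <- c("low_total", "high_total", "low_features",
                       "high_features", "high_mito", "no_ptprc")
      decoy_bcs <- sprintf("%s_decoy_%s-1", sid, decoy_kinds)
      decoy_mu <- matrix(rep(base_mu("nCD4"), length(decoy_kinds)),
                         ncol = length(decoy_kinds),
                         dimnames = list(genes, decoy_bcs))
      dk <- function(kind) which(decoy_kinds == kind)
      decoy_mu[, dk("low_total")] <- decoy_mu[, dk("low_total")] * 0.05
      decoy_mu[, dk("high_total")] <- decoy_mu[, dk("high_total")] * 8
      lf <- rep(0, n_genes); names(lf) <- genes
      lf[uni$hk[1:30]] <- 20
      decoy_mu[, dk("low_features")] <- lf
      decoy_mu[uni$mito, dk("high_mito")] <- config$mito_mean * 40

      cnt <- draw_counts(cbind(mu_mat, decoy_mu))
      # PTPRC: guaranteed positive for real cells and well-behaved decoys
      cnt["PTPRC", ] <- 1L + stats::rnbinom(ncol(cnt),
                                            size = config$nb_size, mu = 1.5)
      cnt["PTPRC", sprintf("%s_decoy_no_ptprc-1", sid)] <- 0L
      cnt[, sprintf("%s_decoy_high_features-1", sid)] <-
        cnt[, sprintf("%s_decoy_high_features-1", sid)] + 1L
      cnt["PTPRC", sprintf("%s_decoy_low_features-1", sid)] <- 1L
      cnt["PTPRC", sprintf("%s_decoy_low_total-1", sid)] <- 1L

      matrices[[sid]] <- expression_matrix(
        Matrix::Matrix(cnt, sparse = TRUE), sid)
      gt_decoy[[sid]] <- data.frame(barcode = decoy_bcs, sample_id = sid,
                                    criterion = decoy_kinds,
                                    stringsAsFactors = FALSE)

      # ---- cell table rows ----
      cell_rows[[sid]] <- data.frame(
        barcode = c(barcodes, decoy_bcs),
        sample_id = sid, patient_id = pat, tissue = tissue,
        replicate = replicates[s_i],
        cell_type = c(lab, rep("qc_decoy", length(decoy_bcs))),
        lineage = c(lin, rep("other", length(decoy_bcs))),
        stringsAsFactors = FALSE)

      # ---- contigs ----
      t_idx <- which(!is.na(assign))
      if (length(t_idx)) {
        meta_now <- do.call(rbind, clone_meta_all)
        cm <- meta_now[match(assign[t_idx], meta_now$clone_id), ]
        n_t <- length(t_idx)
        umis_a <- sample(3:15, n_t, replace = TRUE)
        umis_b <- sample(3:15, n_t, replace = TRUE)
        is_mait <- type_codes[t_idx] == "MAIT"
        tra <- data.frame(
          barcode = barcodes[t_idx], chain = "TRA", cdr3 = cm$cdr3a_aa,
          cdr3_nt = cm$cdr3a_nt,
          v_gene = ifelse(is_mait, "TRAV1-2", "TRAV12-1"),
          j_gene = "TRAJ33", umis = umis_a, reads = umis_a * 8L,
          productive = TRUE, high_confidence = TRUE,
          stringsAsFactors = FALSE)
        trb <- data.frame(
          barcode = barcodes[t_idx], chain = "TRB", cdr3 = cm$cdr3b_aa,
          cdr3_nt = cm$cdr3b_nt, v_gene = "TRBV6-5", j_gene = "TRBJ2-1",
          umis = umis_b, reads = umis_b * 8L, productive = TRUE,
          high_confidence = TRUE, stringsAsFactors = FALSE)
        # secondary low-UMI TRA contigs for ~10% of cells: the dominant
        # (higher-UMI) chain must win
        sec_idx <- which(stats::runif(n_t) < 0.1)
        sec <- if (length(sec_idx)) {
          extra <- make_clones(length(sec_idx), pat)
          data.frame(
            barcode = barcodes[t_idx][sec_idx], chain = "TRA",
            cdr3 = extra$cdr3a_aa, cdr3_nt = extra$cdr3a_nt,
            v_gene = "TRAV8-2", j_gene = "TRAJ12",
            umis = pmin(umis_a[sec_idx] - 1L, 2L), reads = 4L,
            productive = TRUE, high_confidence = TRUE,
            stringsAsFactors = FALSE)
        } else NULL
        contig_rows[[sid]] <- rbind(tra, trb, sec)
      }

      sample_meta[[sid]] <- data.frame(
        sample_id = sid, patient_id = pat, tissue = tissue,
        replicate = replicates[s_i], n_cells = n_real,
        n_decoys = length(decoy_bcs),
        pool_size = sum(gt_rep[[sid]]),
        total_counts = sum(cnt), stringsAsFactors = FALSE)
    }
  }

  cells <- cell_table(do.call(rbind, unname(cell_rows)))
  contigs <- contig_table(do.call(rbind, unname(contig_rows)))
  clone_meta <- do.call(rbind, unname(clone_meta_all))
  clone_meta <- clone_meta[!duplicated(clone_meta$clone_id), ]
  rownames(clone_meta) <- NULL

  viral_decoys <- data.frame(
    cdr3_aa = c("CASSDECOYAAF", "CASSDECOYBBF"), chain = "TRB",
    epitope = c("RAKFKQLL", "YVLDHLIVV"), species = c("EBV", "EBV"),
    source = "synthetic", stringsAsFactors = FALSE)
  viral_ref <- viral_reference(rbind(do.call(rbind, unname(viral_rows)),
                                     viral_decoys))

  gene_sets <- lapply(names(uni$signatures), function(nm) {
    gene_set(nm, uni$signatures[[nm]], source = "synthetic")
  })
  names(gene_sets) <- names(uni$signatures)

  config_out <- unclass(config)
  config_out$qc <- unclass(config_out$qc)
  ground_truth <- list(
    config = config_out,
    samples = do.call(rbind, unname(sample_meta)),
    repertoires = gt_rep,
    assignment = do.call(rbind, unname(gt_assign)),
    clone_meta = clone_meta,
    planted_tracking = do.call(rbind, unname(gt_track)),
    viral_clones = do.call(rbind, unname(gt_viral)),
    reactive = do.call(rbind, unname(gt_react)),
    liver_resident_consensus = do.call(rbind, unname(gt_liver_res)),
    decoys = do.call(rbind, unname(gt_decoy)),
    macro_subtype = do.call(rbind, unname(gt_macro)),
    planted_clone_ids = unlist(planted_ids_all, use.names = FALSE)
  )
  rownames(ground_truth$samples) <- NULL

  out <- list(matrices = matrices, contigs = contigs, cells = cells,
              gene_sets = gene_sets, viral_ref = viral_ref,
              ground_truth = ground_truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(samples = list())
    for (sid in names(matrices)) {
      trip <- write_mtx_triplet(matrices[[sid]], out_dir, prefix = sid)
      cpath <- file.path(out_dir, paste0(sid, "_contigs.csv"))
      sub <- contigs[contigs$barcode %in%
                       cells$barcode[cells$sample_id == sid], ,
                     drop = FALSE]
      df <- as.data.frame(sub)
      df$productive <- ifelse(df$productive, "True", "None")
      df$high_confidence <- ifelse(df$high_confidence, "True", "False")
      utils::write.csv(df, cpath, row.names = FALSE, quote = FALSE)
      paths$samples[[sid]] <- c(trip, contigs = cpath)
    }
    paths$cells <- write_cell_table(cells, file.path(out_dir, "cells.tsv"))
    paths$viral <- write_viral_reference(viral_ref,
                                         file.path(out_dir,
                                                   "viral_reference.tsv"))
    paths$gmt <- write_gmt(gene_sets, file.path(out_dir, "signatures.gmt"))
    paths$ground_truth <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, paths$ground_truth,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
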