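# Fixtures are built in code at test time; nothing binary ships with the
# package.

# small dense expression matrix with named genes/cells
make_expr <- function(counts, genes, barcodes, sample_id = "S1") {
  m <- matrix(counts, nrow = length(genes),
              dimnames = list(genes, barcodes))
  expression_matrix(m, sample_id)
}

# Six-cell QC fixture: one violation of each of the five numeric exclusion
# criteria plus one clean cell, over a 6100-gene universe (the
# high-features criterion needs > 6000 detectable genes at the default
# gates). All cells express PTPRC.
qc_six_cell_fixture <- function() {
  n_genes <- 6100L
  genes <- c("PTPRC", "MT-A", sprintf("G%04d", seq_len(n_genes - 2L)))
  cells <- c("clean", "v_low_total", "v_low_features", "v_high_total",
             "v_high_features", "v_high_mito")
  entries <- list(
    clean = stats::setNames(rep(2, 400), genes[1:400]),
    v_low_total = stats::setNames(rep(1, 305), genes[1:305]),
    v_low_features = stats::setNames(rep(3, 250), genes[1:250]),
    v_high_total = stats::setNames(rep(90, 310), genes[1:310]),
    v_high_features = stats::setNames(rep(1, 6050), genes[1:6050]),
    v_high_mito = c(stats::setNames(rep(2, 400), genes[1:400]),
                    "MT-A" = 302)
  )
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(cells)) {
    e <- entries[[cells[j]]]
    idx <- match(names(e), genes)
    agg <- tapply(e, idx, sum)
    ii <- c(ii, as.integer(names(agg)))
    jj <- c(jj, rep(j, length(agg)))
    xx <- c(xx, as.numeric(agg))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_genes, length(cells)),
                            dimnames = list(genes, cells))
  expression_matrix(m, "qc_fixture")
}

# contig table builder with defaults for the boring columns
make_contigs <- function(barcode, chain, cdr3_nt, umis,
                         cdr3 = toupper(substr(cdr3_nt, 1, 6)),
                         v_gene = ifelse(chain == "TRA", "TRAV12-1",
                                         "TRBV6-5"),
                         reads = umis * 10L,
                         productive = TRUE, high_confidence = TRUE) {
  n <- length(barcode)
  contig_table(data.frame(
    barcode = barcode, chain = chain, cdr3 = rep_len(cdr3, n),
    cdr3_nt = cdr3_nt, v_gene = rep_len(v_gene, n),
    j_gene = rep_len("TRAJ33", n), umis = as.integer(rep_len(umis, n)),
    reads = as.integer(rep_len(reads, n)),
    productive = rep_len(productive, n),
    high_confidence = rep_len(high_confidence, n),
    stringsAsFactors = FALSE))
}

make_cells <- function(barcode, sample_id = "S1", patient_id = "P1",
                       tissue = "tumor", replicate = 1L,
                       cell_type = "cytotoxic CD8 T", lineage = "CD8") {
  cell_table(data.frame(
    barcode = barcode, sample_id = sample_id, patient_id = patient_id,
    tissue = tissue, replicate = replicate, cell_type = cell_type,
    lineage = lineage, stringsAsFactors = FALSE))
}

rep_from_counts <- function(counts, sample_id = "S1") {
  repertoire_from_counts(sample_id, counts)
}

random_repertoire <- function(n_clones, max_count = 20L,
                              sample_id = "S1") {
  counts <- sample.int(max_count, n_clones, replace = TRUE)
  names(counts) <- sprintf("cl%04d", sample.int(10 * n_clones, n_clones))
  repertoire_from_counts(sample_id, counts)
}

# the default synthetic fixture, generated once per test session
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_multisite(simulation_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# brute-force AUC recovery-curve oracle: rebuild the step curve rank by
# rank, independent of the package implementation
oracle_auc <- function(member_ranks, n_set, max_rank) {
  y <- vapply(seq_len(max_rank), function(x) sum(member_ranks <= x),
              numeric(1))
  raw <- sum(y)
  h <- min(n_set, max_rank)
  best <- vapply(seq_len(max_rank), function(x) min(x, h), numeric(1))
  raw / sum(best)
}

# brute-force ssGSEA running-sum oracle
oracle_ssgsea <- function(x, set_genes, universe, alpha) {
  ord <- order(-x, seq_along(x))
  n <- length(x)
  in_set <- universe[ord] %in% set_genes
  num <- 0; den_in <- sum(((n - seq_len(n) + 1)^alpha)[in_set])
  run_in <- 0; run_out <- 0; total <- 0
  n_out <- sum(!in_set)
  for (i in seq_len(n)) {
    if (in_set[i]) run_in <- run_in + (n - i + 1)^alpha / den_in
    else run_out <- run_out + 1 / n_out
    total <- total + (run_in - run_out)
  }
  total
}
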