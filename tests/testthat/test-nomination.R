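make_score_table <- function(scores) {
  structure(list(scores = scores,
                 metadata = data.frame(signature = colnames(scores)),
                 method = "auc", config = unclass(scoring_config())),
            class = "score_table")
}

test_that("filter_tils keeps eligible TILs and logs one reason per cell", {
  bcs <- paste0("b", 1:8)
  cells <- make_cells(
    bcs,
    tissue = c("tumor", "tumor", "tumor", "tumor", "tumor", "tumor",
               "liver", "tumor"),
    cell_type = c("cytotoxic CD8 T", "Treg", "MAIT", "gdT",
                  "cycling T", "cytotoxic CD8 T", "cytotoxic CD8 T",
                  "NK"),
    lineage = c("CD8", "CD4", "CD8", "other", "CD8", "CD8", "CD8", "NK"))
  paired <- setdiff(bcs, c("b4", "b6"))  # gdT and b6 lack paired TCR
  cc <- data.frame(barcode = paired, clone_id = paste0("cl", paired),
                   stringsAsFactors = FALSE)
  contigs <- make_contigs(
    barcode = c("b3", "b1"), chain = "TRA",
    cdr3_nt = c("AAA", "CCC"), umis = 5L,
    v_gene = c("TRAV1-2*01", "TRAV12-1"))
  res <- filter_tils(cells, cc, contigs)
  expect_identical(res$eligible, "b1")
  log <- stats::setNames(res$exclusion_log$reason, res$exclusion_log$barcode)
  expect_equal(log[["b2"]], "treg")
  expect_equal(log[["b3"]], "mait")  # TRAV1-2 allele suffix stripped
  expect_equal(log[["b4"]], "gamma_delta")
  expect_equal(log[["b5"]], "cycling")
  expect_equal(log[["b6"]], "no_paired_tcr")
  expect_equal(log[["b7"]], "non_tumor_tissue")
  expect_equal(log[["b8"]], "non_t_cell")
  # partition: every cell is eligible or logged exactly once
  expect_setequal(c(res$eligible, res$exclusion_log$barcode), bcs)
  expect_equal(anyDuplicated(res$exclusion_log$barcode), 0L)
})

test_that("nominate takes the nearest-rank top percentile, ties included", {
  bcs <- sprintf("c%03d", 1:100)
  cells <- make_cells(bcs)
  scores <- matrix(seq(0.01, 1, length.out = 100), ncol = 1,
                   dimnames = list(bcs, "SigA"))
  st <- make_score_table(scores)
  noms <- nominate(st, bcs, list(SigA = "CD8"), cells)
  expect_length(noms$SigA$barcodes, 5L)  # 100 distinct scores -> exactly 5
  expect_setequal(noms$SigA$barcodes, bcs[96:100])

  # all-equal scores: everything nominated with a degeneracy warning
  st2 <- make_score_table(matrix(0.5, 100, 1,
                                 dimnames = list(bcs, "SigA")))
  expect_warning(noms2 <- nominate(st2, bcs, list(SigA = "CD8"), cells),
                 "all scores equal")
  expect_length(noms2$SigA$barcodes, 100L)

  # small pool fallback
  st3 <- make_score_table(matrix(seq_len(10) / 10, 10, 1,
                                 dimnames = list(bcs[1:10], "SigA")))
  expect_warning(noms3 <- nominate(st3, bcs[1:10], list(SigA = "CD8"),
                                   cells), "eligible cells")
  expect_length(noms3$SigA$barcodes, 1L)
  expect_equal(noms3$SigA$barcodes, "c010")

  expect_error(nominate(st, bcs, list(Missing = "CD8"), cells),
               "configuration error")
})

test_that("consensus is the per-lineage intersection and is monotone", {
  bcs <- sprintf("c%03d", 1:6)
  cc <- data.frame(barcode = bcs,
                   clone_id = c("k1", "k1", "k2", "k3", "k4", "k5"),
                   stringsAsFactors = FALSE)
  sc <- matrix(stats::runif(12, 0.2, 0.9), 6, 2,
               dimnames = list(bcs, c("A", "B")))
  st <- make_score_table(sc)
  noms <- list(
    A = list(barcodes = c("c001", "c002", "c003"), lineage = "CD8"),
    B = list(barcodes = c("c002", "c003", "c004"), lineage = "CD8"))
  res <- consensus(noms, list(CD8 = c("A", "B")), cc, st)
  expect_setequal(res$lineages$CD8$barcodes, c("c002", "c003"))
  expect_setequal(res$lineages$CD8$clonotypes$clone_id, c("k1", "k2"))

  # enlarging a nominated set never shrinks the consensus
  noms_big <- noms
  noms_big$A$barcodes <- c(noms$A$barcodes, "c004", "c005")
  res_big <- consensus(noms_big, list(CD8 = c("A", "B")), cc, st)
  expect_true(all(res$lineages$CD8$barcodes %in%
                    res_big$lineages$CD8$barcodes))

  # disjoint sets -> empty consensus with a note
  noms_dis <- noms
  noms_dis$B$barcodes <- c("c005", "c006")
  res_dis <- consensus(noms_dis, list(CD8 = c("A", "B")), cc, st)
  expect_length(res_dis$lineages$CD8$barcodes, 0L)
  expect_equal(res_dis$lineages$CD8$note, "empty consensus")

  expect_error(consensus(noms, list(CD8 = c("A", "Z")), cc, st),
               "configuration error")
})

test_that("track_consensus reuses clone tracking with zeros for absences", {
  cc <- data.frame(barcode = c("x1", "x2"), clone_id = c("kA", "kB"),
                   stringsAsFactors = FALSE)
  st <- make_score_table(matrix(0.5, 2, 2,
                                dimnames = list(c("x1", "x2"),
                                                c("A", "B"))))
  noms <- list(A = list(barcodes = c("x1", "x2"), lineage = "CD8"),
               B = list(barcodes = c("x1", "x2"), lineage = "CD8"))
  res <- consensus(noms, list(CD8 = c("A", "B")), cc, st)
  liver <- rep_from_counts(c(kA = 12L, zz = 788L), sample_id = "L1")
  blood <- rep_from_counts(c(zz = 10L), sample_id = "B1")
  tr <- track_consensus(res, list(liver, blood))
  expect_equal(tr$frequency[tr$clone_id == "kA" & tr$sample_id == "L1"],
               0.015)
  expect_equal(tr$frequency[tr$clone_id == "kA" & tr$sample_id == "B1"], 0)
  expect_true(all(tr$frequency[tr$clone_id == "kB"] == 0))

  empty <- consensus(list(A = list(barcodes = character(), lineage = "CD8"),
                          B = list(barcodes = character(), lineage = "CD8")),
                     list(CD8 = c("A", "B")), cc, st)
  expect_equal(nrow(track_consensus(empty, list(liver))), 0L)
})
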