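test_that("top_expanded sorts by count with lexicographic tie-break", {
  rep <- rep_from_counts(c(Z = 5L, X = 5L, Y = 1L))
  top <- top_expanded(rep, 2L)
  expect_equal(top$clone_id, c("X", "Z"))
  expect_equal(top_expanded(rep, 10L)$clone_id, c("X", "Z", "Y"))
  empty <- rep_from_counts(stats::setNames(integer(0), character(0)))
  expect_error(top_expanded(empty), "empty repertoire")
})

test_that("track_clones reports exact frequencies and exact zeros", {
  tumor <- rep_from_counts(c(a = 8L, b = 2L), sample_id = "T")
  liver <- rep_from_counts(c(a = 45L, c = 955L), sample_id = "L")
  blood <- rep_from_counts(c(c = 10L), sample_id = "B")
  tr <- track_clones(top_expanded(tumor, 2L), list(liver, blood, tumor))
  expect_equal(tr$frequency[tr$clone_id == "a" & tr$sample_id == "L"],
               0.045)
  expect_equal(tr$frequency[tr$clone_id == "a" & tr$sample_id == "B"], 0)
  # a repertoire's own top clone tracks to its own frequency
  expect_equal(tr$frequency[tr$clone_id == "a" & tr$sample_id == "T"], 0.8)
  expect_error(track_clones(top_expanded(tumor), list()), "non-empty")
})

test_that("viral annotation matches on CDR3beta amino acid, mode-aware", {
  ref <- viral_reference(data.frame(
    cdr3_aa = c("CASSBETAF", "CAALPHAF", "CASSBETAF"),
    chain = c("TRB", "TRA", "TRB"),
    epitope = c("NLVPMVATV", "GILGFVFTL", "AAAAA"),
    species = c("CMV", "InfluenzaA", "ZMV"),
    stringsAsFactors = FALSE))
  clones <- data.frame(
    clone_id = c("c1", "c2"),
    cdr3a_aa = c("CAXXF", "CAALPHAF"),
    cdr3b_aa = c("CASSBETAF", "CASSNOPEF"),
    stringsAsFactors = FALSE)
  ann <- annotate_viral(clones, ref)
  expect_true(ann$viral_match[1])
  expect_equal(ann$n_hits[1], 2L)
  # primary hit = first by (species, epitope): CMV before ZMV
  expect_equal(ann$species[1], "CMV")
  expect_false(ann$viral_match[2])  # beta mode ignores the alpha hit

  # reference row order does not change the annotation
  ref2 <- viral_reference(as.data.frame(ref)[c(3, 1, 2), ])
  expect_equal(annotate_viral(clones, ref2), ann)

  # alpha_or_beta accepts the alpha hit; paired requires both
  ann_ab <- annotate_viral(clones, ref, mode = "alpha_or_beta_aa")
  expect_true(ann_ab$viral_match[2])
  ann_p <- annotate_viral(clones, ref, mode = "paired_aa")
  expect_false(ann_p$viral_match[1])  # beta only, no alpha hit

  empty_ref <- viral_reference(data.frame(
    cdr3_aa = character(), chain = character(), epitope = character(),
    species = character(), stringsAsFactors = FALSE))
  expect_false(any(annotate_viral(clones, empty_ref)$viral_match))
})

test_that("planted cross-site clones recover exact frequencies", {
  fx <- default_fixture()
  gt <- fx$ground_truth
  cc <- assemble_clonotypes(fx$contigs)
  reps <- lapply(gt$samples$sample_id,
                 function(s) build_repertoire(cc, fx$cells, s))
  names(reps) <- gt$samples$sample_id
  for (pat in unique(gt$samples$patient_id)) {
    tumor <- reps[[paste0(pat, "_tumor")]]
    sites <- reps[grep(paste0("^", pat, "_(blood|liver)"), names(reps))]
    rpt <- tracking_report(tumor, sites, fx$viral_ref, n = 20L,
                           patient_id = pat)
    planted <- gt$planted_tracking[
      gt$planted_tracking$patient_id == pat &
        gt$planted_tracking$sample_id != paste0(pat, "_tumor"), ]
    tr <- rpt$tracking
    hit <- merge(tr, planted, by = c("clone_id", "sample_id"))
    # every planted clone that made the tumor top-20 is found at the
    # exact planted frequency
    expect_gt(nrow(hit), 0)
    expect_equal(hit$frequency, hit$count.y / hit$pool_size)
    # per-site sharedness bounded by the request and the site's clones
    for (sid in names(rpt$sharedness)) {
      expect_lte(rpt$sharedness[[sid]], 20L)
      expect_lte(rpt$sharedness[[sid]], nrow(reps[[sid]]$clones))
    }
    # planted viral clones are flagged as putative bystanders
    vir <- gt$viral_clones$clone_id[gt$viral_clones$patient_id == pat]
    flagged <- rpt$clones$clone_id[rpt$clones$putative_bystander]
    expect_true(all(vir %in% flagged))
  }
})
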