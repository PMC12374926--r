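test_that("rank_genes orders by decreasing count with declared tie policy", {
  cfg <- scoring_config()
  expect_equal(rank_genes(c(5, 1, 3), cfg), c(1L, 3L, 2L))
  expect_equal(rank_genes(rep(0, 6), cfg), 1:6)  # stable_index ties
  cfg_r <- scoring_config(tie_policy = "seeded_random", seed = 99L)
  p1 <- rank_genes(rep(2, 8), cfg_r)
  p2 <- rank_genes(rep(2, 8), cfg_r)
  expect_identical(p1, p2)  # reproducible given the seed
  expect_setequal(p1, 1:8)
})

test_that("auc_score worked example and extremal cases", {
  cfg <- scoring_config(max_rank_fraction = 0.5)  # universe 10 -> window 5
  universe <- paste0("g", 1:10)
  # set members sit at ranks 2 and 4 of a strictly decreasing cell
  x <- 10:1
  gs <- gene_set("S", c("g2", "g4"))
  expect_equal(auc_score(rank_genes(x, cfg), gs, universe, cfg), 6 / 9)
  # all members in the top |G| ranks -> 1; none in window -> 0
  expect_equal(auc_score(rank_genes(x, cfg), gene_set("T", c("g1", "g2")),
                         universe, cfg), 1)
  expect_equal(auc_score(rank_genes(x, cfg), gene_set("U", c("g9", "g10")),
                         universe, cfg), 0)
  # empty effective set -> NA
  expect_true(is.na(auc_score(rank_genes(x, cfg), gene_set("V", "zzz"),
                              universe, cfg)))
})

test_that("auc_score equals the exhaustive oracle for all placements", {
  cfg <- scoring_config(max_rank_fraction = 0.4)
  for (n_uni in c(8L, 12L)) {
    universe <- paste0("g", seq_len(n_uni))
    x <- rev(seq_len(n_uni))  # rank i = gene i
    ranking <- rank_genes(x, cfg)
    max_rank <- ceiling(cfg$max_rank_fraction * n_uni)
    for (k in 1:4) {
      placements <- utils::combn(n_uni, k)
      for (j in seq_len(ncol(placements))) {
        ranks <- placements[, j]
        gs <- gene_set("S", paste0("g", ranks))
        got <- auc_score(ranking, gs, universe, cfg)
        expect_equal(got, oracle_auc(ranks, k, max_rank))
      }
    }
  }
})

test_that("auc_score is invariant under strictly monotone transforms", {
  cfg <- scoring_config()
  set.seed(31)
  universe <- paste0("g", 1:60)
  gs <- gene_set("S", sample(universe, 8))
  for (i in 1:100) {
    x <- rpois(60, 3)
    base <- auc_score(rank_genes(x, cfg), gs, universe, cfg)
    for (f in list(function(v) 2 * v + 1, function(v) v^3,
                   function(v) exp(v / 2))) {
      expect_equal(auc_score(rank_genes(f(x), cfg), gs, universe, cfg),
                   base)
    }
  }
})

test_that("raising a member's expression never lowers the score; linear closed form", {
  cfg <- scoring_config(max_rank_fraction = 1)
  universe <- paste0("g", 1:12)
  set.seed(17)
  for (i in 1:30) {
    x <- rpois(12, 4) + seq(0.01, 0.12, by = 0.01)  # break ties
    gs <- gene_set("S", sample(universe, 3))
    s0 <- auc_score(rank_genes(x, cfg), gs, universe, cfg)
    x2 <- x
    mem <- match(gs$genes[1], universe)
    x2[mem] <- x2[mem] + 5
    expect_gte(auc_score(rank_genes(x2, cfg), gs, universe, cfg),
               s0 - 1e-12)
  }
  # |G| = 1, window = whole universe: score linear in the member's rank
  n <- 12L
  for (r in 1:12) {
    x <- numeric(n); x[r] <- 1; x <- x + rev(seq_len(n)) * 10
    gs <- gene_set("S", paste0("g", r))
    got <- auc_score(rank_genes(rev(seq_len(n)) * 10 + replace(numeric(n), r, 1), cfg),
                     gs, universe, cfg)
    expect_equal(got, (n - r + 1) / n)
  }
})

test_that("ssgsea matches the brute-force running-sum oracle", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(6:15, 1)
    universe <- paste0("g", seq_len(n))
    x <- rpois(n, 5) + stats::runif(n) / 10  # tie-free
    k <- sample(2:(n - 2), 1)
    gs <- gene_set("S", sample(universe, k))
    alpha <- sample(c(0, 0.25, 1), 1)
    cfg <- scoring_config(ssgsea_alpha = alpha)
    expect_equal(ssgsea_score(x, gs, universe, cfg),
                 oracle_ssgsea(x, gs$genes, universe, alpha),
                 tolerance = 1e-10)
    # monotone-transform invariance
    expect_equal(ssgsea_score(x^3, gs, universe, cfg),
                 ssgsea_score(x, gs, universe, cfg))
  }
  # in-set genes on top maximize the alpha = 0 running sum
  universe <- paste0("g", 1:8)
  cfg0 <- scoring_config(ssgsea_alpha = 0)
  gs <- gene_set("S", c("g1", "g2"))
  top <- ssgsea_score(c(9, 8, 6, 5, 4, 3, 2, 1), gs, universe, cfg0)
  perms <- replicate(50, ssgsea_score(sample(1:8), gs, universe, cfg0))
  expect_true(all(perms <= top + 1e-12))
})

test_that("score_matrix: planted M1/M2 separation, missing sets, determinism", {
  fx <- default_fixture()
  gt <- fx$ground_truth
  m <- fx$matrices[["P1_tumor"]]
  macro <- gt$macro_subtype[gt$macro_subtype$sample_id == "P1_tumor", ]
  sets <- list(fx$gene_sets$M1, fx$gene_sets$M2,
               gene_set("M1_copy", fx$gene_sets$M1$genes),
               gene_set("absent", c("NOPE1", "NOPE2")))
  expect_warning(st <- score_matrix(m, sets, method = "ssgsea"),
                 "coverage")
  s_m1 <- st$scores[macro$barcode[macro$subtype == "M1"], "M1"]
  s_m2 <- st$scores[macro$barcode[macro$subtype == "M2"], "M1"]
  expect_gt(median(s_m1), median(s_m2))
  s2_m2 <- st$scores[macro$barcode[macro$subtype == "M2"], "M2"]
  s2_m1 <- st$scores[macro$barcode[macro$subtype == "M1"], "M2"]
  expect_gt(median(s2_m2), median(s2_m1))
  # duplicate set -> identical column; disjoint set -> all NA + metadata
  expect_equal(st$scores[, "M1_copy"], st$scores[, "M1"])
  expect_true(all(is.na(st$scores[, "absent"])))
  expect_true(st$metadata$low_coverage[st$metadata$signature == "absent"])
  # AUC scores live in [0, 1]
  st2 <- suppressWarnings(score_matrix(m, sets, method = "auc"))
  expect_true(all(st2$scores[, 1:3] >= 0 & st2$scores[, 1:3] <= 1))
})
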