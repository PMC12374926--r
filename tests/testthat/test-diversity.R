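# independent D50 oracle: brute-force cumulative sum over sorted counts
oracle_d50 <- function(counts) {
  s <- sort(counts, decreasing = TRUE)
  total <- sum(s)
  cum <- 0
  for (k in seq_along(s)) {
    cum <- cum + s[k]
    if (cum >= total / 2) return(list(k = k, index = 100 * k / length(s)))
  }
}

test_that("d50 matches the brute-force oracle and closed forms", {
  # perfectly even repertoire: k = n/2, index 50
  even <- rep_from_counts(stats::setNames(rep(10L, 10), paste0("c", 1:10)))
  expect_equal(d50(even), list(k = 5L, index = 50))
  single <- rep_from_counts(c(only = 7L))
  expect_equal(d50(single), list(k = 1L, index = 100))
  # 50 of 100 reaches half the pool on its own under the >= rule (the
  # same rule that gives the even-repertoire closed form k = n/2)
  worked <- rep_from_counts(c(a = 50L, b = 30L, c = 10L, d = 5L, e = 5L))
  expect_equal(d50(worked), list(k = 1L, index = 20))

  set.seed(3)
  for (i in 1:300) {
    rep <- random_repertoire(sample(1:200, 1))
    got <- d50(rep)
    want <- oracle_d50(rep$clones$count)
    expect_equal(got$k, want$k)
    expect_equal(got$index, want$index)
    expect_gt(got$index, 0)
    expect_lte(got$index, 100)
  }
})

test_that("analytic rarefaction equals exhaustive enumeration (pool <= 12)", {
  # enumerate every m-subset of the cell pool and average distinct clones
  enum_rarefaction <- function(counts, m) {
    pool <- rep(seq_along(counts), counts)
    combs <- utils::combn(length(pool), m)
    mean(apply(combs, 2, function(idx) length(unique(pool[idx]))))
  }
  # worked example: counts {3, 1}, m = 2 -> 1.5
  rep0 <- rep_from_counts(c(a = 3L, b = 1L))
  expect_equal(rarefaction(rep0, 2)$expected_richness, 1.5)

  set.seed(5)
  for (i in 1:10) {
    n_clones <- sample(2:5, 1)
    counts <- sample(1:4, n_clones, replace = TRUE)
    if (sum(counts) > 12) counts <- pmax(counts - 1L, 1L)
    counts <- stats::setNames(counts, paste0("c", 1:n_clones))
    rep <- rep_from_counts(counts)
    for (m in unique(c(1L, sample(seq_len(rep$pool_size), 2, replace = TRUE)))) {
      expect_equal(rarefaction(rep, m)$expected_richness,
                   enum_rarefaction(rep$clones$count, m),
                   tolerance = 1e-12)
    }
  }
})

test_that("rarefaction limits: E[S_1] = 1, E[S_N] = observed richness", {
  set.seed(9)
  for (i in 1:10) {
    rep <- random_repertoire(sample(2:40, 1))
    cv <- rarefaction(rep, c(1L, rep$pool_size))
    expect_equal(cv$expected_richness[1], 1)
    expect_equal(cv$expected_richness[2], nrow(rep$clones))
    full <- rarefaction(rep)
    expect_true(all(diff(full$expected_richness) >= -1e-12))
  }
  expect_error(rarefaction(random_repertoire(3), 10000L), "depths")
})

test_that("analytic rarefaction agrees with Monte-Carlo resampling", {
  # 4 SE here: ~15 comparisons at 2,000 draws each, so a family-wise
  # bound; the acceptance suite applies the per-depth 3 SE bound at
  # 10,000 draws
  set.seed(13)
  for (i in 1:5) {
    rep <- random_repertoire(sample(5:25, 1))
    depths <- unique(c(2L, rep$pool_size %/% 2L, rep$pool_size - 1L))
    depths <- depths[depths >= 1]
    mc <- rarefaction_mc(rep, depths, n_draws = 2000L, seed = i)
    an <- rarefaction(rep, depths)
    expect_true(all(abs(an$expected_richness - mc$mean_richness) <=
                      4 * mc$se + 1 / 2000))
  }
})

test_that("jaccard index: set arithmetic, symmetry, self-unity", {
  a <- rep_from_counts(c(a = 3L, b = 1L, c = 2L))
  b <- rep_from_counts(c(b = 9L, c = 1L, d = 5L), sample_id = "S2")
  expect_equal(jaccard_index(a, b), 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(jaccard_index(a, a), 1)
  disjoint <- rep_from_counts(c(x = 1L, y = 2L))
  expect_equal(jaccard_index(a, disjoint), 0)
  set.seed(21)
  for (i in 1:20) {
    r1 <- random_repertoire(sample(2:30, 1))
    r2 <- random_repertoire(sample(2:30, 1), sample_id = "S2")
    expect_equal(jaccard_index(r1, r2), jaccard_index(r2, r1))
  }
  empty <- rep_from_counts(stats::setNames(integer(0), character(0)))
  expect_warning(v <- jaccard_index(empty, empty), "empty")
  expect_equal(v, 0)

  m <- jaccard_matrix(list(a, b, disjoint))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(S1 = 1, S2 = 1, S1 = 1), ignore_attr = TRUE)
})
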