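test_that("clonotype assembly pairs dominant chains deterministically", {
  contigs <- make_contigs(
    barcode = c("b1", "b1", "b2", "b2", "b2", "b3"),
    chain = c("TRA", "TRB", "TRA", "TRA", "TRB", "TRB"),
    cdr3_nt = c("GCAGCA", "TGTGCC", "AAACCC", "GGGTTT", "TGTTGT", "CCCAAA"),
    umis = c(5L, 6L, 7L, 3L, 4L, 2L))
  cc <- assemble_clonotypes(contigs)
  expect_setequal(cc$barcode, c("b1", "b2"))  # b3 lacks TRA
  expect_equal(cc$cdr3a_nt[cc$barcode == "b2"], "AAACCC")  # UMI 7 beats 3
  expect_equal(cc$clone_id[cc$barcode == "b1"], "GCAGCA|TGTGCC")

  # permutation invariance of contig row order
  perm <- contig_table(as.data.frame(contigs)[sample(nrow(contigs)), ])
  cc2 <- assemble_clonotypes(perm)
  expect_equal(cc2[order(cc2$barcode), ], cc[order(cc$barcode), ],
               ignore_attr = TRUE)

  # UMI tie -> higher reads; reads tie -> smallest cdr3_nt
  tie <- make_contigs(
    barcode = rep("b9", 3), chain = "TRA",
    cdr3_nt = c("TTTTTT", "AAAAAA", "CCCCCC"),
    umis = c(4L, 4L, 4L), reads = c(50L, 40L, 40L))
  tie <- contig_table(rbind(as.data.frame(tie),
                            as.data.frame(make_contigs("b9", "TRB",
                                                       "GGGGGG", 2L))))
  expect_equal(assemble_clonotypes(tie)$cdr3a_nt, "TTTTTT")
  tie$reads <- c(40L, 40L, 40L, 20L)
  expect_equal(assemble_clonotypes(contig_table(tie))$cdr3a_nt, "AAAAAA")

  # non-productive and low-confidence contigs are ignored
  np <- make_contigs(c("b1", "b1"), c("TRA", "TRB"),
                     c("GCAGCA", "TGTGCC"), c(9L, 9L),
                     productive = c(FALSE, TRUE))
  expect_equal(nrow(assemble_clonotypes(np)), 0L)
  expect_equal(nrow(assemble_clonotypes(
    make_contigs(character(), character(), character(), integer()))), 0L)
})

test_that("build_repertoire tallies clones per sample", {
  contigs <- make_contigs(
    barcode = rep(paste0("b", 1:5), each = 2),
    chain = rep(c("TRA", "TRB"), 5),
    cdr3_nt = c("AAA", "TTT", "AAA", "TTT", "AAA", "TTT",
                "CCC", "GGG", "ACG", "CGT"),
    umis = 5L)
  cc <- assemble_clonotypes(contigs)
  cells <- make_cells(paste0("b", 1:5))
  rep <- build_repertoire(cc, cells, "S1")
  expect_equal(rep$pool_size, 5L)
  expect_equal(sort(rep$clones$count, decreasing = TRUE), c(3L, 1L, 1L))
  expect_error(build_repertoire(cc, cells, "nope"), "lookup error")

  # empty sample
  cells2 <- cell_table(rbind(as.data.frame(cells),
                             as.data.frame(make_cells("zz",
                                                      sample_id = "S2"))))
  rep2 <- build_repertoire(cc, cells2, "S2")
  expect_equal(rep2$pool_size, 0L)
})

test_that("expansion bins follow the frequency boundaries, unique first", {
  # worked example: sizes {1, 5, 15, 30, 60} in a pool of 1000
  counts <- c(a = 1L, b = 5L, c = 15L, d = 30L, e = 60L, f = 889L)
  rep <- rep_from_counts(counts)
  bins <- bin_expansion(rep)
  got <- setNames(as.character(bins$bin), bins$clone_id)
  expect_equal(got[c("a", "b", "c", "d", "e")],
               c(a = "unique", b = "small", c = "medium", d = "large",
                 e = "hyperexpanded"), ignore_attr = TRUE)

  # half-open boundaries: the boundary value belongs to the upper bin
  rep2 <- rep_from_counts(c(x = 50L, y = 950L))  # f = 0.05 exactly
  expect_equal(as.character(bin_expansion(rep2)$bin[1]), "hyperexpanded")
  rep3 <- rep_from_counts(c(x = 10L, y = 990L))  # f = 0.01
  expect_equal(as.character(bin_expansion(rep3)$bin[1]), "medium")

  # count 1 is unique even at high frequency
  rep4 <- rep_from_counts(c(x = 1L, y = 4L))  # f = 0.2
  expect_equal(as.character(bin_expansion(rep4)$bin[1]), "unique")

  empty <- rep_from_counts(stats::setNames(integer(0), character(0)))
  expect_error(bin_expansion(empty), "empty repertoire")
})

test_that("binning partitions and is monotone in frequency for count > 1", {
  set.seed(11)
  for (i in 1:20) {
    rep <- random_repertoire(sample(5:60, 1))
    bins <- bin_expansion(rep)
    expect_false(anyNA(bins$bin))
    expect_equal(sum(bins$count), rep$pool_size)
    multi <- bins[bins$count > 1L, ]
    if (nrow(multi) > 1L) {
      ord <- order(multi$frequency)
      expect_true(all(diff(as.integer(multi$bin[ord])) >= 0))
    }
  }
})

test_that("expanded_composition fractions cover expanded-clone cells", {
  contigs <- make_contigs(
    barcode = rep(paste0("b", 1:6), each = 2),
    chain = rep(c("TRA", "TRB"), 6),
    cdr3_nt = c(rep(c("AAA", "TTT"), 4), "CCC", "GGG", "ACG", "CGT"),
    umis = 5L)
  cc <- assemble_clonotypes(contigs)
  cells <- make_cells(paste0("b", 1:6),
                      cell_type = c(rep("cytotoxic CD8 T", 3),
                                    rep("Treg", 1), "NK", "NK"))
  rep <- build_repertoire(cc, cells, "S1")
  comp <- expanded_composition(rep, cells, cc)
  expect_equal(sum(comp), 1)
  expect_equal(comp[["cytotoxic CD8 T"]], 0.75)
  expect_equal(comp[["Treg"]], 0.25)

  # no expanded clones -> empty mapping
  rep1 <- build_repertoire(cc[5:6, ], cells, "S1")
  expect_length(expanded_composition(rep1, cells, cc[5:6, ]), 0L)
})

test_that("repertoire TSV round trip", {
  fx <- default_fixture()
  cc <- assemble_clonotypes(fx$contigs)
  rep <- build_repertoire(cc, fx$cells, "P1_liver1")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rep.tsv")
  write_repertoire(rep, p)
  back <- read_repertoire_tsv(p)
  expect_equal(back$pool_size, rep$pool_size)
  expect_equal(back$clones$count, rep$clones$count)
  expect_equal(back$clones$cdr3b_aa, rep$clones$cdr3b_aa)
})
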