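# immunosite

Multisite single-cell immune profiling from paired gene-expression (GEX)
and T cell receptor (TCR) sequencing.

## The problem

In solid tumors, clonally expanded T cells are not necessarily
tumor-reactive: a sizeable fraction are bystanders whose receptors
recognize viral antigens. Telling these apart — and following candidate
tumor-reactive clones from the tumor into the blood and into distant,
histologically normal ("premetastatic") tissue such as the liver — takes a
pipeline that joins per-cell transcriptomes with per-cell TCR sequences
across many samples of the same patient. `immunosite` implements that
pipeline for the common experimental design of one tumor sample, one
blood sample and several replicate biopsies of a distant site per
patient, with paired 10x-style GEX matrices and CellRanger-VDJ contig
tables as inputs.

## What it computes

- **QC gating** — keep PTPRC⁺ cells with total counts, detected features
  and mitochondrial fraction inside configurable closed intervals
  (defaults: [500, 25000] counts, [300, 6000] features, ≤ 15 % mito);
  per-criterion exclusion bookkeeping.
- **Clonotypes** — a clone is a pair of CDR3α/CDR3β *nucleotide*
  sequences; per barcode and locus the UMI-dominant productive chain is
  selected with a deterministic tie-break. The clonotype-bearing cells of
  a sample form its *TCR pool*, the denominator for clone frequencies
  f = n/N.
- **Expansion bins** — unique (n = 1, checked first), then by frequency:
  rare f < 0.1 %, small [0.1, 1) %, medium [1, 2) %, large [2, 5) %,
  hyperexpanded f ≥ 5 %.
- **Diversity** — D50 (smallest k dominant clones with Σ counts ≥ N/2,
  also as a percent of distinct clones), analytic rarefaction
  E[S_m] = Σ_i (1 − C(N−n_i, m)/C(N, m)), and presence/absence Jaccard
  overlap between repertoires.
- **Tracking & bystanders** — the top-20 expanded tumor clones tracked
  into each blood/liver repertoire (frequency 0 where absent), with
  exact CDR3β amino-acid matches against a VDJdb-style reference flagged
  as *putative* viral bystanders (no HLA restriction is applied).
- **Signature scoring** — per-cell rank-AUC recovery-curve scores
  (area under the cumulative gene-set hit curve within the top 5 % of
  each cell's gene ranking, normalized by the maximum achievable area)
  and ssGSEA rank-weighted ECDF-difference scores; both depend only on
  the within-cell ranking.
- **Nomination** — filter tumor T cells with paired GEX+TCR, drop Tregs,
  MAIT (TRAV1-2 α chain), γδ and cycling cells; per signature take the
  top 5 % of eligible cells of the target lineage (nearest-rank, ties
  included); intersect the two CD8 signatures and the two CD4 signatures
  into per-lineage *consensus* cells/clonotypes; track consensus clones
  into blood and liver.
- **Concordance** — pairwise cell-type-proportion correlation, log-CPM
  pseudobulk correlation and repertoire Jaccard across samples.
- **DGE** — per-gene two-sided Wilcoxon rank-sum on CPM values (exact
  enumeration for groups ≤ 8 cells), BH adjustment, strict
  |log2FC| > 0.5 and p_adj < 0.05 filters.
- **Synthetic data** — a seeded generator of the full multisite design
  (3 patients × {blood, tumor, liver×3}) with recorded ground truth:
  negative-binomial cell-type programs, power-law repertoires, planted
  cross-site clones, planted viral bystanders, planted signature-boosted
  reactive cells, and QC decoys.

## Worked example

```r
library(immunosite)

fx   <- simulate_multisite(simulation_config(seed = 1L))
qcfg <- do.call(qc_thresholds, fx$ground_truth$config$qc)
res  <- apply_qc(fx$matrices[["P1_tumor"]], qcfg)
print(res$report)
#> <qc_report> 326 cells in, 320 kept (boundaries inclusive)
#>   excluded by low_total_reads: 1
#>   excluded by high_total_reads: 1
#>   excluded by low_features: 2
#>   excluded by high_features: 2
#>   excluded by high_mito:   1
#>   excluded by ptprc:       1

cc    <- assemble_clonotypes(fx$contigs)
rep_t <- build_repertoire(cc, fx$cells, "P1_tumor")
print(rep_t)
#> <repertoire> sample 'P1_tumor': 104 clones, pool size 260

d <- d50(rep_t)
cat("D50: k =", d$k, " index =", round(d$index, 2), "\n")
#> D50: k = 11  index = 10.58

top <- top_expanded(rep_t, 5)
annotate_viral(top, fx$viral_ref)[, c("viral_match", "species")]
#>   viral_match    species
#> 1       FALSE       <NA>
#> 2        TRUE        CMV
#> 3       FALSE       <NA>
#> 4       FALSE       <NA>
#> 5        TRUE InfluenzaA
```

The six QC exclusions are the generator's planted decoy cells (one per
criterion); all 320 genuine cells pass. Eleven dominant clones cover half
the tumor TCR pool (10.6 % of its 104 distinct clones — an oligoclonal
repertoire), and two of the five most expanded tumor clones match viral
reference CDR3β sequences exactly: expanded, but putative bystanders, and
indeed never nominated by the signature consensus (see the test suite's
nomination-recovery criterion).

## Pipeline and CLI

`run_pipeline(manifest, out_dir)` chains
qc → repertoire → diversity → tracking → scoring → nomination →
concordance from a JSON manifest (see `fixture_manifest()` for the shape)
and writes a deterministic report bundle plus a `run_log.json` that
materializes every configuration value. The same entry points are exposed
as subcommands of `inst/scripts/immunosite` (`simulate`, `qc`,
`repertoire`, `diversity`, `track`, `score`, `dge`, `pipeline`, …); run it
with no arguments for usage.

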