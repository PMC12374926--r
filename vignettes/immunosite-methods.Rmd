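---
title: "immunosite: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunosite: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(immunosite)
```

This vignette is the package's own account of its methods: what each
stage computes, which conventions were chosen where the field leaves
room, and what the synthetic fixture does and does not establish. It
states no empirical result that the test suite does not itself compute.

## Quality gating

A cell is kept iff (i) its PTPRC (CD45) count is positive (the data are
sorted immune cells, so PTPRC⁻ droplets are ambient or non-immune), (ii)
its total UMI count lies in `[min_total_reads, max_total_reads]`, (iii)
its number of detected features lies in `[min_features, max_features]`,
and (iv) its mitochondrial count fraction is at most `max_mito_pct`/100.
Two conventions deserve note:

* **Boundaries are inclusive.** The exclusion rules are worded as strict
  inequalities ("fewer than 500", "greater than 25,000"), so a cell at
  exactly 500 counts, 300 features or 15.0 % mito passes. The tests pin
  this.
* **"Reads" means UMIs.** Downstream of UMI counting the only available
  per-cell total is the UMI total; the package adopts it and records the
  interpretation in the report.

`excluded_by` keeps six separate counters (low/high total counts,
low/high features, high mito, ptprc); a cell can count under several.
Mitochondrial genes are identified by a symbol prefix (default `MT-`,
human).

## Clonotypes, repertoires, expansion bins

Clonotype identity is the pair of CDR3α and CDR3β **nucleotide**
sequences; amino-acid CDR3s are carried as metadata because public viral
references store amino acids. Assembly considers only productive,
high-confidence TRA/TRB contigs; per barcode and locus the chain with the
highest UMI count wins, with ties broken by read count and then by the
lexicographically smallest CDR3 nucleotide string — making the result
invariant to contig row order. Cells lacking either locus are excluded
from repertoires (a `beta_only` mode exists for sensitivity analysis but
is off by default).

Expansion bins partition clones: `unique` is defined by absolute count 1
and checked **before** any frequency rule, because in a small pool a
singleton can exceed 0.1 %. The remaining bins are half-open intervals of
the clone frequency f with the boundary value assigned upward: rare
f < 0.001, small [0.001, 0.01), medium [0.01, 0.02), large [0.02, 0.05),
hyperexpanded f ≥ 0.05. The prose this mirrors leaves f = 0.05 unassigned
("less than 5 %" vs "greater than 5 %"); the package closes the gap
upward, consistently at every boundary.

## Diversity statistics

* **D50**: order clones by descending count (ties by clone key); k is the
  first position where the cumulative count reaches **at least** half the
  pool; the index is 100·k / (number of distinct clones). The ≥ rule is
  the one under which a perfectly even repertoire of n clones gives
  k = n/2, index 50 — the standard convention in repertoire packages.
  Both k and the percentage are reported, since sources differ in which
  they print.
* **Rarefaction** is the exact hypergeometric expectation
  E[S_m] = Σ_i (1 − C(N−n_i, m)/C(N, m)), computed via `lchoose` in log
  space. It is verified against exhaustive enumeration of all C(N, m)
  subsamples for pools up to 12 cells and against Monte-Carlo resampling
  (10,000 draws) elsewhere. Note a subtlety in the Monte-Carlo
  comparison: near m = N the richness is almost surely constant across
  draws, the estimated SE collapses to zero, and a mean of n draws cannot
  resolve differences below 1/n — the tests therefore allow 3 SE plus
  that resolution floor.
* **Jaccard** overlap is presence/absence on clonotype sets, not
  abundance-weighted; two empty repertoires give 0 with a warning.

## Tracking and viral annotation

The top-n (default 20) expanded tumor clones are tracked into every
blood/liver repertoire of the same patient; an absent clone has frequency
exactly 0. Cross-site identity is nucleotide-level (the clonotype
definition); viral annotation is amino-acid-level and by default
**β-chain only** — β is the discriminative chain in public references,
and requiring the α chain too (mode `paired_aa`) is stricter than the
reference data usually support. When several reference rows match, all
are counted and the first by (species, epitope) order is reported, so
annotation does not depend on reference row order. Because no HLA
restriction is applied, a match is only a *putative* bystander flag.

## Signature scoring

The AUC score ranks a cell's genes by decreasing count — zero-count genes
participate below all detected genes, keeping the window identical across
cells — and measures the recovery curve y(x) = #(set members in the top x
ranks) over x = 1..max_rank, normalized by the maximal area achievable
when min(|G|, max_rank) members occupy the top ranks. `max_rank` defaults
to ⌈0.05 · #genes⌉, the documented default of the method family this
follows; it is exposed in `scoring_config` and recorded in output
metadata. Ties are broken by original gene index by default
(`stable_index`), which makes scores bitwise reproducible; a
`seeded_random` policy reproduces the published behavior of randomizing
ties. Scores depend only on the ranking, hence are invariant under any
strictly monotone transform of expression — a property the tests check,
along with exhaustive-enumeration agreement for every placement of ≤ 4
set genes in universes of ≤ 12 genes.

ssGSEA is the rank-weighted ECDF difference: with genes at positions
1..N by decreasing expression, in-set positions weighted
(N − pos + 1)^α (α = 0.25 by default; α = 0 reduces to the unweighted
Kolmogorov running sum), the score is Σ over positions of (weighted
in-set ECDF − out-set ECDF).

## Nomination

Eligibility: tumor-tissue αβ T cells with a paired clonotype, minus
Tregs (label-based), MAIT cells (mechanically: any productive TRA contig
with V gene TRAV1-2, allele suffixes ignored), γδ cells (label-based;
they also fail the paired-αβ requirement) and cycling cells
(label-based). Label-based rules are deliberate: cluster annotation is
upstream curation, not something this package re-derives. Every
non-eligible cell gets exactly one primary reason, with labeled γδ cells
logged as `gamma_delta` rather than `no_paired_tcr` because the more
specific reason is the useful one.

The "top 5 %" cut is per signature, restricted to eligible cells of the
signature's target lineage. Convention: nominate the k = ⌈p/100 · n⌉
highest-scoring cells plus any cells tied with the k-th score — so with
distinct scores exactly k cells pass, and threshold ties only enlarge the
set. The cut is taken **within lineage** (each signature targets one
lineage and the CD4/CD8 pools are scored separately); pools under 20
cells fall back to max(1, round(p/100 · n)) top cells with a warning.
Consensus is the per-lineage intersection of the nominated sets (two
signatures per lineage by default, generalizing to any number); consensus
clonotypes are ranked by number of nominating signatures, then mean AUC,
then clone key.

## Concordance and differential expression

Pseudobulk is per-gene **sum** → counts-per-million → log1p: CPM makes
replicates of different cell numbers comparable and the log tames the
heavy tail; the aggregation statistic and transform are recorded in the
report metadata since conventions differ. Correlations default to
Pearson on these log-CPM vectors (Spearman by flag); proportion vectors
use the global cell-type vocabulary so they are commensurate across
samples; all three matrices are computed once per unordered pair and are
therefore exactly symmetric.

DGE uses the two-sided Wilcoxon rank-sum on CPM values: exact enumeration
of all C(n_A+n_B, n_A) rank assignments when both groups have ≤ 8 cells
(two-sided p = min(1, 2·min(P≤, P≥))), and the tie-corrected normal
approximation with continuity correction otherwise. log2FC =
log2((mean_A + 1)/(mean_B + 1)) on CPM means. Genes detected in fewer
than `min_cells` (default 3) cells are not tested; BH adjustment runs
over the tested genes. The significance filter is strict on both sides
(|log2FC| > 0.5, p_adj < 0.05), so a gene at exactly 0.5 is excluded.

## The synthetic world

The generator emulates the study design it stands in for: 3 patients,
each with one blood sample (400 cells), one tumor sample (320 cells,
fixed per-type composition) and three liver replicates (260 cells,
multinomial with a patient-specific log-normal composition effect,
sd 0.35). Counts are negative binomial (size 2) over a 611-gene universe:
PTPRC, 10 mitochondrial genes (mean 2), 100 housekeeping genes
(mean 1.5), a 30-gene program per cell type (mean 4), four reactivity
signatures and M1/M2 polarization sets (baseline mean 0.3). Repertoires
draw clone sizes iid from a truncated power law (exponent 2.5, support
1..15); planted on top of that baseline are, per patient: 8 expanded
tumor clones shared into liver and blood at recorded counts, two of them
carrying viral-reference CDR3β sequences (expanded but **not**
signature-boosted — the bystander confound by construction); reactive
clones whose tumor cells have signature-gene means multiplied by 15
(8 CD8 + 2 CD4 cells, ≈ 5 % of the eligible pool, so the planted
prevalence matches the nomination cut); one reactive clone re-planted in
liver replicate 1 so consensus tracking has a planted positive; and 12
liver-only clones shared across the three replicates. Six QC decoys per
sample violate one criterion each.

Deliberate choices and their reasons:

* **Boost factor 15** puts signature genes at program-level means
  (0.3 × 15 = 4.5) — a reactive cell expresses its signature like a cell
  type expresses its program, which is the regime where a rank-based
  score can see it. This is an effect-size statement about the stated
  world, not a tuning knob.
* **QC gates scaled to the synthetic depth** (250/120 lower, 2500/500
  upper, 15 % mito, in `SimulationConfig$qc`): the generator simulates a
  shallower library than a real run, so the absolute published defaults
  would reject every synthetic cell. The package defaults stay at the
  published absolute values and are exercised on a hand-built fixture.
* **PTPRC is drawn as 1 + NB**, guaranteeing positivity for non-decoy
  cells, so QC ground truth is exact rather than probabilistic.
* **Fixed tumor composition** makes the eligible-TIL pool size
  deterministic, so the planted-reactive fraction is exactly known.

What a green fixture run does **not** establish: the generator has no
doublets, no ambient RNA, no batch effects, no UMI saturation, no shared
clones between patients, no V(D)J recombination structure in its random
CDR3 strings, and its expression programs are disjoint blocks rather
than correlated modules. Recovery results on it validate the *mechanics*
(bookkeeping, thresholds, set operations, rank statistics), not
biological sensitivity on real data.

## Degenerate inputs and numerics

Empty repertoires error in `d50`/`rarefaction`/`bin_expansion` and warn
(returning 0) in `jaccard_index`; a gene set disjoint from the universe
yields an all-NA score column plus a coverage warning (threshold 0.8 of
set members found, configurable); an all-tied score distribution
nominates every cell with a degeneracy warning; empty consensus sets
produce empty, well-typed tables throughout. Rarefaction works in log
space; rank statistics avoid floating comparisons by operating on integer
ranks. The pipeline writes no wall-clock timestamps, so rerunning a
manifest reproduces the report bundle byte for byte.

## Known limitations

Signature GMTs shipped by the generator are synthetic stand-ins (the
real published gene lists live in supplementary material not bundled
here); users supply their own GMT and VDJdb-style reference for real
analyses, including the reference release and score threshold, which are
deliberately user-controlled inputs. Normalization, integration,
clustering and cell-type annotation are out of scope — the cell table's
labels are trusted as given. Concordance is descriptive (no testing), and
the DGE module is a minimal two-group rank-sum tool, not a
pseudoreplication-aware mixed model.
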