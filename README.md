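# chromage

Quantifying enhancer remodelling and histone-acetylation gain in aging
tissue.

## The problem

Bulk-tissue cohorts profiled for an active chromatin mark (H3K27ac) across
a range of donor ages show a characteristic pattern: a minority of genomic
regions gain acetylation with age, the gains concentrate in distal
enhancers, and the affected enhancers sit next to genes — prominently
extracellular-matrix (ECM) genes — whose expression rises in step. `chromage`
implements the full analysis chain for detecting and integrating these
changes, for epigenomics researchers who have per-sample coverage tracks,
peak calls, and an expression matrix with sample ages.

The pipeline's core statistics:

* **Binned differential z-score.** The genome is tiled into width-*W* bins
  (1 Mb by default); each sample's input-normalized coverage is aggregated
  per bin, and a test sample's bin value is expressed as
  `z = (x − mean_young) / sd_young` over the young reference cohort
  (leave-one-out when the test sample is itself young). Bins with `z > 2`
  are gained, `z < −2` lost; per-sample gain fractions are compared
  between age groups with an exact Wilcoxon rank-sum test.
* **Peak atlas.** Peaks from all samples are pooled; transitively
  overlapping peaks are merged into atlas entries with per-sample support,
  and single-sample peaks are retained alongside.
* **Super-enhancer calling.** Distal peaks (> 5 kb from any TSS) are
  stitched (gap ≤ 12.5 kb) and rank-ordered by background-corrected
  signal mass; on the rank-signal curve scaled to the unit square, the
  tangent (slope-1) cutoff — the last point below the unit diagonal —
  splits typical from super-enhancers.
* **Trend clustering.** Feature trajectories over ordered age groups are
  assigned to integer model profiles (steps in [−c, c], greedy max-min
  selection of m representatives) by Pearson correlation; profile
  significance comes from a T!-order permutation null with a binomial
  tail and Bonferroni correction.
* **Integration.** Activated enhancer constituents are linked to their
  nearest-TSS genes; the overlap with trend-increasing genes is scored by
  the exact hypergeometric upper tail; a Welch test on log2 expression
  summarizes gene-set (e.g. ECM module) up/down fractions.

A synthetic aging-cohort generator with planted age-responsive loci and a
labelled ECM-like gene module makes every stage testable end to end with
known ground truth — no external data needed.

## Worked example

```r
library(chromage)

cfg <- pipeline_config(
  output_dir = "desk_run",
  synthetic  = default_desk_config(seed = 1),  # 2 x 10 Mb, 9 ChIP samples,
  bin_width  = 1e5,                            # 400 loci, 10% planted at 1.8x/group
  seed       = 1)
res <- run_pipeline(cfg)
print(res$report, row.names = FALSE)
```

Key lines of the report this prints (seed 1):

```
 stage                    metric       value
  bins mean_frac_increased_young       0.095
  bins  mean_frac_increased_aged     0.13875
  bins       p_increased_greater   0.0418945
trends  n_activated_constituents          39
trends        n_increasing_genes          34
integrate      overlap_fraction    0.846154
integrate             overlap_p 1.63283e-54
 truth     planted_locus_recall       0.975
 truth  ecm_intersection_recall       0.825
```

Reading it: aged samples call ~14% of bins as gained versus ~9.5% in young
samples (one-sided rank-sum p = 0.042); 39 enhancer constituents show a
significant monotone increase across the four age groups, and 84.6% of
their target genes are also trend-increasing in expression — an overlap
that would essentially never arise by chance (hypergeometric p ≈ 1e−54).
Of the 40 planted age-responsive loci, 39 are recovered as activated
(recall 0.975), and 82.5% of the planted ECM-like genes land in the
activated-enhancer ∩ up-regulated intersection.

Per-stage tables (bin z-scores and calls, atlas BED + provenance, ranked
enhancer/SE calls, trend profiles/assignments/significance, nearest-gene
map, DE table, gene-set summaries) are written under `output_dir`, each
with a `#` provenance header recording version, seed and parameters.
A thin CLI with per-stage subcommands lives at `inst/cli/chromage.R`:

```sh
Rscript inst/cli/chromage.R all --output-dir desk_run --seed 1
```

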