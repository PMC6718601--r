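---
title: "Methods: quantifying enhancer remodelling in aging tissue"
author: "chromage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enhancer remodelling in aging tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromage` analyses age-related change in an active-chromatin mark
(typically H3K27ac) across a cohort of bulk-tissue samples with ordered
ages, and links the regulatory changes it finds to gene expression. This
vignette describes each statistical component, its assumptions, the
tunable parameters, and the design choices taken where more than one
defensible option existed.

## Data model

All coordinates are 0-based half-open (BED convention). A sample cohort
consists of per-sample ChIP and input coverage tracks (bedGraph),
per-sample peak calls (BED), a TSS annotation, a chromosome-size table, a
gene-expression matrix, and a sample sheet assigning each sample an age, a
coarse group (`young`/`aged`, split at a declared age cutoff) and a fine
group (an ordered category such as adolescent < adult < aging < aged).
Group labels are always taken from the sample sheet, never inferred from
ages, because coarse cutoffs and fine categories can legitimately disagree
near the boundary.

Coverage tracks carry a *read-length equivalent* (default 100 bp): library
size is `sum(value x run length) / read_length`, which makes CPM and RPKM
well-defined when only coverage, not alignments, is available. Bases not
covered by any run carry signal 0.

## Genome-binned differential signal

The genome is tiled into fixed-width bins (`make_bins`; 1 Mb for a
full-size genome, 100 kb for the desk-scale synthetic cohort — the
statistic is width-agnostic). Each sample's ChIP track is normalized to
its input as a per-base ratio of CPM-scaled signals with a pseudocount of
1 (`input_normalize`), and aggregated per bin as the length-weighted mean
(`bin_counts`).

For a test sample, each bin receives a z-score: the number of young-cohort
standard deviations (sample sd, n−1) its normalized count lies from the
young-cohort mean. Bins with z above +2 are called *increased*, below −2
*decreased*; comparisons are strict, so boundary bins are conservative
calls. Bins whose young-cohort dispersion is zero are reported *undefined*
rather than assigned infinite scores. When a young sample itself is
scored, the reference excludes that sample (leave-one-out) to avoid
self-comparison bias; a consequence worth knowing is that young samples
are scored against a smaller reference (heavier t-like tail), so the young
null call rate slightly exceeds the aged one — the one-sided
aged-greater-than-young test below is therefore conservative under the
null.

Before z-scoring, `bin_differential` divides each sample's bin values by
the sample's median bin value (configurable; `sample_scale = "none"`
disables it). Equal-mass CPM scaling transfers differences in total
in-peak mass into an apparent genome-wide background shift: a sample with
more signal in peaks gets a slightly depressed background ratio. The
median bin is background-dominated, so median-centering removes this
composition artifact while leaving relative bin-level gains untouched.
Z-scores remain invariant under any common affine rescaling of all
samples.

Per-sample fractions of increased (and decreased) bins, computed over
defined bins, are compared between coarse groups with a Wilcoxon rank-sum
test (exact distribution for group sizes up to 10 without ties). The
boxplot-style group difference in the increased-bin fraction is the
pipeline's first headline statistic.

## Peak atlas

Peaks from all samples are pooled; overlapping peaks (at least one shared
base; half-open abutment is not overlap) are clustered transitively and
each cluster becomes one atlas entry spanning its union. Entries supported
by two or more distinct samples are annotated `merged`, single-sample
entries `nonoverlapping`; both are retained, so the distinction is
metadata only. Same-sample overlapping peaks are merged beforehand so that
support counting is well-defined. No minimum-overlap fraction is imposed.
The construction is idempotent, conserves every input peak base, and is
invariant to sample order.

## Typical and super-enhancer calling

Peaks whose gap to the nearest TSS exceeds 5 kb (strictly) are enhancers;
the gap is zero when a TSS lies inside the peak, otherwise the distance
from the nearer peak edge. The TSS exclusion is applied *before*
stitching. Distal peaks separated by at most 12,500 bp (the customary
stitching distance for rank-ordering approaches; configurable) are
stitched into candidate regions. Each region's signal is the
background-corrected mass over its constituents — CPM-scaled ChIP minus
CPM-scaled input, summed over constituent bases only and floored at zero,
since negative enhancer mass is meaningless for ranking.

Regions are rank-ordered by signal and the curve is scaled to the unit
square (ranks to x in [0,1], signals to y in [0,1] by the maximum). The
super-enhancer cutoff is the tangent (slope-1) point in its
diagonal-crossing form: the last point of the scaled curve lying strictly
below the unit diagonal; regions with signal strictly above the cutoff
signal are super-enhancers, with equal-signal ties on the super side all
included. Among the candidate discrete tangent rules (first slope-1
crossing, argmin of |slope−1| at crossings, argmin of y−x), this is the
only one that reliably isolates a detached high-signal population: single
large spacings in the upper tail of a continuous background (which occur
with high probability for exponential-like signals) trip every
slope-based local rule, while the diagonal crossing depends only on the
global geometry. The trade-off, stated plainly: on a smooth, unbroken
signal tail the diagonal crossing sits very high, so few regions are
called super. On the desk-scale synthetic cohort (a continuous lognormal
amplitude distribution) per-sample SE counts are accordingly small; the
rule's recovery guarantees apply when the signal distribution genuinely
separates into background and a detached high component. The cutoff is
scale-invariant, and the SE block is always a prefix of the descending
ranking.

Group-level SE sets are built per-sample-first: each group's set is the
union-merge of its member samples' SE spans, and two group SEs are shared
when their spans overlap by at least one base (recorded in the output
metadata, since pooling-before-calling is an equally defensible
alternative). Sample-sample similarity of SE signal uses Spearman
correlation with midranks; zero-variance columns are flagged as NA.

## Trend clustering over ordered age groups

Feature-by-sample matrices (enhancer-constituent RPKM, or gene
expression) are collapsed to group means over the ordered fine groups.
Features whose pseudocounted ratio between the first and last group (in
either direction) is below 2 are removed first (`fold_change_filter`,
pseudocount 0.1 RPKM to stabilize zeros); rows are then log2-transformed
with pseudocount 1, giving fold-change symmetry.

Model profiles are integer series of length T starting at 0 with per-step
changes in [−c, c]. All `(2c+1)^(T−1)` candidates are enumerated and m
representatives chosen by greedy max-min selection under Euclidean
distance: the flat profile is always kept, the first pick is the profile
farthest from flat, and ties resolve lexicographically, so selection is
fully deterministic. Defaults c = 2, m = 50, following the customary
defaults of short-series model-profile clustering; with T = 4 this keeps
m well under the 125 candidates.

Each row is assigned to the profile maximizing Pearson correlation with
its group-mean series (ties to the lower profile id). Correlation makes
assignment invariant under positive affine transforms of a row; the flat
profile has undefined correlation and never receives members; constant
rows are excluded and reported. Note that profiles which are positive
affine images of each other (e.g. 0,1,2,3 and 0,2,4,6) are equivalent
under correlation; the tie rule deterministically routes all such members
to the lower id.

Profile significance uses a column-permutation null: each row's T group
values are permuted uniformly over all T! orders (seeded), rows are
re-assigned, and the permutation-averaged expected count per profile
feeds a binomial upper tail, `P(Binomial(N, e/N) >= observed)`, with
Bonferroni correction over the m profiles (alpha 0.05). Defaults use
1,000 permutation rounds; the 50-seed null calibration in the test suite
uses 300 rounds, which leaves the expected counts stable to well within
the binomial tail's resolution at these problem sizes.

"Activated" enhancer constituents (and up-/down-regulated genes) are the
members of significant profiles whose vectors are monotone non-decreasing
(resp. non-increasing) with at least one strict step; the union over such
profiles is returned along with per-profile membership, so either a
single-cluster or union-of-clusters reading can be reproduced.

## Integration

Each enhancer constituent is assigned the gene with the nearest TSS,
measured from the constituent midpoint (integer floor), no distance cap,
ties to the lexicographically smaller gene id; midpoint-to-TSS is the
deterministic convention used by rank-ordering enhancer tools, and an
edge-to-TSS variant would change little at enhancer widths. The signed
distance is positive when the constituent lies downstream of the TSS in
the gene's strand orientation.

Overlap between activated-enhancer target genes and trend-increasing
genes is scored with the exact hypergeometric upper tail over a gene
universe of expressed genes (row mean above a floor of 0.1, configurable
— the universe choice is the usual silent degree of freedom in such
analyses and is therefore an explicit parameter here).

Two-group differential expression is a deliberately simple stand-in for
platform-specific testing (the upstream analyses it emulates used
microarray pipelines whose details are immaterial here): a per-gene Welch
t-test on log2(x+1), calls `up` when the log2 fold change is at least 1
with p below 0.05. Genes with zero variance in both groups get p = 1 when
means agree and p = 0 otherwise, so constructed degenerate inputs behave
predictably. Gene-set summaries report up/down/unchanged fractions within
a set, and the per-condition fraction of set genes targeted by at least
one enhancer of that condition's call set ("active" = membership in the
condition's enhancer calls; no additional signal threshold, which the
output notes).

## Synthetic aging cohort

The generator builds a fully self-contained cohort with known ground
truth. The default desk configuration: 2 chromosomes x 10 Mb analysed at
100-kb bins; fine groups sized (3, 2, 2, 2) with ages (15, 18, 22 | 32,
38 | 52, 58 | 72, 76) and a young/aged cutoff at 50; 1,000 genes on
regular tiles with jittered TSSs; 400 enhancer loci, each placed
6.5–8.5 kb from its own target gene's TSS — far enough to survive the
5-kb distal filter, near enough to remain that gene's nearest neighbour
by construction; 10% of loci planted, with enrichment and target-gene
expression scaled by `multiplier^(group index)` (default 1.8, i.e. 5.8x
end-to-end; multiplier 1 gives the null cohort).

Coverage is negative-binomial: background mean 20 per 1-kb window with
dispersion size 50, and Gaussian-shaped enrichment of amplitude ~200
(10x background depth, a typical strong-peak enrichment for an active
histone mark at realistic sequencing depth) with lognormal amplitude
spread (sdlog 0.5) and 5% of loci boosted 10x (the heavy tail).
Background is simulated on a 1-kb grid and refined to 100-bp windows
within +/-3 sigma of each locus, where resolution actually matters, then
run-length encoded; this keeps the desk fixture around 10 MB. At a
shallower depth (background ~5 per kb) the planted bin-level gain is
physically undetectable — a 1-kb peak inside a 100-kb bin shifts the bin
mean by less than the ratio noise — so the defaults deliberately emulate
a deeply sequenced library; that is a statement about what the generator
models, not a tuning of any test.

Peaks are emitted wherever *true* enrichment exceeds the background mean
plus 3 sd (peak calling itself is out of scope, and re-calling would
conflate a caller's behaviour with the pipeline's). Expression is
lognormal (baseline meanlog 3, sdlog 1) with multiplicative noise sdlog
0.2 per sample. Everything is deterministic given the seed; writing the
fixture twice yields byte-identical files.

What the generator does *not* model: chromatin-state spatial
correlation, copy-number or mappability artifacts, peak-caller
idiosyncrasies, or expression covariance between genes. Passing tests
therefore demonstrate that the pipeline's statistics recover the planted
structure under honest noise, not that they are robust to every artifact
of real tissue data.

The trend-recovery fixture used in the tests plants 200 of 2,000
features with a geometric increase of 4-fold end-to-end under lognormal
noise (sdlog 0.2). The end-to-end fold sits deliberately above the
2-fold filter threshold: a planted fold exactly at the filter boundary
would be removed for half the rows by noise alone, which would measure
the filter, not the clustering.

## Numerical and degenerate-input conventions

Ratios use pseudocounts (1 in CPM units for input normalization; 0.1
RPKM in the fold filter; 1 in log2 transforms). Zero-dispersion bins are
undefined rather than infinite. Zero-variance correlation columns are NA
with a warning. The tangent cutoff returns zero super-enhancers for
curves that never dip below the diagonal (all-equal signals, signal
linear in rank). All interval operations treat end == start as
non-overlapping. Sorting uses chromosome-table order wherever a size
table is supplied, lexicographic order otherwise; all tie-breaks
(profile ids, gene ids, rank order) are deterministic, which is what
makes byte-identical reruns possible.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
desk configuration above (about 10 s per run), 20 null-cohort
simulations of the binned stage, 50 null trend matrices of 2,000 x 4 at
300 permutations, one 2,000 x 4 recovery matrix at 1,000 permutations,
and 100-seed sweeps of the super-enhancer cutoff — sizes chosen so the
whole suite completes in a few minutes while every statistic is still
estimated from hundreds of independent draws.

## Known limitations

The z-score stage applies no multiple-testing correction across bins
(matching the upstream analysis it reproduces); its calls are
descriptive, and only the group-level rank-sum comparison is
inferential. The leave-one-out asymmetry noted above makes young and
aged null call rates differ by design. The diagonal-crossing tangent
cutoff is conservative on smooth signal tails. The Welch DE test is a
stand-in, clearly labelled in output metadata, not a replacement for a
platform-aware model. Nearest-TSS assignment ignores chromatin contact
structure. The permutation null for profiles treats rows independently,
ignoring feature correlation.
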