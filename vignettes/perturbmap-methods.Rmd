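---
title: "Methods: models, parameters, and design choices in perturbmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in perturbmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

perturbmap analyses pooled CRISPRi screens with a single-cell RNA-seq
readout. This vignette is the package's own account of the statistical
machinery: what each stage assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where design decisions were genuinely
open.

## Guide calling

Guide read counts per construct across cells are bimodal: ambient or
barcode-hopping background near zero, and true integrations at tens to
hundreds of reads. `fit_guide_mixture()` models the background as
Poisson on the raw counts and the signal as Gaussian on log2(count+1),
mixed with weight `w`, fit by EM. Because the likelihood depends only on
the count histogram, EM runs over unique values with multiplicities, so
the default 100 random restarts stay cheap even for millions of cells.
Restarts are tie-broken by likelihood and then by restart order; a cell
is called positive when its posterior signal probability exceeds 0.5
(exposed as `cutoff`). Constructs with fewer than 10 nonzero cells are
skipped rather than fit (too little information for a two-component
model), and all-zero constructs are flagged `no_signal`.

Before fitting, `downsample_guide_reads()` equalizes sequencing depth by
subsampling each cell's guide reads without replacement (multivariate
hypergeometric across constructs) to a per-cell target — 1000 reads/cell
is the convention for a typical deeply sequenced lane.

A cell is a `single_perturbation` when its called constructs target
exactly one gene — one construct, or the two guides of a dual-guide
element sharing a target. Distinct non-targeting constructs are treated
as distinct labels, so each non-targeting guide defines its own control
pseudo-perturbation (these per-guide labels are what the core-control
selection below compares); a cell carrying two different non-targeting
guides is therefore a multiplet, a deliberately conservative convention.

## Control-anchored normalization

All inference is anchored on non-targeting control cells, but some
non-targeting guides produce phenotypes by chance. `select_core_controls()`
compares every pair of control constructs per gene (genes with mean
>1 UMI/cell) with the two-sample Anderson–Darling test, BH-adjusts over
all pairs × genes, counts per-construct average DEGs against all others,
and keeps constructs below a threshold (8 at genome-scale depth, 30 for
deeper essential-gene libraries, following the depth-dependence of the
gene universe). Two implementation choices matter here. First, cells
are scaled to a common total before z-normalization, otherwise gemgroup
depth differences masquerade as construct differences whenever a
construct's cells are unevenly split across gemgroups — with many
gemgroups this averages out, at desk scale it does not. Second,
p-values are extended below the tabulated floor of 0.001 with a
Monte-Carlo grid (see below); otherwise BH across tens of thousands of
pairwise tests cannot call anything.

`compute_depth_factors()` rescales each gemgroup so core-control mean
total UMIs are equal; `apply_qc_filters()` then drops cells below an
adjusted-UMI floor (2000 by default; inclusive, so a cell exactly at the
floor stays) or above a mitochondrial-fraction ceiling (0.25 default,
inclusive). `fit_normalization()` scales every cell to the core-control
median total and records per-gemgroup, per-gene control means and SDs;
`z_transform()` applies `(x − μ)/σ`. Genes with zero control SD in a
gemgroup are masked (NA) there instead of producing infinite z-scores.
By construction, control cells have per-gene z mean 0 and SD 1 within
each gemgroup, which the tests verify to 1e-6. Whether μ/σ should come
from all non-targeting cells or core controls only is ambiguous in
principle; the package uses core controls (the set whose homogeneity was
just established) and accepts any label set via arguments.

## The energy-distance test

Global transcriptional phenotypes are detected by comparing a
perturbation's cells with control cells in the space of the top k = 20
principal components of the z-matrix, restricted to genes with mean
>0.5 UMI/cell and clipped at z = 10 to dampen a handful of strongly
induced outliers. The estimator is the three-double-sum form
2/(n₁n₂)Σ‖x−y‖ − 1/n₁²Σ‖x−x‖ − 1/n₂²Σ‖y−y‖. This biased variant can be
slightly negative on finite same-distribution samples; the permutation
p-value, not the sign, carries the inference. Distances are computed by
per-dimension differencing — the expanded dot-product identity loses
several digits to cancellation and would fail the brute-force oracle
comparison at 1e-10.

Permutation is over pooled labels; since the pooled pairwise distance
matrix is fixed, each permutation only needs the submatrix sums touching
the permuted "perturbed" set, making 10,000 permutations (the default)
cheap. p-values use the add-one rule p = (1+b)/(1+B) so p > 0 always and
the null is uniform on the achievable grid. Controls larger than 5,000
cells are subsampled once per run with the run seed. The PCA solver
switches to a truncated randomized method (irlba) on large inputs; a
small-case test pins agreement with dense SVD up to sign at 1e-8.

## Gene-level testing

Distribution-free tests accommodate batch structure, incomplete
penetrance and heterogeneous programs: the tie-corrected (midrank)
two-sample Anderson–Darling statistic, standardized by its exact
finite-sample variance, and the asymptotic two-sided Mann–Whitney test
(gated at 10 cells minimum), both BH-adjusted per perturbation. Within
the tabulated range the AD p comes from a quadratic fit of log p against
the published critical values; beyond it, `ad_null_grid()` simulates the
null once for the relevant sample sizes and interpolates log p
piecewise-linearly (log-linear extrapolation past the grid). The
statistic implementation agrees with an independent reference to ten
digits, including ties.

"Strong" perturbations have ≥50 AD DEGs at q<0.05, ≥25 quality-filtered
cells and ≥30% on-target knockdown when the target is measured (an
undetected target passes — removing apparently non-functional guides
without penalizing genes absent from the matrix); "weak" shares the
gates with <5 DEGs.

## Profiles, clustering, embedding

Strong perturbations are summarized as pseudobulk mean-z profiles over a
feature set that unions each perturbation's top-10 DEGs (by AD
statistic) with all genes of mean >0.25 UMI/cell in the top 30% of
variance. The target gene's own value is set to 0 — the control mean —
so the direct knockdown cannot dominate similarity. Correlation is the
comparison metric because it is scale-invariant: related perturbations
often differ in magnitude but not direction.

`cluster_items()` implements hierarchical density-based clustering with
noise from a precomputed distance matrix: core distances at
`min_samples`, mutual-reachability single linkage, condensation at
`min_cluster_size`, and excess-of-mass or leaf selection. Defaults are
(4, 1, eom) for perturbations and (10, 10, leaf) for gene programs. The
method is deliberately conservative — unassigned items are noise (−1) —
and one degenerate case is handled explicitly: if the hierarchy never
splits into two min-size children (e.g. all items identical), everything
is returned as a single cluster rather than all-noise.

For embedding, each profile is centered and scaled to unit norm, which
turns Euclidean distance into correlation distance exactly
(‖x̂−ŷ‖² = 2(1−r), verified to 1e-10). `embed_vectors()` then builds a
k-nearest-neighbor graph (k = 7), initializes from the spectral layout
of its normalized Laplacian (principal components above 1,500 items,
where dense eigendecomposition becomes the bottleneck), and refines with
attractive forces on neighbor pairs and repulsive forces on a
deterministic sample of non-neighbors (5 per attractive pair). The
optimizer is pluggable by design; the contract is neighbor preservation,
same-seed reproducibility, and coincident coordinates for identical
inputs (duplicates are embedded once and copied), not bit-compatibility
with any particular solver. Gene-program clustering runs on a 20-D
embedding of the transposed profile matrix by default — clustering the
raw gene vectors directly is exposed too, but the embedding equalizes
program size and dynamic range and yields more clusters.

## Composite phenotypes

Total RNA content is the per-cell total UMI count z-scored against
gemgroup controls (the same standardization machinery as gene scores).
Mitochondrial fraction divides the 13 mitochondrially encoded
protein-coding genes' UMIs by the cell total; TE fraction does the same
for transposable-element metagenes (raw totals in the denominator — the
depth-factor adjustment cancels in a within-cell ratio). Splicing is
quantified at the pseudobulk level (single-cell unspliced fractions are
too sparse): per perturbation and gene, unspliced/(unspliced+spliced),
divided by the mean control fraction, so the pooled control sits at 1 by
construction; genes with zero control unspliced reads are excluded and
only the common quantifiable gene set is reported. Cell-cycle phases
come from a 2-D neighbor-graph embedding of a cell-cycle gene subset
with polygon gates; gates ship as editable configuration because any
fixed gate is data-dependent — the package derives sensible defaults
from synthetic phase clusters but treats them as user input.

## Leverage scores

Within each gemgroup, the clipped z-matrix (genes with mean >0.25
UMI/cell) is decomposed by truncated SVD (k = 20) and each cell's raw
leverage score is the squared norm of its row of the top-k left singular
vectors, normalized to sum to 1 per gemgroup — the leverage sampling
distribution. Scores are then logged and z-scored against control cells
so gemgroups pool. Zero raw scores (possible in degenerate rank cases)
are floored at a tenth of the smallest positive score before the log.
Mean scores track phenotype strength; the per-perturbation SD is the
penetrance/heterogeneity metric, ranked against a lowess fit of SD on
log DEG count (span 0.3 — lowess needs a span wide enough to be stable
at a few hundred points but narrow enough to follow the trend; the value
is exposed). Raw scores are invariant to orthogonal rotations of gene
space and match dense-SVD squared row norms to 1e-8 in tests.

## Copy-number inference and CIN

Genes above 0.05 mean UMI/cell are CPM-normalized, log-transformed, and
expressed as residuals against the control-cell average, clipped at ±3.
Residuals are ordered by genomic position and smoothed with a rolling
window of 100 genes per chromosome; near chromosome ends the window
slides inward instead of shrinking, so noise stays uniform along the
chromosome (shrinking edge windows inflate variance exactly where the
>80%-of-length rule is most sensitive). After per-cell median centering,
values within 1.5 control SDs per window position are zeroed — the SD is
estimated robustly (MAD) because a few outlier control cells otherwise
widen the band enough to mask true lesions — and a running median
(length 5, exposed) removes isolated spikes. TE metagenes have no
genomic position and the mitochondrial contig is not a chromosome-scale
CNV target; both are excluded. A cell is karyotypically unstable when
any chromosome has nonzero values over >80% of its gene-extent-weighted
length; direction is gain/loss when ≥80% of the nonzero weight shares a
sign. The CIN score is the perturbation mean of per-cell sums of squared
CNV values, z-normalized against control pseudo-perturbations.

## The synthetic-data generator

`sim_config()`/`generate_dataset()` emulate the statistical structure the
pipeline must handle: negative-binomial UMI counts (gamma–Poisson with a
single shared dispersion, 0.2 — the accepted single-cell default in the
absence of gene-specific estimates) with lognormal gene baselines
(meanlog −1.3, sdlog 1.4, chosen so the 0.25/0.5/1 UMI expression floors
partition the gene universe realistically), per-gemgroup depth factors,
13 mitochondrial-class genes on a dedicated contig at ~12% of UMIs,
TE metagenes, optional spliced/unspliced layers, on-target knockdown as
a multiplicative mean effect in affected cells, effect-gene shifts
specified in control-SD units (converted to mean multipliers
1 + s·σ/μ so z-space consequences match the normalization's scale),
incomplete penetrance, guide counts as Poisson background plus lognormal
signal (mean ~100 reads), lentiviral-recombination multiplets, and
chromosome-scale copy-ratio lesions. Defaults describe a two-gemgroup,
~5%-non-targeting screen with 85% median knockdown and 5000–6500 mean
UMIs. One seed drives everything; output is byte-identical under a
fixed seed.

What it does **not** emulate: transcriptome-wide co-expression structure
(genes are conditionally independent given the programmed effects),
ambient RNA, doublet transcriptomes, empirical dropout beyond the NB
model, or cell-cycle structure beyond optional programmed phase shifts.
Tests passing on this generator therefore demonstrate correctness of
the algorithms under the stated statistical model, not robustness to
every artifact of real libraries.

## Problem sizes and numerical choices in the test suite

The suite and the acceptance script run everything at desk scale, chosen
to be the smallest sizes at which each property is statistically
meaningful: 600–1,000-cell datasets for normalization, knockdown
recovery and guide calling; 200 null pseudo-perturbations × 1,000
permutations for calibration; 50 replicates for power and for the
penetrance pairing; and a 5,000-cell, 20-perturbation dataset for
end-to-end determinism. Copy-number scenarios use 1,200 genes over five
chromosomes (~240 per chromosome, comparable to the per-chromosome
density of expressed human genes) and deeply covered cells (20,000 mean
UMIs): expression-based CNV inference is depth-limited, because on the
log scale zero counts dominate per-gene residual noise, and the
100-gene window only suppresses that noise as √window.

Other numerical conventions: QC bounds are inclusive; clipping is
one-sided at +10 (only induction produces extreme z under control
anchoring); BH is the standard step-up with NA propagation; permutation
p-values are add-one; all stochastic steps take explicit seeds and the
pipeline derives per-stage seeds from one global seed.

## Known limitations

Core-control selection needs ≥2 control constructs with ≥10 cells each,
and its all-pairs cost grows quadratically in constructs. The AD
Monte-Carlo grid treats group sizes as fixed at their medians, an
approximation that is good for the standardized statistic but not exact.
The embedding optimizer is a compact gradient scheme adequate for
hundreds-to-thousands of items, not a tuned large-scale solver. CNV
inference reports relative, control-anchored copy ratios — a lesion
present in the controls themselves would be invisible — and calls whole
chromosomes, not focal events.
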