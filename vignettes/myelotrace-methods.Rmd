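---
title: "Methods: models, conventions and design choices in myelotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in myelotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`myelotrace` re-implements, as a reusable and fully tested workflow, a
multi-tissue single-cell analysis of myeloid responses to traumatic
brain injury (TBI) in mouse: blood, cortex and hippocampus atlases
sampled at 24 h and 7 days after injury or sham treatment. The package
covers per-tissue preprocessing, subgroup composition dynamics, a
branching-pseudotime model over monocytes, macrophages and microglia,
branch-dependent gene subgroups with over-representation analysis,
per-cell pathway activity scoring, a five-criteria ligand–receptor
screen, and 2^−ΔΔCt qPCR analysis. Subgroup labels are an *input*
(taken from metadata); de-novo clustering, UMAP visualization and
batch integration are deliberately out of scope. A synthetic-data
generator with known ground truth makes every stage testable offline.

# Preprocessing

**Quality control.** Per cell we compute detected genes (count > 0),
total counts and mitochondrial fraction; mitochondrial genes are
recognized by the mouse `mt-` symbol prefix (case-insensitive,
configurable regex). The default filter retains a cell iff
200 ≤ detected ≤ 6,000 and mito fraction ≤ 10%. The boundary is
**inclusive** because the exclusion rule is phrased with strict
inequalities (fewer than 200, more than 6,000, more than 10%); this is
pinned by tests. Filtering is idempotent, and a filter that removes
every cell is an error rather than an empty success. Cells with zero
total counts get a defined mitochondrial fraction of 0 with a warning.

**Normalization.** Counts are depth-normalized to a fixed
pseudo-depth and log-transformed: value = ln(1 + count/total × 10⁴),
natural log. Zeros stay zero and the transform is invariant to
rescaling all counts in a cell.

**Variable genes.** The vst-style recipe: fit a loess trend (span
0.3, degree 2) of log10 variance on log10 mean of the *raw* counts,
standardize each gene's counts by the trend-predicted sd, clip
standardized values at √N (N = number of cells), and rank genes by
the variance of the clipped values. For tiny fixtures where a loess
fit is unstable (fewer than 20 positive-variance genes or fewer than
10 distinct means) a quadratic polynomial trend substitutes. Two
caveats worth knowing: clipping intentionally discounts genes whose
variance comes from one or two extreme cells, and at desk-scale gene
counts (hundreds rather than tens of thousands) a local trend can
partially absorb a cluster of co-located overdispersed genes. The
test suite therefore validates recovery on *bimodal* marker genes,
which is the use the pipeline puts the ranking to.

**PCA.** Selected genes are z-scored per gene with |z| clipped at 10,
then decomposed by exact SVD (the matrices here are desk-scale, so no
randomized solver is needed). Components are ordered by decreasing
singular value, and each component's sign is fixed by making its
largest-magnitude loading positive — this removes the SVD sign
ambiguity, so identical input gives an identical embedding. The
number of components (default 30, 10 in the pipeline's synthetic
default) is a config choice; no value is canonical.

# Composition dynamics

`subgroup_proportions()` tallies cells per subgroup within each
grouping (tissue, or tissue × condition × timepoint) and reports
percentages of the grouping denominator, rounded **half-up to two
decimals** — the precision convention of the printed atlas
compositions the package reproduces. Proportions are pooled over mice
within a grouping, matching how atlas-level percentages are printed;
a per-mouse analysis can be performed by grouping on `mouse`.
`restricted_fractions()` switches the denominator to a subgroup
family — e.g. activated microglia among all microglia, aMG/(MG+aMG),
or Treml4⁺ among all monocytes. `condition_contrast()` reports signed
percentage-point differences (TBI − Sham) per timepoint and attaches
no inferential statistics: these contrasts are descriptive.

# The trajectory model

The published analysis used a reversed-graph-embedding trajectory
tool. Re-implementing that estimator is out of scope; `myelotrace`
instead fits a transparent surrogate that preserves the observable
contract — a small number of states, a root anchored in monocytes,
a pseudotime ordering, and branch-dependent genes:

1. k-means with `k_centroids` centers (default 25, fixed internal
   seed, 10 restarts) summarizes the 2-D embedding;
2. a minimum spanning tree (Prim's algorithm; verified against
   exhaustive spanning-tree enumeration for ≤ 6 nodes) joins the
   centroids;
3. short pendant segments of at most `min_spur_centroids` (default 2)
   centroids are pruned as over-clustering noise, their cells
   reassigned to the nearest surviving centroid; the root-richest leaf
   is never pruned;
4. the root is the degree-1 node whose cells are richest in the
   `root_rule` subgroup; ties go to the leaf holding *more* root
   cells, then to the lower centroid id (a pure-monocyte stub with a
   handful of cells should not outrank the true monocyte terminus);
5. states are maximal unbranched segments: a new state starts at each
   branch point (degree ≥ 3), so a Y-shaped tree has three states and
   a path has one;
6. pseudotime is the geodesic tree distance from the root to the
   cell's orthogonal projection onto the nearest centroid's best
   incident edge, clamped to the edge — non-negative, zero at the
   root.

Branch-dependent genes are found by per-gene one-way equal-variance
ANOVA of normalized expression across states (vectorized, validated
against `aov`), BH-adjusted, significant at adjusted p < 0.05.
Significant genes are clustered on their row-standardized state-mean
profiles by Ward-linkage hierarchical clustering cut at k = 6 — the
six expression subgroups the downstream screen consumes. Subgroup ids
are renumbered in dendrogram order and the profile matrix is sorted by
gene name first, so the partition is deterministic and invariant to
input order. When fitting a joint trajectory across tissues, the gene
universe is intersected first.

# Enrichment and pathway activity

**Over-representation.** For each gene set (intersected with the
universe), the upper-tail hypergeometric probability
P(X ≥ overlap), BH-adjusted across sets, significant at adjusted
p < 0.05. The universe defaults to all genes in the atlas (the
expressed-gene alternative is a config choice). The implementation
uses the exact distribution function; tests compare it against
brute-force enumeration of all possible query draws for universes up
to 25 genes.

**Pathway activity.** A single-sample, rank-based running-sum score
of the ssGSEA/GSVA family, *not* the kernel-CDF estimator of the
original GSVA publication (the original tool is named in the source
analysis without parameters; the surrogate preserves the tested
contract — group-wise activity differences). Per cell, genes are
ranked by expression (ties broken by stable gene order); the walk
steps up by rankᵗ/Σ(member ranksᵗ) at member genes (τ = 1) and down
by 1/(n − m) elsewhere; the score is max + min of the running sum,
which lies in [−1, 1]. Because the statistic is rank-based it is
invariant to any monotone per-cell transform — "log2 input" is a
convention, not a requirement. One honest caveat, pinned in tests:
with τ = 1 the score of a *random* gene set has a positive location
offset (large-rank up-steps come early); the score is therefore
interpreted comparatively between cell groups, never as an absolute
activation level. Group comparisons use Student's t-test on the raw
p-value at 0.05 by default — mirroring the source analysis, which
applied no multiplicity correction at this step — with an optional BH
flag.

# The ligand–receptor screen

A candidate ordered pair (A → B) over the branch-gene subgroup map is
retained iff all five predicates hold: (1) A in gene subgroup 1, 2, 3
or 6; (2) A annotated "secreted"; (3) B in subgroup 4 or 5; (4) B
annotated "plasma membrane"; (5) an undirected protein–protein
interaction record links A and B. Interpretation choices, made
explicit because the source leaves them open: the subgroups are the
six branch-gene subgroups of the trajectory step (the only 1–6
numbering in the analysis); the direction is fixed
microglia → monocyte/macrophage with no reverse screen; self-pairs
are excluded; and a gene annotated both secreted and membrane is
rejected at input validation. In the orchestrated pipeline the
ligand-eligible subgroup ids are those whose mean profile peaks in
the microglial states and the receptor-eligible ids those peaking in
the monocyte/macrophage root state, which reproduces the numbering
convention without hard-coding cluster labels. The screen records the
predicate outcomes of every candidate satisfying at least four
predicates as an audit trail, and the tests hold it equal to a
brute-force conjunction oracle on randomized fixtures.

Differential-expression annotation of surviving pairs follows the
source analysis: per (gene, subgroup, timepoint), a two-sided
Student's t-test of log-normalized per-cell expression, TBI vs Sham,
with star labels at strict thresholds (* < 0.05, ** < 0.01,
*** < 0.001; 0.05 exactly earns no star). Per-cell tests treat cells
as replicates and therefore pseudoreplicate; a per-mouse pseudobulk
mode (`pseudobulk = TRUE`) is provided for robustness. Sidedness is
never stated in the source; two-sided is the conservative default
throughout.

# qPCR analysis

Technical replicates are averaged per biological replicate and gene;
ΔCt = Ct_target − Ct_reference per biological replicate;
ΔΔCt = ΔCt − mean(control ΔCt); fold change per replicate is 2^−ΔΔCt.
The reported fold change is the mean across treated biological
replicates with its SD on the fold-change scale (matching the
mean ± SD presentation of the validation table; a log-scale SD is
available by flag). The p-value comes from a Student's t-test on the
ΔCt values — the log-scale measurement, standard practice where the
source is ambiguous — with BH adjustment across target genes. Exact
invariances pinned by tests: a global Ct shift changes nothing,
swapping group labels inverts the fold change, ΔΔCt = 0 gives fold
change 1 exactly.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the
emulated study conditions. Counts are negative binomial with a common
dispersion (φ = 0.4; variance μ + φμ²) and log-normal library-size
factors; per-gene baselines are log-normal around `baseline_mean`
with the named study genes (Ccl2, Ccl7, Tnf, Grn, Ccr2, Tnfrsf1b,
Flna) held at a stable moderate baseline, since the study reports
them as robustly expressed in myeloid cells and a near-silent gene
cannot carry a planted effect. Marker elevations and
condition × timepoint effects act multiplicatively (2^log2fc) on the
mean. The default design: the full subgroup roster per tissue
(8 blood, 13 cortex, 17 hippocampus subgroups); chemokine effects
(Ccl2, Ccl7, Tnf, +1.5 log2) in CNS microglia at 24 h and Grn
(+1.2 log2) at 7 d; receptor effects (Ccr2, Tnfrsf1b at 24 h, Flna at
7 d) in blood monocytes; and a doubled activated-microglia,
macrophage and Treml4⁺-monocyte compartment at TBI 24 h. Per-group
cell numbers are a config knob (default 30 per
subgroup × condition × timepoint; the original per-mouse counts are
not published), and mice are assigned round-robin within groups
(3 per condition × timepoint).

Trajectory data places cells uniformly along the segments of a
rooted tree in a 2-D latent space with isotropic Gaussian noise
(sd 0.3 against segment lengths of ~5), the monocyte label on the
root segment, and six gene programs with pairwise-distinct activity
patterns over the three states. qPCR plates draw Gaussian Ct noise
(sd 0.2 cycles) per well around design values, with a per-sample
random intercept shared by reference and targets so it cancels in
ΔCt. PPI tables contain the designed true pairs plus random decoy
edges drawn from genes outside them; the screen's test fixtures
additionally construct decoy *candidates* engineered to fail exactly
one named criterion each, so a screen defect localizes to the
criterion it breaks.

All randomness flows from one seed: each generator call re-seeds R's
default Mersenne-Twister stream with a documented per-generator
offset, so a fixed seed gives bit-identical output regardless of call
order, and the pipeline's md5 manifest is reproducible end to end.

What the generator does **not** emulate: doublets, ambient RNA,
batch effects, droplet-level technical structure, realistic gene–gene
correlation, or amplification-efficiency drift in qPCR. Passing
tests therefore demonstrate correctness of the algorithms under the
declared generative model, not robustness to every artifact of real
10x data.

# Problem sizes and numerical conventions

The test suite and the acceptance script run the generator at
deliberately desk-scale sizes — ~60 cells per
subgroup × condition × timepoint (~8,000 cells across three tissues),
150–400 genes, 450-cell trajectories, 50–100 seeded qPCR plates —
sizes at which every planted effect is comfortably detectable and the
whole suite runs in well under a minute. Key conventions collected in
one place: half-up rounding for printed percentages; inclusive QC
boundaries; strict star thresholds; two-sided tests everywhere;
zero-variance t-tests resolve to p = 1 (equal means) or the p = 0
limit with a warning (unequal); BH clipped at 1 and order-preserving;
k-means and the embedding's SVD sign convention pinned for
determinism; MST ties resolved by Prim's scan order (exact ties have
measure zero in continuous embeddings).

# Known limitations

The trajectory surrogate recovers tree *topology and ordering*, not
the curved geometry a reversed-graph-embedding method estimates, and
its state count depends on the spur-pruning threshold at very noisy
embeddings. The pathway score is comparative, not absolute. Per-cell
DE tests overstate confidence relative to per-mouse pseudobulk (both
are provided). The composition module reproduces pooled printed
percentages; it does not model per-mouse variability.
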