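---
title: "Quantifying 3D co-localization of TF binding sites: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D co-localization of TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tf3dnet)
```

# The problem

Chromosome folding places transcription-factor (TF) binding sites that
are distant in sequence next to each other in space. `tf3dnet` measures
that spatial co-localization at two levels of description: population
Hi-C contact maps, where co-localization appears as contact enrichment
above the distance-decay expectation, and single-cell genome structures,
where it appears as sites sharing a spatial neighborhood across all
coordinate models of a cell. From either measure the package derives
per-site scores, per-TF-pair enrichment, significance calls against
permutation nulls, and TF proximity sub-networks.

# Contact-based scores

## Expected profile and filters

Only intra-chromosomal contacts are used. The expected contact at
separation $s$ (in bins) is the empirical mean of normalized contacts
over all retained bin pairs at that separation on the chromosome,
counting zeros — not a fitted curve — so the observed/expected ratio is
exactly 1 on average by construction. Three filters precede scoring,
all with strict inequalities read literally from their stated rules:

* bins whose total raw reads fall strictly below one third of the
  per-chromosome median (over bins with nonzero totals) are masked;
* the diagonal and five 5-kb bins (25 kb) either side are never
  consumed;
* a locus pair must carry strictly more than 20 raw reads, evaluated on
  the merged window (the rule's scope per base pair vs merged window is
  not fixed by its source; `ccl_config(raw_filter_scope =)` exposes the
  choice).

## Adaptive bin merging

Distal 5-kb bins hold very few reads, so bins are merged to 25 kb when
loci are more than 100 kb apart, and to 55 kb beyond 1 Mb. Merged
windows are centered on each locus's base bin — centering minimizes
positional bias, since the rule's source does not specify alignment —
and the expected value of a merged window is the sum of base-resolution
expected values over the window's separation offsets, which keeps
observed/expected scale-consistent across merge levels (a flat map
scores exactly 1 at every level). Separation is measured between base
bin indices, making the score a pure function of the bin pair; windows
that run off the chromosome or touch a masked bin invalidate the pair.

## CCL scores

The homotypic score of a site $i$ is
$\mathrm{CCL}_i = \sum_j \ln(\mathrm{Obs}_{ij}/\mathrm{Exp}_{ij})$ over
ChIP-seq-identified sites $j$ of the same TF on the chromosome;
heterotypic scores run a TF's sites against another TF's bound sites
and are directional; integrated scores add heterotypic scores over a
partner group. The natural log is used for all variants for internal
consistency. Numerical edge cases: a pair whose observed contact is
zero against a positive expectation contributes nothing and is counted
in a skip diagnostic rather than propagating $-\infty$; zero expected
values likewise skip the pair; pairs falling in the same base bin are
never consumed, which also removes self-pairs. Query loci default to
all putative sites (with a `query = "bound"` switch, since the
pairing rule's source alternates between both readings).

# Permutation nulls and pair calling

The null for direction $A \to B$ permutes the binding sites of all
panel TFs except $B$ within each chromosome (optionally within
sub-compartment × chromosome strata), preserving every TF's
per-stratum site count; $B$ stays fixed. Because the pooled site
positions never change, the package scores each position against $B$
once and treats a permutation as a random per-stratum reassignment of
labels, which makes thousands of permutations cheap without changing
the statistic.

Observed counts of sites above the pooled-null top 20/10/5% cutoffs
are compared with per-permutation counts. The reported p-value is the
smoothed estimator $(1+b)/(1+n_\mathrm{perm})$. This estimator is
valid but conservative for a discrete count statistic with heavy ties;
its null distribution is *not* exactly uniform, which matters only
when the p-values themselves are the object of study. For such
calibration diagnostics the package also offers the standard
randomized (PIT) variant, which breaks ties uniformly and is exactly
uniform under the null; the conservative variant remains the default
for inference. Benjamini–Hochberg correction is applied across pairs
separately per fraction, and a pair is significant only when both of
its directions pass; how the three fractions combine into one
per-direction decision is not fixed by the method's source, so it is a
configuration enum (`any` — the default — `all`, or a single
fraction).

The CE score is a signed Kullback–Leibler divergence between observed
and pooled-null score histograms on unit-width bins (natural log, sign
from the median shift, ties signed positive — the magnitude is then
near zero anyway). When an observed bin has zero null probability, one
pseudo-observation is added to every null bin before normalization;
histograms pool sites genome-wide. Sub-networks come from hierarchical
clustering of $d(A,B) = e^{-(CE_{AB}+CE_{BA})/2}$ (Ward's method by
default, average linkage and squared-Euclidean row distance as
alternatives). The dynamic cut is implemented as a height scan: among
cluster counts whose smallest cluster reaches the minimum size
(default 3), the cut maximizing mean silhouette width wins, with a
plain $k=2$ fallback — a deliberate simplification of tree-shape-based
dynamic cuts, defensible because the clustering outcome is robust
across methods in this setting.

# Structure-based scores

Structures are strings of 100-kb particles with about ten alternative
coordinate models per cell. Model units are arbitrary, so the particle
radius is estimated per structure as half the median sequential
inter-particle distance (the repulsive radius of such models
corresponds to half the ideal sequential separation); this convention
is the package's own. QC superposes every model onto the first by
rigid-body least squares (superposition is required for RMSD between
free-floating models to mean anything) and keeps particles whose
across-model RMSD — the square root of summed per-coordinate sample
variances, $\sqrt{\sum_m \lVert x_m - \bar x\rVert^2 / (M-1)}$ — stays
below one radius.

Proximity is demanded in *every* model (within 1.5, 2 or 3 radii), and
pairs closer than four particles in sequence (300 kb) are discarded to
suppress trivial linear clustering. Spatial density uses inverse-cube
distance weighting, computed per model and then averaged (averaging
stabilizes against single-model noise; the aggregation order is the
package's choice). SDE compares the density with circular permutations
of the site track — independent random offsets per chromosome,
separately within A and B compartments, preserving sequential
clustering and compartment composition. The printed orientation is
$\log_2(r^0_i/r_i)$, under which planted hubs score *negative*; since
the score's verbal description ("enrichment of observed density") and
its printed formula disagree in their source, both orientations are
exposed (`orientation = "as_printed"` default, `"enrichment"` for
$\log_2(r_i/r^0_i)$). Z-normalization standardizes on the quartile of
particles with the lowest sequential site density, where values are
closest to a random background.

PE counts consistently proximal site pairs between two TFs (unordered
within-set pairs for the homotypic diagonal) against permutations that
shuffle all site-particle assignments within chromosome × compartment ×
crowding-stratum cells; crowding is the number of sites of any TF on
consistently proximal particles, split into five equal rank groups per
compartment (remainder to the lowest groups, ties by site order). The
enrichment log base is not stated for PE in its source; base 2 is used
to match the explicitly base-2 SDE, with a `log_base` switch. One
shared set of permuted configurations is evaluated for all TF pairs of
a matrix, which mirrors how a single control set serves all
combinations and keeps the cost linear in permutations.

# The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
with planted, known signal:

* **Contact maps** decay as $c\,s^{-\alpha}$ (default $\alpha = 1$,
  $c = 300$ at 5-kb bins — chosen so that merged windows at the
  separations the filters admit typically clear the 20-read rule, as
  deep Hi-C maps do) with multiplicative log-normal noise
  ($\sigma = 0.3$, a stand-in chosen for heavy-tail realism; no
  generative model is prescribed by the method's source) and Poisson
  raw counts. Planted TF pairs multiply the baseline at their site
  bin-pairs by a factor $f \ge 1$. Planting must stay sparse: the
  expected profile is empirical, so if planted pairs cover a large
  fraction of all bin pairs the profile absorbs the signal — a real
  property of observed/expected scoring, and the reason recovery
  experiments use long chromosomes, modest site counts and unenriched
  background TFs in the panel.
* **Structures** are off-lattice random walks with step length twice
  the particle radius, no excluded volume (sufficient for
  distance-based statistics), alternating A/B blocks, and ten models
  produced by random rigid motion plus coordinate jitter of 0.2 radii
  (below the 0.5-radius level at which model-consistency filters would
  start to fire). Planted spatial hubs relocate sequentially spread
  particles into a sphere of 1.2 radii — at most half the 3-radius
  proximity threshold, so in-sphere pairs are mutually proximal; a
  naive sphere around a walk point would capture mostly sequential
  neighbors, which the 300-kb exclusion then discards.
* **Occupancy data** lay out promoter/enhancer cassettes (TSS with
  H3K4me3/H3K27ac, strong promoters additionally with H3K36me3
  overlapping the TSS ±1-kb window by ≥300 bp; chromatin-state
  enhancers with H3K4me1 and H3K27ac or H3K27me3), DHS at cassettes
  plus random background, ambiguous and methylated decoy regions, and
  putative motif sites inside DHS, bound with a configurable
  probability (optionally modulated per site to plant
  occupancy–score correlation).

All draws flow from one seed; identical specifications reproduce
bit-identical outputs. What the generator does **not** emulate: TADs
and loops, polymer physics, sequence-level motifs, mappability
structure, and trans-contact decay. Tests passing on these data show
the estimators implement their definitions and recover planted signal
under the stated noise; they do not certify performance on real Hi-C
biases the generator omits.

# Problem sizes and determinism

The shipped checks use desk-scale conditions chosen to keep the full
suite in the minutes range while leaving enough statistical room: null
calibration runs 50 replicates of a 10-TF panel (60 sites per TF on a
6-Mb chromosome) at 200 permutations; contact-based group recovery uses
two planted groups of 8 TFs at enrichment 3 plus 8 background TFs, 40
sites each on 12 Mb; structure-based recovery uses two planted hubs of
8 TFs, 60 sites each, on two 8-Mb chromosomes at 100 permutations. The
reference analyses behind the method run at 1000 permutations on
genome-scale data; every permutation count here is a parameter, not a
constant. All stochastic steps take explicit seeds and restore the
caller's RNG state.

# Known limitations

* The dynamic-tree cut is a silhouette-based height scan, not the full
  hybrid tree-cut algorithm.
* The sign of CE rests on a median comparison and becomes unstable
  when a large fraction of the TF panel shares enrichment with the
  fixed partner (the permutation pool is then itself enriched); panels
  should contain unenriched TFs, as real panels do.
* Trans-contact CCL is out of scope (cis contacts only); structure PE
  offers the trans mode instead.
* No boundary correction is applied near the modelled nuclear surface
  for large distance thresholds; thresholds above 3 radii should be
  avoided.
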