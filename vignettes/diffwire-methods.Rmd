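---
title: "Differential wiring analysis of weighted co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential wiring analysis of weighted co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffwire)
```

## The problem

Two patient cohorts — say tumors that later progressed and tumors that did
not — can differ in ways that single-gene statistics miss. Beyond a shift in
a gene's mean expression (differential expression, DE) or a change in its
variance (differential variability, DV), the *co-expression* of a gene with
the rest of the transcriptome can change while its marginal distribution
stays put. We call this third mode differential wiring (DW). diffwire
implements a complete two-condition weighted co-expression workflow around
these three measures: condition-specific network inference, consensus
modules, permutation-based module preservation, per-gene DE/DV/DW calls with
a binomial changed-edge null, module-level enrichment of affected genes,
differentially wired hub identification, and module–trait association. A
synthetic-data generator with planted ground truth closes the loop, so every
stage has a recovery test.

## The model, stage by stage

**Preprocessing.** Input is a gene × sample matrix of nonnegative
normalized counts. Values are transformed as log2(x + 1); genes on a
user-supplied exclusion list and genes with variance at or below a floor
(default 0, i.e. strictly constant genes) are removed; samples are screened
by their inter-array correlation (IAC, the mean Pearson correlation with all
other samples), with a flag threshold of 0.65. Flagged samples are reported,
not dropped, unless dropping is requested — an outlier decision belongs to
the analyst.

**Condition networks.** For each condition separately, the biweight
midcorrelation (median/MAD centring, Tukey bisquare weights with tuning
constant 9) is computed between all gene pairs; genes with zero MAD fall
back to Pearson standardization with a warning. The unsigned adjacency is
|cor|^β, with β chosen per condition as the smallest candidate (1..20)
whose connectivity distribution reaches a signed scale-free fit R² of 0.80.
The fit bins connectivity into 10 equal-width bins, drops empty bins, and
regresses log10(frequency) on log10(mean k); the sign requires a negative
slope. Equal-width (not equal-count) bins are essential: quantile bins make
every bin frequency identical and the regression degenerate.

**One universe.** The two condition networks are restricted to a single
shared gene universe: genes are ranked by the mean of their two condition
connectivities and the top 50% are kept. Ranking by the mean (rather than
filtering each network separately) guarantees the two networks — and the
consensus and DW stages downstream — share one gene set.

**TOM and modules.** Adjacency is transformed to the unsigned topological
overlap measure, TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij) with
ℓ_ij the shared-neighbour sum, and genes are clustered by average linkage on
1 − TOM. Branches are extracted by a dynamic tree-cut variant described
under *Numerical choices*; branches smaller than the minimum module size
(default 30) fall to the reserved "unassigned" (gray) pseudo-module, and
modules are named M1, M2, ... by decreasing size.

**Consensus.** The consensus similarity is the entrywise minimum of the two
condition TOMs, so a high consensus value demands strong topological overlap
in *both* conditions. The same clustering procedure applied to the consensus
yields consensus modules; modules whose eigengenes correlate above 0.8 (in
the reference condition) are merged iteratively, closest pair first, with
eigengenes recomputed after each merge. An optional 95th-percentile ratio
scaling of the second TOM is available for the case where unequal β values
leave the two TOMs on visibly different scales; it is off by default.

**Eigengenes and membership.** A module eigengene (ME) is the first
principal component of the module's standardized expression submatrix over
one condition's samples, unit norm, with its sign fixed to correlate
nonnegatively with the module's mean profile. Membership is kME(g, m) =
cor(x_g, ME_m); intramodular connectivity kIM(g) is the sum of g's
adjacencies to its own module's other genes. On coherent modules kME and kIM
rank genes almost identically (Pearson r > 0.9 in the reference simulation).

**Preservation.** Whether a reference-condition module is more than a random
gene set — in its own network (quality) or in the other condition's network
(preservation) — is judged by permutation: `n_perm` (default 200) random
gene sets of the module's size drawn from the universe provide a null for a
density statistic (mean off-diagonal adjacency) and a connectivity statistic
(correlation of kIM computed in the reference vs the test network).
z_summary is the mean of the two Z scores and is read on the conventional
bands: below 2 no evidence, 2–10 moderate-to-high, above 10 high.

**Differential network analysis.** DE uses the moderated t of limma
(empirical-Bayes variance shrinkage), signed condition 2 − condition 1, with
Benjamini–Hochberg adjustment and a 0.05 flag threshold. DV is the classical
two-variance F test per gene (two-sided, BH, 0.05). DW compares every gene
pair's Pearson correlations across conditions by Fisher's r-to-z,
z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)); an edge is changed at
p < 0.01. Each gene's changed-edge count n_i is then tested against
Binomial(N − 1, r), where r is the global changed-edge rate, with the
inclusive upper tail P(X ≥ n_i); genes at p < 0.01 are flagged DW. Trials
are N − 1, not N: a gene has N − 1 potential edges. Modules are tested for
enrichment of each affected class by a one-sided Fisher's exact test,
Bonferroni-corrected by the number of proper modules. DW hubs are DW-flagged
genes with kME above 0.8 in the reference condition, reported sorted by kME.
A DW gene left unassigned by the consensus clustering — which is exactly
what happens to a strongly rewired gene, since the minimum suppresses
membership that holds in only one condition — is judged by the module it
correlates with most strongly in the reference condition.

**Traits and gene sets.** Gene significance is |cor(x_i, trait)| over
samples with a non-missing trait value; module–trait association is the
Pearson correlation of the eigengene with the trait, with a two-sided p from
the t transform on n − 2 degrees of freedom, reported unadjusted (a BH
column is appended). Over-representation of GMT gene sets in modules uses
the binomial tail P(X ≥ k) with X ~ Binomial(module size, set share of the
universe), BH-adjusted within each module; a hypergeometric option exists.

## The synthetic generator

`generate_dataset()` draws, for each module m and condition c, an eigengene
vector E_{m,c} ~ N(0, I) *independently per condition* — module
co-membership, not eigengene identity, is what the consensus stage should
recover. Gene g with loading u_g has latent expression
x = u_g E + ε, ε ~ N(0, 1 − u_g²), so cor(x, E) = u_g by construction.
Loadings follow a fixed profile per module: the top 20% of genes (the hubs)
draw from `hub_loading_range` (default 0.85–0.95, matching the kME range
reported for real differentially wired hub genes); the remainder decays
linearly from 0.75 to the background upper bound (default 0.40). The gap
around 0.8 makes hub status well-defined at the kME > 0.8 threshold.
Background genes are pure noise.

Planted signal: DW genes (default 10, drawn from hubs) keep their
condition-1 wiring and lose it in condition 2 — by default the loading is
zeroed (`dw_mode = "zero"`); the alternative `"reassign"` moves it to
another module's eigengene, which additionally rewires the receiving
module's genes in ways the truth labels do not record, so zeroing is the
default for unambiguous recovery scoring. DE genes (default 30, log2 shift
1.0) are drawn from non-hub module genes: a mean shift leaves correlations
untouched, and module genes survive the connectivity filter so the planted
signal remains visible to the pipeline. DV genes (default 30, variance scale
4) are drawn from background genes, where total variance is residual
variance and the planted F ratio equals `dv_scale` exactly; on a module gene
the unscaled eigengene share would attenuate the ratio and blur what
"planted DV" means. Each gene carries at most one label.

Traits equal the driver module's condition-specific eigengene plus N(0,
0.5²) noise, with 20% of entries missing. Latent values map to counts via
2^(x + b_g + 8) − 1, where b_g is a per-gene baseline ~ N(0, 2.5²)
truncated at ±2 SD: real expression spans orders of magnitude across genes,
and it is this baseline spread that makes IAC values high (≈0.8–0.9 here)
as they are on real arrays. The offset of 8 keeps even low-baseline genes
clear of the zero floor, so log2(count + 1) recovers x + b_g + 8 exactly
(up to a handful of clipped entries in a million).

What the generator does *not* emulate: negative-binomial count noise and
library-size effects, batch structure, covariate-driven subgroups (e.g.
HPV status), and correlated trait missingness. Passing recovery tests on
this generator therefore demonstrates the pipeline's statistical machinery,
not robustness to those real-data complications.

## Numerical choices

* **Tree cut.** A flat cut of the average-linkage dendrogram cannot
  separate modules here: between-module joins accumulate gradually just
  under the dendrogram ceiling (heights 0.98–0.995 at the default scale),
  below any usable static cut, while a cut low enough to separate them
  would shred weakly attached members. `detect_modules()` therefore
  decomposes the tree into branches: an edge above a branch is cut when the
  join to its parent lies above `cut_height` (0.995) *or* when the
  detachment ratio (parent height − branch top height)/(1 − branch top
  height) exceeds `detach_ratio` (0.5) — i.e. the branch joins the rest of
  the tree across more than half of its remaining dissimilarity range. On
  the reference simulation the five planted branches have detachment ratios
  ≥ 0.66 while intra-module branches stay ≤ 0.29, so the rule has a wide
  margin; single genes are never detached on their own.
* **Quality-mode preservation.** With test network = reference network the
  connectivity statistic is identically 1 for the module and for every null
  draw, so its Z is 0/0 noise; quality rows report z_connectivity as NA and
  z_summary equals the density Z. Preservation mode uses the mean of both.
* **Scale-free fit.** Ten equal-width bins, empty bins dropped, signed R².
  The signed index can be negative (ascending slope), so a target of 0 is
  not vacuous; the selection rule is "smallest β with signed fit ≥ target,
  else the best fit with a warning".
* **Degenerate inputs.** Correlations of magnitude 1 are clamped to
  1 − 1e-12 before atanh (warned); zero-MAD genes fall back to Pearson
  (warned); zero variance in both conditions gives DV p = 1, in exactly one
  condition the numerical lower bound (both warned); permutation p-values
  are lower-bounded by 1/(n_perm + 1); a null permutation SD of 0 yields
  Z = +Inf with a warning. Connectivity-filter ties break lexicographically
  by gene id, making every stage deterministic given the seed.
* **Problem sizes.** The package's reference simulation is 1,000 genes
  (five modules of 150 plus 250 background genes) with 60 samples per
  condition; null calibration uses 20 cohorts of 1,000 genes at 50 + 50.
  These sizes give each statistic enough resolution to measure calibration
  and recovery while a full end-to-end run stays in the seconds range.

## Open design points and how they were resolved

* The eigengene-merge threshold is not derivable from first principles;
  0.8 is the default and configurable.
* β is selected on the full gene set, then the connectivity filter is
  applied; the reverse order would couple the filter to each candidate β.
* The consensus minimum is taken at the TOM level (the similarity actually
  clustered), not on raw adjacency; quantile scaling is off by default.
* Per-edge p-values enter the 0.01 cut unadjusted. An edge-level multiple
  testing correction would drive the null changed-edge rate to zero and
  with it the binomial null's rate parameter.
* DE/DV flag thresholds (BH 0.05) are configuration, not constants; the DW
  machinery runs on the filtered network universe.

## Known limitations

The binomial changed-edge null treats a gene's N − 1 edge tests as
independent trials. They are not: all edges of one gene share that gene's
sampled alignment with each module's eigengene, and a modest (≈2.5 SD)
shift of that alignment between conditions flips a large block of its edges
at once. The per-edge test stays calibrated (the global changed-edge rate
sits at the per-edge alpha under the null) and the per-gene *mean* count is
correct, but the count distribution is overdispersed, most visibly for
high-membership genes in strong modules. Consequently the DW gene list at
p < 0.01 contains, besides the planted rewired hubs (whose binomial
p-values are astronomically small, 1e-88 and beyond), a tail of
moderate-p false positives (1e-3 to 1e-15) concentrated among module hubs.
In the reference simulation this caps DW-hub precision well below 1 while
recall stays at 1; users who need a conservative hub list should rank by
dw_p rather than treat the 0.01 flag as a verdict, or tighten `dw_alpha`.
A permutation-based per-gene null would remove the defect at substantial
cost and is outside the present scope.

Other limitations: unsigned networks only (no signed or signed-hybrid
variant); two conditions only; no blockwise decomposition for very large
gene sets; preservation uses one density and one connectivity statistic
rather than a large statistic battery, which is sufficient for the
z_summary bands interpreted here but is not a drop-in for richer
preservation reports.
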