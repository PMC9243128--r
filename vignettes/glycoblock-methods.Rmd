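---
title: "Methods: multi-block integration of plasma N-glycan profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block integration of plasma N-glycan profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoblock)
```

# The problem

Total plasma N-glycome profiling by hydrophilic-interaction UPLC quantifies
39 chromatographic peaks (GP1–GP39), each expressed as a percentage of the
total integrated area, so every sample is a composition closed to 100%.
Disease-associated shifts in glycosylation — branching, galactosylation,
sialylation, fucosylation — are spread across many correlated peaks, and
the analytical questions are (i) which peaks and derived structural traits
differ between a patient group and controls, and (ii) whether a sparse
multivariate signature discriminates the groups. `glycoblock` implements
the full chain for a two-group design (here: type II diabetes vs healthy
controls): preprocessing, derived traits, univariate screening, cluster
signatures, a sparse multi-block discriminant model, and relevance-network
inference — together with a synthetic glycome generator so every stage is
testable without access to cohort data.

# Preprocessing

**Batch correction.** Plate artefacts are removed with parametric
empirical-Bayes location/scale adjustment (the ComBat model): each feature
is standardised against its grand mean and pooled variance, per-plate
location and scale estimates are shrunk toward normal / inverse-gamma
priors fitted across features by the method of moments, and the coupled
location/scale updates are iterated to a `1e-6` fixed point. The two-group
label is kept in the mean model by default (`preserve_group = TRUE`) so
biological signal is not absorbed into plate estimates; this is safe when
groups are balanced over plates, which both the emulated design and the
generator guarantee. With a single plate the correction is the identity
(γ\* = 0, δ²\* = 1). `eb = FALSE` gives the plain per-plate
standardisation — the large-sample limit of the EB variant and exactly
idempotent, which the EB variant is not: shrinkage leaves a small residual
plate offset that a second pass would partly remove, a property of this
algorithm family rather than of this implementation.

**Median quotient normalisation.** Per-sample dilution is estimated as the
median, over peaks, of the ratio to the feature-wise median spectrum, and
divided out. The recovered factors are exact when samples are scaled
copies of a common spectrum; on real data they are a robust estimate.

**Rank transformation.** Analyses downstream of preprocessing run on
per-feature ranks (average ranks for ties). Because "rank transformed" is
ambiguous, both plain average ranks and the Blom inverse-normal transform
Φ⁻¹((r − 3/8)/(n + 1/4)) are provided; the pipeline default is average
ranks standardised to zero mean and unit variance, which is what the
multi-block stage expects. The stage order is fixed as batch correction →
quotient normalisation → ranks, following the natural narrative of the
preprocessing chain, but each stage can be toggled.

**Plate check.** `pca_batch_check()` tests the leading five centred-SVD
components for plate association with Kruskal–Wallis; a pipeline run
reports the component-1 p-value before and after correction.

Derived traits are computed from the *normalised, pre-rank* matrix: ratio
traits are scale-free, but ranks would destroy the arithmetic the trait
formulas assume.

# Derived traits

The 21 derived traits are declarative data — a CSV of
`trait_id, family, formula` where formulas are sums, differences, scalar
multiples and ratios of sums over peak ids (token `TOTAL` is the panel
sum). The shipped table groups the traits under the six canonical
families: branching (A1, A2, TRIA, TETRA), degree of branching (LB, HB),
galactosylation (G0–G4, A2G), sialylation (S1–S4), sialylation of
biantennary (A2S0, BAMS, BADS) and fucose position (CF, AF). The exact
laboratory assignment of peaks to structures is not published for this
panel, so the shipped formulas follow common plasma-glycome conventions
(e.g. GP30–GP32 triantennary/trigalactosylated, GP26/GP34/GP36
tetra-antennary, early peaks core-fucosylated biantennary) and are
explicitly convention-based: any laboratory table can be dropped in via
`read_trait_definitions()` without touching code.

Note that several families overlap by construction — HB is the union of
the TRIA and TETRA peak sets, BAMS is S1 restricted to biantennary peaks —
so the six families are *not* separable correlation clusters and a
clustering of trait profiles should not be expected to recover them. This
matches the observation in cohort data that peak clusters show no clean
correspondence to trait families; the package's cluster-recovery tests
therefore use the generator's peak-correlation blocks, which are disjoint.

# Univariate screening

Group comparisons use Pearson chi-square without continuity correction for
categorical tables (the variant that reproduces published contingency
statistics), pooled-variance Student's t (Welch by flag), and Mann–Whitney
U. The U statistic is reported in the min convention; its p-value is an
exact enumeration of all label assignments (valid under ties) when the
smaller group has fewer than eight observations and the enumeration is
tractable, and the tie-corrected, continuity-corrected normal
approximation otherwise. FDR control is Benjamini–Hochberg step-up,
reported in input order. The one-sample Kolmogorov–Smirnov check against a
normal with estimated moments is flagged approximate (estimated parameters
make the asymptotic p conservative) and is intended only as a screening
diagnostic. `screen_features()` combines per-feature Mann–Whitney tests,
a BH family over all features, and per-cluster K/k counts at a chosen α.

BH families are kept explicit: cohort-characteristics tests, peak tests
and trait tests are adjusted as separate families.

# Cluster signatures

Feature signatures are Spearman correlation matrices clustered by Ward's
minimum-variance method on the dissimilarity d = 1 − r (raw-profile
Euclidean input is also accepted). Ward linkage is the Lance–Williams
update on squared Euclidean distances with heights on the distance scale
(`hclust` `ward.D2`, verified against a naive O(n³) implementation). The
number of clusters is an explicit cut (`k = 4` for peaks and `k = 6` for
traits by default) because cutting by height is not reproducible across
datasets. The clustered image map applies independent row and column Ward
clusterings and reorders the matrix by both leaf orders.

# The sparse multi-block discriminant core

Given J column-standardised blocks X⁽¹⁾…X⁽ᴶ⁾ on the same N samples and a
symmetric design matrix C with entries c_ih ∈ [0, 1], sGCCA maximises

$$\sum_{i \ne h} c_{ih}\, \mathrm{cov}\!\left(X^{(i)} a^{(i)}, X^{(h)} a^{(h)}\right)$$

subject to ‖a⁽ʲ⁾‖₂ = 1 and a sparsity constraint per block. Sparsity is
parameterised operationally as `keepX`, the number of nonzero loadings per
block and component — the working form of the L1 bound, and the form in
which the reference analysis states its choice of 10 selected peaks per
component.

The optimizer is cyclic block-coordinate ascent: for block j the gradient
direction is z⁽ʲ⁾ = X⁽ʲ⁾ᵀ Σ_{h≠j} c_jh X⁽ʰ⁾a⁽ʰ⁾; the update truncates z⁽ʲ⁾
to its keepX largest-magnitude entries and renormalises. This truncation
is the exact maximiser of the coordinate step under the cardinality
constraint, so the objective is provably non-decreasing — the property the
test suite asserts on every fit. The classical soft-threshold (L1-style)
proximal step is available as `shrink = "soft"`; under a *fixed-cardinality*
schedule its effective L1 bound varies between iterations and the
unpenalised objective can dip, which is why it is not the default.
Further numerical choices:

* covariance uses the 1/(N−1) convention throughout;
* initialisation is the leading right singular vector of each block
  (deterministic); random restarts are available because the problem is
  non-convex;
* convergence at max-absolute loading change < `1e-6`, capped at 100
  iterations, with the full objective trace kept in the diagnostics;
* dimensions are extracted by regression deflation
  X_{d+1} = X_d − s_d (s_dᵀ X_d)/(s_dᵀ s_d), so later components are
  orthogonal to earlier scores within each block;
* the sign convention makes the largest-magnitude loading of each
  dimension positive, flipping all blocks of the dimension together —
  flipping blocks independently could change the sign of cross-block
  covariances and hence the achieved objective.

With two blocks, full design and no sparsity the first component equals
the leading singular pair of the cross-covariance matrix; the test suite
uses that closed form, plus an exhaustive 0.1° grid on the unit circles
for P_j = 2, as independent oracles.

**Supervised wrapper (DIABLO).** The outcome enters as a centred/scaled
dummy-indicator block that is never penalised. The default design
connects every pair of blocks with weight 1 (a fully connected design; the
data–data weight is tunable via `design_data`). Prediction maps new
samples through the stored centring/scaling and deflation, then assigns
the class of the nearest centroid in each block's component space
(`centroid-dist`; Mahalanobis and a regression-based `max-dist` are also
offered), and combines blocks by a vote weighted by each block's
component-outcome correlation. Which blocks enter the model is open in
the reference description; the pipeline default is peaks + derived traits
+ outcome.

Model evaluation uses a stratified 80/20 train/test split, stratified
K-fold cross-validation (K = 5 by default — the reference analysis says
only "K-fold" — with `folds = N` honoured as leave-one-out) reporting
balanced error, and rank-based (Mann–Whitney) AUC with ties counted one
half. The model-level AUC score is the ensemble-weighted difference of
distances to the two class centroids on component 1; this score definition
is not fixed by the reference description and is documented here as the
package's choice.

# Relevance networks

For blocks i and h the similarity of variables p and q is
Σ_d cor(x_p, z_d)·cor(x_q, z_d), with z_d the average of the two blocks'
dimension-d component scores — the standard relevance-network construction
from latent-component models. The default uses one component, matching
the observation that one relevant component remains at the |0.5| cut-off.
Edges with |similarity| ≥ 0.5 (the conventional, deliberately arbitrary
threshold producing interpretable graphs) form a weighted bipartite graph;
hubs are reported by degree with eigenvector centrality as a tiebreaker.
`circos_edges()` provides the complementary data-level view: Spearman
correlations among the selected variables with within/between-block flags
and a per-variable annotation of the class with the higher mean.

# The synthetic glycome generator

`simulate_glycome()` emulates the statistical structure the chain assumes,
not chromatograms: latent Gaussian log-abundances with block-diagonal
correlation (default blocks of 16/16/4/3 peaks at ρ = 0.5, mirroring the
four observed peak clusters), a case shift of `effect_size` (default 0.8
log units) on the effect peaks (default GP34, GP32, GP26, GP31, GP36,
GP30 — the component-1 peaks of the reference analysis), per-plate
location/scale artefacts on the log scale, exponentiation and row closure
to 100. Defaults are the study conditions: 219 controls vs 232 cases on
four plates with both groups on every plate. A logistic-normal rather
than Dirichlet construction is used because a Dirichlet cannot encode
arbitrary positive peak correlations. Two deliberate modelling points:

* a plate offset uniform over peaks would vanish under closure, so the
  location artefact is modulated across peaks by a fixed profile
  (1 + 0.8·sin(2πj/p)) — real plate effects are peak-dependent;
* closure spreads a planted shift on six peaks into small compensatory
  shifts on all other peaks, so at cohort scale most peaks show some group
  difference; this spill-over is a real property of compositional data,
  and it is why parameter-recovery tests score the *ranking* (top-10
  selection) rather than exclusive significance.

Baseline log-abundances decay linearly from 2 to −1 so early chromatogram
peaks dominate, loosely mimicking real peak-height inequality; σ = 0.35
gives coefficient-of-variation magnitudes typical of plasma glycome
percentages. What the generator does **not** emulate: heavy-tailed
measurement error, peak co-elution artefacts, missing peaks, covariate
structure (age/sex are simulated but carry no effect), and realistic
trait-family geometry beyond what the peak blocks induce. Passing tests
demonstrate that the chain recovers what it assumes, not that those
assumptions hold for any particular cohort.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest sizes
chosen to make the stochastic checks stable: 20-seed repetitions for
recovery and calibration checks at n = 100/100 or 50/50, 50 seeds for the
optimizer oracles, 100 seeds for the Ward oracle at n = 8, and the full
219/232 cohort scale for the end-to-end pipeline. Every stochastic step
takes an explicit seed, and a pipeline run is bitwise reproducible under a
fixed seed.

# Known limitations

* Exact trait formulas are conventions, not the unpublished laboratory
  table; sum-trait values depend on that choice (ratio traits less so).
* The EB batch model assumes additive/multiplicative plate effects per
  feature on the analysed scale; artefacts that reorder samples within a
  feature are not corrected.
* The min(n) < 8 rule for exact Mann–Whitney p-values is a convention;
  for very unbalanced designs the enumeration cap falls back to the
  normal approximation.
* The sGCCA objective is non-convex; the SVD initialisation is
  deterministic but not guaranteed globally optimal for J > 2 with
  sparsity. Random restarts are available.
* Compositional closure is handled by normalisation and ranks, not by
  log-ratio geometry; an isometric log-ratio variant is out of scope.
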