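---
title: "From bucketed NMR spectra to perturbed metabolic pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bucketed NMR spectra to perturbed metabolic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stocsynet)
```

## The problem

Serum metabolomics of staged disease — here the model system is gastric
carcinogenesis observed across five pathological stages (control CON, then
GS, LGD, HGD, GC) — asks three nested questions of a set of 1D ^1^H NMR
spectra:

1. *Which signals discriminate a disease stage from control?*
2. *Which metabolites co-vary in a stage-specific way, suggesting shared
   pathway regulation?*
3. *Which metabolic pathways do those co-varying metabolites implicate,
   once projected onto a reference metabolic network?*

`stocsynet` implements the full chain: spectral preprocessing, statistical
recoupling of variables (SRV), PCA/PLS-DA/OPLS-DA discrimination with a
VIP-and-loading-correlation significance rule, R-STOCSY/OR-STOCSY
correlation extraction, shortest-path reconstruction of perturbed
subnetworks on a KGML-derived metabolite–enzyme graph, and
betweenness-centrality pathway-impact scoring.

## Preprocessing

The input is a samples × buckets intensity table on a descending, uniform
chemical-shift axis (the default axis is δ 9.00→0.00 at 0.001 ppm, i.e.
9000 buckets). Three operations, in this order:

* **Region exclusion** (`exclude_region()`, default δ 5.7–4.6): the
  residual-water region is *set to zero* rather than deleted, preserving
  axis geometry. Running it before normalisation guarantees the water
  region contributes nothing to row sums.
* **Segment alignment** (`align_segments()`): within user-chosen segments,
  each sample is shifted by the integer number of buckets (≤ `max_shift`)
  maximising cross-correlation with the pointwise median spectrum, ends
  padded with the segment's edge value. This is a deliberately minimal
  re-implementation of interval correlation-shifting alignment: its only
  job here is to remove the small per-peak position jitter that would
  otherwise break the bucket-to-bucket correlations SRV relies on. Shifts
  are edge-padded, not circular, so signal never wraps across a segment
  boundary. The pipeline aligns within each assignment-map window (padded
  by `max_shift + 1` buckets) — a whole-axis shift cannot correct
  peak-specific jitter.
* **Total-sum normalisation** (`normalize_total_sum()`, constant 100):
  rows are scaled to a common integral so spectra of different overall
  concentration are comparable. The order exclusion → alignment →
  normalisation is the package default; the operations are pure functions,
  so any other order can be composed explicitly.

Bucket membership in any ppm window is by bucket-*centre* inclusion in the
closed interval — stated here because boundary handling is a recurring
source of off-by-one disagreements between implementations.

## SRV clustering

High-resolution bucketing produces thousands of strongly redundant
variables. SRV merges consecutive buckets into peak-coherent clusters
using the *coupling landscape*: element *i* is the Pearson correlation
across samples between buckets *i* and *i*+1 (`coupling_landscape()`).
Clusters are maximal runs of buckets whose internal boundary correlations
all reach `landscape_threshold` (default 0.8); runs shorter than
`round(singlet_size / resolution)` buckets (default 0.01 / 0.001 = 10, the
base width of a resolved weak singlet) are discarded (`build_clusters()`).
Zero-variance buckets get boundary correlation 0 by convention and
therefore break runs. Cluster intensity is the *sum* of member buckets —
sum, not mean, so that cluster intensities keep the integral semantics of
the normalised spectrum (`summarize_clusters()`).

This is the run-merging form of SRV. The published method's further
refinements (correlation·covariance landscapes, supercluster aggregation)
are intentionally out of scope: the role SRV plays in this chain —
dimension reduction to statistically coherent peak-level variables — is
fully served by the simpler rule, which has the advantage of being exactly
specifiable and testable. The threshold can alternatively be calibrated as
the 95th percentile of boundary correlations inside a user-declared
signal-free noise region (`srv_params(noise_region = ...)`).

`coverage_fraction()` reports the share of total absolute intensity
captured by the clusters. On real serum spectra this is well below 100%
because broad macromolecule envelopes and noise are not recouped; the
synthetic generator reproduces that property (see below).

## Discrimination and the significance rule

All multivariate models work on the autoscaled cluster matrix (column mean
0, sd 1, n−1 divisor; zero-variance columns dropped with a warning).

* **PCA** (`pca_nipals()`): NIPALS extraction with deterministic
  initialisation (column of greatest variance), convergence at relative
  score change < 1e-10 (max 500 iterations), and a sign convention making
  each loading's largest-magnitude element positive. Q² is estimated by
  row-wise 7-fold cross-validation (held-out rows projected onto training
  loadings).
* **PLS-DA** (`plsda()`): PLS1 on the centred ±1 class code, control
  coded −1 (the class coding is this package's choice; results are
  invariant up to sign). Q² by 7-fold cross-validation with
  contiguous-block folds after a seeded shuffle — a vendor-style default.
* **OPLS-DA** (`oplsda()`): the orthogonal-projection extraction — weight
  w ∝ X'y; orthogonal weight is the X-loading minus its projection on w;
  the orthogonal component is deflated and the predictive component
  refitted. One orthogonal component is the default, matching the
  convention of reporting a single tp1/to1 score plane. The predictive
  component is oriented so that tp1 correlates positively with the case
  class, which fixes direction semantics ("up" = higher in the stage than
  in control); the largest-element-positive sign convention applies to the
  PCA and orthogonal components, where no such anchor exists.
* **VIP** is computed on the predictive component(s) only, so
  mean(VIP²) = 1 holds by construction for every fit — a useful algebraic
  sentinel that the tests assert on every model.
* **Response permutation testing** (`permutation_test()`): the class code
  is permuted `n_perm` times (default 200) with X intact; the model is
  declared *valid* only if the original Q² exceeds every permuted Q² and
  the regression line of the Q² points against |corr(y_perm, y)|
  intersects the vertical axis below zero.

Variables of a fitted OPLS-DA model are labeled by a two-criterion rule
(`select_differential()`): VIP > 1 *and* |r| above the two-tailed critical
value of the Pearson correlation at df = n1+n2−2, where r is the
correlation of the (scaled) variable with tp1. The critical value is
`critical_r(n1, n2, alpha)` = √(t²/(t²+df)), reported to 3 decimals; at
the study's group sizes (11 or 15 vs 32), the α = 0.01 values are 0.389
and 0.372 and the α = 0.05 values 0.301 and 0.288. Labels:
`very_significant` (VIP > 1, |r| > r*₀.₀₁), `significant` (VIP > 1,
r*₀.₀₅ < |r| ≤ r*₀.₀₁), else `NS`.

A caveat the tests make explicit: VIP is a *relative* importance measure.
If nearly every variable in the matrix is class-informative, VIPs crowd
around 1 and the gate loses meaning. The acceptance simulations therefore
keep a realistic majority of non-differential clusters in the matrix.

Univariate support: per-metabolite one-way ANOVA with Tukey–Kramer
honestly-significant-difference comparisons (`anova_tukey()`, built on
`stats::aov`/`stats::TukeyHSD`) and row-standardised z-score matrices for
heatmap display (`zscore_matrix()`). Linear discriminant boundaries in a
2-D score plane come from the equal-covariance LDA (`linear_boundary()`).

## R-STOCSY and OR-STOCSY

The statistical total correlation spectroscopy matrix over SRV clusters is
C = X'X/(NS−1) on the autoscaled matrix — exactly the pairwise Pearson
correlation matrix (`correlation_matrix()`). Edges are unordered cluster
pairs with |r| ≥ 0.9 (`threshold_edges()`; the threshold is applied to
|r|, with the sign retained for display). Each cluster maps to a
metabolite by maximal ppm-window overlap, ties broken toward the nearer
window centre (`assign_clusters()`); edges are then `intra` (same
metabolite — same spin system, useful for assignment), `inter` (different
metabolites — candidate pathway-level co-regulation) or `unassigned`
(`classify_edges()`). Inter edges deduplicate to unique metabolite pairs,
the network stage's input.

OR-STOCSY (`orthogonal_filter()`) removes the class-orthogonal structured
variation before correlating: the orthogonal components of the OPLS
extraction are deflated from X, and the columns are re-autoscaled so that
the downstream matrix is still a true correlation matrix (the
re-autoscaling is this package's choice; without it C's diagonal shrinks
by whatever variance was removed). Each removed score is uncorrelated with
the class code by construction (checked at 1e-8). The filter targets the
*dominant* structured y-orthogonal variation: a weak confounder that
barely registers in the X-loading of the predictive score may need a
second orthogonal component to be captured, which is why the confounder
simulations remove two.

The behavioural contract, demonstrated in the tests: correlations driven
by a latent factor unrelated to class (a confounder) drop below the 0.9
threshold after filtering, while correlations driven by the class contrast
itself survive. Note the corollary: in a *stage-vs-control* OR-STOCSY,
biological co-variation that is identical in both groups is treated as
systematic variation of no interest and removed — that is the point of the
supervised variant, and why the unfiltered R-STOCSY matrix is the right
object for overall correlation screening.

## Network reconstruction and pathway impact

Pathway definitions are read from KGML XML files (`parse_kgml()`):
`entry` elements typed compound/enzyme/gene (genes collapse to their
enzyme identity), with compound–enzyme edges derived from `reaction`
elements (the enzyme whose `reaction` attribute names a reaction is linked
to each of its substrates and products) and from compound-subtyped
`relation` elements. Fragments merge into one bipartite metabolite–enzyme
"biograph" by node-id union (`build_biograph()`), accumulating pathway
membership; bipartiteness is preserved by construction and checked in the
tests by 2-colouring.

For every inter-metabolite correlation pair, *all* shortest paths between
the two metabolites are extracted (`extract_subnetwork()`,
igraph-backed) — all, not one arbitrary representative, because
deterministic output and the full set of implicated intermediates both
require it. Interior metabolites of those paths that are not themselves
measured are the NMR-invisible intermediates; enzymes on the paths are the
implicated enzymes. Metabolites absent from the pathway files (lipoprotein
signals and other non-KEGG species in real data) are kept aside as
external correlation-only nodes. Path length is unweighted and undirected;
a `max_len` cut-off is available (default unlimited) for users who want to
exclude biologically implausible long routes.

Pathway impact uses relative betweenness centrality on each pathway's
*metabolite projection* (two metabolites adjacent iff they share an enzyme
in that pathway): impact = Σ betweenness over hit metabolites ÷ Σ
betweenness over all pathway metabolites, with hits/pathway-size as the
fallback when every centrality is zero (complete or edgeless projections).
Betweenness uses the unordered-pair convention — stated explicitly because
conventions differ by a factor 2, though the ratio cancels it. The hit set
is the measured-and-correlated metabolites of the stage's perturbed
network, not the invisible intermediates. Enrichment is the hypergeometric
upper tail over the biograph's metabolite universe (the universe choice is
a documented default; the pathway library or the measured set are
defensible alternatives). A pathway is flagged at impact ≥ 0.3. Raw
enrichment p is reported alongside impact; Benjamini–Hochberg adjustment
is available but off by default.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is demonstrated.

* **Signatures** (`make_metabolite_library()`): each metabolite is a 1–3
  peak Lorentzian multiplet (halfwidth 0.002 ppm, multiplet span ≤ 0.02
  ppm) placed in its own disjoint window of the 9–0 ppm axis, with a
  KEGG-style compound id. Disjoint placement gives an unambiguous
  cluster→metabolite ground truth; overlapping placement is available.
* **Concentrations** (`simulate_concentrations()`): log-normal. The
  log-concentration is a residual N(0, `base_log_sd`²) plus latent-factor
  contributions (factor value × loading) plus log multiplicative group
  effects. The default residual scale is 0.2 — a 20% biological
  coefficient of variation, conventional for serum metabolites. This
  scale matters twice: it is what makes clusters of the *same* metabolite
  correlate near 1 (concentration variation must dominate the residual
  position-jitter noise), and what makes non-differential metabolites form
  SRV clusters at all.
* **Planted correlations**: `true_correlations` records the closed-form
  factor-model correlation on the *log* scale, r = Σl₁l₂σ_f² /
  √(var₁·var₂). The analysis operates on intensities (the exponentiated
  scale), where the Pearson correlation of log-normal pairs is compressed
  — mildly for positive r at small variance, severely for negative r at
  large variance (a log-scale r of −0.95 at σ² ≈ 0.8 becomes ≈ −0.4 in
  intensity). Designs that plant recoverable strong pairs therefore use
  positive loadings with factor sd ≈ 0.55 over residual 0.1, giving an
  intensity-scale pair correlation ≈ 0.96.
* **Rendering** (`render_spectra()`): bucket intensity is the
  concentration-weighted Lorentzian sum, with a per-sample, per-metabolite
  position jitter (sd 0.002 ppm) exercising the alignment step, additive
  Gaussian noise, and a broad-hump *background* carrying (by default) 50%
  of total spectral area with 5% per-hump amplitude variation. The
  background plays the role of the protein/lipoprotein envelope of real
  serum: it keeps SRV coverage meaningfully below 100% and — critically —
  stabilises the total-sum normaliser. With only ~15 narrow signals and no
  background, closure (every normalised variable sharing the fluctuating
  row total) distorts correlations badly; with a dominant stable
  background it is negligible, as in real spectra.
* **Toy pathways** (`make_toy_kgml()`, `random_pathway_topology()`):
  KGML files with known topology, shared compounds across files carrying
  identical ids.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: J-coupling fine structure and peak-shape
distortions, baseline and phase artifacts, heteroscedastic noise,
metabolite-specific variance structure (the residual CV is global),
overlap between different metabolites' multiplets (optional but off in the
ground-truth designs), and any real pathway database. Results on real
sera additionally depend on assignment quality and the database version,
which is why the counts reported for the original rat-serum study (153
clusters, 92/31/20/39/52 correlations, per-stage pathway lists) are
context, not targets.

## Numerical choices and degenerate inputs

* NIPALS: tolerance 1e-10 on relative score change, ≤ 500 iterations,
  variance-ordered deterministic start.
* Autoscaling drops (never silently keeps) zero-variance columns.
* Zero-variance buckets: boundary correlation 0, breaking SRV runs.
* All-zero rows fail normalisation with the sample named; all-zero
  matrices fail `coverage_fraction()`.
* `exclude_region()` is idempotent; a window outside the axis is the
  identity.
* Cluster→metabolite ties break toward the nearer window centre.
* LDA falls back to a pseudo-inverse (flagged) on singular pooled
  covariance.
* Every random draw flows from an explicit seed through `set.seed`
  discipline; rerunning any pipeline or generator call with the same seed
  is bit-identical.

## Problem sizes used in the test suite

The packaged simulations run at 200 samples per group for parameter
recovery (10 replicates), 50 replicates of 43 × 153 null matrices for the
labeling-rule calibration (group sizes 11 vs 32, the study's GS/CON
design; 153 variables, the study's cluster count), and 70-pathway toy
libraries for the KGML round trip. These sizes were chosen so each claim
is demonstrated at the scale the corresponding analysis actually runs at,
while keeping the whole suite executable in about a minute of CPU.

## A complete run

```{r pipeline, eval = FALSE}
report <- run_pipeline(default_config(seed = 42))
print(report)
```

The default configuration simulates the five-stage design (group sizes
32/11/15/15/11), with three differential metabolites whose fold change
grows along the stage order up to 3-fold, two latent-factor pairs, and a
six-pathway toy library whose first pathway carries the structured
metabolites in its interior. The report shows the stage-wise progression:
discrimination quality (R²Y, Q²) rising from GS to GC, OR-STOCSY edges
appearing in the later stages, and the perturbed pathway flagged at
impact ≥ 0.3 — the qualitative signature the method is designed to
recover.

## Known limitations

* The SRV rule is the run-merging form; superclusters and
  covariance-weighted landscapes are not implemented.
* OPLS-DA handles two classes only (contrasts are always pairwise, as in
  the staged design); multi-class discrimination is out of scope.
* Missing values are rejected, not imputed.
* The orthogonal filter with one component can under-remove a weak
  confounder; inspect the removed scores (attribute `removed_scores`) and
  increase `n_ortho` when the filtered correlation matrix still shows
  suspect structure.
* Q² for PCA uses row-wise cross-validation, which is optimistic relative
  to element-wise schemes; it is reported for model-size guidance, not
  inference.
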