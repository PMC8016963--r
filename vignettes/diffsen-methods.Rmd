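---
title: "Methods: predicting transporter-mediated drug resistance with DiffSen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting transporter-mediated drug resistance with DiffSen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Membrane transporters of the ABC and SLC families can export drugs out of
tumor cells before they reach their targets. A cell line that carries an
overactive efflux transporter for a drug will look *less sensitive to the
drug than its dependency on the drug's target predicts*: silencing the
target kills it, but the drug does not. `diffsen` turns this discrepancy
into a quantitative target variable and asks which transporter features
predict it.

## The DiffSen statistic

For a drug $d$ with primary target $g$ and cell line $c$,

$$\mathrm{DiffSen}(d, c) \;=\; z\big(s(d, c)\big) \;-\; z\big(v(g, c)\big),$$

where $s$ is viability under drug treatment, $v$ is viability under
silencing of $g$ (shRNA or CRISPR), and $z(\cdot)$ denotes per-profile
z-scoring across cell lines. Both inputs are first put in the *viability*
orientation (higher = more viable = more resistant), so positive DiffSen
flags candidate transporter-mediated resistance and a *positive*
correlation of a transporter's expression with DiffSen reads as
resistance-driving.

Choices behind this formula:

* **Z-scoring before subtracting.** Public sensitivity screens report
  AUC-like summaries on incompatible scales; dependency screens report
  normalized viabilities. Subtracting raw values would mostly measure the
  scale difference. Per-profile z-scoring is the minimal transform that
  makes the difference meaningful within a panel and transferable across
  panels. It also gives DiffSen two exact invariances that the test suite
  asserts: invariance to positive affine rescaling of either input, and
  antisymmetry under swapping the inputs. `raw` and `rank` modes are
  available through `compute_diffsen(mode = )` for sensitivity analyses.
* **Population SD.** Z-scores use the $1/n$ (population) standard
  deviation, the convention of `scipy.stats.zscore`; `(1, 2, 3)` maps to
  `(-1.2247, 0, 1.2247)`. The choice is irrelevant to every correlation
  computed downstream (z-scoring is affine) but is fixed so outputs are
  reproducible to the digit.
* **Two-target drugs** use the mean of the two z-scored silencing
  profiles, re-z-scored — a scale-free combination. Drugs with three or
  more primary targets are excluded altogether (below).
* Cells with a missing value in either profile are excluded from that
  drug's DiffSen only; fewer than 10 usable cells is an error.

## The filtering cascade

Modeling DiffSen only makes sense for drugs whose cellular effect is
actually captured by silencing a single gene. Four filters run in order,
per dataset, and every removal is recorded with a reason:

1. **Target count** — only drugs with one or two primary targets are kept
   (polypharmacology cannot be recaptured by a single knockdown).
2. **Same-target concordance** — drugs sharing a target should share
   sensitivity profiles. For every same-target pair we compute Pearson
   correlation and its two-sided p over shared non-missing cells; a drug
   survives when the *lower median* of its pairwise p-values is below
   `alpha` (default 0.05), i.e. when it is concordant with at least half
   of its peers. The lower median (type-1 quantile) rather than the
   interpolated one matters only for even peer counts: a drug identical to
   one peer and unrelated to a second should pass this step and be judged
   by the target-size rule instead.
3. **Target size** — after the concordance removals, a target retaining
   fewer than three drugs is removed with all its drugs (too little
   replication to trust the target's signal). Applied iteratively until
   stable.
4. **Drug-vs-silencing concordance** — the drug's sensitivity profile must
   correlate (p < `alpha`) with its target's silencing profile. On null
   data this removes 95% of drugs by construction; the acceptance suite
   verifies the empirical removal rate over 500 simulations.

A one-way ANOVA screen (`lineage_anova`) reports per-feature
lineage-specificity of transporter expression across lineages with more
than `min_cells_per_lineage` (default 10) cell lines; it is reported, not
used as a filter, since lineage-specific expression is a property of the
biology rather than a data defect.

## Models

Per drug and dataset the cells are split 70/30 (seeded, per-drug derived
seeds); feature selection and all tuning touch only the training cells.

* **Feature selection**: Pearson correlation of each feature with DiffSen
  on the training cells; the top `k = 50` by *signed* correlation are
  selected (highest positive correlation first, matching the resistance
  interpretation; `ranking = "absolute"` is available). Ties break
  lexicographically; constant features score 0. `k` is a judgment call —
  large enough to hold a handful of true transporters plus correlated
  passengers, small enough for stable regressions at 100–300 training
  cells.
* **Candidate families**: lasso (L1) and ridge (L2) via glmnet over a
  logarithmic lambda grid anchored at the critical lambda of the
  standardized problem (30 points; down to $10^{-4}\lambda_{max}$, up to
  $10^{2}\lambda_{max}$ for ridge whose shrinkage is gentler), scored by
  the mean over five seeded folds of the Pearson correlation between
  held-out predictions and held-out DiffSen; and a random forest (ranger)
  tuned over variables-per-split $\{\lfloor\sqrt p\rfloor, \lfloor
  p/3\rfloor, \lfloor p/2\rfloor\}$ and $\{250, 500, 1000\}$ trees by
  minimum out-of-bag MSE, with `cv_score` the correlation of out-of-bag
  predictions with the response.
* **Winner**: highest `cv_score`; ties break toward the simpler family
  (lasso, then ridge, then forest). Test performance is the Pearson
  correlation between the winner's predictions and held-out DiffSen; a
  model is *successful* when the two-sided p-value is below 0.05 — raw,
  uncorrected, one decision per drug-dataset pair.
* **Cross-dataset transfer**: features are restricted to those profiled in
  both panels, training uses all usable training-panel cells, and
  evaluation uses only test-panel cells absent from the training panel, so
  shared cell lines can never inflate the transfer estimate.

Two numerical caveats, both quantified in the test suite: picking the
lambda (or forest grid point) that maximizes the CV correlation makes the
*reported* `cv_score` mildly optimistic under the null (measured mean up
to ~+0.05 at n = 100, p = 50), and the forest's out-of-bag correlation is
mildly pessimistic and cannot reach 1 even on noiseless signal (measured
~0.98). Neither affects test-set calibration, which is what "successful"
is based on; the type-I acceptance test confirms the nominal 5% rate.

## Rank aggregation and enrichment

For each *successful* model the full feature universe is ranked by the
training correlation (rank 1 = most resistance-associated; ties get
average ranks). Rank vectors are averaged per drug across all of the
drug's successful models (within- and cross-dataset alike), and per
*structure group* across the models of all member drugs. Structure groups
are the connected components of the drug graph with edges at Tanimoto
coefficient > 0.35 on 2D atom-pair fingerprints (ChemmineR); components
may chain structurally dissimilar drugs through intermediates, which is
documented behaviour, and synthetic cohorts may supply bit sets directly.

Enrichment of an annotated transporter set on an aggregated list is a
one-sided rank-sum test that the annotated features sit nearer the top
than random placement allows. For universes of at most 12 features (at
most 8 annotated) the p-value is computed by exhaustive enumeration of all
$\binom{n}{k}$ placements; otherwise by a finite-population normal
approximation on the sum of $k$ positions drawn without replacement
(exact mean and variance under ties, continuity-corrected). A weighted
GSEA-style statistic was deliberately avoided: it would introduce
unstated weighting parameters where a plain rank-sum answers the
question. The per-transporter cell-line check (`cellline_enrichment`)
asks, via one-sided Wilcoxon tests, whether the 10 highest- (or lowest-)
expressing cell lines concentrate at the resistant end of the
DiffSen-sorted cell list; ties at the tail boundary break
deterministically by cell id.

The overall importance score maps mean ranks onto $(0, 1]$ as
$(n - \bar r + 1)/n$.

## The synthetic cohort generator

The generator exists so that every stage is testable against known ground
truth without any external download. It emulates, per dataset $i$ and
with all randomness driven by one seed:

* partially overlapping cell-line panels (a shared core of
  `overlap_fraction` per panel);
* lognormal-like transporter expression with lineage-specific shifts
  (gene-specific loadings times per-lineage magnitudes) plus binary
  genetic flags;
* a latent dependency per target gene shared by all panels, observed by
  the silencing screen through Gaussian noise;
* drug viability
  $s = \mathrm{gain}_i\,[\alpha\, dep + \beta \sum_{t \in planted} z(E_t)
  + \varepsilon] + \mathrm{offset}_i$, with per-panel affine gain/offset
  emulating AUC-versus-viability scale differences, and two-target drugs
  averaging two latent dependencies;
* planted transporter sets shared within a target family by default —
  the generative counterpart of the premise that structurally similar
  same-target drugs are exported by the same transporters, and the reason
  the same-target concordance filter is satisfiable when $\beta$
  dominates;
* structure groups equal to target families, with fingerprints built from
  global/group/private bit blocks sized to hit prescribed within- and
  between-group Tanimoto targets up to integer rounding.

Defaults (`sim_config()`) describe the validation conditions used
throughout the tests and the acceptance script: two panels of 200 cell
lines with 50% overlap, 300 transporter features, five targets with four
drugs each (20 drugs), three planted transporters per drug with effect
size $\beta = 2$ against unit noise. The type-I study uses $\beta = 0$
with 200 drugs across 50 targets at 100 cells — sizes chosen so each
study completes in minutes on one core while leaving the binomial and KS
calibration checks adequately powered.

What the generator does *not* emulate — and hence what passing tests do
not show about real panels: dose-response curve shape and AUC estimation,
batch structure and normalization artifacts, identifier mismatches across
sources, copy-number effects beyond binary flags, correlated transporter
co-expression modules, and expression-activity decoupling
(post-translational regulation of transporters). Recovery rates on
synthetic cohorts are an upper bound on what real panels would give.

## Degenerate inputs and tie-breaking, in one place

* Constant matrix rows: dropped by `zscore_rows` (reported), scored
  `r = 0` in feature selection, `F = 0, p = 1` in the lineage ANOVA.
* Correlation on fewer than 3 shared cells: pair skipped and logged
  (same-target filter) or the drug removed with reason
  (silencing-concordance filter).
* Constant predictions in a CV fold: fold correlation scored 0.
* All ordering ties (features, cells, drugs, groups) break
  lexicographically under C collation, so every output is byte-stable
  across runs and platforms.
* Master seed fans out through a polynomial rolling hash
  (`seed, stage, dataset, drug`), so adding a drug never perturbs another
  drug's results.

## Limitations

The package deliberately stops at the harmonized-TSV boundary: parsing
native public-database dumps, identifier alias resolution, clinical
validation and survival analysis are out of scope. Enrichment depends on
the completeness of the annotation catalog supplied; an empty
intersection with the feature universe is flagged untestable rather than
silently significant. Cross-dataset transfer requires features profiled
in both panels and at least 10 evaluable cells after overlap exclusion;
refusals carry machine-readable reasons in the run report.
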