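---
title: "Methods: connectome-based prediction of age and cognition"
author: "connpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of age and cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connpred)
```

# The problem

Normal aging is accompanied by cognitive decline, and both constructs leave
distributed traces in resting-state functional connectivity. `connpred`
implements a connectome-based predictive-modelling pipeline that (i) learns
separate linear models predicting chronological age and cognitive scores
from whole-brain connectivity, (ii) interprets the models through their
per-edge weight maps at three spatial levels, (iii) quantifies how much the
age and cognition models overlap, (iv) stress-tests the weight maps
(bootstrap, fold-level inter-correlation, network-restricted models, a CPM
cross-check), (v) asks whether predictive edges mediate the age–cognition
association, and (vi) transfers frozen models to an external cohort by dot
product. A synthetic-cohort generator with the same statistical skeleton
makes every stage testable without imaging data.

# Connectome representation

A subject's parcellated time series (nodes × timepoints) is reduced to
pairwise Pearson correlations, Fisher z-transformed
(`z = atanh(r)`), and vectorized. Two conventions are fixed package-wide:

* **Edge order** is the row-major upper triangle: (1,2), (1,3), …, (1,n),
  (2,3), …, (n−1,n). For a symmetric matrix this equals R's
  `m[lower.tri(m)]`, and `edge_pairs()` / `edge_index()` expose the
  bijection. One unambiguous layout prevents silent misalignment between
  weight maps from different stages.
* **Clipping**: |r| is clipped to `1 − 1e-7` before `atanh`, keeping edges
  finite while preserving ordering. Perfect correlations cannot occur in
  real data; the clip only matters for degenerate synthetic inputs.

A 246-node parcellation yields `246 * 245 / 2 = 30135` edges; eight
canonical networks (VIS, SMN, DAN, VAN, LIM, FPN, DMN, SUB) yield
`8 * 9 / 2 = 36` network pairs (within-network cells included). The
packaged 246-node atlas is a constructed stand-in with plausible network
sizes, shipped so structural counts and examples work out of the box; any
atlas TSV (`node_id`, `node_label`, `network_label`) can be supplied.

# The predictive engine

## PLSR via SIMPLS

Models are partial least squares regressions solved with the SIMPLS
algorithm, implemented directly on centred cross-products. Predictors and
target are mean-centred with **training statistics only**; edges share
units, so no variance scaling is applied by default. The returned
coefficient vector is expressed on the raw feature scale, so prediction for
any subject is `intercept + x · B` — the same dot product used later for
frozen-model transfer, with the training centring baked into the intercept.
For a single response SIMPLS coincides with PLS1, which the test suite
exploits by cross-checking predictions against an independent PLS
implementation.

## Component selection

The number of latent components is genuinely open in this family of
analyses. The default rule selects it per training fold by an internal
5-fold cross-validation over 1–20 components, minimizing RMSE; the inner
fold assignment is a deterministic `rep_len` split so that fitting is a
pure function of its inputs. A fixed-component mode (`n_components = k`)
exists for reproducibility experiments and is what the heavier simulations
in the test suite use (k = 2 at the default generator settings, which is
also what the automatic rule selects there). Worth knowing: once a target
is predicted nearly perfectly, additional components chase residual edge
noise and can swamp the coefficient map without hurting predictions —
interpretation is more component-sensitive than accuracy.

## Repeated cross-validation and inference

`repeated_cv()` places the model in k-fold cross-validation (default 10)
repeated with fresh random partitions (default 200), reporting r, CV R²
(`1 − SSE/SST`, possibly negative) and RMSE as mean ± SD across
repetitions, plus the per-fold coefficient vectors (reps × folds maps).
Nothing computed on a test fold ever enters training: centring, component
selection and the optional covariate screen all see training folds only
(verified by a leakage test that perturbs test-fold targets and checks the
training-fold coefficients bitwise).

Significance uses label permutation: the target is shuffled and the full
CV pipeline re-run per iteration. The null statistic uses a reduced number
of repetitions (default 1, recorded in the output) since the null mean
stabilizes quickly. P-values use the add-one estimator
`(1 + #{null ≥ obs}) / (1 + n_perm)`, which never returns zero and gives
the floor `1/5001 ≈ 2.0e-4` at 5000 iterations.

Two covariate-control devices mirror common practice: `partial_accuracy()`
correlates the residuals of observed and predicted scores after regressing
both on covariates (the "controlling for head motion" reading; an
alternative — residualizing the target before fitting — answers a different
question and is not implemented), and `screen_out_covariate_edges()`
retains only edges whose partial correlation with the target given a
covariate (typically age) is significant, applied inside each training
fold.

`cpm_fit_predict()` implements the classical CPM alternative: edgewise
correlation screening at p < 0.01, sign-split positive/negative strength
sums, and a bivariate linear model on the strengths. It exists as a
multicollinearity cross-check on the PLSR maps, not as the primary engine.

# Weight-map interpretation

The per-edge coefficients of the fold models are averaged into a
connection-level map (2000 maps at the default 200 × 10 settings). Two
aggregations follow:

* **Node level**: each node receives the signed sum of its incident edge
  weights, so the node total equals twice the edge total (handshake
  identity, asserted in tests). An absolute-value variant sits behind a
  flag; signed sums are the default because cancellation between opposing
  edges is informative.
* **Network level**: for each of the 36 network pairs, weights are summed
  and divided by the pair's edge count (size-normalized mean), with
  positive and negative weights additionally summarized separately. The
  cell order is fixed: row-major over the upper triangle of the 8 × 8
  network grid, diagonal included. Pairs with zero edges (possible only
  with single-node networks) are reported as NA with an edge count of 0.

`overlap()` compares two same-level maps by Pearson correlation against a
permutation null built by shuffling the entries of one map (10 000
iterations, two-sided add-one p). Shuffling one map is sufficient because
the correlation depends only on the relative alignment; two-sided inference
is used because overlap may legitimately be negative, and on the synthetic
default it is.

# Stability battery

* `weight_intercorrelation()`: Pearson r over distinct pairs of fold maps.
  All ~2 × 10⁶ pairs of 2000 maps are wasteful; a seeded random subset
  (default 10 000 pairs) estimates the same mean and SD.
* `bootstrap_weights()`: subjects resampled with replacement (default
  5000), the full-data model refit per resample with the same
  component-selection rule, coefficient vectors averaged; degenerate
  resamples with a constant target are redrawn and counted.
* `network_restricted_cv()`: the whole CV engine re-run on each network
  pair's edges alone, plus the Spearman correlation between a pair's edge
  count and its accuracy — probing whether network size rather than
  identity drives restricted-model accuracy. Pairs with fewer than two
  edges are skipped with a warning.

# Mediation

`mediate_edge()` estimates the simple mediation model with age as
predictor, one edge as mediator, a cognitive score as outcome, and
covariates (gender, mean FD) in every regression: `a` from
`m ~ x + cov`, `b` and the direct effect `c'` from `y ~ x + m + cov`, the
total effect `c` from `y ~ x + cov`. For OLS with a shared covariate set
`a·b + c' = c` exactly, which the tests assert to 1e-8. Inference on the
indirect effect `a·b` uses subject-level bootstrap resampling (default
10 000): percentile confidence interval (BCa was considered and rejected
as unnecessary at these sample sizes) and a two-sided p from the bootstrap
sign distribution with add-one smoothing. The proportion mediated is
`a·b / c`, the dominant convention of the standard mediation workflow; it
is reported as NA whenever `|c|` falls below a tolerance, never as a
spurious ratio. `mediate_topk()` applies this per edge to the k largest
positive (or most negative) predictive weights — ties broken by edge index
— and controls BH-FDR within exactly that family of k tests; the k = 100
and k = 300 analyses are treated as distinct families.

# Frozen-model transfer

For external validation the model is refit once on the full discovery
cohort (not averaged over fold models; both artifacts can be saved) and
applied to an external cohort as a pure dot product — no refitting, no
recentring with external statistics, since the training centring lives in
the intercept. An atlas fingerprint recorded at training time guards
against applying a model to a different parcellation. Validation
correlates predicted scores with external age, partials out mean FD, and
applies Bonferroni correction across all models tested on that cohort
(age + 8 metrics = 9 in the full design).

# The synthetic cohort generator

`simulate_cohort()` emulates an adult-lifespan cohort:

* **Age** uniform over 19–89 years — the simplest lifespan stand-in for an
  approximately uniform population cohort.
* **Cognition**: eight metrics share a single standardized slope on age
  (default −0.6) with metric-specific independent residuals, mirroring the
  empirical pattern that all cognitive domains decline with age without
  modelling each task. Optional per-metric missingness never removes a
  subject's last metric.
* **Motion**: mean framewise displacement is lognormal
  (`meanlog = log(0.12)`, `sdlog = 0.35`) and mildly age-correlated, so
  FD-control analyses have something real to remove.
* **Edges**: each edge is
  `baseline + beta_age·std(age) + beta_cog·std(cog_resid) +
  confound_slope·mean_fd + N(0, noise_sd)`, where `cog_resid` is the
  age-independent component of the primary metric. Defaults:
  baseline 0.25, confound slope 0.15 z/mm, noise SD 0.5 z.

`default_effect_map()` plants the network structure the analysis is meant
to detect: within-network edges of DMN, VAN and SMN load negatively on age
and positively on cognition (the shared, opposite-signed core);
within-SUB edges are age-dominant; within-DAN edges are
cognition-specific; within-LIM edges strengthen with age; SMN-to-DAN/VAN/FPN
between-network edges strengthen with age and predict lower cognition.
The age-dominant and cognition-specific classes are essential, not
decorative: if every effect edge carried both loadings in a fixed ratio,
age and the cognition residual would be nearly collinear in edge space and
neither map would be identifiable.

Amplitudes (0.12 z per SD of age, 0.07 z per SD of the cognition residual,
with ±25% per-edge jitter) were chosen once so that, at n = 300 with noise
SD 0.5, age prediction lands near r ≈ 0.88 rather than saturating —
saturation makes extra PLS components fit pure noise and destroys the
coefficient map — while each planted edge remains individually detectable
(per-edge |t| ≈ 2–4). Two caveats follow. First, cognition is predicted
about as well as age here (r ≈ 0.9), which is more optimistic than real
cohorts; pushing cognitive predictability down to realistic levels would
make per-edge loadings individually undetectable at n = 300, and the
generator's job is recoverability. Second, the generator omits much of
what makes real fMRI hard: no autocorrelated time series or hemodynamics,
no site/scanner effects, no heavy-tailed motion artefacts, no spatially
correlated noise. Passing tests therefore certify the statistical
machinery — absence of leakage, calibration of permutation and bootstrap
inference, correctness of the aggregations — not performance on real data.

`simulate_timeseries()` closes the loop for the connectome constructor: a
target edge vector is back-transformed to correlations, repaired to the
nearest valid correlation matrix by eigenvalue clipping (floor 1e-8) and
diagonal rescaling, and sampled as i.i.d. multivariate-normal timepoints.
A target whose repair changes any correlation by more than 0.05 is
rejected rather than silently replaced.

# Numerical and reproducibility choices

* Every stochastic routine takes an explicit integer seed; cohorts, CV
  partitions, permutations, bootstraps and pair subsampling are all
  bitwise reproducible, and `full_run()` writes an MD5 manifest so two
  runs of one configuration can be compared file by file.
* Permutation and bootstrap p-values use add-one estimators, bounded away
  from zero.
* On-disk tables are TSV with explicit identifier columns; doubles are
  serialized with 17 significant digits so read–write round trips are
  exact.
* Degenerate inputs fail loudly: zero-variance nodes are named, constant
  targets are refused, empty screening masks raise an error instead of an
  empty model, rank-deficient covariates raise a collinearity error.

# Problem sizes used in the shipped tests

The test suite and the acceptance script run the full design at reduced
size, chosen as the smallest scales at which the statistical claims are
meaningful: cohorts of 60–500 subjects on 24–60-node atlases (276–1770
edges), 200 × 10 cross-validation only for the structural fold-map count,
5000 permutations only for the p-floor check, 199 permutations × 200 null
datasets for calibration, and bootstrap sizes of 199–10 000 depending on
the assertion. The 246-node default atlas is exercised for structural
counts; model fitting at 30 135 edges works identically but is not needed
to validate the mathematics.

# Known limitations

* Linear, single-output models only; nonlinear trajectories and
  multi-target PLSR are out of scope.
* The mediation analysis is associational; no sensitivity analysis for
  sequential ignorability is provided.
* The FD-control implementation adjusts the *accuracy estimate* (partial
  correlation); it does not residualize the target before fitting.
* The packaged 246-node atlas is synthetic; analyses of real data should
  supply the actual parcellation table.
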