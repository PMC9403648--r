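# connpred

Connectome-based prediction of age and cognition in R.

Aging and cognitive decline leave overlapping traces in resting-state
functional connectivity. `connpred` is for researchers who want to build
and *interpret* linear predictive models on whole-brain connectomes: it
learns separate models for chronological age and cognitive scores, compares
their weight maps at the connection, node and network level, stress-tests
those maps, asks whether predictive edges mediate the age–cognition
association, and transfers frozen models to external cohorts. A
synthetic-cohort generator with the same statistical skeleton makes the
entire pipeline runnable and testable without any imaging data.

## The model

Each subject's connectome is the vector of Fisher-z node-pair correlations,
`z_ij = atanh(r_ij)` over the upper triangle of the node × node matrix
(30 135 edges for 246 nodes). For a target y (age or a cognitive z-score)
and feature matrix X (subjects × edges), a partial least squares regression
solved with SIMPLS yields per-edge coefficients **B** and an intercept, with

    y_hat = b0 + X B

evaluated in repeated 10-fold cross-validation (accuracy r, CV R², RMSE as
mean ± SD over repetitions; significance by label permutation with
p = (1 + #{null ≥ obs}) / (1 + n_perm)). The fold-level coefficient maps
are averaged and summarized:

* node level — signed sum of each node's incident edge weights;
* network level — per network pair, the edge-weight sum normalized by the
  pair's edge count, sign-split into positive and negative contributions
  (36 cells for 8 networks).

Overlap between two models' maps is their Pearson correlation against an
entry-permutation null. Mediation of the age → cognition association by an
edge m uses the standard paths (a: m ~ age; b, c′: cognition ~ age + m;
c: cognition ~ age), indirect effect a·b with bootstrap percentile CI, and
BH-FDR over the top-k weighted edges. Transfer to an external cohort is the
frozen dot product `b0 + X_new B`, validated as a partial correlation with
external age controlling mean framewise displacement, Bonferroni-corrected
across models.

## Worked example

```r
library(connpred)

# an 8-network, 60-node atlas and a synthetic adult-lifespan cohort
atlas <- make_atlas(c(VIS = 7, SMN = 9, DAN = 6, VAN = 6, LIM = 6,
                      FPN = 7, DMN = 10, SUB = 9),
                    c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN", "SUB"))
spec <- synthetic_spec(atlas, n_subjects = 300, seed = 42)
coh  <- simulate_cohort(spec)

cv_age <- repeated_cv(coh$connectomes, coh$cohort$age,
                      folds = 10, reps = 5, n_components = 2, seed = 1)
cv_age
#> Repeated 10-fold CV, 5 repetitions
#>   r    = 0.885 +/- 0.002
#>   R2   = 0.765 +/- 0.004
#>   RMSE = 9.891 +/- 0.088

cv_cog <- repeated_cv(coh$connectomes, coh$cohort$gF,
                      folds = 10, reps = 5, n_components = 2, seed = 2)

ov <- overlap(network_summary(average_maps(cv_age$fold_weight_maps), atlas)$map,
              network_summary(average_maps(cv_cog$fold_weight_maps), atlas)$map,
              n_perm = 10000, seed = 3)
sprintf("network-level overlap: r = %.2f, permutation p = %.2g", ov$r, ov$p)
#> "network-level overlap: r = -0.69, permutation p = 0.0002"
```

Age is predicted from connectivity at r ≈ 0.885 (RMSE in years), and the
age and cognition weight maps are strongly anticorrelated at the network
level — the edges that strengthen with age are the ones predicting lower
cognitive scores, the package's core interpretive contrast. `full_run()`
chains every stage (generation, prediction, permutation inference,
interpretation, overlap, stability, mediation, transfer) into an output
directory with a checksum manifest.

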