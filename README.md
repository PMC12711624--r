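# omicsfactor

Latent-factor analysis of multi-omics cancer cohorts, with survival
stratification and single-cell signature scoring.

Deeply profiled tumour cohorts measure the same patients across several
molecular layers — somatic mutations, mRNA, proteins, phospho-sites —
and the clinically interesting axes of patient heterogeneity are usually
shared across layers rather than visible in any single one.
`omicsfactor` is built for that setting: it factorises a multi-view
dataset into a small number of per-patient latent scores, asks which
factors track clinical variables and survival, transfers factor scores
to independent cohorts that may share only one omics layer, distils a
factor into a portable gene signature, and locates the cell population
expressing that signature in single-cell data. A synthetic-data
generator with fully known planted structure backs every stage with
ground-truth tests.

## The model

Each omics view `m` is a samples x features matrix `Y_m` (z-scored;
binary mutation views are centred). The package fits the multi-view
Gaussian factor model

    Y_m ≈ Z W_m',   m = 1..M

where `Z` (n x K) holds shared per-sample factor scores and `W_m` holds
view-specific loadings, by alternating least squares with

- a per-view residual variance `tau_m`,
- a standard-normal prior on the scores (fixes the score/loading scale
  gauge),
- per-(factor, view) ARD precisions `lambda_km` that shrink
  factor-view pairs carrying no signal — the mechanism that makes
  factors with distinct view-activity patterns individually
  identifiable,
- missing entries (including wholly absent views) excluded from every
  sufficient statistic.

Every update is the exact minimiser of one penalised objective, so the
objective is non-increasing across sweeps. Downstream:

- **Variance decomposition** `R2[k, m] = 1 − SS(Y_m − z_k w_mk') / SS(Y_m)`.
- **Projection** of a new cohort on matched features:
  `Z_new = Y_new pinv(W')` (SVD pseudo-inverse; equivalently least
  squares), reducing to `Y w / (w'w)` for one factor.
- **Signature extraction**: varimax-rotate loadings, threshold
  max-normalised absolute rotated weights, validate candidates by their
  cross-layer (mRNA-protein) correlation.
- **Enrichment**: a competitive gene-permutation test contrasting
  `|loading|` inside vs outside each gene set,
  `p = (1 + #{|t_null| ≥ |t_obs|}) / (1 + n_perm)`, BH-adjusted.
- **Survival**: Kaplan-Meier, log-rank and Cox proportional hazards
  (Efron ties) on score-stratified groups, via the `survival` package.
- **Single-cell module score**: mean signature expression per cell
  minus the mean of expression-bin-matched control genes.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort (200 patients; binary mutation view plus mRNA, protein
and phospho views; 5 planted factors, one tied to stage and survival;
30 planted signature genes). Condensed:

```r
library(omicsfactor)

cfg  <- simulation_config(seed = 7)          # the study conditions
sim  <- generate_multiomics(cfg)
fit  <- fit_factor_model(sim$dataset, K = 8) # ARD on by default
align_factors(sim$truth$Z_true, fit)         # planted-factor recovery
```

      factor_a factor_b   corr
    1        1        1 -1.000
    2        2        5  0.988
    ...
    mean |corr| over planted factors: 0.9956

All five planted factors come back essentially exactly even though the
model was over-provisioned with K = 8 (ARD deactivates the surplus).
Projecting a 150-patient validation cohort that shares only the protein
layer, then splitting at the median projected score:

    Log-rank chi2 = 32.42, p = 1.24e-08
    Univariable Cox on the projected score:
             coef     HR CI low CI high p
    score -0.7331 0.4804 0.3824  0.6036 0

The hazard ratio per unit score (0.48, i.e. high factor scores are
protective) recovers the planted log-hazard of −0.7. The extracted
signature (rotated weight > 0.5, mRNA-protein correlation > 0.5)
recovers the planted 30-gene set at precision and recall 1.0, and in the
synthetic single-cell data the designated cell type scores highest:

    cell_type        n    mean
    myofibroblast  436  1.338     # planted target population
    tcell          831 -0.240
    Signature-positive cells: tumour 0.208 vs normal 0.041, ratio 5.09

matching the planted five-fold enrichment of that cell type in tumour
tissue.

Run the full sequence with:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_factors.R
Rscript analysis/04_project_survival.R
Rscript analysis/05_signature_enrichment.R
Rscript analysis/06_sc_score.R
```

Tables land in `results/`.

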