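---
title: "Multi-omics latent factors: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics latent factors: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the methods account of `omicsfactor`: the model behind
each stage, the assumptions it makes, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do
and do not establish about real data.

## The factor model

Given views $Y_m \in \mathbb{R}^{n \times D_m}$ over a shared sample
universe, the package fits

$$Y_m = Z W_m^\top + E_m, \qquad
  E_{m,ij} \sim \mathcal{N}(0, \tau_m),$$

with shared scores $Z \in \mathbb{R}^{n \times K}$ and per-view
loadings $W_m$. Estimation is penalised alternating least squares on
the joint objective

$$J = \sum_m \Big[ \frac{\mathrm{RSS}_m}{2\tau_m}
   + \frac{N_m}{2}\log\tau_m
   + \sum_k \Big( \frac{\lambda_{km}}{2}\lVert w_{mk}\rVert^2
   - \frac{D_m}{2}\log\lambda_{km} \Big) \Big]
   + \frac{1}{2}\lVert Z\rVert_F^2,$$

where $N_m$ counts observed entries. Sums run over observed entries
only, so blockwise-missing views and feature-level dropout are handled
without imputation. Each coordinate update — loadings (per-feature
ridge), residual variances ($\tau_m = \mathrm{RSS}_m/N_m$), ARD
precisions ($\lambda_{km} = D_m / \lVert w_{mk}\rVert^2$, capped), and
scores (per-sample generalised least squares) — is the exact minimiser
of $J$, so $J$ is non-increasing per sweep; the trace is stored in
`fit_meta$objective_trace` and asserted in the test suite.

Three terms deserve comment, because each one is load-bearing:

- **The score prior** $\tfrac12\lVert Z\rVert_F^2$ pins the scale gauge
  between scores and loadings. Without it the optimiser can inflate $Z$
  while deflating every $W_m$, driving all ARD precisions to their cap
  and erasing their discriminative shrinkage — after which factors are
  only identified up to rotation and drift freely. With the prior, score
  columns stay near unit scale and $\lambda_{km}$ remains informative.
- **Per-(factor, view) ARD** is what turns "factors are identified up to
  rotation" into "factors are identified": two factors active in the
  same set of views remain rotationally confounded, but factors with
  distinct view-activity patterns are separated because rotating them
  mixes loading mass into view blocks the penalty wants empty. The
  generator's default activity pattern therefore gives every planted
  factor a distinct active-view set.
- **The precision cap** (`1e3`) bounds how hard a factor-view pair can
  be shrunk. An unbounded precision makes collapse an absorbing state:
  a pair pruned early (while the scores are still settling) can never
  recover. At the cap, the effective ridge is strong (order $n$) but a
  pair sitting on real signal regrows within a few sweeps.

**Initialisation.** SVD of the row-concatenated, per-view
$1/\sqrt{D_m}$-scaled, zero-imputed data (imputation is used only here),
followed by a varimax rotation of the stacked per-view-normalised
initial loadings. The rotation starts the ALS near sparse, axis-aligned
factors, in the basin the ARD penalty prefers; without it the fit starts
at the PCA mixture and must rotate its way out, which is slow and can
stall. The whole procedure is deterministic, so a fit is reproducible
bit-for-bit from its configuration.

**View weighting.** Each view enters through its own Gaussian
likelihood with its own $\tau_m$. We considered additionally
down-weighting large views (so that, say, an 800-feature phospho view
cannot out-vote a 300-gene mutation view) but rejected it: implementing
the down-weight consistently on likelihood and prior reduces the ARD
axis-locking force to $O(1)$ per factor-view pair, and in experiments
the fit then drifted off the planted factors (matched correlation fell
from 0.94 to 0.63 as sweeps increased). Per-view residual variances
already provide the first-order balancing.

**The binary mutation view** is centred per feature and modelled with
the same Gaussian likelihood. This is a deliberate simplification: the
generator draws mutations through a logistic link, and a Gaussian fit
can only capture the linear component of that signal. It is adequate
for variance-explained summaries — which is all the downstream stages
use the mutation view for — and avoids a variational Bernoulli scheme
that the rest of the pipeline would not exploit. Correspondingly, the
"planted signal fraction" recorded for the binary view is the linear
$R^2$ of the centred view on the true scores, not the (larger) total
generative signal.

**Defaults.** `K = 15` mirrors common practice for cohort-scale
multi-omics decompositions (the analysis scripts use `K = 8` against 5
planted factors to exercise ARD pruning); convergence is declared at a
relative objective change below `tol = 1e-6` (a deliberately slow,
conservative criterion) with `max_iter = 1000`; ARD is on by default. A
factor is reported inactive in a view when its $R^2 < 10^{-4}$.

## Preprocessing filters

The per-view filters follow the conventions of proteogenomic cohort
studies, with strict inequalities throughout: binary mutation features
are kept when mutated in **more than** `min_mutated = 10` samples;
continuous features are ranked by per-feature SD (denominator $n-1$,
observed entries only, ties at the cutoff broken lexicographically by
feature id) for top-$k$ selection; proteomic features are kept at a
detection rate **strictly above** `min_rate = 0.8`. Z-scoring is
per-feature on observed entries; zero-variance features have no defined
z-score and are dropped with a warning rather than imputed. Top-variable
selection is computed on pre-z-scored values (after z-scoring every SD
is 1 and the ranking is meaningless). Filters never alter values or
sample order, and independent filters commute — both properties are
asserted in the suite.

## Cross-cohort projection

A new cohort is scored as the least-squares solution of
$Y \approx Z W^\top$ on the intersection of its features with the model
loadings: $Z = Y\,\mathrm{pinv}(W^\top)$, with the pseudo-inverse
computed by SVD and singular values below `rcond = 1e-10` of the
largest truncated. For a non-square $W$ this is the only coherent
reading of "inverting" the loading matrix, and for a single factor it
reduces to $Y w / (w^\top w)$. The smallest retained singular value is
reported as `conditioning` so unstable projections are visible. The new
cohort is z-scored with its own means and SDs — the projection
deliberately performs no cross-platform harmonisation beyond that.
Samples with partial feature missingness are solved per-sample on their
observed features; all-missing samples get `NA` scores.

Score stratification exposes median, quantile and fixed-threshold
rules; ties at the cut-point go to the low group, deterministically.
Published cohort splits often imply bespoke, unstated cut-points, so
the rule is always an explicit argument rather than something inferred.

## Varimax rotation and signature extraction

`varimax_rotate()` implements the classic SVD-sweep varimax
(criterion $\sum_k [\mathrm{mean}(w^4) - \mathrm{mean}(w^2)^2]$,
Kaiser row-normalisation off by default, identity for $K = 1$), checked
in the tests against a brute-force rotation-angle grid and against
`stats::varimax`. Signature extraction then:

1. rotates the weight view's loadings and takes the rotated column most
   aligned with the requested factor (largest $|R_{kj}|$);
2. standardises the factor sign so the largest-|weight| feature is
   negative (matching the convention of reporting such factors with
   top features on the negative side), then scales weights to unit
   maximum absolute value — absolute thresholds like 0.5 or 0.74 are
   only meaningful on a normalised scale, so the package fixes one and
   documents it;
3. keeps genes with $|w| >$ `weight_thresh` (absolute value: a signed
   reading would return nothing for a negatively oriented factor);
4. keeps candidates whose mRNA-protein Pearson correlation across
   common samples exceeds `corr_thresh` (strictly); `corr_thresh <= -1`
   disables the filter, which is how the stricter focused-signature
   path (higher weight threshold, no correlation filter) is expressed.

An empty result is a warning, not an error: on thresholds this is a
legitimate outcome the caller should see, not a crash.

## Enrichment of loadings

The competitive permutation test contrasts $|loading|$ between in-set
and out-of-set genes with a pooled-variance two-sample t statistic; the
null permutes gene labels preserving set size, and
$p = (1 + \#\{|t_{null}| \ge |t_{obs}|\})/(1 + n_{perm})$, so p-values
are bounded below by $1/(n_{perm}+1)$ and never zero. Gene permutation
(rather than sample permutation) is the right null here because only
the loading vector — not sample-level data — feeds the test. The
absolute-value statistic makes the result invariant to the factor's
arbitrary global sign. For small universes an exact mode enumerates
every same-size subset; the suite checks it against full enumeration on
a 6-gene universe. BH is used for all FDR adjustment.

## Clinical association and survival

Pearson tests use the exact $t = r\sqrt{(n-2)/(1-r^2)}$ reference;
constant inputs are flagged and excluded from the (single-pass,
matrix-wide) BH adjustment. Ordinal and binary encodings are fixed and
documented — stage I-IV → 1-4, MSS/MSI-L/MSI-H → 0/1/2, F/M → 0/1 —
because a reproducible correlation matrix needs a fixed encoding;
multi-level categoricals are routed to the Kruskal-Wallis test instead.

Kaplan-Meier, log-rank and Cox fits delegate to the `survival` package
(product-limit estimator; two-group log-rank with hypergeometric
variance; Efron tie handling by default, Breslow available), behind
interfaces that return plain, typed result objects. The test suite
still validates the engine against independent oracles: a
hand-tabulated O/E/V log-rank table, a 1-D grid maximisation of the
partial likelihood, equality of the log-rank statistic with the Cox
score test at $\beta = 0$, and a 200-replicate coverage simulation of
the planted hazard coefficient. Complete separation is detected and
reported as `converged = FALSE` (with an optional ridge rescue), and
dropping event-free strata before fitting is an explicit, logged
utility — never a silent fix.

## Single-cell module scoring

The module score of a cell is the mean normalised expression of the
signature genes minus the mean over expression-bin-matched control
genes: genes are cut into `n_bins = 24` equal-frequency bins of
dataset-average expression (ties broken by gene id), and each signature
gene draws `n_ctrl = 100` controls from its bin, excluding signature
genes, with replacement when the bin is smaller. The defaults follow
the established single-cell scoring convention. Control matching makes
the score exactly zero on a constant matrix and invariant to global
expression shifts, and increasing `n_ctrl` provably reduces
control-sampling variance — all asserted in the tests.
Library-size normalisation (`normalize_counts()`: counts per 10k,
log1p) is provided but never applied silently. The positivity threshold
for "signature-positive" cells is a parameter: published analyses of
this kind typically do not state one.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions used throughout: 200 samples; a 300-feature binary
mutation view and continuous mRNA (1000), protein (800) and phospho
(800) views; 5 factors with distinct view-activity patterns; residual
SDs 0.7 / 0.5 / 1.0 on unit-variance per-factor signal for mRNA /
protein / phospho; 30 signature genes loading only on the prognostic
factor at weight −0.8 (background on that factor uniform within ±0.2);
survival exponential with log-hazard −0.7 per unit prognostic score
under uniform administrative censoring calibrated to a 30% censoring
rate; 4-level ordinal stage from a unit-noise threshold model on the
negated prognostic score; 10% of samples missing each view. The noise
SDs were chosen once so that (i) signature genes' mRNA-protein
correlation clears the 0.5 extraction threshold, (ii) planted versus
background loadings straddle the 0.5/0.74 weight thresholds after max
normalisation, and (iii) per-view variance-explained totals are
asymmetric in the way deeply profiled tumour cohorts are (high in
proteomic layers, low in mutations).

What the generator emulates: shared low-rank structure across views
with view-specific noise, a logistic-link binary layer, blockwise view
missingness, a prognostic factor with proportional-hazards survival and
an ordinal stage link, an MSI-like categorical tied to another factor,
and single-cell negative-binomial counts with one cell type
over-expressing the signature and shifting frequency between tissues.
What it does not emulate: batch effects, heavy-tailed or heteroscedastic
noise, realistic mutation co-occurrence or signatures, miRNA biology,
gene-gene correlation beyond the factor structure, and single-cell
zero-inflation beyond what negative-binomial sampling produces. Passing
tests therefore demonstrate correctness of the machinery under the
stated generative assumptions, not robustness to everything real
cohorts do.

## Problem sizes and runtime choices

The suite and the acceptance script run the full-scale study (n = 200,
~2900 features, K = 8) once or twice and otherwise use reduced cohorts
(40-150 samples, tens of features per view) and 200-replicate
simulations for calibration, coverage and power checks; these sizes
give stable acceptance margins while keeping the whole suite around a
minute of compute. Exact reproducibility is part of the contract:
identical configuration and seed give bit-identical datasets, fits and
serialized model containers.

## Known limitations

- Gaussian treatment of the binary view bounds its variance-explained
  summaries at the linear component of the logistic signal.
- Factors sharing an identical view-activity pattern remain identified
  only up to rotation; ARD cannot separate them (no spike-and-slab
  sparsity is implemented).
- The projection performs no batch harmonisation; cross-platform shifts
  beyond per-feature z-scoring will bias transferred scores.
- Cox diagnostics stop at separation detection; proportionality
  checking (e.g. Schoenfeld residuals) is out of scope.
- `align_factors()` uses greedy matching with pairwise-exchange
  refinement; it attains the optimum on well-separated correlation
  matrices (and is oracle-checked at K = 5) but is not a guaranteed
  Hungarian solver at large K.
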