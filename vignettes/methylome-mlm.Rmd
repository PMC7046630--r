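---
title: "Mixed-model methylome-wide association: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model methylome-wide association: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylmlm)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The variance-component model

All mixed-model machinery rests on one random-effect model for an
n-vector trait `y` (here 0/1 case–control status), covariates `C`, and an
n × m matrix `W` of standardized DNA methylation values:

```
y = C beta + W u + e,   var(y) = V = W W' sigma_u^2 + I sigma_e^2
                                  = A sigma_o^2 + I sigma_e^2
```

with `A = W W'/m` the omics relationship matrix (ORM) and
`sigma_o^2 = m sigma_u^2`. The assumptions worth keeping in mind:

* probe effects `u` are exchangeable draws from one normal distribution —
  adequate for absorbing structure spread over many probes, questionable
  for the handful of large-effect probes (which is exactly what the
  multi-component engine relaxes);
* residuals are homoscedastic on the observed 0/1 scale. For a binary
  trait this is the linear-model approximation that underlies observed-
  scale variance partitioning;
* `rho^2 = sigma_o^2 / (sigma_o^2 + sigma_e^2)` is reported **only on the
  observed scale**. There is deliberately no liability-scale option in the
  API: methylation captures consequences of disease (medication, immune
  activation) as well as causes, so the liability transform's causal
  interpretation would be unearned. Instead every fit reports
  `sigma_P2 = sigma_o^2 + sigma_e^2`, which for a covariate-free model
  approaches the binomial variance `P(1 - P)` of the case fraction, so
  readers can see how much phenotypic variance covariates have removed.

### REML: algorithm and numerical choices

`reml_fit()` maximizes the restricted likelihood by average-information
(AI) updates with these specifics:

* **Starting values**: the trait variance split equally across all
  components (`var(y) / (q + 1)` each) — the standard neutral start.
* **Step control**: an AI step is accepted only if the restricted
  log-likelihood does not decrease; otherwise it is halved (up to 30
  times). The accepted-iteration likelihood path is therefore
  non-decreasing by construction.
* **Boundary handling**: variances are floored at `1e-6 * var(y)`. A
  component pinned at the floor with a negative score is frozen and the
  AI system re-solved for the free components (an active-set step);
  without this, boundary solutions (`sigma_o^2 -> 0`) stall against the
  floor and never register as converged.
* **Convergence**: change in restricted log-likelihood below `1e-8`, or
  no step-halved move improves it (numerically at an optimum, possibly on
  the boundary), within 100 iterations.
* **Fast path**: with a single relationship matrix the model is rotated
  into the eigenbasis of `A`, where `V` is diagonal and every iteration
  costs `O(n p^2)` after one eigendecomposition. The generic dense path
  handles any number of components. The two paths are required by the
  test suite to agree to `1e-6` on the same instance (`engine = "dense"`
  forces the generic path).
* **Uncertainty**: the sampling covariance of the variance components is
  taken from the inverse AI matrix at convergence; the standard error of
  `rho^2` follows by the first-order delta method. The source cohort work
  reports standard errors without stating a method; the delta method is
  our documented choice.

## The association engines

`mwas_linear()` is per-probe OLS with a t-test on `n - p - 2` degrees of
freedom; `mwas_pc_adjusted()` appends the top 10 ORM principal components
(eigenvectors scaled by the root eigenvalue, sign-fixed so the
largest-magnitude loading is positive). `mwas_moa()` is the two-step
mixed-model test: the null model (no probe fixed effect) is fitted once by
REML; each probe is then tested by GLS at the fitted `V̂`,

```
b_i = w_i' V^-1 (y - C beta) / (w_i' V^-1 w_i),  se_i = (w_i' V^-1 w_i)^-1/2
```

with chi-square (1 df) p-values, all probes rotated once into the
eigenbasis of `A`. The tested probe remains inside the random component —
the documented cost in power of avoiding m separate REML fits. The test
suite checks the two-step statistic against the exact joint
fixed-effect REML oracle on a small instance: agreement is close in the
bulk (median relative chi-square difference under 2%) and loosest for the
strongest-signal probes, which is precisely the self-shrinkage the
multi-component engine removes.

`mwas_moment()` relaxes the single-distribution assumption: an initial
linear scan splits probes into a "most-associated" group and the rest,
each fitted as its own random component, and for every tested probe all
probes within ±50 kb on the same chromosome (boundaries inclusive,
including the probe itself) are excluded from **both** components.
Exclusion from both groups — rather than only the target's — is our
reading of "excluding the window" in the absence of a stated convention;
it is the conservative option against proximal contamination and is the
behaviour the downdate-vs-rebuild oracle tests pin down.

Numerical design of the per-probe solve: the two variance components are
estimated once from the full group ORMs under the null model and reused
across probes as per-probe effect variances `sigma_j^2 / m_j`. With that
parametrization the window exclusion is an exact low-rank downdate of
`V`, solved per probe by the Woodbury identity against one precomputed
`V^-1` — a few thousand probes cost seconds instead of thousands of REML
fits. (Estimating the components "per chromosome on the full groups"
would recompute the identical quantity 22 times, since the full-group
ORMs do not depend on the tested chromosome; it is therefore computed
once.) `moment_config(refit_variance_per_probe = TRUE)` enables the exact
slow path — a fresh two-component REML on the downdated ORMs for every
probe — used in tests to confirm the reuse approximation is faithful.

Tunable parameters, with defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `window_bp` | 100000 | bp | "100 kb window centred on the probe" read literally as ±50 kb inclusive, same chromosome |
| `group_p_threshold` | `0.05/m` | p-value | the grouping rule is only described qualitatively in the source; Bonferroni on the initial scan is a defensible sparse default, and it is config, not a claim |
| `refit_variance_per_probe` | `FALSE` | flag | the reuse path is the accuracy/speed compromise; the exact path exists for verification |
| `sd_min` (filtering) | 0.02 | beta SD | probes with less variation carry little power and inflate the testing burden |

Every result table carries the genomic inflation factor
`lambda = median(chi^2) / qchisq(0.5, 1)`, computed from p-values through
the inverse chi-square survival function.

## Preprocessing choices

* **Standardization** uses the population (divisor-n) convention, so the
  ORM diagonal averages exactly 1; the source does not specify a
  convention and this one makes `trace(A)/n = 1` exact rather than
  approximate.
* **Residualization** fits ordinary least squares of each probe on the
  covariates, slide/batch included as fixed-effect indicator columns. The
  source treats slide as a random effect in its adjustment; with many
  individuals per slide the fixed/random distinction is negligible for
  residuals, and the fixed-effect version keeps the stage closed-form.
  This is a deliberate, documented simplification.
* **Re-standardization**: whether residualized probes were re-standardized
  before association testing is unstated in the source; this package
  re-standardizes (`standardize_probes()` after `residualize_probes()`),
  so effect sizes stay in per-SD units.
* **Deconvolution** solves, per individual, nonnegative least squares
  against the reference signatures with the *inequality* constraint
  `sum(pi) <= 1` (Houseman-style): unconstrained NNLS is accepted when its
  mass is below 1, otherwise the solution is recomputed with the sum
  pinned to 1 via a heavily weighted penalty row (weight `~1e4` times the
  design scale, enforcing the boundary to well below the noise level).
  Remaining mass is unexplained signal, not forced into cell types. One
  cell type is dropped from covariate designs (eosinophils when present,
  else the last) to avoid compositional collinearity.

## Scoring and classification

BLUP weights are `u_hat = sigma_u^2 W' V^-1 (y - C beta_hat)`, verified in
tests against the ridge closed form. Profile scores in a target cohort
standardize the target's probes **within the target sample**: a genuinely
external cohort has no access to the discovery scaler, so target moments
are the honest choice (the source does not state which scaler it used).
Combined probe + cell-composition scores are sums of separately derived
components, not a joint refit, matching the description of using the two
effect-size sets "together". AUC uses the midrank Mann–Whitney estimator
with DeLong variance (checked against pROC in the test suite); the
logistic p-value is a Wald test on the standardized score, unadjusted by
default with a covariate-adjusted variant available (`classify_scores(C=)`)
since the source leaves adjustment unstated.

`rb_estimate()` corrects the effect-correlation denominator by the mean
squared standard error in each input and takes its standard error from a
delete-one jackknife over probes; the estimate is clipped to [−1, 1] with
a flag. The overlapping-samples covariance correction is omitted because
the cohorts compared here are independent. `replication_n()` implements
the standard two-sample normal-approximation formula; two-sided is the
default and one-sided is available, because the source's printed
replication size (3478) is not exactly reproduced by either convention
(the standard two-sided formula at d = 0.14 gives ≈ 3783, one-sided
≈ 3456) and the exact convention used there is unstated. The package
documents both and claims neither.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` builds beta values as

```
beta = plogis( qlogis(mixture) + batch + covariate effects
               + causal case shift + noise )
```

* **Cell-type mixtures**: per-individual proportions are Dirichlet draws
  (concentration 60, i.e. realistic inter-individual spread of a few
  percentage points) around whole-blood means (neutrophils 55%, CD4T 15%,
  CD8T 9%, monocytes 9%, B cells 6%, NK 6%); cases' mean composition is
  shifted by `ctp_case_shift` (default +1 percentage point neutrophils,
  compensated across the other types — the modest neutrophilia regime of
  ALS-scale whole-blood studies). Every probe carrying a cell-type
  signature thereby differs between cases and controls: the confounding
  that inflates OLS and that mixed models are built to absorb.
* **Batch structure**: probe-by-batch offsets (SD 0.15 on the logit
  scale) over 20 slide-like levels, with cases over-represented on half
  the levels (the default `batch_confounding = 0.30` places 65% of cases
  on one half of the slides). The imbalance matters: the cell-composition
  subspace has rank ≤ K−1 = 5 and would be removed almost entirely by 10
  ORM PCs, while batch confounding of rank ~20 is only partially removed
  — which is what preserves the characteristic inflation ordering
  (OLS > PC-adjusted > mixed models) that real cohorts show. The two
  confounding strengths were calibrated once, against the inflation
  magnitude reported for the motivating cohort (lambda for uncorrected
  OLS in the 1.2–1.35 range), and then frozen.
* **Causal probes**: `n_causal` probes receive a case shift calibrated by
  Newton steps on the logit scale so the realized beta-scale difference is
  `effect_sd` standard deviations of the probe (default 0.15 SD, the
  magnitude of top reported blood DNAm disease associations). Signs are
  random.
* **Annotation**: probes sit on 22 autosomes at 20–60 kb spacing, so many
  causal probes have non-causal neighbours within the ±50 kb exclusion
  window — deliberately exercising the multi-component engine's windowing.
* **Pairs**: discovery and target cohorts share the reference, annotation
  and causal effects but have independent individuals, batch draws and
  noise; the target keeps a random `probe_overlap` fraction of probes.

Not emulated: array intensities or IDAT-level noise, sex chromosomes,
probe cross-hybridization (exclusion lists are accepted but synthetic data
does not need them), age/smoking *predictor training* (covariates are
generated directly), and any cohort-specific missingness (the data model
rejects missing values). Consequently, passing tests demonstrate that the
estimators are correct and calibrated **under this generative model**;
they cannot certify behaviour under platform artefacts the generator does
not produce.

A note on empirical false-positive rates: because probes are deliberately
correlated through shared cell-type factors, the single-replicate FPR of
even an exactly calibrated test fluctuates far more than a binomial
calculation suggests. The calibration suites therefore average 20
replicates (cohorts of 400 individuals by 2000 probes — sizes chosen so
the whole suite runs in about a minute on one CPU) and judge the mean
against the binomial interval of a single scan's probe count.

## Known limitations

* The two-step association tests reuse null-model variance components;
  per-probe exact fits exist only as the slow verification path.
* The multi-component engine retains a slight residual inflation under
  strong correlated confounding (its window exclusion removes the
  self-shrinkage that makes the single-component test conservative); the
  same ordering is visible in the source cohort's reported inflation
  factors. The suites quantify it rather than hide it.
* Backward-elimination logistic regression is implemented exactly as
  described (drop the largest Wald p until all remain below 0.05); it
  inherits the known instability of stepwise selection and refuses
  separated data rather than switching to penalized fits.
* `rho^2` standard errors are first-order delta-method approximations and
  can be optimistic near the `[0, 1]` boundary.
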