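---
title: "Occupancy models with false-positive misclassification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy models with false-positive misclassification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occumis)
```

## The model and its assumptions

`occumis` fits single-season site-occupancy models to detection/
non-detection histories `y[i, j]` collected over `J` replicates at each of
`M` sites. The hierarchical model is

* occupancy: `z[i] ~ Bernoulli(psi[i])`, `logit(psi[i]) = X_psi[i, ] %*% beta`;
* detection given presence: `y[i, j] | z[i] = 1 ~ Bernoulli(p[i, j])`,
  `logit(p[i, j]) = X_p %*% alpha`;
* false positives given absence: `y[i, j] | z[i] = 0 ~ Bernoulli(p10)`.

The conventional occupancy model (OM) sets `p10 = 0`, so an unoccupied site
can only produce an all-zero history; the misclassification model (MM)
estimates a single constant `p10` on the logit scale. The latent state is
marginalized, giving per site

```
L_i = psi_i * prod_j p_ij^y (1 - p_ij)^(1 - y)
    + (1 - psi_i) * prod_j p10^y (1 - p10)^(1 - y)
```

with the second product replaced by the all-zero indicator in the OM.

Assumptions worth stating explicitly:

* **Closure** within the season: `z[i]` does not change across replicates.
* **Conditional independence of replicates** given `z[i]`. In designs where
  replicates are spatial sub-units (e.g. hunting zones within a site) rather
  than repeat visits, this is an approximation — local heterogeneity in
  abundance can induce extra-binomial variation that the model ignores. The
  simulator makes the same assumption, so parameter-recovery results do not
  probe this risk.
* **Constant `p10`**: the false-positive process is intercept-only. This
  matches settings where a single per-replicate misidentification rate is a
  reasonable summary; covariate-driven false positives are out of scope.
* **No verified detections**: the MM implemented is the
  detection/non-detection-only variant. No observation can be declared a
  certain detection, which is the situation in interview data.

## Identifiability of the misclassification model

With only uncertain detections, the MM likelihood is invariant under
swapping the roles of "occupied with detection rate p" and "unoccupied with
false-positive rate p10" (label switching). The standard resolution,
adopted here, is the constraint `p11 > p10`: detections are more likely at
occupied sites. `occu_fit()` starts the optimizer at `logit_p10 = -3`
(`p10` ≈ 0.047, small) and the detection intercept at `+1`; after
convergence, if the site-mean detection probability falls below the fitted
`p10`, the model is refit from a swapped start and the higher-likelihood
interior solution kept, with a warning recorded either way.

When the data contain no false positives, the `p10` MLE sits at its zero
boundary. The likelihood is then flat in `logit_p10`, Wald theory does not
apply, and the package reports the corresponding standard error as
undefined rather than as a large meaningless number (see *Numerical
choices*).

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `restarts` (`occu_fit`) | 5 | optimizer starts | one deterministic start plus standard-normal perturbations; MM likelihoods can be multimodal |
| `reltol` | 1e-8 | relative objective change | optimizer stopping rule |
| Hessian step | 1e-5 | per coordinate | central finite differences at the MLE |
| `phase2_cut` (`two_phase_select`) | 2.0 | ΔAIC | which conventional models get an MM counterpart; mirrors the averaging threshold |
| `cut` (`model_average`) | 2.0 | ΔAIC | the competitive set: models within 2 AIC units of the best |
| `p10` (simulation) | 0 | probability per replicate | conventional data unless false positives are requested |
| `missing_rate` (simulation) | 0 | probability per observation | exercises the likelihood's missing-data path |

AIC is plain `2k - 2 logLik` (no small-sample correction), with `k`
counting every estimated coefficient including `logit_p10`. Akaike weights
are `exp(-dAIC/2)`, normalized; model averaging restricts to the ΔAIC < 2
set, renormalizes the weights, and averages **on the probability scale**,
since the quantities of interest are probabilities of occupancy and
detection. For MMs the averaged detection probability is `p11` (detection
given presence); the weighted `p10` — with OMs contributing zero — is
carried separately.

## What the simulator emulates, and what it does not

`sim_config()` defaults encode the survey design the package targets:
`M = 225` sites of 5 × 5 km (5625 km², about 21.6% of a 26 000 km² region),
`J = 6` spatial replicates per site (1350 plots), and four site covariates
— elevation, ruggedness, forest area, human-settlement density — drawn
standard normal, i.e. already standardized, because the analysis always
standardizes covariates. Occupancy and detection are logit-linear with
optional two-way interaction terms; false positives are
`Bernoulli(p10)` at unoccupied sites; missingness is missing-at-random.

The simulator does **not** produce spatially autocorrelated covariate
fields, correlated replicates, observer heterogeneity, or covariate-driven
false positives. Passing parameter-recovery tests therefore shows that the
estimator is correct under the model's own assumptions at the study's
sample size — not that the model is robust to violations of those
assumptions in real interview data.

Replicate-level (survey-specific) detection covariates are supported in the
data model and likelihood (stacked replicate-major design rows) but default
off; predictions onto a grid require site-level detection formulas, since a
grid cell has no replicate structure.

## Numerical choices

* **Log-domain likelihood.** `log(p)` and `log(1 - p)` are computed as
  `plogis(eta, log.p = TRUE)` of the linear predictor, and the two mixture
  terms are combined by a stable two-term log-sum-exp. This keeps the
  objective finite at the extreme linear predictors optimizers visit.
* **Analytic gradient.** The score has closed form via the posterior
  occupancy weight `wA_i = psi_i A_i / L_i`; it is verified against central
  finite differences in the test suite. BFGS with this gradient makes the
  replicated simulation studies cheap.
* **Independent oracle.** `brute_force_site_loglik()` recomputes every site
  likelihood by explicit enumeration of the latent state in plain
  probability space, sharing no code with the vectorized path; the suite
  checks agreement to 1e-10 and that probabilities over all `2^J` histories
  sum to 1.
* **Standardization convention.** Sample standard deviation with
  denominator `n - 1`; mains are standardized first and interaction columns
  are products of standardized mains, not re-standardized. The
  centering/scaling record is stored in the fit and re-applied to any
  prediction grid.
* **Curvature and SEs.** The Hessian of the negative log-likelihood is
  computed by central differences (step 1e-5) and inverted for the
  covariance. SEs are reported as undefined — with an explicit warning —
  when the Hessian is singular or near-singular (condition number above
  1e10), and for any parameter whose Wald SE exceeds 10 on the logit scale:
  such an interval spans essentially (0, 1), so the parameter is at a
  boundary or on a flat ridge (e.g. `p10` on false-positive-free data, or
  `psi` and `p` separately with `J = 1`).
* **Ties and ordering.** Ranking sorts by AIC with a stable label
  tie-break, so `two_phase_select()` output is invariant to candidate
  order. Design-matrix columns are ordered intercept, mains in declaration
  order, then interactions, so parameter vectors are reproducible.
* **Degenerate inputs.** Zero-variance covariates, non-binary detection
  entries, duplicate or unmatched `site_id`s, missing covariate cells, and
  sites with no observed replicate are all hard errors with informative
  messages; fitting failures inside a candidate sweep are collected
  per-model rather than aborting the run.

## Design decisions that were genuinely open

* **Interaction notation.** A component written `rug * pop + for` expands to
  both main effects plus the product term (the conventional expansion),
  which is how interaction models report coefficients for mains and product
  together.
* **Candidate enumeration.** "All combinations including interactions" is
  combinatorially explosive taken literally; the default enumerator crosses
  all main-effect subsets per component and allows at most one two-way
  interaction per component, which covers the model shapes such analyses
  publish while keeping the set bounded (a cap refuses larger requests and
  points to the explicit-list interface, which reproduces any exact set).
* **Phase-2 entry.** Conventional models with ΔAIC < 2 get misclassification
  counterparts; the final ranking and weights are computed jointly over that
  union so weights sum to 1 across OMs and MMs together.
* **Validation problem sizes.** The replicated studies use the survey's own
  scale: 200 recovery replicates at `M = 225`, `J = 6` with all four
  covariates on both components and `p10 = 0.03`; 100 replicates for the
  overestimation property (`p10 = 0.05`, intercept-only) and 100 for the
  AIC-preference property (`p10 = 0.08`, `M = 500`). The recovery study's
  "moderate" truth is `beta = (0.25, 0.5, -0.5, 0.5, -0.5)`,
  `alpha = (0.5, 0.5, -0.5, 0.5, -0.5)`: effects large enough to matter,
  small enough that neither probability saturates.

## Known limitations

* Wald intervals are first-order asymptotics; at `M = 225` the
  `logit(p10)` sampling distribution is noticeably left-skewed (its mean
  bias approaches the 0.15 design bound in some replicate sets), so
  profile-likelihood intervals would be preferable for `p10` near zero —
  they are not implemented.
* Model-averaged predictions carry no unconditional (selection-aware)
  variance; only point surfaces are produced.
* Single season only: no colonization/extinction dynamics, no abundance
  (N-mixture) extension, no Bayesian estimation.
* Grid geometry is opaque (`cell_id`, optional `easting`/`northing` carried
  through); no projection math or basemap rendering is done.

```{r example, eval = FALSE}
# a compact end-to-end run at survey scale
cfg <- sim_config(
  beta_psi = c("(Intercept)" = 0.25, elev = -0.5, rug = 0.6, pop = -1.2),
  alpha_p = c("(Intercept)" = 0.4, pop = -0.5),
  p10 = 0.04, seed = 7
)
sim <- simulate_dataset(cfg)
d <- occu_data(sim$detections, sim$site_covariates)
sel <- two_phase_select(d, candidate_set(list(occu_spec("elev + rug + pop", "pop"))))
avg <- model_average(sel, d$site_covariates_raw)
occupancy_summary(avg, avg, d)
```
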