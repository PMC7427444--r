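---
title: "Auditing model misspecification in ERGMs of brain functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing model misspecification in ERGMs of brain functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ergmaudit)
```

## The model

Each subject-session contributes one undirected binary graph $y$ on a
fixed node set (regions of interest), modeled as an exponential random
graph:

$$P_\theta(Y = y) = \frac{\exp(\theta^T g(y))}{c(\theta)}$$

with $g(y)$ a vector of sufficient statistics and $c(\theta)$ the sum of
$\exp(\theta^T g)$ over all $2^{\binom{n}{2}}$ graphs.  Four nested
specifications are fit to every graph:

* **base** — `edges` plus selective mixing: one count per unordered pair
  of node labels (resting-state network or subcortical structure).
* **structural** — base plus nodal covariates derived from the subject's
  structural connectivity graph (degree, local efficiency, clustering
  coefficient, each entering as $\sum_{(u,v) \in E} (x_u + x_v)$) and a
  `nodematch` count on latent structural clusters.
* **gwesp** — base plus the fixed-decay geometrically weighted edgewise
  shared partner statistic
  $v(y;\lambda) = e^{\lambda} \sum_{i\ge1} [1-(1-e^{-\lambda})^i]\,EP_i(y)$,
  a triadic-closure term that discounts edges with many shared partners.
* **complete** — all of the above.

The audit asks: which selective-mixing conclusions flip when the
triadic-closure and/or structural terms are omitted?  A term significant
only in the base model is a false positive (FP) of the reduced model; a
term significant only in the fuller model is a false negative (FN); both
or neither significant are TP/TN, pooled as "none".  Error counts per
cortical grouping (within-cortical / within-subcortical /
cortico-subcortical) and subject group feed a baseline-category
multinomial logit whose exponentiated coefficients are reported as odds
ratios.

### Assumptions

Graphs are binary, undirected, hollow; dyads within one graph are
exchangeable given the model terms; sessions are treated as independent
observations in the rate regressions (no subject-level random effect —
matching the source analysis, and listed under limitations).

## Design choices that were genuinely open

**Reference mixing cell.**  The edges term plus a *full* set of mixing
cells is exactly collinear (the cells partition the dyads), so one cell
must be dropped.  We drop the within-category cell of the *most
frequent* label (ties broken lexicographically).  Dropping the
lexicographically first cell instead — for the default parcellation,
the 6-node basal ganglia block with only 15 dyads — makes every mixing
coefficient a contrast against a noise-dominated baseline: in pilot
fits all mixing z-scores collapsed toward 1 and no term was ever
cleanly significant.  A maximum-size reference is the minimum-variance
baseline, the same reason dummy coding conventionally uses the largest
category.

**GWESP decay.**  The decay is fixed, not estimated (no curved-ERGM
machinery).  Default $\lambda = 0.5$, overridable per graph;
`select_gwesp_decay()` optionally profiles the maximum
pseudo-likelihood over the grid $0.1, 0.2, \ldots, 1.0$, since the
published per-subject decays (0.45, 0.6) come with no stated selection
rule.

**Significance.**  $\alpha = 0.05$, two-sided Wald tests.  Terms with
separation symptoms (exploding standard error, |estimate| > 15) are
flagged and treated as non-significant rather than aborting the fit:
zero-edge cells occur routinely in small subcortical blocks, and a
pipeline that dies on them would discard whole sessions.

**Latent structural clusters.**  The latent attribute is a stand-in for
an unpublished latent-space construction: classical MDS of geodesic
distances (disconnected pairs at the maximum finite distance + 1, so
every node is embedded) to two dimensions, then k-means; with
`k = "auto"` the cluster count maximizes the mean silhouette width over
$k = 2..6$.  The construction is isolated behind `latent_clusters()` so
it can be swapped.

**Covariate scaling.**  Structural covariates are z-scored before
entering the model: raw degree and the unit-interval clustering and
efficiency metrics differ by orders of magnitude, and a common scale
makes their coefficients comparable.  Constant columns map to zero.

## Estimation

**MPLE.**  Logistic regression of each dyad's state on its change
statistics $g(y^+_{ij}) - g(y^-_{ij})$ evaluated at the observed graph.
For the dyad-independent specifications (base, structural) this *is*
the maximum likelihood estimate; `mcmcmle_fit()` short-circuits to it
and says so in the fit's `note`.

**Sampler.**  Metropolis-Hastings over uniformly proposed dyad toggles,
acceptance $\min(1, e^{\pm\theta^T\Delta})$, implemented in C++ with
incremental change statistics ($O(n \cdot \bar c)$ per proposal, with
$\bar c$ the mean common-neighbour count).  Defaults: burn-in $10n^2$
proposals, thinning $n^2$.  One caveat worth knowing: at $\theta$
exactly zero every proposal is accepted, so the edge-count *parity*
alternates deterministically and an even thinning interval samples a
single parity class; the test suite uses odd thinning where this
matters.  A sustained sampled density below 0.01 or above 0.99 raises a
near-degeneracy warning; inside `mcmcmle_fit()` it aborts the fit with
`converged = FALSE`.

**MCMC-MLE.**  Geyer–Thompson refinement from the MPLE start: simulate
at the current $\theta$, maximize the importance-sampled
log-likelihood-ratio surrogate by damped Newton steps capped at 0.5 per
component (large steps destroy the importance weights), re-simulate.
Iteration stops when the relative parameter change falls below $10^{-3}$
— or, because with a fixed simulation budget the steps plateau at the
Monte Carlo noise floor rather than shrinking indefinitely, when a
Hotelling-type statistic ($\mathrm{ESS} \cdot d^T H d$, with ESS
combining importance-weight concentration and lag-1 chain
autocorrelation) says the step is indistinguishable from noise at the
90% level, after at least three refinements.  Wald standard errors come
from the inverse of the simulated statistic covariance (the estimated
Fisher information) at the final $\theta$.

**Exact oracle.**  For $n \le 5$, `enumerate_exact()` computes the full
distribution by brute force.  The test suite drives the sampler and the
change statistics against it (total-variation distance, probability
ratios), and drives the incremental C++ change statistics against an
independent loop-based recomputation.

## Goodness of fit

`gof_report()` simulates `n_sims` graphs (default 1000) at the fitted
parameters and compares each model statistic and each
edgewise-shared-partner bin against the simulated envelope.  The
Monte-Carlo p-value is the add-one-corrected two-sided form
$p = \min(1,\, 2\min\left(\tfrac{\#\{s \ge o\}+1}{m+1},
\tfrac{\#\{s \le o\}+1}{m+1}\right))$, which is super-uniform under the
null and reproduces the coarse granularity (steps of 0.2 at $m = 9$)
seen in small tabulated displays.

## The synthetic world

The generator emulates the geometry of the source cohort, not its
physiology:

* 154 nodes: 134 cortical over seven RSN labels (near-equal by default —
  the real ROI-to-RSN assignment is unpublished), 14 thalamic, 6 basal
  ganglia;
* structural graphs from a stochastic blockmodel over the label blocks
  (within-block probability 4x between-block), calibrated into the
  observed structural density range 0.0531–0.0632;
* functional graphs drawn from the **complete**-model ERGM at known
  $\theta$, with the edges coefficient tuned by damped logit fixed-point
  iteration into the patient-like (0.1039–0.1524) or HCP-like
  (0.1676–0.2159) density range.

Scenario parameters are package defaults (the source reports no fitted
$\theta$), chosen for two properties: complete-model fits are
non-degenerate at $n = 154$, and the audit has events.  The second
property forced a recalibration during development: with every
within-RSN cell at the same mixing strength, sessions produced
essentially *no* FP/FN flips — every term sat far from the significance
boundary, unlike the observed cohort in which every patient showed
errors.  The committed world gives the within-RSN cells heterogeneous
strengths (0.15–0.7), cross-cells 0–0.1, *identically in both
scenarios*; the conscious-like scenario has GWESP 0.6, nodematch 0.35
and covariate coefficients 0.20/0.12/0.08, the unconscious-like
scenario attenuates these to 0.10, 0.08 and 0.05/0.03/0.02.  The rate
difference between scenarios therefore isolates the triadic-closure and
structural-coupling contrast, which is the mechanism under audit.  In
the patients scenario, 7 of 12 subjects are unconscious at the acute
session (with GCS verbal/motor subscales drawn consistently, so the
GOS-E inference rule `infer_gose()` — GOS-E 2 iff V ≤ 3 and M ≤ 4 — is
exercised end to end), and all chronic sessions are conscious,
mirroring the retained study cohort's 7/5/12 group split.

What the generator does **not** emulate: BOLD time series, partial
correlation graph estimation, tractography, spatial embedding of ROIs,
or subject-level heterogeneity in the generating $\theta$ beyond the
scenario split.  A green test therefore establishes that the estimation
and audit machinery is correct and that the direction of the group
difference follows from the stated mechanism — not that the synthetic
cohort is a statistical twin of the patient data, whose raw graphs are
not public.

## Numerical choices

* Chain defaults: burn-in $10n^2$, thinning $n^2$; density tuning uses
  shorter pilot chains ($6n^2$ burn-in, 30 samples) and stops within
  0.04 logits of the target.
* Newton iterations (multinomial logit): convergence at gradient
  max-norm $10^{-8}$, step halving on likelihood decrease, observed
  information for Wald SEs, AIC $= 2k - 2\ell$; empty-cell separation
  flagged at |coef| > 20 or SE > 100.
* MPLE rank deficiency is an error naming the aliased terms; separation
  is a flag, not an error (see above).
* All randomness flows from explicit integer seeds; cohorts are pure
  functions of their configuration, and the sampler is bit-reproducible
  under a fixed seed.

## Limitations

* MPLE standard errors for dyad-dependent specifications are
  anti-conservative; the pipeline's `method = "mcmcmle"` is the
  defensible default for final inference, `"mple"` the fast screen.
* Sessions enter the rate regressions as independent observations;
  repeated measures per subject are not modeled.
* The latent-cluster construction is a committed stand-in; nothing
  guarantees it matches the unpublished original.
* The fit census (192) and error-rate directions are reproducible by
  design; published odds-ratio magnitudes are not, because the patient
  graphs they derive from are not available.
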