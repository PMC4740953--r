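---
title: "Hierarchical LBA modelling of two-choice emotion identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical LBA modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hlba` models two-choice response times with the Linear Ballistic
Accumulator (LBA).  On every trial two accumulators race toward a response
threshold `b`: each starts at an activation drawn uniformly on `[0, A]`,
grows linearly at a drift rate drawn once per trial from `Normal(v, s)`,
and the first to reach `b` determines the choice; the observed RT is the
crossing time plus a non-decision offset `t0`.  There is no within-trial
noise — the model is ballistic by construction.  One accumulator carries
the drift mean of the *correct* response (`v_c`, interpreted as perceptual
processing efficiency), the other of the error response (`v_e`).

Per subject the package estimates seven parameters: `A`, the threshold
offset `k = b - A` (so `b > A` holds on the sampling scale without
rejection tricks), `t0`, and condition-specific drift means `v_c`/`v_e`
for FACE and OVAL trials.  The drift standard deviation is fixed at
`s = 1`; it sets the evidence scale and is not identifiable jointly with
the other parameters.

The likelihood of an observed (choice, RT) pair is the *defective* race
density: the winner's first-passage density times the loser's survivor
function at `t = rt - t0`.  The closed forms of the single-accumulator
CDF/PDF are standard; both are implemented directly with the survivor
computed in its own form (not `1 - F`) to avoid cancellation.  Densities
are floored at `1e-300` before taking logs, and start-point ranges below
`1e-6` switch to the analytic `A -> 0` limiting density.  A response
earlier than `t0` has log density exactly `-Inf`.

Two deliberate conventions around the "both drifts negative" event (the
race never finishing, probability `pnorm(-v_c) * pnorm(-v_e)`):

* the likelihood is left defective — no renormalization, matching the
  standard closed form;
* the forward simulator redraws both drifts until at least one is
  positive, because the task forces a response on every trial.

The two disagree by `O(pnorm(-v_c) pnorm(-v_e))` of probability mass (about
0.4% at typical parameters).  Tests that compare simulated choice
proportions against quadrature therefore condition the analytic mass on a
response having occurred.

A related numerical fact worth knowing: the race RT density has a `t^-2`
tail (a winner whose sampled drift is barely positive while the loser's is
negative), so the *unconditional mean* RT of the model diverges
logarithmically.  Sample means of simulated cohorts are finite and
well-behaved at realistic sample sizes, but any oracle comparison of
"analytic mean RT" is done within a finite window (we use `rt <= 10` s).

## The hierarchy

Subjects are exchangeable within group.  Every subject-level parameter
`p` has a group-specific hyperdistribution: a normal with mean `mu_p` and
standard deviation `sigma_p` truncated to positive values.  The two groups
(`MDD`, `HCL`) have disjoint hypers, fitted in one joint state — this is
equivalent to fitting the groups separately while sharing all code paths.
There is no cross-group shrinkage, no covariate regression inside the
hierarchy, and no correlated multivariate hyperdistribution.

The hyperpriors are the package's own choice (they are not a
reconstruction of any published setting): `mu_p ~ TN+(1, 3)` for the
geometry (`A`, `k`) and all drift means, `mu_t0 ~ TN+(0.3, 0.3)` seconds,
and `sigma_p ~ TN+(0, 1)` throughout.  On the scale fixed by `s = 1` these
are weakly informative: drift means of plausible magnitude 0.5–4 and
non-decision times of a few hundred milliseconds sit well inside one prior
standard deviation.  All of this is configurable via
`hyperprior_config()`.

## The sampler

The joint posterior is sampled with differential-evolution MCMC: the
proposal for a block is `theta + gamma * (theta_m - theta_n) + eps`, with
`theta_m`, `theta_n` the same block in two other randomly chosen chains
and `eps` uniform jitter of half-width 0.001.  The proposal is symmetric,
so plain Metropolis acceptance applies; proposals outside the support are
rejected through a `-Inf` posterior, never clamped.

Blocking:

* one 7-dimensional block per subject (crossover at
  `gamma = 2.38 / sqrt(14)`), conditional on the chain's current hypers;
* one 2-dimensional block per group and parameter for `(mu_p, sigma_p)`
  (crossover at `gamma = 2.38 / 2`), conditional on the subject values.

The hyper pairs are updated separately rather than as one 14-dimensional
group block because, conditional on the subject parameters, the
`(mu_p, sigma_p)` pairs are independent across parameters: a joint
14-dimensional crossover proposal is rejected almost always against the
tight conditional (we measured ~2% acceptance), which freezes the chains
and then lets migration collapse the population.  Pairwise updates accept
at healthy rates (~20–40%) and mix well.

Migration — cyclically copying whole chain states among a small random
subset — runs only during the *first half* of burn-in, with probability
0.1 per iteration and subsets of at most `n_chains / 4`.  Copying states
reduces population diversity by design; confining it to early burn-in and
letting crossover re-equilibrate the spread afterwards avoids the
population-collapse failure mode while still rescuing stuck chains.

Initialization: by default each chain starts from moderate truncated
normals with every subject's `t0` started below 90% of that subject's
fastest RT, redrawn (up to 100 times) until the posterior is finite.  Raw
hyperprior draws are available via `init = "hyperprior"`, but they
frequently start chains on the floored-likelihood plateau and waste
burn-in.

Defaults are 20 chains and 5000 retained samples per chain with the first
half of the run (2500 iterations) discarded; chain count, retention,
burn-in, jump factor, jitter and migration rate are all `sampler_config()`
fields.  Convergence is reported (rank-normalized split R-hat and a basic
Geyer effective sample size per parameter) but never used for automatic
stopping; `pipeline_fit()` warns above R-hat 1.1.  In our fits the drift
hypermeans mix quickly (R-hat near 1 within a few hundred retained
iterations at study-like sizes) while the start-point geometry `A`/`k` is
the slowest direction — a well-known weak identifiability of the LBA, and
the reason convergence summaries are reported per parameter.

## Group comparison

The group-level statistic is a probability-of-superiority odds ratio.  For
each retained draw of a group's `(mu, sigma)` for the drift of interest we
compute the mean of the implied positive-truncated normal,
`mu + sigma * dnorm(mu/sigma) / pnorm(mu/sigma)`; the two groups' draw
sequences are then compared exhaustively: `count` is the fraction of
cross-pairs in which one group's value strictly exceeds the other's (ties
count zero), and the odds ratio is `count / (1 - count)`, oriented so the
reported value is at least 1 with the favored group recorded.  A count of
exactly 0 or 1 is reported as an infinite odds ratio with a flag, not an
error.  The exhaustive count is computed by sorting (`O(N log N)`); the
naive `O(N^2)` enumeration is kept in the test suite as the oracle.

Because "samples drawn from the true distribution" admits a second
reading, `compare_groups(mode = "predictive")` instead draws one value
from the truncated normal per posterior draw (a plug-in predictive
comparison).  The default (`"hyper_mean"`) compares the per-draw
distribution means.

## Brain–behavior linking

Individual-level point estimates are posterior *medians* per subject.
These are Spearman-correlated, within group, against per-subject
percent-signal-change values for each region in a long-format ROI table.
Midranks handle ties (the standard definition of `r_s`), and two-sided
p-values use the t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` — adequate at group sizes in the
tens — with a seeded permutation mode for verification.  `|rho| = 1` is
reported with `p = 0`.  No multiple-comparisons correction is applied at
this stage.  Trials faster than 150 ms are removed before fitting by
`filter_valid()` (inclusive threshold; configurable).

## The synthetic cohort generator

No subject-level data accompany the study design we emulate, so
`generate_cohort()` is a first-class, tested module rather than a test
fixture.  It reproduces the design constants: 26 MDD and 37 HCL subjects;
one run of 80 trials (60 FACE in counterbalanced mirrored emotion blocks
of FEAR/HAPPY/SAD, 20 OVAL), 6 s per trial — 1.5 s cue, 3.0 s morph,
0.8 s hold, 0.7 s blank — plus a 10 s terminal blank, 490 s in total.
Behavior is simulated trial-by-trial from the LBA forward model with
subject parameters drawn from group-specific truncated-normal hypers.

The default generating hypers were calibrated once, before any inference
test existed, to land on the published behavioral scale (roughly 80%
accuracy and 2.2 s mean RT): `A = 1`, `k = 3`, `t0 = 0.35` s,
`v_c = 2.3`, `v_e = 1.0` on FACE trials, with OVAL slightly easier.  The
MDD correct-drift mean carries a small bump (2.32 vs 2.28) so the
expected group effect is weak, mirroring a near-null group comparison.
These constants live in `cohort_config()`, not in code.

ROI values use a Gaussian copula: the subjects' *true* `v_c_face` values
are rank-transformed to normal scores `z`, mixed as
`r z + sqrt(1 - r^2) eps` with `r = 2 sin(pi rho_s / 6)` (the exact
latent correlation giving Spearman `rho_s`), and scaled to
percent-signal-change units.  The default targets `rho_s = -0.45` within
the MDD group and 0 within HCL, around group PSC levels of 0.32 and 0.77.
Because the association is built on the *true* drifts, estimation noise
attenuates any correlation computed from fitted medians: users should
expect `|observed rho| <= |target rho|`.  Targets with `|rho_s| >= 1` are
rejected as infeasible.

What the generator does *not* emulate: fMRI time series, missing data,
exclusions, emotion-specific drift differences (emotions are labels on
FACE trials only; the model collapses them), RT truncation at the
response window, or contaminant processes (fast guesses, lapses).
Passing recovery tests therefore show that the estimation machinery is
faithful to its own generative model — not that real data meet these
assumptions.

## Problem sizes used in the test suite

The automated checks run at desk scale, chosen as the smallest sizes at
which the targeted property is decided cleanly:

* simulator-vs-likelihood agreement at `n = 1e5` trials (KS distance
  below 0.01);
* the analytic normal toy target at 20 chains x 2000 retained samples;
* hypermean recovery on 20 replicates of 20 + 20 subjects x 320 trials,
  fitted with 20 chains x 1000 retained samples after 500 burn-in
  (coverage of the true `mu` for `v_c_face` by the central 95% interval,
  demanded at 80% or better);
* the end-to-end negative brain-behavior association on 20 replicates of
  the full default design (63 subjects x 80 trials) with short chains
  (12 x 300), where only the correlation's sign is asked of each
  replicate.

## Known limitations

* The start-point geometry (`A`, `k`) mixes slowly and is weakly
  identified at 80 trials per subject; its hypers can show elevated R-hat
  while the drift hypers are well mixed.
* With strongly separated groups and many retained draws, the exhaustive
  count can reach exactly 1, producing the flagged infinite odds ratio.
* The t-approximation p-value for Spearman is approximate under heavy
  ties; use the permutation mode when ties dominate.
* One run of 80 trials identifies subject-level drifts only coarsely;
  individual medians are strongly shrunk toward the group mean, which is
  intended (and is why the linking tests ask only for the sign of the
  correlation).
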