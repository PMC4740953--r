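# hlba

Hierarchical Bayesian Linear Ballistic Accumulator (LBA) modelling of
two-choice response times, with a posterior odds-ratio statistic for
comparing group-level drift-rate hyperdistributions and Spearman linking of
individual-level drift estimates to brain activation.

## What problem this solves

In two-choice perceptual tasks, raw accuracy and mean RT confound several
cognitive components.  Evidence-accumulation models separate them: the LBA
describes each trial as a race between two ballistic accumulators that
start at an activation drawn uniformly on `[0, A]`, grow linearly at a
drift rate drawn from `Normal(v, s)` (with `s = 1` fixing the scale), and
trigger the response whose accumulator first reaches the threshold
`b = A + k`, after which the observed RT is the crossing time plus a
non-decision offset `t0`.  The drift mean of the correct-response
accumulator, `v_c`, indexes perceptual processing efficiency.

`hlba` fits this model *hierarchically* to two groups at once (e.g.
depressed vs. healthy-control cohorts performing a facial
emotion-identification task with FACE and OVAL trial conditions): every
subject-level parameter is drawn from a group-specific positive-truncated
normal hyperdistribution `TN+(mu_p, sigma_p)`, and all subject and hyper
parameters are sampled jointly with differential-evolution MCMC (blocked
crossover proposals built from the states of other chains).

Two downstream analyses are built in:

* **Group comparison.**  For each posterior draw of `(mu, sigma)` the mean
  of the implied truncated normal is computed; the two groups' draw
  sequences are compared exhaustively, `count = P(group A value > group B
  value)`, and reported as an oriented odds ratio `count / (1 - count) >= 1`.
* **Brain-behavior linking.**  Per-subject posterior medians of `v_c` are
  Spearman-correlated (two-tailed, midranks) with per-subject ROI
  percent-signal-change values, within group.

Because no subject-level data are distributed with the emulated study
design, the package includes a first-class synthetic-cohort generator
reproducing that design (26 + 37 subjects; 80 trials — 60 FACE / 20 OVAL —
over 490 s) with ground truth for recovery studies, including an ROI table
with a controlled negative rank association to the true correct drift.

## Worked example

```r
library(hlba)

cohort <- generate_cohort(cohort_config(seed = 42))
trials <- filter_valid(cohort$trials)          # drop RTs faster than 150 ms
summarize_behavior(trials, by = "condition")
#>   group condition n_subjects  mean_rt     sem_rt accuracy_pct sem_accuracy
#> 1   HCL      FACE         37 2.121337 0.07058056     79.23423     1.963755
#> 2   HCL      OVAL         37 1.880215 0.06629745     88.37838     1.562680
#> 3   MDD      FACE         26 2.286763 0.24055738     80.96154     1.910773
#> 4   MDD      OVAL         26 1.898037 0.06604393     88.46154     1.635407

draws <- run_sampler(trials,
                     config = sampler_config(n_chains = 12, n_samples = 500,
                                             burn_in = 500, seed = 1))

compare_groups(draws, parameter = "v_c_face")
#> Odds ratio 7.668:1 in favor of MDD (count 0.8846 over 3.6e+07 pairs)

medians <- posterior_medians(draws, "v_c_face")
roi_correlations(medians, cohort$roi, draws$subj_group)
#>          roi group         rho p_two_sided  n
#> 1 L_fusiform   HCL  0.08961593 0.597869940 37
#> 2 L_fusiform   MDD -0.53094017 0.005258927 26
```

Reading the output: the simulated cohort lands on the intended behavioral
scale (~80% FACE accuracy, ~2.2 s mean RT).  The oriented odds ratio says
that in ~88% of cross-paired posterior draws the MDD drift hypermean
exceeded the HCL one — a modest group effect in the generated direction.
The correlation table recovers the built-in negative association between
correct-FACE drift and fusiform percent signal change within the MDD group
(`rho = -0.53`, `p = 0.005`) and finds none in HCL, where none was
generated.  (This short 12 x 500 fit is for illustration; `sampler_config()`
defaults to 20 chains x 5000 samples.)

A YAML-configurable command-line front end over the same stages
(`generate`, `fit`, `compare`, `correlate`, `report`) ships in
`inst/cli/hlba-pipeline.R`.

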