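---
title: "Models and methods behind mratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mratio` estimates metacognitive efficiency — the M-ratio, meta-d′/d′ —
from trial-level rating data in a two-alternative (match/nonmatch) task,
and asks whether efficiency differs between experimental conditions. The
motivating design is a delayed match-to-sample experiment with a
*prospective* judgment made before the decision (a binary bet or a binary
memory belief, depending on the instruction group) and a *retrospective*
5-point confidence rating made after it, crossed with a within-participant
difficulty manipulation. The package provides the estimation machinery
(single-subject maximum likelihood and a hierarchical Bayesian group
model), the surrounding behavioral statistics, a generative simulator of
the task, and an orchestration layer. This vignette explains the models,
the defaults, and the choices that were genuinely open.

# Type-1 and type-2 signal detection model

The type-1 task is modeled with equal-variance Gaussian signal detection:
evidence $x \sim N(\pm d'/2, 1)$ with the match class as signal, response
"match" iff $x > c$. From the hit and false-alarm rates,
$d' = z(HR) - z(FAR)$ and $c = -\tfrac{1}{2}(z(HR) + z(FAR))$. Point
estimates use the Hautus-style edge correction — $1/(2K)$ added to every
cell of the stimulus × response × rating count table — so the normal
quantiles stay finite for perfect cells; likelihoods always use raw
counts. The uncorrected closed form is available via
`compute_type1_sdt(..., correction = "none")`.

The type-2 (metacognitive) model is the response-conditional meta-d′
construction: a metacognitively ideal observer with type-1 sensitivity
meta-d′ generates the ratings, with the type-1 criterion rescaled to
$c' = c \cdot \text{meta-}d'/d'$ and $K-1$ ordered type-2 criteria on each
side of $c'$. Rating probabilities are truncated-normal masses of the
criterion segments, conditional on the response region. Meta-d′ equals
$d'$ (M-ratio 1) when ratings use the same evidence as the decision —
the optimality anchor — and falls below it when metacognitive information
is lost.

`fit_meta_d_mle()` maximizes the conditional multinomial likelihood over
meta-d′ and the type-2 criteria, with the type-1 parameters fixed at
their point estimates. Numerical choices: the criteria are parameterized
as log-scale outward increments from $c'$ (the ordering constraint
becomes a box constraint), optimization is bounded L-BFGS-B with meta-d′
restricted to $[-5, 5]$ (beyond the identifiable range at realistic trial
counts), three starts at $\{0.5, 1, 1.5\} \times \hat d'$, ties broken by
likelihood then by smaller $|$meta-d′$|$, and cell probabilities floored
at $10^{-12}$. The test suite checks the optimizer against an exhaustive
grid search that exploits the separability of the binary-rating
likelihood.

# The hierarchical group model

Efficiency is modeled on the log scale. For participant $s$ in difficulty
cell $c$,

$$\lambda_{s,c} = \mu + \beta_I x_I(s) + \beta_D x_D(c) +
  \beta_{ID} x_I x_D + u_s + \epsilon_{s,c}, \qquad
  \text{meta-}d'_{s,c} = e^{\lambda_{s,c}} \hat d'_{s,c},$$

with effect coding $x_I, x_D \in \{-0.5, +0.5\}$ (confidence and hard
coded positive, so each $\beta$ is a full cell difference),
$u_s \sim N(0, \sigma_u^2)$ the participant random intercept (the "mixed"
part of the design) and $\epsilon_{s,c} \sim N(0, \sigma_e^2)$ cell-level
noise. Rating counts enter through the response-conditional type-2
likelihood above; type-2 criteria are estimated per participant × cell.
Priors are weakly informative on the scale of log efficiency ratios:
$\mu, \beta \sim N(0,1)$, $\sigma_u, \sigma_e \sim$ Half-Normal(1),
criterion increments Half-Normal(1). The pre-rating phase ($K=2$) and
post-rating phase ($K=5$) are fitted as separate, independent models.

Two modeling details deserve emphasis because both were diagnosed, not
assumed:

**Stabilized type-1 estimates with propagated uncertainty.** The
classical two-stage approach fixes each cell's $(d', c)$ at its raw
point estimate. At 36 trials per cell the sampling SD of $\hat d'$ is
roughly 0.45 — comparable to a hard condition's true $d'$ — so a
nontrivial fraction of cells land near or below zero. Because meta-d′
$= e^{\lambda}\hat d'$, such cells can only reconcile their (genuinely
informative) rating data by driving $\lambda$ strongly negative, which
biases the group posterior and, since low-$d'$ conditions are hit
hardest, manufactures a spurious difficulty effect (we measured a mean
posterior median of about $-0.6$ on the difficulty contrast under an
all-null generator). `prepare_mratio_cells()` therefore shrinks each
cell's $d'$ and $c$ toward its instruction × difficulty group mean with
empirical-Bayes weights (delta-method sampling variance against the
estimated between-participant variance), which preserves group
contrasts while suppressing the noise that caused the bias.

Treating the stabilized values as exact would in turn understate the
posterior width of the design effects, because the error of a
stabilization group mean is *shared* by every cell of that group and
feeds straight into the group contrasts rather than averaging out. The
model therefore samples the type-1 parameters instead of fixing them:
each cell's $(d', c)$ gets an independent normal prior centered on its
stabilized estimate with its residual cell-level EB standard deviation,
and each instruction × difficulty group additionally gets a shared
offset pair with the group-mean estimation SD. With this decomposition
the decision rule is calibrated in the package's own null test (fires
in ≤ 2 of 20 null replicates at the reduced MCMC settings). Raw
unshrunken estimates (with their full independent sampling SDs) remain
available with `stabilize_type1 = FALSE`, and a cell table without the
SD columns reproduces the classical fixed-type-1 two-stage fit.

**Per-cell type-2 criteria.** Sharing a participant's criteria across
the two difficulty cells looks parsimonious but couples the cells'
likelihoods: the fit then compromises between two cells whose best-fit
criterion placements differ, which we measured to attenuate both
within-participant and group effects by roughly half even at 600 trials
per cell. Criteria are therefore per participant × cell.

## Sampling and diagnostics

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
written in C++: single-site random-walk updates for all parameters
(random effects non-centered), plus ancillarity–sufficiency interweaving
moves — location proposals for $\mu$ and the $\beta$s compensated through
the standardized random effects, and log-scale moves that rescale them —
which decorrelate the funnel directions of the hierarchy at no
likelihood cost. Proposal scales adapt toward a 0.44 acceptance rate
during burn-in only, so retained draws come from fixed kernels. All
randomness flows from a mandatory integer seed; a fixed seed and fixed
data give bit-identical draws. Defaults follow the design being modeled:
3 chains × 10,000 iterations with 1,000 burn-in; the test suite runs
scaled-down chains (3 × 1,500/500 for the replication studies, smaller
still for unit tests). The sampler is validated in the test suite
against an independent JAGS implementation of the identical model on a
shared dataset, against its own priors with empty data, and against
ground truth in recovery studies.

Summaries per fixed effect: pooled-chain posterior median, the shortest
sorted-draw interval for the 95% HDI, probability of direction (pd, the
posterior mass on the dominant sign, zeros split evenly), rank-normalized
split R-hat (maximum of the bulk and folded statistics), and tail-ESS
(minimum ESS of the 5% and 95% quantile indicators, Geyer-truncated
autocorrelation sums). The decision rule declares an effect iff the 95%
HDI excludes 0 *and* pd > 0.95; fits with any R-hat ≥ 1.01 are flagged
non-converged but still reported.

# Behavioral statistics

Exclusions mirror the task's rules: a trial is dropped when any of its
three responses is missing or faster than 100 ms (a missing response
time counts as a missing response); a participant is dropped when, in
either difficulty, all valid trials share one pre-rating value or fewer
than 18 valid trials remain. "Identical responses" is interpreted as the
pre-rating — the judgment participants were explicitly told not to fixate
— and is the configurable default rather than a guess about other
response fields. Scores follow the betting payoff (+2/−1 high-risk,
+1/0 low-risk), with the confidence group's score emulated by mapping
high belief to the high-risk bet, the only order-preserving binary
mapping. The two-way mixed ANOVA uses the classical error strata
(between-participant error for instruction; participant × difficulty
error within) via `stats::aov`, with generalized η² computed with all
participant-variance sums of squares in the denominator. The paired
*t* test comes with Cohen's d on the difference scores and a JZS Bayes
factor (Cauchy prior, scale $\sqrt{2}/2$) computed by numerical
integration of the marginal likelihood with a log-scale integrand;
Levene's test uses mean centering (the original statistic) and the Holm
step-down correction across the two difficulty conditions — the only
place the source analysis applied a multiplicity correction.

# The generative simulator

`simulate_task_data()` draws cohorts from a generative SDT observer so
every pipeline stage can be tested without external data. Per trial:
stimulus with $P(\text{match}) = 0.5$; evidence and response from the
type-1 model at the difficulty's $d'$; a metacognitive sample $y$ per
phase; and the rating obtained by thresholding $y$ *on the side of the
type-1 response* — a binary bet is "high" when the evidence clearly
exceeds the criterion in the response direction. When the metacognitive
sample equals the decision evidence this is exactly the ideal observer
(M-ratio 1). Metacognitive efficiency is controlled by a single
parameter: for targets below 1, $y = x + \sigma_m Z$ with the noise SD
solved numerically so the observer's *asymptotic fitted* M-ratio equals
the target (solved on a memoized monotone grid of asymptotic fits over
expected count tables obtained by numerical integration); targets above
1 are allowed with a warning and realized by adding an independent
second stimulus sample, $y = x + \kappa z$.

Defaults encode the study conditions: groups of 104 (bet) and 100
(confidence); 6 sessions × 12 trials with difficulty blocked in session
halves, order alternating by participant parity; $d'$ calibrated to 70%
(easy) and 60% (hard) expected accuracy — 1.049 and 0.507 at an unbiased
criterion; binary pre-rating threshold 0.5 and post-rating thresholds
(0.2, 0.6, 1.1, 1.7) evidence units from the criterion. True log
M-ratio follows the same two-way linear model as the analysis, with
grand means $\log 0.65$ (pre) and $\log 0.8$ (post) — efficiencies below
1, prospective lower, as observed empirically — instruction effects
$-0.4$ (pre) and $-0.15$ (post), a post-phase difficulty effect $-0.25$,
zero interactions, $\sigma_u = 0.15$, $\sigma_e = 0.1$, and participant
intercepts correlated 0.5 across phases to carry prospective information
into the retrospective phase. Response times are log-normal (median
800 ms, log-SD 0.4); 3% of trials lapse (missing, or uniform 0–99 ms
fast responses), and 5% of participants are chronic lapsers
(per-trial lapse probability 0.5), so realistic cohorts exercise the
trial- and participant-level exclusion rules.

What the simulator deliberately does not emulate: the auditory stimuli
themselves (difficulty enters only through $d'$, not through tone-series
correlations), learning or fatigue across sessions, feedback-driven
strategy shifts, response-time structure beyond what the exclusion rules
need, and any systematic type-1 bias differences between groups. Passing
tests therefore certify the estimation machinery under the stated
generative model, not the full richness of real behavior.

# Known limitations

* Two-stage estimation (even stabilized) is not full joint inference
  over type-1 and type-2 parameters; at very low trial counts a residual
  downward bias in the *grand mean* log M-ratio remains (contrasts are
  unaffected in our calibration tests, which is why the decision rule
  stays calibrated).
* With 36 binary pre-rating trials per cell, a single cell carries
  little metacognitive information; group-level inference leans on
  pooling, and single-subject MLE fits at that size should not be
  interpreted individually.
* The HDI is computed from sorted draws and assumes a unimodal marginal
  posterior, which holds for all monitored parameters in practice.
* M-ratios above ~1.3 are outside the simulator's calibratable
  super-optimal range and are clamped with a warning.
* The pd statistic is reported as max(share positive, share negative)
  and is uninformative below 0.5 by construction.

# Problem sizes used by the automated checks

The package's own test suite runs the replication studies at reduced
sizes chosen to make the full suite complete in well under half an hour:
20 replicates of 40 + 40 participants at 3 × 1,500/500 MCMC for the
effect-recovery and null-calibration studies, one full-size cohort
(104 + 100) at 3 × 3,000/1,000 for the dissociation check, and
10,000-trial single-observer simulations for calibration checks. The
acceptance script analyzes one full-size cohort at 3 × 3,000/1,000 per
phase.
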