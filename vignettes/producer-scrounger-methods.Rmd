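---
title: "Models and methods: simulating and analyzing the producer-scrounger game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analyzing the producer-scrounger game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psforage)
```

# The scientific setting

In social foraging, group members split between two mutually exclusive
strategies: *producing* (searching for, discovering and collecting
resources) and *scrounging* (joining another member's discovery and
collecting part of it). The distribution of the two strategies is the
producer–scrounger game. `psforage` implements three layers around it:

1. a closed-form **rate-maximization model (RMM)** of the equilibrium
   producer proportion;
2. a **discrete-event simulator** of a four-player virtual foraging task,
   which doubles as the package's synthetic-data generator;
3. the **measurement and analysis layer**: the producer's index,
   questionnaire scoring (Big Five, metatraits, antisociality screen), and
   a nonparametric comparison/correlation/bootstrap pipeline.

This vignette explains each model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the simulation-based
tests do and do not establish about real data.

# The rate-maximization model

`rmm_producer_proportion()` evaluates $P = a/F + 1/G$: the equilibrium
fraction of producers rises with the finder's share $a$ (the food a producer
secures before scroungers join), falls with patch richness $F$, and falls
with group size $G$. `rmm_producer_proportion_cost()` discounts the finder's
share by the production time $t$: $P = (a/t)/F + 1/G$, which captures why
costlier searching depresses producing and reduces to the plain form at
$t = 1$.

Two numerical choices, both visible in the output rather than hidden:

* The raw formulas are not confined to $[0, 1]$ (at $t = 0.01$ s the
  cost-discounted form explodes). We return the raw value *and* a clamped
  value with a `clamped` flag, and validate $t > 0$. Whether the model
  should be clamped or renormalized is genuinely open; clamping keeps the
  output interpretable as a proportion without distorting comparisons
  between parameter settings, which depend only on ordering.
* `rmm_sweep()` never drops invalid grid rows; they are flagged with a
  reason (`valid = FALSE`), so a sweep over a file of parameter
  combinations is auditable row for row.

For comparison with simulations, the finder's share is not a free input but
estimated from event logs (`estimate_finders_share()`): the mean fraction of
a discovery's collected units taken by its finder. The task itself never
fixes $a$; in the simulator it emerges from collection timing.

# The foraging-task simulator

## The task being emulated

The emulated task is a four-player arena with four symmetric patch zones.
Producing means pressing a search key for `search_cost` seconds inside a
patch; with probability 0.5 a search succeeds and `food_per_patch = 5` units
appear. Scrounging means joining another player's discovery and collecting
part of it. Sessions last 240 s. The two standard conditions differ only in
search cost: `condition_low_cost()` (F5-0s, 0.01 s — strictly positive so
event ordering stays well defined) and `condition_high_cost()` (F5-8s, 8 s).
A pre-training preset (one patch, one unit per success, stop after five
collected units) is provided for completeness but excluded from analysis
datasets.

## Abstractions

Pixel-level 3D movement is irrelevant to response counts and the producer's
index, so space is abstracted to zone-level states: an agent is in a patch
or traveling, with a fixed symmetric `travel_time` between zones. The
original arena geometry enters only through the number of patches (4) and
that symmetry.

The task's human participants need no decision rule; simulated agents do.
Each agent repeatedly chooses among produce / scrounge / idle by a softmax
over utilities:

* $u_{produce} = b + S_i - c \cdot t$, with intercept $b$
  (`baseline_logit`), an agent-specific signal $S_i$ (below), cost
  sensitivity $c$ and search cost $t$;
* $u_{scrounge} = o - o_c \cdot t$ when a joinable discovery by another
  agent exists, $-\infty$ otherwise (`scrounge_opportunism` $o$,
  `scrounge_cost_spillover` $o_c$);
* $u_{idle} = 0$, waiting `decision_pause` seconds.

The spillover term encodes that a costly-production ecology suppresses
*opportunities* to express either strategy, not just producing: with 8-s
searches discoveries are rare and player attention is locked into long
presses, so joining also becomes less likely per unit time. Without it, the
softmax mechanically makes scrounging more attractive whenever producing
gets more expensive, which contradicts how participants behave.

Collection is unit-by-unit (`collect_time` per unit) by all agents attached
to a discovery — the finder from the moment of success, joiners from
arrival — interleaved in event order. The finder's share is therefore an
emergent quantity. A discovery stays joinable for `scrounger_join_window`
seconds, and a patch holding an active discovery cannot be searched until
the discovery is exhausted *and* its last collection has completed, which
guarantees at most one live discovery per patch: the event log alone then
identifies which discovery every join and collect belongs to. Join
decisions are resolved on arrival against the current state, so a logged
`join` always refers to a patch with uncollected units.

## Response definitions

A **producer response** is a successful search whose discoverer collects at
least one unit of it (producing = finding *and* collecting); a **scrounger
response** is a join followed by collecting at least one unit of that
discovery, symmetric with the producer definition. Both are configurable
(`require_collection = FALSE` counts bare successes/joins) because the
original task's logging convention for uncollected finds is unknown.
Failed searches are logged but never counted.

## Default configuration and calibration

The emulated task's published description fixes $F$, $t$, the success
probability, session length, group size and patch count. It does not state
travel speed, collection rate, how long a discovery remains joinable, or any
decision-rule parameter; those defaults were chosen once, by calibrating the
simulator against the magnitudes a typical session of this task produces —
median producer responses near 18 under low cost and near 3 under high
cost, scrounger responses rare in both (medians about 1 and 0.5), producer
index medians near 0.9 — and then frozen:

| parameter | default | units | role |
|---|---|---|---|
| `travel_time` | 3 | s | move between zones |
| `collect_time` | 2 | s | pick up one unit |
| `scrounger_join_window` | 5 | s | discovery joinability |
| `decision_pause` | 4 | s | idle re-decision interval |
| `baseline_logit` | 1.4 | logit | produce propensity |
| `cost_sensitivity` | 0.36 | logit/s | produce cost penalty |
| `scrounge_opportunism` | -1.6 | logit | join propensity |
| `scrounge_cost_spillover` | 0.15 | logit/s | join cost penalty |
| `policy_noise_sd` | 0.8 | logit | stable individual preference |

Under these defaults, 50 seeded session pairs give median producer
responses of 19 (low cost) and 4 (high cost), scrounger medians of 1 and 0,
and index medians of about 0.9 and 1 — the same order and magnitude as the
task, with high-cost producing strictly below low-cost producing in every
batch of seeds, as both the rate-maximization model and agent-based theory
predict. These are the *study conditions* of every simulation-based test in
the package; they are set here, not adjusted per test.

## Cohorts with controllable ground truth

`generate_cohort()` draws latent Big Five traits from a multivariate normal
on the 1–5 scale (clamped; defaults in `trait_config_default()`: means
3.3–3.7, SDs 0.5–0.6, modest positive correlations among O, C, E, A and a
mild negative one with N, as in young-adult community samples), plus a
nonnegative antisociality latent on the 0–2 per-item scale, anticorrelated
with agreeableness and conscientiousness and located so that roughly 15% of
a cohort screens above the 12-point cutoff.

The central generator feature is the **coupling** contract: a requested
trait–index correlation is realized, in expectation, in a default low-cost
session. The produce signal is $S = w'z + e$ with standardized traits $z$
and an agent-level preference $e \sim N(0, \sigma_b^2)$ unrelated to
personality. Given target correlations $c$ and the inter-trait correlation
matrix $R$, the weights solve $\mathrm{corr}(z, S) = c/\lambda$ in closed
form ($w = \beta R^{-1} u$, $u = c/\lambda$,
$\beta = \sigma_b / \sqrt{1 - u'R^{-1}u}$; infeasible combinations with
$u'R^{-1}u \ge 1$ are rejected). The attenuation $\lambda = 0.72$ between
the signal and the *realized* index — which loses signal to search
stochasticity, group interaction and the roughly 19-response count ceiling —
was estimated once by Monte Carlo (30 cohorts of 200 agents) and frozen.
With it, a requested agreeableness coupling of 0.45 is recovered at
$0.44$–$0.45$ on average, both at $n = 200$ and at the study-sized
$n = 38$.

Because $\lambda$ is calibrated under the *low-cost* condition, couplings
are promises about that condition; under high cost the expressed correlation
is attenuated further — which is itself the ecological effect the package
exists to study.

## Questionnaire generation

`generate_questionnaires()` inverts the scoring step so round trips are
testable: each item is `clamp(round(latent + noise))` on its scale, with
reverse-keyed items stored inverted so scoring recovers the latent. At
`noise_sd = 0` the generator is deterministic and emits the floor/ceiling
mix whose mean is the nearest $1/k$ grid point to the latent, making the
noise-free round trip exact on that grid. The default `noise_sd = 0.7`
(response-scale points) leaves scored-vs-latent correlations near 0.95,
typical of a well-behaved self-report scale.

What the generator does *not* emulate: acquiescence and social-desirability
response styles, item-specific difficulty, within-session learning, fatigue
or motivation loss, or players communicating. Passing recovery tests on
synthetic cohorts therefore establishes that the *pipeline* is unbiased and
calibrated, not that real questionnaire data are this clean.

# Scoring

Item-to-scale keys are instrument metadata, not study output, so they ship
as editable CSVs (`inst/extdata/bfi_key.csv`, `apsd_key.csv`) following the
standard published Big Five Inventory key and the three-factor screen
structure (callous–unemotional, impulsivity, narcissism; two items load on
no factor and count toward the total only). Users of a divergent translation
can point `read_scoring_key()` at their own file.

Choices worth stating:

* Trait scores are item *means* (1–5), reverse-keying as $6 - x$; factor
  scores of the antisociality screen are *sums*, so the total is comparable
  with the published 12-of-40 cutoff (a per-item-mean option exists for
  correlation work).
* Stability is $\mathrm{mean}(C, A, 6 - N)$: on averaged 1–5 scores,
  $6 - N$ is the only involution consistent with "emotional stability as
  inverse neuroticism". Plasticity is $\mathrm{mean}(E, O)$.
* A total of exactly 12 classifies *above* the cutoff (threshold-inclusive
  reading of a screening cutoff); the threshold is an argument.
* Participants with missing or out-of-range responses are excluded and
  logged, mirroring incomplete-questionnaire exclusion in human studies;
  nothing is imputed.
* For externally deposited data whose neuroticism may be stored already
  reversed, `complete_scores()` exposes a `neuroticism_direction` flag
  rather than guessing.

# The statistical pipeline

`run_full_analysis()` reproduces the standard report: condition comparison,
cutoff-group comparison, 13-variable correlation matrix, bootstrap CIs.

* **Routing.** Shapiro–Wilk per variable per condition; any departure (or a
  constant sample) routes that variable to the rank-based branch. The
  parametric branch (paired/Welch t) exists and is labeled in the output,
  but on realistic foraging counts the gate essentially always selects the
  rank tests.
* **Wilcoxon signed-rank.** Zero differences dropped; tie-corrected
  variance; *no* continuity correction — so the reported $z$ can differ in
  the second decimal from implementations that apply one. Effect size is
  the matched-pairs rank-biserial $r_{pb} = (W^+ - W^-)/(W^+ + W^-)$.
  For $n \le 12$ nonzero pairs the p-value is exact, from full enumeration
  of the $2^n$ sign patterns of the observed ranks (valid under ties).
* **Mann–Whitney U.** Both orientations are reported (published tables mix
  the two conventions); the under-cutoff group is first. For
  $n_1 n_2 \le 400$ the p-value is exact: the permutation distribution of
  the rank sum over all $\binom{N}{n_1}$ subsets, computed by dynamic
  programming over doubled midranks (ties handled; subset counts stay below
  $2^{53}$, so double-precision counting is exact). Beyond that, the
  tie-corrected normal approximation without continuity correction.
* **Correlations.** Pearson $r$ with two-sided p from the t transform,
  pairwise-complete, star tiers at 0.05/0.01/0.001. Signed $r$ is primary
  and $r^2$ derived. No multiplicity correction is applied — matching how
  such matrices are conventionally reported — and the report states its
  uncorrected cell count (78) instead.
* **Bootstrap.** Case resampling (paired rows jointly), percentile interval
  by default, BCa behind a flag, deterministic under the seed. Resamples on
  which the statistic is undefined are tolerated to 10% and dropped; more
  than that errors, since the interval would no longer describe the
  intended statistic. In coverage simulations at $n = 38$ against a planted
  correlation of 0.45, the percentile interval covers truth about 93–95% of
  the time.
* **Exclusions.** Listwise for comparisons, pairwise for correlations;
  every excluded participant appears with a reason in the report metadata,
  and undefined producer's indexes ($p + s = 0$) stay `NA` rather than
  being imputed as 0, which would bias medians.

# Problem sizes in the test suite

The packaged checks run at sizes chosen to give stable Monte-Carlo
estimates while staying comfortable on a single CPU: 1,000 random event
logs against the brute-force tally oracle; exhaustive enumeration of every
Mann–Whitney instance with $n_1 n_2 \le 36$ and every signed-rank instance
with $n \le 8$; 1,000 null replicates per test for type-I calibration
(acceptance band 2–8% at $\alpha = 0.05$); 50 seeded session pairs for
magnitude realism; 100 replicate studies at $n = 38$ for coupling recovery
and CI coverage ($B = 1000$); 200 replicate null studies for the star-rate
calibration of the correlation matrix (counted over the 22 index–trait
cells, the cells that are actually null by construction — trait–trait and
trait–screen cells have true correlations under the default generator).

# Known limitations

* The simulator's decision rule is a stationary softmax: no learning within
  or across sessions, no spatial strategy, no imitation or communication.
* The coupling calibration constant is tied to the default low-cost
  condition; substantially different ecologies (longer sessions, other
  group sizes) shift $\lambda$ and would need recalibration for exact
  recovery.
* Timing constants unavailable from the task description (travel, collect,
  join window, decision pause) are documented defaults, not inferred task
  values; conclusions that depend on their exact values should be checked
  by sensitivity analysis (`gft_condition()` makes every constant a
  parameter).
* The analysis pipeline reports uncorrected p-values by design; users who
  need family-wise control should apply `p.adjust` to the tidied tables.
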