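# psforage

Tools for studying the **producer–scrounger (P-S) game** in human social
foraging. In a group foraging task, each player continually chooses between
*producing* — searching for food at some time cost, with probabilistic
success — and *scrounging* — joining another player's discovery and taking
part of it. `psforage` packages everything needed to study how ecology and
personality shape that choice:

* a **discrete-event agent-based simulator** of a four-player virtual
  foraging task (patch zones, costly probabilistic searches, joinable
  discoveries), doubling as a synthetic-data generator with controllable
  ground truth: trait–strategy couplings, questionnaire noise, antisociality
  rates;
* the **rate-maximization model** of the equilibrium producer proportion,

  $$P = \frac{a}{F} + \frac{1}{G} \qquad\text{and}\qquad
    P = \frac{a/t}{F} + \frac{1}{G},$$

  where $a$ is the finder's share, $F$ the food per patch, $G$ the group
  size and $t$ the time cost of producing;
* the **producer's index**
  $(p - s)/(p + s)$ over producer responses $p$ and scrounger responses $s$,
  ranging from $-1$ (pure scrounger) to $1$ (pure producer);
* **psychometric scoring**: the 44-item Big Five Inventory (trait means with
  reverse-keying), the stability and plasticity metatraits
  (mean of C, A, inverse N; mean of E, O), and the 20-item Antisocial
  Process Screening Device with its three factors and 12-point cutoff;
* the full **nonparametric analysis pipeline**: Shapiro–Wilk routing,
  Wilcoxon signed-rank (tie-corrected $z$, matched-pairs rank-biserial
  $r_{pb}$, exact enumeration for small $n$), Mann–Whitney $U$ (both
  orientations, exact permutation distribution via the shift algorithm),
  a 13-variable Pearson correlation matrix with star tiers, and
  case-resampling bootstrap confidence intervals (percentile or BCa).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted reports, `autoplot()` for each result type.

## Worked example

Simulate a 40-person study in which agreeableness is coupled to producing at
$r = 0.45$, score the questionnaires, and run the full analysis:

```r
library(psforage)

cohort  <- generate_cohort(40, coupling = c(A = 0.45), seed = 2026)
dataset <- run_experiment(cohort, seed = 2026)   # F5-0s and F5-8s conditions
scores  <- score_instruments(dataset$items)
report  <- run_full_analysis(dataset$foraging_summary, scores, B = 1000, seed = 2026)
report
```

```
<ps_analysis>  n = 40 analyzed (40 in, 0 excluded), conditions F5-0s vs F5-8s

Condition comparison (F5-0s vs F5-8s):
            variable  n    m1   sd1   mdn1    m2   sd2 mdn2
      producer_index 39  0.83 0.208  0.905 0.741 0.574    1
  producer_responses 40 18.60 4.361 20.000 4.000 2.428    4
 scrounger_responses 40  1.52 1.519  1.000 0.325 0.616    0
               method statistic  p_value effect stars
 wilcoxon signed-rank     0.165 8.69e-01  0.037
 wilcoxon signed-rank     5.520 3.39e-08  1.000   ***
 wilcoxon signed-rank     4.267 1.98e-05  0.963   ***
...
```

Producer responses collapse from a median of 20 under near-free searching to
4 when each search costs 8 s — the qualitative prediction of the
cost-discounted rate-maximization model (`rmm_producer_proportion_cost(1, 5, 4, 8)`
gives $P = 0.275$ against $0.45$ at $t = 1$). The planted coupling is
recovered where the ecology lets agents express their preference, and only
there:

```r
ct <- tidy(report, "correlations")
ct[ct$var2 == "A" & grepl("producer_index", ct$var1), ]
#>                   var1 var2     r     r_squared  p_value stars  n
#> 1 producer_index.F5-0s    A 0.407     0.165     0.00923    **  40
#> 2 producer_index.F5-8s    A 0.236     0.056     0.14776        39

tidy(report, "bootstrap") |> dplyr::filter(trait == "A")
#>   condition trait estimate lower upper   (95% percentile, B = 1000)
#> 1     F5-0s     A    0.407 0.182 0.628
#> 2     F5-8s     A    0.236 0.047 0.423
```

`autoplot(report, type = "conditions")`, `"correlations"`, `"cutoff"` and
`"bootstrap"` draw the corresponding figures; `write_report(report, dir)`
emits the tables as CSV plus a markdown rendering and a run log.

External per-participant data (e.g. a spreadsheet export with its own
column names) enter through `read_dataset(..., column_map = ...)`; raw item
responses or pre-scored traits are both accepted, and out-of-range rows are
excluded with logged reasons, never silently.

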