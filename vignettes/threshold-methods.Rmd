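---
title: "Detection and rejection thresholds from forced-choice ascending panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and rejection thresholds from forced-choice ascending panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshpanel)
library(dplyr)
```

## The problem

Odorants such as rotundone — the sesquiterpene behind the peppery note of
some red wines — show enormous individual variation in detectability,
including a *specific anosmia*: a sizeable minority of consumers cannot
smell the compound at any realistic concentration while their olfaction is
otherwise normal. Panel studies of such compounds present every panelist
with the same fixed ascending ladder of spiked samples and a forced-choice
task at each step: a triangle test (one spiked sample among three, guessing
rate 1/3) for detection, or a paired preference (2AFC, guessing rate 1/2)
for acceptability. `threshpanel` implements the full analysis chain for
this design: per-panelist best estimate thresholds (BETs), group summaries
and comparisons, the graphical group-threshold method, consistency-gated
consumer rejection thresholds, and a seeded generator of synthetic panels
with the same psychophysical structure.

All concentrations are in ng/L and every logarithm in the package is base
10. Ladders are typically decade-spaced, so base 10 keeps slopes readable;
the base only rescales slopes and never moves a threshold.

## Individual BETs: the three-branch decision rule

For one panelist with ordered outcomes on a ladder $c_1 < \dots < c_m$:

1. **Standard rule.** If the top-level answer is correct, find the lowest
   level $L$ with all answers at $L$ and above correct. The BET is
   $\sqrt{c_L \cdot c_{L-1}}$, with $c_0 = c_1 / r_{\text{low}}$ (the
   hypothetical level one local step below the ladder) when $L = 1$.
2. **Adaptation rule.** Otherwise, a run of at least three consecutive
   correct answers ending strictly below a later incorrect answer is taken
   as evidence of real sensitivity — three in a row by chance has
   probability $(1/3)^3 \approx 3.7\%$ — with the higher-level misses
   attributed to adaptation (temporary desensitisation after exposure).
   The BET is the geometric mean of the run's starting concentration and
   the level below it. If several runs qualify, the package uses the run
   with the *lowest* starting concentration: the most conservative
   sensitivity claim consistent with anchoring the estimate at the start
   of a run. Runs longer than three qualify as well, since the chance
   argument only gets stronger with length.
3. **Non-responder imputation.** Otherwise the panelist is counted
   anosmic. For display purposes only, a BET is imputed as the geometric
   mean of the top level and the theoretical next level above
   ($c_{m+1} = c_m \cdot r_{\text{high}}$); imputed values never enter
   means or tests.

Branch order matters: the standard rule is tried first and the adaptation
rule only when the top-level answer is wrong. Ladder extensions use the
*local* step ratio between the two adjacent extreme levels, so a mixed-step
ladder such as 3.75–750 ng/L extends by its own end spacing (×2) rather
than a global fitted ratio.

The group threshold over responders is the geometric mean of their BETs
(antilog of the mean of logs); conditions are compared with a
pooled-variance two-sample t-test on the logged responder BETs, giving
$n_a + n_b - 2$ degrees of freedom. Pooling (rather than Welch) is the
package's default because it is the textbook companion of the method and
keeps the degrees of freedom exact and interpretable.

```{r bet-example}
ladder <- concentration_series(c(0.2, 2, 20, 200, 2000))
classify_and_estimate(c(FALSE, TRUE, TRUE, TRUE, FALSE), ladder)
```

## The graphical group threshold

Each outcome is coded 0/1 and an unweighted ordinary least-squares line is
fitted to the individual codes against $\log_{10} c$. The group threshold
is the antilog of the concentration where the line crosses the
chance-adjusted criterion $(1 + p_{\text{chance}})/2$ — 2/3 for the
triangle test, i.e. performance halfway between chance and perfect. The
package deliberately fits a straight line to the binary codes, not a
logistic curve: fidelity to the published graphical method is the point,
and for balanced complete panels the individual-code fit is identical to a
per-level proportion fit weighted by per-level $n$ (a tested invariant).

**Confidence bounds** are computed by inverse prediction: the two
concentrations where the pointwise $(1-\alpha)$ confidence band for the
regression mean crosses the criterion, obtained in closed form; this is
algebraically Fieller's interval for $(\text{criterion} -
\text{intercept})/\text{slope}$. Published studies using this method
report bounds without stating a construction, so these bounds are
validated by their statistical behaviour (they bracket the estimate and
tighten with data), not against any printed pair of numbers.

**Definedness.** A non-positive slope — the signature of an anosmic group
flat at chance — yields an undefined threshold with a warning rather than
an error. When the slope is positive but the crossing falls outside the
tested range, a two-tier rule applies: within one local ladder step beyond
the range the threshold is reported with an `extrapolated` flag; beyond
that guard it is undefined. The guard exists because a near-flat line
crosses any criterion *somewhere*, and reporting a crossing ten decades
above the ladder as a "threshold" would be meaningless. The same guard is
shared with the rejection module.

## Consistency-gated rejection thresholds

Preference data are gated before fitting: a panelist is a *consistent
preferer* (all top-3 choices spike) or *consistent rejecter* (all top-3
blank), anything mixed a non-responder. The gate exploits that three
identical choices arise by chance with probability $(1/2)^3 = 12.5\%$ per
direction — 25% for either direction; both variants are exposed by
`chance_consistency_probability()`, and the per-direction 12.5% is the
figure usually quoted.

The rejection regression reuses the 0/1 OLS machinery with spike coded 1:
a negative-slope line crossing 0.25 gives the rejection threshold (the
concentration where the group prefers the blank three times out of four);
a positive-slope line crossing 0.75 would give a group preference
threshold. The 0.25/0.75 criteria are parameters, not constants.
`segment_report()` fits the all-consistent and rejecters-only segments and
reports the preferers-only segment descriptively (per-level spike
proportions) without a threshold when it has fewer than 10 members — a
handful of panelists cannot support a crossing estimate, and the
polarisation itself (a small segment preferring the spike at every high
level) is the finding worth reporting.

## The synthetic panel generator

No raw per-panelist response data are publicly available for studies of
this design, so the package ships a generator that emulates their
psychophysical structure and makes every stage testable end to end:

* **Population.** Each panelist is anosmic with probability
  `anosmic_fraction` (default 0.40, the rough share reported for
  rotundone); otherwise their log10 threshold is normal with median
  `threshold_median` (default 50 ng/L, between the reported orthonasal and
  retronasal group geometric means) and SD `threshold_log_sd` (default 1
  decade — individual BETs in such studies span the whole 4-decade
  ladder).
* **Detection.** A logistic function of $\log_{10} c$ centred at the
  individual threshold with slope `psychometric_slope` (default 3 per
  decade, a moderately steep transition of roughly one ladder step);
  logistic rather than any other sigmoid because it inverts in closed
  form for recovery tests.
* **Task model.** Pure high-threshold guessing: a true detection always
  yields a correct triangle answer; otherwise the panelist guesses at
  `chance_level`. Guessing carries no partial information — this matches
  the chance-correction arithmetic (1/3 floor, 2/3 criterion) that the
  downstream analyses assume.
* **Adaptation.** After a true detection, the detection probability at the
  next level is multiplied by `adaptation_carryover` (default 0.85, a mild
  one-step carryover consistent with adaptation affecting a handful of
  panelists out of a hundred; no study reports a magnitude, so this is a
  package calibration choice). Setting it to 1 disables adaptation; low
  values produce the characteristic correct-run-then-miss patterns that
  trip the BET adaptation branch.
* **Preference.** $P(\text{choose spike}) = 1/2 + d \cdot \tfrac12
  p_{\text{detect}}$ with direction $d = \pm 1$ drawn with
  `preferer_fraction` (default 0.25, the reported minority share):
  polarisation appears exactly when the compound becomes perceptible, with
  no separate liking-magnitude parameter.

Sub-streams are seeded as `seed`, `seed + 1`, `seed + 2` for subjects,
triangle and preference draws, so the same subjects can be pushed through
both tasks reproducibly.

What the generator does *not* emulate: serving-order and positional
biases, replicate triads, intensity ratings, taste/chemesthetic
contributions in by-mouth tasting, and inverted-U (like-low, reject-high)
preference shapes. Tests passing on synthetic panels therefore validate
the estimators under the stated psychophysical model, not the full
messiness of real panels.

## Known estimator behaviour, measured by the test suite

Two properties of the chain are worth stating plainly; both are computed,
not assumed, by the acceptance checks:

* **Chance inflation of the responder count.** A latent anosmic guessing
  at 1/3 is classified a responder with probability 0.374 (exactly, by
  enumerating all 32 outcome patterns: a lucky top-level answer, or a
  chance run of three). A panel with 40% latent anosmia therefore shows a
  *classified* responder fraction near 0.71, not 0.60 — the classified
  anosmic share understates latent anosmia. Conversely, an observed
  responder share of ~60% is consistent with well over half the panel
  being latent non-detectors.
* **ASTM below graphical under adaptation.** With strong adaptation
  carryover (≤ 0.3) the ASTM geometric-mean estimate falls below the
  graphical estimate in essentially all simulated replicates, because the
  adaptation branch anchors BETs at the start of low-concentration runs
  while the graphical line pools all levels. The unweighted OLS line is
  itself biased low (recovery ratio ≈ 0.75 in the simulated conditions)
  when the true threshold sits above the ladder midpoint, since the
  chance floor at the low levels drags the fitted line.

## Problem sizes and numerical choices

Simulation-based checks use panels of 200 (recovery), 56 (estimator
ordering, 50 replicates) and 10,000 (gating calibration and chance-rate
checks, binomial 3-SD tolerances); recovery and ordering statements are
medians/fractions over fixed replicate seeds rather than single draws, so
they measure estimator behaviour, not seed luck. Crossings are solved in
closed form; the theoretical group-curve crossing uses `uniroot` at
tolerance 1e-10 over a bracket wide enough to saturate the logistic. Ties
and degenerate inputs (saturated groups, flat groups, empty segments,
zero responders) return flagged results rather than errors wherever a
real panel could produce them.

## Worked end-to-end example

```{r pipeline}
cfg_o <- panel_sim_config(n_panelists = 56, seed = 101)
cfg_r <- panel_sim_config(n_panelists = 53, seed = 102)
tri_o <- simulate_triangle(draw_subjects(cfg_o), cfg_o, condition = "orthonasal")
tri_r <- simulate_triangle(draw_subjects(cfg_r), cfg_r, condition = "retronasal")
report <- run_study1(tri_o, tri_r)
report
```

```{r rejection}
cfg_p <- panel_sim_config(n_panelists = 86,
                          series = concentration_series(c(3.75, 7.5, 37.5, 75, 375, 750)),
                          threshold_median = 50, psychometric_slope = 3,
                          seed = 103)
seg <- segment_report(simulate_preference(draw_subjects(cfg_p), cfg_p))
seg$counts
glance(seg$fit_rejecters)
```

## Limitations

The unweighted-OLS graphical method is kept as published rather than
replaced by logistic regression, with the documented low bias; the
confidence-bound construction is a standard calibration interval but not
guaranteed to match any particular published pair of bounds; the BET
adaptation branch is a heuristic whose tie-breaks (lowest qualifying run)
are package decisions; and rejection thresholds by design cannot express
inverted-U preference patterns.
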