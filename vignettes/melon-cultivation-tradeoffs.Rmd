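---
title: "Quality-yield-water trade-offs in hydroponic melon cultivation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-yield-water trade-offs in hydroponic melon cultivation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melonopt)
library(dplyr)
```

## The problem

A hydroponic netted-melon (*Cucumis melo* L.) grower chooses a cultivar, a
coir-slab substrate volume and a planting density. These choices pull
against each other: denser planting raises areal yield but dilutes
per-fruit photosynthate (lower weight and sugar); restricting the root zone
(10 L slabs instead of the 20 L standard) imposes mild water stress that
concentrates assimilates in the fruit — higher soluble solids (Brix) and
better water productivity — while cutting substrate cost. No single
combination wins on every axis, so the analysis treats strategy selection
as a finite multi-objective optimization: score every treatment on quality,
yield and water productivity, and report the non-dominated (Pareto) set.

`melonopt` implements this analysis for a 3 cultivar ('Dalgona', 'Hero',
'Kingstar') x 2 substrate volume (10/20 L per slab) x 2 density (3/4
plants per slab) factorial laid out as a randomized complete block design
(RCBD) with three blocks, and ships a calibrated synthetic generator that
stands in for the raw per-fruit data, which are not deposited.

## Core quantities

**Water productivity.** WP = Y / V_ir, total fruit yield (kg/10a, with
10 a = 1,000 m^2) over irrigation water supplied (m^3/10a). Per-treatment
irrigation volumes are never tabulated directly; they are recovered as
V_ir = Y / WP from the summary table, and `water_productivity()` inverts
that identity exactly (`irrigation_volumes()`).

**Grading.** Fruits are graded Premium / Superior / Medium / Inferior
either by Brix (cuts at 14, 12, 10 °Bx, lower-closed: 14.0 is Premium) or
by the panel netting score (1 = excellent ... 5 = bad, rounded to the
nearest step and mapped 1/2/3/>=4 to the four tiers). The netting tier map
is a package default, configurable in `net_grade()`; only the 1-5 scale
itself is fixed by the panel protocol.

**Quality score.** Sugar is min-max normalized to 0-100,
n = (x - min)/(max - min) * 100; panel netting is reverse-normalized
(lower is better), n = (max - x)/(max - min) * 100; the composite is
alpha * sugar + beta * netting with channel weights 0.7/0.3 (premium
market) or 0.8/0.2 (public market). For treatment-level scores the bounds
are the range of the *treatment means* across the whole trial, jointly for
all treatments, so the treatment holding both maxima scores exactly 100.
The source analysis never spells out how its printed composite values were
produced; this definition (normalize treatment means, premium-channel
weights) is the package's documented choice, and printed composites are
not treated as reproducible anchors.

**Economics.** Revenue = sum over tiers of production (kg/10a) x wholesale
price (USD/kg, mean/min/max per tier); production is split across tiers by
the fruit-level grade distribution. Net profit = revenue - total cost;
ROI = 100 x net profit / cost. Two interpretive choices are worth flagging.
First, tier prices are read as USD per kg: the one fully printed
revenue/yield pair (29,127 USD over 4,339 kg) implies 6.71 USD/kg, between
the Superior and Premium tier means, which is consistent with per-kg
mixed-grade pricing and not with per-fruit pricing. Second, ROI is based on
total cost, the only definition consistent with the printed
(revenue, profit, ROI) triple (29,127; 21,213; 268.0%).

**Pareto frontier.** With all objectives oriented to "larger is better"
(minimize-sense columns are negated, never reciprocated), treatment a
dominates b iff a >= b in every objective and a > b in at least one.
The frontier is the non-dominated subset. With 12 candidates an exhaustive
all-pairs scan is the reference implementation; ties (identical objective
vectors) all stay on the frontier, since strict dominance cannot hold
between equals. Dominance is invariant under any strictly increasing
per-column transform, so the frontier is the same on raw values and on
0-100 normalized scores — the tests assert this.

## The synthetic generator and its calibration

The raw trial data are unavailable, so `simulate_trial()` generates
per-fruit records: treatment mean + block effect + independent Gaussian
residual per response (weight, Brix, net score, length, diameter, flesh
thickness), fruit counts allocated to blocks as evenly as possible, and
net scores clamped to the 1-5 panel scale (generated continuous by
default, because the panel's treatment means are non-integer).

The treatment-mean surface is taken from the packaged calibration table
(`load_fixture("trial_calibration")`) and decomposed into grand mean +
main effects + interaction remainder, so `implied_means()` reproduces the
table exactly. Where the calibration values come from:

* Fruit dimensions, flesh thickness and panel net means are the published
  per-treatment values.
* Mean fruit weights follow from the published yields: yield per 10 a
  equals mean fruit weight x projected plants per 10 a (one fruit per
  plant), and the two published weight anchors (Kingstar 10 L: 1.68 and
  1.40 kg) confirm the identity. Weights are stored at 2 decimals.
* Mean Brix is anchored at the published extremes (Dalgona 10 L/3 plants
  peak of 14.5 °Bx; Kingstar 20 L near 10.2-10.4 °Bx); the remaining cells
  are calibration choices respecting the reported orderings (cultivar
  ranking, 10 L above 20 L, weak density effect). They are synthetic, not
  measurements.
* Irrigation volumes are Y/WP per treatment, so the generator's data
  reproduce the tabulated water productivity exactly.

Residual standard deviations are free generator parameters — the trial
reports no within-treatment variances. Defaults (weight 0.12 kg, Brix
0.6 °Bx, net 0.15, length 0.5 cm, diameter 0.4 cm, flesh 1.8 mm) are
plausible magnitudes for glasshouse melon fruit. The net-score sd is
deliberately small: the published panel means sit in a tight 1.2-1.6 band
with no significant treatment separation, and a small sd also keeps the
[1,5] clamp's truncation bias (about 0.006 at sd 0.15) negligible against
simulation error, so the generator's means stay honest.

What the generator does *not* emulate: correlations between responses
(each is drawn independently; real fruit weight and diameter are strongly
correlated), non-Gaussian tails, block-by-treatment interaction, and any
physiological mechanism (the root-restriction effect exists here only as
calibrated mean differences). Passing tests therefore demonstrate that the
pipeline recovers the structure this generator injects — not that the
published trial would be recovered from its real raw data. One visible
consequence: with mean 14.0-14.5 °Bx and sd 0.6, some simulated Dalgona
10 L fruits fall below the 14 °Bx premium cut, whereas the publication
reports all such fruits as premium; simulated grade shares are
approximations, and nothing downstream treats them as printed anchors.

The default fruit count is 42 per treatment with 41 in the last (503
total, matching the reported destructive-measurement count; the figure
caption's n = 500 is an unresolved source discrepancy we carry as-is). The
default seed 20200129 is the sowing date written as yyyymmdd — a
documented constant only.

## Statistical reporting

`three_way_anova()` runs the classical balanced fixed-effects
decomposition (via `stats::aov`) for C, S, D and their interactions, F
against the residual mean square, stars at 0.05/0.01/0.001. It refuses
unbalanced input rather than silently switching to Type-II/III sums of
squares; the pipeline aggregates fruits (subsamples) to block-level cell
means first, which keeps the design balanced even with the 503rd fruit
missing and matches how subsampled RCBD data are conventionally analysed.
Blocks are not modelled as random effects (out of scope).

`tukey_hsd()` takes pairwise decisions from the studentized range
(`stats::TukeyHSD`) and assigns compact letters by greedy insert-absorb,
ordered so "a" marks the highest mean; two groups share no letter iff
their difference is significant — the suite property-tests exactly this.
Letters can be scoped per trial (all 12 treatments in one family, the
summary-table convention) or per cultivar (the figure convention);
`run_config(letter_scope=)` selects one.

Pearson correlations across the 12 treatment summaries are descriptive; no
p-values are attached at n = 12. A constant metric yields NA entries with
a warning, never a silent zero. The six-metric performance matrix (quality
score, yield, WP, ROI, flesh thickness, fruit weight) reuses the same
min-max normalization as the Pareto stage, all columns maximize-sense;
degenerate (constant) columns normalize to 0 with a warning.

## Numerical conventions and degenerate inputs

* Internal computation is at full precision; rounding (yields to whole kg,
  WP/percentages to 1 decimal, plant counts to integers) happens only at
  reporting time. Acceptance-style reproductions round exactly once, at
  the end.
* Planting distances printed as truncated decimals are stored as exact
  fractions (33.3 cm is 100/3 cm); only the exact fraction reproduces the
  planned 2,000 plants/10a, so exactness is the rule
  (`load_fixture("table4")` carries numerator/denominator columns).
* Normalization with max = min raises an error in scalar use and maps to 0
  with a warning in matrix contexts; observations outside the stated
  bounds are clamped with a warning.
* Tier intervals are closed at the lower Brix bound (14.0 -> Premium).
* The cost fixture reproduces the published system-average costs
  (7,198 and 8,222 USD/10a) from the published substrate and fertilizer
  components, a per-seedling cost of 0.98 USD x plants/10a (which yields
  the published 33.3% seedling-cost step, the exact plants-per-10a ratio),
  and a single fixed+other bucket of 3,130.2 USD/10a for the components
  only shown graphically. Labor/maintenance/energy are carried as explicit
  zero columns rather than guessed splits.

## Problem sizes in the test suite

The suite runs in well under a minute on one CPU: Pareto oracle
equivalence up to 200 candidates x 6 objectives against a brute-force
all-pairs oracle; ANOVA against a direct cell-means sums-of-squares oracle
at 5-6 fruits per cell; Tukey decisions against direct `ptukey`
computation; generator mean-recovery at 200 and at 834 fruits per
treatment (about 10,000 fruits), requiring 95% of treatment x response
cells within 3 standard errors.

## Known limitations

* Quality-score composites printed in the source cannot be reproduced
  exactly (their construction is unspecified); the package's definition is
  internally consistent and spans 0-100 by construction.
* Per-treatment revenues other than the two printed examples are
  demonstration outputs of the pricing model, not validated values.
* The generator's independence and normality assumptions make simulated
  grade-share distributions approximate (see above).
* Single-season, single-site price and cost tables; no discounting,
  amortization or price forecasting.
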