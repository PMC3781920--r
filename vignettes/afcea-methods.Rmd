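---
title: "Model and methods behind afcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind afcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcea)
```

## The decision problem

Patients with paroxysmal atrial fibrillation (AF) who have failed a first
antiarrhythmic drug can either be switched to amiodarone (200 mg/day) or
offered catheter ablation of the pulmonary veins. Ablation is more likely
to restore and maintain normal sinus rhythm (NSR), which carries a lower
ischemic-stroke risk and a better quality of life, but it has a large
upfront cost and procedural risks. Amiodarone is cheap but less effective
and exposes patients to pulmonary toxicity. `afcea` implements the
published Canadian cost-effectiveness comparison of these two strategies as
a reusable, tested model: a one-year treatment phase chained into a
three-month-cycle Markov cohort model, evaluated from the perspective of a
publicly funded health system in 2010 Canadian dollars.

The basecase cohort is 65-year-old males with a CHADS$_2$ score of 2 and
44% long-term warfarin use; the basecase horizon is five years (chosen
because the underlying trials ran for twelve months), discounted at 5% per
year.

## Model structure

**First year.** The rhythm outcome at twelve months comes from trial
evidence: the probability of NSR on amiodarone is the random-effects pooled
proportion of five trial arms (0.258; see below), and the ablation-arm
probability applies the published relative risk of 2.93, giving
$2.93 \times 0.258 = 0.756$. Ablation patients additionally face
per-procedure complication risks (stroke 0.003, TIA 0.002, tamponade
0.008, pulmonary-vein stenosis 0.016), scaled by the mean 1.27 procedures
per patient; procedural strokes enter the permanent post-stroke state,
non-stroke complications cost their unit price plus seven days of full
disutility. Drug-arm patients face an annual pulmonary-toxicity
probability of 0.00832 (derived from a cumulative 1.9% over 27.54 months),
fatal with probability 0.091, irreversible (utility weight 0.6, $3,799 per
year thereafter) in 25% of survivors.

Rather than a separate decision-tree computation, the first year is run
*as the first four cycles of the Markov engine* with strategy overlays:
procedure and follow-up costs at cycle 0, the twelve-month rhythm split
applied as the entry distribution, and NSR-to-AF recurrence suppressed
until the rhythm outcome is resolved at one year. This keeps stroke,
bleeding and background mortality risk alive during year 1 — without it,
five-year stroke counts cannot reach the published magnitude.

**Markov phase.** States are NSR, AF, post-ischemic-stroke (a four-cycle
first-year tunnel, then a chronic state), post-intracranial-haemorrhage
(same shape), and dead; a parallel set of "irreversible pulmonary
toxicity" copies of every living state carries the 0.6 utility overlay and
the annual toxicity cost. Per cycle, rhythm-state occupants face:

* ischemic stroke at the CHADS$_2$ annual probability (0.04 at score 2) in
  AF, reduced by $1/1.6 = 0.625$ in NSR;
* major bleeding at 0.0129/year on warfarin (0.0058 divided by the
  placebo-versus-warfarin risk ratio 0.45) and 0.0058/year off it, with
  33.2% of major bleeds intracranial (the rest gastrointestinal: a $6,023
  cost without change of state);
* NSR-to-AF recurrence at 0.036/year (ablation) or 0.221/year (drug arm);
  ablation patients who recur switch to amiodarone, its toxicity hazard,
  and (by default) warfarin at the cohort proportion;
* background mortality from the life table; post-event states instead use
  28-to-30-day case fatality scaled to one year (ischemic $\times 1.78$,
  ICH $\times 1.2$) in the tunnel and population mortality $\times 2.3$
  (ischemic) or $\times 1$ (ICH) afterwards.

Ablation patients stop warfarin after one cycle (three months); drug-arm
patients keep the cohort's 44% warfarin use throughout. Amiodarone and
warfarin costs attach to NSR and AF occupants per arm and phase; stroke
states carry event costs and utilities only.

## Evidence synthesis

The pooled NSR proportion uses DerSimonian–Laird random effects on
*untransformed* proportions with binomial within-study variance
$p(1-p)/n$. The scale was chosen because it is the only standard choice
that reproduces both the published pooled value (0.26, 95% CI 0.17–0.34)
and every published study weight (15.5/22.4/27.6/8.8/25.7%); a logit-scale
pooling does not. The implementation is the package's own
(`pool_proportions()`), cross-checked in the tests against `metafor`'s
DL estimator to 10 decimal places. Boundary event counts use a
$(x+0.5)/(n+1)$ continuity rule, which the shipped table never triggers.

The pooled estimate is carried in the basecase at three decimals (0.258):
the published derivation chain ($2.93 \times 0.26$ printed as 0.756) is
only arithmetically consistent with the unrounded estimate, not with the
two-decimal display value.

## External tables and what the synthetic stand-ins do (and do not) show

Three inputs of the original analysis are not published: national life
tables, age/sex-specific 28-to-30-day case fatality after stroke and ICH,
and age/sex population utility norms. The package generates deterministic
parametric stand-ins:

* `make_life_table()` — Gompertz–Makeham hazard
  $\mu(a) = c + A e^{b a}$ with a female hazard ratio of 0.65, tuned so a
  65-year-old male has an annual death probability of about 0.015 and a
  five-year survival of about 0.92 — the magnitude of recent Canadian
  period life tables;
* `make_event_mortality_table()` — case fatality rising with age on the
  log-odds scale, anchored at the published cohort-level figures (0.189
  ischemic, 0.48 ICH) at the cohort's mean age;
* `make_utility_table()` — utility linear in age, 0.83 at 65, falling
  0.03 per decade, clamped to $[0,1]$.

The stand-ins are deterministic curves, not random draws, so every
acceptance quantity is exactly reproducible. They emulate the *shape* the
model assumes (monotone mortality, non-increasing utility) but not the
banded, cause-specific detail of the real sources; results that depend on
the absolute level of these inputs (the headline ratio, the sensitivity
grid's absolute dollar values) therefore carry a band of fixture error,
while results driven by printed parameters (derived probabilities,
orderings, distribution calibration) do not. Real tables can be dropped in
via `read_life_table()` and friends using a plain `age, sex, value`
delimited schema.

## Numerical and structural choices

* **Rate conversions** use constant-hazard compounding,
  $p_{cycle} = 1-(1-p_{year})^{t}$, not division by four; the inverse
  round-trips to machine precision and recompounding recovers the annual
  probability within $10^{-9}$.
* **Within-cycle event order** is death, stroke, bleed, toxicity/rhythm,
  composed sequentially so each transition row sums to one by
  construction; ordering effects at three-month probabilities are below
  $10^{-3}$ and the composition is validated against a 10,000-individual
  microsimulation using the same per-cycle rows.
* **First-year event costs** ($61,413 ischemic, $58,159 ICH) are applied
  as a one-off at the event. The alternative — spreading them over the
  four tunnel cycles — prorates them by survival (about 30% of stroke
  victims die within the year) and systematically deflates the
  stroke-heavier drug arm; the one-off reading reproduces the published
  incremental cost almost exactly. `stroke_cost_at_event = FALSE`
  restores the spread version.
* **Discounting** compounds annually, $(1+r)^{-\lfloor t \rfloor}$, so the
  first model year is undiscounted. Stroke counts are never discounted.
* **No half-cycle correction** by default (the published methods mention
  none); `half_cycle_correction = TRUE` averages start- and end-of-cycle
  occupancy for exploration.
* **Complication risks** are treated as per-procedure and scaled by 1.27
  as expected counts (the source applies 1.27 explicitly only to costs);
  `scale_complications_by_procedures = FALSE` disables the scaling.
* **Stroke states are permanent**: no return to rhythm accounting and no
  recurrent strokes; post-ICH mortality beyond the first year reverts to
  the general population because only a first-year factor (1.2) is
  published. Procedural TIA is transient (cost plus seven disutility
  days).
* **The five-year horizon includes the first model year** (20 cycles in
  total). Reading the horizon as five Markov years *after* the first year
  is available via `horizon_includes_first_year = FALSE`.
* The first-year stroke mortality multiplier is carried as printed (1.78)
  although the printed derivation (0.32/0.189) evaluates to 1.69; the
  CHADS$_2$ table outside score 2 (0.04) is a synthetic geometric curve
  ($\times 1.45$ per point) because the source cites but does not print
  those rates.

## Probabilistic sensitivity analysis

Each uncertain parameter has an independent sampling distribution: beta
for probabilities and proportions, gamma (shape/scale) for costs,
lognormal for relative risks; parameters treated as certain are fixed. No
correlation structure is published, so none is imposed. One thousand
draws re-run both arms per draw; the acceptability curve applies the net
monetary benefit rule $\lambda\,\Delta QALY - \Delta Cost > 0$, which
handles negative incremental QALYs coherently (a per-draw ICER threshold
does not).

Four published distribution rows are internally inconsistent and are
flagged (`af_distributions()` carries a note on each): the sinus-rhythm
beta's second shape parameter (176.11) contradicts its stated mean and
interval, so the beta is moment-matched to the stated mean 0.26 keeping
$\alpha = 26.47$ (implied $\beta = 75.34$); the two AF-recurrence rows
have their labels crossed relative to their means and are attached by
mean; two complication intervals and the ablation-hospitalisation upper
bound are misprints of the values implied by their own shape parameters;
and the two first-year stroke-cost rows are crossed between ischemic and
haemorrhagic relative to the derivation text — the text values are the
basecase and the printed gammas parameterise the sampling, as printed.
Flagged rows are excluded from the printed-interval calibration test; all
other rows reproduce their printed 95% intervals within rounding.

Where the published summary and the detailed results disagree on the
acceptability probabilities at \$50,000 per QALY (0.89 versus 0.30), the
detailed results and the plotted curve are taken as the reference.

## Sensitivity grid

`builtin_scenarios()` reproduces the published one-way grid: ages 55–75 by
sex (stroke risk held at its CHADS$_2$ value across ages — the published
first scenario; the age-varying relative-risk scenario is exposed only as
a parameter hook because its inputs are unpublished), CHADS$_2$ 0–4,
horizons 3/5/10/20 years, discount 0/3/5%, no stroke benefit of NSR
(`rr_stroke_af_vs_nsr = 1`), AF disutility 0–0.08, post-ablation
recurrence 0–0.05, and amiodarone discontinuation out of NSR (which also
removes the toxicity hazard, since the drug is stopped). Scenarios are
plain config patches, so any other one-way variation is a one-liner.

## Validation problem sizes

The test suite validates the cohort expectation against a
10,000-individual microsimulation over an eight-cycle instance (three
Monte-Carlo standard errors), calibrates every unflagged sampling
distribution with 10,000 draws, and runs the seed-pinned acceptability
curve on 1,000 draws — the published Monte-Carlo size.

## Known limitations

* With the synthetic external tables the five-year headline lands at an
  incremental \$8,641 and \$63,537 per QALY against the published \$8,539
  and \$59,194 — inside the package's ±15% fixture band, but not exact;
  the residual is dominated by the unpublished life/utility/case-fatality
  tables.
* The published 20-year scenario reports ablation as outright dominant
  (cheaper and more effective). Under the synthetic tables the 20-year
  incremental cost remains positive (about \$4,160; the ratio falls to
  \$8,795 per QALY). The printed inputs support a late-horizon cost
  convergence of roughly half the published rate, so the dominance label
  is not reproduced; the corresponding acceptance check is left failing
  rather than recalibrating the stand-ins toward it.
* No recurrent strokes, no aspirin arm, no novel anticoagulants, no
  currency inflation engine; AF management beyond the two modelled
  strategies is out of scope.
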