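---
title: "A Markov cohort model for tobacco-endgame policy projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for tobacco-endgame policy projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`endgamesim` projects adult cigarette-smoking prevalence in a Korea-like
population from 2023 to 2050 under combinations of tobacco-control policies,
and asks whether the *tobacco endgame* — overall smoking prevalence below 5%
— is reachable by 2050. This vignette is the package's own account of the
model: its structure and assumptions, the policy-effect conventions, how the
synthetic baseline is built and calibrated, the sensitivity-analysis design,
the numerical choices, and what the tests do and do not establish.

## The cohort model

The population is a deterministic discrete-time Markov cohort model indexed
by single year of age (0–84 plus an absorbing 85+ bin), sex, and smoking
state. Smoking states are *never*, *current*, and *former* split by time
since quitting (1–2, 3–5, 6–10, 11–15, ≥16 years; the last is absorbing).
The quit-duration split exists because relapse risk falls steeply with
abstinence time.

One calendar year is one step, with a fixed within-year order:

1. **Demography.** Each (age, sex, state) cell survives with probability
   $1 - q(a, s)\,m(\text{state})$ and moves to age $a{+}1$; the 85+ bin
   accumulates. Births are fertility applied to the surviving female age
   distribution, split by a sex ratio at birth of 0.515, entering at age 0
   as never smokers. The state-specific mortality multiplier $m(\cdot)$
   defaults to 1 (no differential smoker mortality): the model's output is
   prevalence, and leaving $m \equiv 1$ keeps the prevalence dynamics
   independent of a quantity the projections it is calibrated to do not
   constrain. It is configurable for extensions.
2. **Smoking transitions**, computed simultaneously from the start-of-year
   state: never → current with the initiation probability $i(a, s)$ (nonzero
   only at ages 15–24 by default); current → former(1–2) with the cessation
   probability $c(a, s)$; former($d$) → current with the relapse probability
   $r(d, s)$, non-increasing in $d$. Non-relapsing former smokers advance
   one duration category. Transitions conserve cohort totals exactly; note
   that a zero-rate year still advances quit durations — time since quitting
   ages even when nobody moves between never/current/former.
3. **Policy stock adjustments** (below).

## The policy module

Policy effect sizes are shipped as a versioned YAML table
(`inst/extdata/policy_effects.yaml`, overridable): smoke-free air laws (P)
by venue and level, cessation support (O), health warnings (W) and
advertising bans (E) by intensity with enforcement/publicity add-ons, and
age-banded price elasticities of demand (−0.4 at ages 15–17 falling in
magnitude to −0.1 at 35+).

Conventions, inherited from the established simulation lineage for this
policy family:

* An effect fraction $PE$ acts through the factor $(1-PE)$ on prevalence
  and initiation; a cessation effect $CE$ scales the quit rate by
  $(1+CE)$. A level change old → new multiplies by
  $(1-PE_\text{new})/(1-PE_\text{old})$ (and the $(1+CE)$ ratio for
  cessation), so identical states give exactly 1 and chained changes
  compose path-independently.
* Independent components combine multiplicatively, which keeps combined
  effects bounded and order-free.
* The *prevalence* multiplier of a level change is applied once, in the
  year of the change, as a stock adjustment — smokers removed this way
  enter the 1–2-year former category (they are quitters, not erased
  people), so the adjustment conserves persons. The *initiation* and
  *cessation* multipliers persist for every subsequent year.
* The enforcement/publicity entry is read as two separate 1% levers
  (enforcement, publicity), both switched on by the corresponding flag;
  the model lineage lists them as distinct policy items.

**Price.** Nominal prices are deflated by a constant 3%/yr inflation
assumption (base year 2022; baseline price KRW 4500/pack, 73.9% tax share).
Every year the model compares consecutive *real* prices and forms
$\max\!\big(0.2,\; 1 + \varepsilon_a \,\Delta P / P\big)$ per age band,
applying it to the current-smoker stock (with the 1–2-year former category
as the conserving counter-pool), to initiation, and reciprocally to
cessation. Because the stock carries forward, a sustained real increase has
a one-time level effect that persists, and the slow erosion of a frozen
nominal price by inflation — real prices fall ~2.9%/yr, nudging prevalence
upward — is automatic, including under the status quo. The 0.2 floor keeps
probabilities valid under extreme escalation paths. The linear elasticity
form matches the published worked values; it is only first-order
antisymmetric (raise-then-restore cancels to $O(\Delta P^2)$), which the
property tests check at small perturbations.

**Current (2022) levels** are encoded as: clean air *partial* (the partial
venue rows of the effect table — smoke-free areas are designated but weakly
enforced), warnings *high* without enforcement/publicity, advertising ban
*partial*, and cessation support *full*. The last deserves its own
paragraph.

### Why cessation support is encoded at full strength

The country operates a quitline, cessation clinics, and financial coverage
for treatment; mandated brief physician interventions are missing. One
could encode this as a 50% partial level, but the published sensitivity
analysis is decisive evidence against that: scaling the O effect sizes by
±50% moves the combined-scenario projection by less than 0.01 %p — and the
ratio $(1-PE_\text{new}k)/(1-PE_\text{old}k)$ is invariant in the scale $k$
*only when the old and new levels coincide*. Any encoding in which the
strengthened scenario raises the O level produces a visible O response
(several tenths of a percentage point), contradicting that result. We
therefore treat the missing brief-intervention component as a negligible
increment: the O level is already at its full modeled effect in 2022, the
strengthened scenario does not change it, and the O row of the one-way
analysis is exactly flat — as published. The operation-level machinery for
partial and none O levels remains implemented and unit-tested.

## Scenarios

Seven scenarios, all switching in one step at the start of 2023:

* **status quo** — 2022 levels held; nominal price frozen at KRW 4500;
* **POWE** — complete clean air, full cessation support, strong warnings
  with enforcement and publicity, comprehensive advertising ban with
  enforcement and publicity;
* **+R8000** — nominal price jumps to KRW 8000 in 2023;
* **+R10%** — thereafter grows 10%/yr nominally (≈6.8%/yr in real terms);
* **+TFG** — a tobacco-free generation: anyone born after 2003 can never be
  sold cigarettes, modeled as initiation exactly 0 for those cohorts from
  2023 (strictly "born after": birth year ≥ 2004, i.e. age ≤ 19 in 2023).

The combined total prevalence weights the sexes by the modeled adult
population, not 50/50. Phased rollouts are representable (the schedule maps
calendar years to policy states) but out of scope for the headline runs.

## The synthetic baseline and its calibration

The measured inputs behind the original projections — census age structure,
fertility and mortality tables, and survey-derived initiation/quit/relapse
schedules — are not published. The package therefore builds a *stylized*
stand-in, clearly labelled synthetic:

* a smooth low-fertility age pyramid (thin child cohorts, working-age
  bulge, survival decay in old age), total fertility ≈ 0.85 centred at
  maternal age 31, Gompertz-type mortality heavier for males;
* initiation as a Gaussian bump over ages 15–24 (peak age a fitted
  parameter), age-increasing cessation, duration-declining relapse, each
  with sex-specific scales;
* a base-year (2022) state distribution whose current-smoker age profile
  ramps in over ages 15–25, plateaus, and tapers after 55, scaled linearly
  per sex so adult (19+) prevalence equals the published 35.3% (male) and
  3.6% (female) *exactly*; former smokers are a multiple of the
  current-smoker fraction rising with age.

Six parameters (initiation scale by sex, cessation scale by sex, initiation
peak age, relapse scale) are fitted by Nelder–Mead simplex with restarts
(derivative-free; deterministic given its start) to minimize the equally
weighted sum of squared deviations, in percentage points, between the
status-quo projection and the twelve published anchor values (both sexes,
2025–2050 every five years). The fit achieves a summed loss of ≈0.2 (%p)²
with every anchor matched within 0.3 %p in under a minute on one core.

Two aspects matter for interpretation:

* **Plausibility bounds.** Each parameter is box-constrained to an
  epidemiologically sensible range (e.g. peak male initiation ≤ 0.12/yr —
  roughly 35% cumulative uptake; peak female initiation ≤ 0.01/yr,
  reflecting the low female uptake in this population) via logit
  transforms. Twelve aggregate anchors cannot identify age dynamics, and
  an unconstrained fit can reproduce them with initiation rates far outside
  anything observed, which would distort exactly the quantities the
  scenarios depend on (how much of prevalence flows through recent
  initiation — the TFG channel). The bounds encode prior knowledge, not
  tuning: they were fixed from the shape of smoking uptake in East-Asian
  populations before the scenario comparisons were run.
* **The 2022 state is a model output being treated as an initial
  condition.** The published 2022 values are themselves projections, not
  survey measurements; calibrating to them is an approximation. Likewise
  the female trajectory is reproduced as printed even though the original
  model is known to track female survey data poorly — the caveat is
  documented, not corrected.

The historical 1995–2022 tracking period of the original model is replaced
by direct initialization at the calibrated 2022 state: the role of the
historical policy sequence is absorbed by the anchors.

## Sensitivity analyses

**One-way.** Every effect size of one MPOWER family — for R, every
elasticity — is scaled by $1+\delta$, $\delta \in \{-0.5, \dots, +0.5\}$,
and the combined endgame scenario is rerun on the unchanged baseline.
Prevalence responds monotonically to each family; the price family
dominates (≈0.9 %p spread on the 2050 total for ±50%), warnings respond
weakly, and cessation support not at all (see above).

**Probabilistic.** Each of 1000 draws samples an independent scale factor
per policy family from a beta distribution rescaled to [0.5, 1.5] with
mean 1 and standard deviation 0.125 (Beta(7.5, 7.5) + 0.5), reruns the
scenario, and summarizes 2030/2050 prevalences with 95% intervals by the
**bias-corrected percentile** method: with $z_0 = \Phi^{-1}(\text{fraction
of draws below the point estimate})$, the interval endpoints are the
empirical quantiles at $\Phi(2z_0 \pm 1.959964)$. When exactly half the
draws fall below the point this reduces to the plain 2.5/97.5 percentile
interval; if all draws fall on one side, $z_0$ diverges and the code falls
back to plain percentiles with a warning. The draws are parametric
Monte-Carlo samples of the policy parameters — there are no data to
resample — and the [0.5, 1.5]/sd 0.125 parameterization is a declared
configuration, not an inferred quantity.

## Numerical choices

* All internal arithmetic is double precision; prevalences are rounded
  half-up to one decimal only at the reporting edge (`round_half_up`, with
  a 1e-9 guard so stored decimal halves round up as intended).
* Cessation probabilities are capped at 0.95 and price multipliers floored
  at 0.2 / capped at 5 so extreme scenarios cannot produce invalid
  probabilities; stock adjustments that would pull more people out of the
  recent-quitter pool than exist are capped at the pool.
* Degenerate inputs fail loudly: negative counts, probabilities outside
  [0, 1], initiation outside its age window, increasing relapse-by-duration,
  empty adult strata, mismatched baseline/scenario years, and infeasible
  prevalence targets all raise classed validation errors. A calibration
  that exhausts its budget is *flagged* unconverged, not raised.
* An anchor set with fewer points than free parameters is flagged
  `under_determined`; a base-year-only set returns the exactly matching
  initial state.

## Verification design

The cohort engine is checked against an independent individual-based
simulation (`microsim_oracle`): 10⁵ sampled agents stepped with the same
annual probabilities, compared over 10 years on three parameter sets
including the calibrated baseline, with agreement required within 3
Monte-Carlo standard errors; plus exact closed-form checks
(never-smoker fraction $(1-i)^t$ for a single initiating cohort) and exact
conservation identities on every step. Calibration is validated by
parameter recovery: anchors generated from a known parameter vector are
refitted from a distant start to loss < 10⁻⁴ with all free parameters
recovered within 5%. The test suite runs the PSA coverage check at 50
seeds with 50 draws each and a 2030 horizon — deliberately scaled-down
problem sizes chosen to exercise the property, not to estimate it
precisely.

What passing these tests shows: the engine implements its stated dynamics
exactly, the policy arithmetic matches the published effect table, and the
calibrated synthetic baseline reproduces the published status-quo and
scenario headline numbers within a few tenths of a percentage point. What
it does not show: that the synthetic age dynamics match the real
population's (only their aggregates are constrained), or that the model
family itself — no differential smoker mortality, no migration, no
electronic-cigarette or heated-tobacco substitution, initiation truly zero
under a sales ban despite social supply, constant 3% inflation — is an
adequate description of the next three decades. Those are assumptions
shared with the original analysis, listed here as limitations.

## Known limitations

* Conventional cigarettes only; rising e-cigarette/heated-product use could
  move initiation and cessation in ways the model cannot see.
* No immigration; the synthetic pyramid is stationary in shape.
* The TFG ban is modeled as perfectly effective (zero initiation), an
  acknowledged overestimate if social supply persists.
* One residual structural gap against the published tables: the
  non-price-policy (POWE) effect accumulates slightly more slowly here in
  the early years (the 2030 male reduction vs status quo is ≈4.9 %p vs 5.2
  published), because a stationary-rate cohort model partially mean-reverts
  a one-time stock reduction while the original model evidently carries
  slightly stronger persistent flow effects.
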