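---
title: "Modelling the lifetime cost-effectiveness of infant-feeding modification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifetime cost-effectiveness of infant-feeding modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedcea)
```

## The decision problem

Protein content in infant formula influences early BMI trajectories: infants
fed a higher-protein (HP) formula face a higher risk of becoming overweight
or obese in early childhood than infants fed a lower-protein (LP) formula.
Because excess weight tracks from childhood into adulthood and drives both
health-care costs and quality-of-life losses over a whole lifetime, a small
early shift in incidence can have large long-run economic consequences.
`feedcea` quantifies those consequences with a cohort simulation: it follows
a birth cohort under each feeding strategy from age 0 to age 100 and compares
discounted lifetime costs and quality-adjusted life years (QALYs).

## Model structure

The simulation has two parts.

**Childhood-to-adolescence model (ages 0–18).** Four BMI states: normal
weight (underweight included), overweight, obese, dead. Children move between
states once per year according to age- and sex-specific transition
probability matrices. For ages inside the intervention-effect window (six
annual cycles, ages 0–5) the matrices are arm-specific: the LP matrices are
the HP matrices with the probabilities of *becoming* overweight and obese
(the transitions out of normal weight) multiplied by the intervention
relative risks, the difference being returned to the stay-normal entry. From
age 6 onward both arms share COMMON matrices — the trial effect decays at
school age. In childhood the BMI categories are defined on national reference
percentiles (normal ≤ P90 < overweight ≤ P97 < obese, right-closed
boundaries, `classify_child()`); childhood mortality comes from the life
table and is applied uniformly across BMI states.

The model tracks *history*: any probability mass that ever occupies
overweight or obese carries a sticky `EVER_OWOB` flag. At age 18 the cohort
hands over to the adult model split by current category **and** history.

**Adulthood model (ages 18–100).** Categories follow the WHO adult cut-points
(normal < 25 ≤ overweight < 30 ≤ obese kg/m², `classify_adult()`). The
per-cycle death probability is the life-table `qx` multiplied by the adult
overweight/obese relative risk of the current category and — for the
`EVER_OWOB` cohort — additionally by the childhood-history relative risk;
products above 1 are clamped and counted. Each cycle, the cohort accrues
age/sex/state-specific direct plus indirect costs (EUR, 2015 price level) and
EQ-5D utilities; utilities only accrue from `child_qaly_start_age` (default
18) because no validated preference-based instrument exists for young
children.

## Economic outputs

All increments are LP − HP. With per-person discounted lifetime cost $C$ and
QALYs $Q$:

* $\Delta C = C_{LP} - C_{HP}$, $\Delta Q = Q_{LP} - Q_{HP}$;
* ICER $= \Delta C / \Delta Q$, flagged undefined when
  $|\Delta Q| < 10^{-12}$;
* net monetary benefit $\mathrm{NMB}(w) = \Delta Q \cdot w - \Delta C$ on a
  willingness-to-pay grid $w$; the curve is affine by construction and the
  tests assert this at machine precision;
* the cost-effectiveness acceptability curve (CEAC) is the fraction of PSA
  draws with strictly positive NMB at each $w$ (ties count as not
  cost-effective — a measure-zero event that must nevertheless be
  deterministic);
* averted years with overweight/obesity are reported as the reference-free
  difference $PY_{HP} - PY_{LP}$ (person-years are undiscounted natural
  years); per-arm "averted" values require an explicit reference scenario
  because the baseline that any single arm is measured against is a modelling
  choice, while the difference cancels it algebraically;
* population savings scale the per-person saving by the formula-fed share
  (default 19%, the German share; 30% reproduces a US-like setting) and the
  birth-cohort size (default 700,000, an annual German birth cohort).

Sex-specific results are computed first and pooled as the `sex_mix`-weighted
average (default 51.2% male).

## Numerical choices

* **Cycle order and half-cycle correction.** Rewards accrue on the
  cycle-start occupancy for the full year; mortality, then category movement
  follow. No half-cycle correction is applied — this matches the spreadsheet
  lineage of models of this type and is documented so the choice can be
  revisited. The individual-level cross-validation uses the identical order.
* **Discounting.** Both costs and QALYs are discounted at the same rate
  (default 3%/year) referenced to birth (cycle 0 = age 0). Note that with
  discounting referenced to birth, discounted lifetime QALYs from age 18
  cannot exceed $\sum_{a=18}^{99} 1.03^{-a} \approx 17.8$; headline QALY
  figures near 47–48 in this literature are effectively undiscounted
  quantities.
* **Interval-to-annual conversion.** `annualize_two_state()` uses the
  constant-rate identity $p_1 = 1-(1-p_t)^{1/t}$, which inverts $t$-fold
  composition exactly. For competing destinations
  (`annualize_multistate()`) each destination is converted independently and
  the residual goes to the diagonal; this is the cited method's standard
  usage, and the composition error it incurs for dense rows is measured in
  the test suite (absolute tolerance 0.01 on a 3-destination row over 3
  years) rather than hidden. Because annualization never inflates
  off-diagonal mass, the stay residual of a valid interval row is provably
  non-negative; the proportional-rescale branch is defensive only.
* **Transition matrices and mortality are kept orthogonal.** The engine
  treats the stored matrices as category movement *conditional on survival*
  (live 3×3 block renormalized) and takes all mortality from the life table
  and relative risks. Generated bundles therefore carry zero death mass in
  live transition rows.
* **Row validation.** Rows must be stochastic within 1e-9; the DEAD row must
  be exactly absorbing; every (age, sex) lookup must resolve or the loader
  raises an error naming the cell.

## Probabilistic sensitivity analysis

Per draw: intervention and mortality relative risks are sampled lognormally
(parameters backed out of their 95% CIs, $\sigma = (\ln hi - \ln lo)/(2
z_{0.975})$), every cost cell is sampled from a gamma distribution matched to
its mean/SE by the method of moments, and utilities are fixed by default
(a uniform option with half-width $\sqrt{3}\,SE$ — the uniform with that
mean and SE — exists for range-only parameters). Transition rows themselves
are not sampled. Both arms share each draw's parameters and the LP matrices
are re-derived from the sampled relative risks, so with the effect fixed at
1 every draw has exactly zero increments — the common-random-numbers
contract the tests assert. Draw *i* seeds its own substream derived from the
master seed, making results independent of the number of draws and of any
parallel scheduling; percentiles are empirical type-7 quantiles at 2.5/97.5.

## The synthetic world

The real trial panel, the national child/adolescent and adult surveys, and
the literature cost/utility schedules behind models of this type are not
redistributable, so `make_truth()` generates a self-consistent stand-in with
known ground truth. Its defaults state one fixed world:

* childhood incidence of overweight/obesity out of normal weight rising
  linearly with age (≈1.9%→7% per year over ages 0–17, obesity about a
  quarter of it), adult overweight incidence drifting upward to age 60;
  remission falling with age;
* HP arm childhood incidence 25% above the population matrices; baseline
  intervention relative risks 0.80 (95% CI 0.66–0.97) for overweight and
  0.70 (0.53–0.92) for obesity, maintained six years — effect sizes of the
  magnitude early-nutrition trials report;
* Gompertz–Makeham mortality with an infant bump and a female advantage;
  adult mortality relative risks 1.10 (overweight), 1.45 (obese), 1.12
  (childhood history);
* annual costs strictly ordered obese > overweight > normal at every age and
  component (direct costs rising with age; indirect costs concentrated in
  working ages 18–66), gamma SEs at 25% of the mean — yielding discounted
  lifetime costs in the EUR 10^4 range;
* utilities 0.95 at age 18 declining with age, minus 0.02 (overweight) and
  0.07 (obese);
* age-0 distribution 96% normal / 2.8% overweight / 1.2% obese (newborn
  excess weight near zero);
* the seed jitters global incidence/cost/mortality scale factors by ±5% so
  property tests range over distinct valid worlds.

The generator emulates the *structure* of the real inputs — ages, schemas,
arm design, plausible magnitudes — not their values. A green test therefore
establishes that the machinery is correct (conservation, recovery,
cross-validation, contract algebra), **not** that the package reproduces any
published cohort's absolute numbers: those depend on calibrated national
parameter tables that are inputs, not code. Features of real data the
generator does not emulate include covariate-driven heterogeneity beyond
age/sex, secular trends, measurement error in BMI classification, and
informative dropout (panel dropout is random).

## Cross-validation

`run_microsim()` is a genuinely separate individual-level implementation:
persons are simulated one by one with sampled categorical transitions and
Bernoulli deaths under the same cycle order. On the baseline world, the
deterministic cohort totals (lifetime cost, QALYs, person-years with
overweight/obesity) agree with a 200,000-person microsimulation within 3
Monte-Carlo standard errors — the acceptance suite runs this check for two
arm/sex combinations.

## Known limitations

* No disease-specific comorbidity pathways: cost and utility differences
  enter only through BMI category, age and sex.
* No cohort heterogeneity beyond sex; no covariate-adjusted transition
  estimation (panel estimation is transition counting with nearest-age
  filling of empty rows).
* Childhood cost accrual is a configuration switch (`accrue_child_costs`,
  default on) because source descriptions of this model family are ambiguous
  about whether first-decade costs were accrued; QALY accrual before
  adulthood is off by default for the instrument-validity reason above.
* Population savings are a single multiplicative scaling; no discounting
  across successive birth cohorts and no budget-impact time profile.
* YAML run configurations are not supported (no YAML parser among the
  package's dependencies); configurations are JSON with unknown keys
  rejected.
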