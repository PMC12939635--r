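---
title: "Modelling the mouse-utopia collapse: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the mouse-utopia collapse: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouseutopia)
```

## The system being modelled

Calhoun's best-known experiment placed eight house mice (four of each sex) in
a closed 2.57 m square universe with unlimited food and water and no
predators or disease pressure, and followed the colony for years. The
population grew exponentially (620 mice, 150 of them adults, by day 315),
kept growing more slowly to roughly 2200 by day 560, then collapsed: social
behaviour disintegrated under crowding — the *behavioral sink* — litters were
abandoned, a class of withdrawn, non-breeding males ("beautiful ones")
appeared, the last litter was born around day 600, and the colony eventually
went extinct.

`mouseutopia` is an individual-based simulator of that trajectory with a
one-day time step. Every mouse is an agent with a sex, a birth day, a
reproductive state and an *individual deviation factor* in $[0,1]$ that
crowding degrades. The model deliberately excludes spatial movement,
aggression and wounds, food consumption and inbreeding: the published record
does not constrain them, and the collapse mechanisms studied here act through
population counts alone.

## Mortality: a survivorship law turned into a daily hazard

Lifespans follow the parametric survivorship curve

$$S_i(t) = 1 - \exp\!\big(-\alpha_i (T_{i,\max} - t)\big), \qquad
i \in \{\text{male}, \text{female}\},$$

with defaults $T_{\max} = 1000$ / $1143$ days and $\alpha = 4.87\times10^{-3}$
/ $4.16\times10^{-3}$ per day (male / female) — a laboratory-mouse
survivorship fit, rescaled so the longest-lived simulated mice match the very
old survivors recorded at the end of the experiment.

A survivorship curve does not by itself say how agents die day by day. We
convert it to the conditional daily hazard

$$h(t) = \frac{S(t) - S(t+1)}{S(t)},$$

the probability of dying during day $t$ given survival to its start, with
$h(t) = 1$ forced for $t \ge T_{\max} - 1$ because $S(T_{\max}) = 0$. Two
properties make this the right construction. First, the identity
$\prod_{a<T}(1-h(a)) = S(T)/S(0)$ holds exactly, so a cohort killed by
daily Bernoulli draws reproduces the curve as the fraction still alive
(verified in the test suite to $10^{-9}$, and empirically with $10^4$
simulated agents to Kolmogorov distance $< 0.02$). Second, it absorbs the
fact that $S(0) \approx 0.992 \ne 1$: all agents are alive at age 0 by
construction, and only hazard ratios matter. Ages are integer days, matching
the engine's clock.

## The growth phase

Five parameters govern unrestricted growth; all are constant within a run:

| parameter | default | units | meaning |
|---|---|---|---|
| `mate_readiness` | 0.01 | /female/day | probability a non-pregnant female attempts conception |
| `litter_mean`, `litter_sd` | 10, 1 | pups | Gaussian litter-size distribution |
| `p_male` | 0.54 | — | sex ratio at birth |
| `initial_delay` | 60 | days | no conceptions before this day ("initial turmoil") |
| `zone_mode` | `"none"` | — | optional natal-zone bookkeeping |

The defaults are calibration preset `set1`; `set2` (litters $8 \pm 2$,
$p_\text{male} = 0.52$) and `set3` (readiness 0.02, litters $10 \pm 4$, delay
70) are alternative sets whose ensembles are also consistent with the day-315
census. Litter sizes are drawn as
$\max(0, \text{round}(d_\text{mother} \cdot X))$, $X \sim N(\mu, \sigma)$,
rounding half away from zero, with no upper clamp by default (`litter_cap`
exists but literature maxima describe data, not a mechanism). Gestation is a
uniform integer in $[19, 23]$ days.

The daily cycle runs in a fixed order: **mortality → deliveries →
conceptions → density effects → census**. Deaths first prevents dead mice
from mating or delivering; density effects use the end-of-day census so that
newborns count toward crowding. Conception draws one candidate father
uniformly from eligible males, accepts him with probability equal to his
deviation factor, and does not retry on rejection — the simplest reading of
selection "from the list of males". A female whose litter rounds to zero
still consumes her pregnancy; a sire's death during gestation does not
cancel a litter (his last recorded deviation is used for the pups).

### Adult census age vs. mating age

Two age thresholds are deliberately distinct:

* `adult_age` (default 65 days) is a *census* category: it defines the
  reported adult count and when males face the beautiful-ones test. With the
  observed 33-day doubling time, the fraction of the population older than 65
  days is $2^{-65/33} \approx 0.26$, matching the reported 150 adults among
  620 mice.
* `mating_age` (default 15 days) is the *effective* minimum age for entering
  the mating pool. It is the engine's one free timing constant and was set by
  matching the reported growth-phase conditions under `set1` demography:
  gating mating at the census adult age slows growth to a ~54-day doubling
  time (ensemble means near 250 at day 315), while no gate at all overshoots
  (~26-day doubling, means near 2700). A 15-day gate reproduces the reported
  trajectory, with both census components hit jointly in roughly 1–2% of
  runs — the same "tens of acceptable results after thousands of runs" rarity
  reported for the original calibration. The value is an effective constant
  absorbing unmodelled delays (weaning, oestrus, partner finding), not a
  claim about mouse puberty, and it is configurable.

### Zones

The universe's cells are modelled only as optional bookkeeping
(`zone_mode = "natal"`, default 16 zones): pups inherit the mother's zone and
per-zone births are tallied, but zones never affect dynamics — nothing is
known about mobility between cells, and per-zone birth counts reported for
the experiment are internally inconsistent, so no zone anchor is packaged.
The test suite checks that natal bookkeeping conserves births and leaves the
trajectory bit-identical to `zone_mode = "none"` at equal seeds.

## The behavioral sink

Collapse is driven by three mechanisms, all gated by population-count
thresholds (the pen area is constant, so counts stand in for density), all
evaluated with strict exceedance ($N > $ threshold — an arbitrary but fixed
choice, documented for reproducibility):

1. **Deviation decay** (above `n_crit_individual`, default 400): every living
   mouse's deviation factor is multiplied once per day by
   $N_\text{crit}/N < 1$. Deviation scales a male's siring acceptance and a
   female's litter size — exactly those two roles, with no effect on
   mortality or readiness. A newborn receives the parental mean, so a pup can
   exceed one parent but never the larger of the two, and the population mean
   cannot be raised by breeding.
2. **Litter abandonment** (above `n_crit_social`, default 300): a due litter
   is discarded with probability `p_abandon` (default 0.3) at delivery — the
   pregnancy ran its course, matching the account that mothers were excluded
   for a pregnancy "that successfully ends with delivery" and then lost the
   whole litter.
3. **Beautiful ones** (above `n_crit_social`): each living adult male faces a
   single lifetime Bernoulli test with probability `p_beautiful` (default
   0.1) at his first end-of-day as an adult while the threshold is exceeded;
   success permanently removes him from father selection. A one-time test was
   chosen over a daily hazard because a daily rule would compound
   probabilities the original account never describes.

The decay cadence (once per simulated day while above threshold) follows the
engine's only clock; any other cadence would be uninferable. All three
mechanisms read the end-of-day census. The critical densities default to the
300–400 range found to give the best qualitative match; `p_abandon` and
`p_beautiful` have no published values, so the defaults were fixed once at
moderate levels that a behavioural ecologist would consider plausible for
"some predefined probability" and "some percentage of males", and are
exposed as parameters.

With these defaults and `set1` demography the ensemble median rises to a
peak of roughly 480 mice shortly after day 340, sits on a plateau, declines
monotonically in trend, and reaches extinction within 1500 days, with the
last birth long preceding extinction — the qualitative shape of the
experiment. The simulated peak is far below the experimental ~2200: the
published record gives no simulated peak value to target, and the collapse
thresholds that produce the right *shape* cap the population near the
critical densities. This is a known, accepted limitation.

## Calibration metric and run selection

Calibration minimises the consistency metric

$$\text{consistency} = \left(\frac{n_\text{total} - 640}{640}\right)^2 +
\left(\frac{n_\text{adult} - 150}{150}\right)^2,$$

evaluated at day 315. The metric's reference total is 640 while the
narrative run-selection filter uses the reported census of 620 — the two
passages genuinely disagree, so `consistency()` hard-codes 640/150 and
`select_matching_runs()` defaults to 620/150 (±20 on both counts), each
overridable. Post-extinction days count as population 0 in ensemble
statistics, so dying ensembles average correctly. Ensemble standard
deviations use divisor $n$ (population SD) and quartiles use R's default
(type 7) — both unspecified upstream, both fixed here for determinism.

## Reproducibility

A run is fully determined by (configuration, seed): one seeded stream per
run, run $k$ of an ensemble seeded `base_seed + k`, so ensembles are
order-independent and embarrassingly parallel. Trajectory CSVs are written
with fixed formatting (mean deviation at 6 decimal places, the precision at
which records store it), making outputs byte-identical across repeats; a
JSON manifest recording the configuration snapshot, seed and tool version is
written next to every output.

## What the simulator does and does not establish

The generator emulates the study conditions: 8 founders, the calibrated
phase-B parameter sets, published gestation and delay intervals, and
count-triggered collapse mechanisms. It does not emulate spatial structure,
individual behavioural heterogeneity beyond the deviation factor,
time-varying parameters, or the post-day-800 experimental manipulations —
so passing tests show the mechanisms are sufficient to reproduce the
*shape* of the colony's history and the day-315 census statistics, not that
they are what happened in the physical universe. The experiment was run
once; its trajectory is treated as a single draw from a wide distribution
(ensemble spreads reach several tens of percent of the mean), which is why
run selection, not mean fitting, is the primary comparison device.

Test and acceptance ensembles use 200 growth-phase runs (day 315 horizon)
and 30 collapse runs (day 1500 horizon) — sizes at which every qualitative
check above is stable across seeds while the whole suite runs in about a
minute on a laptop.

```{r example, eval = FALSE}
# a growth-phase run that passes the census selection
run <- run_simulation(preset_params("set1", seed = 5097))
compare_to_anchors(run)

# the full collapse
p <- preset_params("set1", horizon = 1500,
                   sink = list(enabled = TRUE, n_crit_individual = 400,
                               n_crit_social = 300, p_abandon = 0.3,
                               p_beautiful = 0.1))
ens <- run_ensemble(p, 30, base_seed = 2000)
plot(ens)
```
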