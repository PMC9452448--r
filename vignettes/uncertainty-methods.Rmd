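---
title: "Representing decision uncertainty in multi-strategy cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing decision uncertainty in multi-strategy cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(psacurves)
library(ggplot2)
```

## The problem

A probabilistic sensitivity analysis (PSA) propagates parameter uncertainty
through a decision-analytic model: model parameters are drawn repeatedly from
their distributions and the model is re-evaluated, yielding, for each of $S$
strategies and $N$ iterations, a cost $C_{sn}$ and a health effect $E_{sn}$
(QALYs or life-years). Policy makers need to know not only which strategy is
best on average, but how certain that choice is and how much is lost if the
choice turns out wrong. When a handful of strategies is compared this is
routinely communicated with a cost-effectiveness acceptability curve; when
dozens or hundreds of near-equivalent strategies are compared — screening and
surveillance schedules are the typical case — most standard displays break
down, and the analyst needs alternatives that stay readable.

This package implements the full catalogue of displays on the PSA matrix,
plus two adaptations that address the breakdown: a relaxed acceptability
curve and a heat map joining acceptability and expected loss.

## The benefit algebra

Costs and effects are combined at a willingness-to-pay threshold $\lambda$
(currency per effect unit) into one of three benefit measures, applied cell
by cell:

$$\mathrm{NMB} = \lambda E - C, \qquad
  \mathrm{NHB} = E - C/\lambda, \qquad
  \mathrm{ROI} = (\lambda E - C)/C.$$

Net monetary benefit (NMB) is the default everywhere; NHB is $\mathrm{NMB} /
\lambda$ cell-for-cell, so all winner-counting methods agree between the two.
ROI is supported because it is used in practice, but it is not translation
invariant — adding a constant cost to every strategy reorders ROI — so
loss-type summaries computed from ROI answer a subtly different question.
`compute_benefit()` allows it and labels the result; the choice is the
analyst's. NHB and ROI are undefined at $\lambda = 0$ and ROI requires
strictly positive costs; both are errors, not warnings.

## Methods along a WTP axis

With NMB as an $N \times S$ matrix at each grid threshold:

* **CEAC** (`ceac()`): per strategy, the fraction of iterations in which it
  attains the iteration maximum NMB. Exact ties split the win equally among
  the tied strategies, so columns sum to one exactly; in real PSA draws ties
  have probability zero, but constructed and duplicated-strategy inputs are
  handled deterministically.
* **CEAF** (`frontier_strategy()`, and the `on_frontier` column everywhere):
  the strategy with the highest *expected* NMB, which can differ from the
  highest-probability strategy.
* **ELC** (`elc()`): per strategy, the mean over iterations of
  (iteration max NMB − strategy NMB). The frontier strategy attains the
  per-threshold minimum — $E[\mathrm{loss}_s] = E[\max_t \mathrm{NMB}_t] -
  E[\mathrm{NMB}_s]$, so argmin loss = argmax expected benefit, an identity
  the tests check exactly.
* **EVPI** (`evpi()`): $E[\max_s \mathrm{NMB}_s] - \max_s E[\mathrm{NMB}_s]$.
  This equals the lower envelope of the expected loss curves, and the
  implementation computes it *as* that envelope, so the identity is exact to
  the bit; the test suite checks the defining formula independently by
  enumeration.
* **Expected benefit plot** (`expected_benefit_curve()`): mean NMB with an
  empirical 95% band. The band uses linear interpolation between order
  statistics (`quantile()` type 7); percentile conventions differ enough
  across software that the choice is documented and tested.

`frontier_segments()` partitions the WTP grid into intervals of constant
frontier strategy. The boundary between adjacent frontier strategies is
reported as their ICER, $\Delta \bar C / \Delta \bar E$ from mean costs and
effects — computed analytically, not read off the grid. Because expected NMB
is affine in $\lambda$, the expected loss curves of the two strategies
intersect exactly at that ICER; the suite verifies the crossing to a relative
tolerance of $10^{-9}$. A boundary with zero mean-effect difference has no
ICER and is flagged rather than reported as ±Inf.

## Methods at a fixed WTP

The default fixed threshold is 50,000 currency units per effect unit,
overridable everywhere.

* **Incremental NMB** (`incremental_nmb()`): per iteration, NMB minus the
  iteration maximum, except the winner carries max minus second-highest.
  Exactly the winning strategy is non-negative per iteration; with ties at
  the maximum all tied strategies carry zero.
* **Densities** (`benefit_density()`): normalized smoothened histograms of
  NMB or incremental NMB on one shared equal-width bin grid over the pooled
  range (reference settings: 100 bins for NMB, 500 for INB). Smoothing is a
  single pass of a three-point weighted moving average with kernel
  $(\alpha, 1, \alpha)/(1+2\alpha)$, default $\alpha = 0.5$, reflecting at
  the edges; the pass preserves mass and reduces to the identity at
  $\alpha = 0$. It sits in one internal function so a different smoother can
  be swapped in. The returned curve is renormalized so the trapezoid
  integral over bin midpoints is exactly 1; "normalized histogram" in this
  package always means normalized under that same integration rule, which is
  what the unit-integral guarantee (deviation below $10^{-6}$) refers to.
  A degenerate input (all values equal) yields a flagged single-spike
  density on an artificial unit-width range instead of a division by zero.
* **Stochastic dominance** (`stochastic_dominance_curves()`) and the
  **incremental benefit curve** (`incremental_benefit_curve()`): exact
  empirical step functions — $P(\mathrm{NMB} \ge x)$ and
  $P(\mathrm{INB} \le x)$ respectively — evaluated at the pooled observed
  values with no binning, so no smoothing choices can bias them. The two
  orientations follow the convention that dominance curves read
  "greater-or-equal" and cumulative incremental curves "less-or-equal"; the
  x = 0 reference of the IBC (where the winner rule switches) is carried as
  metadata.
* **Return-risk space** (`return_risk()`): per-strategy mean and sample
  (n−1) standard deviation of NMB. Interpreting sd as the whole story
  presumes normal NMB; the density plots show when it is not.
* **Cumulative rankogram** (`cumulative_rankogram()`): competition ("min")
  ranks per iteration, rank 1 = highest NMB, so ties keep "rank 1" aligned
  with the CEAC's counting; then $P(\mathrm{rank} \le r)$ per strategy.

## The adaptations: relaxed CEAC and the heat map

With many near-equivalent strategies the strict CEAC *collapses*: every
strategy's probability of being exactly best is small, the curves pile up
near zero, and the display stops discriminating. Two mechanisms drive this —
heavy penalization of all non-optimal strategies (only the single winner per
iteration is counted) and strong between-strategy correlation, which makes
near-ties pervasive.

`relaxed_ceac()` loosens what counts as cost-effective, per iteration:

* rank scheme — within-iteration rank $\le k$;
* absolute scheme — NMB within $\delta$ currency units of the iteration max;
* relative scheme — loss $\le (1 - f)\,\lvert\max \mathrm{NMB}\rvert$.

The relative rule is stated through the loss deliberately: when the
iteration maximum is positive it is exactly "NMB at least $f$ of the best"
(e.g. $f = 0.9995$, within 0.05% of the best), but stating it as
$\mathrm{NMB} \ge f \cdot \max$ flips meaning when the maximum is negative;
the loss form preserves the intended semantics for all signs, accepts only
exact ties when the maximum is zero, and stays monotone in $f$. Neutral
parameters ($k = 1$, $\delta = 0$, $f = 1$) reduce exactly to the strict
CEAC, relaxed probabilities dominate strict ones pointwise, and the curves
are *not* renormalized — several strategies may be acceptable at once, so
the columns legitimately sum to more than one. No default threshold is
applied: the threshold choice determines what the curve means and must be
motivated by the analyst; $f \in \{0.995, 0.9995\}$ are conservative
reference values when NMB differences are smaller than the measurement
accuracy of costs and effects.

`nmb_heatmap()` joins the CEAC and the ELC per (strategy, WTP): one quantity
on the y axis, the other on a color scale, with frontier-ICER tick marks and
per-interval frontier labels from `frontier_segments()`. The join is pure —
dropping the color column recovers the base method exactly — and either the
strict or a relaxed CEAC can supply the probabilities. The `base = "elc"`
variant is the one that stays readable with many strategies, since expected
loss does not collapse.

```{r heatmap-example}
p <- example_psa()
hm <- nmb_heatmap(p, wtp_grid(0, 1e5, 2000), base = "elc")
autoplot(hm)
```

## The synthetic generator

No real PSA datasets ship with the package; `synth_spec()` /
`generate_psa()` emulate the structure that drives the phenomena of
interest. Real PSAs evaluate every strategy on the same parameter draw per
iteration, which correlates strategies strongly. The generator draws one
shared standard-normal pair per iteration and mixes it with
strategy-specific noise at weight $\rho$, standardized so the marginal sd is
exactly the specified sd:

$$\mathrm{noise} = \frac{\rho z + (1-\rho) u}{\sqrt{\rho^2 + (1-\rho)^2}},$$

giving between-strategy correlation $\rho^2 / (\rho^2 + (1-\rho)^2)$ for
costs and effects alike. At $\rho = 1$ noise cancels from every
between-strategy difference — the limit where decision uncertainty vanishes
while marginal uncertainty remains. Noise lives on the cost and effect
scales (not the NMB scale), the way shared parameter draws act in real
models, and a moment-matched log-normal cost option keeps costs positive.

`preset_scenarios()` fixes four study conditions: `few3` and `few5` (3 and 5
clearly separated strategies — both sizes are exposed because small
comparisons of either size are common), `mid` (37 strategies), and `many`
(108 strategies with tightly clustered means). Means sit on a convex
cost-effect gradient so successive strategies join the frontier as WTP
grows; sds (2,500 currency units for costs, 0.25 effect units) are large
relative to adjacent mean differences in the clustered presets, and
$\rho = 0.95$ gives the high output correlation typical of model-based PSAs.
Defaults are $N$ = 10,000 iterations and a reference WTP of 50,000. These
values were chosen once as a realistic caricature of screening-portfolio
analyses, not calibrated to reproduce any published figure; on `many` the
strict CEAC maximum at the reference WTP is a few percent while the expected
loss curves remain separated and the relative relaxation raises the maximum
probability — the qualitative collapse pattern, verified in the test suite.

What the generator does *not* emulate: skewed or multimodal effect
distributions, heteroscedastic strategy noise, structural correlation beyond
a single shared factor, and cost-effect dependence within a strategy.
Passing tests therefore demonstrate correctness of the computations and the
qualitative regimes, not agreement with any particular real dataset.

## Numerical choices

* Ties are detected by exact floating-point equality after computation:
  with continuous PSA draws ties are measure-zero, and in constructed test
  inputs exactness is precisely what is wanted. Frontier ties resolve to the
  lowest strategy index (deterministic output); CEAC ties split probability
  equally (exact normalization); rank ties use competition ranks.
* Means are plain arithmetic means; standard deviations use the sample
  (n−1) convention.
* All computation is in double precision; CEAC normalization, the EVPI
  envelope and the frontier duality hold exactly, and the ICER crossing is
  verified to $10^{-9}$ relative.
* The default WTP grid is 0–100,000 in steps of 500; frontier ICERs are
  computed analytically, so grid resolution affects only where segments are
  *displayed*, not the reported ICERs.
* CSV round-trips are bit-exact: doubles are written with 17 significant
  digits and parsed with correctly-rounded `strtod`.

Problem sizes in the shipped tests and the acceptance script — 200
enumeration instances at $S \le 4$, $N \le 6$; identity checks at $N$ of a
few dozen; the collapse scenario at $S = 108$, $N = 10{,}000$ — were chosen
so the whole battery states its properties at sizes where brute-force
enumeration is feasible and the Monte-Carlo assertions have comfortable
margins.

## Known limitations

* Value-of-information analysis beyond the EVPI envelope (EVPPI, population
  EVPI) is out of scope, as are stochastic league tables and Bayesian
  posterior-predictive variants of the CEAC.
* The relaxed CEAC's threshold has no principled default; the package
  refuses to pick one silently.
* Downstream methods are well defined under NMB and NHB; under ROI the
  loss- and rank-based methods are computed as specified but inherit ROI's
  lack of translation invariance.
* The smoothing pass is one fixed, mass-preserving kernel; density shapes
  near sharp modes depend on `n_bins` and `smooth_param`, which is exactly
  why the cumulative displays (dominance, IBC) are preferable when curves
  lie close together.
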