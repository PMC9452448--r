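# psacurves

Decision-uncertainty curves and plots for probabilistic sensitivity analysis
(PSA) in cost-effectiveness analyses that compare **many strategies**.

## The problem

A PSA re-evaluates a decision-analytic model under repeated parameter draws,
producing a cost and an effect (QALYs or life-years) per strategy per
iteration. At a willingness-to-pay threshold λ these combine into the net
monetary benefit

```
NMB = λ·E − C        (also supported: NHB = E − C/λ, ROI = (λ·E − C)/C)
```

and the analyst must communicate both the *probability* that each strategy
is cost-effective and the *loss* incurred when the chosen strategy turns out
wrong. The standard display, the cost-effectiveness acceptability curve
(CEAC: per strategy, the fraction of iterations in which it has the highest
NMB), collapses when dozens of near-equivalent, highly correlated strategies
are compared — every probability is small and the curves become
indistinguishable. The expected loss curve (ELC: per strategy, the mean of
`max NMB − NMB` over iterations) does not collapse, its lower envelope *is*
the expected value of perfect information (EVPI), and adjacent frontier
strategies' loss curves cross exactly at their ICER.

`psacurves` implements, on a plain PSA table:

* **WTP-axis methods** — CEAC + frontier (CEAF), ELC, EVPI, expected benefit
  plot with 95% band, frontier segments with analytic boundary ICERs;
* **fixed-WTP methods** — net-benefit and incremental-benefit densities
  (normalized smoothened histograms), stochastic dominance curves,
  incremental benefit curve, return-risk space, cumulative rankogram;
* **adaptations for many strategies** — a relaxed CEAC (rank / absolute /
  relative schemes) and a heat map joining CEAC and ELC in one figure with
  ICER ticks and frontier region labels;
* a **synthetic-PSA generator** with tunable between-strategy correlation
  and preset scenarios (3 / 5 / 37 / 108 strategies), so everything is
  testable without external data;
* CSV readers/writers (wide and long layouts, bit-exact round-trip),
  `ggplot2::autoplot()` methods for every result, broom-style `tidy()` /
  `glance()`, and a command-line interface.

## Worked example

```r
library(psacurves)

p <- example_psa()          # 3 strategies x 200 iterations, correlated draws
ceac(p, wtp = c(20000, 50000, 80000))
#> # A tibble: 9 × 4
#>   strategy   wtp value on_frontier
#>   <fct>    <dbl> <dbl> <lgl>
#> 1 S1       20000  0.97 TRUE
#> 2 S1       50000  0.1  FALSE
#> 3 S1       80000  0    FALSE
#> 4 S2       20000  0.03 FALSE
#> 5 S2       50000  0.88 TRUE
#> 6 S2       80000  0.65 TRUE
#> 7 S3       20000  0    FALSE
#> 8 S3       50000  0.02 FALSE
#> 9 S3       80000  0.35 FALSE
```

At €20,000/QALY the cheap strategy S1 wins 97% of iterations; by €50,000 the
frontier has moved to S2; at €80,000 S2 is still on the frontier but wins
only 65% of iterations — S3 is closing in. How much is actually at stake:

```r
evpi(p, wtp = c(20000, 50000, 80000))
#> # A tibble: 3 × 3
#>     wtp   evpi strategy
#>   <dbl>  <dbl> <fct>
#> 1 20000   13.9 S1
#> 2 50000  163.  S2
#> 3 80000 1372.  S2
```

Perfect information is worth €14 per decision at λ = 20,000 but €1,372 at
λ = 80,000, where the S2/S3 choice is genuinely uncertain. The frontier
switches at the ICERs:

```r
frontier_segments(p)
#> # A tibble: 3 × 5
#>   strategy wtp_low wtp_high boundary_icer icer_defined
#>   <fct>      <dbl>    <dbl>         <dbl> <lgl>
#> 1 S1             0    31500        31897. TRUE
#> 2 S2         32000    92500        92658. TRUE
#> 3 S3         93000   100000           NA  TRUE
```

so S1 is optimal below its ICER with S2 (€31,897/QALY), S2 up to €92,658,
then S3. The ELC curves of S1 and S2 cross exactly at 31,897. Relaxing the
CEAC (count strategies within 0.5% of the iteration best) and joining both
displays:

```r
relaxed_ceac(p, wtp = 50000, relax = relaxation("relative", f = 0.995))
#> # A tibble: 3 × 4
#>   strategy   wtp value on_frontier
#>   <fct>    <dbl> <dbl> <lgl>
#> 1 S1       50000 0.115 FALSE
#> 2 S2       50000 0.9   TRUE
#> 3 S3       50000 0.035 FALSE

autoplot(nmb_heatmap(p, base = "elc"))   # ELC with P(cost-effective) as color
```

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/psacurves.R simulate --preset many --seed 1 --out-csv psa.csv
Rscript inst/cli/psacurves.R ceac --input psa.csv --out-csv ceac.csv --out-fig ceac.png
Rscript inst/cli/psacurves.R relaxed-ceac --input psa.csv --scheme relative --f 0.9995 --out-csv relaxed.csv
```

See the vignette (`vignettes/uncertainty-methods.Rmd`) for the models,
conventions and design choices.

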