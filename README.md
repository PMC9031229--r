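# qolindex

Entropy-weighted quality-of-life index construction and panel analysis
for provincial aging data.

## What this package is for

China's 31 provincial units differ sharply in how well their oldest-old
(people aged 80 and above) live. The active aging framework views that
quality of life as three jointly necessary dimensions — **health**,
**participation** and **security** — and a provincial evaluation of it
needs four pieces of machinery that this package provides as one tested
pipeline:

1. **An abridged current (period) life table.** Provincial life
   expectancy is rarely published directly; it is derived from
   age-specific central death rates m(x). For a closed age interval of
   width *n* with separation factor *a* (average years lived by those
   dying in the interval),

       q = n·m / (1 + (n − a)·m),   L = n·l(x+n) + a·d,

   with q = 1 and L = l/m in the open interval; T is the reverse
   cumulative sum of L and e = T/l. `life_table()` builds the full table
   from a radix of 100,000; `life_expectancy_at_birth()` feeds the ALE
   indicator.

2. **An entropy-weighted composite index** over 16 indicators in the
   three dimensions (5 health, 5 participation, 6 security; the
   disability rate is the only cost-type indicator). Indicators are
   min–max standardized with polarity,

       positive: P = (x − x_min)/(x_max − x_min)
       negative: P = (x_max − x)/(x_max − x_min),

   then weighted objectively by information divergence: with
   cross-observation shares p_ij = P_ij / Σ_i P_ij, the normalized
   entropy is e_j = −(1/ln n) Σ_i p_ij ln p_ij, the divergence
   d_j = 1 − e_j, and w_j = d_j / Σ d_j. The overall index is
   A_i = Σ_j w_j·P_ij; dimension scores B1–B3 use within-dimension
   renormalized weights. See `score_panel()`.

3. **Regional disparity and level classification.** Coefficient of
   variation (sd/mean) per region and nationally
   (`disparity_table()`), signed percent change (`percent_change()`),
   exact Fisher–Jenks natural-breaks classification into
   high/higher/medium/lower/low areas (`jenks_breaks()`), and grade
   transition accounting across waves with leap detection
   (`classify_and_transition()`).

4. **Fixed-effects panel regression** of the index on nine demographic,
   economic and security covariates (`panel_fe()`, formula interface),
   a random-effects comparator (`panel_re()`), and the Hausman
   specification test H = d′[V_FE − V_RE]⁻¹d (`hausman_test()`).

Because the underlying yearbook data are not machine-readable, the
package ships a first-class synthetic-data module
(`generate_indicator_panel()`, `generate_covariate_panel()`): seeded
provincial panels with a configurable four-region mean gradient,
polarity-exercising disability rates, a life-table-generated life
expectancy indicator, and covariate panels with known coefficients and
entity effects optionally correlated with a regressor. Every stage of
the pipeline is validated against it.

## Worked example

```r
library(qolindex)

cfg <- sim_config(seed = 1)
mf  <- run_pipeline(cfg, "all", out_dir = "qolrun")
sc  <- attr(mf, "results")$scores
head(summary(sc), 4)
```

```
National and regional QoL index summary
    group year mean_A  max_A max_province  min_A   min_province
 national 2005 0.4509 0.7294     Zhejiang 0.1460        Sichuan
 national 2010 0.4960 0.8221     Shanghai 0.1443 Inner Mongolia
 national 2015 0.5504 0.9183     Shanghai 0.1652 Inner Mongolia
     east 2005 0.6770 0.7294     Zhejiang 0.6007          Hebei
```

The national mean of the synthetic index rises from 0.4509 to 0.5504
across the three waves (the configured common improvement trend), and
the eastern region leads in every wave (the configured regional
gradient). The regression stage recovers the data-generating
coefficients:

```r
summary(attr(mf, "results")$fe)
```

```
Fixed-effects (within) panel regression
      estimate std_error t_value p_value ci_lower ci_upper stars
POO    -0.0168    0.0029 -5.7064  0.0000  -0.0226  -0.0109   ***
ODR     0.0197    0.0029  6.8462  0.0000   0.0140   0.0255   ***
AHS     0.0828    0.0380  2.1764  0.0340   0.0065   0.1591    **
...
R-squared: 0.878 | F: 42.507 (p = 0.0000) | obs: 93 (31 entities)
```

Each estimate sits close to its true value in `cfg$beta` (e.g. POO
−0.0168 vs a true −0.013, ODR 0.0197 vs 0.022, AYE 0.1655 vs 0.163) with
the truth inside every 95% confidence interval. With the default
`rho = 0` (entity effects uncorrelated with regressors) the Hausman test
correctly declines to reject random effects; refit after
`sim_config(seed = 1, rho = 0.8)` and it flips to recommending fixed
effects.

Published reference averages of the index are available for the growth
arithmetic:

```r
ref <- reference_index_averages()
percent_change(ref$national[1], ref$national[3])
#> 4.253798  (printed as +4.25%)
```

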