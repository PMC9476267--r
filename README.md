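# grazemix

Grazing-personality behaviours from GPS tracking, and their association
with candidate-gene genotypes, in one tested R pipeline.

Free-ranging beef cows on steep rangeland differ consistently in *how*
they graze: how far they walk, how much ground they cover, how much
climbing they do, how tightly their daily paths fold back on themselves.
Those repeatable individual differences — grazing personalities — matter to
anyone managing hill-country pasture, and there is growing evidence they
are partly genetic (the GRM5 glutamate-receptor locus is the motivating
candidate). grazemix is for movement ecologists and animal-breeding
researchers who have (a) GPS collar relocations, (b) a digital elevation
model and (c) per-animal genotypes, and want to go from raw fixes to
genotype effect estimates without hand-rolling any of the steps.

The pipeline:

1. **Trajectories** — read fix tables (CSV, or projected GPX), build
   per-cow step statistics (step length, speed, heading, turning angle),
   and remove GPS outliers with a speed/turn spike filter.
2. **Terrain** — read an ESRI ASCII DEM, derive slope and aspect with
   Horn's 3x3 method, annotate every fix.
3. **Behaviours** — eleven per-cow-per-day metrics: horizontal / vertical /
   3-D distance, elevation range and gain, three herd-relative elevation
   metrics, the 85th slope percentile, the daily minimum-convex-polygon
   home range `hr_mcp` (ha) and the movement tortuosity
   `sp_tortuosity = ho_dist / hr_mcp` (m/ha). Day-coverage (216 of 288
   fixes at 5-min cadence), terrain-window (first up-to-28 days with mob
   median slope > 8 deg) and minimum-days (7) filters mirror standard
   field practice.
4. **Association** — per behaviour: Pearson correlation matrix over cows;
   random-structure selection across twelve candidate combinations
   (always including cow identity) by an AIC / df / BIC cascade; dominance
   (variant presence/absence) and genotype mixed models with an ML-tested
   age-class term, REML final fits, Satterthwaite tests, back-transformed
   marginal means, Benjamini-Hochberg pairwise post-hocs and compact
   letter displays.
5. **Synthetic herds** — a seeded generator (terrain, herd structure,
   genotype frequencies, biased correlated-random-walk trajectories with
   genotype- and age-dependent home-range attraction) so the whole chain
   is testable against known ground truth.

The central quantities, for a cow's fixes `(x_i, y_i)` with DEM elevations
`z_i` on a day:

    ho_dist = sum_i ||(x,y)_{i+1} - (x,y)_i||        (m/d)
    hr_mcp  = area(convexhull{(x_i, y_i)}) / 10^4     (ha/d)
    sp_tortuosity = ho_dist / hr_mcp                  (m/ha)

and the association model for, say, log home range:

    log(hr_mcp)_{cd} = beta_0 + beta_A * hasA_c + beta_age * age_c
                       + u_cow(c) + u_mob(c) + e_{cd}

fitted on daily records `d` nested in cows `c` with lme4/lmerTest.

## Worked example

```r
library(grazemix)

cfg <- default_config(seed = 1)
cfg$simulate$n_mobs <- 4L; cfg$simulate$cows_per_mob <- 12L
cfg$simulate$days <- 10L
out <- run_pipeline(cfg, "grazemix-out")

glance(out$association)[, c("behaviour", "age_included", "p_value",
                            "random_label")]
```

```
   behaviour     age_included  p_value random_label
 1 ho_dist       FALSE        3.95e- 2 cow_id
 2 ve_dist       FALSE        6.05e- 1 cow_id + farm
 ...
10 hr_mcp        TRUE         1.40e-12 cow_id + genotype
11 sp_tortuosity TRUE         4.01e-13 cow_id + genotype
```

The simulated herd (48 cows, 36 surviving the filters with 360 retained
cow-days) carries a built-in genotype effect on home-range attraction and
an age trend; the genotype models for `hr_mcp` and `sp_tortuosity` detect
it (p ~ 1e-12) and retain the age-class term (`age_included = TRUE`),
while the terrain behaviours — simulated without genetic structure — stay
quiet. Per-variant marginal means come back in measured units:

```r
tidy(out$association) |>
  dplyr::filter(behaviour == "hr_mcp")
```

```
  behaviour variant mm_present mm_se p_value
1 hr_mcp    A             5.52 0.578   0.140
2 hr_mcp    B             4.04 0.347   0.224
3 hr_mcp    C             4.77 0.343   0.240
```

i.e. cows carrying variant A average 5.5 ha/day of explored area against
4.0-4.8 ha/day for B- and C-carriers (at this small herd size the
dominance contrasts are not individually significant — the genotype model
above is the powered test). The home-range/tortuosity trade-off is
structural:

```r
corr <- out$correlations
corr$r[corr$behaviour1 == "hr_mcp" & corr$behaviour2 == "sp_tortuosity"]
#> [1] -0.97
```

Cows confined to smaller areas fold their (nearly constant) daily distance
into them, so tortuosity rises as home range shrinks. Significant genotype
models additionally emit BH-adjusted post-hoc letters per
genotype x age-class group (`out$association$posthoc`).

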