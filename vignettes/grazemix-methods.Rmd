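---
title: "From GPS collars to genotype effects: the grazemix methods"
author: "grazemix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GPS collars to genotype effects: the grazemix methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grazemix turns raw GPS relocations of free-ranging beef cows plus a digital
elevation model (DEM) into eleven daily *grazing-personality behaviours*,
and tests whether those behaviours are associated with genotypes at a
candidate gene (the GRM5 glutamate-receptor locus is the motivating case)
using linear and generalised linear mixed models. This vignette documents
the model choices, the tunable parameters, what the synthetic-herd
generator does and does not emulate, and the numerical decisions a careful
reader should know about.

## The phenotypes

Fixes arrive as `(cow_id, timestamp, x, y)` in a metric planar projection
(UTM-like; all distances are Euclidean). Per cow-day the package computes:

| behaviour | unit | definition |
|---|---|---|
| `ho_dist` | m/d | sum of planar step lengths |
| `ve_dist` | m/d | sum of absolute elevation changes (DEM-annotated) |
| `three_d_dist` | m/d | sum of 3-D step hypotenuses |
| `ele_range` | m | daily max minus min elevation |
| `ele_gain` | m/d | sum of positive elevation increments |
| `rel_ele` | 0-1 | (cow mean elev - herd min) / herd range |
| `rel_ele85` | 0-1 | same with the cow's 85th elevation percentile |
| `rel_ele_range` | 0-1 | cow elevation range / herd range |
| `slope85` | % (and deg) | 85th percentile of per-fix slope |
| `hr_mcp` | ha/d | area of the convex hull of the day's fixes (100% MCP) |
| `sp_tortuosity` | m/ha | `ho_dist / hr_mcp` |

"Herd" statistics pool all fixes of the cow's *mob* (the management group
on one farm in one year) on the same calendar day; mob is also the grouping
actually used as a random factor, so the two notions coincide throughout.
Days run midnight-to-midnight in a configurable timezone (UTC default for
synthetic data); steps never cross the day boundary.

Quality filters, in order:

1. **Outlier removal.** GPS position errors show up as impossible speeds or
   teleport-and-return spikes. A sequential scan measures each fix's
   incoming speed from the last *accepted* fix and flags fixes above
   `speed_max` (default 2.5 m/s sustained — brisk for a grazing cow), or
   fixes whose in- and outgoing speeds both exceed `spike_speed`
   (1.5 m/s) while turning by more than 150 degrees. Measuring from the
   last accepted fix means a single spike costs one fix, not two.
   Thresholds are configuration fields and are logged in every output.
2. **Day coverage.** Days with fewer than 75% of the expected fixes are
   dropped: at the 5-minute cadence that is 216 of 288 fixes.
3. **Terrain window.** Per mob, the first up-to-28 calendar days on which
   the mob's median per-fix slope exceeds 8 degrees (rolling-or-steeper
   rangeland) are retained.
4. **Minimum days.** Cows with fewer than 7 retained valid days are
   excluded entirely.

Days whose fixes are too few or collinear get a zero hull; such days
contribute missing values (not zeros or infinities) to `hr_mcp` and
`sp_tortuosity` at the profile stage, so a cow can still qualify on the
other nine behaviours — which is why those two behaviours can have a
smaller n than the rest.

Terrain annotation reimplements the standard GIS operations directly:
Horn's 3x3 finite-difference slope/aspect with replicated borders, slope
carried both in degrees (`atan` of the gradient) and rise/run percent, and
nearest-cell sampling at fix locations (bilinear optional, elevation only).
Aspect is degrees clockwise from north of the downslope direction and flat
cells are flagged, not zeroed. Slope in percent and in degrees are both
kept end-to-end because the two conversions (`tan`-based versus linear
approximations) diverge on steep ground and published tables are not always
explicit about which was used; no downstream result in this package depends
on the choice. DEM I/O uses the plain-text ESRI ASCII grid format.

## The association models

Modelling happens at the **daily record** level — the repeated measurements
are the point of the cow-identity random intercept — with per-cow profile
means used for the behaviour-by-behaviour Pearson correlation matrix
(pairwise-complete, two-sided t-test p-values, 0.05/0.01/0.001 stars).

Transformations follow the behaviour catalogue: natural log for the seven
strictly positive behaviours, and a 0-1 proportion scale for the three
herd-relative behaviours and `slope85` (percent / 100, capped just below 1
so a logit link always exists).

**Random-structure selection.** Twelve candidate random-intercept
combinations are screened per behaviour, every one containing `cow_id` and
the list spanning farm, sampling year, farm-within-year, mob, sire and
genotype (the three structures that recur in rangeland data — year with
farm:year, mob alone, mob plus sire — are guaranteed members). Candidates
are fitted as intercept-only models by maximum likelihood and ranked by a
deterministic compromise: lowest AIC; among candidates within two AIC units
of the best, fewest parameters, then lowest BIC, then enumeration order.
Finally the choice is simplified when a strictly nested simpler candidate
is not rejected by a likelihood-ratio test at 0.05. The "best compromise of
AIC, BIC, degrees of freedom and significance" that practitioners apply by
judgment is here an explicit cascade so results are reproducible; the full
ranking table is kept.

**Fixed structure.** The genetic predictor under test is always retained:
either a variant-presence indicator (`has_A`, `has_B`, `has_C` — the
dominance coding: a cow carries the variant or it does not) or the
five-level genotype factor after rare-genotype exclusion (genotypes under
5% overall frequency are dropped; in the motivating survey that removes AA
at 3/306 cows, leaving 303). Cow age class (1: under four years, 2: four to
five, 3: six plus) is kept only when the ML likelihood-ratio comparison of
models with and without it is significant at 0.05. Final models are
refitted by REML.

**Estimation.** Gaussian responses use `lmerTest::lmer` so fixed effects
carry Satterthwaite degrees of freedom. Bounded 0-1 responses use a
logit-link binomial `lme4::glmer` with unit weights — continuous
proportions make this a quasi-likelihood device rather than a literal
binomial model, and `glmer` warns accordingly (the warning is muffled
deliberately); fixed effects then carry Wald z tests. The alternative
`glmm_mode = "logit-lmm"` fits a Gaussian mixed model to the
epsilon-clipped (1e-4) logit of the response instead, and is also the
automatic fallback when the binomial fit fails to converge at all (the
PIRLS iterations are fragile on continuous proportions; the object records
when this happened). A penalised-quasi-likelihood route was considered and
rejected because the available implementation cannot handle crossed random
factors such as sire and mob.

**Reporting.** Estimated marginal means average over the levels of the
other fixed factors with equal weights and are back-transformed to measured
units (`exp` or inverse logit) with delta-method standard errors. Pairwise
post-hoc contrasts are computed on the link scale, adjusted with the
Benjamini-Hochberg procedure over the family of pairs, and summarised as a
compact letter display built by insert-and-absorb, so two groups share a
letter exactly when their adjusted p-value is at or above alpha. Models are
accepted when at most 5% of scaled (Pearson) residuals fall beyond plus or
minus 3. P-values are **not** adjusted across the eleven behaviours; each
behaviour is a separate question and the reports say so.

```{r example}
library(grazemix)
cfg <- default_config(seed = 1)
out <- run_pipeline(cfg, "grazemix-out")
glance(out$association)        # per-behaviour genotype models
tidy(out$association)          # per-variant marginal means and p-values
autoplot(out$correlations)     # behaviour correlation heatmap
```

## The synthetic herd

There is no public data set at desk scale with the full structure this
pipeline needs (trajectories, terrain, herd bookkeeping, genotypes), so the
package ships a generator whose defaults are fixed once to the study
conditions of the motivating survey: four farms over two sampling years
forming fourteen mobs, 5-minute fixes over 7-28 days, i.i.d. dropout (5%
default; a bursty Markov option exists, off by default), genotype
frequencies equal to the published survey table (AA 1%, AB 6%, AC 10%,
BB 12%, BC 36%, CC 35%), and age classes at 0.3/0.4/0.3 — the survey does
not publish an age distribution, so this is a realistic mix for a breeding
herd aged 3-10 years, chosen once.

Movement is a biased correlated random walk: gamma step lengths (mean 12 m
per 5-minute fix, about 3.5 km/day), wrapped-normal turning noise
(concentration 1.5), and a home-point bias whose weight grows with distance
from home as `d / (d + R0 / attraction)` with R0 = 280 m. Attraction is the
single effect-size dial: it leaves daily distance nearly unchanged while
shrinking the hull, so expected log home range falls and tortuosity rises
monotonically as attraction grows — which both creates per-genotype effects
(BB strongest attraction, AB/AC weakest, attraction rising with age class,
mirroring the qualitative published pattern) and reproduces the negative
home-range/tortuosity correlation structurally. Terrain is
Gaussian-spectral-filtered white noise (96x96 cells of 16 m, 180 m relief,
correlation length 8 cells), which puts median herd slopes in the 10-20
degree band — comfortably past the 8-degree gate — and 85th-percentile
slopes near 45%. Per-cow random streams are derived from the master seed by
stable string hashing, so adding a cow to a configuration never perturbs
the tracks of existing cows. Homes are drawn near a mob centre at the cow's
preferred elevation quantile.

With these defaults a cow walks about 3.4 km/day over a 4-7 ha daily hull
with tortuosity in the 600-900 m/ha band — the right order of magnitude
for published rangeland herds, though the simulator is deliberately
simple. What it does **not** emulate: behavioural states (grazing, resting,
travelling), collar failure beyond dropout, inter-cow interaction, pasture
quality, weather, or realistic autocorrelation in GPS error. Consequently
the home-range/tortuosity correlation is mechanically strong (near -1)
where real herds show about -0.3, and passing tests on synthetic herds
demonstrates that the *pipeline arithmetic and inference machinery* are
correct under known ground truth — not that the biology of any real herd
will look like this.

For calibration studies of the inference layer alone (confidence-interval
coverage, type-I error, power, selection behaviour), `simulate_phenotypes()`
draws daily records directly from the assumed mixed model
(mob, cow and residual variances 0.25 / 0.3 / 0.5 on the log scale —
log-scale spreads typical of the daily metrics) without the GPS layer.
The shipped checks use 200 replicates of 300 cows in 14 mobs with 5-7 days
per cow, sizes chosen to estimate a 95% coverage probability to about a
1.5-point standard error while a full run stays in the minutes range on one
CPU; trajectory-level tests use herds of 10-20 cows over 7-10 days for the
same reason.

## Numerical details worth knowing

- Quantiles (slope85, rel_ele85) use the linear-interpolation rule
  (R type 7); the 85th percentile of 1..100 is 85.15.
- The convex hull uses `chull` plus the shoelace formula; tests verify it
  against an independent gift-wrapping implementation to 1e-9. Hull area
  never decreases when a fix is added.
- Turning angles live in (-pi, pi] (a reversal is +pi), measured
  counterclockwise from +x; they are undefined across gaps longer than
  twice the fix interval and for the first step, while distances still
  accumulate across gaps.
- Rebuilding a trajectory after outlier removal recomputes every step
  statistic; running detect-remove twice changes nothing the second time
  on clean data.
- Tied AIC candidates resolve by enumeration order; the tie-break is
  documented output, not chance.
- Zero herd elevation range leaves the relative metrics undefined rather
  than dividing by zero; a cow alone in its mob-day likewise gets no
  relative metrics (it would trivially span its own band).
- `select_random_structure` skips candidates that fail to converge and
  records them in the ranking table.
- Exact fits (zero residual variance) report a 0% outlying-residual
  fraction rather than NaN.

## Known limitations

- The binomial-on-proportions GLMM is a pragmatic replica of common field
  practice, not a principled likelihood; a beta-family model would be the
  statistically cleaner choice and is intentionally out of scope.
- GeoTIFF rasters are not read; convert to ESRI ASCII first. GPX input is
  accepted but its lon/lat fields are taken as planar x/y — feed projected
  GPX only.
- Satterthwaite degrees of freedom apply to the Gaussian models only;
  binomial fits use Wald z.
- The simulator's trade-off between home range and tortuosity is built in
  by construction; it validates sign conventions and recovery machinery,
  and nothing more.
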