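---
title: "Methods: from activity assays to trophic cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from activity assays to trophic cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind **shybold**, the
parameters of its synthetic-data generators, and the numerical choices made in
the estimators. It is a methods reference, not a tutorial; see the README for
a worked example.

## 1. Study design being modelled

The package models a three-layer field study of behavioural types in a
grassland food chain:

1. **Open-field assays.** Each grasshopper is placed in a 24 × 16 cm arena
   and its position recorded once per minute for 15 minutes, under three
   contexts: foraging, exploration of a novel arena, and exposure to predator
   cues. Activity is the summed distance moved. Individuals below the 25th
   percentile of activity are classified *shy*, above the 75th *bold*.
2. **Habitat-domain observations.** Shy and bold individuals are observed
   repeatedly in vegetation up to 88 cm tall; each observation is a height
   (cm) and a substrate (grass vs. goldenrod), with and without a spider
   present.
3. **Mesocosms.** Blocks of five cages — a no-herbivore control plus four
   treatments crossing personality (shy/bold) with predation risk
   (absent/present) — are stocked with five grasshoppers each; after the
   season the plant community is harvested and grass, goldenrod, and other
   forb biomass weighed, and surviving grasshoppers counted.

## 2. Activity and repeatability

`step_distances()` computes Euclidean distances between the 15 consecutive
positions; an assay contributes 14 steps. `partition_assay()` groups steps
3–14 into three 4-minute blocks (the first two steps are an acclimation
period and are dropped by `step_table(trim = TRUE)`).

Repeatability is the intraclass correlation from a random-intercept model fit
by REML:

$$R = \frac{\sigma^2_{ind}}{\sigma^2_{ind} + \sigma^2_{res}}.$$

For count-like scores, `estimate_repeatability(distribution = "poisson")`
fits a Poisson GLMM with log link and an observation-level random effect
(OLRE) to absorb overdispersion. On the latent scale the distribution-specific
variance is $\ln(1/\lambda + 1)$ with
$\lambda = \exp(\beta_0 + (\sigma^2_{ind} + \sigma^2_{olre})/2)$, and it is
added to the denominator; an observation-scale transformation is also
reported. Confidence intervals come from a parametric bootstrap
(`stats::simulate()` on the fitted model, refit, percentile interval);
bootstrap replicate $b$ is seeded with `seed + b`, so intervals are
reproducible and independent of `n_boot`. Because step distances are logged
(`log(pmax(d, 0.5))` to handle stationary minutes), the Gaussian path is the
default.

For balanced designs the Gaussian estimator agrees with the closed-form
one-way ANOVA ICC, $(MS_B - MS_W)/(MS_B + (k-1) MS_W)$, to numerical
precision; this is enforced in the test suite.

`lifetime_repeatability()` re-estimates $R$ using only individuals assayed in
two or more rounds, quantifying how much consistency survives across the
season rather than within a round.

## 3. Synthetic assay generator

`gen_assay_dataset()` draws, per individual, a Gaussian intercept on the
log step-distance scale and simulates a correlated random walk on the integer
arena grid: each minute a log-normal step length is drawn
(`mean_log_step = log(3)` cm), a direction is sampled, and up to 100
directions are retried if the step would leave the arena (falling back to
wall reflection). Context shifts (`forage = 0`, `explore = +0.15`,
`predator = -0.35` on the log scale) move whole assays up or down.

Two numerical points matter:

- **Grid-rounding compensation.** Rounding positions to integer centimetres
  adds variance beyond the configured residual `skew`. The generator sizes
  the individual-level variance as
  $\sigma^2_a = R_{target} \cdot (\mathrm{skew}^2 + v_{round})$, where
  $v_{round}$ is the delta-method variance contributed by rounding, so the
  *realized* ICC of logged distances tracks `icc_target`. Long steps near
  walls are still clipped, which biases recovered $R$ slightly downward at
  high targets (about 0.02–0.03 at $R = 0.6$); acceptance tests average over
  20 replicates of 500 individuals and require the mean within 0.05.
- If `icc_target` is so high that the implied residual variance would be
  non-positive, the generator refuses with an error stating the maximum
  attainable target.

## 4. Utilization distributions and overlap

`bin_heights()` builds the discrete vertical utilization distribution on
5-cm, lower-inclusive bins `[0,5), [5,10), …`, with the canopy maximum
(default 88 cm) closing the final bin. `kde_ud()` estimates a continuous
density on a 1-cm grid using a Gaussian kernel with Silverman's `bw.nrd0`
bandwidth and **boundary reflection** at 0 and the canopy top (each point is
mirrored about both boundaries and the density renormalized by trapezoidal
integration), avoiding the mass leakage a plain KDE shows at the ground.
Degenerate (zero-variance) samples fall back to a 1-cm bandwidth with a
warning.

`isopleth(ud, level)` returns the **highest-density region**: grid cells are
accumulated in decreasing density order until the captured mass reaches
`level`. The region may be disjoint (bimodal use); endpoints are reported as
closed intervals. For a Normal(40, 10) sample the 50% region converges to
40 ± 6.745 and the 95% to 40 ± 19.6, which the acceptance suite checks at
50,000 draws.

Overlap is Bhattacharyya's affinity
$BA = \sum_i \sqrt{p_i\, q_i}$. The radical form is used (a variant without
the square root circulates in some write-ups, and is available as
`radical = FALSE`, but only the radical form satisfies $BA(p, p) = 1$).
With `level = 0.5` each distribution is first restricted to *its own* 50%
isopleth, renormalized, and summed over the union of the two cores — so core
overlap measures whether the animals' centres of use coincide, not their
tails. `domain_chi2()` contrasts binned counts with a Pearson chi-square
(zero-total bins dropped, optional pooling of adjacent sparse bins with
expected counts below 5). `domain_report()` assembles the standard four
comparisons: full-extent (95%) overlap, core (50%) overlap, core overlap
under predation, and core overlap of goldenrod use.

## 5. Population metrics

The coefficient of relative plasticity for individual $i$ is
$CRP_i = V_i / V_p$: the sample variance of the individual's repeated scores
over the variance of the population's individual mean scores. $CRP > 1$ means
the individual is more variable than the population is differentiated.
`population_summary()` and `change_scores()` compare pre- and post-season
mesocosm populations (mean personality score, CRP variance, survival), with
empty populations flagged `extinct`.

## 6. Trophic cascade model

`standardize_biomass()` converts raw harvests to per-block impacts,
$\Delta = y_{treatment} - y_{control}$, removing additive block effects
exactly. `fit_trophic_model()` then fits

$$\Delta_{grass} \sim \text{personality} \times \text{predation} +
  \text{survival} + (1 \mid \text{block})$$

with `lmerTest` (Satterthwaite degrees of freedom), personality dummy-coded
shy = 0 / bold = 1. Convergence warnings are captured (the fit is kept,
flagged `converged = FALSE`); only outright failure falls back to a
fixed-effects `lm`. Note that after standardization the fitted block variance
reflects the *shared control residual* (every $\Delta$ in a block subtracts
the same noisy control), not the generator's additive `block_sd`.

`permute_labels()` tests the personality main effect or the
personality × predation interaction by refitting under label permutations,
with $p = (1 + \#\{|\hat\beta^{perm}| \ge |\hat\beta^{obs}|\})/(n_{perm}+1)$.
Refits reuse the model structure (fixed-effect columns are rebuilt and the
deviance function re-optimized) rather than re-parsing the formula, which
makes 199 permutations × 200 simulations feasible on one CPU.

The permutation scheme matters. By default labels are exchanged only between
cages sharing a block *and* a predation status (`strata = "block_predation"`):
standardized impacts are correlated within blocks (shared control residual),
and with the interaction in the model the personality coefficient is a
contrast among predation-free cages, so freer shuffles produce permuted
designs with an unbalanced personality contrast and a wider permutation null.
In calibration simulations (200 null datasets, 199 permutations) the free and
within-block schemes rejected at rate 0.01 — conservative — while the
block × predation scheme rejected at 0.06, consistent with the nominal
$\alpha = 0.05$; the acceptance suite enforces type-I error within
[0.02, 0.08]. The freer schemes remain available via `strata = "block"` and
`strata = "none"` for sensitivity analysis.

## 7. Mesocosm generator defaults

`mesocosm_sim_config()` defaults encode the modelled study: 10 blocks × 5
treatments, 5 grasshoppers stocked, baseline biomass (grass 55 g, goldenrod
40 g, other forbs 18 g), grass effects herbivory −20, personality −23.73,
predation −4.75, interaction +34.31 (so bold herbivores suppress grass unless
predators push them into the goldenrod canopy), survival probability 0.484,
`block_sd = 8`, `residual_sd = 15`. Noise-free settings
(`block_sd = residual_sd = 0`) recover the configured coefficients exactly,
which anchors the estimator tests.

## 8. Respirometry

`respiration_rate()` implements flow-through respirometry arithmetic:

$$\text{rate} = \frac{F \cdot 1000 \cdot \Delta_{ppm} \cdot 10^{-6}
  \cdot \frac{273.15}{273.15 + T}}{m}
  \quad [\mu\text{l CO}_2\, \text{g}^{-1}\, \text{min}^{-1}]$$

with flow $F$ in ml/min (default 200), animal mass $m$ in g, and a
temperature correction to standard conditions. The worked example —
10 ppm differential, 0.1 g animal, 200 ml/min at 0 °C — gives exactly
20 µl g⁻¹ min⁻¹. `risk_contrast()` compares baseline and predator-cue rates
with a paired $t$ test, whose $F = t^2$ equals the one-way repeated-measures
ANOVA $F$.

## 9. Pipeline and reproducibility

`run_pipeline(run_config(seed = ...))` runs simulate → score → domains →
populations → cascade, writing CSV/JSON artifacts and a manifest with MD5
checksums and a config digest. Per-module seeds derive from the global seed by
a 31-bit polynomial hash (`derive_seed()`), so module outputs are stable even
if other stages change. `validate_inputs()` checks external files against the
trajectory/height/mesocosm schemas and returns an itemized violation table.

## 10. Problem sizes and limitations

Acceptance-scale runs use 500 individuals × 3 contexts for repeatability
recovery (≈ 4 minutes for 60 datasets), 50,000 draws for isopleth limits, and
200 simulations × 199 permutations for calibration (≈ 8 minutes), all on one
CPU. Known limitations: the assay generator's wall clipping slightly
attenuates high ICC targets; KDE boundary reflection assumes the density is
locally flat at the boundary; the chi-square contrast treats repeated
observations of the same individual as independent; and the permutation test
permutes cage-level labels, so it does not address within-cage pseudo-
replication beyond what the block random effect absorbs.
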