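---
title: "Models and methods: direct and indirect genetic effects on survival in group-housed laying hens"
author: "cagesurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cagesurv)
```

## The problem

In commercial layer lines housed in small cages, mortality from cannibalism
depends on an individual's own genes (the direct genetic effect, DGE) and on
the genes of its cage mates (the indirect or social genetic effect, IGE).
Selecting against mortality is hard for three compounding reasons: the
heritable signal is small, most hens are still alive when recording stops
(heavy right-censoring), and a hen that dies stops expressing its indirect
effect, so the social environment is itself time-dependent. `cagesurv`
implements a family of four mixed models for this setting, an
average-information REML engine to fit them, a cage-level cross-validation
scheme that handles censored phenotypes by tied ranks, and the algebra that
puts monthly variance components and breeding values back on the
survival-time (days) scale.

Because the motivating commercial data are proprietary, the package carries a
synthetic-population generator whose defaults encode the study conditions the
models were designed for: per hatch, each of 36 sires is mated to 8 dams with
an average of 12.3 female offspring per dam; two hatches go to two laying
houses; hens are randomly allocated to 4-bird cages nested in
house-row-level fixed-effect classes; the laying period is T = 13 months of
c = 30.4 days; all survivors are censored at 416 days.

## The four models

With `y` survival days (censored records set to 416) or monthly 0/1 survival,
`A_D` the focal's direct effect, and the sum running over the n − 1 = 3 cage
mates:

* **STM** (survival-time model): `y = fixed(class) + A_D + sum(A_I) + cage + e`,
  genetic pair `(A_D, A_I) ~ N(0, C ⊗ A)` with `A` the numerator relationship
  matrix, one residual variance. Fitted with an animal or a sire-dam
  parameterization.
* **RMM.t**: monthly 0/1 survival with *random regressions on time*
  `t_m = 1..13`: `y = fixed(class × poly6(t)) + A_D·t_m + sum(A_I)·t_m +
  cage_km + cage_k·t_m + PE·t_m + e_m`. No genetic intercepts — at entry all
  hens are alive, so there is no variance at t = 0 and variance grows as
  `t²`. Two cage terms (an iid cage-month effect and a cage regression on
  time) and a separate residual variance per month.
* **RMM.p**: identical to RMM.t but the regressions are on
  `x_m = sqrt(p_m (1 − p_m))`, with `p_m` the class-specific mean survival at
  month m, so fitted variances track the binomial variance profile instead of
  `t²`. Degenerate class-months (`p_m` of 0 or 1) are floored/capped at
  `1/(2N)` before the square root.
* **GLMM**: logit link on monthly survival with genetic, cage-month and
  permanent-environment *intercepts* only — the nonlinear link supplies the
  change of variance over time — and a binomial residual, fitted by penalized
  quasi-likelihood (PQL).

The monthly models default to a *sire-dam* parameterization (genetic effects
attached to the parents) because animal models on binary data suffer the
extreme-category problem. Separate sire and dam effects are fitted, each
carrying a quarter of the additive variance, so sire-dam variances rescale to
the animal scale by a factor 4; a one-effect-per-pair variant (factor 2) is
available behind `sire_dam_combined = TRUE`. Which convention a given
commercial analysis uses is rarely documented; the factor is therefore an
explicit knob of `translation_ctx()` with 4 as the default.

**Time-dependent IGE.** Optionally, the indirect-effect incidence of each
monthly record includes only cage mates alive at the start of that month;
after the focal's own death its cage composition is frozen at the
death-time set (those records are no longer affected by later deaths). The
time-dependent variant is known to inflate the indirect variance — the
incidence then depends on the outcomes themselves — and the analysis scripts
reproduce that behaviour on synthetic data.

## The engine

All models share the structure `y = Xb + Z_D u_D + Z_I u_I + Σ_k Z_k u_k + e`
with `(u_D, u_I) ~ N(0, C ⊗ A)` and iid terms `u_k`. Every iid term here is
*cage-local* (cage, cage-month, cage slope, permanent environment of a caged
hen), so the engine absorbs them into a blocked marginal residual
`R = D + Σ_k σ²_k Z_k Z_k'`, block-diagonal by cage (blocks of 4 rows for the
day-scale model, 52 = 4 hens × 13 months for the monthly models; block
patterns are cached, so only a handful of distinct blocks are ever
factorized). The mixed-model equations then carry only the fixed effects and
the genetic pair: a few hundred equations for sire-dam models, a sparse
system over the pruned pedigree for animal models.

REML is maximized by AI-REML: Newton steps with the average-information
matrix, preceded by three EM warm-up iterations (monotone and robust far from
the optimum; skipped when an explicit start is supplied). Scores are analytic — including the per-month residual
variances and the G-side derivatives of `C` — whenever the coefficient matrix
can be inverted densely (the sire-dam path); on the sparse animal path, where
exact traces would need a selected inverse of a large sparse matrix, the
score is computed by central finite differences over the five parameters and
the same AI Hessian is used. Safeguards: step-halving against likelihood
decrease, projection of variances onto a floor of `1e-8 × s_ref` (with
`s_ref` the fixed-effects-adjusted phenotypic variance), bending of `C` to
positive semidefiniteness by eigenvalue flooring at `1e-6 × trace`, an
active-set rule that freezes variances pinned at their floor with an inward
score, and an EM fallback if a Newton step fails outright. Convergence:
`|Δ logL| < 1e-8` together with a relative parameter change `< 1e-6`
(parameters measured against their natural scale, so slope variances of
order 1e-4 are not judged against day-scale variances). Component standard
errors come from the inverse AI matrix over the informative parameters.

The GLMM path iterates the usual PQL linearization (working response
`z = η + (y − p)/(p(1−p))`, weights `p(1−p)`, dispersion fixed at 1) and
re-estimates the working model's components with the same engine until the
linear predictor moves by less than 1e-6. PQL is a deliberate choice: it is
the approximation the field's standard software applies to this model class,
and its mild variance bias on binary data is accepted and documented rather
than hidden.

## Cross-validation and accuracy

Whole cages are assigned to 5 random folds (redrawn until every fixed-effect
class appears in every training set). Variance components are estimated once
on the complete data; per fold only the BLUP solve is repeated with the
validation cages' phenotypes removed. This follows standard animal-breeding
practice and is an explicit design choice — re-estimating components per fold
would multiply the cost fivefold without changing ranks materially.

Observed phenotypes are survival days adjusted by an uncensored-records-only
OLS on the fixed classes; censored hens, whose true survival exceeds the
cutoff, all receive the average of the top ranks they jointly occupy (5
censored among 10 all get (6+7+8+9+10)/5 = 8). The OLS deliberately excludes
censored records so class means are not attenuated toward the cutoff; whether
the original analyses included them at 416 d is not documented, so this is
flagged as a divergence risk. Predicted phenotypes combine the focal's direct
EBV with the indirect EBV of its three start-of-experiment mates; for
monthly models ranks are scale-invariant, and for the time-regression model
the EBV can also be placed on days explicitly via `translate_ebv_to_days()`.
The pooled rank correlation is the Pearson correlation of fold-mean-centred
within-fold ranks (the fixed-fold-effect analogue of a bivariate analysis of
ranks), with a leave-one-fold-out jackknife SE. Dividing by the upper bound
`sqrt((σ²_AD + (n−1)σ²_AI)/σ²_P)` gives the approximate accuracy. The bound's
printed form in the source material lacks the operator between the two
numerator terms; the sum interpretation is the only one consistent with its
own printed values (0.31 and 0.37), and is what `sqrt_r2()` implements.

## Scale translation

Survival time is the day-sum of the monthly survival indicators,
`ST = c · Σ_m S_m`. Under the time-regression model a slope effect `a`
contributes `c · S · a` to ST with `S = Σ t_m = 91`, so slope variances map
by `(cS)²` and iid per-month variances (cage-month, monthly residuals) by
`c² · Σ_m σ²_m`. Month coding `t_m = 1..13` is owned by a single constant
(`month_scores()`) shared by fitting and translation. Sire-dam genetic
variances are rescaled to the animal scale first. Because the parental
effects carry only half the additive variance, the sire-dam fits park the
Mendelian half in the cage and individual environmental terms; the day-scale
map removes exactly those shares (`((n−2)σ²_AI + 2σ_ADI)/2` from cage,
the remainder of `(σ²_AD + (n−1)σ²_AI)/2` from the residual) so that the
assembled phenotypic variance equals the actual variance of ST. A
Monte-Carlo oracle in the test suite verifies the whole map against the
empirical ST variance within 2 %. Translation is deliberately refused for
the `x_m`-regression model and the GLMM, where the corresponding map involves
intractable integrals.

Derived parameters follow the standard social-genetics algebra: total
breeding-value variance `σ²_TBV = σ²_AD + 2(n−1)σ_ADI + (n−1)²σ²_AI`,
phenotypic variance `σ²_P = σ²_AD + (n−1)σ²_AI + σ²_cage + σ²_e`,
`T² = σ²_TBV/σ²_P`, and `r_A = σ_ADI/(σ_AD σ_AI)`.

## The generators

The **binary generator** is the study-condition generator: each month, a live
hen survives with probability
`logit⁻¹(μ_m + class + A_D + Σ_{alive mates} A_I + cage + PE)`; deaths are
applied simultaneously at month end (the data are monthly, and the
time-dependent incidence is defined on alive-at-month-start sets), survivors
are censored at 416 d. A logistic generative rule was chosen deliberately: it
keeps records in {0,1} and makes *all four* fitted models approximations of
the truth, mirroring the real-data situation; no fitted model is privileged.
Defaults: flat baseline monthly survival 0.96 (≈57 % survival over 13
months), class SD 0.25, cage variance 0.22 and permanent-environment variance
0.17 on the logit scale, and `logit_genetic_defaults()` =
[[0.112, 0.012], [0.012, 0.03]], chosen once so that a survival-time analysis
of generated data lands near commercial-line magnitudes (direct SD ≈ 25–30 d,
indirect SD ≈ 10 d, r_A ≈ 0.2, phenotypic SD ≈ 135 d). Litter sizes are
multinomial given the cohort total `round(n_dams × 12.3)`. Intermediate
pedigree generations carry only the selected breeders (36 + 288 per
generation), which preserves five generations of relationship depth at a
compact size. Deaths from unrelated causes (predators etc.) are not
simulated, but a drop-with-retained-id hook exists so the fitting path
tolerates such records.

The **linear-Gaussian generator** emits continuous monthly records directly
from the time-regression equation and a day-scale view that is *exactly*
`c × (monthly sum)`. No thresholding is applied: under this generator both
the day-scale model and the monthly model are correctly specified and the
translation map is exact, which is what makes sharp parameter-recovery and
cross-model-consistency checks possible. Its defaults put the day-scale truth
at direct variance 784, covariance 57, indirect variance 100, cage 1150
(650 slope + 500 cage-month), permanent environment 1200 and residual 8015 —
a phenotypic SD of about 107 d.

What passing tests on these generators show — and what they do not: they
demonstrate that the estimation machinery, the censoring-aware ranking, and
the scale translation are internally correct and consistent at realistic
magnitudes. They cannot show that any of the four models is the right model
for real cannibalism-driven mortality, which is nobody's claim; the binary
generator has no behavioural dynamics (no victim-specific pecking networks,
no age-staggered housing), a flat baseline hazard, and exact 4-hen cages
throughout.

## Problem sizes and numerical choices

The heavy validation runs use sizes chosen to exercise realistic structure at
tractable cost: parameter recovery and cross-model consistency use 20
replicate populations of 36 sires × 8 dams × ~10.45 offspring (≈2960 hens,
≈740 four-hen cages, five pedigree generations, ~38 500 monthly records);
the censoring-robustness comparison uses 20 smaller populations (24 × 4 × 6 ≈
576 hens, 144 cages) because it needs twenty cross-validations per model and
scenario; the analysis scripts under `analysis/` use the 144-cage size
throughout so the whole pipeline re-runs in minutes. In the replicate studies
the monthly fits are warm-started from the survival-time components
(`rmm_start_from_stm()` inverts the day-scale map and splits cage and
residual by a documented 50/50 and 85/15 rule) and the REML convergence
tolerance is relaxed to `|Δ logL| < 1e-6` (component estimates and rank
correlations are unchanged at the digits compared); the engine default stays
at 1e-8. "Near
the zero bound" for a variance with true value zero is defined as: at the
floor, or within two model SE of zero — with a true zero roughly half the
unconstrained estimates are negative, so "exactly at the floor" alone is the
wrong yardstick; this definition was fixed before the check was first run.

Mid-period censoring robustness applies the `half_at_midpoint` scheme to the
*fitting* records only; the observed-phenotype side of the rank correlation
keeps the all-censored-at-end records, emulating a comparison in which only
the model input degrades.

## Known limitations

* PQL is first-order and biased downward for binary data with large cluster
  variances; the GLMM path inherits this, as its documented cross-check
  against an independent PQL implementation (not against exact quadrature)
  makes explicit.
* The sparse (animal-model) REML path uses finite-difference scores; exact
  analytic scores there would require a selected-inverse routine that is not
  worth its complexity for five parameters.
* Sire-dam models leave the Mendelian half of the genetic variance in the
  cage/residual terms; the translation removes it analytically, but the
  corresponding sampling covariances are ignored in the reported SEs.
* Unknown-parent groups, genomic relationships, maternal effects,
  heterogeneous cage sizes and proportional-hazards likelihoods are out of
  scope.
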