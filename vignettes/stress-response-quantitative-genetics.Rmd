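---
title: "Quantitative genetics of integrated stress responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of integrated stress responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Acute stress responses couple behaviour (flight, freezing, thigmotaxis,
shelter use) with endocrine physiology (glucocorticoid release). If natural
selection has favoured particular *combinations* of these traits, their
additive genetic variation should be integrated: the additive genetic
covariance matrix **G** should carry strong correlation structure, and a
single major axis (**g**~max~, the first eigenvector of **G**) should
capture much of the multivariate genetic variance. `qgstress` implements the
full quantitative-genetic workflow needed to test that hypothesis in a
pedigreed population of Trinidadian guppies (or any comparable design):

1. trait extraction from open-field (OFT), shoaling (ST) and emergence (ET)
   trial trajectories, including a random-swim null model that turns raw
   arena coverage into *relative area covered*;
2. pedigree handling and the additive (numerator) relationship matrix
   **A**;
3. univariate, bivariate character-state (GxE) and multivariate animal
   models fitted by REML;
4. eigen-analysis of **G** with parametric-bootstrap uncertainty;
5. a synthetic-study generator that reproduces the breeding design and
   assay structure, so every stage can be exercised and calibrated without
   any external data.

## The animal model

For observation $j$ of individual $i$ the univariate model is

$$y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + a_i + p_i + g_{k(i)} + e_{ij},$$

with $\mathbf{a} \sim N(0, \sigma^2_A \mathbf{A})$ structured by the
pedigree, permanent-environment effects $p_i \sim N(0,\sigma^2_{PE})$
capturing non-genetic consistency across repeat trials, housing-group
effects $g_k \sim N(0,\sigma^2_{G})$, and trial-level residuals. Adjusted
heritability is $h^2 = V_A / (V_A + V_{PE} + V_{group} + V_{res})$ —
"adjusted" because the denominator conditions on the fixed effects (assay
repeat, order caught from the group, temperature, time of day, age, sex,
generation). Repeatability replaces the numerator by $V_A + V_{PE}$.

Multi-trait models replace each scalar variance by a trait × trait
covariance matrix; the genetic term has covariance
$\boldsymbol\Sigma_A \otimes \mathbf{A}$. Residual covariance is estimable
only between traits measured on the same occasion — the four OFT traits —
so residual covariances involving emergence time or cortisol are fixed at
zero by construction (`residual_blocks`).

### Parameterisation and engines

Every covariance matrix is written as $\Lambda\Lambda'$ through a loading
matrix. Unstructured matrices use a Cholesky factor with log-scale
diagonal; the constrained genetic structures of the character-state ladder
are lower-rank loadings (`"shared"`: one factor, one loading — equal
variances with correlation +1; `"rank1"`: one factor, free loadings —
context-specific variances with correlation ±1). This keeps every matrix
positive semi-definite without boundary constraints on correlations, and a
correlation fixed at +1 never requires optimising on the edge of a
parameter space.

The restricted likelihood is evaluated through the mixed-model equations,
$-2\ell_R = (n-p)\log 2\pi + \log|\mathbf{R}| + \log|\mathbf{G}^*| +
\log|\mathbf{C}| + \mathbf{y}'\mathbf{P}\mathbf{y}$, with analytic
gradients for the loading and residual parameters. Three evaluation
engines share one parameter space and return identical likelihood values
(asserted in the tests):

* **generic** — any model; dense Cholesky of the MME coefficient matrix;
* **uni** — single trait: the genetic and permanent-environment effects
  collapse into one per-individual effect whose prior is diagonalised by
  the eigendecomposition of **A**, and the data cross-products are
  constant across evaluations, making each iteration cheap;
* **paired** — one observation per trait per individual (the
  character-state model): rotating by the eigenvectors of **A** makes the
  individual-level covariance block diagonal ($s_i\boldsymbol\Sigma_A +
  \mathbf{E}$) and the group term is handled by Woodbury identities.

Optimisation uses `nlminb` (quasi-Newton) from moment-based starting
values, with warm starts along nested model ladders; convergence at the
default tolerances is to a relative objective change below 1e-10. When a
tolerance below 1e-12 is requested, a Newton polish on the analytic
gradient refines the stationary point to ~1e-9 gradient norm (the balanced
half-sib oracle test requires variance components at 1e-6 relative
precision, which plain quasi-Newton line searches do not reliably
deliver). Boundary variance components are kept above `exp(-16)` of a
trait's scaled variance (≈ 1e-7 of the phenotypic variance), i.e.
numerically zero; a single jittered-restart scheme is available through
`qg_control(restarts = )` but defaults to one start, because the
moment-based and warm starts proved sufficient on all tested problems and
restarts triple the cost of simulation studies.

Standard errors come from the inverse observed information of the
unconstrained parameters (finite differences of the analytic gradient),
propagated to the component scale — and to $h^2$, repeatability and
correlations — by the delta method. Because variance-component sampling
distributions are right-skewed at realistic design sizes, interval
coverage is evaluated with lognormal Wald intervals,
$\hat v \exp(\pm 1.96\,\mathrm{se}/\hat v)$.

### Likelihood-ratio testing

Nested fits are compared with $\chi^2 = 2\Delta\ell_R$ (clipped at zero).
A single variance tested on its boundary uses the equal mixture
$\chi^2_{0,1}$, whose p-value is $\tfrac12 P(\chi^2_1 \ge x)$ — exactly
0.5 at $x = 0$. The character-state GxE ladder applies this mixture to the
context-specific-variance comparison as well, following the convention of
the analysis it reproduces; strictly, equal context variances given a
correlation of +1 is an interior hypothesis, so the mixture is mildly
anti-conservative in theory — the test suite therefore checks its size
empirically (it holds ≈ 5% at the study scale). The overall
genetic-integration test compares the full multivariate model against a
diagonal-**G** fit on $t(t-1)/2$ degrees of freedom.

Wald F statistics for fixed-effect contrasts use a Satterthwaite-type
denominator df, $2v^2/\widehat{\mathrm{Var}}(v)$ with
$v = L\,\mathrm{cov}(\hat\beta)\,L'$; agreement with other software's
proprietary df approximations is approximate by nature.

## Trajectory traits and the random-swim null model

The OFT arena is 20 × 30 cm on a 1 × 1 cm grid. Conventions, chosen where
the tracking software's are unknowable:

* **grid cells** are half-open, $[i, i+1)$, with the far wall folded into
  the last cell; a cell counts as visited if the path spends *any* length
  in it. Visited cells are enumerated exactly by splitting each inter-frame
  segment at every gridline crossing — no subdivision step size to tune,
  and no traversed cell can ever be skipped. (A point-sampling oracle at
  0.01 cm agrees exactly whenever positions are quantised to a coarse
  tracking lattice; for unquantised paths it can miss cells holding less
  than 0.01 cm of path, which is the oracle's resolution limit, not a
  counting error.)
* the **middle zone** is the centred rectangle similar to the arena and
  scaled by $1/\sqrt2$ per side — the only similar rectangle whose area
  equals that of the border zone around it (half the arena each);
* **freezing bouts** are maximal runs with instantaneous speed (inter-frame
  displacement × fps, unsmoothed) below 4 cm/s lasting ≥ 2.5 s; a bout
  truncated by the end of the trial counts if long enough;
* **shoaling tendency** is time in the third of the long axis nearest the
  shoal minus time in the farthest third;
* **emergence times** are censored at 900 s before log transformation and
  optionally negated so that high values mean fast emergence;
* default frame rate is 25 fps (configurable; the source recordings'
  rate is not fixed by the protocol).

*Relative area covered* asks whether a fish covered more or less of the
arena than a random swimmer of the same track length. The null model draws
per-frame displacement vectors (with replacement) from a step pool,
rejects draws that leave the tank, splits accepted moves longer than 1 cm
into sub-steps, and stops once the cumulative distance reaches the target
length; 100 target lengths spanning the observed range, each simulated
five times, are fitted with a fourth-order polynomial of area on track
length. Relative area = observed − predicted. With an empirical step pool
from real tracking files this regression explained ~98% of simulated
variance in the original study; the package's synthetic stand-in pool — an
exponential mixture of slow "freeze-like" (mean 0.1 cm) and fast "cruise"
(mean 0.8 cm) steps with uniform headings, clearly labelled synthetic —
achieves $R^2 \approx 0.91$, and no claim is made to reproduce the
original figure, which depends on the unavailable empirical pool. The
fitted quartic can wiggle by a fraction of one grid cell at the saturating
top of the length range; predictions are monotone over the informative
range.

## The synthetic-study generator

`simulate_study()` reproduces the design the models assume:

* a maternal-full-sib-nested-in-paternal-half-sib pedigree (default 3
  generations of 12 sires × 4 dams × 12 offspring ≈ 576 phenotyped fish in
  the final generation; the emulated study used up to 5 generations, and
  the generator allows them, but family counts per generation are free
  parameters because the source design did not fix them);
* mixed-family, sex-balanced housing groups of 16–20 adults, with
  full-sib families dispersed across groups by a greedy capacity-
  constrained assignment (no group ever holds more than half of a small
  family);
* 2 repeat trials per assay by default (OFT/ET/ST), per-assay inclusion
  probabilities calibrated to the emulated study's phenotyping counts
  (OFT 0.99, ET 0.6, ST 0.4, cortisol 0.45), or `include_all = TRUE` for
  calibration work;
* trait values built as intercept + fixed-effect contributions + genetic
  deviation + permanent-environment draw + group draw + trial residual.
  Genetic deviations descend the pedigree by Mendelian sampling —
  founders $N(0, \boldsymbol\Sigma_A)$, offspring receiving the parental
  mean plus a deviation with variance share
  $1 - \tfrac14(1+F_s) - \tfrac14(1+F_d)$ — so the stacked values have
  covariance $\mathbf{A} \otimes \boldsymbol\Sigma_A$ exactly;
* two-context cortisol with genetic covariance
  $r_{A,13}\sqrt{V_{A1}V_{A3}}$ between contexts (the character-state
  representation of genetic variance in habituation), group and residual
  variances per context, and context means on the ln ng/hr scale.

Defaults are the published point estimates (univariate components via
`guppy_variance_components()`, the GxE parameters via
`cortisol_gxe_model()`, the multivariate **G** via `guppy_g_matrix()`), so
recovery experiments target the printed values. Traits are simulated
directly on their analysis scales (√freezings, ln emergence, ln cortisol),
matching how the models treat them. Covariate distributions are the
generator's own choices where the protocol is silent: temperature uniform
on 23–24.9 °C shared within a group-trial, time of day uniform over the
testing window, age normal around 200 days, body mass log-normal, order
caught an exact permutation within each group; continuous covariates are
emitted raw and mean-centred/scaled (`_z`).

What the generator does **not** emulate: video artefacts and tracking
noise, diel hormone rhythms beyond a linear time-of-day covariate, water
chemistry, selection or non-random mating, and any dependence between
assay inclusion and phenotype (missingness is completely at random).
Passing recovery tests therefore demonstrate correctness of the estimation
machinery under the assumed generating process, not robustness to the many
ways real data depart from it.

## G-matrix post-processing

`eigen_decomposition()` reports eigenvalues in descending order,
proportions of genetic variance per axis (numerically negative boundary
eigenvalues are reported raw but clipped to zero for the proportion
accounting), and eigenvectors oriented so each axis's largest-magnitude
loading is positive. The parametric bootstrap re-simulates complete
response vectors from the fitted model over the same pedigree and design,
refits (warm-started from the point estimate), and stores replicate **G**
matrices; non-converged replicates are flagged and excluded from
intervals, never silently dropped. Loading intervals align each replicate
eigenvector to the point estimate by the sign of their dot product, with
axes matched by rank — a documented limitation when neighbouring
eigenvalues are nearly degenerate, where rank-matching can swap axes and
widen intervals. Bivariate 95% genetic confidence ellipses are the
contours $x'G_2^{-1}x = \chi^2_{2,0.95}$, returned as 256 boundary points
from the major axis.

The bootstrap replicate count is configurable; 200 is a practical desk
default (the original analysis used 5000), and the test suite uses smaller
counts on smaller designs.

## Problem sizes used by the test suite

All sizes are the package's own desk-scale choices: univariate recovery
runs 100 replicate studies on a fixed 576-fish, 2-OFT-repeat design at the
published √freezings components; the GxE null calibration runs 100
replicates of a 320-fish paired-context design; multivariate **G**
examples use ~100 fish and 3 traits with single-digit bootstrap counts.
The full-size analysis (five generations, six traits, thousands of
bootstrap replicates) is one configuration change away but takes hours,
not minutes.

## Known limitations

* Residual structures beyond co-observation blocks (autoregression,
  heterogeneous trial variances) are not modelled.
* The Satterthwaite denominator df is implemented for single-row
  contrasts only.
* The paired character-state engine requires complete context pairs;
  individuals missing one context are dropped with a message (the generic
  engine accepts them, at higher cost).
* Axis-rank matching in the bootstrap (above).
* Wald/delta standard errors degrade for components at or near their
  boundary, where the likelihood is not locally quadratic; boundary
  components are better judged by their LRT.

## A minimal end-to-end run

```{r example}
library(qgstress)

cfg <- pipeline_config(seed = 1, n_sires = 6, dams_per_sire = 3,
                       offspring_per_dam = 8, n_generations = 2,
                       g_traits = c("rel_area", "time_in_middle",
                                    "sqrt_freezings"),
                       n_boot = 50, out_dir = "qgstress-report")
report <- run_study_pipeline(cfg)
print(report)
```
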