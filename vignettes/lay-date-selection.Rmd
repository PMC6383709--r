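---
title: "Models and methods for lay-date selection, heritability and plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for lay-date selection, heritability and plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the
assumptions behind them, the tunable parameters that matter, and the
numerical and design choices made where more than one defensible option
existed. It states no empirical result: numbers come from the test suite
and from `scripts/acceptance.R`, which recompute them at run time.

## Data model

The unit of analysis is the breeding record: one clutch, with the
female's identity, the social male attending the nest, the season
(austral, September–February, labelled by its starting year), the lay
day (days since 1 September; day 0 = 1 September), optional hatch and
fledge days, counts of eggs, hatchlings, fledglings and recruits, and
female covariates (age in years, tarsus length in mm, pedigree-based
inbreeding coefficient). Records dated September–December belong to the
season starting that year; January–August to the previous one. Where a
lay day is missing but the hatch day is known, the lay day is imputed as
hatch − 17 days (the laying-plus-incubation interval, recoverable by
regressing lay on hatch dates where both exist). Clutches are numbered
within female × season in lay-day order, regardless of success; ties are
broken by hatch day and then stable input order, and are reported.
"Start of breeding season" is the first clutch's lay day. Fitness of a
clutch is the number of its offspring that are themselves observed
breeding in a later season — as dam, social male, or genetic sire — so
recruitment in the final season is unobservable and flagged as
truncated.

The **temperature cue** for season *j* is the mean daily maximum
temperature over the 50 days strictly before the grand-mean start of
breeding, computed once across all seasons and anchored to each season's
calendar. The window length (50 days) and a 10% missing-day tolerance
are arguments; the grand mean uses every season with data, since
restricting to a subset of years is a caller decision, not a property of
the statistic.

## The fitness-optimum model

Expected fitness is a Gaussian curve of the standardized lay date
(`standardize()` keeps the centre and scale so optima can be reported in
days and calendar dates):

$$Z_i = A \exp\!\left(-\left(\frac{x_i - \lambda_{j(i)}}{\sigma}\right)^2\right),
\qquad \lambda_j = \mu + B\,\theta_j + u_j,\qquad
u_j \sim \mathcal{N}_{[-2,2]}(0, \sigma^2_U),$$

with a Poisson layer for counts and a Binomial layer (per-clutch trials)
for stage survival. Priors: $\mu \sim U(-2,2)$, $\sigma \sim U(0,100)$,
$A \sim U(0, A_{\max})$, $1/\sigma^2_U \sim \Gamma(0.001, 0.001)$, and
$B \sim N(0, 10^6)$ when a cue is supplied. The wide $\sigma$ prior
deliberately includes an effectively flat curve, so "no optimum" is a
region of the parameter space rather than a separate model; $A_{\max}$
is 5 for fitness counts and 1 for survival probabilities, which also
guarantees the Binomial success probability stays inside (0, 1). The
bounds $[-2, 2]$ correspond roughly to the 2%–98% quantiles of a
standardized lay-date distribution: optima outside the observed range of
laying are not estimable and are excluded a priori.

Model fitting is gated by a **quadratic pretest**: a GLMM with linear
plus quadratic lay-date terms must beat the linear model by more than 2
AIC units before the curve model is fitted, because a monotone fitness
trend gives the Gaussian curve nothing identifiable to estimate.

**Truncation semantics.** The year effect $u_j$ is truncated to
$[-2,2]$ while $\mu$ is bounded on the same interval, so a drawn
$\lambda_j = \mu + u_j$ can leave $[-2,2]$; the fitted object reports
the fraction of such draws rather than silently re-truncating, since the
two conventions differ and the printed fraction lets a user judge
whether it matters for their data.

### Sampler

Estimation is adaptive Metropolis-within-Gibbs (compiled in C++):
random-walk proposals with reflection at the prior bounds for bounded
parameters, per-parameter scales adapted toward 0.44 acceptance during
burn-in only (so the post-burn-in chain is a fixed Markov kernel), and
year effects updated against their year's records only. Chains start
from dispersed random points; reproducibility comes from R's RNG, one
seed per chain (`seed + chain − 1`).

Two numerical choices deserve note:

* **The $\sigma^2_U$ plateau.** $\Gamma(0.001, 0.001)$ on the precision
  is close to log-flat over hundreds of log-units, and for large
  $\sigma^2_U$ the truncated-normal likelihood of the year effects
  saturates (the distribution tends to uniform on $[-2,2]$). The
  posterior mass out there is negligible, but an unbounded log-scale
  random walk that wanders onto the plateau accepts almost every
  proposal and can strand for thousands of iterations. The log variance
  is therefore reflected inside $[10^{-8}, 10^{6}]$ — far beyond
  anything meaningful for a variance of effects confined to $[-2,2]$ —
  and adapted proposal scales are capped. This is a numerical bound on
  the sampler, not a change of model.
* **Convergence.** With ≥2 chains the fit reports the classic
  Gelman–Rubin PSRF per parameter,
  $\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$, flagged at 1.1. Identical
  chains give $\hat R = \sqrt{(n-1)/n}$, the formula's floor. A
  split-chain variant is available. Single-parameter stationarity uses a
  Cramér–von Mises bridge statistic with a fixed-bandwidth Bartlett
  long-run variance (bandwidth $\approx 1.5\,n^{1/3}$), iteratively
  discarding up to half the chain; the fixed bandwidth is what lets a
  trending chain fail the test, since adaptive (AR-fit) spectral
  estimators absorb trends into the variance and rarely reject.

Posterior summaries follow the quantitative-genetics convention:
kernel-density mode (Gaussian kernel, Silverman bandwidth, configurable
since modes are bandwidth-dependent), median, and 95% highest-posterior-
density intervals. HPD rather than equal-tail intervals matter for
variance parameters, whose posteriors are right-skewed with mass piled
near zero.

The **posterior predictive check** simulates replicate datasets from
posterior draws and locates the observed zero fraction within the
replicate distribution — the natural statistic for recruit counts, which
are prone to zero inflation. The **pMCMC** for the cue slope is twice
the fraction of draws whose sign differs from the posterior median's.

## The animal model

Lay date (in days, per clutch) is decomposed as

$$y = X\beta + Z_a a + Z_{pe}\,pe + Z_m m + Z_y yr + e,$$

with clutch number the only non-intercept fixed effect (it absorbs most
of the right skew of lay dates, since replacement clutches are laid
weeks later), additive genetic effects $a \sim N(0, A\sigma^2_A)$
structured by the pedigree relationship matrix, and i.i.d. permanent
environment (female), social-mate, year and residual effects. The
phenotypic variance for heritability excludes the year component but
includes the fixed-effect variance, computed per posterior draw as the
population variance (denominator $n$) of $X\beta$ over the observed
records: $h^2 = V_A / (V_F + V_{Mate} + V_{PE} + V_A + V_R)$,
$r^2 = (V_A + V_{PE})$ over the same denominator.

**Priors.** The residual variance takes a scaled-inverse-$\chi^2$ prior
with $V = 1$, $\nu = 0.02$ (minimally informative). Each random-effect
variance takes the marginal distribution implied by parameter expansion
with $V = 1$, $\nu = 1$, $\alpha_\mu = 0$, $\alpha_V = 1000$: writing
the effect as $\alpha\gamma$ with $\alpha \sim N(0, 1000)$ and
$\sigma^2_\gamma$ inverse-gamma(½, ½) makes the variance
$1000 \times F(1,1)$-distributed — equivalently, a half-Cauchy prior
with scale $\sqrt{1000}$ on the standard deviation. This keeps mass near
zero (so a null $V_A$ is not pushed upward) without the boundary
pathologies of the inverse-gamma.

**Sampler.** Rather than Gibbs-cycling between effects and variances —
which mixes poorly when $V_A$ and $V_{PE}$ trade off — the sampler
integrates *all* location effects out analytically: for a variance
vector $v$, the marginal log-posterior needs one sparse Cholesky
factorisation of the mixed-model equations
$C = W'W/\sigma^2_e + \mathrm{blockdiag}(0, A^{-1}/\sigma^2_A, I/\sigma^2_{PE}, \ldots)$,
assembled at the slot level from a precomputed sparsity pattern. The
five log-variances move as one joint random-walk proposal (scales
adapted toward 0.25 acceptance during burn-in; the residual proposal
scaled by $1/\sqrt{n}$ since it is far better identified), so the
variance chain targets the marginal posterior directly; location effects
(and hence $V_F$, $h^2$) are drawn from their exact Gaussian conditional
at each retained iteration. $A^{-1}$ is built directly from the pedigree
with the inbreeding-adjusted rules, after pruning to phenotyped females
and their ancestors (a pure size optimisation — relationships among kept
individuals are unchanged, which the tests verify).

The reference protocol is 500,000 iterations, thinning 10, burn-in
3,000, with an effective-sample-size warning threshold of 8,000;
simulation studies and examples use shorter runs (stated per test below)
with the warning threshold lowered accordingly.

**Mother–daughter regression.** Daughter mean lay dates regressed on
mother mean lay dates estimate $h^2$ as twice the slope (single-parent
regression). The raw slope is reported alongside, flagged prominently,
because published values are sometimes left undoubled; fewer than 30
pairs triggers a low-power warning.

## Selection statistics

Relative fitness is $w_i = W_i / \bar W$. The Robertson differential is
$S = \mathrm{cov}(\text{trait}, w)$ with the sample ($n-1$) covariance —
the denominator is switchable since conventions differ — and a
record-level non-parametric bootstrap SE (seeded; degenerate resamples
are skipped and counted). Lande–Arnold gradients regress $w$ on the
internally standardized trait and its square; $\gamma$ defaults to twice
the quadratic coefficient (the curvature of the selection surface), with
a raw-coefficient mode, because both conventions circulate. The unit of
analysis is the breeding record (brood); female-season aggregation is a
caller-side `dplyr::summarise()` away.

## Phenology model selection

Candidate age encodings for the start of breeding season: linear,
quadratic, broken lines with a knot at 2 or knots at 2 and 6
(hinge terms $\max(0, \text{age} - k)$), one slope per age transition,
and a first-year indicator plus a flat 2–6 segment and a slope above 6.
On integer ages the "breaks at 2 and 6" and "first-year + break at 6"
bases span the same column space — ages 1 and 2 are two points, so a
segment slope and a jump are indistinguishable — and they return
identical log-likelihoods; which label wins a selection run is numerical
noise, and both are provided.

The stepwise procedure: (1) each candidate variable alone against the
null model, discarded unless it improves AIC by more than 2 (the
operationalisation of "significant on its own"; the threshold is an
argument); (2) survivors form a full model, with mutually exclusive
encodings reduced to the best-AIC member; (3) iterated drop-one,
keeping a drop whenever it lowers AIC, to a fixed point; (4) the
inferential model is the most parsimonious subset within ΔAIC < 2 of the
best predictive model. AIC is computed at ML while reported estimates
come from REML (Gaussian case; Satterthwaite p-values via lmerTest), the
standard resolution of the ML/REML tension in mixed-model AIC. The full
trace (model, k, logLik, AIC, decision) is returned and serialisable as
TSV. Inbreeding, which deletes most rows when included, is meant to be
tested in a separate reduced-data pass rather than pooled — the
candidate list is caller-controlled, so this is a usage convention
documented here rather than enforced.

Year enters as a random intercept by default; the temporal-trend test
adds standardized year as a fixed effect with and without the year
random term, exposed through `fit_mixed_model()` arguments.

## Stage-wise survival and female outcomes

Each juvenile transition (egg→hatchling, hatchling→fledgling,
fledgling→recruit, egg→recruit) is a per-clutch Binomial (trials = count
at the earlier stage), modelled with the AIC procedure over quadratic
lay date, clutch number, a young/middle (2–6)/old (>6) age class, and
standardized tarsus, with year and female random intercepts. Stages with
no variation are skipped with a flag. When the quadratic lay-date term
survives, the optimum model ($A_{\max} = 1$) is fitted for that stage.
Note one structural caveat: the Gaussian curve forces survival toward 0
far from the optimum, while a real stage may have a floor; when the
generating process has a floor, the fitted optimum shifts toward the
side with data support, which is visible in the synthetic study.
Reclutching (more than one clutch) and female survival to the next
season are Binomial mixed models on the female-season table; the final
season is right-censored for survival and excluded.

## The synthetic study generator

`generate_breeding_data()` simulates the study the package was designed
for: two founder releases, 16 seasons, overlapping generations,
polygamy with ~60% extra-pair paternity, clutches of 3–5 eggs,
adult survival 0.75 with a carrying cap enforced by removing surplus
new recruits (as translocation harvests do). Lay dates combine the age
structure (first-year +12.5 d; flat over 2–6; +1.33 d/yr beyond 6),
tarsus (−1.70 d/mm), a temperature cue (−18.28 d/°C on the window mean),
an extra year effect (SD 5.3 d), breeding values transmitted down the
realized pedigree (V_A = 27), permanent environment (46.1), mate (14.6)
and per-clutch residual (161) effects — the ~830 days² scale of real
lay-date data. Hatching is flat at 0.73; hatchling→fledgling follows a
Gaussian curve of lay day (peak 0.82 near mid-October, floor 0.12),
which is the sole source of stabilizing selection; fledglings recruit
with probability 0.33 and feed back into later breeder pools. Because
clutch-level fitness compounds that curve with its floor, clutch sizes
and the clutch-number mixture, the Gaussian-curve model is (by design)
misspecified for the generated recruit counts: the fitted fitness
optimum is a pseudo-true quantity that can sit well before the survival
curve's peak and varies noticeably between simulated studies, while the
optimum-versus-mode discrepancy itself is robust. The well-specified
recovery checks use `simulate_optimum_data()`, which draws directly from
the curve model.
Temperatures are an annual sinusoid (warmest mid-January) plus daily
noise and a per-season offset; the cue window is anchored at day 51,
matching the grand-mean start of breeding the default configuration
realises, so the cue the analysis measures is the cue the birds respond
to. Defaults were chosen once to land near ~300 breeding females,
~1,400 clutch records and a lay-date mode in early November; demographic
parameters not fixed by that target (founder numbers, adult survival,
the cap) are ordinary values for a managed island passerine.

One base seed fans out to per-component streams (temperature, then
demography) through a fixed integer scheme, so regenerating one
component is stable under unrelated config edits, and the whole study is
byte-identical under a repeated seed.

What the generator does *not* emulate: observation error in dates or
counts, unbanded immigrants, partial pedigree knowledge (every chick's
genetic sire is recorded; real studies reconstruct paternity with
uncertainty), nest failure before laying is complete, density-dependent
survival, or any particular island's real temperature record. Passing
recovery tests on this generator therefore shows the estimators are
correct under the model's own assumptions at realistic size and
signal-to-noise — not that those assumptions hold in any particular
field system.

## Power analysis

`run_power_study()` simulates a trait over the observed record structure
with breeding values from the pedigree, equal variances $v$ for the
permanent-environment, mate and year effects ($v$ defaults to 7% of the
total, the share these components hold in real lay-date data), and
$V_A$, $V_R$ solved so the heritability (year excluded) hits the target
and the total variance (year included) matches the data scale.
Infeasible allocations error with the offending component. Each
replicate is refitted with the animal model (reduced chains by default,
flagged through the stored settings) and summarised by posterior mean,
median, mode and 95% HPD interval of $h^2$; `summarize_power()` turns a
replicate table into fractions above a reference estimate and CI
coverage of the target.

## Problem sizes used by the tests

The acceptance-style tests run at sizes chosen to exercise the full
stack while staying desk-scale: optimum-model recovery and
mode-displacement detection use 20 replicates of 1,400 records × 16
years with 2 chains × 10,000 iterations; the zero-heritability bound
uses the full ~1,500-record synthetic study; the $h^2 = 0.4$ coverage
and the power study use a ~470-record, 10-season study with 4,000-
iteration fits (15–20 replicates); stepwise-selection replicates use
10-season studies. The vignette states these as the package's chosen
simulation sizes; the same code scales to reference-length runs by
raising the protocol arguments.

## Known limitations

* The optimum sampler is single-site random walk; for very flat
  likelihoods ($\sigma$ near its upper bound) mixing of $\sigma$ and $A$
  slows, which the PSRF table makes visible.
* The animal model's joint variance proposal trades per-iteration
  mixing for exact marginalisation; effective sample sizes per iteration
  for $V_A$ are modest and long runs remain necessary for tight
  credible intervals on small variance components.
* $V_A$ and $V_{PE}$ are genuinely confounded in short pedigrees with
  strong repeated-measures structure; at a true $h^2$ of a few percent,
  posterior mass concentrates low and some additive variance is absorbed
  by the permanent-environment component. The power study is the honest
  instrument for judging what the data could detect.
* The per-female random effect on the fitness optimum (heterogeneity in
  individual optima) is not implemented; the year level is the only
  optimum-varying stratum.
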