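---
title: "Methods: covariate-adjusted inference for two-stage adaptive multi-arm designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariate-adjusted inference for two-stage adaptive multi-arm designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amad)
```

## The design

`amad` implements a two-stage adaptive multi-arm design (AMAD): stage 1
randomises `J` subjects to each of `K` active interventions and a shared
control (arm 0); an interim analysis applies a pre-specified selection rule
to the stage-1 treatment statistics; stage 2 randomises a further `J`
subjects per arm to the control and to each selected intervention. The total
sample size with top-1 selection is therefore `J*(K+1) + 2J`. The final
analysis must deal with two complications at once: multiplicity (many-to-one
comparisons) and adaptivity (the stage-2 design depends on stage-1 data).

Everything in the package is organised around the linear analysis model

$$Y_{jk} = \alpha_0 + \sum_{k=1}^{K}\beta_k\,\mathbb{1}(T_j = k)
  + \gamma_1 X_{1jk} + \gamma_2 X_{2jk} + \epsilon_{jk},
  \qquad \epsilon_{jk}\sim N(0,\sigma^2),$$

fitted by OLS to stage-1 data (selection), stage-2 data (post-selection
inference), and the pooled data (the "overall" estimator). Setting a
$\gamma_p$ to zero is exactly "not adjusting for $X_p$"; the adjustment set
is a first-class argument everywhere and, deliberately, the *same* set is
used at the interim and final analyses. Covariates are not centred: the
contrast coding makes $\hat\beta_k$ invariant to covariate location, so
centring would change nothing that the package reports.

The data-generating model draws $(X_1, X_2, Y)$ *jointly* from a per-arm
multivariate normal in which the covariates are mutually independent and
covariate $p$ has correlation $\rho_p$ with the outcome. Simulating jointly
(rather than outcome-given-covariate) matters: it makes the covariate means
irrelevant to every operating characteristic, which is why the benchmark
grid can fix them at 0.5 without loss.

## Selection

`select_top(k)` ranks arms by the covariate-adjusted stage-1 t-statistic
$\hat\beta_k^{(1)}/\tau_{(1),k}$ and keeps the best `k`;
`select_threshold(c)` keeps every arm whose statistic exceeds `c` and flags
futility when none does. t-statistics (estimated $\sigma$) rather than
z-statistics are used because $\sigma$ is never known in practice; with
J = 100 per arm the difference is negligible. Exact ties are broken by the
lower arm index — a measure-zero event for continuous data, fixed
deterministically so that reruns are bit-identical. Random tie-breaking was
rejected for exactly that reason.

## Testing: Dunnett, combination, closure

Strong familywise error control is obtained by closed testing. For every
non-empty subset $S$ of elementary hypotheses $H_{0k}\colon \mu_k \le 0$,
a stage-wise Dunnett p-value is computed from that stage's fit:
$p_S = 1 - P\!\left(\max_{k\in S} Z_k \le \max_{k\in S} t_k\right)$ under a
central multivariate normal whose correlation is the plug-in contrast
correlation $G_{ij}/\sqrt{G_{ii}G_{jj}}$ from the realized design
($G = [D^{\!\top}D]^{-1}$ restricted to the treatment block). Stage-wise
p-values are merged by the weighted inverse-normal combination
$p = 1 - \Phi\!\left(w_1\Phi^{-1}(1-p_1) + w_2\Phi^{-1}(1-p_2)\right)$, and
an elementary hypothesis is rejected only if every intersection containing
it is rejected at level $\alpha$ (one-sided $\alpha = 0.025$ throughout the
benchmarks). A Fisher product combination is provided as an alternative.

Three design choices deserve a note, because each had a genuine alternative:

* **Normal, not multivariate-t, Dunnett kernel.** The stage-wise statistics
  are t-statistics, but the joint Dunnett probability is evaluated under the
  multivariate normal. With J = 100 per arm the residual df are ~295+ at
  stage 1, where the two are indistinguishable to well below the
  Monte-Carlo resolution of any benchmark here; the normal kernel permits a
  deterministic quadrature (`mvtnorm`'s Miwa algorithm, 128 grid points)
  rather than the randomised Genz–Bretz integration, keeping every p-value
  reproducible bit-for-bit and leaving the engine's RNG stream untouched.
  The univariate case uses the exact tail (`df` honoured if supplied).
* **Stage weights.** $w_t = \sqrt{n_t/(n_1+n_2)}$ by default, i.e.
  $w_1 = w_2 = 1/\sqrt2$ for the equal-stage benchmark design. Weights are
  pre-specified in the scenario and never data-dependent (beyond the planned
  stage sizes); the combination is symmetric under swapping $(p_1, w_1)$
  with $(p_2, w_2)$.
* **Deselected arms.** When $S$ contains no selected arm there is no stage-2
  information, and the combined test is made incapable of rejecting by
  setting $p^{(2)}_S := 1$ (which forces a combined p-value of 1 under the
  monotone inverse-normal map). A deselected intervention can therefore
  never be claimed effective — its marginal rejection probability is bounded
  by its selection probability, which is why each elementary hypothesis
  rejects at roughly half the FWER under the null with top-1 selection out
  of two arms. Threshold-rule trials that select nothing still count in
  every error-rate denominator.

## Estimation and the conditionally unbiased estimator

Interim selection biases the naive estimators upwards: the selected arm had
to look good at stage 1. The package reports four estimators per selected
arm `s`:

* stage-1 $\hat\beta_s^{(1)}$ (drives selection; conditionally biased
  upwards),
* stage-2 $\hat\beta_s^{(2)}$ (unbiased — post-selection data only — but
  inefficient),
* overall $\hat\beta_s$ from the pooled fit (biased, roughly half the
  stage-1 bias with equal stage sizes),
* the UMVCUE $\hat U_s$, the uniformly minimum-variance estimator unbiased
  *conditional on the realized selection event*.

The UMVCUE construction conditions on the complete sufficient statistics
$Z_{i,s} = \hat\beta_i^{(1)} + (V_{i,s}/\tau_{(2),s}^2)\hat\beta_s^{(2)}$,
$i = 1,\dots,K$, where $V_{i,s} = \sigma^2[D^{(1)\top}D^{(1)}]^{-1}_{i,s}$.
Conditionally on the $Z$'s, a bivariate-normal calculation gives

$$\hat\beta_s^{(2)} \mid Z \;\sim\; N\!\left(m_s,\ \eta_s^2\right),
  \qquad
  m_s = \frac{\tau_{(2),s}^2 Z_{s,s}}{\tau_{(1),s}^2 + \tau_{(2),s}^2},
  \qquad
  \eta_s = \frac{\tau_{(2),s}^2}{\sqrt{\tau_{(1),s}^2 + \tau_{(2),s}^2}},$$

free of the unknown $\beta_s$ — this conditional slope
$\tau^2_{(2),s}/(\tau^2_{(1),s}+\tau^2_{(2),s})$ and residual variance
$\eta_s^2$ are verified by simulation in the test suite. Holding the $Z$'s
fixed, each ranking inequality
$\hat\beta_i^{(1)}/\tau_{(1),i} \ge \hat\beta_{i+1}^{(1)}/\tau_{(1),i+1}$
(arms relabelled into the realized ranking order) is *linear* in
$\hat\beta_s^{(2)}$, so the selection event restricts $\hat\beta_s^{(2)}$ to
an interval $[c_2, c_1]$, with $\min\{\emptyset\} = +\infty$ and
$\max\{\emptyset\} = -\infty$ for unconstrained sides (a single intervention
gives an untruncated interval). The UMVCUE is then the mean of
$N(m_s, \eta_s^2)$ truncated to $[c_2, c_1]$:

$$\hat U_s = m_s - \eta_s\,
  \frac{\phi(W_1) - \phi(W_2)}{\Phi(W_1) - \Phi(W_2)},
  \qquad W_l = (c_l - m_s)/\eta_s .$$

Because flattened renderings of this formula are easy to mis-transcribe
(which $\tau$ is a standard deviation, which bound standardises to which
$W$), the package does not trust any single reading: the closed form
(`umvcue()`), an adaptive-quadrature evaluation of the defining ratio of
integrals (`umvcue_numeric()`, relative tolerance 1e-10) and a
Rao–Blackwell Monte-Carlo oracle (`umvcue_mc()`) are all implemented
independently and required to agree (1e-6 / 3 Monte-Carlo SEs) in the test
suite, on hand-built bundles and on freshly simulated trials. The
Monte-Carlo oracle arbitrated the sign convention of the correction term on
asymmetric cases before the closed form was frozen.

Further choices:

* **Top-k with k ≥ 2** conditions each selected arm's UMVCUE on the *full*
  observed ranking (all K−1 consecutive inequalities), not merely on
  membership of the selected set. That is the conservative reading of the
  rank-based construction; it uses slightly more conditioning information
  than strictly necessary for unbiasedness, never less.
* **Threshold rules** have no special closed form: their per-arm crossing
  constraints are also linear in $\hat\beta_s^{(2)}$, so the same interval
  machinery applies, with the quadrature route as the general fallback.
* **Plug-in variances.** $\tau^2$ and $V$ use each fit's own estimated
  $\sigma^2$ (stage-1 $\hat\sigma^2$ for selection and stage-1 quantities,
  stage-2 $\hat\sigma^2$ for $\tau_{(2),s}^2$). The estimator is derived
  under known variances; the test suite confirms it remains empirically
  unbiased under plug-in at J = 100.
* **Tail stability.** The truncated-normal mean is evaluated in log space:
  both $\log\phi$ and $\log\Phi$ differences are formed with
  `pnorm(log.p = TRUE)` and a log1p-based difference, so intervals eight or
  more standard deviations into a tail still return a finite mean hugging
  the near bound (the Mills-ratio regime) instead of 0/0. The quadrature
  route refuses regions of mass below 1e-300 rather than dividing by zero.
* **No UMVCUE interval.** No established construction yields valid
  confidence intervals for the UMVCUE, so none is attached; Wald intervals
  accompany only the three naive estimators, with the caveat that the
  stage-1 and overall intervals inherit the selection bias of their centres.

## The replication engine

`run_grid()` replicates trials under each scenario with every adjustment
approach analysing the *same* stage-1 data (required for the disagreement
measure to be meaningful); approaches whose selected sets coincide share
stage-2 data, while differing selections imply genuinely different stage-2
trials and get independent draws. Each replication runs on its own
pre-assigned L'Ecuyer-CMRG substream spawned from the root seed, so results
are independent of the worker count and any single replication can be
reproduced in isolation. Bias and MSE are *unconditional over selection*:
each replication contributes the selected arm's error against that arm's
true effect. Stage-2 data are drawn from the same arm distributions as
stage 1 — no time trend; modelling one is out of scope, and the pooled fit
correspondingly contains no stage main effect.

## The benchmark scenario grid

`scenario_grid()` encodes the study conditions used throughout: K = 2,
J = 100, $\mu_{X_1} = \mu_{X_2} = 0.5$, unit variances, top-1 selection,
one-sided $\alpha = 0.025$, crossed over four correlation patterns
(DGM1 (0,0), DGM2 (0,0.2), DGM3 (0.2,0.2), DGM4 (0.1,0.6)) and five outcome
mean configurations (Null (0,0,0); LFC50 (0,0,0.22); LFC80 (0,0,0.304);
STEP50 (0,0.11,0.22); STEP80 (0,0.152,0.304)). The LFC effect sizes are the
ones that calibrate the unadjusted analysis under DGM1 to 50% and 80%
disjunctive power, which the acceptance suite re-verifies rather than
assumes. A supplementary many-covariate situation (six extra covariates
uncorrelated with the outcome) needs no special code path: construct a
scenario with `n_covariates = 8` and zero trailing correlations.

What the generator does *not* emulate — and hence what passing benchmarks do
not certify about real trials: non-normal outcomes or covariates, dropout
and missing data, recruitment-timing and time trends between stages,
covariate-adaptive randomization, and population drift. The four-arm COPD
preset (`inhance_scenario()`) is parameterised from published arm-level
summary statistics (means and SDs of trough FEV1, baseline FEV1,
reversibility); the source does not report covariate–outcome correlations,
so they are an explicit argument with default `c(0.7, 0.2)` — a strong
baseline/follow-up correlation for lung function and a weak positive one
for reversibility, typical of bronchodilator trials. Conclusions sensitive
to that default should vary it.

## Problem sizes in the shipped checks

The test and acceptance runs use 1e4 replications for headline cells and
3e3 for the error-control sweep across all DGM-by-configuration cells with
true nulls, with every comparison at 3 Monte-Carlo standard errors of the
quantity at that replication count (plus half a unit of printed precision
where a rounded reference value is involved). These sizes put the
Monte-Carlo SE of an error rate near 0.0016 — small enough to separate real
miscalibration from noise — while keeping a full suite run within minutes
on one core. `scripts/acceptance.R` recomputes the same quantities from
scratch at 1e4 replications per cell from a user-supplied seed.

## Known limitations

* Two stages only; no error-spending, group-sequential boundaries, or
  sample-size re-estimation (the sample-size search described for this
  design family is a thin loop over `run_grid()` that users can script).
* Intersection tests other than Dunnett (Simes, Šidák, likelihood ratio)
  are not implemented.
* Binary and survival endpoints are out of scope; the mean difference is
  collapsible, which is precisely what makes the marginal/conditional
  distinction harmless here — odds and hazard ratios would not be.
* The UMVCUE's conditioning assumes the pre-specified rule was actually
  followed; `amad()` warns and conditions on the observed selected set when
  the stage-2 arms contradict the recomputed selection, but the resulting
  estimator is then only as trustworthy as that conditioning.
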