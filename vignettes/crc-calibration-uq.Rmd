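---
title: "Methods: natural-history model, Bayesian calibration, and the value of calibrated-parameter uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: natural-history model, Bayesian calibration, and the value of calibrated-parameter uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crcuq` implements a complete, desk-scale pipeline for studying how the
uncertainty of *calibrated* microsimulation parameters should be
characterized in a cost-effectiveness analysis (CEA), using a nine-state
natural-history model of colorectal cancer (CRC) as the test bed. This
vignette is the package's methods account: the model and its assumptions,
the calibration machinery, the screening CEA, the four uncertainty
characterizations, and the numerical and design choices that were
genuinely open.

## The natural-history model

Nine health states follow the adenoma–carcinoma sequence: `normal`,
`small_adenoma` (< 1 cm), `large_adenoma` (>= 1 cm), preclinical
(asymptomatic, undiagnosed) early- and late-stage CRC, clinical early- and
late-stage CRC, CRC death, and other-cause death. The two death states are
absorbing. Progression is a continuous-time Markov process with
age-dependent adenoma onset

$$\lambda_1(a) = l\,\gamma\,a^{\gamma-1},$$

a Weibull hazard in age $a$ with scale $l$ and shape $\gamma$, and
constant annual rates elsewhere: $\lambda_2$ (small to large adenoma),
$\lambda_3$ (large adenoma to preclinical early CRC), $\lambda_4$
(preclinical early to preclinical late), $\lambda_5$ (preclinical early to
clinical early), $\lambda_6$ (preclinical late to clinical late),
$\lambda_7$ and $\lambda_8$ (CRC death from clinical early/late stage).
Other-cause mortality $\mu(a)$ applies from every alive state. Collecting
these in the 9x9 generator $Q(a)$, the annual-cycle transition matrix is
the matrix exponential

$$P(a, t) = \exp(t\,Q(a)), \qquad t = 1,$$

so an individual can cross several states within one year (e.g. large
adenoma to clinical CRC). `transition_probability_matrix()` evaluates the
exponential with `Matrix::expm` (Padé scaling-and-squaring); the test
suite cross-checks it against an independently coded truncated-series
oracle.

Modelling assumptions worth making explicit:

* Clinical early-stage CRC does not progress to clinical late-stage: once
  detected, treatment is implicit and the only exits are CRC death
  ($\lambda_7$) and other-cause death.
* Ages are integer years, the cycle length is fixed at one year, and the
  cohort (women aged 50) is followed to age 100. No half-cycle correction
  is applied anywhere — the microsimulation accrues per annual cycle.
* The cohort enters at age 50 with adenoma prevalence `padeno`, a fraction
  `psmall` of which are small, plus fixed preclinical early/late CRC
  prevalences of 0.12% and 0.08% (the printed values are percentages).
* $\mu(a)$ enters $Q(a)$ as an annual *rate*; life tables supplying
  probabilities $q_x$ are converted via $-\log(1 - q_x)$.

Two equivalent model evaluators exist: `cohort_trace()` propagates
expected state occupancy deterministically (the expectation of the
microsimulation) and `simulate_individuals()` draws individual annual
paths by a single categorical draw per year from the relevant row of
$P(a)$. Tests verify that microsimulation means converge to the trace at
the Monte-Carlo rate.

### Output conventions

`model_outputs()`/`aggregate_outputs()` reduce either evaluator to four
age-specific quantities: adenoma prevalence (carriers over alive),
proportion of small adenomas (small over carriers), and clinical CRC
incidence by stage per 100,000 person-years *at risk*. "At risk" means
alive without clinical CRC, the cancer-registry convention; the source
material is silent on the denominator, and this choice is flagged here
deliberately. An incidence event is an individual non-clinical at age $a$
and clinical at $a+1$; the rare within-year path through a clinical state
to CRC death is excluded identically in both evaluators, so the two remain
mutually consistent. Cells with an empty denominator are `NA`, never a
silent zero.

## Background mortality fixture

The package ships a synthetic Gompertz–Makeham schedule,
$\mu(a) = A + B e^{ka}$ with $A = 9\times10^{-4}$, $B = 6\times10^{-6}$,
$k = 0.112$, chosen once so that remaining life expectancy at 50 is 33.2
years — plausible for US women around 2014, the cohort the model
emulates. It stands in for a published life table so the package has no
external data dependency; `read_life_table()` accepts any
`age,mortality_rate` (or `qx`) CSV if you want a real schedule.

## Synthetic calibration targets

`generate_targets()` defines the study conditions: the microsimulation is
run at the generating ("true") parameter values with 100 replications —
adenoma-related targets on cohorts of 500 individuals, stage-specific
incidence targets on cohorts of 100,000 — and each target cell is
summarized by its mean across replications and its standard error, taken
as the *standard deviation across replications*. Each replication is one
study of the stated size, so this SD is the sampling error of one observed
dataset, which is exactly what the likelihood below needs; dividing by
$\sqrt{100}$ would instead describe the precision of the simulated mean.
A floor of $10^{-6}$ keeps degenerate zero-variance cells usable; cells
undefined in every replication are dropped with a warning.

Age bins were an open choice. Adenoma prevalence and the small fraction
are taken cross-sectionally at ages 50, 55, 60, 65 and 70; incidence in
five-year bins from 52–56 to 82–86. Age 50 is included for the adenoma
targets because `padeno` and `psmall` are defined as age-50 quantities:
an age-50 prevalence cell directly informs the product
`padeno * psmall`, and with it the joint posterior of the two initial
parameters shows the moderate positive correlation (~0.5) expected from a
prevalence constraint, rather than an inflated one.

## Bayesian calibration

Nine parameters
$\theta_u = (p_{adeno}, p_{small}, l, \gamma, \lambda_2,\dots,\lambda_6)$
are calibrated; $\theta_k = (\lambda_7, \lambda_8)$ are treated as known
(registry-estimable). Priors (see `crc_priors()`): beta for the two
proportions, lognormal for the seven positive parameters. Each target cell
$y_{ta}$ is modelled as

$$y_{ta} \sim \mathrm{Normal}\big(\phi_{ta}(\theta),\ \sigma_{ta}\big),$$

with $\phi$ the expected model output and $\sigma_{ta}$ the target SE;
cell log-densities add up to the calibration log-likelihood. By default
$\phi$ comes from the deterministic cohort trace. This is an intentional
design decision: $\phi$ is defined as an expectation, the trace computes
that expectation exactly, the likelihood becomes noise-free, and desk-scale
calibration becomes feasible (one evaluation costs ~6 ms). A stochastic
variant (`n_micro` in `log_likelihood()`) estimates $\phi$ by
microsimulation instead; it is orders of magnitude more expensive and
makes the likelihood surface noisy, but it is the fuller representation of
a simulation model whose outputs are themselves estimates. One observable
consequence of the noise-free choice: along near-non-identified parameter
ridges (notably $\lambda_4$–$\lambda_5$, which the incidence targets
constrain mostly through a product-like combination) the deterministic
posterior is an extremely sharp ridge with pair correlation ~0.95; a noisy
likelihood rounds such ridges and yields visibly lower pair correlations
at the same marginal widths.

### The IMIS sampler

`run_imis()` implements incremental mixture importance sampling on
transformed parameters (logit for proportions, log for positive
parameters, Jacobian-corrected densities):

1. draw $n_0$ points from the prior;
2. *optimization stage*: quasi-Newton (BFGS) maximizations of the
   log-posterior started from the best initial draws; each distinct local
   maximum contributes a Gaussian mixture component with inverse-Hessian
   covariance, seeded with $b$ draws. With a posterior concentrated on a
   curved 9-dimensional ridge this stage is what makes desk-scale runs
   mix: without it the incremental stage alone needed an order of
   magnitude more iterations and still under-covered the ridge;
3. incremental stage: compute importance weights
   $w \propto p(\theta)L(\theta)/q(\theta)$ under the current mixture
   proposal $q$, centre a new component at the highest-weight draw with
   covariance estimated from its $b$ nearest neighbours
   (weight-adjusted, ridge-regularized by $10^{-8}\,\mathrm{tr}$ when
   ill-conditioned), draw $b$ new points, recompute all weights;
4. stop once the effective sample size $ESS = 1/\sum \tilde w_i^2$
   reaches its target (or at `max_iters`), then resample with
   replacement.

Hyperparameters were open choices. Full profile: $n_0 = 5000$, $b = 500$,
ESS target 5000. Desk profile (`imis_control_desk()`): $n_0 = 1000$,
$b = 100$, ESS target 1000, at most 100 increments, 6 optimizer starts,
final resample of 5000 — a calibration then takes 1–2 minutes on one
core and typically converges in 25–70 increments. Batch likelihood
evaluations are order-independent, so they could be parallelized without
changing results; the implementation runs them serially.

`crc_calibrate()` wraps targets + priors + sampler into a fitted-model
object with the usual verbs (`summary`, `coef`, `predict`, `plot`,
`simulate`, `residuals`). `summary()` reports posterior means, SDs, the
MAP draw (highest evaluated posterior density), equal-tailed 95% credible
intervals and the 9x9 Pearson correlation matrix of the resampled draws.
`predict()`/`posterior_predictive()` evaluates model outputs over
posterior draws and reports 95% posterior-predicted intervals per target
cell — the internal-validation check that the calibrated model
reproduces its own targets.

## Screening cost-effectiveness

`simulate_strategy()` overlays 10-yearly colonoscopy screening from age
50 (stopping at 85) on the microsimulation. Detected small/large adenomas
are removed (polypectomy, return to normal) and put the individual under
surveillance every 5/3 years with an adenoma-onset hazard ratio of 2/3
(low/high risk class, absorbing at the higher class); detected preclinical
CRC converts to the clinical state of the same stage. A negative exam
returns the individual to the 10-year routine clock — including after a
negative surveillance exam, an open point resolved here in favour of the
simpler single "next due age" bookkeeping. Within a cycle the order is:
test and relocation, then the annual transition draw, then accrual based
on the post-test state; individuals dying within the cycle accrue neither
that cycle's utility nor annual care cost. False positives in the normal
state carry no cost beyond the colonoscopy itself.

Costs (colonoscopy $10{,}000$; annual clinical early/late care
$21{,}524$/$37{,}000$) and stage utilities (preclinical 1.000, clinical
early 0.855, late 0.300; non-CRC states 1) follow the external parameter
table (`cea_param_table()`). The discount rate is *not* part of that
table; the package defaults to 3%/year on both costs and QALYs
(configurable, including 0). Absolute EVPI magnitudes depend on this
choice, so it is surfaced prominently rather than buried.

The two strategies are always simulated with common random numbers: the
transition-uniform stream consumes exactly `n` draws per cycle regardless
of who is alive or relocated, and detection draws use a separate stream,
so incremental outcomes difference out most Monte-Carlo noise.

## The four uncertainty characterizations and the value of information

`draw_parameters()`/`run_psa()` implement four PSAs that differ only in
how parameter uncertainty enters:

* **A1** — $\theta_u$ resampled from the joint IMIS posterior; external
  parameters sampled from distributions refit to their printed value
  (mean-anchored) and 95% interval (percentile least squares) —
  `fit_external_distributions()`;
* **A2** — $\theta_u$ fixed at the MAP; externals sampled;
* **A3** — $\theta_u$ from the posterior; externals fixed at their means;
* **A4** — each component of $\theta_u$ sampled *independently* from a
  beta (proportions) or lognormal (positive parameters, including $l$ and
  $\gamma$) distribution moment-matched to its posterior mean and SD —
  the correlation-free characterization.

`evpi_curve()` computes per-patient expected value of perfect
information,

$$EVPI(\lambda) = \mathrm{E}\big[\max_s NB_s\big] - \max_s \mathrm{E}[NB_s],
\qquad NB_s = \lambda\,\mathrm{QALY}_s - \mathrm{Cost}_s,$$

over a willingness-to-pay grid of \$0–150,000 in \$1,000 steps (covering
every threshold at which the approaches are compared). Expected
behaviour, asserted by the test suite at desk scale: the spread of
incremental outcomes orders A4 > A1 > A3 with A1 ≈ A2; EVPI is
non-negative everywhere; at \$66,000/QALY the correlation-free A4 has the
largest EVPI and A3 the smallest. Ignoring the posterior correlations
(A4) overstates the value of resolving uncertainty — the central
methodological point this pipeline exists to demonstrate.

Nested Monte-Carlo noise deserves a caution: each PSA draw evaluates both
strategies on a finite cohort (`n_micro`), and that within-draw noise
inflates both outcome spreads and EVPI. The desk profile (500 draws x
2,000 individuals) is adequate for the orderings above but overstates
absolute EVPI dollar values; before quoting absolute values, double
`n_micro` until the EVPI curve stabilizes (the full profile uses 5,000
draws x 100,000 individuals).

## Problem sizes used by the shipped checks

The test suite and the bundled acceptance script run entirely at the desk
profile, a deliberate package choice: targets from 30 replications
(cohort sizes 500/100,000 as above), IMIS to ESS 1000 with 5,000
resampled draws, posterior-predictive checks on 300 draws, PSAs of 150
draws x 2,000 individuals. A full-profile run (`crc_config("full")`)
reproduces the generating study scale and is sized for a cluster, not a
laptop.

## Known limitations

* One lesion per person: detection sensitivity applies to the person's
  current state, not to individual adenomas of a multi-adenoma carrier.
* The deterministic likelihood sharpens near-non-identified ridges (see
  above); pairwise posterior correlations along such ridges are
  configuration-sensitive quantities.
* Synthetic targets only: the pipeline calibrates to data the model
  itself generated, which validates machinery (parameter recovery,
  coverage), not the model's fidelity to any real population. Passing
  tests say nothing about real screening policy.
* No colonoscopy complications, adherence, competing screening
  modalities, sex-mixed cohorts, or population-level EVPI scaling.
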