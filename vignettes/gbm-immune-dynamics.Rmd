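---
title: "Modelling glioblastoma-immune dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glioblastoma-immune dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmimmune)
```

## The model

`gbmimmune` implements a three-population ODE model of the glioma
microenvironment: tumor cells $C$, activated (CD3$^+$) T cells $T$, and
monocytic myeloid-derived suppressor cells (MDSCs) $M$, all in units of
cells and days:

$$
\begin{aligned}
\frac{dC}{dt} &= \lambda_C C\Big(1-\frac{C}{C_\mathrm{max}}\Big) - \eta T C,\\
\frac{dT}{dt} &= \frac{a_T + s_T T C}{1+\rho T (T+\epsilon_C C)} - r T M - d_T T,\\
\frac{dM}{dt} &= s_M C + \alpha\frac{C}{q+C} - d_M M.
\end{aligned}
$$

Tumor cells grow logistically and are killed by T cells. T cells are
activated at a constant rate $a_T$ and stimulated by tumor contact at rate
$s_T$; both terms are damped by the PD-L1–PD-1 checkpoint factor, where
$T(T+\epsilon_C C)$ counts checkpoint complexes ($T + \epsilon_C C$ is the
free PD-L1 level, with tumor cells over-expressing PD-L1 by the factor
$\epsilon_C$, and only T cells carry PD-1). T cells are additionally
suppressed by MDSCs at rate $r$ and die at rate $d_T$. MDSCs are recruited
by tumor-secreted chemokines (CCL2/CCL7, ligands of their CCR2 receptor)
at rate $s_M$, expand saturably with tumor load ($\alpha$, $q$), and die
at rate $d_M$.

The 13 parameters, their units and literature ranges live in
`literature_ranges()`; the package-wide default values (`default_params()`)
are the modes of a reference ABC posterior (`reference_posterior()`)
obtained for a murine high-grade glioma model fitted to longitudinal cell
counts.

### Analytic structure used by the package

* **Positivity and boundedness.** Solutions started non-negative stay
  non-negative, $C \le \hat C = \max\{C(0), C_\mathrm{max}\}$, and $T$, $M$
  admit explicit bounds through the auxiliary function
  $g(T) = (a_T+s_T T\hat C)/(1+\rho T^2)$, maximized at `T_m`
  (`population_bounds()`).
* **Tumor-free equilibrium.** With $C=0$ the MDSC equation forces $M=0$
  and $T_0^*$ solves the cubic $d_T\rho T^3 + d_T T - a_T = 0$, which has
  exactly one positive root (one coefficient sign change). The Jacobian
  eigenvalues there are $\lambda_1=\lambda_C-\eta T_0^*$,
  $\lambda_2=-2a_T\rho T_0^*/(1+\rho {T_0^*}^2)^2-d_T<0$, and
  $\lambda_3=-d_M<0$: the state is locally stable exactly when
  $\lambda_C<\eta T_0^*$, i.e. when early immune kill pressure outruns
  tumor growth (`tumor_free_equilibrium()`).
* **Global stability.** Combining the bounds gives the asymptotic T-cell
  floor $\beta=\gamma/(r\hat M+d_T)$ with
  $\gamma=a_T/(1+\rho\hat T(\hat T+\epsilon_C\hat C))$; when
  $\lambda_C<\eta\beta$ the tumor is driven extinct from any positive
  initial state (`global_stability_condition()`). The condition is
  sufficient and typically extremely conservative: at the default modes
  $\hat T$ is of order $10^{14}$, so $\beta$ is astronomically small.
* **Tumorous equilibria.** Any fixed point with $C^*>0$ must satisfy
  $T^*=\lambda_C(1-C^*/C_\mathrm{max})/\eta$ and
  $M^*=(s_M C^*+\alpha C^*/(q+C^*))/d_M$; substituting into the T-cell
  equation leaves one scalar equation in $C^*$, scanned on 2,000
  log-spaced points over $(0, C_\mathrm{max}]$ with bracketed root
  finding, and each root is classified by the eigenvalues of the analytic
  Jacobian (`tumorous_equilibria()`). The sufficient-condition flag
  $C_\mathrm{max}\epsilon_C\eta/\lambda_C<1$ is reported but never used to
  skip the search. Closed-form uniqueness/stability conditions for the
  tumorous branch are not re-derived here.

## Numerical choices

* **Solver.** `deSolve::lsoda` (adaptive, automatic stiff/non-stiff
  switching) on a compiled right-hand side, `rtol` $10^{-8}$, `atol`
  $10^{-6}$ cells; populations span many orders of magnitude.
* **Positivity guard.** Exact solutions stay positive, but during steep
  extinction transients the integrator can undershoot zero by roughly its
  absolute tolerance, and a negative tumor count feeds back through the
  logistic and checkpoint terms and diverges. The compiled right-hand side
  therefore evaluates all interactions at $\max(y,0)$, which freezes
  sub-tolerance excursions instead of amplifying them. On output, values
  in $(-100\,\mathrm{atol}, 0)$ are clamped to zero (local truncation
  error is controlled per step, not globally, hence the small multiple);
  anything more negative marks the trajectory as failed, and failed solves
  score infinite fitting error downstream.
* **Cubic root.** $T_0^*$ uses a Cardano form rearranged so the two
  radicals never cancel catastrophically (their product is known in closed
  form), followed by one Newton polish; a bracketed `uniroot` solve on
  $[0, a_T/d_T+1]$ cross-checks it to $10^{-6}$ relative.
* **Time unit** is days throughout; cell counts are continuous (ODE limit
  of counts). Default output grid is hourly.

## The synthetic-data generator

`generate_observed()` emulates the structure of the murine experiment the
model was developed against: 35,000 glioma cells implanted at day 0;
cohorts of mice euthanized at days 7, 13, 20, 24, 27, 34; per-mouse counts
of tumor cells, CD3$^+$ T cells and MDSCs. Defaults — and thus the study
conditions for every test — are: ground truth = the reference posterior
modes, 2 mice per day (within the experimental 1–4, and giving 36 data
points in total), and multiplicative lognormal noise with CV 0.2
(mean-preserving; cell counts are positive and right-skewed; the true
within-day variance structure of such data is unknown, so the CV is an
explicit knob, not an estimate).

What the generator does *not* emulate: measurement pipeline artefacts
(image segmentation, 2D-to-3D volume conversion), between-mouse biological
parameter variation (all mice share one ground truth), and missingness.
Passing recovery tests therefore show that the inference machinery is
self-consistent under the stated noise model — not that the model is
identified by real murine data.

```{r synth}
d <- generate_observed(noise_cv = 0.2, seed = 42)
head(observed_stats(d))
```

## ABC rejection

`abc_rejection()` draws parameter sets uniformly inside a prior box,
simulates each from $(35000, 0, 0)$, and scores each population by the
mean relative error over the observation days,
$E = \frac1n\sum_i |d_i-x_i|/d_i$, where $d_i$ is the per-day mean count
(per-day minimum and maximum are available as alternate trials). A draw is
accepted when $E_C\le0.75$, $E_T\le0.72$ and $E_M\le0.78$ simultaneously;
the posterior is the smallest 25% of accepted draws by
$E_\mathrm{total}=E_C+E_T+E_M$ (ceiling size, ties by draw index).
Summaries report mean, median, sample SD, and a kernel-density mode
(Silverman bandwidth, computed on the $\log_{10}$ scale for positive
samples spanning two or more decades, matching the right-skewed marginals
of rate parameters).

The prior box (`default_priors()`) is a documented reconstruction: the
published analysis states only that parameters were sampled uniformly over
its histogram axes, which are not printed numerically. Three bounds are
reported verbatim as uniform posterior fits ($s_T$: $10^2$–$10^7$, $s_M$:
0–0.1, $q$: $10^9$–$10^{11}$); for parameters with flat posteriors the
bounds were chosen so a uniform density reproduces the published
posterior mean and SD; the right-skewed parameters keep their literature
ranges widened to cover the published posterior support. Every bound can
be overridden. Note the deliberate scale choice for $\rho$: its literature
range (cell$^{-2}$) and its published posterior differ by orders of
magnitude; the package follows the posterior scale and treats $\rho$'s
units as configuration.

All draws come from a single `set.seed` call up front, so a run is fully
reproducible from one integer seed.

## 1-Wasserstein family fitting

`fit_distribution()` fits each of six candidate families (gamma, logistic,
Weibull, exponential, uniform, normal) to a posterior marginal by
minimizing the 1-Wasserstein (earth mover's) distance, evaluated on 2,048
equi-probable quantiles, starting from method-of-moments and refined by
derivative-free local search. Parameters are always reported by name
(shape/scale, location/scale, ...) because positional conventions for
these families are ambiguous across software.

One estimator property matters for family *selection*: the W1 objective is
dominated by the extreme quantiles, so a family that nests another (gamma
$\supset$ exponential) essentially always improves W1 by absorbing tail
sampling noise — by tens of percent even on data truly drawn from the
nested family — while a structurally wrong simpler family is off by an
order of magnitude or more (measured on known generators in the test
suite). The selector therefore treats fits within a factor two of the
minimum as tied and prefers the family with fewer parameters.

## Posterior-predictive envelope and best-fit errors

`posterior_predictive_envelope()` simulates `n_draws` (default 10,000)
parameter sets — resampled from an ABC posterior, or sampled independently
per parameter from fitted families truncated to the prior box (the default
reading for reproducing published envelopes) — and accumulates the hourly
mean and SD of each population. Each data point is classified by
$z=|{\rm count}-{\rm mean}|/{\rm SD}$ at its day, and the counts within
$\sigma/4$, $\sigma/2$, $3\sigma/4$, $\sigma$ are reported. The envelope
SD carries parameter uncertainty only — not the observation noise — so
with a tight posterior the expected coverage of noisy data within
$1\sigma$ is structurally below 100%.

`best_fit_error()` scores one parameter set against the per-day mean, min,
or max statistic, the three trials used to select "best fit" parameter
sets; `abc_best_fit()` re-scores a stored ABC run under any of the three
statistics and returns its minimal-error draw.

## eFAST

`efast_design()`/`efast_run()` implement the extended Fourier Amplitude
Sensitivity Test from scratch. Each parameter-of-interest block assigns
the parameter under study the maximum frequency
$\omega_\mathrm{max}=(N_S-1)/(2M)$ with $M=4$ harmonics (so
$N_S = 2049$ samples per curve give $\omega_\mathrm{max}=256$), and
spreads the complementary parameters over integer frequencies up to
$\omega_\mathrm{max}/(2M)$, preventing aliasing of the first $M$
harmonics. Parameters travel along periodic search curves in $s \in
(-\pi,\pi)$: the arcsine curve
$x = \tfrac12 + \tfrac1\pi\arcsin(\sin(\omega s + \varphi))$ samples its
range uniformly; the exponential curve
$x = n_i e^{v_i \sin(\omega s+\varphi)}$ with $v_i=\ln(1/n_i)$
concentrates samples around a nominal value $n_i$ (the posterior mode,
normalized into the unit range) and suits right-skewed posteriors. Random
phases $\varphi$ are redrawn for each of $N_R$ resamplings (default 5,
i.e. $10{,}245$ model evaluations per block); indices are reported as
resampling means with standard errors.

Because the $s$-grid is uniform, the power at integer frequency $j$ is
$|\mathrm{FFT}(y)_{j+1}|^2$. The first-order index $S_i$ sums power at
$\omega_\mathrm{max}$ and its $M$ harmonics over total power; the
total-order index $S_{Ti}=1-V_c/V$ takes the complementary variance $V_c$
from all frequencies up to $\omega_\mathrm{max}/2$, the standard
complementary band (which includes the complementary fundamentals *and*
their harmonics). Failed model evaluations are imputed with the per-curve
median up to 5% per curve (the Fourier analysis needs a complete ordered
sample); more aborts the block. The estimator reproduces closed-form
Sobol indices of linear-additive and Ishigami test functions within 0.05.

`run_efast_on_model()` applies this to the model outputs $C$, $T$, $M$ at
one or more end times, with the six right-skewed parameters
($\lambda_C$, $C_\mathrm{max}$, $\eta$, $\rho$, $\epsilon_C$, $r$) on the
exponential curve anchored at the posterior modes and the other seven on
the uniform curve; `curves = "uniform"` switches everything to uniform for
comparison, since the exponential curve skews harder than the posteriors
justify.

## Problem sizes used by the tests and the acceptance script

The shipped test-suite and `scripts/acceptance.R` run the pipeline at
reduced but honest scale, chosen as the package's own study sizes: ABC at
20k–100k draws (the reference analysis used $10^6$; the acceptance rate is
scale-free), envelopes at 10,000 draws (full scale), eFAST at
$N_S \in \{513, 1025\}$ with 2–3 resamplings for model runs (full
$N_S=2049$, $N_R=5$ for the design-arithmetic checks), and property suites
over 200/1,000/50 randomized cases as appropriate. The `analysis/`
scripts state their own sizes and scale up trivially.

## Known limitations

* The prior box is a reconstruction (see above); quantities that depend on
  its exact axes — most visibly the ABC acceptance *rate* — can differ
  substantially from published values obtained with the unpublished axes
  and the original murine dataset.
* Tumorous equilibria are located numerically; roots narrower than the
  2,000-point log grid could in principle be missed (grid size is
  configurable).
* The global-stability screen is sufficient only; its failure says
  nothing.
* No treatment terms (anti-PD-1, CCR2 antagonists) are modelled; the
  parameters $\rho$, $r$, $s_M$ are the natural handles for such
  extensions.
* The linear regime around the tumor-free state can be microscopic when
  $s_T \hat C$ is large (the slaved T-cell response to a tumor
  perturbation is then enormous); eigenvalue classifications remain
  correct but basin sizes are not part of the analysis.
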