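---
title: "From field residues to dietary risk: the models behind resrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From field residues to dietary risk: the models behind resrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resrisk)
```

resrisk implements the computational chain used in supervised pesticide
field-trial studies: validate the analytical method, fit dissipation
kinetics, and convert residue summaries into deterministic and probabilistic
dietary-risk estimates for consumer subgroups. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical choices —
in particular the ones where the conventions of the field leave the design
genuinely open.

## 1. Method validation

Quantification rests on a linear calibration of instrument response against
standard concentration, fitted by ordinary least squares
(`fit_calibration()`). The matrix effect compares the slope of the
matrix-matched curve ($K_1$) with the solvent curve ($K_2$):

$$\mathrm{ME}\% = \left(\frac{K_1}{K_2} - 1\right) \times 100$$

A positive value is signal enhancement, a negative value suppression.
`matrix_effect()` reports the signed value as primary and also the
magnitude, because validation reports conventionally print magnitudes;
$|\mathrm{ME}| \ge 20\%$ flags a significant effect requiring matrix-matched
calibration.

Recovery experiments are summarized by `compute_recovery()`: mean recovery
is $100 \times \overline{m}/s$ for measured concentrations $m$ at spike
level $s$, and precision is the relative standard deviation
$100 \times \mathrm{SD}(m)/\overline{m}$. The RSD uses the sample ($n-1$)
standard deviation — the usual default of analytical software, and the
conservative choice at the replicate counts (3–5) typical of validation
work.

`screen_loq()` establishes the method limit of quantification as the lowest
fortification level whose mean recovery falls in 70–120% with RSD at most
20%. These bounds follow the residue-guideline convention for trace-level
analytes; both are arguments, so stricter bands can be imposed. When no
level passes, the result says so explicitly rather than raising an error —
"no LOQ establishable" is a legitimate validation outcome.

## 2. Dissipation kinetics

Residue decline is modelled as first-order decay,

$$C_t = C_0\, e^{-kt}, \qquad T_{1/2} = \frac{\ln 2}{k},$$

with the dissipation percentage $\mathrm{DT}\% = 100\,(C_0 - C_t)/C_0$.
`fit_first_order()` estimates $C_0$ and $k$ by least squares on
$\ln C_t \sim t$. Log-linear fitting is the dominant convention in residue
studies, is exactly invertible on noiseless data, and weights the (usually
more reliable) early samples less extremely than nonlinear least squares on
the original scale would. A nonlinear refinement (`method = "nls"`) is
available for users who prefer original-scale residuals; on clean data the
two agree to numerical precision. The reported $r^2$ is always that of the
log-linear fit, so it is comparable across methods.

Three details deserve attention:

* **Censoring.** Observations below the LOQ carry a flag rather than a
  value. The default policy substitutes LOQ/2 before fitting, with `drop`
  and `loq` selectable. No substitution policy is innocent: for a
  short-half-life compound whose tail samples are censored, LOQ/2
  substitution flattens the late slope and biases the half-life upward —
  the stage-3 analysis script demonstrates exactly this on the fast
  (4.3-day) synthetic series. Dropping censored points avoids that bias at
  the cost of discarding the information that the residue was *low*.
* **Non-decaying series.** If the fitted slope is non-negative the fit is
  returned with the half-life flagged undefined instead of erroring, so a
  site with increasing residues surfaces in summary tables rather than
  aborting a batch.
* **Degenerate input.** Fewer than three usable points, or fewer than two
  distinct days, is an error: a two-point "fit" would be exactly
  interpolating and its $r^2$ meaningless.

## 3. Deterministic dietary risk

Acute risk uses the national estimated short-term intake,

$$\mathrm{NESTI} = \frac{LP \times HR \times v}{bw}, \qquad
  \%\mathrm{ARfD} = \frac{\mathrm{NESTI}}{\mathrm{ARfD}} \times 100,$$

where $LP$ (kg/day) is the 97.5th-percentile single-day consumption, $HR$
(mg/kg) the highest residue from supervised trials, $v$ the unit-to-unit
variability factor (default 3, the standard value for medium-sized fruit
such as grapes), and $bw$ (kg) the subgroup bodyweight. Chronic risk uses
the estimated daily intake over registered foods,

$$\mathrm{EDI} = \frac{\sum_i \mathrm{STMR}_i \times F_i}{bw}, \qquad
  \%\mathrm{ADI} = \frac{\mathrm{EDI}}{\mathrm{ADI}} \times 100,$$

with $\mathrm{STMR}_i$ the supervised-trials median residue and $F_i$ the
mean daily intake of food $i$. Risk strictly above 100% of the reference
dose is flagged unacceptable; exactly 100% passes, matching the usual
reading of "lower than 100%".

Where a parent compound is monitored together with a metabolite,
`total_residue()` aggregates them. The default is a plain concentration sum
(conversion factor 1): for the cyazofamid/CCIM pair this reproduces the
reference highest residue exactly (0.31 + 0.47 = 0.78 mg/kg). A
molecular-weight ratio can be supplied where a residue definition demands
parent-equivalent conversion; for this pair the choice is consequential
(CCIM is roughly half the parent's mass), so the factor is an explicit
argument rather than a hidden constant.

## 4. Probabilistic exposure

The probabilistic model replaces the point estimates with distributions.
Consumption $x$ and residue $c$ are fitted to lognormal distributions
(`fit_lognormal()`: mean and SD of the logs, the maximum-likelihood
estimator with the $n$ denominator), and per-capita exposure is simulated
as

$$y_i = \frac{\sum_k x_{ik}\, c_{ik}}{bw_i}$$

over foods $k$, with `simulate_exposure()` drawing $x$ and $c$
independently — no dependence structure between how much someone eats and
how contaminated their portion is, which is the standard assumption absent
survey evidence to the contrary. Bodyweight is a per-subgroup constant by
default, matching how reference bodyweights are published; a CV may be
supplied to sample it. `percentile_report()` converts the sample into
empirical quantiles (linear interpolation between order statistics, the
`stats::quantile` type-7 default) expressed as percent of the ADI or ARfD,
and `stratified_run()` loops subgroups × compounds, recording per-subgroup
failures without aborting the batch.

Two structural facts make this model testable without survey microdata.
First, when both sigmas are zero the model collapses to the deterministic
one: the chronic P50 equals `risk_quotient()` exactly. Second, for a single
food the exposure is itself lognormal with
$\mu_y = \mu_x + \mu_c - \ln bw$ and
$\sigma_y = \sqrt{\sigma_x^2 + \sigma_c^2}$, giving a closed-form quantile
oracle against which the Monte-Carlo sampler is checked at $n = 10^5$.

The default iteration count is 1000, mirroring common practice in
spreadsheet-based risk software. At that size a P99.9 estimate rests on a
single expected tail observation and is noisy; the percentile report keeps
it because regulators ask for it, but conclusions at P99.9 should use
larger `n_iter` (the closed-form check above shows the sampler converges
correctly as $n$ grows).

## 5. The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth. It emulates:

* first-order decay observed with **multiplicative lognormal noise**
  (median 1, CV `noise_cv`) — residue measurements are positive and
  right-skewed, so additive Gaussian noise would be the wrong shape and
  could produce negative concentrations;
* **LOQ censoring** that flags sub-LOQ values while retaining the latent
  number, so censoring policies can be scored against the truth;
* **lognormal subgroup consumption** and truncated-normal bodyweight
  (default CV 0, a point mass, matching deterministic reference usage);
* **spike-recovery tables** with chosen recovery mean and RSD.

Default study conditions follow the reference grape-trial design: sampling
at 0, 3, 7, 14, 21 and 28 days after application; half-lives spanning
17.8–28.9 days (pyraclostrobin regime), 4.3–7.8 days (cyazofamid regime)
and 16.9 days (CCIM); initial deposits of 0.25–0.65 mg/kg; LOQ
0.05 mg/kg; measurement CV 8% for fixture series. Subgroup large portions
and bodyweights are the published Chinese reference values (general
population 0.570 kg/day at 53.23 kg; children 0.366 kg/day at 16.14 kg;
women of childbearing age 0.297 kg/day at 52.6 kg; variability factor 3).
Mean daily grape intakes are not published per subgroup, so the generator
defaults to 0.045, 0.055 and 0.043 kg/day — values chosen once as
realistic for a commodity of this kind, with children's intake-per-bodyweight
deliberately the highest, since that ordering drives the subgroup ranking
every stage reproduces.

What the generator does **not** emulate: chromatographic signals, sampling
design effects (compositing, unit-to-unit variability beyond the scalar
factor $v$), correlation between consumption and residue, seasonal or
regional covariates of either, and real survey microdata. Passing tests
therefore demonstrate that the chain of equations is implemented correctly
and is internally consistent — not that any particular field dataset would
yield these numbers.

## 6. Numerical choices and reproducibility

* All seeds are explicit arguments; generators and simulators restore the
  caller's RNG state, so a fixed seed yields bit-identical tables.
* Pipeline outputs carry provenance headers (package version, seed, a
  32-bit FNV-1a hash of the config file) and numeric columns are written
  with 17 significant digits, so a write/read round trip preserves doubles
  exactly and repeated runs are byte-identical.
* Quantiles use type 7 throughout; changing the quantile rule moves extreme
  percentiles at small $n$, so it is fixed rather than configurable.
* Test and acceptance problem sizes: kinetics bias checks use 200 simulated
  trials of 6 timepoints; quantile oracles use $10^5$ draws; everything
  else runs at 1000–20,000 draws. These sizes were chosen so each
  stochastic check has comfortable margin against its tolerance.

## 7. Known limitations

* The log-linear fit gives no standard errors for $T_{1/2}$ on the original
  scale; users needing uncertainty on half-lives should bootstrap series.
* `fit_lognormal()` substitutes censored values before transforming rather
  than maximizing a censored likelihood; at heavy censoring rates a Tobit-
  style estimator would be less biased.
* The double-exponential (biphasic) dissipation model sometimes discussed
  for fast-then-slow decline is not implemented; all kinetics here are
  single first-order.
* Cumulative aggregation across compounds (hazard-index style) is out of
  scope; reports are per compound.
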