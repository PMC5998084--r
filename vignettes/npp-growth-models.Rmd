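---
title: "Multilevel growth models for grassland NPP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel growth models for grassland NPP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Grassland net primary productivity (NPP, gC·m⁻²·yr⁻¹) observed repeatedly
over a large region has a nested structure: yearly observations sit within
small watersheds, and watersheds sit within counties. Drivers act at
different levels — climate varies by watershed and year, terrain and soils
are fixed watershed attributes, and socioeconomic pressure (GDP, population
density, livestock production) is a county-by-year quantity. Pooling
everything into one regression ignores the group effects and misattributes
variance; `nppgrowth` instead implements the three-level growth-model
workflow for such panels, together with the per-pixel trend grading and
land-use change accounting that usually accompany it, and a synthetic
generator with known ground truth so that every stage can be validated by
parameter recovery rather than by eyeballing.

The package's defaults emulate a typical alpine-grassland monitoring
design: 18 counties, 1,817 watersheds, six unevenly spaced survey years
(1988, 1995, 2000, 2005, 2008, 2012 — a mean interval of 4.8 years), and
roughly 2.2% missing watershed-years.

# The model

Write $y_{tij} = \log(\mathrm{NPP}_{tij})$ for watershed $i$ in county $j$
at time $T_t$ (years since the first survey). The unconditional growth
model is

$$y_{tij} = \pi_{000} + \pi_{100} T_t + \beta_2 T_t^2
          + e_{00j} + e_{10j} T_t
          + \mu_{0ij} + \mu_{1ij} T_t + \varepsilon_{tij},$$

with county effects $(e_{00j}, e_{10j}) \sim N(0, \tau_c)$, watershed
effects $(\mu_{0ij}, \mu_{1ij}) \sim N(0, \tau_w)$ and i.i.d. residuals
$\varepsilon_{tij} \sim N(0, \sigma^2)$. Conditional models add
standardized covariates: climate main effects and quadratics, grassland
share and type, reserve membership, watershed terrain/soil/location
attributes, county socioeconomic indicators, and cross-level interactions
with time and with grassland share. The null (empty) model drops all fixed
terms except the intercept and keeps random intercepts only; its variance
components give the intraclass correlations

$$\mathrm{ICC}_w = \frac{\tau_{00,w}}{\sigma^2 + \tau_{00,w} + \tau_{00,c}},
\qquad
\mathrm{ICC}_c = \frac{\tau_{00,c}}{\sigma^2 + \tau_{00,w} + \tau_{00,c}}.$$

ICCs are computed from intercept variances only, even when random slopes
are fitted: the slope components are on a different scale (per year
squared) and cannot be summed with the intercept components into a single
variance budget.

# Estimation

`nested_lmm()` is a from-scratch Gaussian mixed-model estimator
specialised to two strictly nested random levels.

* **Profiled deviance.** For a candidate relative covariance factor
  $\Lambda(\theta)$ (random-effect covariance $= \sigma^2 \Lambda
  \Lambda'$), the fixed effects, conditional modes of the random effects
  and $\hat\sigma^2$ all have closed forms from the penalized
  least-squares system
  $\min_{u,\beta} \lVert y - X\beta - Z\Lambda u\rVert^2 + \lVert u \rVert^2$,
  solved through a sparse Cholesky factorisation of
  $\Lambda'Z'Z\Lambda + I$ (the `Matrix` package supplies the sparse
  linear algebra) and a Schur complement for $\beta$. The numerical
  optimisation therefore runs over at most six parameters however large
  the panel.
* **Parameterization.** $\theta$ is a log-Cholesky vector per level:
  logged diagonal entries and a free off-diagonal. Every iterate maps to a
  valid (PSD) covariance, and a vanishing variance component is reached
  smoothly as a log-diagonal goes very negative (log-diagonals are clamped
  at ±20, i.e. relative standard deviations between about 2e-9 and 5e8, so
  a "zero" component is reported as a numerically zero variance rather
  than breaking the factorisation).
* **Optimiser.** Deterministic: Nelder–Mead from the identity-scaled
  start (all log-diagonals 0, covariances 0), refined by BFGS with
  numerical gradients, relative tolerance 1e-12 on the deviance; the
  better of the two stages is kept and the convergence flag reports it
  honestly. No randomness enters the fit.
* **ML vs REML.** ML is the default because the package's model ladder
  compares fits by AIC and likelihood-ratio tests across different fixed
  parts; REML is available by flag, and on balanced nested layouts its
  variance components coincide with the closed-form nested-ANOVA
  estimators (a property the test suite asserts at interior optima — the
  identity does not hold when a component truncates at the zero boundary).
* **Inference conventions.** Reported t statistics are asymptotic z (no
  denominator-df correction); the AIC parameter count is fixed effects +
  free covariance parameters + the residual variance. `lr_test()` accepts
  a pooled `lm()` fit as the reduced model, which is the baseline used for
  "multilevel vs pooled regression" chi-squared statements, and flags the
  boundary-variance caveat (the reported p is conservative for variance
  component tests).
* **Degenerate inputs.** Rank-deficient fixed-effect designs are rejected
  naming the collinear columns; a response that the design interpolates
  exactly (zero noise) is kept finite by flooring the penalized residual
  sum of squares at 1e-300, so coefficient recovery still works in the
  noise-free limit.

On data where lme4 fits the same model, the estimator reproduces lme4's
log-likelihood, fixed effects and variance components; the test suite
asserts agreement to 1e-4 relative on randomized small instances against a
tightly converged `lmer` reference. lme4 is used only as an independent
cross-check, never inside the package.

# Trend analysis

`fit_trend()` implements the textbook closed-form least-squares slope
$$\theta_{slope} = \frac{n\sum_i i\,y_i - \sum_i i\sum_i y_i}
                        {n\sum_i i^2 - (\sum_i i)^2},$$
with the index $i$ running over observation rank $1..n$ by default —
survey years are unevenly spaced and the rank convention treats each
survey as one step; `spacing = "calendar"` switches to regression on the
actual years. Significance is the regression F test with $(1, n-2)$
degrees of freedom, and trends are graded into five classes with half-open
boundaries: p = 0.05 grades as no change, p = 0.01 as significant (not
extremely significant), and a slope of exactly zero is never graded as
change. With only two observations the slope is defined but the p-value is
reported as `NA`. `trend_map()` vectorises the same computation across a
gridded stack and reports class percentages over valid, resolved pixels
(they sum to 100 by construction).

# Change accounting

`decompose_change()` splits the change in total NPP between two dates into
contributions by land-use transition: retained grassland contributes its
end-minus-start difference, pixels converted into grassland are credited
their full end value, pixels converted out are debited their full start
value. This is the minimal additive ledger — the three components sum to
the total change exactly, by construction, on every input — and shares are
reported as component ÷ total × 100 with signs kept (so shares can be
negative or exceed 100 when components offset). Totals are carried in
whatever mass unit value × area implies, unchanged. `annual_rate()`
exposes both the arithmetic (pct/years) and geometric (compound)
convention because published summaries are frequently ambiguous about
which was used; the choice is an explicit argument, never a default guess.

# The synthetic generator

`generate_panel()` simulates the full generative model with known ground
truth and returns, alongside the panel, the exact random-effect draws,
the per-row fixed predictor and residuals. Defaults are one fixed set of
study conditions, not tuning knobs:

* **Design:** 18 counties × ~101 watersheds (1,817 total), six survey
  years, missingness 239/10,902 ≈ 2.2% completely at random (the missing
  mechanism in real panels is typically undocumented; MCAR is the neutral
  default).
* **Covariates:** independent Gaussians, dispersions from
  `npp_sd_defaults()` (precipitation 158.5 mm, temperature 2.28 °C,
  sunlight 201.05 h, …). Means are free knobs (`npp_mean_defaults()`
  holds plausible alpine-grassland values) and immaterial to recovery
  tests, because the models consume standardized covariates. Covariates
  respect the panel structure: climate and grassland share vary by
  watershed-year, terrain/soil/location are fixed per watershed,
  socioeconomic indicators vary by county-year.
* **Effects:** `npp_true_effects()` uses the published growth-model
  estimates where available (GDP −0.093, HPD −0.299, meat 0.146,
  grassland share 0.033, time × grassland −0.003, grassland × GDP −0.021,
  …) and modest magnitudes with the reported signs elsewhere (negative
  time × precipitation −0.010, positive time × temperature +0.010,
  hump-shaped precipitation/temperature responses). Grassland types are
  sampled with meadow rare (0.4%), reserve membership at 40%.
* **Random structure:** correlated intercept + slope at both levels by
  default, matching the model equations. Published tables report only
  intercept variances (1.781 watershed, 1.354 county, residual 0.160 for
  the growth model; 0.977/0.905/0.550 for the null model), so the default
  slope variances had to be chosen once: 0.002 (watershed) and 0.001
  (county) with zero intercept–slope covariance — trajectory standard
  deviations of about 0.045 and 0.032 per year, modest against a 0–24
  year time axis. Scalar `tau` arguments give the intercept-only
  structure, which is what every test reproducing table-shaped output
  uses.

What the generator deliberately does **not** emulate: spatial
autocorrelation among watersheds, the real joint distribution of the
covariates (they are independent Gaussians here), non-random missingness,
and measurement error in NPP itself. Passing recovery tests therefore
demonstrates that the estimator and pipeline are correct under the stated
generative model — not that the published coefficients would reproduce on
the real rasters and yearbooks, which are outside the package's scope.

`generate_grid()` plays the same role for the gridded stages: per-pixel
linear trends plus Gaussian noise, and start/end land-use layers realising
requested retained/converted-in/converted-out fractions within integer
rounding. Grids are plain base-R arrays with CSV/JSON serialization
(`write_grid()`/`read_grid()`); no geospatial dependency is required
anywhere in the package.

# Testing philosophy and problem sizes

Two distinct questions are kept apart in the test suite:

* **Is the estimator right?** Checked against closed forms (nested
  ANOVA, dense multivariate-normal likelihood, OLS limits), against an
  independent implementation, and by optimality probes. These checks are
  tight (1e-4 relative or better).
* **Does the pipeline recover the truth?** Checked by simulation. Here
  the yardstick matters: with only 18 counties, the *realized* variance
  of 18 county draws scatters around the configured $\tau_c$ with a
  standard deviation near $\tau_c\sqrt{2/18} \approx 33\%$, so module
  tests compare the estimated group components against the realized draw
  variances (which is what the estimator can see), while the residual
  component — whose pool is the full observation count — is compared
  against its configured value. For the same reason, single-panel
  coefficient checks on county-level covariates (18 × 6 effective cells)
  are averaged over replicates; their asymptotic-z standard errors are
  mildly anti-conservative at that group count.

Simulation sizes were chosen to keep the default test run fast while
leaving Monte-Carlo error well below the asserted tolerances: confidence-
interval coverage uses 500 panels of 8 counties × 5 watersheds × 4 years;
recovery and interaction-sign studies use 100 panels at 18 counties × 25
watersheds × 6 years; trend-test calibration uses 10,000 null series; the
draw-covariance convergence check uses 10,000 watersheds.

# Known limitations

No crossed random effects, non-Gaussian responses, or residual
spatial/temporal correlation structures; no small-sample df corrections
(Satterthwaite/Kenward–Roger); the exact covariate membership of the
conditional ladder steps is a convention (`growth_step_terms` order:
climate → grassland → watershed characteristics → socioeconomic →
interactions) and is user-overridable via the `terms` argument; reserve
membership enters the default ladder as a binary dummy, with the four-zone
factor carried in the panel for users who want the finer coding.
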