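# nppgrowth

Multilevel growth models, trend grading and change accounting for
grassland net primary productivity (NPP) panels.

## What it is for

Regional grassland monitoring produces nested longitudinal data: NPP
(gC·m⁻²·yr⁻¹) observed in a handful of survey years for each small
watershed, watersheds nested in counties, with drivers acting at every
level — climate by watershed-year, terrain and soils fixed per watershed,
socioeconomic pressure by county-year. The package is for analysts who
want to (i) decompose how much NPP variation sits between counties,
between watersheds, and within watersheds over time, (ii) attribute
trajectories to climate and human-activity drivers with cross-level
interactions, (iii) grade per-pixel NPP trends by significance, and
(iv) account for how land-use conversion contributed to total NPP change
— all on data whose structure they can simulate with known ground truth.

## The model

The core is a three-level growth model for $y_{tij} = \log \mathrm{NPP}$
of watershed $i$ in county $j$ at time $T_t$ (years since first survey):

$$y_{tij} = \pi_{000} + \pi_{100} T_t + \beta_2 T_t^2 + x_{tij}'\beta
        + e_{00j} + e_{10j} T_t + \mu_{0ij} + \mu_{1ij} T_t
        + \varepsilon_{tij}$$

with county effects $\sim N(0,\tau_c)$, watershed effects
$\sim N(0,\tau_w)$, residuals $\sim N(0,\sigma^2)$, and standardized
covariates $x_{tij}$ (absent in the unconditional model, intercept-only in
the null model). `nested_lmm()` estimates it from scratch: profiled ML/REML
deviance over a log-Cholesky parameterization of the relative covariance
factors, solved per iterate by sparse penalized least squares, so the
numerical optimisation never exceeds six parameters. Intraclass
correlations use the intercept components:
$\mathrm{ICC}_w = \tau_{00,w} / (\sigma^2 + \tau_{00,w} + \tau_{00,c})$,
and likewise for the county level.

Per-pixel trends use the closed-form least-squares slope over observation
rank with an F test at $(1, n-2)$ df, graded into five classes
(extremely significant decrease, significant decrease, no change,
significant increase, extremely significant increase) at the 0.01/0.05
half-open boundaries. Change accounting splits total NPP change additively
into retained-grassland, converted-in (credited full end value) and
converted-out (debited full start value) contributions.

## Worked example

Simulate a quarter-scale survey (18 counties × 25 watersheds, six years)
with published-scale variance components, fit the unconditional growth
model, and decompose the variance:

```r
library(nppgrowth)

fe <- npp_true_effects(); fe[] <- 0
fe["intercept"] <- 5.135; fe["time2"] <- 0.001
cfg <- panel_config(n_counties = 18, watersheds_per_county = 25,
                    fixed_effects = fe,
                    tau_watershed = 1.781, tau_county = 1.354,
                    sigma2_resid = 0.160, seed = 1)
gen <- generate_panel(cfg)
fit <- unconditional_growth(gen$panel)
fit
#> Nested linear mixed model (ML)
#>   formula: log(npp) ~ time + I(time^2)
#>   groups:  450 watersheds in 18 counties; 2649 observations
#>   logLik -2352   AIC 4717
#> Fixed effects:
#> (Intercept)        time   I(time^2)
#>      5.1098     -0.0003      0.0010
#> Variance components:
#>   sigma2 (residual): 0.1664
#>   tau (watershed):
#>           intercept
#> intercept    1.8595
#>   tau (county):
#>           intercept
#> intercept    1.0127
icc(fit)
#> Variance decomposition (intercept components):
#>   watershed share: 0.612
#>   county share:    0.3333
#>   residual share:  0.05476
```

The fit recovers the generative quadratic (true intercept 5.135, time 0,
time² 0.001) and the residual and watershed components (0.160, 1.781)
within sampling error; the county component (estimate 1.01 against a
configured 1.354) illustrates why group-level components are uncertain
with 18 counties — the realized spread of 18 county draws is itself that
far from its expectation. The ICC line reads: 61% of log-NPP variance lies
between watersheds within county, 33% between counties, 5% within
watershed over time.

Trend grading and change accounting work the same way from gridded
stacks:

```r
tr <- fit_trend(c(310, 322, 301, 348, 355, 379), 1:6)
tr
#> NPP trend: slope 14.03 per step, p = 0.02085 [sig_increase], n = 6
```

`run_pipeline()` chains the stages (simulate/read → trend map →
accounting → model ladder → ICC → comparison) from a single YAML/list
config and writes a JSON report embedding the seed and config hash.

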