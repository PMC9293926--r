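# streamtemp

Timescale-dependent environmental controls on stream water temperature.

Stream temperature tracks air temperature, but the apparent influence of
landscape controls — riparian shade, catchment geology, land use, reach
elevation — depends on the timescale over which temperatures are
averaged. Reach-scale controls on surface heat exchange leave their
imprint on daily means; catchment-scale hydrogeology (notably cool
groundwater from volcanic formations) increasingly dominates monthly
means. `streamtemp` implements the complete analysis chain used to
quantify this dependence on paired air–water logger networks, plus a
synthetic-data generator that emulates a 130-station, four-catchment
summer monitoring design so everything is testable without field data.

## The model

For observation *i* at site *j*,

```
Tw_ij = alpha + beta_air * Ta_ij + beta X_j + gamma_c(j)
        + b0_j + b1_j * Ta_ij + e_ij
```

with site-level random intercept/slope `(b0_j, b1_j) ~ N(0, D)`,
fixed catchment contrasts `gamma`, five environmental covariates `X_j`
(cultivated %, Quaternary and pre-Quaternary volcanic %, reach
elevation, riparian forest %), and — for daily data — continuous-time
AR(1) residuals, `cor(e_s, e_t) = phi^|s-t|`, valid across the gaps a
summer-only campaign leaves. The likelihood is evaluated per site
(CAR(1) innovations whitening + rank-2 Woodbury; never an N×N matrix),
with `beta` and `sigma^2` profiled out; REML by default, ML for
likelihood-ratio comparisons. Model assessment uses marginal/conditional
R² (variance-component form with the random-slope extension), adjusted
ICC, population-level RMSE and (generalised) VIFs. Relative importance
of the environmental predictors over an air + catchment baseline is
established by all-subsets dominance analysis: complete, conditional and
general dominance, with general weights equal to Shapley values of the
R² game.

## Worked example

The numbered scripts under `analysis/` run the full workflow: simulate
the network (`01`), aggregate hourly records to daily/monthly means at
the 75% completeness threshold (`02`), fit both models (`03`), run the
dominance analysis (`04`) and the recovery checks (`05`), writing tables
under `results/`. A condensed version:

```r
library(streamtemp)

sites <- generate_sites(n_sites = 130, n_catchments = 4, seed = 20180601)
truth <- truth_params("day")            # daily-scale generating parameters
# ... hourly simulation + aggregation as in analysis/01-02 ...

fit <- fit_lmm(paired_day, sites, lmm_spec(env_covariates(), "day"))
print(fit)
```

```
Air-water temperature LMM (REML, day timescale, errors: car1)

Fixed effects:
                 term      coef       se        t    df          p
1         (Intercept) 15.729950 0.785631  20.0221 29972  1.345e-88
2                 air  0.308632 0.008858  34.8439 29972 8.503e-261
3       catchmentKiso -0.763349 0.383925  -1.9883   121  4.904e-02
4    catchmentSorachi -4.187268 0.372507 -11.2408   121  1.640e-20
5     catchmentTeshio -3.920085 0.367509 -10.6666   121  3.955e-19
6          cultivated  0.030063 0.007494   4.0118   121  1.048e-04
7     volc_quaternary -0.017686 0.006961  -2.5408   121  1.233e-02
8  volc_prequaternary -0.005823 0.006122  -0.9512   121  3.434e-01
9           elevation -0.046176 0.001969 -23.4516   121  7.848e-47
10    riparian_forest -0.017692 0.006612  -2.6757   121  8.489e-03

Random effects:
  Residual standard deviation (sigma)    1.399
  Site (intercept) standard deviation    1.248
  Site (air slope) standard deviation    0.098
  Correlation at lag 1 (phi)             0.970
  Intraclass correlation (ICC)           0.749

Observations: 30103 sites: 130
Marginal / Conditional R2: 0.700 / 0.925
```

Read: each degree of air warming raises daily water temperature by
~0.31 °C on average (sites vary, SD ~0.10); the northern catchments run
~4 °C colder; cultivated land warms and geology/elevation/riparian
forest cool the streams; residuals one day apart correlate at 0.97. The
fit recovers the generator's truth (air slope 0.315, sigma 1.518 at
daily resolution, phi 0.962, elevation −0.044) from the aggregated
hourly records. The ML likelihood-ratio test against the air + catchment
baseline gives chi² = 232 on 5 df, and the dominance stage decomposes
the baseline-to-full marginal-R² increment (0.40) into per-predictor
Shapley shares with pairwise complete/conditional/general dominance
levels:

```
General dominance weights (shares %):
                   weight   share
elevation          0.3779 93.5837
riparian_forest    0.0170  4.2173
cultivated         0.0069  1.7063
volc_quaternary    0.0017  0.4255
volc_prequaternary 0.0003  0.0671
```

(In the default synthetic regime reach elevation dominates because its
covariate spread, times its coefficient, yields by far the largest
between-site contrast — see the methods vignette,
`vignettes/stream-temperature-timescales.Rmd`, for that design choice
and everything else about the model.)

The recovery stage confirms calibration at the study's design scale:

```
monthly air slope: truth 0.622, mean estimate 0.626 (bias +0.70%)
95% Wald CI coverage: 10/10
daily CAR(1): truth 0.800, estimates 0.799 0.799 0.807 0.804 0.811 (mean 0.804)
```

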