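# metamorph

Growth-curve model selection and endpoint analysis for factorial
larval-rearing experiments.

## What this is for

Coastal populations of some freshwater amphibians breed in brackish
wetlands, and a standard way to ask whether they have adapted is a
common-garden rearing experiment: tadpoles from salt-exposed (coastal)
and salt-naive (inland) populations are reared at several conspecific
densities in fresh or saline (4 ppt) water, in replicate spatial blocks,
and followed through metamorphosis. `metamorph` implements the full
analysis of such an experiment — 3 densities (2/4/8 per container) × 2
salinities × 2 locations × 6 blocks = 72 units — for researchers in
ecological and evolutionary physiology who want the growth-curve and
endpoint analyses in one tested, reproducible pipeline.

Two analyses are provided:

**Growth.** Weekly cup-mean total length $Y(t)$ is fitted by maximum
likelihood with the Gompertz model

$$Y(t) = S_0 \exp\left[\tfrac{\gamma}{\alpha}\left(1 - e^{-\alpha t}\right)\right]$$

where $S_0$ is initial size, $\gamma$ the maximum size-specific growth
rate and $\alpha$ its exponential decay rate. Treatments may structure
$\gamma$ and $\alpha$ through any of the structures `1`,
`Location + Salinity + Density`, `Location * Salinity + Density`,
`Location + Salinity * Density`, `Location * Salinity * Density`
(log link; $S_0$ and the residual sd always shared), and all 17
parameterizations are compared by AICc,
$-2\ell + 2k + 2k(k+1)/(n-k-1)$, with Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$.

**Endpoints.** Survival (binomial, aggregated per container), age at
metamorphosis (Poisson, per individual) and total length at
metamorphosis (Gaussian on the log scale) are analysed with block
random-intercept mixed models (ML; Laplace approximation via lme4),
simplified by likelihood-ratio backward elimination from the full
three-way interaction model, with per-factor chi-square tests and fitted
per-cell means.

A seeded synthetic-data generator (`sim_config()`, `simulate_dataset()`)
emulates the design and the assumed distributional structure so the
whole pipeline is testable end to end; see the methods vignette
(`vignettes/methods.Rmd`) for the model details and the generator's
defaults.

## Worked example

```r
library(metamorph)

ds  <- simulate_dataset(build_design(), sim_config(seed = 42))
sel <- gompertz_select(growth_data(ds))
print(sel, n = 5)
```

```
Gompertz model comparison (AICc), 17 parameterizations

 rank                         gamma                         alpha df dAICc weight
    1 Location + Salinity * Density Location + Salinity * Density 16   0.0  0.458
    2 Location + Salinity + Density Location + Salinity * Density 14   0.5  0.352
    3 Location * Salinity + Density Location + Salinity * Density 15   2.6  0.122
    4 Location + Salinity * Density Location + Salinity + Density 14   5.5  0.030
    5 Location * Salinity * Density Location + Salinity * Density 21   7.4  0.012
```

The table reads like a published AICc comparison: `df` is the parameter
count (shared $S_0$ and $\sigma$ plus the dummy-coded columns for
$\gamma$ and $\alpha$), `dAICc` the difference from the best model, and
`weight` the model's share of evidence. Here the generating structure
($\gamma$ additive, $\alpha$ with the salinity × density interaction)
is rank 2 within half an AICc unit of a slightly richer rank-1 model —
near-ties among nesting structures are expected with AICc, which is why
the weights, not the rank-1 row alone, carry the conclusion.

```r
print(best_fit(sel))
```

```
Gompertz growth fit (maximum likelihood)
  gamma: Location + Salinity * Density | alpha: Location + Salinity * Density
  logLik -423.709 | k = 16 | n = 567 | AICc 880.41 | converged
  S0 = 5.904 mm, sigma = 0.5109 mm
```

(the generator used $S_0 = 6$ mm and $\sigma = 0.5$ mm). Endpoint
analyses and the one-call pipeline:

```r
report <- analyze_endpoints(ds)           # survival, age, length
run_pipeline(run_config(seed = 42, out_dir = "run1"))
```

The pipeline writes the dataset CSVs, `model_table.csv`, `fits.json`,
`endpoint_report.json`, `manifest.json` and a human-readable
`summary.txt`; identical seeds give byte-identical outputs. A thin
command-line wrapper with `simulate`, `fit-growth`, `select`,
`endpoints` and `run-all` subcommands is installed at
`inst/scripts/metamorph-cli.R`.

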