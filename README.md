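# scalescape

Scale-specific time series modelling of community dynamics, for inferring
the relative resilience of alternative ecological states.

## What it does

Communities under contrasting regimes — say, the wet and dry states of a
semiarid floodplain wetland — can differ not just in richness or biomass
but in the *temporal structure* of their dynamics: at how many distinct
temporal scales species fluctuate coherently (cross-scale structure), how
many taxa track each scale (within-scale redundancy), and how many track
none (stochastic species). These attributes are read as facets of
ecological resilience. `scalescape` implements the full inference chain
for equidistant multispecies time series (e.g. monthly phytoplankton
biovolume, mm³ L⁻¹):

1. **STARS** — a sequential t-test regime-shift detector delimits
   alternative states on a univariate driver such as flooded area, with
   critical difference `t(2l−2, α) · sqrt(2σ²_l / l)` and a Huber-weighted
   regime shift index;
2. **AEM** — asymmetric-eigenvector-map temporal eigenfunctions are built
   from the linear time vector of each state window; the eigenfunctions
   with Moran's I above −1/(n−1) (positive temporal autocorrelation) are
   the temporal predictors, ordered slow → fast (12 of 23 for a 24-month
   window);
3. **RDA** — the Hellinger-transformed species matrix is regressed on a
   forward-selected predictor subset (permutation tests with the double
   stopping criterion on the Ezekiel-adjusted R²,
   `R²adj = 1 − (1−R²)(n−1)/(n−m−1)`); canonical axes are tested
   sequentially by permutation, and the leading significant axes are the
   detected temporal scales;
4. **Attribution** — each taxon's raw biovolume series is assigned by
   Spearman rank correlation to the significant axis it tracks best, or to
   the stochastic set, giving count tables whose per-axis and stochastic
   counts partition the taxon total.

Per-sample community metrics (richness S, Shannon H, diversity D = exp(H),
evenness E = D/S, total biovolume) and a balanced two-factor
repeated-measures ANOVA with Huynh-Feldt correction are included, as is a
synthetic-data generator that plants known temporal scales for validation.

## Worked example

```r
library(scalescape)

sim <- simulate_two_states(n_sites = 1, seed = 42)   # wet: 3 planted scales; dry: 2
cfg <- analysis_config(n_permutations = 199, seed = 42)
run <- run_pipeline(sim$communities, driver = sim$driver, config = cfg)
run
```

```
scalescape pipeline run: 2 site-state window(s)

Resilience attributes per site and state:
 site state n_scales within_scale stochastic_n stochastic_pct total_taxa adj_r2
   S1   wet        3        8,7,6           17             45         38  0.263
   S1   dry        2        10,10           28             58         48  0.262

State contrast (second minus first):
 site d_n_scales d_stochastic_pct  d_adj_r2
   S1         -1               13 -0.000419
```

The wet-state model detects three temporal scales with 8, 7 and 6 taxa
tracking them and 17 of 38 taxa (45%) stochastic; the dry state loses one
scale and gains stochastic taxa — the qualitative signature of eroded
resilience (over many seeds the dry state's adjusted R² is also lower on
average; in this particular run it is essentially tied). `plot(run$fits[[1]])`
draws the modelled temporal patterns (lc scores) per scale, and
`summary(run$fits[[1]])` shows the forward-selection trace, the sequential
axis tests and the per-taxon attribution.

Single-window modelling uses the fitting function directly:

```r
fit <- scale_rda(sim$communities[["S1.wet"]], n_perm = 999, seed = 1)
summary(fit)
```

A thin command-line wrapper lives at `inst/scripts/scalescape.R`
(`simulate`, `stars`, `run` subcommands).

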