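# gridfrog

Spatial analysis of migrant–resident aggregation in gridded mark–recapture
data.

## The problem

Territorial, visually oriented animals — the motivating system is a
dendrobatid poison frog surveyed on small plantation plots — may settle
near established conspecifics ("conspecific attraction") rather than
avoiding them. On a gridded study plot this shows up as three spatial
signatures of new arrivals (juveniles and migrant adults) relative to
resident adults:

1. **Clumping** of seasonal home-range centroids, measured by the
   Clark–Evans index R = r̄_obs / r̄_E — the observed mean nearest-neighbour
   distance (NND) from each migrant centroid to its closest resident
   centroid, over its expectation under complete spatial randomness (CSR).
   R < 1 indicates clumping, R ≈ 1 randomness, R > 1 uniformity. Because
   plots are small (12 m × 9 m), r̄_E uses Donnelly's boundary correction,
   `r̄_E = 0.5·√(A/n) + (0.0514 + 0.041/√n)·P/n`, with A the plot area, P
   its perimeter and n the pattern-size equivalent (number of competitor
   points + 1).
2. **Shared sites**: per survey, the proportion of occupied 1.5 m grid
   cells holding individuals of both classes of a migrant–resident pair.
3. **Short nearest-neighbour distances**: the NND distribution function
   G(r) estimated with the spatial Kaplan–Meier border correction (each
   NND censored at the distance to the plot edge), summarised against the
   CSR curve `G(r) = 1 − exp(−λπr²)` by the maximum absolute deviation
   (MAD) statistic `u = max_r |Ĝ(r) − G(r)|`.

Each observed statistic is compared with density-matched CSR simulations
(10 replicates per analysis unit by default) through paired linear
mixed-effect contrasts with season nested within plot as a random effect.
Seasonal abundance of juveniles, females and males is described by five
candidate mixed models ranked by AICc with Akaike weights.

The package classifies individuals into cohorts from capture tenure:
juveniles (`J`, < 19 mm snout–vent length), resident adults (`RF`/`RM`,
observed in the same plot the previous season, and all first-season
adults) and migrant adults (`MF`/`MM`). A synthetic capture-history
generator with known spatial truth (uniform or resident-clustered migrant
settlement) makes the whole pipeline testable without field data.

## Worked example

Simulate a study in which migrants settle 0.5 m (Gaussian sd) from a
randomly chosen resident, then run the full analysis:

```r
library(gridfrog)
cfg <- pipeline_config(
  synthetic = synthetic_config(attraction_mode = "attraction", seed = 42),
  seed = 42)
fit <- run_full_pipeline(cfg)
print(fit)
#> Migrant-resident aggregation analysis
#>   full data: 4057 captures of 188 individuals; subset (>= 3): 4057 captures of 188 individuals
#>   20 plot-season analysis units; 10 null replicates per unit (seed 42)
#>
#> Paired observed-vs-null contrasts:
#>   pair statistic estimate  p_value mean_observed mean_null n_units     method
#>   J-RF         R  -0.5655 9.64e-07        0.4528    1.0183      20 lmm-nested
#>   J-RF       MAD   0.2140 2.36e-05        0.6976    0.4836      20 lmm-nested
#>   J-RF    shared   0.0509 5.91e-04        0.0880    0.0368     251 lmm-nested
#>   ...
#>    all         R  -0.3750 3.83e-12        0.6183    0.9930     104 lmm-nested
#>    all       MAD   0.0836 6.28e-05        0.6294    0.5458     104 lmm-nested
#>    all    shared   0.0360 2.03e-07        0.0657    0.0298    1175 lmm-nested
```

Reading the pooled (`all`) rows: observed R averages 0.62 against a null
mean of 0.99 (clumped, paired difference −0.375, p ≈ 4e−12); MAD
statistics exceed their CSR replicates by +0.084 (one-tailed p ≈ 6e−5,
shorter NNDs than random); and migrants share occupied cells with
residents at 6.6% of sites versus 3.0% expected by chance. `summary(fit)`
adds per-pair mean R ± SE and the AICc ranking of the five abundance
models; `plot(fit, statistic = "R")` draws the per-pair R bar chart
against the CSR reference line. With `attraction_mode = "csr"` the same
pipeline shows no systematic effect.

Individual stages are exported (`classify_cohorts()`, `clark_evans_r()`,
`g_estimate()`, `mad_statistic()`, `shared_sites_table()`,
`null_statistics()`, `paired_contrast()`, `rank_abundance_models()`), and
field data can be supplied as a CSV of capture records via
`pipeline_config(captures = "captures.csv")`; see `?read_captures` for
the column layout.

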