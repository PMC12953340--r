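# metalrisk

Probabilistic human-health risk assessment of trace-metal exposure (As,
Cr, Cu, Mn, Ni, Pb, Zn) in residential garden soil and indoor vacuum
dust.

`metalrisk` is for environmental scientists and public-health analysts
working with home survey data — citizen-science soil/dust programs,
contaminated-site screening around legacy industry, or any dataset of
per-home trace-metal concentrations. It implements the full analysis
chain as a tidyverse-native pipeline:

- **Ingestion & QA** — delimited sample tables with below-detection
  cells substituted at half the instrument LOD, home-level averaging
  (typically 5 garden-soil samples per home plus an optional matched
  dust sample), and standard-reference-material percent-recovery
  reports.
- **Enrichment & benchmarking** — Mn-normalised enrichment factors
  `EF = (TE/RE)_sample / (TE/RE)_background` with the five standard
  bands (≤2 minimal, 2–5 moderate, 5–20 significant, 20–40 very high,
  >40 extreme), and strict-exceedance counts against guidelines such as
  the NEPM HIL-A residential values.
- **Nonparametric statistics** — Mann-Whitney (exact for small untied
  samples), Kruskal-Wallis with Dunn's post hoc, Spearman correlations
  of concentrations against home metadata.
- **Monte Carlo risk engine** — route-specific average daily doses

  `ADD_ing = C·IngR·CF·ExpF·ED / (BW·AT)`,
  `ADD_inh = C·InhR·ExpF·ED / (PEF·BW·AT)`,
  `ADD_derm = C·SA·AF·ABS·CF·ExpF·ED / (BW·AT)`,

  hazard quotients HQ = ADD/RfD summed into the hazard index HI
  (threshold 1), and lifetime cancer risks CR = LADD×SF summed into TCR
  (threshold 1e-4) for As and Pb, over 10,000 seeded iterations for
  child (2 y) and adult Australian residential scenarios.
- **Sensitivity** — Spearman tornado analysis of every sampled input
  against HI.
- **Synthetic data** — a copula-based generator reproducing the
  home-structured survey design (lognormal concentrations calibrated to
  regional summary statistics, home-age rank correlations with dust
  As/Pb/Zn, below-LOD injection, background soils) so the whole
  pipeline runs and tests without any measured data.

See the methods vignette (`vignettes/metalrisk-methods.Rmd`) for the
model, its assumptions and the default parameter values.

## Worked example

```r
library(metalrisk)
library(dplyr)

# A synthetic 75-home survey (5 soil samples/home, ~30% with matched dust)
ds <- generate_dataset(generator_config(), seed = 42)
samples <- substitute_half_lod(ds$samples, lod_vanta_vmw())
homes <- aggregate_homes(samples, ds$homes)

# Probabilistic risk for children exposed to indoor dust
dust_summary <- homes |>
  filter(medium == "indoor_dust") |>
  group_by(metal) |>
  summarise(mean = mean(mean_concentration), sd = sd(mean_concentration))

risk <- run_monte_carlo(dust_summary, default_scenario("child"),
  n_iter = 10000, seed = 42, keep_inputs = TRUE, medium = "indoor_dust")
risk
#> <risk_distribution> 10000 iterations, child_2y, indoor_dust
#>   HI : mean 0.952, median 0.802, p95 2.09, max 11.9
#>   TCR: mean 8.46e-06, median 5.53e-06, p95 2.54e-05, max 0.000201

exceedance_summary(risk, "HI")
#> # A tibble: 1 × 6
#>   metric threshold fraction first_percentile maximum n_iter
#>   <chr>      <dbl>    <dbl>            <dbl>   <dbl>  <int>
#> 1 HI             1    0.346             65.4    11.9  10000

head(sensitivity_tornado(risk), 5)
#> # A tibble: 5 × 3
#>   input   rho  rank
#>   <chr> <dbl> <int>
#> 1 IngR  0.530     1
#> 2 C_Pb  0.407     2
#> 3 C_As  0.406     3
#> 4 C_Cr  0.307     4
#> 5 ExpF  0.244     5
```

Reading this: the mean hazard index for this (synthetic, deliberately
contaminated) dust dataset sits just below the cautionary threshold of
1, but 34.6% of simulated child exposures exceed it — the threshold is
crossed from the 65th percentile of the distribution upward, with a
worst case of HI ≈ 12. Mean TCR (8.5 × 10⁻⁶) is below the 10⁻⁴ level of
concern. The tornado ranks the ingestion rate and the Pb/As
concentrations as the main drivers of HI variability. Enrichment
factors against the generated background soils land Pb/Zn/Cu in the
significant band (`enrichment_factor(homes, bg_means)`), as designed
for a contaminated scenario.

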