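---
title: "Methods: probabilistic trace-metal risk assessment with metalrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic trace-metal risk assessment with metalrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
library(dplyr)
```

## The problem

Residential environments accumulate trace metals — As, Cr, Cu, Mn, Ni, Pb
and Zn — from legacy industry, traffic, degraded paints and building
materials. Garden soil and indoor vacuum dust are the two media through
which residents, children above all, are chronically exposed via
incidental ingestion, dermal contact and inhalation of resuspended
particles. Deterministic screening assessments collapse all behavioural
and environmental variability into single point estimates; `metalrisk`
instead propagates that variability through a Monte Carlo model, so the
output is a distribution of risk across the exposed population rather
than one number, and upper-percentile scenarios become visible.

The package covers the full analysis chain: ingestion and QA of measured
sample tables, below-detection-limit handling, home-level aggregation,
geochemical enrichment factors, guideline benchmarking, nonparametric
comparisons, the probabilistic risk engine, and a Spearman tornado
sensitivity analysis. A synthetic-data generator reproduces the
statistical structure of a home survey so the entire pipeline is testable
without any measured data.

## Data model and quality assurance

Samples live in a long tibble with one row per (home, medium, location,
sample, metal). Media are `garden_soil`, `indoor_dust` and
`background_soil`; a home typically contributes five soil samples (front
garden, back garden, drip line, vegetable garden, plus one unspecified
location) and at most one dust sample.

Measurements below the instrument limit of detection (LOD) are assigned
exactly half the corresponding detection limit before any statistics or
simulation — the conventional substitution for left-censored
environmental concentrations at modest censoring rates. Built-in LOD
tables cover the two pXRF instruments typically used for these media
(`lod_vanta_vmw()` for soil, `lod_vanta_vmr()` for dust); a `"<x"` cell
token overrides the instrument LOD for that single cell. The substitution
is idempotent and never touches an unflagged value. We deliberately do
not implement maximum-likelihood or Kaplan–Meier censored estimators:
at the few-percent censoring rates typical of these media the half-LOD
convention is standard practice and keeps every downstream statistic a
plain function of one concentration column.

Instrument accuracy is summarised by standard-reference-material percent
recoveries (`compute_recovery()`): 100 × measured / certified per metal,
their arithmetic mean, and relative standard deviations when replicates
are supplied. Recoveries are scale-equivariant, so unit changes cannot
distort them.

Samples are averaged per (home, medium) into a representative home
concentration (`aggregate_homes()`). Background soils are keyed by
medium, never by home, and are excluded from home summaries.

## Enrichment factors and benchmarking

Anthropogenic input is assessed by the enrichment factor

$$EF = \frac{(TE/RE)_{sample}}{(TE/RE)_{background}}$$

with Mn as the reference element RE — of this suite it is the element
dominated by pedogenic sources, with little indoor or industrial input.
The five conventional bands are: EF ≤ 2 minimal, 2–5 moderate, 5–20
significant, 20–40 very high, > 40 extremely high; boundaries are closed
on the left band (an EF of exactly 20 is still "significant"). The EF of
the reference element against itself is reported as not applicable rather
than the trivial 1. EF is invariant to common rescaling of either
medium's concentrations, which the tests exercise as a property.

Home means are benchmarked against a guideline set — by default the NEPM
Health Investigation Level A residential soil values (As 100, Cr 100,
Cu 7000, Mn 3000, Ni 400, Pb 300, Zn 8000 mg/kg), every value
user-overridable. Exceedance is strict (`>`): a home mean exactly at the
guideline does not count. Total-Cr data benchmarked against the Cr(VI)
guideline is flagged with a caveat in the report, since that comparison
is conservative by construction. Indoor dust has no dedicated guideline;
benchmarking it against the residential-soil values follows the common
practice justified by the large outdoor-soil fraction of indoor dust, and
should be read as a conservative screen.

Descriptive summaries use the sample SD, linear-interpolation percentiles
(R type 7), and a t-based confidence interval on the mean with n − 1
degrees of freedom.

## Nonparametric comparisons

Concentration data in these media are strongly right-skewed, so all
comparisons are rank-based: Mann-Whitney U for two media (exact
enumeration when both groups have ≤ 8 untied observations, tie-corrected
normal approximation otherwise, and a paired signed-rank option for
home-matched designs), Kruskal-Wallis H with Dunn's post hoc z tests
across construction-material groups (Bonferroni adjustment by default,
capped at 1), and Spearman correlation against home age (t approximation
for the p-value, average ranks for ties). Dunn comparisons are always
reported regardless of the omnibus p-value; interpretation is the
caller's. Both raw and adjusted pairwise p-values are returned, since
per-metal analyses are often reported unadjusted.

## The risk model

For a concentration $C$ (mg/kg) the route-specific average daily doses
(mg/kg/day) are

$$ADD_{ing} = \frac{C \cdot IngR \cdot CF \cdot ExpF \cdot ED}{BW \cdot AT},
\quad
ADD_{inh} = \frac{C \cdot InhR \cdot ExpF \cdot ED}{PEF \cdot BW \cdot AT},
\quad
ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot CF \cdot ExpF \cdot ED}{BW \cdot AT}$$

the standard residential formulation used by USEPA RAGS and Australian
enHealth guidance. Non-carcinogenic risk is expressed per metal and route
as the hazard quotient $HQ = ADD / RfD$ and summed over all metals and
all three routes into the hazard index HI (cautionary threshold 1).
Summing across both metals and routes is the conservative reading of a
"total" index and mirrors the treatment of total carcinogenic risk.
Carcinogenic risk uses the lifetime averaging time: $CR = LADD \times SF$
summed into TCR (cautionary threshold 1 × 10⁻⁴) over the carcinogens —
As and Pb, the only metals of this suite with established slope factors
in the major toxicological databases.

`default_toxicity()` ships conventional screening RfDs and slope factors
compiled from public databases (IRIS/OEHHA-style values); they are
defaults to make the package runnable, not authoritative toxicology, and
any cell can be overridden or replaced wholesale from a file.

### Exposure scenarios

Two default scenarios describe an Australian residential setting for a
young child (2 years) and an adult. Parameters that dominate behavioural
variability are sampled; physical constants are points:

| Parameter | Child | Adult | Units |
|---|---|---|---|
| IngR | triangular(10, 50, 100) | triangular(5, 25, 50) | mg/day |
| InhR | triangular(5, 9, 13) | triangular(10, 15, 20) | m³/day |
| ExpF | triangular(180, 345, 365) | same | days/year |
| ED | uniform(2, 6) | uniform(10, 30) | years |
| BW | trunc-normal(15, 2) on [8, 30] | trunc-normal(70, 10) on [40, 120] | kg |
| SA | trunc-normal(2800, 300) | trunc-normal(5700, 600) | cm² |
| AF | 0.2 | 0.07 | mg/cm²/day |
| ABS | 0.001 | 0.001 | — |
| PEF | 1.36 × 10⁹ | same | m³/kg |
| CF | 10⁻⁶ | same | kg/mg |

Central values follow enHealth/NEPC residential guidance (child soil
ingestion 50 mg/day, adult 25 mg/day; adherence and surface-area values
from USEPA residential defaults); the triangular spreads express
behavioural ranges around them. The non-carcinogenic averaging time is
linked per iteration to the sampled duration (AT = ED × 365), the
definitionally consistent choice — a consequence is that ED cancels out
of HQ and only influences cancer risk, where AT is the fixed lifetime
70 × 365 days. A scenario file can instead supply AT as any independent
distribution. Bioavailability is the conservative 100% by default,
exposed as a relative-bioavailability multiplier `rba`.

Concentrations are sampled as lognormals moment-matched to the per-metal
mean and SD of the dataset ($\sigma^2 = \ln(1 + sd^2/mean^2)$,
$\mu = \ln(mean) - \sigma^2/2$) — the central distributional assumption
of the engine, chosen because trace-metal concentrations in these media
are classically lognormal-like. It is an assumption, not a claim about
any particular dataset; heavier-tailed data will have their extreme upper
percentiles understated.

All parameters are drawn independently — correlations among exposure
parameters (e.g. body weight with skin surface area) are not modelled,
which mildly misstates tail probabilities when such correlations are
strong.

### Monte Carlo

`run_monte_carlo()` draws all inputs independently per iteration
(default 10,000 iterations, a size at which the quantities reported here
— means and the 86th–99th percentiles — are stable to well under the
differences being interpreted), evaluates every metal × route, and
stores per-iteration HQ, HI, CR and TCR. Runs are bit-reproducible given
a seed; with every spec degenerate the run reproduces the deterministic
dose composition exactly, which the acceptance tests verify bit-for-bit.
Exceedance reporting gives the fraction of iterations above the
cautionary threshold and the first percentile of the empirical
distribution at which the threshold is crossed
(100 × (1 − fraction)).

## Sensitivity analysis

`sensitivity_tornado()` computes the Spearman correlation of every
*sampled* input (per-metal concentration draws and each non-point
exposure parameter) against the per-iteration HI, ordered by |ρ| for a
tornado plot. Point-valued inputs are excluded rather than reported as
zero; simple (not partial) correlations are used, so correlated inputs
share credit. Under the default scenario the linked averaging time makes
ED's correlation with HI ≈ 0 by construction (it is excluded from the
tornado only if held at a point; when sampled it appears with its
near-zero ρ, which is informative in itself).

## The synthetic generator

`generate_dataset()` emulates the survey structure the pipeline assumes:

- per home, five garden-soil samples drawn from a two-level lognormal —
  the total log-variance matches the configured sample-level mean/SD,
  and a within-home component with coefficient of variation 0.3 (a
  typical garden-scale heterogeneity; the configured value is capped at
  the total variance) is nested inside the between-home remainder;
- a configurable fraction of homes (default 23/75) contributes one
  matched indoor-dust sample; dust concentrations are produced by
  quantile transform of a Gaussian copula, so each metal's marginal is
  exactly the moment-matched lognormal while home age attains target
  Spearman correlations with dust As/Pb/Zn (defaults 0.573, 0.471,
  0.533) through the $r = 2\sin(\pi \rho_s/6)$ normal-score relation;
  infeasible correlation targets are rejected at configuration time via
  a positive-definiteness check;
- home ages are truncated-normal (mean 50, SD 25, range 1–120 years);
  construction materials are assigned with no concentration effect by
  default (an optional multiplicative knob exists for power studies);
- a configurable fraction of cells (default 2%) is flagged below-LOD and
  takes LOD/2; six background-soil records are drawn around synthetic
  low crustal-style levels (As 2, Cr 15, Cu 12, Mn 350, Ni 6, Pb 14,
  Zn 35 mg/kg with 10% dispersion), chosen so that soil at the default
  contaminated means lands in the moderate-to-significant EF bands.

Default concentration summaries are calibrated to published regional
summary statistics for a legacy-industrial area (e.g. indoor dust Pb
mean 245, SD 282 mg/kg). What the generator does *not* emulate: spatial
structure, instrument noise, heavy tails beyond lognormal, and
correlations among metals within a home beyond those induced by the home
age link. Pipeline tests passing on generated data therefore demonstrate
the correctness of the computations and the plumbing, not distributional
claims about any real survey.

## Numerical choices

- Triangular sampling by inverse CDF; truncated normals by rejection
  (bounds excluding essentially all mass are rejected at construction).
- Percentiles: linear interpolation (R type 7) throughout.
- Kruskal-Wallis on completely constant data returns H = 0, p = 1
  instead of the 0/0 the tie-corrected formula produces.
- Exact Mann-Whitney switches to the normal approximation at the first
  tie or when either group exceeds 8 observations.
- Empty HQ/CR sets sum to 0 (vacuous hazard), and an all-point Monte
  Carlo run is valid and exactly deterministic.

## A worked run

```{r example, eval = FALSE}
ds <- generate_dataset(generator_config(), seed = 42)
samples <- substitute_half_lod(ds$samples, lod_vanta_vmw())
homes <- aggregate_homes(samples, ds$homes)

dust_summary <- homes |>
  filter(medium == "indoor_dust") |>
  group_by(metal) |>
  summarise(mean = mean(mean_concentration), sd = sd(mean_concentration))

risk <- run_monte_carlo(dust_summary, default_scenario("child"),
  n_iter = 10000, seed = 42, keep_inputs = TRUE, medium = "indoor_dust")
glance(risk)
exceedance_summary(risk, "HI")
plot_tornado(sensitivity_tornado(risk))
```

## Known limitations

- Half-LOD substitution biases means slightly at high censoring rates.
- The lognormal concentration model and independent parameter draws are
  assumptions; bootstrap resampling of observed home means is the
  planned alternative for datasets that defy the lognormal.
- The HI sums across metals and routes without toxicological interaction
  terms, the conventional additive screen.
- Pb cancer potency is small and its slope-factor basis differs from
  As's; TCR here is a screening quantity, not an etiological estimate.
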