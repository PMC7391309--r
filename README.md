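# isarmech

**Why do larger islands hold more species?** The island species–area
relationship (ISAR) can arise in qualitatively different ways: *passively*,
because larger islands simply hold more individuals sampled from a shared
regional pool; through *disproportionate effects*, where island area itself
shifts the relative abundances or persistence of (especially rare) species;
or through *within-island habitat heterogeneity*, which spatially clumps
communities. `isarmech` implements the individual-based rarefaction
framework that separates these mechanisms from abundance survey data, for
community ecologists and island biogeographers.

## The method in brief

For each island the package computes three diversity numbers:

- **S_total** — Chao1 estimated total richness,
  `S_obs + F1² / (2 F2)` from the singleton and doubleton counts
  (bias-corrected form when `F2 = 0`);
- **S_n** — expected richness in a standardized sample of
  `n_ref = max(n_max, 2 · n_min)` individuals, by exact hypergeometric
  rarefaction for `n ≤ N` and Chao1-conditional extrapolation beyond;
- **S_PIE** — the effective number of species `1 / (1 − PIE)` of
  Hurlbert's probability of interspecific encounter
  `PIE = N/(N−1) · (1 − Σ pᵢ²)`, which tracks the common species.

Each metric is regressed on island area on natural-log axes (the power law
`S = C · Area^z`), and the slope pattern yields a mechanism verdict: a flat
S_n means passive sampling cannot be rejected; S_n rising without S_PIE
implicates rare species only; both rising implicates common species too.
With plot-level data, within-island β-diversity (the pooled-to-mean-plot
ratio of S_n and of S_PIE) is regressed on area to test whether
compositional heterogeneity contributes. A synthetic-archipelago generator
with known ground-truth mechanisms (`scenario_config()`,
`simulate_archipelago()`) makes the whole inference chain testable.

## Worked example

Simulate an archipelago where rare species are disproportionately lost on
small islands, then fit and classify:

```r
library(isarmech)
cfg <- scenario_config("disproportionate_rare",
                       island_areas = 10^seq(-1, 3, length.out = 20),
                       seed = 1)
fit <- isar(simulate_archipelago(cfg), alpha = 0.05)
summary(fit)
```

```
Island species-area relationship [disproportionate_rare] — log(metric) ~ log(area), n_ref = 3464
 response intercept se_intercept   slope se_slope r2_adj  p_slope n_islands
  S_total      7.07      0.02050 0.02720  0.00566  0.538 0.000141        20
      S_n      6.74      0.00943 0.00766  0.00260  0.287 0.008730        20
    S_PIE      4.39      0.02350 0.01280  0.00650  0.132 0.064200        20
ISAR mechanism verdict (alpha = 0.05): disproportionate_rare
```

Read the table as the classic ISAR regression report: `slope` is the
power-law exponent *z* with its standard error, `r2_adj` the adjusted R²,
and `p_slope` the two-sided test of *z* = 0. Here total richness rises
steeply with area and standardized richness S_n rises too (p = 0.009), so
passive sampling is rejected; S_PIE does not rise significantly
(p = 0.064), so the effect is confined to the rarer species — which is the
scenario's ground truth. The per-island table behind the fit is
`fit$diversity`:

```
  island_id area_km2    N S_obs S_total   S_n S_PIE
1    isl001   0.1000 1732   588    1019 813.4 77.51
2    isl002   0.1624 1785   590    1104 822.9 73.55
3    isl003   0.2637 1840   641    1235 888.6 85.87
4    isl004   0.4281 1897   638    1302 881.9 83.01
```

Field data enter through two (optionally three) tidy CSVs:

```r
fit <- run_isar_analysis(abundances = "abundances.csv",   # island_id, species_id, abundance
                         metadata   = "metadata.csv",     # island_id, area_km2
                         plots      = "plots.csv",        # island_id, plot_id, species_id, abundance
                         taxon = "lizards", out_dir = "results/")
```

which writes the per-island diversity table, the regression table, the
β-diversity table, a JSON verdict, and a plain-text run log recording
`n_ref`, per-island extrapolation ratios, and every exclusion.
`run_simulation_study()` repeats simulate-and-fit over many seeds to
measure rejection rates and verdict frequencies for any scenario.

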