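# corrscape

Do the narrow strips of semi-natural habitat that thread through intensive
farmland — field margins, road verges, ditches — work as dispersal corridors
for vascular plants? `corrscape` implements a complete analysis pipeline for
that question, built around two ideas:

1. **Isolation by resistance.** The network of linear landscape elements
   (LLE) is rasterised at 1-m resolution: element cells get resistance
   0.01 (conductivity 100), a 5-m buffer that closes gaps below 10 m gets
   the doubled resistance 0.02, and the hostile field matrix is infinite.
   The isolation of two vegetation plots is the circuit-theory *effective
   resistance* between their cells — it decreases with every additional
   connecting path, unlike least-cost distance.
2. **Floristic similarity as a dispersal proxy.** For every pair of plots
   within a study area the unweighted Jaccard index `J = c / S` is computed
   (shared species `c` over union `S`), for all species and for subsets by
   phytosociological group and dispersal-distance class. If elements act as
   corridors, similarity should decay more steeply in resistance distance
   than in plain Euclidean distance.

The comparison is made with binomial-logit mixed models (lme4): fixed
effects are the z-scored isolation measure, the element-type combination of
the pair (margin–margin / margin–ditch / ditch–ditch) and their interaction;
crossed random intercepts for study area and for each plot of the pair; an
observation-level random effect when a proportion model is overdispersed.
Per combination the simple slope is `b_main (+ b_interaction)` with standard
error `sqrt(se_main² + 2·cov + se_int²)`, t-tested under bracketing degrees
of freedom `df_max = N − p − g − 1` and `df_min = n − p − g − 1`. Slopes of
the two measures are compared with `Z = (b₁ − b₂) / sqrt(se₁² + se₂²)`, main
effects with a parametric bootstrap, and predicted similarity gains are
translated into species counts via `Δc = ΔJ × S`.

A seeded synthetic generator (field-mosaic landscapes, plot placement,
kernel-based multi-generation colonisation with corridor- and
matrix-channelled species) makes the whole pipeline testable end to end
without any field data.

## Worked example

Eight synthetic 500-m study areas with 5–8 plots each, communities spread
over ten generations, then the full comparison:

```r
library(corrscape)

lconf <- landscape_config(area_side_m = 500, n_areas = 8,
                          min_plot_spacing_m = 50, buffer_m = 150, seed = 1)
run <- run_pipeline(lconf, community_config(seed = 1))
run
#> <cs_run> 55 plots, 167 pairs (167 connected), 106 species

correlation_check(run$pair_table)
#> # A tibble: 1 × 3
#>       r        p     n
#> 1 0.481 4.89e-11   167
```

Resistance and Euclidean distance are only moderately correlated (r ≈ 0.48),
so the two isolation measures are genuinely distinguishable. Fitting both
models for three species sets and keeping the margin–margin rows:

```r
t1 <- compare_isolation_models(run$pair_table,
        c("all", "dispersal:short", "dispersal:long"))
dplyr::filter(tibble::as_tibble(t1), lle_combo == "margin-margin")
#>   species_set     b_euclid b_resist  delta se_delta        p
#> 1 all               -0.509   -0.731 -0.222    0.120 0.0635
#> 2 dispersal:short   -0.361   -1.43  -1.07     0.313 0.000607
#> 3 dispersal:long    -0.847   -0.735  0.112    0.170 0.508
```

Short-distance dispersers — the corridor-dependent guild in this synthetic
world — show a far more negative slope in resistance distance than in
Euclidean distance (Δ = −1.07, Z-test p < 0.001), while long-distance
dispersers, which move through the matrix, show no such excess. Translating
the extra similarity gain into species counts:

```r
table2_report(t1)
#>   species_set     incr_euclid incr_resist delta_incr mean_s delta_spec
#> 1 all                   0.366       0.466     0.0997   44.4          4
#> 2 dispersal:short       0.243       0.520     0.277    12.8          4
```

Reading the second row: moving a margin–margin pair from its most isolated
to its best connected state raises predicted Jaccard similarity by 0.52
under the resistance model but only 0.24 under the Euclidean model; with a
mean union of ~13 short-dispersal species that difference corresponds to
about 4 additional shared species attributable to corridor connectivity.

`autoplot()` methods exist for rasters, slope tables and prediction tables,
and `plot_distance_decay()` shows the raw similarity-vs-isolation scatter.

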