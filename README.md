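# markddd

Marked point-pattern analysis of conspecific **d**istance-, **d**ensity- and
aggregation-**d**ependence (DDD) of tree ecosystem services.

Hyperdominant tropical trees such as the Brazil nut deliver ecosystem
services — harvested seed and stored carbon — whose per-tree magnitude can
depend on the tree's conspecific neighbourhood.  Given an inventory of tree
locations with per-tree marks (seed production in kg, above-ground biomass
from DBH) organised in polygonal concessions, `markddd` answers two
questions:

1. **Do the marks depend on the conspecific neighbourhood?**  Four mark
   correlation functions, each tested against a mark-shuffling null model
   with pointwise simulation envelopes:
   - the mean normalized mark of trees by nearest-neighbour distance bin
     \[r − h, r + h\];
   - Schlather's mark correlation — the Pearson correlation between the
     marks of nearest-neighbour pairs in a bin (a mark analogue of
     Moran's I);
   - the density correlation — the Pearson correlation between a focal
     tree's mark and its conspecific neighbour count within radius r;
   - the aggregation correlation — the Pearson correlation between a focal
     tree's mark and the Clark–Evans index of its r-neighbourhood,
     CE = d̄ / E(d) = 2 d̄ √ρ (1 = random, < 1 = aggregated).

   Marks are normalized by concession means, and the boundary edge
   corrections the statistics need (nearest-neighbour rule, focal-radius
   rule, within-disc circumference rule) are built in.

2. **What does that imply for plot-based assessment?**  A scaling
   experiment rasterizes the pattern at a ladder of grid-cell sizes and
   regresses measured per-hectare totals on expected ones (tree count ×
   grand mean).  The slope is the accuracy and R² the precision of plots of
   that size; negative DDD drags fine-scale slopes below 1.

A synthetic-data generator (`simulate_scenario()`) produces landscapes with
the marginal structure of large concession inventories (sparse aggregated
patterns, right-skewed marks, concession-level mean shifts) and
configurable DDD effects, so the whole pipeline is testable end to end
without access to proprietary inventories.

## Worked example

```r
library(markddd)

# a synthetic landscape with a unimodal nearest-neighbour response:
# depressed marks below 30 m, elevated at 50-90 m
pat <- simulate_scenario(scenario_presets()$unimodal, seed = 42,
                         n_concessions = 6, area_range_ha = c(400, 900))
pat
#> Marked point pattern: 2098 trees in 6 concessions (3958.6 ha total)
#>   overall density 0.530 trees/ha; DBH present for 1771 trees

f1 <- mark_correlation(pat, mark = "seed", fun = "nnmean", bins = "near_5",
                       envelope = envelope_config(n_sim = 199, seed = 1))
f1
#> Mark correlation function: nearest-neighbour mark mean (seed marks, normalized)
#>   edge correction dropped 5.2% of trees
#>   envelopes: 199 randomizations, rank 5 (pointwise two-sided level 0.050)
#>   significant bins: 7 of 15 evaluated
#>      r   stat   n     lo    hi n_sim_eff significant flag
#> 1    5 0.8246 182 0.9071 1.107       199        TRUE
#> 2   15 0.8636 461 0.9260 1.056       199        TRUE
#> 3   25 0.8814 452 0.9383 1.066       199        TRUE
#> 4   35 0.9934 334 0.9302 1.076       199       FALSE
#> 5   45 1.1453 227 0.9237 1.096       199        TRUE
#> 6   55 1.3213 128 0.8760 1.159       199        TRUE
#> ...
```

Reading the table: `stat` is the mean normalized seed production of trees
whose nearest conspecific sits in the 10 m bin around `r`; values
significantly below the envelope (`lo`) at r < 30 m show the imposed
short-range depression, and values above `hi` at 45–75 m the elevated
plateau — trees with nearest neighbours at those distances out-produce
their concession average.  `plot(f1)` draws the familiar
dots-and-envelopes figure.

The scaling experiment on the same landscape:

```r
sc <- scaling_curve(pat, "seed", scaling_config(cell_sizes_m = c(50, 100, 200)))
sc
#> Plot-size scaling (seed marks, through-origin regression): 3 cell sizes
#>   cell_label cell_area_ha n_cells  slope  ci_lo  ci_hi r_squared
#> 1       50 m         0.25   15516 0.9354 0.9226 0.9482    0.5687
#> 2      100 m         1.00    3788 0.9464 0.9248 0.9681    0.6600
#> 3      200 m         4.00     923 0.9753 0.9350 1.0156    0.7102
```

Small plots are biased low (slope < 1) because DDD makes locally dense
cells under-produce relative to the grand mean; by 4 ha cells the slope's
confidence interval includes 1 and precision (R²) has risen.  `plot(sc)`
shows both profiles against cell area on a square-root axis.

An end-to-end run (simulation or CSV/GeoJSON inputs → all four functions
with envelopes for both marks → scaling curve → result CSVs + manifest) is
`run_pipeline()`; a thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

## Package layout

| Area | Functions |
| --- | --- |
| Data model | `marked_pattern()`, `concession_window()`, `rect_window()` |
| Spatial queries | `nearest_neighbours()`, `neighbour_counts()`, `boundary_distances()`, `neighbour_info()` |
| Allometry | `latas_to_kg()`, `agb_from_dbh()`, `allometry_params()` |
| Mark functions | `mark_correlation()`, `make_bins()`, `edge_filter_nn()`, `clark_evans_neighbourhood()` |
| Null model | `envelope_config()`, `shuffle_marks()`, `build_envelopes()` |
| Scaling | `scaling_curve()`, `rasterize_pattern()`, `scaling_regression()`, `residual_correlogram()`, `cell_size_m()` |
| Synthetic data | `scenario_config()`, `scenario_presets()`, `simulate_scenario()`, `simulate_points()`, `simulate_marks()`, `generate_windows()` |
| I/O & pipeline | `read_trees()`, `read_windows_geojson()`, `write_trees()`, `write_windows_geojson()`, `run_pipeline()`, `project_lonlat()` |

See the methods vignette (`vignettes/markddd-methods.Rmd`) for the
statistical model, the edge-correction rules, the null-model contract and
the generator's scope and limitations.
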