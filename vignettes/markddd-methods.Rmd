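---
title: "Methods: marked point-pattern analysis of distance-, density- and aggregation-dependence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marked point-pattern analysis of distance-, density- and aggregation-dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hyperdominant tropical trees such as the Brazil nut (*Bertholletia excelsa*)
supply ecosystem services — seed harvests and carbon storage — whose per-tree
magnitude may depend on the tree's conspecific neighbourhood: how far away
the nearest conspecific grows, how many conspecifics surround the tree, and
how clumped that neighbourhood is.  `markddd` quantifies these conspecific
distance-, density- and aggregation-dependence (DDD) signals in large tree
inventories organised in polygonal management units ("concessions"), and
asks what the consequences are for plot-based estimates of per-hectare seed
production and above-ground biomass (AGB).

The package operates on a *marked point pattern*: tree locations in planar
metric coordinates, each carrying quantitative marks (seed production in kg
per year, AGB in kg) and a concession membership.  Inventories of this kind
are sparse (around 0.5 trees/ha), span concessions from tens to thousands
of hectares, and mix trees with and without DBH measurements.

# Marks and allometry

Seed production is recorded by harvesters in *latas* (tin cans) of fresh
in-shell seed; one lata holds approximately 11.66 kg, and `latas_to_kg()`
applies this linear conversion.  AGB is derived from DBH with the
diameter-only pantropical allometric model

$$\ln(\mathrm{AGB}) = -1.803 - 0.976\,E + 0.976 \ln \rho_w
  + 2.673 \ln D - 0.0299 \,[\ln D]^2,$$

with $D$ the DBH in cm, $\rho_w$ the wood density (default 0.59 g cm⁻³,
the accepted value for *B. excelsa*) and $E$ an environmental-stress
surrogate.  Inventories of this species rarely include tree heights, which
is why the diameter-only form is the default; $E$ is site-dependent and not
known for typical concession landscapes, so it defaults to 0 and is exposed
in `allometry_params()` together with the full coefficient vector — any
other diameter-based model can be substituted without touching the
statistics.  Trees without DBH carry the seed mark only; AGB analyses
exclude them and report the exclusion count.

# Normalization

All mark correlation functions operate on marks divided by the mean mark of
the tree's own concession (`normalize_marks()`), so within each concession
the normalized marks average exactly 1.  This removes between-concession
differences in mean productivity or biomass — environmental gradients and
harvester-specific estimation styles — that would otherwise masquerade as
spatial structure when statistics are pooled across concessions.  The
normalization applies to all four functions; the first two would otherwise
not be interpretable as relative elevation/depression, and the correlation
functions would be dominated by between-concession mean differences.  Raw
marks remain available (`normalize = FALSE`) for sensitivity analysis.

# The four mark correlation functions

All neighbour relations are conspecific and confined within a concession:
normalization and the edge rules are concession-level concepts, and
neighbours across tenure boundaries are not observable in single-unit
inventories.  `mark_correlation()` computes, per distance bin:

1. **Nearest-neighbour mark mean** (`"nnmean"`): the mean normalized mark of
   trees whose nearest conspecific neighbour lies in $[r-h, r+h]$.  Values
   below/above 1 indicate that trees with neighbours at that distance
   produce less/more than their concession average.
2. **Schlather's mark correlation** (`"schlather"`): the Pearson correlation
   between the marks at the two ends of each (tree, nearest-neighbour) pair
   in the bin — a mark analogue of Moran's I.  Pairs are ordered by
   default, so mutual nearest neighbours contribute in both orientations;
   `pair_mode = "unique"` collapses them.
3. **Density correlation** (`"density"`): the Pearson correlation between a
   focal tree's mark and its cumulative conspecific neighbour count within
   radius $r$.
4. **Aggregation correlation** (`"aggregation"`): the Pearson correlation
   between a focal tree's mark and the Clark–Evans index of its
   $r$-neighbourhood.  Because aggregated neighbourhoods have an index
   below 1, a *positive* correlation means lower marks in more aggregated
   neighbourhoods.

## Distance bins

Nearest-neighbour distances up to 150 m are binned into contiguous closed
intervals $[r-h, r+h]$ for bandwidths $h \in \{1.5, 5, 10\}$ m (centres
$h, 3h, 5h, \dots$); between 150 and 350 m the interval width doubles to
keep bins populated, since few trees have nearest neighbours that far.  The
density and aggregation functions use the cumulative radius ladder
$10, 20, \dots, 350$ m.  For $h = 10$ the near regime ends at the last full
bin below 150 m (centre 130 m): 150 is not divisible into width-20 bins, and
a truncated terminal bin would not be comparable with its neighbours.  A
distance on a shared bin boundary belongs to the lower bin — an explicit
deterministic tie-break, relevant only for exactly replicated coordinates.

## Edge corrections

Statistics near a window boundary are biased because part of the
neighbourhood is unobserved.  Three rules are applied:

* Functions 1–2 drop trees whose boundary distance is smaller than their
  nearest-neighbour distance (their true nearest conspecific could lie
  outside the window).  The dropped fraction is always reported.
* Functions 3–4 only use focal trees at least $r$ from the boundary, so the
  circular neighbourhood is fully observed.
* Inside an $r$-neighbourhood, the Clark–Evans calculation additionally
  drops members closer to the circumference than to their nearest member —
  the within-disc analogue of the first rule.

## The neighbourhood Clark–Evans index

For a focal tree and radius $r$, the members are all conspecifics within
$r$ (the focal excluded).  Each member's nearest-member distance is found,
members failing the circumference rule are dropped, and the index is

$$\mathrm{CE} = \bar d \,/\, E(d) = 2 \bar d \sqrt{\rho},$$

with $\bar d$ the mean retained nearest-member distance and $\rho$ the
focal tree's *concession* density in trees m⁻² (densities are reported per
hectare but converted internally so the ratio is dimensionless).  Under
complete spatial randomness $E(d) = 1/(2\sqrt{\rho})$, giving 1 for random,
$<1$ for aggregated and $>1$ for regular neighbourhoods.  The index is
undefined (and flagged, never silently zero) with fewer than two members
after exclusions.

A calibration subtlety documented here because it matters for
interpretation: the circumference rule removes members *selectively* —
those with large nearest-member distances are more likely to fail it — so
the retained $\bar d$ is slightly biased low.  The bias is of order
$E(d)/r$: negligible when neighbourhoods hold many members, but a CSR
pattern sparse enough that $E(d)$ approaches $r$ will average visibly below
1.  The package's calibration experiments therefore use densities at which
a 100 m neighbourhood holds a few hundred members (mean index ≈ 0.97–0.99);
at typical concession densities of ~0.5 trees/ha the index is simply
undefined for most 100 m neighbourhoods, which the per-bin `n` column makes
visible.

# The null model and simulation envelopes

Statistical reference is a *mark-shuffling* null: marks are randomly
permuted across trees while all locations stay fixed, destroying any
mark–location association while preserving both the spatial pattern and the
mark distribution exactly.  By default marks are normalized once and then
shuffled globally (across concessions); a stricter conditional null that
shuffles within concessions is available (`scope = "within_concession"`).
Re-normalizing after each shuffle would make the null statistic's mean
depend on the permutation; normalizing once keeps the observed and null
statistics on the same scale.

With `n_sim = 199` randomizations and `rank = 5`, the envelope bounds are
the 5th-lowest and 5th-highest null values per bin — the pointwise 2.5th
and 97.5th percentiles, since a rank-$k$ bound of $n$ exchangeable draws is
exceeded with probability $k/(n+1)$.  A bin is flagged significant only if
the observed statistic falls *strictly outside* the closed envelope.  The
test is pointwise: with ~15–50 bins per function, a few flagged bins are
expected by chance even under the null, and no multiple-testing correction
across bins is applied.  Replicate seeds are all spawned up front from one
master seed, so results are identical regardless of evaluation order.

# Plot-size scaling experiment

To connect tree-level DDD to plot-based assessment, `scaling_curve()`
rasterizes each concession at a ladder of cell sizes (the arc-second ladder
1–40″ converted at a reference latitude, or metric sizes), and compares two
per-hectare surfaces per cell: *measured* (the summed marks of the trees in
the cell) and *expected* (tree count × the grand mean mark over all trees).
The regression of measured on expected across cells gives the accuracy
(slope; 1 = unbiased) and precision (R²) of plots of that size.  Negative
DDD makes dense cells under-produce relative to the grand mean, pulling
fine-scale slopes below 1; coarser cells average the effect away and the
slope rises toward 1.

Choices the data do not dictate, made explicit:

* Regression is through the origin by default (a cell with zero expected
  value structurally has zero measured value); `with_intercept` mode is
  available, and excludes empty cells so zero-inflation does not dominate
  the intercept fit.
* Cells only partially inside the window are dropped at the default
  `min_coverage = 1` (coverage measured by exact polygon–rectangle
  clipping); lowering the threshold admits boundary cells with their true
  coverage recorded.
* Grids are aligned to each window's bounding-box corner with half-open
  cell membership, and each concession is gridded separately.
* Arc-second cells are east–west narrowed by $\cos(\text{latitude})$
  (spherical radius 6,371 km); at 12°S a 3.33″ cell is ≈1 ha.

Residual spatial autocorrelation is checked with a distance-binned
Moran-type correlogram of the regression residuals
(`residual_correlogram()`): per centroid-distance bin, the Pearson
correlation over symmetrized residual pairs, with a pointwise envelope from
99 residual permutations at rank 3 (two-sided level 0.06).  This is a
deliberate simplification of spline-based correlograms: it answers the same
qualitative question (is there residual structure, and at what range?) with
the package's own permutation machinery.

# The synthetic-data generator

Because concession inventories of this kind are not openly deposited, every
stage is validated on synthetic landscapes (`simulate_scenario()`) that
emulate the documented marginal structure: several rectangular concessions
with areas drawn from 16–4,575 ha, tree density 0.53 trees/ha (homogeneous
Poisson, or a Thomas cluster process thinned to the target density for
aggregated patterns), lognormal DBH truncated at the 10 cm inventory
threshold with ~15% of trees unmeasured, and right-skewed seed marks with a
landscape mean near 30 kg (per-tree lognormal noise, CV ≈ 0.8) shifted by
concession-level lognormal baselines (SD ≈ 35% on the log scale, matching
the documented between-concession spread).

Mark effects are multiplicative and act on exactly the quantities the
analysis estimates:

$$\text{mark}_i = \text{baseline}_{c(i)} \times g(d_i^{NN}) \times
  e^{-\beta\, n_i(r_c)} \times \max\{0,\, 1 + \gamma\,(\mathrm{CE}_i(r_a) - 1)\}
  \times \varepsilon_i,$$

where $g$ is a piecewise-linear nearest-neighbour distance response,
$n_i(r_c)$ the neighbour count within $r_c$, and $\mathrm{CE}_i(r_a)$ the
neighbourhood aggregation index *computed with the same estimator and edge
exclusions as the analysis*, so that recovery of an aggregation effect is a
genuine round trip rather than a tautology.  Presets: `null` (no effects),
`fine_negative` (30% depression below 30 m), `unimodal` (depression below
30 m, +15% plateau at 50–90 m, decline beyond 150 m), and `ddd_full` (all
three effects).  Multiplicative lognormal structure keeps marks
non-negative and right-skewed, mimicking per-tree production (mean ≈ 30 kg,
SD ≈ 27 kg, maxima a few hundred kg).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real inventories: georeferencing error (tens of
metres for some field records), irregular concession polygons, spatially
correlated environmental gradients in the marks, harvester-specific
estimation bias beyond a mean shift, temporal variation in seed production,
and any genetic or pollination mechanism behind DDD.  DBH (hence AGB) is
drawn independently of locations, so AGB-mark recovery experiments require
attaching effects to the seed mark.

# Numerical choices and degenerate inputs

* Nearest-neighbour search is exact (per-concession distance matrices, no
  approximate index); ties break to the smallest `tree_id`.  Coincident
  trees within a concession are an error naming the pair — a zero
  nearest-neighbour distance would poison the edge rules.
* Correlation bins need ≥ 3 contributing pairs/trees and non-zero variance;
  otherwise the statistic is `NA` with an explanatory flag (`"empty"`,
  `"unstable"`, `"undefined"`), never a silent 0.
* Envelope bins where some null replicates are undefined report the reduced
  effective replicate count.
* Containment tests tolerate 1 µm of boundary jitter; trees outside their
  window are an error naming the tree.
* All statistics require planar metric coordinates.  Geographic input is
  converted explicitly via `project_lonlat()` (default UTM zone 19S);
  nothing is inferred from coordinate magnitudes.

# Problem sizes used by the validation suite

The shipped tests exercise the pipeline at sizes chosen to make the
statistical claims sharp while staying desk-scale: oracle-equivalence
checks on patterns of ≤ 500 trees against direct-loop implementations
(agreement to 1e-10); null calibration of the envelope test over 150–200
independent landscapes of a few hundred trees each (per-bin rejection rate
within binomial tolerance of the nominal 5%); power checks for the
fine-scale depression on 20 landscapes of ~5,000 trees (≥ 80% of replicates
flag a below-envelope bin under 30 m); and CSR calibration of the
aggregation index over ≥ 500 neighbourhoods of ~250 members.  These sizes
are the package's own validation design, not statements about any
particular dataset.

# Known limitations

* Envelope tests are pointwise; global envelope corrections are out of
  scope and flagged bins must be read accordingly.
* The Clark–Evans edge exclusion has the small selective bias described
  above; comparisons should be made against the shuffled null (which shares
  the bias) rather than against the literal value 1.
* Schlather's function inherits the data sparsity of nearest-neighbour
  pairs at long range: expect unstable flags beyond ~200 m at realistic
  densities.
* No inhomogeneous-intensity corrections: within-concession density trends
  are attributed to the pattern, not modelled away.
* The pipeline treats each concession as an isolated window by design;
  cross-concession neighbour relations are never used.
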