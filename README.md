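# paestate

Has a protected-area network actually slowed habitat conversion? `paestate`
answers that question for gridded land-conversion data and a site register,
using a *compare-to-everywhere* design: land inside the protected estate is
contrasted with all unprotected land, both as a current snapshot and as a
decadal trajectory, and each site's conversion rate is compared before
versus after its gazettement. It is aimed at conservation scientists
evaluating estate performance from historical land-use reconstructions
(HYDE-style fraction grids) or satellite land-cover classifications
(GlobCover / GLC2000-style class rasters).

## What it computes

* **Time-resolved protection layers.** The register is filtered (IUCN
  categories Ia–IV, polygons ≥ 1 km², dated records for historical work,
  gazettement cutoff) with a fully reconciled exclusion report, then merged
  into a non-overlapping estate per decade, overlaps tagged with the
  strictest category and counted once.
* **Exact zonal overlay.** Per-cell fractional coverage of the estate
  (polygon∩cell area / cell area, exact for the package's rectangle
  geometry), giving area-weighted converted percentages inside and outside,
  per-site values, and the decadal inside/outside trajectory against the
  estate as it existed in each decade.
* **Effectiveness statistics.** Standardised major axis (model II)
  regression with slope `b = sign(r)·sd(y)/sd(x)` and the classical
  F-based confidence interval; a likelihood-ratio common-slope test for the
  inside vs outside trajectories; per-site pre/post-gazettement conversion
  rates and their paired t-test; size–conversion scaling (log-log SMA with
  a unity test); per-site conversion histograms and size-quantile profiles.
* **A synthetic landscape simulator** with known ground truth — contagious,
  accessibility-biased stochastic clearance with a tunable protection
  effect and realistic register degeneracies — so the whole pipeline is
  testable end to end without external data.

## A worked example

```r
library(paestate)
manifest <- run_demo(seed = 1, protection_multiplier = 0.5)
```

```
<pipeline_manifest>
  estate area: 27465 km^2
  converted inside 11.65% vs outside 15.47% (final year)
  mean per-site conversion 12.3%; 0 sites > 50% converted
  trajectory SMA slopes: inside 0.7089, outside 1.0296 (p = 0.000)
  conversion rate 0.910%/decade before vs 0.715%/decade after gazettement
  paired t = 3.562, df = 74, p = 0.001 (75 sites)
```

The demo simulates a 120 × 120 grid of 8 km cells over 16 decades
(1850–2000) with 100 protected sites whose true clearance hazard is halved
after establishment, then runs the full filter → merge → overlay →
statistics chain. The output shows the generated effect being recovered:
land inside the estate ends less converted than outside (11.65% vs 15.47%),
the inside trajectory rises more slowly (SMA slope 0.71 vs 1.03 percentage
points per decade), and per-site conversion slows from 0.910 to 0.715
%/decade after gazettement (paired t = 3.56 on 75 sites with both pre- and
post-gazettement decades; the rest are excluded with logged reasons).

Fitted objects are tidyverse-friendly:

```r
tidy(manifest$historical$paired_t)
#> # A tibble: 1 × 5
#>   estimate statistic parameter  p.value     n
#>      <dbl>     <dbl>     <dbl>    <dbl> <int>
#> 1    0.195      3.56        74 0.000647    75

plot_trajectory(manifest$historical$trajectory)
autoplot(manifest$current$size_scaling)
```

Real data enter through `read_register_geojson()` /
`read_ascii_grid()` / `load_fraction_series()` / `reclassify()` (packaged
class maps: `load_class_map("globcover")`, `load_class_map("glc2000")`),
then `pipeline_config()` + `run_pipeline()`.

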