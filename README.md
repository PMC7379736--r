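# dendrores

Spatiotemporal analysis of tree resilience to extreme drought from
tree-ring networks.

## The problem

Semi-arid mountain forests record every growing season in their ring
widths. After an extreme drought year, individual trees differ sharply in
how much growth they lose (resistance) and how fast they regain it
(recovery), and the regional pattern of those differences shifts from one
drought to the next. `dendrores` is for dendroecologists who have a
multi-site network of ring-width series plus monthly climate tables and
want a reproducible path from raw measurements to per-tree resilience
indices, site proportions, driver regressions and resilience maps.

The core quantities are the Lloret resistance and recovery components.
With ring-width indices (RWI, width divided by a fitted growth trend),
`Dr` the index in the drought year, and `PreDr`, `PostDr` the mean
indices over the 4 years before and after:

    Rt = Dr / PreDr        (resistance; < 1 means growth loss)
    Rc = PostDr / Dr       (recovery;  > 1 means rebound)

A tree is high-resistance when `Rt > 0.75` and high-recovery when
`Rc > 1.25`; the site-level responses are the proportions of such trees,
written `P_Rt>0.75` and `P_Rc>1.25`.

The pipeline stages:

1. **I/O** — Tucson (RWL) ring-width files, long-format climate CSV, site
   tables; nearest-grid-point matching by great-circle distance.
2. **Detrending** — cubic smoothing spline with a 50% frequency-response
   cutoff at half the series length; biweight robust-mean site
   chronologies.
3. **Event detection** — first differences of regional May–June scPDSI;
   years more than 1.5 SD below the mean are extreme droughts.
4. **Resilience** — per-tree `Rt`/`Rc` per event, classification,
   site proportions, Kruskal–Wallis comparisons across events.
5. **Coherence** — Gleichläufigkeit (GLK) among trees in an 11-year event
   window, index SD, mean age.
6. **Driver regression** — p-value-thresholded stepwise least squares
   (enter < 0.1, remove > 0.15) of the site proportions on climatic
   (ΔPDSI, ΔDTR, seasonal aggregates) and stand-internal factors.
7. **Mapping** — Thiessen (Voronoi) polygons carrying the site
   proportions, exported as GeoJSON, with high/low area fractions.

Because no tree-level data ship with the source study, the package
includes a synthetic-region generator (`generator_config()`,
`generate_region()`) whose defaults emulate the study conditions — 28
sites, 849 juniper-like trees, three planted region-wide droughts
(1969/1979/1995), chronology–scPDSI correlation ≈ 0.47 — with known
ground truth for every stage. See `vignette("resilience-methods")` for
the model, the numerical choices and what the generator does and does not
emulate.

## Worked example

A small synthetic region end to end:

```r
library(dendrores)

cfg <- pipeline_config(
  out_dir   = "demo_run",
  generator = generator_config(n_sites = 6, total_trees = 120, seed = 42),
  seed      = 42)
man <- run_pipeline(cfg)
summarize_run(man)
```

which prints:

```
Regional tree resilience summary
--------------------------------
 event_year n_trees mean_Rt mean_Rc P_high_Rt P_high_Rc n_floored
       1969     120   0.897    1.26     0.733     0.267         1
       1979     120   0.750    1.72     0.517     0.542         2
       1995     120   0.598    1.99     0.342     0.683         4
mean chronology ~ May-June scPDSI r: 0.50
Kruskal-Wallis across events: Rt H = 77.14 (p = 1.8e-17), Rc H = 33.35 (p = 5.7e-08)
P_high_Rt = 1.23 + 0.081*delta_pdsi (R2 = 0.50)
P_high_Rc = -0.29 - 0.0908*delta_pdsi (R2 = 0.56)
high-area fractions (share of bbox):
 event_year high_rt_area high_rc_area
       1969        1.000        0.000
       1979        0.414        0.586
       1995        0.000        1.000
```

Reading this: the three planted drought years were detected from the
scPDSI differences alone; mean resistance falls across the events (0.90 →
0.60) while mean recovery rises (1.26 → 1.99); the proportion of
high-resistance trees drops from 73% to 34% as the high-recovery
proportion climbs to 68%; and on the map the area of high resistance
contracts to nothing while high recovery expands to the whole region.
`n_floored` counts trees whose event-year ring was missing, giving
near-infinite recovery values that are flagged and kept out of `mean_Rc`.
All stage tables (`records.csv`, `site_summaries.csv`, `design.csv`,
`models.json`, `map_<year>.geojson`, …) are in `demo_run/`, and
re-running the same config reproduces them byte for byte.

A thin command-line wrapper with `generate` / `run` / `report` verbs
lives at `inst/cli/dendrores.R`:

```sh
Rscript inst/cli/dendrores.R run --config analysis.yml
```

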