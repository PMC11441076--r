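# neurofate

Longitudinal neuron-fate and cortical-microstructure analysis for weekly 3D
nucleus point clouds, with a synthetic-data generator that makes every stage
verifiable by parameter recovery.

## The problem

In vivo two-photon imaging of fluorescently labelled neuronal nuclei yields,
for each weekly session, a 3D cloud of centroids (x, y, z in µm) with a
per-nucleus neurofibrillary-tangle flag. From these clouds the analysis must

* register sessions into a common frame from fiducial nuclei (closed-form
  least-squares **absolute orientation**: uniform scale *s*, proper rotation
  *R*, translation *t* minimising Σᵢ ‖s·R·pᵢ + t − qᵢ‖²),
* link nuclei across weeks (gated mutual nearest neighbours) and call a
  **disappearance** only when absence persists through the final session,
* assign longitudinal **tangle status** (ever-tangled = initially tangled +
  newly tangled; tangle objects retained at ≥ 100 voxels ≈ 49 µm³),
* compute two bespoke spatial statistics:
  * the **neighbour-volume change** — the volume of the tetrahedron spanned
    by a neuron's 4 nearest persistently-present neighbours, compared across
    the 2 weeks before its disappearance,
    `100 · (V_last − V_first) / V_first`, with the cube-root distance
    equivalent `d · ((1 + pct/100)^{1/3} − 1)`;
  * the single-snapshot **local enlargement ratio** —
    `d3 / mean(d3 of neurons within 100 µm) − 1` where d3 is the mean
    3-nearest-neighbour distance, with neurons above the strict 0.60 cutoff
    flagged as sitting in rarefied microstructure;
* summarise fates per group: loss fractions, weekly losses, cumulative and
  weekly **hazard ratios**, and the uncorrected Pearson **2×2 chi-square**.

The package is aimed at groups doing longitudinal cell tracking in cortex
(or analysing single-time-point cleared-tissue sections) who need these
statistics reproducible from plain centroid tables rather than from
interactive image-analysis sessions.

## Worked example

```r
library(neurofate)

cfg <- simulationConfig(nNeurons = 1500, seed = 1)   # the default regime
sim <- simulateLongitudinal(cfg)
res <- runPipeline(sim$sessions)

table(fates(res$tracks))
#>   ambiguous disappeared   persisted
#>          13         123         864

round(res$summary$lossPctAll, 1)      # total loss over 4 weeks, percent
#> [1] 12.1

round(unlist(res$summary$hazardRatio), 2)  # non-tangle vs tangle
#> cumulative     weekly
#>       5.74       6.00

str(res$volumeChangeSummary)
#> List of 3
#>  $ dyingMeanPct     : num 30.3
#>  $ persistentMeanPct: num -1.07
#>  $ nDying           : int 32
```

The tracked loss fraction recovers the planted ~10% true loss plus a known
~1.5% false-disappearance rate at the 8 µm matching gate. The dying
neurons' neighbour-volume change recovers the planted 29.5% ramp (here
30.3% over 32 measurable dying neurons) while persistent neurons sit near
0%. A single simulated field holds only a handful of tangle-bearing
deaths, so the one-run hazard ratio is noisy by design; the recovery tests
pool 20 simulations, where the exposure-based weekly ratio converges to
the planted value.

The published worked-example numbers are recomputed (not asserted) from the
bundled count tables:

```r
rr <- referenceReproductions()
signif(rr$chiSquare, 3)          # 17.8   died/survived x tangle status
rr$lossPct                       # 10.3 2.6 11.6 0.5 2.8 0.1  (percent)
rr$humanEnlargedPct              # 2.00 0.49 (percent of neurons enlarged)
round(rr$cumulativeHazardRatio, 2)  # 4.53
round(rr$distanceEquivalentUm, 1)   # 2.2  (um, from 29.5% at 24.0 um)
round(rr$tangleCutoffUm3)           # 49   (um^3 at 100 voxels)
```

A thin command-line wrapper lives in `inst/scripts/neurofate`
(`simulate` and `run-all` subcommands over CSV/JSON/YAML files).

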