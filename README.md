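# cypridtrack

Automated tracking and behavioural classification of barnacle cypris
larvae (cyprids) in fixed-camera grayscale image sequences.

Cyprids — the settlement-stage larvae of barnacles — explore immersed
surfaces on paired antennules before attaching permanently, and the
structure of that exploration is the quantity of interest in settlement
and antifouling research. The accepted repertoire has four behaviours:
**swimming**, **wide search** (stepped walking with near-regular step
lengths), **close search** (tortuous walking confined to a small area)
and **inspection** (stationary probing about one attachment point).
`cypridtrack` turns an image stack of many dark larvae on a bright
substratum into per-animal behaviour records, with no manual scoring.

## Method at a glance

* **Imaging** — iterative background brightening recovers the static
  background exactly when every pixel is animal-free at least once;
  thresholded background subtraction plus 8-connected labelling yields
  segments with size *n* and centroid CE = (Σxᵢ/n, Σyᵢ/n).
* **Tracking** — each animal is the equivalent ellipse
  (CE, a, b, θ) of its filled component. Segments associate across
  frames by pixel overlap. Fused blobs are resolved per animal by
  minimizing `W = a₁·N_black + a₂·N_white − a₃·N_cyprid` over a small
  deterministic candidate set; splitting blobs assign animals to
  fragments by minimizing `Et = w₁·Es + w₂·Ed + w₃·Ep` (size, axial
  direction and shared-pixel errors, each normalized to [0, 1]).
  Vanished animals are retained as `missed` for a patience window.
* **Kinematics** — each ellipse reduces to three points, CE and the
  terminal points `TP₁,₂ = CE ± a(cos θ, sin θ)` with θ lifted to a
  temporally continuous direction; dwell *nodes* are extracted from each
  path by a streaming radius test (radius 1.7 px, > 14 members).
* **Ethology** — wide search: windows of 4 steps with `St/m < 0.2` and
  `max |SL − 0.85·CL| / (0.85·CL) < 0.3`; inspection: terminal-point
  node whose body-direction range exceeds 30°; close search: chains of
  short inspection nodes closer than 4 × 0.85·CL; swimming: everything
  else. Events tile each track; summaries report counts, totals and
  truncated averages per behaviour.
* **Synthetic data** — a seeded generator scripts all four behaviours,
  renders them as noisy image sequences with ground-truth labels, and
  backs every end-to-end test.

## Worked example

```r
library(cypridtrack)
arena  <- reference_arena()    # 160 x 120 px arena, 7 x 3 px animal, 33 fps
script <- reference_script()   # swim / wide search / swim / close search / swim / inspect
sim    <- simulate_sequence(script, arena, seed = 42)

track <- track_sequence(sim$frames, run_config())
res   <- classify_track(track, run_config())
res$events
#>   cyprid_id    behaviour start_frame end_frame duration_s step_count
#> 1         1     swimming           0        97      2.970         NA
#> 2         1  wide_search          98       247      4.545          7
#> 3         1     swimming         248       361      3.455         NA
#> 4         1 close_search         362       554      5.848         NA
#> 5         1     swimming         555       658      3.152         NA
#> 6         1   inspection         659      1484     25.030         NA

summarize_events(res$events)
#>      behaviour event_number     total average unit
#> 1  wide_search            1  7.000000       7 step
#> 2 close_search            1  5.848485       5    s
#> 3   inspection            1 25.030303      25    s
```

The six scripted phases come back as six events in the scripted order:
one wide-search bout of 7 steps, one close-search bout of 5.8 s, one
inspection bout of 25 s, with swimming filling the gaps; frame-level
agreement with the script is 98.3% on this seed (transition frames
around node boundaries account for the remainder). `track` itself is a
plain data frame (frame, time, id, ellipse parameters, provenance) and
every table can be written to CSV (`write_track()`, `write_ethogram()`,
`write_summary()`).

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cypridtrack.R", package = "cypridtrack"))') \
    track --input frames/ --track-csv track.csv --background-png bg.png
```

with subcommands `track`, `classify`, `simulate` and `summarize`.

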