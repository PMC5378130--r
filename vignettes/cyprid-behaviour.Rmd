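---
title: "Tracking and classifying cyprid settlement behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and classifying cyprid settlement behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypridtrack)
```

## The problem

Barnacle cypris larvae (cyprids) explore immersed surfaces on a pair of
antennules before committing to permanent attachment. Their exploration is
conventionally partitioned into four behaviours: **swimming** in the water
column, **wide search** (stepped walking over a large area with
near-regular step lengths), **close search** (tortuous walking with
frequent direction reversals confined to a small area) and **inspection**
(stationary probing while attached at one point, the body oscillating
about the attachment). Quantifying these behaviours objectively, for many
animals at once and over the hours a settlement sequence can take, needs a
fully automated tracking and classification pipeline. `cypridtrack`
implements one: a fixed-camera background-subtraction tracker that keeps
per-animal identities through blob merges and splits, followed by a
deterministic rule-based classifier operating on dwell nodes of the
animal's centre and terminal-point paths.

## Tracking model

Frames are grayscale matrices with dark animals on a bright, static
substratum. The pipeline assumes a fixed camera and approximately constant
illumination; nothing adapts over time.

**Background.** `build_background()` starts from the first frame and, on
repeated passes over the sequence, copies into the model any pixel of a
later frame brighter than the model by more than `diff_threshold`
(default 30 intensity units). Because animals are strictly darker than the
substratum, the fixed point of this update is the true background wherever
every pixel is animal-free in at least one frame. A `max_passes` guard
(default 50) bounds the iteration and flags non-convergence, which can
otherwise occur under slow illumination drift.

**Segmentation.** Foreground pixels are those where `background − frame`
exceeds `bin_threshold`. The default, 70, is half the nominal
blob/background contrast of the synthetic renderer (200 versus 60); for
real footage it should be set to roughly half the observed contrast.
Components are labelled with 8-connectivity — thin diagonal body outlines
must not fragment — and components below `min_area = 5` px are dropped,
mirroring the acquisition requirement that an animal's boundary span at
least five pixels. Segment centroids are real-valued pixel-coordinate
means, never rounded; coordinates are 0-based, x rightward, y downward.

**Ellipse representation.** Each animal is the equivalent ellipse of its
filled component: same centroid and second-order central moments. For a
solid ellipse the moment eigenvalues are $a^2/4$ and $b^2/4$, so the
semi-axes fall directly out of the eigendecomposition; orientation is
defined modulo 180° and normalized to $[0, 180)$. A boundary
least-squares fit was considered and rejected: segmentation yields filled
regions, for which moments are both cheaper and less noise-sensitive.
Pixel sets with fewer than five pixels or (near-)collinear geometry raise
a classed degenerate-geometry error; the tracker then freezes the previous
state with provenance `missed`.

**Association and identity.** Segments of consecutive frames are
associated by pixel-set intersection (at least one shared pixel), and the
connected components of the resulting bipartite graph fall into the five
situations the tracker handles: one-to-one continuation, merge, split,
exit, entry. A many-to-many component is reachable in principle and is
resolved by the same assignment machinery as a split.

*Merges* are resolved per animal by scoring candidate ellipses with
$W = a_1 N_{black} + a_2 N_{white} - a_3 N_{cyprid}$, where $N_{black}$
counts background pixels wrongly claimed inside a candidate, $N_{white}$
counts the animal's pixels left outside, and $N_{cyprid}$ counts the
animal's *remaining* pixels (the overlap between the fused segment and the
animal's pixels in the previous frame) captured inside. The candidate set
comprises the moment fit of the remaining pixels, the fit of remaining
plus all free pixels, and an ellipse obtained by deterministic fixed-point
refinement seeded from the animal's previous ellipse: segment pixels under
the 20%-inflated ellipse are selected and refitted, three times. The
refinement is what carries identity through deep crossings — when two
bodies pass through one another the fused blob is an X whose arms continue
the two body axes, and an ellipse seeded with an animal's own axis locks
onto its own arm, while purely set-based candidates exchange pixels
between the animals. Each animal's support is then the disjoint share of
segment pixels nearest to its refined ellipse in normalized elliptical
distance. The weights $a_1 = a_2 = a_3 = 1$ are package defaults
(config-exposed); the three counts are commensurate (all pixel counts), so
unit weights are the neutral choice.

*Splits* assign animals to fragments by minimizing
$Et_{ij} = w_1 Es_{ij} + w_2 Ed_{ij} + w_3 Ep_{ij}$ with all three error
terms normalized to $[0, 1]$ so unit weights are comparable: size error
$Es = |s_i - s_j| / \max(s_i, s_j)$, direction error
$Ed = \min(|\Delta\theta|, 180 - |\Delta\theta|)/90$ (orientations live on
the axial circle), and shared-pixel error
$Ep = 1 - N_{shared}/\min(s_i, s_j)$. The assignment is exhaustive over
injective maps for up to four animals and greedy beyond; equal costs
resolve to the lowest id taking the lowest label, and every iteration
order in the tracker is deterministic, so output is a pure function of
frames and configuration.

*Missed animals* keep their last geometry for `miss_patience = 10` frames
(about 0.3 s at 33 fps) and their frozen pixel support continues to take
part in association, so a brief detection dropout does not break a track.
A fragment of a splitting blob that no active animal claims is first
offered to a nearby missed animal (within two body lengths) — an animal
starved of pixels during an overlap re-emerges exactly this way — before a
new identity is minted. Far or late re-appearances get new identities;
retired tracks are never re-linked.

## Classification model

**Three points per animal.** Each tracked ellipse is reduced to the
centre CE and the two terminal points at the major-axis ends,
$TP_{1,2} = CE \pm a(\cos\theta, \sin\theta)$. Because a fitted
orientation is only defined modulo 180°, `continuous_direction()` lifts
the per-frame orientation to a continuous series (each step bounded by
±90°), which both pins each terminal point to a consistent body end and
gives the inspection classifier a wrap-free angle series. The first
frame's labelling is arbitrary.

**Nodes.** `extract_nodes()` scans each of the three paths once: a
running node accepts the next point while it lies within `dis_th = 1.7`
px of the running centre (the mean of the members so far); a point beyond
the radius closes the node if it holds strictly more than `mn_th = 14`
members, otherwise the accumulated points are discarded; either way a new
node starts at the current point. The trailing points at the path's end
face the same membership test — without that, the terminal dwell directly
before settlement would be lost. Both thresholds are the published
operating values at 33 fps and 1280 × 960 px; at other magnifications
`dis_th` should scale with the body length. Streaming semantics (the
membership test uses the centre at insertion time) make the procedure
order-dependent by design; members are always temporally consecutive.

**Wide search** looks at centre-path nodes. For every window of four
consecutive step lengths $SL$ (distances between consecutive nodes), the
window flags its five nodes when $St/m < 0.2$ (standard deviation over
mean; R's sample standard deviation is used) and the maximum relative
deviation from the nominal step, $MC = \max |SL - 0.85\,CL| / (0.85\,CL)$,
is below 0.3. The body length $CL$ is estimated as twice the median
semi-major axis over the track — robust against merge frames where the
fitted ellipse inflates.

**Inspection** looks at terminal-path nodes: a node is inspection when
the body direction over its member span sweeps more than 30°, measured as
the minimal circular arc containing the sampled directions; the
comparison is strict, so a range of exactly 30° does not qualify.

**Close search** is a chain of brief inspection events: consecutive
inspection nodes (from both terminal paths merged in time order — the
attached end alternates between $TP_1$ and $TP_2$ across pivots) chain
when their centres lie closer than four nominal steps
($4 \times 0.85\,CL$) and each holds fewer members than
`inspection_member_cap_s` seconds' worth of frames (default 20 s, 660
members at 33 fps). The cap keeps genuine, minutes-long inspection bouts
out of close-search chains; it is deliberately a separate and much larger
threshold than the node-extraction `mn_th`, which would otherwise erase
nearly every inspection node from chaining. Chained nodes lose their
inspection weight, so the two labels never overlap.

**Temporal gate.** Both the step windows and the chain require
consecutive nodes to be separated by at most `max_step_gap_s = 2` s.
This gate is a package addition: the step and chain rules are otherwise
purely spatial, and a swimming excursion that happens to return near its
departure point would be bridged into walking or close search. Two
seconds comfortably covers real inter-node transit (a few frames) while
excluding swimming bouts.

**Ethogram.** Node-level weights map back to frame spans (a run of
wide-search nodes spans its whole stepped interval; an inspection node
its member span; a chain its first to last node). Precedence within a
frame is close search > inspection > wide search, and every unclaimed
frame is swimming — swimming is the exact complement of the other three.
Adjacent same-label spans merge into events; wide-search events report a
step count (nodes in the run minus one). Summaries per behaviour report
the event count, the total (steps for wide search, seconds otherwise) and
the average per event truncated toward zero, matching the published
convention in which 1949 s over 11 events averages 177 s and 45 s over 2
events averages 22 s.

## The synthetic generator

Laboratory videos are not available, so validation rests on
`generate_trajectory()` / `render_frames()`: behaviour-scripted motion of
elliptical animals rendered onto a bright arena with additive Gaussian
noise. Phase transitions occur exactly at scripted times, making the
frame-level ground truth unambiguous; a single integer seed fixes every
random draw, and identical seeds give bit-identical trajectory tables.
Rasterization is hard-thresholded (no anti-aliasing) so segment sizes are
deterministic; overlapping animals fuse naturally into one blob.

The motion models emulate the classifier's target phenomenology — ballistic
swimming much faster than walking; wide search as dwell–step–dwell with
near-constant steps of 0.85 CL; close search as short body pivots (60°
sweeps about one terminal point) linked by 1–2-step walks; inspection as
a pinned terminal point with sinusoidal body oscillation above the 30°
range. They do not emulate appendage-level animation, hydrodynamics,
illumination drift, shadows or animal shape change, so passing recovery
tests demonstrates the correctness of the pipeline's logic under its
stated assumptions, not robustness to every artefact of real footage.

Validation runs use a 160 × 120 px arena with 7 × 3 px semi-axes at
33 fps (`reference_arena()`): the full 1280 × 960 geometry scaled down
while preserving the body-size-to-step ratios the classifier depends on.
The scripted inspection phase lasts 25 s — longer than the 20 s member
cap, as real inspection bouts (averaging minutes) are. Crossing fixtures
(`crossing_sequence()`) randomize crossing angle (30–150°), approach
distance and speed; an exactly simultaneous coincidence of two identical
animals at a point is information-theoretically unresolvable without
motion prediction, which this tracker (like the original design)
deliberately does not do.

## Numerical choices and degenerate inputs

* Centroids and node centres are kept in double precision throughout;
  terminal-point geometry holds to 1e−9 relative tolerance.
* Ellipse fits reject < 5 pixels or moment matrices with smaller
  eigenvalue below 1e−9 (collinear input) via classed errors.
* Ties everywhere resolve deterministically: lowest id, lowest label,
  first candidate in documented order.
* A frame that fails segmentation is logged and skipped; all animals are
  carried as missed across it.
* `strict_mn` switches the node membership test between strictly greater
  (default, as implemented) and at-least; the published description does
  not disambiguate.
* Problem sizes in the test suite and acceptance script — 50 scripted
  runs of ≈ 45 s each and 100 crossing events — are the package's chosen
  validation conditions, small enough to run routinely while large enough
  that the recovery rates are stable across seeds.

## Known limitations

* Identity through crossings relies on body orientation and pixel
  continuity; near-coincident crossings at shallow angle difference can
  still swap identities (measured ≈ 5% of randomized crossing events).
* The tracker models no motion (no velocity prediction, no global
  smoothing, no appearance model), by design.
* `CL` estimation assumes the semi-major axis is stable over a track;
  tracks dominated by merged frames would bias it.
* The classifier's thresholds are the published operating point for one
  acquisition geometry; other magnifications or frame rates need `dis_th`,
  `mn_th` and `inspection_member_cap_s` revisited together.
* Settlement (permanent attachment) is not a fifth class; a settled
  animal simply ends its record in a long inspection event.
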