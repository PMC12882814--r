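---
title: "Quantifying perivascular dendritic-cell niches: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular dendritic-cell niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcniche)
```

# The problem

Activated conventional dendritic cells — the CCR7+ / LAMP3+ / mregDC state —
cluster around tumor blood vessels, where they are both the source of T-cell
stimulation and the target of regulatory T cell (Treg) suppression. Turning
that biology into numbers requires a chain of spatial statistics over three
kinds of data:

1. **segmented static imaging**: marker surfaces (FSCN1 for DCs, CD31 /
   LYVE-1 for vessels, Ccl19 / CCL21 for chemokine sources) and typed,
   point-located cell tables;
2. **spatial-transcriptomic cell maps**: typed cells on which graph
   neighborhoods and label-permutation enrichment are computed;
3. **time-lapse object tracks**: DC and Treg centroids with equivalent radii
   from intravital two-photon imaging.

`dcniche` implements that chain end to end — cluster detection, vessel
typing, niche assignment, neighborhood enrichment, proximity profiles,
contact dynamics, signature scoring — together with a synthetic-scene
generator that plants known structure so every stage can be validated
against ground truth without any imaging data.

# The rules, with their parameters

## DC cluster detection (2-D sections)

Detections below **5 μm²** are discarded (area ≥ 5 kept; "smaller than"
excludes strictly). A Delaunay triangulation is built on detection
centroids; edges longer than **22.5 μm** are cut; connected components
seed the clusters; any two clusters containing detections whose
border-to-border distance is strictly below **20 μm** are merged
transitively; clusters with total member area below **500 μm²** are
dropped. The transitive merge formalizes what is a manual curation step in
practice — a deterministic, order-independent rule was chosen so that the
same input always yields the same partition, and the test suite checks the
partition against a brute-force union-find pipeline.

## DC cluster detection (3-D volumetric)

Points linked at mutual distance ≤ **20 μm**; components with fewer than
**5** members removed; components wider than the **100 μm** maximum
diameter are split by repeatedly deleting the longest remaining
within-component link until all diameters comply. Iterative longest-link
removal was chosen over any seed-based splitting because it is
deterministic and does not depend on point order; exact ties are broken by
vertex index.

## Vessel typing and niche assignment

CD31+ surfaces are **blood vessels (BV)** when their overlap-area ratio to
LYVE-1+ surfaces is below **0.01%**, **lymphatic (LV)** at or above it
(the boundary value classifies as LV). Ccl19 coverage is any strictly
positive overlap. A DC farther than the association cutoff from every
vessel is non-vessel-associated; otherwise it takes the class of the
nearer of (closest BV, closest LV). The cutoff comparison is inclusive
(≤ cutoff qualifies, "more than 20 μm away" excludes). Three measurement
dialects are preset in `association_config()`:

| preset | cutoff | distance |
|---|---|---|
| `mouse` | 20 μm | border-to-border |
| `human_fast` | 50 μm | border-to-border |
| `human_multispectral` | 100 μm | centroid-to-centroid |

An exact distance tie within the cutoff assigns BV, deterministically.
Ties are measure-zero on continuous data; the fixed rule replaces a
visual-inspection resolution that cannot be reproduced. A cluster is
vessel-associated when at least **50%** of its member area lies within the
cutoff of that vessel class; dual qualification resolves to the larger
proximal area. A vessel is "cluster-associated" when the summed area of
DCs within 20 μm reaches **500 μm²** (inclusive).

## Neighborhood enrichment

The spatial graph is the Delaunay triangulation of the cell map with edges
above the **99th percentile** of edge lengths removed
(linear-interpolation percentile; edges strictly above the cutoff go).
Neighborhoods are **k cell layers** — graph balls of radius k hops,
excluding the index cell; k = 5 is the default analysis radius and k = 10
the tumor-region extension used when delimiting analysis areas.

`permutation_enrichment()` tests whether a target type is enriched around
a selected cell set: the observed statistic is the mean per-cell
neighborhood *density* (target count / neighborhood size) over selected
cells, normalized by the baseline density — the target fraction among
non-selected cells. The null is built by shuffling the labels of
**non-selected cells only** (**1000** permutations by default), keeping
the graph and the selected cells' labels fixed. Two choices here were
genuinely open and are worth stating:

* *Density* is per-cell ratio averaged over cells (mean of ratios), not
  pooled counts over pooled sizes; both are implemented and the choice is
  a parameter. Mean-of-ratios weights each selected cell equally, which
  matches "mean neighborhood densities" more naturally than
  size-weighting.
* The baseline uses non-selected cells only, matching the shuffling
  universe — the null then has the correct mean by construction.
* Cells with empty neighborhoods contribute density 0 rather than being
  dropped (configurable); dropping them changes the weighting of the
  observed and null statistics identically, so calibration is unaffected.
* The p-value uses the add-one estimator `(1 + #[null ≥ obs]) / (1 + B)`,
  which never returns 0 and is exact for the permutation null.

`pairwise_enrichment()` gives the per-(source, target) z-score matrix
against an all-label permutation null, optionally ignoring edges between
same-labelled cells ("without intra-cluster edges") so that a type's own
clustering cannot masquerade as enrichment. The observed statistic (mean
target count per source cell) is asymmetric; because label permutations
preserve class sizes, the z-scores of (A→B) and (B→A) agree up to Monte
Carlo noise — the analytic convention this mirrors is not published in
enough detail to assert more, and the implementation makes the permutation
null explicit rather than reproducing a closed form bit-for-bit.

`nh_sum()` / `group_composition()` compute the cell × neighborhood-type
count matrix (with its "all" column) and per-group composition ratios:
group sums normalized to the "all" sum with a **0.001** pseudocount, as a
ratio to the same frequency in all remaining cells, optionally
renormalized across groups for one display type.

## Proximity profiles

`nearest_by_type()` is the nearest-distance table (squared distances
internally, square root at the end; the index cell is never its own
nearest neighbor). The headline summaries use strict thresholds where the
source rules are phrased as "< r": a DC "has a nearby Treg" below
**50 μm**; a DC–CD8 niche is a DC with a CD8 cell within the contact
threshold, labelled Treg-proximal below **100 μm**; contact-site
distributions over vessel classes use the static **≤ 5 μm**
surface-distance rule.

## Track dynamics

Tracked objects are spheres (centroid + equivalent radius); the surface
distance at a frame is `max(0, centroid distance − r₁ − r₂)`. A contact
episode is a maximal run of consecutive co-observed frames with surface
distance strictly below **5 μm**; an episode of *n* frames lasts
*n* × the local frame interval (the object was observed in contact for
*n* sampling intervals — the convention is configurable since
frames-vs-intervals is not standardized). Missed detections break
episodes; an optional gap tolerance (default 0) can bridge them.
Cumulative interactions count, per DC over time, Tregs with
centroid-to-centroid distance strictly below **20 μm**; both the
per-frame partner count and the cumulative count of *episodes started*
are returned. Whether "cumulative interactions" should count Treg-frames
or distinct episodes is ambiguous in the field; episodes are the headline
because they are invariant to the frame rate, and the per-frame counts
allow the other convention to be derived. Track speed is total path
length over total elapsed time (μm/s), undefined for single-frame tracks.

## Signature scoring

A cell's score for a gene set is the mean expression of the signature
genes minus the mean of a control pool sampled per signature gene from
genes of comparable dataset-mean expression (**25** bins, **50** controls
per gene, capped at bin size). The binned-control scheme is the standard
single-cell scoring convention; the parameters are pinned defaults, not
published values. Scores above a bimodal-valley cutoff are positive
("above" is strict); **0.5** is the whole-panel dialect and **1.5** the
within-cDC dialect, and `find_score_valley()` offers a kernel-density
valley finder when the cutoff must be read off the data.

# What the synthetic generator emulates — and what it does not

`generate_scene()` builds 1000 × 1000 μm fields (default) with 8 blood
and 5 lymphatic vessels as capsules (segment + radius, radii 5–12 μm,
lengths 40–120 μm), LYVE-1 overlays on lymphatics, Ccl19 shells on half
the blood vessels, and DC detections as disks of 20–60 μm². Placement is
constraint-based: perivascular DCs sit at a border distance drawn inside
90% of the cutoff from their anchor vessel, non-associated DCs are
rejection-sampled to clear every vessel by cutoff + 10 μm, and vessels
keep enough mutual clearance that a planted DC is always nearest to its
anchor. The planted labels are therefore *geometrically consistent*, and
the association estimator recovers planted mixtures essentially exactly —
the ±0.05 validation band absorbs rounding, not placement noise.

`generate_tracks()` confines each DC's random walk to a private territory
on a grid and pins Tregs to their partner DC at half the contact
threshold during planted episodes, pushing them outside
threshold + margin otherwise; the planted episode set is recovered
exactly by construction. `generate_expression()` draws gene baselines
uniformly on the log scale and shifts signature genes by a configured
effect in a positive fraction of cells; with the default 20-gene
signature, noise 0.6–0.7 per gene yields the two score modes ~6 SD apart
that make threshold classification nearly error-free.

Passing tests on these scenes shows the *rules* are implemented correctly
and the estimators are calibrated. It does not show robustness to what
real tissue adds: segmentation errors, non-convex and touching surfaces,
density gradients, vessel branching, z-projection artifacts, tracking
identity switches, or expression count noise. The generator places cells
distributionally — there is no chemotaxis or mechanistic motility model —
so effect sizes measured on it say nothing about biological effect sizes.

# Numerical choices

* Polygon areas and centroids use the shoelace formula; overlap areas use
  exact convex clipping (Sutherland–Hodgman) after ear-clipping
  triangulation, with union areas by inclusion–exclusion recursion —
  exact up to floating point, no rasterization.
* Border distances are vertex-to-edge minima with explicit containment
  and edge-crossing tests for the overlap-zero case; bulk paths prune
  with centroid ± circumradius bounds before exact evaluation.
* The Delaunay triangulation is Bowyer–Watson with *ghost triangles* and
  a symbolic vertex at infinity: the in-circle predicate for hull-adjacent
  cases degenerates to an orientation test on real coordinates, so no
  large synthetic coordinates enter the arithmetic (a finite super-triangle
  demonstrably mis-triangulates near the hull). Near-cocircular quadruples
  resolve by determinant sign — an arbitrary valid member of the Delaunay
  family, as in any floating-point implementation.
* Coincident cell coordinates are de-duplicated stably; duplicates attach
  to their representative with zero-length edges and are reported in the
  graph's `duplicate_map` attribute. All-collinear inputs yield the chain
  along the line; fewer than three points yield the complete graph.
* All stochastic entry points take explicit seeds, draw from a local RNG
  scope and restore the caller's RNG state; identical configuration +
  seed reproduces results byte-for-byte, including written files.

# Validation scales

The shipped validation (test suite and `scripts/acceptance.R`) runs the
clustering oracle on 50 scenes of up to 300 detections, the Delaunay
oracle on 200 point sets of up to 50 points, enrichment calibration on
500 replicates of 200 cells with 1000 permutations each, association
recovery on planted fractions 0.2/0.5/0.8 at 1000 DCs over 20 seeds,
exact recovery of 500 planted contact episodes, and the bimodal
classifier at 5000 cells. These sizes were chosen so the whole suite
completes in a few minutes on one CPU while every statistical check
retains enough replicates for its stated tolerance.

# Known limitations

* Surfaces are 2-D simple polygons; genuinely 3-D surface meshes are out
  of scope (tracks carry z, static geometry does not).
* Non-simple (self-intersecting) polygons are not detected up front;
  geometric results on them are undefined.
* The pairwise enrichment matrix is a permutation analogue of an
  analytically-normalized method; z-scores are comparable within one
  analysis, not across tools.
* Vessel subtypes (arterial / venous / capillary) are consumed as input
  columns when supplied; no marker-based subtype inference is attempted.
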