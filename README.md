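# dcniche

Spatial quantification of activated (CCR7+) dendritic-cell niches in tumor
tissue, from segmented imaging, spatial-transcriptomic cell maps, and
time-lapse object tracks.

Tumor CCR7+ DCs (a.k.a. LAMP3+ / mregDCs) form clusters around blood
vessels, where regulatory T cells contact and suppress them. `dcniche`
implements the quantitative layer of that biology as a tested, reusable R
pipeline:

* **DC cluster detection** — Delaunay triangulation on detection centroids
  (edge cut 22.5 μm), transitive border-to-border merging (< 20 μm), and a
  500 μm² minimum-area filter; plus the 3-D fixed-radius rule (≥ 5 DCs
  within ≤ 20 μm, 100 μm maximum diameter).
* **Vessel typing & niche assignment** — blood vs lymphatic vessels by the
  LYVE-1 overlap-area ratio (0.01% rule), Ccl19-coverage flags, and per-DC /
  per-cluster association with the nearer vessel class within a cutoff
  (20 μm mouse; 50 μm border / 100 μm centroid human dialects).
* **Neighborhood statistics** — k-cell-layer graph neighborhoods on
  percentile-pruned Delaunay graphs, label-permutation enrichment of a
  target type around selected cells (score = mean neighborhood density /
  baseline density, 1000 permutations), pairwise enrichment z-scores
  without intra-cluster edges, and cell × neighborhood composition ratios
  with a 0.001 pseudocount.
* **Proximity profiles** — nearest-distance tables by cell type, nearby-
  neighbor fractions (< 50 μm), DC–CD8 niche Treg status (< 100 μm), and
  contact-site distributions over vessel classes (≤ 5 μm).
* **Track dynamics** — DC–Treg contact episodes (surface distance < 5 μm,
  duration = run length × frame interval), cumulative interaction curves
  (< 20 μm), and track speeds.
* **Signature scoring** — per-cell gene-set scores against expression-
  binned control genes (25 bins, 50 controls/gene) with bimodal-threshold
  classification (0.5 / 1.5 dialects) and an automatic valley finder.
* **Synthetic scenes** — generators for tissue scenes, expression matrices
  and tracks with *planted, geometrically consistent* ground truth, so
  every stage is validated against known answers.

The enrichment score for target type *t* around selected cells *S* on
spatial graph *G* is

```
score = mean_{i in S} [ #targets in N_k(i) / |N_k(i)| ]  /  baseline
```

where `N_k(i)` is the k-layer graph neighborhood of cell *i* (excluding
*i*) and `baseline` is the fraction of target cells among non-selected
cells; the null distribution shuffles non-selected labels only, and
`p = (1 + #[null ≥ observed]) / (1 + n_perm)`.

## Worked example

```r
library(dcniche)

scene <- generate_scene(scene_config(n_dc = 300, n_treg = 150, n_other = 600,
                                     perivascular_fraction = 0.4, seed = 17))

vessels <- classify_vessels(scene$surfaces$cd31, scene$surfaces$lyve1)
vessels <- ccl19_coverage(vessels, scene$surfaces$ccl19)
table(vessels$class)
#> BV LV
#>  8  5

det   <- filter_detections(scene$detections)       # drop areas < 5 um^2
assoc <- associate_cells(det, vessels)             # 20 um border rule
round(prop.table(table(assoc$label)), 3)
#>   BV none
#>  0.4  0.6
```

The estimated BV-associated fraction (0.4) recovers the planted
`perivascular_fraction` exactly: the generator places perivascular DCs
within the cutoff of their anchor vessel and all others beyond it.

```r
clusters <- associate_clusters(delaunay_cluster(det), det, vessels)
clusters[, c("cluster_id", "n_members", "total_area_um2", "association")]
#>   cluster_id n_members total_area_um2 association
#> 1        cl1        15       617.5122          BV
#> 2        cl2        15       625.2493          BV

g   <- prune_percentile(delaunay_graph(scene$cells), 99)
sel <- scene$cells$cell_id[scene$cells$cell_type == "DC"]
enr <- permutation_enrichment(scene$cells, g, sel, "Treg", k = 5,
                              n_perm = 1000, seed = 17)
sprintf("Treg enrichment around DCs: score %.3f, p = %.4f", enr$score, enr$p_value)
#> "Treg enrichment around DCs: score 0.705, p = 0.7822"
```

Two of the planted perivascular groups are dense enough to pass the
500 μm² cluster filter, and both associate with blood vessels. Tregs are
placed uniformly in this scene, so their enrichment around DCs is
compatible with the null (score near 1, large p).

```r
ep <- data.frame(dc_id = "dc1", treg_id = "treg1", start_frame = 3, end_frame = 8)
tracks <- generate_tracks(track_config(n_dc_tracks = 4, n_treg_tracks = 6,
                                       n_frames = 40, planted_episodes = ep,
                                       seed = 17))
detect_contacts(tracks)
#>   dc_id treg_id start_frame end_frame n_frames duration_min
#> 1   dc1   treg1           3         8        6            9
```

The single planted contact episode (6 frames at 90 s) is recovered with
its 9-minute duration and no false episodes.

`run_pipeline()` wires the stages into three workflows (`niche`,
`enrichment`, `tracks`) from a YAML/JSON/list configuration and writes
tidy CSV/JSON outputs plus a provenance record; identical configuration
and seed reproduce outputs byte-for-byte.

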