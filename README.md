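# osteoconnect

Segmentation and connectomics of osteocyte networks in 2D confocal
microscopy images.

Osteocytes — the most abundant bone cells — communicate through
thousands of thin dendritic processes running through canaliculi in the
mineralised matrix. This lacunocanalicular network degenerates with age
and in genetic models of bone disease, but quantifying it from confocal
scans is notoriously laborious: the processes are only 1.5–3 px wide at
a typical 150 nm/px resolution. `osteoconnect` is for bone biologists
and image analysts who want a reproducible, scriptable 2D pipeline from
raw greyscale scans to per-image network statistics and group
comparisons.

The package provides:

* **Threshold segmentation** into background / osteocyte / dendrite:
  Gaussian smoothing (σ = 2 px), a manual intensity split at 70
  (0–255), an Otsu- or Canny-based core step
  (Canny hysteresis 70/220; Otsu clamped at 80), 3×3 morphological
  closing of the dendrite mask, and elementwise subtraction of
  overlaps (osteocyte wins).
* **Connectomics**: classes dilated (4×4 discrete ellipse for
  osteocytes, 2×2 cross for dendrites), connected components, and a
  graph with osteocytes as nodes and dendrite components as
  connections. A component touching two or more osteocytes links them
  pairwise; one contact is a *dead end*; routes via intermediate
  osteocytes are never counted. Connection lengths follow the 1-px
  skeleton (diagonal steps √2) between contact points; diameters come
  from the distance transform sampled on the skeleton
  (2·mean EDT − 0.5 px).
* **Evaluation**: per-class Dice `2|P∩G|/(|P|+|G|)` and
  IoU `|P∩G|/|P∪G|`, mean IoU, overall foreground Dice, with per-image
  and pooled batch reductions.
* **Dendrite regularisation utilities**: the inverse component-size
  penalty `λ · Σ_c 1/|c|` (merging fragments strictly lowers it) and
  2×2/3×3 label dilation.
* **Group comparison**: two-sided Mann–Whitney U (exact for combined
  n ≤ 20 without ties), significance stars, and the
  percentage-change protocol (positive = decrease vs reference).
* A **seeded synthetic-scene generator** with ground-truth masks and
  graphs, including young/aged cohort presets (aged: osteocyte density
  −38.03 %, connectivity −43.3 %, more and shorter dead ends), so the
  whole chain is testable offline. No public labelled dataset of
  osteocyte confocal scans exists; all shipped validation runs on these
  synthetic scenes.

See `vignettes/osteoconnect-methods.Rmd` for the full model
description, parameter rationale and limitations.

## Worked example

```r
library(osteoconnect)

# a synthetic "young" scan: 500x500 px at 150 nm/px
scene <- simulate_scene(young_scene_params(seed = 42))
scene$graph
#> <ground_truth_graph> 11 nodes, 23 edges, 258 dead ends

# segment with the Otsu-cored pipeline and score it against the truth
seg <- segment_image(scene$image, segmentation_params("otsu"))
evaluate_segmentation(seg, scene$mask)
#> <seg_metrics>
#>   dice: osteocyte=0.844  dendrite=0.648
#>   iou:  osteocyte=0.730  dendrite=0.479
#>   mean_iou=0.604  dice_overall=0.734

# connectomics of the *predicted* mask
g <- build_graph(seg, pixel_size_nm = 150)
compute_metrics(g)
#> <connectomics_metrics>
#>   n_nodes: 13
#>   deadends_per_node: 0
#>   connections_per_node: 12
#>   mean_connection_length_um: 57.33
#>   mean_connection_diameter_um: 1.096
#>   mean_network_diameter_um: 0.3425
```

The osteocyte class segments well (Dice 0.84) while the thin dendrites
are much harder (0.65) — the expected ordering for structures at the
diffraction limit. On this crowded prediction the dendrite fragments
merge into few large components, which inflates connections and removes
dead ends relative to the ground truth; the sparse validation preset
(`sparse_scene_params()`), where structures are well separated, recovers
the generated graph exactly.

Group comparison on ground-truth cohorts (30 images per group):

```r
cohort <- generate_cohort(n_per_group = 30, seed = 1, render = FALSE)
cmp <- compare_cohorts(
  lapply(cohort$group_a, function(s) graph_metrics(s$graph)),
  lapply(cohort$group_b, function(s) graph_metrics(s$graph)),
  c("n_nodes", "connections_per_node"))
cmp[, c("metric", "mean_a", "mean_b", "p_value", "stars",
        "percent_change")]
#>                 metric mean_a mean_b  p_value stars percent_change
#> 1              n_nodes   7.13  4.200 6.85e-06  ****           41.1
#> 2 connections_per_node   2.64  0.868 3.47e-07  ****           67.1
```

The aged preset loses ~41 % of its osteocytes and ~67 % of its
connectivity per node (the density drop mirrors the preset's −38 %
parameter; the connectivity drop compounds the density and
connection-probability decreases), both highly significant by
Mann–Whitney U.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","osteoconnect",package="osteoconnect"))')
Rscript $CLI simulate --config scene.yaml --out scenes --seed 3 --n 10
Rscript $CLI segment --method otsu scenes/scene_001_image.png pred.png
Rscript $CLI metrics pred.png scenes/scene_001_mask.png --csv metrics.csv
Rscript $CLI connectome pred.png --graph out.graphml --csv network.csv
Rscript $CLI compare group_a.csv group_b.csv --out comparison.csv
Rscript $CLI run --config pipeline.yaml
```

Every artefact of `run` is listed in a manifest with MD5 checksums and
accompanied by a JSON provenance sidecar; identical configs and seeds
reproduce every file byte for byte.

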