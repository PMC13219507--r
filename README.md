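# actionclouds

Tools for asking a simple question about action perception: **do the
visual features that distinguish short action videos predict how well an
observer tells those actions apart?** The package implements the full
analysis chain for three manual action categories — grasping (approach,
contact and enclosure of an object), touching (approach and contact) and
reaching (approach only) — from pixel-level video features to a
permutation-tested link with three-alternative categorization behavior.
A seeded synthetic-scene generator stands in for the original stimuli and
behavioral sessions, so every stage runs end to end with no external data.

## What it computes

**Dynamic feature point clouds.** Per-frame features are extracted from
grayscale clips (normalized to 180 × 160 px at 30 Hz) within nested
body-part masks (hand ⊆ hand-and-arm ⊆ agent, plus the two complements):
luminance and contrast; histograms of oriented gradients (9 unsigned bins,
8 × 8 px cells, 2 × 2-cell blocks); Canny edges; the silhouette, its size
and its seven Hu moment invariants; dense optical flow with flow
histograms (HOF), motion energy and silhouette-center kinematics. Each
feature's per-frame values are pooled along the temporal axis with an
explicit frame-index column, giving one N × D point cloud per video,
feature and mask.

**Chamfer distance.** Two videos are compared per feature with the
bidirectional mean squared nearest-neighbour distance

    CD(M, N) = 1/|M| Σ_m min_n ‖m − n‖² + 1/|N| Σ_n min_m ‖n − m‖² ,

computed either brute-force or with a blocked reduction whose temporary
memory stays O(block²) regardless of cloud size. For each test the three
category pairs give a feature distance triplet (grasp–touch, grasp–reach,
touch–reach).

**Behavior distance.** Trial tables become row-stochastic confusion
matrices; each session is classified as G-T-R (all three categories
generalized), G-TR (grasp only, touch and reach collapsing onto one shared
target) or GTR (failure), using one-tailed binomial z-tests against chance
(1/3) and a >50% shared-target rule. Matrices are bias-adjusted per
pattern, and each category pair is reduced to a 2 × 2 table whose
`sensitivity + specificity − 1` (Youden's J) forms the behavior distance
triplet.

**Multimodal correlation.** Triplets are pooled across tests into distance
vectors, compared by cosine similarity, and tested by permuting the
behavioral index values (10,000 shuffles by default); the null mean is the
baseline similarity and the p-value is the fraction of permuted
similarities above the observed one.

## Worked example

```r
library(actionclouds)

scene  <- scene_config(n_frames = 12)          # 180x160 px, 30 Hz scene
videos <- lapply(setNames(nm = action_categories()),
                 generate_action_video, config = scene)
clouds <- lapply(videos, function(v)
  extract_feature_cloud(v$clip, v$masks$hand, "hog", "hand"))
clouds$grasp
#> <feature_cloud hog|hand: 56 points x 12 dims>

feature_distance_triplet(clouds, test_id = 1)
#>   test_id feature mask        pair     value
#> 1       1     hog hand grasp-touch  75.26825
#> 2       1     hog hand grasp-reach 136.18304
#> 3       1     hog hand touch-reach  11.39565
```

The hand-mask HOG clouds separate grasping from the two other categories
far more than they separate touching from reaching — exactly the structure
a grasp-only observer shows behaviorally:

```r
tt <- generate_behavior_trials("G-TR", 300, default_target_map("M1"), seed = 7)
cm <- build_confusion(tt)
classify_performance_pattern(cm)
#> [1] "G-TR"
behavior_distance_triplet(cm, test_id = 1)
#>   test_id        pair     value
#> 1       1 grasp-touch 0.9580420
#> 2       1 grasp-reach 0.9513889
#> 3       1 touch-reach 0.0000000
```

Pooled over a battery of tests, `correlate_all()` (or `run_pipeline()`)
relates the two sides. The `analysis/` scripts run the whole study on a
simulated nine-test battery:

```sh
Rscript analysis/01_simulate.R          # videos + masks + trial tables
Rscript analysis/02_extract_features.R  # feature point clouds
Rscript analysis/03_distances.R         # chamfer triplets  -> results/distances.csv
Rscript analysis/04_behavior.R          # Youden triplets   -> results/behavior.json
Rscript analysis/05_correlate.R         # permutation tests -> results/results.csv
```

On this battery the action-component features within the hand mask (HOG,
HOF, Hu moments, silhouette size) correlate with behavior at cosine
similarities around 0.85 against a ~0.68 permutation baseline (p ≈ 0.001),
while full-frame contrast does not (p ≈ 0.31).

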