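# tissueseg

Volumetric instance segmentation of densely packed cells in membrane-stained
microscopy volumes, in two steps:

1. **Boundary detection.** A compact 3D (or 2D) U-Net — plain or residual,
   batch or group normalization, trained with a combined binary
   cross-entropy + Dice loss `L = α·L_BCE + β·L_Dice` (α = β = 1 by
   default) — predicts a per-voxel boundary probability map `p(x) ∈ [0,1]`.
2. **Graph partitioning.** The map is thresholded at δ = 0.4; a watershed
   seeded at the regional maxima of the Gaussian-smoothed (σ = 2) distance
   transform produces supervoxels (regions < 50 voxels are absorbed by their
   largest-contact neighbor). A region adjacency graph is built on the
   supervoxels, each edge carrying the mean boundary probability `p_e` over
   its interface; the signed weight
   `w_e = log((1−p_e)/p_e) + log((1−β)/β)`, with splitting bias β = 0.6,
   feeds one of three partitioners — GASP (average linkage agglomeration),
   the mutex watershed, or greedy multicut (minimizing `Σ_{e cut} w_e`,
   with an exact enumeration oracle for small graphs). The partition is
   projected back to the voxel grid as the final cell labeling.

Everything needed to develop and test the pipeline without microscopy data
is included: a synthetic Voronoi tissue generator (ground-truth labels,
binary boundary targets, noisy membrane images, boundary drop-outs), the
standard evaluation metrics (adjusted Rand error `1 − AdjRand`, variation
of information split/merge `H(seg|GT) + H(GT|seg)`, boundary
precision/recall/F1 curves, PSNR, SSIM), HDF5/TIFF I/O, and a YAML-driven
pipeline runner with a command-line interface.

The package is aimed at developmental biologists and image analysts who
need per-cell geometry from 3D stacks with stained cell contours (plant
organs being the motivating case), and at method developers who want a
small, fully scriptable reference implementation of the
boundary-CNN + graph-partitioning recipe.

## Worked example

Segment a synthetic 64³ tissue of 20 cells whose boundary map has been
corrupted with 5% membrane drop-outs and Gaussian noise (sd 0.1):

```r
library(tissueseg)

cfg <- tissue_sim_config(shape = c(64, 64, 64), n_cells = 20,
                         membrane_sigma = 0, noise_gaussian_sd = 0.1,
                         gap_fraction = 0.05, rng_seed = 42)
labels <- generate_voronoi_labels(cfg)           # ground truth
target <- labels_to_boundary_target(labels, sigma = 1.0)
bmap   <- corrupt_boundary_map(target, cfg)      # stand-in for a CNN map

sv  <- dt_watershed(bmap, watershed_params())    # delta 0.4, sigma 2, min 50
rag <- build_rag(sv, bmap)
seg <- project_partition(sv, gasp_average(rag, beta_bias = 0.6))

segmentation_scores(seg, labels)                 # GASP result
#>        arand voi_split voi_merge
#> 1 0.03442885 0.1138184 0.1222745
segmentation_scores(sv, labels)                  # DT watershed baseline
#>       arand voi_split voi_merge
#> 1 0.1585988 0.4942876 0.1199171
```

The watershed alone over-segments (43 supervoxels for 20 cells, split
error 0.49); partitioning the 43-node / 188-edge adjacency graph merges the
fragments and recovers exactly 20 segments with an adjusted Rand error of
0.034. `mutex_watershed()` and `multicut_greedy()` are drop-in
replacements for `gasp_average()`; a trained network
(`build_network()`, `train_boundary_cnn()`, `predict_tiled()`) replaces
the simulated boundary map on real data.

The same pipeline is scriptable from the shell:

```sh
tissueseg synth --shape 64,64,64 --n-cells 20 --seed 42 --out tissue.h5
tissueseg segment --input tissue.h5 --dataset boundary --algorithm gasp \
                  --out segmentation.h5
tissueseg evaluate --seg segmentation.h5 --gt tissue.h5 --out scores.csv
```

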