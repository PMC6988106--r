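# atrialscar

Fully automatic quantification of left atrial (LA) scar from late
gadolinium enhancement (LGE) MRI, for cardiac image-analysis researchers
studying atrial fibrillation ablation. Instead of segmenting scar in the
voxel grid — hopeless when the atrial wall is ~2 mm thin, neighbouring
structures enhance as brightly as scar, and the automatic LA segmentation
is off by millimetres — the method classifies each node of the
endocardial **surface mesh**:

- the LA cavity segmentation is triangulated (marching tetrahedra on the
  0.5 iso-surface) into the graph `G = {X, N}`: mesh vertices are nodes,
  mesh edges the neighbourhood system;
- each node carries elongated multi-scale intensity patches sampled along
  its outward normal (default 13 × 13 × 17 samples, three scales with
  doubling step);
- a unary CNN predicts the per-node scar probability `L̂ᵢ` and a siamese
  pairwise CNN predicts the label similarity `M̂ᵢⱼ` of adjacent nodes from
  the similarity map `Gᵢⱼ = FᵢFⱼ + (1−Fᵢ)(1−Fⱼ)` of their patch features
  plus their geodesic distance;
- the labeling minimizing the submodular energy

  `E(l) = Σᵢ Wᵢᵗ(lᵢ) + λ Σ₍ᵢⱼ₎ M̂ᵢⱼ·[lᵢ ≠ lⱼ]`,

  with `Wᵢᵗ(1) = 1 − L̂ᵢ`, `Wᵢᵗ(0) = L̂ᵢ` and λ = 0.4 by default, is found
  exactly by max-flow/min-cut.

Training draws a random shift `γ ~ U(−R, +R)` (R = 8 mm) along each
node's normal when extracting its patches, so the classifier tolerates
imperfect automatic LA segmentation. Balanced node sampling (all scar +
boundary nodes, equally many background nodes) handles class imbalance.

The package also provides a synthetic LGE phantom generator with full
ground truth (cavity, wall, connected scar patches, enhanced confounders
abutting the wall, bias field, noise, and a smoothly perturbed "automatic"
segmentation), the four classical baselines (2SD and Otsu thresholding,
multi-component Gaussian mixtures with and without voxel graph-cuts),
surface-node metrics (scar Dice, generalized Dice, accuracy, sensitivity,
specificity) and a seeded end-to-end experiment pipeline with parameter
studies.

## Worked example

A complete experiment at reduced scale (34-voxel phantoms, two patch
scales, converged short training; a few minutes on one CPU):

```r
library(atrialscar)

cfg <- experiment_config(
  n_train = 2, n_test = 1,
  phantom = list(grid_shape = c(34, 34, 34), cavity_radius_mm = 9,
                 cavity_irregularity = 1.5, n_scar_patches = 3,
                 scar_area_fraction = 0.25, noise_sigma = 3,
                 seg_error_mm = 1),
  msp  = msp_config(dims = c(5, 5, 17), n_scales = 2, shift_R_mm = 8),
  arch = net_config(channels = c(6, 12), d_feat = 16, hidden = 16),
  train_t = train_config(epochs = 25, lr = 0.05),
  train_n = train_config(epochs = 8, lr = 0.02),
  max_train_nodes = 600, max_train_edges = 500,
  lambda = 0.4, seed = 41)

res <- run_pipeline(cfg)
res$per_case[, c("method", "dice_scar", "gdice", "accuracy")]
#>    method dice_scar gdice accuracy
#> 1 learngc   0.89906 0.946    0.946
#> 2     2sd   0.00738 0.711    0.711
#> 3    otsu   0.88191 0.922    0.922
#> 4    mgmm   0.51588 0.456    0.456
#> 5 mgmm_gc   0.88133 0.922    0.922
```

Each row scores one test case on its evaluation surface: `learngc` is
the full learned graph-cuts method on the automatic-segmentation
surface; baselines run in a 3 mm dilated wall mask of the manual
segmentation and are scored on that surface. `dice_scar` is the
node-level Dice of the scar class; `gdice` weights both classes. The
2SD rule collapses here because the dilated wall mask mixes wall, scar,
confounder and background intensities, inflating its threshold; Otsu
separates the bimodal histogram well but mislabels the wall segments
next to the enhanced aorta/RA-wall analogues, which is exactly the
failure mode that motivates learned potentials.

Single stages are exported too — `make_phantom()`,
`extract_surface()`, `project_labels()`, `extract_msp()`,
`train_t_net()`, `classify_scars()`, `threshold_otsu()`,
`surface_metrics()`, … — see the help pages and the methods vignette
(`vignettes/methods.Rmd`).

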