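# spinereg

Coarse-to-fine rigid registration of cross-source spinal surface point
clouds, for surgical-navigation research: aligning a pre-operative
CT-derived surface of the spine with an intra-operative scan of the
surgically exposed anatomy. The two clouds differ in sensor, point
density and initial pose (per-axis rotations up to ±170°, translations
beyond 100 mm), and share only a tiny patch — overlap ratios of 1–4 %.

## Method

The coarse stage is a learned point-matching algorithm built on
surface-variation curvature:

1. **Curvature feature.** Each point carries
   σ = λ₃ / (λ₁ + λ₂ + λ₃), the eigenvalue ratio of its 5 mm
   neighborhood covariance — zero on planes, up to 1/3 for isotropic
   neighborhoods, invariant under rigid motion.
2. **Matcher.** A hierarchical set-abstraction encoder (three SA
   layers + one feature-propagation layer, fed rotation-invariant
   local geometry plus curvature) produces keypoint descriptors;
   self/cross graph attention conditions each cloud on the other; a
   temperature-scaled softmax over descriptor similarities,
   φ = softmax(f̂_X f̂_Yᵀ / T), yields matching distributions, reduced
   to mutual-argmax correspondences. Training minimizes the symmetric
   negative log-likelihood of ground-truth correspondences with Adam.
3. **Region traversal.** The pre-operative cloud is decomposed into 25
   farthest-point-sampled local regions; the intra-operative cloud is
   matched against each, a pose is estimated per region by RANSAC, and
   the best region supplies the coarse transform (by rotation error
   against ground truth in the evaluation protocol, by inlier
   consensus in blind deployment mode).
4. **Refinement.** Point-to-point ICP (robust, Welsch-weighted, with a
   final symmetric-correspondence polish) aligns the full clouds from
   the coarse pose.

Accuracy is measured as e_r = arccos((tr ΔR − 1)/2) and e_t = ‖Δt‖
for ΔT = T T_G⁻¹ against the ground-truth transform T_G.

A parametric vertebra-phantom generator (`make_phantom()`,
`make_pair()`) produces registration pairs with exact ground truth —
blade-like spinous process, tip tubercles, mm-scale surface relief,
independent cross-source sampling, calibrated 1.3–4.3 % overlap,
large random poses, optional Gaussian noise — so training, evaluation
and the noise-robustness sweep run end-to-end with no external data.
See the methods vignette (`vignettes/registration-methods.Rmd`) for
models, assumptions and design choices.

## Worked example

```r
library(spinereg)

# a registration pair with known ground truth
pair <- make_pair(pair_spec(n_preop = 16384, density_ratio = 2, seed = 42))
pair
#> <synthetic_pair> preop 16384 pts, intraop 622 pts, overlap 1.82 %, noise 0.00 mm

# train the matcher on a handful of pairs (reduced-scale protocol)
train_pairs <- lapply(1:12, function(i)
  make_pair(pair_spec(n_preop = 16384, density_ratio = 2, seed = 400 + i)))
model <- train_matcher(training_pairs_from_synthetic(train_pairs),
                       encoder_config(),
                       training_config(epochs = 20, batch_size = 2,
                                       learning_rate = 1e-2,
                                       temperature_init = 0.1,
                                       correspondence_radius = 2.5,
                                       seed = 11))

# register: coarse region search + RANSAC, then ICP refinement
res <- register_clouds(pair$preop, pair$intraop, model,
                       mode = "oracle", T_G = pair$ground_truth)
res
#> <registration_result> mode=oracle region=2
#>   coarse: e_r = 9.741 deg, e_t = 5.354 mm
#>   fine:   e_r = 1.678 deg, e_t = 0.892 mm
```

The coarse stage recovers the pose of a ~2 %-overlap patch from an
arbitrary initial pose to within ten degrees and a few millimetres;
ICP then refines toward the sampling-resolution floor of the surfaces
(averaged over many pairs, fine errors land well under a degree and a
quarter of a millimetre). `run_experiment()` and
`noise_sweep()` aggregate such registrations into error tables and
per-noise-level summaries; `cumulative_distribution()` produces
empirical CDF curves of errors and runtimes.

A thin command-line front end over the same functions lives at
`inst/cli/spinereg.R` (subcommands `simulate`, `curvature`, `regions`,
`register`), reading and writing PLY/PCD/XYZ clouds and plain-text
4×4 transforms.

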