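# facevalence

Decoding emotional valence from mouse facial expressions.

Head-fixed mice make stimulus-specific facial movements: appetitive
tastants (sucrose, low-salt) and aversive events (bitter quinine, tail
shock) move the ears, mouth, snout and whiskers in opposite,
valence-consistent directions, while the pupil dilates under any arousing
stimulus. `facevalence` is a tested R implementation of a complete
analysis framework for this setting, aimed at behavioral neuroscientists
who work with side-view face video, pose-estimation keypoint tables and
fiber-photometry recordings:

* **Appearance descriptors** — histogram-of-oriented-gradients (HOG)
  frame vectors (8 unsigned orientation bins, 16 × 16 px cells at the
  1024-px reference input, per-cell L2 normalization), frame-to-frame
  motion energy, apex-frame selection, and a PCA → 2-D neighbor embedding
  → k-means view of expression space.
* **Valence prototypes** — per-stimulus subprototype frames chosen to be
  maximally typical of their stimulus and maximally different from the
  neutral baseline, averaged into a positive and a negative prototype
  vector; any frame stream is then scored by cosine similarity
  `cos(a,b) = a·b / (‖a‖‖b‖)` to each prototype, giving similarity
  timecourses, cumulative similarities and drug-session valence indices.
* **Coregistration** — six-landmark least-squares affine alignment with a
  similarity-transform refinement, frame warping, and red/cyan overlay QC,
  so prototypes transfer across animals.
* **Facial kinematics** — confidence filtering (< 0.9 discarded and
  linearly interpolated) and 5-frame median smoothing of 37-keypoint
  tracks (8 pupil, 4 eye, 5 ear, 5 nose, 3 mouth, 12 whisker points); ten
  geometric features (ear angle/length/width/fold, mouth inclination,
  snout–mouth length, nose extension, whisker angle, pupil size, eye
  opening); baseline-relative proportional changes with nearest-water
  correction; keypoint PCA and response latencies.
* **Learned decoders** — a compact residual frame classifier with
  trial-level splits and a label-shuffle chance control, a Siamese
  contrastive embedding trained with the cross-mouse pair strategy
  (same-valence pairs from different mice, different-valence pairs from
  the same mouse) under the margin loss
  `L = 1/(2N) Σ [ yᵢ dᵢ² + (1−yᵢ) max(m−dᵢ, 0)² ]`,
  gradient-weighted class-activation maps (class and similarity
  variants), occlusion-sensitivity analysis with per-region retraining,
  and an LSTM decoder of 200-dimensional keypoint trajectory windows
  (25 timepoints × 4 keypoints × x/y).
* **Fiber photometry** — asymmetric penalized-least-squares (airPLS)
  photobleaching correction, 410 nm isosbestic motion correction by
  least-squares regression, ΔF/F = (signal − fitted control)/fitted
  control, peristimulus averages with 4 s baselines, water-normalized
  peak ratios, and permutation-tested Spearman correlations between
  neural signal and facial valence similarity.
* **Synthetic cohorts** — a fully seeded generator that renders schematic
  mouse faces with controllable valence-dependent geometry, keypoint
  ground truth, event tables and dual-channel photometry traces, so every
  stage above is testable end to end without any recordings.

## A worked example

```r
library(facevalence)

# a small synthetic cohort: 3 mice, 2 trials per stimulus, 30 fps
spec   <- cohort_spec(n_mice = 3, trials_per_stimulus = 2,
                      frame_size = 128, seed = 11)
cohort <- build_cohort(spec, valence_effects())  # with keypoint tracks

# valence prototypes from the designated prototype mouse (m01),
# scored on a held-out mouse's sucrose trial
proto <- cohort_prototype(cohort, k = 5, canvas = 64)
trial <- Filter(function(tr) tr$mouse_id == "m02" &&
                  tr$stimulus == "sucrose", cohort_trials(cohort))[[1]]
idx    <- trial_window_frames(trial, c(0.5, 2))
frames <- lapply(render_trial(trial, idx[seq(1, length(idx), 5)], 128),
                 resize_image, side = 64)
tc <- score_stream(hog_matrix(frames, hog_config(64)), proto)
summary(tc$diff)
#>   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.1171  0.1195  0.1269  0.1251  0.1299  0.1321
```

Every `diff` value is positive: throughout the stimulus window this
(held-out) sucrose trial resembles the positive prototype more than the
negative one. Shock trials give the mirror image (negative `diff`), which
is the prototype-similarity readout the drug and photometry analyses
build on.

The ten-feature geometry battery on the same cohort:

```r
kin <- cohort_kinematics(cohort)
kin$sign_by_stimulus$ear_angle
#>  bitter    nacl   shock sucrose
#>      -1       1      -1       1
```

Water-corrected ear-angle changes share a sign within each valence and
flip between valences — the patterned kinematics that make the ear the
most informative facial region.

An end-to-end run of all stages (synthesis, registration, HOG,
prototypes, kinematics, decoders, photometry, report):

```r
run_pipeline(list(out_dir = tempfile("fv_")))
```

A thin command-line wrapper over the same function ships at
`inst/cli/facevalence.R`.

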