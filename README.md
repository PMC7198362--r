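# bstemseg

Segmentation of internal brainstem structures from MP2RAGE-derived MRI
images, for neuroimaging researchers who need subject-level probabilistic
maps of brainstem tissue types (gray-matter nuclei, white-matter tracts,
the CSF/tissue boundary) without an anatomical atlas of those structures.

The MP2RAGE sequence yields two co-registered images per subject: a
bias-reduced T1-weighted image (UNI; white matter bright, CSF dark) and a
quantitative T1 relaxation map (T1 map; the opposite ordering). `bstemseg`
implements a complete pipeline on top of them:

1. **Anchored linear rescaling.** With `wm` and `csf` the intensity
   histogram modes of high-confidence (probability > 0.9) white-matter and
   CSF voxels, each modality is rescaled as `I_cal = I * fact - shift`,

   ```
   fact  = (Ref1 - Ref2) / (wm - csf)
   shift = (csf * Ref1 - wm * Ref2) / (wm - csf)
   ```

   so the UNI modes map exactly to (Ref1, Ref2) = (100, 20) and the T1-map
   modes to (20, 100). Negative voxels are repaired from 6-connected
   neighbours, and the quotient `RATIO = UNI_cal / T1map_cal` (99th-
   percentile outliers capped) forms a third, contrast-amplified channel.
2. **First-pass segmentation.** k-means (k = 6, squared Euclidean distance,
   k-means++ restarts) on the z-scored channel triplet inside a brainstem
   tissue mask; cluster numbering is harmonized across subjects by optimal
   centroid matching to a reference subject.
3. **Probabilistic priors.** The per-subject binary cluster maps are
   aligned by iterative diffeomorphic (stationary-velocity-field) template
   building; the group averages are probabilistic priors, projected back
   into each subject through the inverse deformations.
4. **Refinement.** Voxels whose label disagrees with the prior argmax are
   reassigned when the alternate prior is >= 0.75 or exceeds the original
   by >= 0.20; labels become probabilistic maps `prior x standardized
   centroid-distance weight`.
5. **Evaluation and morphometry.** Low-silhouette and miss-classification
   quality indices, ROI mean-intensity extraction with normality-gated
   group tests and FDR control, and deformation-based morphometry (Jacobian
   determinant maps, permutation max-T family-wise error control).

A synthetic multi-subject brainstem phantom with known ground-truth labels,
noise, bias fields and invertible per-subject warps makes every stage
testable without MRI data.

## Worked example

```r
library(bstemseg)

spec <- phantom_spec(seed = 7)          # 48 x 56 x 40, 1 mm, moderate noise
cohort <- generate_cohort(spec, 8)
res <- segment_cohort(cohort, replicates = 10, seed = 7,
                      compute_silhouettes = FALSE)
print(res)
#> pipeline_result: 8 subjects, channels all3
#>   mean miss-classification index: 6.73%

print(res$calibrated[[1]]$factors$uni)
#> uni scale factors: fact = 0.0395272, shift = 18.7693 (wm mode 3004.75, csf mode 980.826)

dice_scores(res$segmentations[[1]]$final_labels,
            cohort[[1]]$truth_labels, box = res$box)$dice
#> [1] 0.976 0.994 0.979 0.932 0.976 0.986
```

The UNI scale factor ~0.04 maps the subject's white-matter mode (~3005)
onto the bright anchor 100 and its CSF mode (~981) onto the dark anchor 20.
The mean miss-classification index of 6.7% is the share of first-pass
voxels falling outside their cluster's group prior (threshold 0.3); the
per-class Dice values compare the final refined labels with the phantom's
ground truth (class 4 is the thin periaqueductal-like column, hence the
lowest value).

The channel-combination experiment of the method — does clustering on all
three channels beat any single channel? — is reproduced with:

```r
ex <- run_input_combo_experiment(cohort, combos = c("all3", "uni", "ratio", "t1map"),
                                 replicates = 10, seed = 7,
                                 compute_silhouettes = FALSE)
ex$table[, c("combo", "missclassification")]
#>   combo missclassification
#>    all3           6.726042
#>     uni           7.510892
#>   ratio          10.089992
#>   t1map          14.260725
```

A thin command-line wrapper is installed at `inst/cli/bstemseg`
(`bstemseg phantom | run | combos`), driven by a YAML configuration with
the sections of `default_config()`.

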