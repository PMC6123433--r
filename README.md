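# nucleomorph

Interpretable deep learning on nuclear morphometry: predicting clinical
estrogen-receptor (ER) status from H&E histology via pre-defined nuclear
features rather than raw pixels.

## The problem and the approach

ER status in breast carcinoma is determined by immunohistochemistry, but
nuclear morphology on routine H&E sections carries correlated signal:
ER-negative tumours tend to have larger, more pleomorphic nuclei. Black-box
CNNs on raw pixels can exploit this but resist inspection. `nucleomorph`
implements a hybrid alternative for computational-pathology researchers:

1. **Segment** nuclei with classical operators — rescale to 0.5 µm/px
   (bicubic), HSB brightness channel, global Otsu ∧ local adaptive
   threshold (radius 20 px = 10 µm), distance-transform watershed — and
   measure, per nucleus *i*: centroid (x, y), major/minor axis lengths,
   their ratio, area A, perimeter P, circularity 4πA/P², and major-axis
   orientation θᵢ ∈ (0°, 180°].
2. **Encode** each image as a sparse 12-channel image at 2 µm/px, zero
   except at nucleus centres `(x₂, y₂) = (floor(x₁/4), floor(y₁/4))`:
   channels 1–6 the shape features, channels 7–12 binary angle features

   φᵢⱼ = 1 if 30(j−1) < θᵢ ≤ 30j, else 0,  j = 1…6.

3. **Train** a small fully convolutional network (six conv layers, five
   2×2 max pools, one global mean, one batch-normalisation, ≈ 4.6×10⁵
   parameters) on randomly sampled 100 px (200 µm) patches that inherit
   the image-level label, with flip/rotate augmentation realised exactly
   as a permutation of the angle channels.
4. **Predict** a spatial heatmap of ER-negative evidence; the specimen
   score is `sigmoid(batchnorm(mean logit))`; evaluate with Mann–Whitney
   AUC and stratified bootstrap CIs.
5. **Interrogate** the model: digital staining (red overlay where
   p > 0.5), ranking of patches into 15 score groups with intra-patch
   mean/variance morphometry, and a 12-feature logistic-regression
   baseline on the same moments.

A seeded synthetic module generates labeled nuclei point fields (Thomas
cluster process; class-dependent log-normal areas — ER-negative larger and
more heterogeneous) and renders H&E-like images, so every stage is
testable end to end without external data.

## Worked example

```r
library(nucleomorph)

## --- segmentation on a rendered ground-truth fixture ---
truth <- generateSnapshot(generatorConfig(widthUm = 200, heightUm = 200,
    density = 1200, parentDensity = 1200, minSpacing = 16, edgeMargin = 10),
    classLabel = 0, seed = 7)
img  <- renderHE(truth, seed = 8)
snap <- segmentImage(img, nativeRes = 0.5)
#> segmentImage: 26 nuclei detected in 'image'
concordanceQC(snap, truth)
#> [1] 1
#> attr(,"passesQC")
#> [1] TRUE

## --- encode, train, score a small synthetic cohort ---
cohort <- generateCohort(10, generatorConfig(), seed = 1)   # 10 per class
feats  <- lapply(cohort, encodeSnapshot)
feats[[1]]
#> SparseFeatureImage 'syn_c0_001': 200 x 200 x 12 @ 2 um/px, 465 occupied px, 9 collision(s)

sp  <- splitCohort(feats, 0.6, seed = 1, stratify = TRUE)
net <- buildNetwork(networkConfig(), seed = 1)
net
#> NucleoNet: widths [32,64,96,128,224], 446595 parameters, untrained
net <- trainNetwork(net, feats[sp$train],
                    config = trainConfig(epochs = 15, epochsPhase2 = 5,
                                         patchesPerEpoch = 50, seed = 1))
tab <- scoreSpecimens(net, feats[sp$test])
tab
#>   specimen_id score label
#> 1  syn_c0_003 0.302     0
#> 2  syn_c0_006 0.261     0
#> 3  syn_c0_008 0.227     0
#> 4  syn_c0_010 0.256     0
#> 5  syn_c1_004 0.680     1
#> 6  syn_c1_006 0.807     1
#> 7  syn_c1_009 0.837     1
#> 8  syn_c1_010 0.767     1
rocAuc(tab$score, tab$label)
#> [1] 1
```

The scores are the specimen-level ER-negative evidence in [0, 1]: the four
class-0 (ER-positive-like) specimens score ≈ 0.23–0.30, the four class-1
specimens ≈ 0.68–0.84, so the held-out AUC — the probability that a random
ER-negative specimen outscores a random ER-positive one — is 1.0 on this
small planted-effect cohort after a training run of a couple of minutes on
one CPU.

`runPipeline()` drives the same chain from a YAML config and writes a JSON
run manifest (seeds, config hash, package version) next to its outputs;
`inst/scripts/nucleomorph.R` is a thin command-line wrapper
(`run`, `simulate`, `segment`, `encode`, `evaluate`).

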