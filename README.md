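# crcd — confidence-region contour detection for brain-tumour MRI

`crcd` extracts brain-tumour regions from greyscale MRI slice stacks. It is
aimed at medical-image analysts who need a deterministic, fully inspectable
region-extraction pipeline for enhancing tumours — the bright cores whose
boundary intensities blend into normal tissue so that plain thresholding
either misses the faint growing rim or floods into brain.

## The method

For slices `x` with intensities in [0, 1], the pipeline is:

1. **Window adjustment** — `clip(αx + β, 0, 1)` with `α = 1/(h − l)`,
   `β = −lα` for the window `(l, h) = (0.36, 0.78)` where enhancing-tumour
   intensities concentrate.
2. **Biggest blob** — Otsu binarization, 8-connected component labelling,
   selection of the maximal-area component per slice.
3. **Pattern fusion** — per-slice blobs are unioned within user-defined
   runs of similar slices ("patterns", e.g. 65–69 and 70–74), then across
   patterns into the *resultant blob*; its pixel count is the *confidence
   score* CS, and an RGB overlay keeps per-pattern provenance.
4. **RSF level set** — from the blob's bounding box, φ evolves under
   `φ ← φ + Δt [δ_ε(φ)(λ_in e_in − λ_out e_out) + ν δ_ε(φ) κ(φ) + μ(∇²φ − κ(φ))]`
   where `e_in`, `e_out` are squared residuals against Gaussian-kernel
   (13×13, σ=3) local fitted means — the region-scalable fitting energy.
5. **Confidence region** — per-quadrant means `ā_q` with the whole-image σ
   define the 95% band `[ā_q − 1.96σ, ā_q + 1.96σ]`; pixels are kept
   (`p ≥ ā_q`), brightened (`p + ā_q` in the band below the mean) or
   flattened to `ā_q`, Haar-smoothed, multi-Otsu classified, and the top
   class inside the dilated blob is the final tumour mask CR.

Evaluation uses the Dice overlap index `2|A∩B|/(|A|+|B|)`, Jaccard
`|A∩B|/|A∪B|`, MSE and PSNR.

A seeded synthetic phantom (drifting bright disc with an enhancing rim on
an elliptical brain, two pattern groups, Gaussian noise) makes the whole
pipeline testable without clinical data.

## Worked example

```r
library(crcd)
ph  <- make_phantom(phantom_spec(seed = 1))   # 10 slices, patterns 65:69 / 70:74
fit <- crcd(ph)                               # full pipeline
fit
#> Confidence-region contour detection
#>   10 slice(s) (65:74), 2 pattern(s)
#>   confidence score: 1182 px (resultant blob)
#>   final confidence-region mask: 1148 px
summary(fit)
#> CRCD fit summary
#>   pattern 1: slices 65:69, blob 1039 px (red)
#>   pattern 2: slices 70:74, blob 1044 px (green)
#>   confidence score 1182 px; bounding box rows 47:86 cols 47:85
#>   RSF: 300 iteration(s), 108 contour px, final energy 9.606e+05
#>   confidence interval: sigma 0.2568, quadrant means 0.192 0.201 0.204 0.206
#>   final mask 1148 px
eval_report(fit$mask, phantom_truth_union(ph), name = "phantom seed 1")
#> Segmentation evaluation (phantom seed 1)
#>   DOI  0.9379
#>   JI   0.8831
#>   MSE  0.009277
#>   PSNR 20.33 dB
```

The confidence score (1182 px) is the fused blob's area — the pipeline's
raw evidence for tumour. The final confidence-region mask trims that
evidence to the tumour-bright class, and its Dice of 0.94 against the
union of the per-slice truth discs says the recovered region overlaps the
true tumour almost completely, with the residual disagreement confined to
the faint outer rim. `plot(fit)` shows the score image, the RGB pattern
overlay, the RSF contour and the final mask.

Real volumes enter through `load_volume("t1.nii.gz", slice_offset = 0)`
(NIfTI or PNG/TIFF stacks), and a command-line wrapper covers the same
pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","crcd.R",package="crcd"))') \
  segment t1.nii.gz --slices 65:74 --pattern 65:69 --pattern 70:74 --out seg/
```

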