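# roraseg

Fully automated en-face segmentation of **retinal pigment epithelium and
outer retinal atrophy (RORA)** in macular SD-OCT volumes, for researchers
quantifying atrophy in dry age-related macular degeneration.

RORA is graded per b-scan by its lateral extent only — the clinically
relevant quantity is the top-down (en-face) atrophy footprint and its area.
The package implements the full pipeline around that reading:

* **Layer-prior training targets.** The 2D target for a b-scan is the
  intersection of the annotated lateral atrophy extent with the
  photoreceptor–RPE–choroid band from a retinal layer segmentation, so the
  network attends to the layers whose state defines RORA
  (hypertransmissive choroid, attenuated RPE, degenerating
  photoreceptors). An ablation mode trains instead on the 1D
  maximum-probability projection, where the vertical target span is
  undefined.
* **Focal loss training.** A compact convolutional encoder–decoder
  (U-Net-style, implemented in the package with compiled conv primitives
  and hand-written backprop) is optimised with Adam on the focal binary
  cross-entropy `FL(p_t) = −(1−p_t)^γ log p_t`, γ = 2.
* **Max-projection inference.** Per-b-scan probability maps are
  max-projected along depth and thresholded at 0.5 to give a binary
  en-face atrophy map; layer masks are never needed at inference.
* **Evaluation.** Per-volume en-face Dice, precision, recall and Cohen's
  kappa; cohort mean ± sd; Bland–Altman limits of agreement for areas;
  patient-grouped k-fold cross-validation; iRORA/cRORA lesion grading by
  the 250 µm width rule with cross-b-scan connectivity and the
  isolated-iRORA discovery rate.
* **Synthetic OCT phantom.** A layered-retina generator with atrophic
  footprints (RPE attenuation + choroidal hypertransmission +
  photoreceptor thinning), drusen confounders, speckle noise and exact
  paired ground truth, so the whole pipeline is testable without clinical
  data.

## Worked example

```r
library(roraseg)

## a 30-volume synthetic cohort, one patient each (desk scale: 16 b-scans
## of 64 x 128 px over 6 x 6 mm)
prof <- desk_profile(seed = 1)
cohort <- generate_cohort(30, base = prof$synth, seed = 1)
cohort[[5]]
#> rora_bundle: patient P005, 16 b-scans, 8 annotated interval(s), en-face positives 446

## the untrained layer-prior network
build_network(prof$train)
#> RORA segmentation model (tiny encoder, prior mode): 15067 parameters, untrained

## lesion grading of one volume's annotation (all lesions here exceed 250 um)
table(classify_lesions(cohort[[5]]$annotation)$grade)
#> cRORA
#>     8

## generation, training on 24 volumes, held-out evaluation on 6 -- one call
res <- run_holdout(prof)
res$report
#> cohort report: 6 volume(s)
#>   dice      0.958 ± 0.026
#>   precision 0.920 ± 0.047
#>   recall    1.000 ± 0.000
#>   kappa     0.951 ± 0.027
```

Mean Dice 0.958 with perfect recall means the model recovers essentially
the whole atrophic footprint on held-out phantoms, with the mild
over-segmentation bias expected of maximum projection (precision 0.92;
predicted areas run slightly above the reference areas). The layer-prior
ablation (`run_ablation`) and patient-grouped cross-validation
(`run_crossval`) mirror the full experiment design; a thin command-line
driver for simulate/train/predict/evaluate/crossval/ablation ships in
`inst/cli/rora.R`.

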