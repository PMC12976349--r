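# synthecv

Automated, blood-draw-free quantification of myocardial extracellular
volume (ECV) from paired native and post-contrast short-axis cardiac T1
maps, with the full method-agreement statistics suite needed to validate
such a pipeline against a manual reference.

## Who this is for

ECV is a CMR biomarker of diffuse myocardial fibrosis. The conventional
measurement needs two manual inputs: expert contours on the T1 maps and a
laboratory hematocrit (HCT) drawn within 24 h of the scan. `synthecv`
implements the fully automated alternative — automatic segmentation,
measurement-mask refinement, and a *synthetic* hematocrit regressed from
the native blood-pool T1 itself — for researchers batch-processing T1
mapping cohorts, and for methodologists who want every stage testable
against ground truth.

## The model

With R1 = 1/T1 (contrast-induced relaxation enhancement proportional to
local contrast concentration, equilibrated between blood and myocardial
extracellular space):

    ECV = (1 − HCT) · (1/T1_myo_post − 1/T1_myo_native)
                      ─────────────────────────────────────
                      (1/T1_blood_post − 1/T1_blood_native)

Synthetic ECV is the same computation with HCT replaced by a stratified
linear regression on native blood-pool R1:

    HCT_synthetic = α(sex, field) + β(sex, field) · R1_blood_native

The automated measurement chain is: segmentation (epicardial + endocardial
LV contours, with papillary muscles inside the endocardial contour, and the
RV cavity) → myocardial ring = epicardium ∖ endocardium, eroded with a 3×3
structuring element against partial-volume contamination → blood pool
separated from papillary muscles by Otsu's threshold inside the cavity,
then eroded the same way → median T1 per region → HCT regression → ECV →
classification against clinical thresholds (30 %, or the adapted 29.5 % for
synthetic ECV).

Three segmentation backends share one contract: a ground-truth `oracle`
(phantom labels), a model-free `classical` two-stage Otsu backend, and an
optional trainable `learned` backend (multinomial elastic-net pixel
classifier, a desk-scale stand-in for a segmentation network).

Because patient images cannot ship with the package, a digital phantom
generator (`cohort_config()`, `generate_cohort()`) renders short-axis
scenes — LV cavity, myocardial ring, papillary muscles, RV crescent — with
known per-subject HCT, ECV and tissue T1 values drawn from published cohort
statistics, plus optional partial-volume banding and noise. Every pipeline
stage is validated against this known truth.

## Worked example

```r
library(synthecv)

# conventional ECV at published 1.5 T validation-cohort means:
# HCT 41.7 %, myocardium 1036 -> 449 ms, blood 1559 -> 311 ms
round(100 * compute_ecv(1036, 449, 1559, 311, 0.417), 1)
#> [1] 28.6

# end to end on a 30-subject phantom cohort, automated backend
ecv_cli(c("run-all", "--out", "demo", "--n", "30", "--seed", "7",
          "--backend", "classical"))
#> [generate] 30 subjects -> demo (0.8s)
#> [quantify] backend=classical, 30 subjects, 0 flagged (43.1s)
#> [report] demo/report.json
```

`demo/results.csv` holds one row per subject (medians, hematocrits, the
four contour-by-HCT ECV variants, classifications); `demo/report.json` the
cohort-level agreement statistics. For this run (fractions reported as %):

| variant (all field strengths)           | mean ± SD      | p vs reference |
|-----------------------------------------|----------------|----------------|
| manual contours, laboratory HCT (ref)   | 27.4 ± 5.8 %   | –              |
| automated contours, laboratory HCT      | 27.5 ± 5.9 %   | 0.016          |
| manual contours, synthetic HCT          | 27.4 ± 5.5 %   | 0.966          |
| automated contours, synthetic HCT       | 27.5 ± 5.5 %   | 0.748          |

Bland–Altman of fully automated synthetic vs reference ECV: bias 0.11
points, limits of agreement −3.45 to +3.67 points; Pearson r = 0.95;
threshold concordance 93.3 % (30 %/30 %) and 90.0 % (30 %/29.5 %). Against
the phantom's known truth the automated arm recovers ECV with MAE 1.47
points and bias 0.09 points. The same flow is available programmatically
via `generate_cohort()`, `run_cohort_pipeline()` and `agreement_report()`.

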