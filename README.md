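# dcehabitat

Automated detection and quantitative scoring of prostate tumor habitats
from dynamic contrast-enhanced (DCE-) MRI.

## What it does, and for whom

Prostate DCE-MRI acquires a T1-weighted signal–time curve in every voxel
after a contrast bolus. Well-perfused tumor tissue enhances earlier and
washes out faster than benign gland, but reading a dozen dynamic frames
by eye is unreliable, and pharmacokinetic modeling is fragile at the
~30 s temporal resolution of routine clinical protocols. `dcehabitat`
is for imaging scientists and radiation-oncology/radiology researchers
who want a reproducible, fully automated semi-quantitative analysis of
such series:

1. **Motion correction** — each frame is aligned to its corrected
   predecessor by an in-plane affine transform maximizing mutual
   information over the prostate dilated by 18.75 mm; a correction is
   kept only if it lowers the sum of squared differences there.
2. **Pattern recognition** — baseline-corrected prostate voxel curves
   form a non-negative matrix `D` (voxels × frames), factorized by NMF
   as `D ≈ W S` with `k = 3` temporal patterns. The *well-perfused*
   pattern `S_wp` is the one maximizing `AUC_{0–90 s}(S_m)`; its weight
   map `W_wp` images the suspicious tissue.
3. **Segmentation** — `W_wp` is thresholded (Otsu, or a β-purity rule:
   voxel in ROI iff `W_wp / Σ_m W_m > β%`; default β = 60), cleaned of
   components < 0.05 cc, rejected if < 0.5 cc, and assigned to the
   peripheral zone if > 10% of it lies in the PZ (else transition zone).
4. **Kinetics** — six features of the ROI curve (reconstructed from the
   factorization, hence de-noised): early/late AUC (60–120 / 240–330 s),
   wash-in `(s_m − s_0)/τ` and early/late AUFC from a bi-exponential fit
   `S(t) = s_0 + A(e^{−k_2(t−t_0)} − e^{−k_1(t−t_0)})`, and wash-out,
   the negated slope of a linear fit over 270–330 s — each also as a
   ratio to the same feature of the gluteus maximus muscle curve.
5. **Scoring** — a feature value `F` generalizes to every voxel as
   `W_wp · F/ω` (ω = mean of `W_wp` over the ROI, so the ROI mean is
   exactly `F`), then bins to a 1–10 aggressiveness score on a scale
   bounded by the cohort's 5th/95th feature percentiles.

A synthetic pelvic phantom generator (ellipsoidal prostate, posterior
PZ, muscle sample, graded spherical lesions, Gaussian/Rician noise,
point-spread blur, injectable inter-frame motion) provides ground truth
for every stage, so the whole pipeline is testable without patient data.

## Worked example

```r
library(dcehabitat)

sigma <- sigma_for_snr(kinetics_presets()$lesion_g34, 20)  # SNR-20 noise
ph <- make_phantom(phantom_config(
  noise = list(model = "gaussian", sigma = sigma), seed = 2))

res <- run_pipeline(ph$series, ph$truth$prostate, ph$truth$pz, ph$truth$gm,
                    biopsies = simulate_biopsies(ph),
                    motion_correct = FALSE, seed = 2)
print(res)
print(res$features)
```

```
<pipeline_result> complete
<seg_result> 0.727 cc, zone PZ
<aggressiveness_map> early_aufc_ratio, F = 8.084, omega = 63.4, scores 1-10
<feature_set> (muscle-normalized)
    feature          raw     ratio valid
  early_auc 3595.6132964 7.0945295  TRUE
   late_auc 2309.7473185 0.8026727  TRUE
    wash_in    1.1122624 6.1606024  TRUE
 early_aufc 3750.4037159 8.0837233  TRUE
  late_aufc 2304.9699651 0.8000868  TRUE
   wash_out    0.1644442 6.3540657  TRUE
```

The phantom's grade 3+4 lesion was segmented as a 0.727 cc
peripheral-zone ROI (Dice 0.845 against the true lesion mask). The ROI's
early area under the fitted curve is 8.08 times the muscle's — the
`early_aufc_ratio` feature used for the map, whose mean over the ROI
equals `F = 8.084` by construction. The simulated biopsy track through
the lesion reads back a map mean of 8.49 against a usROI feature of
8.30, illustrating the map/feature concordance that the evaluation
module quantifies cohort-wide.

Cohort-level simulation (24 phantoms with grades 6 < 3+4 < 4+3 < 8):

```r
co  <- run_cohort(phantom_cohort(n = 24, seed = 1))
spearman_assoc(co$table$early_aufc_ratio, co$table$gs_group4)  # rho ~ 0.95
concordance(co$biopsies, "early_aufc_ratio")                   # r ~ 1.00
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/dcehabitat.R` (`phantom`, `motion-correct`, `nmf`, `segment`,
`run-all` subcommands).

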