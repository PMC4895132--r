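# mammocad

Quantitative characterization and benign/malignant classification of
mammographic lesions, with a fully synthetic, ground-truthed test bed.

Microcalcifications (0.1–1 mm calcium deposits) and masses are the two
key mammographic signs of early breast cancer, and their morphology
carries the diagnostic signal: malignant calcification clusters tend to
be numerous, elongated or irregular; malignant masses tend to be
spiculated and non-solid. `mammocad` is for researchers building or
benchmarking computer-aided diagnosis (CAD) pipelines on such lesions.
It provides:

* **Feature extraction** from an 8-bit grayscale image plus binary
  lesion masks: 15 microcalcification descriptors (count, size,
  density, circularity, solidity, sandy/linear proportions,
  spiculation, intensity statistics, cluster eccentricity), 26 mass
  descriptors (shape ratios, radial-signature spiculation, intensity
  statistics, and Haralick gray-level co-occurrence texture:
  energy, entropy, correlation, inverse difference moment,
  sum/difference statistics, mutual information), and their 41-feature
  combination. All features are invariant to translation and 90°
  rotation.
* **A stacked denoising autoencoder (SDAE) classifier**: sigmoid
  encoder/decoder layers *h* = σ(W₁x + b₁), x̂ = σ(W₂h + b₂) trained
  layer-wise on the masking-noise denoising reconstruction objective,
  stacked greedily, topped with a two-class softmax and fine-tuned
  end-to-end by minibatch SGD with Polyak tail averaging. Training is
  bit-reproducible from a seed.
* **Benchmarks** — RBF-SVM, k-nearest neighbours, and closed-form
  ridge-regularized LDA — under a common fit/score/predict contract.
* **An evaluation protocol** — accuracy, sensitivity = TP/(TP+FN),
  specificity = TN/(TN+FP), ROC/AUC (trapezoid = Mann–Whitney), and
  stratified 10-fold cross-validation — producing per-scenario
  comparison tables for calcifications alone (15 features), masses
  alone (26) and both combined (41).
* **A phantom generator** producing mammogram-like images with
  class-conditional lesion morphology and exact truth masks, a
  feature-table simulator with controllable linear or XOR class
  structure, and simple top-hat / Otsu plumbing detectors.

## Worked example

```r
library(mammocad)

# a malignant phantom case with ground truth
case <- generate_case(label = 1, seed = 42)
case
#> lesion_case: 256x256, label=1, 9 calcifications, mass=yes

fv <- case_features(case, scenario = "combined")   # 41 named features
round(fv[c("calc_number", "calc_linear_proportion", "mass_solidity",
           "mass_spiculation", "mass_entropy")], 3)
#>            calc_number calc_linear_proportion          mass_solidity
#>                  9.000                  0.222                  0.723
#>       mass_spiculation           mass_entropy
#>                  0.245                  5.101

dice_overlap(detect_mass(case$image), case$mass_mask)
#> [1] 0.89

# the three-scenario comparison on a simulated cohort mirroring a
# 1000-train / 204-test study composition (32.3% / 52.5% malignant),
# with an XOR (linearly inseparable) class structure
tabs <- simulate_study_tables(41, structure = "xor", effect = 3, seed = 1)
cfg <- train_config(epochs_pretrain = 150, epochs_finetune = 1000,
                    corruption_p = 0.2, seed = 1)
report <- run_scenario(tabs$train, tabs$test, "combined",
                       configs = list(sae_hidden = c(100, 100),
                                      sae_cfg = cfg, cv_folds = 5),
                       seed = 1)
report
#> Scenario: combined  (train n=1000, test n=204)
#>        accuracy  sensitivity  specificity    AUC      CV mean±sd
#> SVM       83.3%        0.692        0.990  0.938     0.864 ± 0.033
#> KNN       80.9%        0.645        0.990  0.925     0.854 ± 0.032
#> LDA       48.5%        0.065        0.948  0.521     0.648 ± 0.016
#> SAE       85.3%        0.738        0.979  0.945     0.771 ± 0.151
```

The report reads like the usual CAD comparison table: the linear
discriminant collapses on the XOR structure (48.5%, AUC 0.52) while the
nonlinear classifiers recover it, and the deep model edges out the SVM
on test accuracy and AUC. `write_report(report, "report.json",
"report.md")` saves it.

A thin command-line front end with verbs `simulate-images`,
`simulate-table`, `extract`, `train`, `evaluate` and `compare` is
installed at `system.file("cli", "mammocad.R", package = "mammocad")`.

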