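# TIMEscore

Bootstrap out-of-bag immune biomarker scoring for immunotherapy response.

## What this package is for

Only a subset of patients with recurrent or metastatic head and neck
squamous-cell carcinoma (RM-HNSCC) benefit from anti-PD-1 monotherapy, and
the standard companion biomarker (PD-L1 immunohistochemistry, summarised
as a combined positive score, CPS) is only weakly predictive. TIMEscore is
an R implementation of the multidimensional alternative: a panel of tumor
immune microenvironment (TIME) expression features — immune-cell-type and
T-cell-state signatures plus single immunomodulatory genes — integrated by
regularized logistic regression into a 0–100 score that predicts disease
control (CR/PR/SD, "non-progressor") versus progression (PD,
"progressor").

It is written for computational biologists and biostatisticians who want
to build, validate or stress-test biomarkers of this design: every stage
is a documented, seeded, unit-tested function, and a synthetic-cohort
generator makes the whole pipeline runnable without patient data.

## The method

* **Features.** Counts are normalized to log2 CPM
  (`log2(1e6·c/lib + 1)`), genes are z-scored across samples (population
  SD), and a signature score is the mean of its member genes' z-scores
  (panels supplied as GMT; a 62-feature placeholder panel ships in
  `inst/extdata/`).
* **Candidate models.** L2-penalized logistic regression maximizing
  `ℓ(w,b) − ‖w‖²/(2C)` (intercept unpenalized, Newton–Raphson, gradient
  norm < 1e-6), swept over `C ∈ 2^(−10..6)` with greedy forward feature
  selection on stratified 5-fold cross-validated AUC.
* **Analytic variability.** Candidate scores on technical replicates
  (9 replicates × 6 biological samples by default) are mean-centered per
  biological sample; variability = 4 × pooled SD ("4*std").
* **Final model.** Maximize CV AUC subject to AUC ≥ 0.76 and 4*std ≤ 20.
* **The score.** For each of B = 1000 bootstrap iterations, refit the
  fixed feature set on an n-with-replacement draw and score out-of-bag
  patients as 100 × P(non-progression); average per patient. Classify at
  the cohort median (ties → progressor); report quartiles.
* **Evaluation.** Confusion-matrix metrics (sensitivity, specificity,
  PPV, NPV, LR±, diagnostic odds ratio...), disease control rates with
  Fisher exact tests, relative risk, Mann–Whitney ROC/AUC, per-quartile
  DCR, head-to-head predictor comparison, Kaplan–Meier/log-rank and Cox
  proportional hazards — plus `reconstructConfusion()`, which exhaustively
  inverts a printed (rounded) metric table into its unique exact integer
  confusion matrix.

## Worked example

```r
library(TIMEscore)

## end-to-end synthetic study emulation: 103 patients, 62 features,
## 3 informative, trained, selected, OOB-scored and evaluated
summary <- runPipeline(defaultPipelineConfig(seed = 1))
summary$model$features      # "feat01" "feat02" "feat31" "feat33" "feat37"
summary$model$variability_4std  # 11.61
summary$oob_auc             # 0.9742
summary$threshold           # 30.54  (cohort median score)
summary$survival$cox_hr     # 0.413  (non-progressors vs progressors)
summary$survival$logrank_p  # 0.00012
summary$comparator$comparator_auc  # 0.625 (CPS-like comparator)
```

The selected model picks up the two strongest informative features first
(the weakest of the three is displaced by noise features admitted at
small CV-AUC increments — expected at n = 103), its OOB AUC of 0.97
reflects the deliberately clean synthetic signal, predicted
non-progressors live markedly longer (hazard ratio 0.41), and the noisy
univariate comparator discriminates far less (AUC 0.63) — the qualitative
pattern this biomarker design is built to exhibit.

Inverting a published metric table into exact counts:

```r
cm <- reconstructConfusion(n = 103, prevalence = 0.41,
                           sensitivity = 0.79, specificity = 0.70)
confusionCounts(cm)
#> TP FP FN TN
#> 33 18  9 43
round(diagnosticMetrics(cm)[["dor"]], 2)
#> 8.76
```

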