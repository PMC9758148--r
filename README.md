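# creatinet

Discovering blood-test factors associated with serum creatinine from
incomplete laboratory panels.

## What this is for

Serum creatinine is the routine indicator of kidney function, and eGFR is
derived from it by the Cockcroft–Gault formula
`((140 − age) × weight) / (72 × creatinine)` (× 0.85 for females), so the
two are inversely related by construction. Routine blood-test records are an
attractive place to search for parameters associated with creatinine — they
cover healthy and sick people alike — but they are brutally incomplete
(40–98% missing per analyte, because physicians order only the tests they
need) and strongly inter-correlated (CBC indices at r = 0.7–0.95).

`creatinet` implements the full analysis pipeline for this setting, for
biostatisticians and epidemiologists working with lab-panel-shaped data:

1. **Multiple imputation** (`multipleImpute`) — the iterative
   impute–train–repredict engine with pluggable cores: chained least-squares
   regression, random-forest (missForest-style), a discrete Bayesian-network
   core, and a shallow denoising autoencoder; plus a KNN baseline
   (`knnImpute`). The target variable is excluded from the entire process so
   nothing about creatinine leaks into its predictors (bit-exact guarantee,
   tested).
2. **Masked-value evaluation** (`maskObserved`, `maskedMse`,
   `evaluateMethods`) — hide observed cells, impute, score by
   min–max-normalized MSE `Σ(xᵢ − x̄ᵢ)²/N`; all methods are scored on
   identical hidden cells.
3. **Peak-based discretization** (`peakCutpoints`, `assignClasses`) — the
   two highest peaks of a variable's distribution become cut points
   (one-decimal, classes `[min,c1) / [c1,c2] / (c2,max]`), with a tercile
   fallback for unimodal variables.
4. **Classification** (`correlationPrune`, `crossValidate`) — predictors
   pruned at |r| > 0.5 (and known kidney markers force-excluded), min–max
   scaling and grid search inside stratified ten-fold CV, reporting accuracy
   and macro-F1 with 95% CIs, micro/macro multiclass ROC-AUC and
   row-normalized confusion matrices.
5. **Interpretation** (`ruleForest`, `extractRules`,
   `directionOfAssociation`, `importanceRanking`) — decision rules from the
   top levels of a bagged CART forest, cross-tree deduplicated, with
   direction-of-association labels and impurity importances.
6. **Bayesian network** (`learnStructure`, `fitParameters`,
   `posteriorTable`, `predictClass`) — mutual-information screening against
   a permutation null, BIC hill-climbing, exact inference by variable
   elimination, and posterior tables P(target class | given class) with a
   monotonicity verdict.

Because data of this kind are private, the package includes a first-class
synthetic generator (`defaultPanelConfig`, `generateLabPanel`): a Gaussian
copula over the 46-parameter panel with the observed missingness profile,
block correlations (MCV–MCH ≈ 0.92), a trimodal creatinine marginal,
demographics with a derived eGFR column, MCAR/MAR mechanisms, and planted
positive vitamin-D and ferritin effects on creatinine — the known truth that
every stage is tested against.

## Worked example

```r
library(creatinet)

cfg   <- defaultPanelConfig(nRecords = 3000, seed = 4)
truth <- generateComplete(cfg)
study <- runAssociationStudy(completeTable(truth), seed = 4)
study$report
```

```
Association report for Creatinine
Top predictors:
  1. Vitamin D (25 OH) (importance 0.349, rule direction: direct)
  2. Ferritin (importance 0.319, rule direction: direct)
  3. Iron (importance 0.066, rule direction: indeterminate)
  4. ESR 1 h (importance 0.036, rule direction: indeterminate)
  5. Serum Albumin (importance 0.035, rule direction: indeterminate)
Posterior P(Creatinine | Vitamin D (25 OH)): verdict direct (rho 0.63)
Posterior P(e GFR | Vitamin D (25 OH)): verdict inverse (rho -0.27)
```

Reading: the forest ranks the vitamin-D analog first and its splits always
send higher vitamin D toward higher creatinine classes (*direct*); the
learned Bayesian network agrees (posterior of creatinine given vitamin D is
monotone increasing), and the derived eGFR column shows the mirror-image
*inverse* verdict, exactly as its construction from creatinine implies. Both
planted effects are recovered; the remaining predictors carry no direction.

On incomplete data, run the imputation engine first:

```r
panel <- generateLabPanel(cfg)   # ~42-98% missing per column
res   <- multipleImpute(maskedTable(panel), core = "bayesian_network",
                        exclude = "Creatinine", seed = 4)
res
#> ImputationResult[bayesian_network]: 10 iterations, max iterations (last change 2.07e-03)
```

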