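# refbias

Accuracy assessments of binary classifiers — diagnostic tests, remote-sensing
classifications, machine-learning models — almost always score the classifier
against a *reference standard* that is silently assumed to be a gold standard.
When the reference itself is imperfect, the cross-tabulation is an **apparent**
confusion matrix, and every metric computed from it (Recall, Precision,
Specificity, NPV, Youden's J, F1, MCC, likelihood ratios) as well as the
prevalence estimate can differ substantially from the truth. `refbias`
implements the closed-form forward models for this distortion, sweeps them
across the prevalence scale, verifies them with a case-level Monte-Carlo
generator, and inverts them to correct an observed matrix.

## The model

With true prevalence *P* and a classifier of known quality
(Recall_C, Specificity_C), the **true** confusion matrix in proportion space is

    TP = P·Recall_C            FP = (1−P)(1−Specificity_C)
    FN = P(1−Recall_C)         TN = (1−P)·Specificity_C

An imperfect reference (Recall_R, Specificity_R) relabels cases. If its errors
are **conditionally independent** of the classifier's, each true cell is
redistributed across the reference columns, e.g.

    TP′ = P·Recall_R·Recall_C + (1−P)(1−Specificity_R)(1−Specificity_C)

If its errors are **maximally correlated** (every reference error lands on a
case the classifier also mislabelled; feasible when the reference is at least
as accurate per class), false negatives migrate to TN′ and false positives to
TP′:

    TP′ = P·Recall_C + (1−P)(1−Specificity_R)

Both structures share the reference-positive marginal, the apparent prevalence

    P′ = P·Recall_R + (1−P)(1−Specificity_R)

whose inversion `P = (P′ − (1−Specificity_R)) / (Recall_R + Specificity_R − 1)`
(the classical Rogan–Gladen form) anchors `correct_independent()`, the
algebraic inverse of the independent-error model that recovers the true
prevalence and classifier rates from an apparent matrix.

## Worked example

A classifier with true Recall = Specificity = 0.8 at prevalence 0.1, scored
against a 0.9/0.9 reference whose errors are correlated with the classifier's
(N = 1000):

```r
library(refbias)
clf <- classifier_profile(0.8, 0.8)
ref <- reference_profile(0.9, 0.9, "correlated")
scale_matrix(apparent_matrix_correlated(0.1, clf, ref), 1000)
#> <confusion_matrix (apparent), N = 1000>
#>           reference
#> classifier pos neg
#>        pos 170  90
#>        neg  10 730
```

The same matrix through the CLI (`inst/cli/refbias.R`):

```
$ Rscript inst/cli/refbias.R metrics 170 90 10 730
accuracy     0.90  (0.9)
recall       0.94  (0.944444444444444)
precision    0.65  (0.653846153846154)
specificity  0.89  (0.890243902439024)
npv          0.99  (0.986486486486487)
youden_j     0.83  (0.834688346883469)
f1           0.77  (0.772727272727273)
mcc          0.73  (0.73108015498629)
lr_pos       8.60  (8.60493827160494)
lr_neg       0.06  (0.0624048706240487)
prevalence   0.18  (0.18)
```

Every number here is inflated relative to the truth: the classifier's real
accuracy is 0.80, its real precision at this prevalence 0.31, the real
prevalence 0.10. The apparent precision (0.65) is more than double the true
value, and the apparent prevalence (0.18) nearly double — entirely an artefact
of the imperfect reference. Correcting an *independent*-error matrix recovers
the generating parameters:

```r
correct_independent(confusion_matrix(90, 170, 90, 650, "apparent"),
                    reference_profile(0.9, 0.9, "independent"))
#> $p: 0.1   $recall: 0.8   $specificity: 0.8   $clamped: FALSE
```

`run_sweep(standard_scenarios())` reproduces the full study design — a 0.8/0.8
classifier against 2%, 10% and 18%-error references under both error
structures, plus a coin-tossing classifier against a 30% correlated-error
reference — over the 21-point prevalence grid {0.01, 0.05, …, 0.95, 0.99},
294 paired true/apparent rows in a tidy table. `sample_cases()` draws per-case
(truth, classifier, reference) label triples whose expected cross-tabulation
equals the closed forms, and `mc_check()` verifies that agreement.

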