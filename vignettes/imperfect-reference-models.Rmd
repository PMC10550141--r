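---
title: "Apparent accuracy under imperfect reference standards: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent accuracy under imperfect reference standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbias)
```

## The problem

A binary accuracy assessment cross-tabulates a classifier's labels against a
reference labelling and reads metrics off the resulting 2 × 2 confusion
matrix. The package fixes the orientation once and for all: reference labels
in the columns, classifier labels in the rows, so `tp` is
classifier-positive ∧ reference-positive. Everything downstream — the eleven
metrics, the forward models, the correction — assumes each case belongs
unambiguously to one of two classes.

The metrics' familiar properties (recall and specificity independent of
prevalence, MCC = 0 for a coin-tosser, and so on) are theorems about scoring
against *truth*. Real reference standards err. Scoring against an imperfect
reference produces an *apparent* matrix, and the package's purpose is to make
the map from (true prevalence, classifier quality, reference quality, error
structure) to that apparent matrix — and back — explicit, tested and
reusable.

## Forward models

**True matrix.** `true_matrix(p, clf)` places mass
`p·recall`, `p(1−recall)`, `(1−p)(1−spec)`, `(1−p)·spec` in proportion space
(total 1). Prevalence endpoints 0 and 1 are rejected throughout: several
metrics are undefined there and the standard grid deliberately avoids them.

**Independent errors.** When reference mistakes are conditionally independent
of the classifier's, each true cell splits across the reference columns by
the reference's per-class correctness rates; `apparent_matrix_independent()`
implements the four joint-product equations. Two structural facts follow and
are enforced as tested invariants: the classifier row sums are conserved
(reference error only moves cases between columns), and the total mass stays
1.

**Correlated errors.** `apparent_matrix_correlated()` implements the
*maximal*-correlation relabelling: every reference error lands on a case the
classifier also mislabelled, so classifier false negatives absorb the
reference's missed positives (moving to TN′) and false positives absorb its
false alarms (moving to TP′). This is feasible only when the reference is at
least as accurate as the classifier on each class
(`recall_r ≥ recall_c`, `spec_r ≥ spec_c`); outside that region the
procedure has no defined meaning and the package raises an error naming the
violated inequality rather than truncating silently. Partial correlation is
not parameterised: no mechanism for it is specified by the relabelling
procedure, and inventing one would be a different model. The reference-column
marginals — hence the apparent prevalence — are identical under both
structures.

**Apparent prevalence and transitions.** `apparent_prevalence()` is the
linear marginal `p·recall_r + (1−p)(1−spec_r)`. Its fixed point
`(1−spec_r)/(2−recall_r−spec_r)` is where the apparent prevalence crosses the
truth: below it prevalence is inflated (at `p = 0.01` with an 0.82/0.82
reference, more than 18-fold), above it deflated.
`transition_prevalence()` also exposes the classical transition expressions
for precision and NPV, which depend on the reference profile alone. A caveat
discovered while validating: under this package's independent-error forward
model the exact zero of (apparent − true) precision *also depends on the
classifier profile* (for a 0.8/0.8 classifier and 0.9/0.9 reference it sits
near p = 0.2, not at the formula's 0.5), so the precision/NPV expressions
should be read as the literature's reference-only characterisation, exact for
the prevalence fixed point, approximate as a precision/NPV crossing. The
tests assert the fixed-point property, which is exact.

**Correction.** `correct_independent()` is the algebraic inverse of the
independent model: prevalence by the Rogan–Gladen form
`(p′ − (1−spec_r))/(recall_r + spec_r − 1)`, then a per-row 2 × 2 linear
solve for the classifier's recall and specificity. It requires the
reference's Youden index to be nonzero (otherwise the misclassification map
is singular). On inconsistent empirical input, recovered values outside
[0, 1] are clamped and flagged (`clamped = TRUE`) with a warning rather than
rejected — an observed matrix plus a mis-stated reference quality is exactly
the situation a user needs diagnosed, not refused. A recovered prevalence of
exactly 0 or 1 leaves the classifier rates undefined (`NA`).

## Undefined values and numerical choices

Zero denominators (empty rows or columns) yield `NA_real_`, never an error,
so sweeps over degenerate corners complete; a perfect specificity yields
`lr_pos = Inf`. CSV serialisation writes `NA` as an empty field and infinity
as `inf`/`Inf`; JSON uses `null` and `"inf"`. Cells are stored as doubles
even when they arrive as integer counts, because MCC's marginal product
overflows 32-bit integers already around n ≈ 50 000. The prevalence grid is
built from integer hundredths (`c(1, seq(5, 95, 5), 99) / 100`) so equality
comparisons against grid points are exact. Display rounding is two decimal
places; full precision is kept internally.

## The scenario sweep

`standard_scenarios()` encodes the study conditions: a "good" classifier
(recall = specificity = 0.8, J = 0.6) against references with 2 %
(0.98/0.98), 10 % (0.90/0.90) and 18 % (0.82/0.82) error, each under both
error structures, plus a coin-tossing classifier (0.5/0.5, J = 0) against a
30 % correlated-error reference (0.7/0.7) — values chosen to represent a
classification many fields would call good, references usually more accurate
than the classifier, and a reference quality still within the range reported
in applied literature. All use the 21-point grid and a display sample size
of N = 1000. `run_sweep()` is fully deterministic and emits one true and one
apparent row per (scenario, grid point): 294 rows. Two headline facts it
reproduces: apparent MCC reaches 0.96 for the good classifier under the
*least* accurate correlated reference (at p = 0.5), and reaches 0.65 for the
coin-tosser whose true MCC is 0 everywhere — both directions of the trap
that motivates the package.

## The synthetic-case generator

`sample_cases()` is the case-level counterpart of the closed forms, not a
convenience fixture: truth is Bernoulli(p); the classifier errs per class at
its stated rates; an independent reference errs per class at its own rates;
a correlated reference errs *only* on classifier-error cases, with
conditional probability `(1−recall_r)/(1−recall_c)` on positives and
`(1−spec_r)/(1−spec_c)` on negatives. Those conditionals are the unique
choice that keeps the reference's marginal error rates at `1−recall_r` and
`1−spec_r` while concentrating all errors on classifier-error cases — the
sampling interpretation of the deterministic relabelling, and the key
correctness trap the tests guard (marginal preservation is asserted under
both structures). Sampling runs on an isolated RNG stream restored on exit,
so identical `(n, p, clf, ref, seed)` reproduce identical samples and the
caller's RNG state is untouched. `mc_check()` compares empirical cell
proportions with the closed form via per-cell z-scores; the acceptance-level
checks use n = 10⁶ draws with a 4-standard-error band, under which the
binomial standard error per cell is about 5 × 10⁻⁴.

What the generator emulates is exactly the models' assumptions: exchangeable
cases, constant per-class error rates, error correlation that is either zero
or maximal. Real data violate all three (covariate-dependent error rates,
partial correlation, non-exchangeable sampling designs), so passing tests
certify the implementation against its own model family, not the model
family against any particular data set.

## Scope decisions

The metric suite always means overall accuracy `(tp+tn)/n` by `accuracy`.
ROC/PR curve construction, confidence intervals, multi-class MCC, latent
class analysis and estimating reference quality from data are out of scope.
Where the correlated procedure would need to draw errors from
classifier-correct cells (reference less accurate than the classifier), the
package errors; it does not extrapolate. The command-line interface
(`inst/cli/refbias.R`, subcommands `metrics`, `sweep`, `simulate`,
`correct`) is a thin wrapper over the exported functions; matrix counts are
always ordered TP FP FN TN in the fixed row/column orientation stated above,
which the help text repeats because terminology varies across disciplines.

## Problem sizes

The test suite works at desk scale by design: closed-form checks on a
6 × 3 × 2 × 3 × 2 parameter lattice, brute-force phi-coefficient
cross-checks on expansions of up to 200 cases, Monte-Carlo crosstabs at
2 × 10⁵ draws in unit tests and 10⁶ in the acceptance-level checks. The full
suite and the acceptance script each complete in well under two minutes on a
single CPU.
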