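#' True confusion matrix from prevalence and classifier quality
#'
#' The matrix observed against a gold-standard reference, in proportion
#' space (total mass 1):
#' `tp = p * recall`, `fn = p * (1 - recall)`,
#' `fp = (1 - p) * (1 - specificity)`, `tn = (1 - p) * specificity`.
#' The prevalence of the result equals `p` exactly, and its recall and
#' specificity equal the profile values at every prevalence — the
#' prevalence-independence that holds only under a gold standard.
#'
#' @param p True prevalence, strictly inside (0, 1). The endpoints are
#'   rejected: several metrics degenerate there.
#' @param clf A [classifier_profile()].
#' @return A [confusion_matrix()] with `provenance = "true"`, `n = 1`.
#' @examples
#' true_matrix(0.1, classifier_profile(0.8, 0.8))
#' @export
true_matrix <- function(p, clf) {
  check_open_prob(p)
  stopifnot(inherits(clf, "classifier_profile"))
  confusion_matrix(
    tp = p * clf$recall,
    fp = (1 - p) * (1 - clf$specificity),
    fn = p * (1 - clf$recall),
    tn = (1 - p) * clf$specificity,
    provenance = "true"
  )
}

#' Apparent confusion matrix under independent reference errors
#'
#' When reference mistakes are conditionally independent of the
#' classifier's, each true cell is redistributed across the reference
#' columns by the reference's per-class correctness rates:
#' \deqn{TP' = p R_R R_C + (1-p)(1-S_R)(1-S_C)}
#' \deqn{FP' = p (1-R_R) R_C + (1-p) S_R (1-S_C)}
#' \deqn{FN' = p R_R (1-R_C) + (1-p)(1-S_R) S_C}
#' \deqn{TN' = p (1-R_R)(1-R_C) + (1-p) S_R S_C}
#' where R/S are recall/specificity and subscripts C and R denote the
#' classifier and the reference. Row sums (the classifier's marginal
#' behaviour) equal the true matrix's row sums exactly: reference error
#' only moves cases *between columns*.
#'
#' @param p True prevalence in (0, 1).
#' @param clf A [classifier_profile()].
#' @param ref A [reference_profile()] with `error_structure` `"independent"`
#'   (or `"gold"`, in which case the result equals [true_matrix()]).
#' @return A [confusion_matrix()] with `provenance = "apparent"`, `n = 1`.
#' @examples
#' # x1000: the (90, 170, 90, 650) worked example
#' m <- apparent_matrix_independent(0.1, classifier_profile(0.8, 0.8),
#'                                  reference_profile(0.9, 0.9, "independent"))
#' scale_matrix(m, 1000)
#' @export
apparent_matrix_independent <- function(p, clf, ref) {
  check_open_prob(p)
  stopifnot(inherits(clf, "classifier_profile"),
            inherits(ref, "reference_profile"))
  if (!ref$error_structure %in% c("independent", "gold")) {
    stop("reference profile must have independent (or gold) error structure",
         call. = FALSE)
  }
  rc <- clf$recall; sc <- clf$specificity
  rr <- ref$recall; sr <- ref$specificity
  confusion_matrix(
    tp = p * rr * rc             + (1 - p) * (1 - sr) * (1 - sc),
    fp = p * (1 - rr) * rc       + (1 - p) * sr * (1 - sc),
    fn = p * rr * (1 - rc)       + (1 - p) * (1 - sr) * sc,
    tn = p * (1 - rr) * (1 - rc) + (1 - p) * sr * sc,
    provenance = "apparent"
  )
}

#' Apparent confusion matrix under maximally correlated reference errors
#'
#' Here every reference mistake lands on a case the classifier also
#' mislabelled: truly positive cases wrongly labelled negative by the
#' reference are drawn from the classifier's false negatives (moving
#' FN mass to TN'), and truly negative cases wrongly labelled positive
#' are drawn from its false positives (moving FP mass to TP'). In
#' proportion space:
#' `tp' = p * recall_c + (1-p)(1 - spec_r)`,
#' `fp' = (1-p)(spec_r - spec_c)`,
#' `fn' = p (recall_r - recall_c)`,
#' `tn' = (1-p) spec_c + p (1 - recall_r)`.
#'
#' Feasibility requires the reference to be at least as accurate as the
#' classifier on each class (`recall_r >= recall_c`,
#' `spec_r >= spec_c`): otherwise there are not enough classifier-error
#' cases to absorb the reference's errors and the relabelling procedure
#' is undefined. Violations raise an error naming the inequality.
#' Reference-column marginals (hence apparent prevalence) are identical
#' to the independent model's at the same parameters.
#'
#' @inheritParams apparent_matrix_independent
#' @param ref A [reference_profile()] with `error_structure` `"correlated"`
#'   (or `"gold"`).
#' @return A [confusion_matrix()] with `provenance = "apparent"`, `n = 1`.
#' @examples
#' # x1000: the (170, 90, 10, 730) worked example
#' m <- apparent_matrix_correlated(0.1, classifier_profile(0.8, 0.8),
#'                                 reference_profile(0.9, 0.9, "correlated"))
#' scale_matrix(m, 1000)
#' @export
apparent_matrix_correlated <- function(p, clf, ref) {
  check_open_prob(p)
  stopifnot(inherits(clf, "classifier_profile"),
            inherits(ref, "reference_profile"))
  if (!ref$error_structure %in% c("correlated", "gold")) {
    stop("reference profile must have correlated (or gold) error structure",
         call. = FALSE)
  }
  check_correlated_feasible(clf, ref)
  rc <- clf$recall; sc <- clf$specificity
  rr <- ref$recall; sr <- ref$specificity
  confusion_matrix(
    tp = p * rc + (1 - p) * (1 - sr),
    fp = (1 - p) * (sr - sc),
    fn = p * (rr - rc),
    tn = (1 - p) * sc + p * (1 - rr),
    provenance = "apparent"
  )
}

check_correlated_feasible <- function(clf, ref) {
  if (ref$recall < clf$recall) {
    stop(sprintf(paste0(
      "infeasible correlated model: reference recall (%g) < classifier ",
      "recall (%g); correlated errors require recall_r >= recall_c"),
      ref$recall, clf$recall), call. = FALSE)
  }
  if (ref$specificity < clf$specificity) {
    stop(sprintf(paste0(
      "infeasible correlated model: reference specificity (%g) < classifier ",
      "specificity (%g); correlated errors require spec_r >= spec_c"),
      ref$specificity, clf$specificity), call. = FALSE)
  }
  invisible(TRUE)
}

#' Apparent matrix dispatching on the reference's error structure
#'
#' @inheritParams apparent_matrix_independent
#' @param ref A [reference_profile()]; `"gold"` returns [true_matrix()].
#' @return A [confusion_matrix()].
#' @export
apparent_matrix <- function(p, clf, ref) {
  stopifnot(inherits(ref, "reference_profile"))
  switch(ref$error_structure,
    gold        = true_matrix(p, clf),
    independent = apparent_matrix_independent(p, clf, ref),
    correlated  = apparent_matrix_correlated(p, clf, ref)
  )
}

#' Apparent prevalence under an imperfect reference
#'
#' The reference-positive marginal
#' `p * recall_r + (1 - p) * (1 - spec_r)` — identical under both error
#' structures, since correlated relabelling preserves the reference
#' column marginals. This is the classical apparent-prevalence relation:
#' at low true prevalence the apparent value can be inflated many-fold
#' (e.g. 0.01 -> 0.1864 with an 0.82/0.82 reference, over 18 times too
#' high).
#'
#' @param p True prevalence in (0, 1).
#' @param ref A [reference_profile()].
#' @return A probability.
#' @export
apparent_prevalence <- function(p, ref) {
  check_open_prob(p)
  stopifnot(inherits(ref, "reference_profile"))
  p * ref$recall + (1 - p) * (1 - ref$specificity)
}

#' Transition prevalences of an imperfect reference
#'
#' Classical transition points from the misclassification literature,
#' determined by the reference standard alone:
#' `(1 - spec_r) / (2 - recall_r - spec_r)` for precision and
#' `(1 - recall_r) / (2 - recall_r - spec_r)` for NPV, marking where
#' their apparent values switch between under- and over-estimation. The
#' apparent prevalence crosses the identity line at the same expression
#' as precision's: it is the exact fixed point of
#' [apparent_prevalence()], above which prevalence is under-estimated
#' and below which it is inflated.
#'
#' @param ref A [reference_profile()] with `recall + specificity < 2`
#'   (a gold reference has no transition; requesting one is an error).
#' @param which One of `"precision"`, `"npv"`, `"prevalence"`.
#' @return A probability in (0, 1).
#' @examples
#' transition_prevalence(reference_profile(0.9, 0.9, "independent"), "precision")
#' @export
transition_prevalence <- function(ref, which = c("precision", "npv", "prevalence")) {
  which <- match.arg(which)
  stopifnot(inherits(ref, "reference_profile"))
  denom <- 2 - ref$recall - ref$specificity
  if (denom <= 0) {
    stop("no transition point exists for a gold (error-free) reference",
         call. = FALSE)
  }
  switch(which,
    precision  = (1 - ref$specificity) / denom,
    prevalence = (1 - ref$specificity) / denom,
    npv        = (1 - ref$recall) / denom
  )
}

#' Correct an apparent matrix for independent reference error
#'
#' Algebraic inverse of [apparent_matrix_independent()]. Given an
#' apparent matrix and the reference's known recall and specificity, it
#' recovers the true prevalence by the Rogan-Gladen-type relation
#' `p = (p' - (1 - spec_r)) / (recall_r + spec_r - 1)` where `p'` is the
#' apparent prevalence, then inverts each classifier row (a 2 x 2 linear
#' system per row) to recover the classifier's true recall and
#' specificity. Requires `recall_r + spec_r != 1` (Youden's J of the
#' reference nonzero), otherwise the misclassification map is singular.
#'
#' On noisy or inconsistent empirical input the recovered values can
#' fall outside \[0, 1\]; they are clamped and flagged rather than
#' rejected, so the correction stays usable on real data. A recovered
#' prevalence of exactly 0 or 1 leaves the classifier rates undefined
#' (`NA`) and sets the flag.
#'
#' @param apparent A [confusion_matrix()] (any positive total; it is
#'   normalised internally).
#' @param ref A [reference_profile()] with `error_structure`
#'   `"independent"` or `"gold"`.
#' @return A list with `p` (recovered true prevalence), `clf` (a
#'   [classifier_profile()] with the recovered rates, `NA`-bearing
#'   fields replaced by clamped values where needed), `recall`,
#'   `specificity` (the raw recovered values before clamping) and
#'   `clamped` (logical flag).
#' @examples
#' ref <- reference_profile(0.9, 0.9, "independent")
#' correct_independent(confusion_matrix(90, 170, 90, 650, "apparent"), ref)
#' @export
correct_independent <- function(apparent, ref) {
  stopifnot(inherits(apparent, "confusion_matrix"),
            inherits(ref, "reference_profile"))
  if (!ref$error_structure %in% c("independent", "gold")) {
    stop("correction assumes independent (or gold) reference errors",
         call. = FALSE)
  }
  if (apparent$n <= 0) stop("apparent matrix has zero total", call. = FALSE)
  rr <- ref$recall; sr <- ref$specificity
  j_ref <- rr + sr - 1
  if (j_ref == 0) {
    stop("reference recall + specificity = 1: misclassification map is not invertible",
         call. = FALSE)
  }
  # normalise to proportions
  tp <- apparent$tp / apparent$n; fp <- apparent$fp / apparent$n
  fn <- apparent$fn / apparent$n; tn <- apparent$tn / apparent$n
  p_app <- tp + fn
  p_raw <- (p_app - (1 - sr)) / j_ref

  clamped <- FALSE
  p <- p_raw
  if (p < 0) { p <- 0; clamped <- TRUE }
  if (p > 1) { p <- 1; clamped <- TRUE }

  # invert each classifier row: apparent row cells are a known linear mix of
  # the row's true column masses (x = p*rate_pos, y = (1-p)*rate_neg)
  # top row: tp' = rr*x + (1-sr)*y, with x + y = tp' + fp'
  row1 <- tp + fp
  x1 <- (tp - (1 - sr) * row1) / j_ref      # = p * recall_c
  # bottom row: tn' = (1-rr)*x2 + sr*y2, x2 + y2 = fn' + tn'; y2 = (1-p)*spec_c
  row2 <- fn + tn
  y2 <- (tn - (1 - rr) * row2) / j_ref      # = (1 - p) * spec_c

  recall_raw <- if (p > 0) x1 / p else NA_real_
  spec_raw   <- if (p < 1) y2 / (1 - p) else NA_real_
  if (p != p_raw) {
    recall_raw <- NA_real_
    spec_raw <- NA_real_
  }

  clamp01 <- function(v) {
    if (is.na(v)) return(NA_real_)
    if (v < 0 || v > 1) { clamped <<- TRUE; return(min(max(v, 0), 1)) }
    v
  }
  recall_c <- clamp01(recall_raw)
  spec_c <- clamp01(spec_raw)
  if (clamped) {
    warning("recovered parameters fell outside [0, 1] and were clamped; ",
            "the apparent matrix is inconsistent with the stated reference quality",
            call. = FALSE)
  }
  clf <- if (!is.na(recall_c) && !is.na(spec_c)) {
    classifier_profile(recall_c, spec_c)
  } else NULL
  list(p = p, clf = clf, recall = recall_c, specificity = spec_c,
       clamped = clamped)
}
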