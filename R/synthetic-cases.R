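#' Sample per-case label triples
#'
#' Finite-sample generator with exactly the joint distribution the
#' closed-form models assume, used as the Monte-Carlo oracle for the
#' forward models. For each case:
#' \itemize{
#'   \item truth ~ Bernoulli(`p`);
#'   \item the classifier labels a positive case correctly with
#'     probability `recall_c` and a negative one with `spec_c`;
#'   \item under an \strong{independent} reference, the reference labels
#'     correctly with probability `recall_r` / `spec_r`, regardless of
#'     the classifier;
#'   \item under a \strong{correlated} reference, the reference never
#'     errs on a case the classifier got right; on classifier-error
#'     cases it errs with conditional probability
#'     `(1 - recall_r) / (1 - recall_c)` (positives) or
#'     `(1 - spec_r) / (1 - spec_c)` (negatives), so that the marginal
#'     reference error rates are exactly `1 - recall_r` and
#'     `1 - spec_r`.
#' }
#' Sampling uses an isolated RNG stream: the caller's `.Random.seed` is
#' untouched, and identical `(n, p, clf, ref, seed)` always reproduce
#' the identical sample.
#'
#' @param n Number of cases (positive integer).
#' @param p True prevalence in (0, 1).
#' @param clf A [classifier_profile()].
#' @param ref A [reference_profile()].
#' @param seed Integer seed.
#' @return Object of class `case_sample`: a list with `records` (tibble
#'   with factor columns `truth`, `clf_label`, `ref_label`, levels
#'   `pos`/`neg`), `seed`, and the generating parameters.
#' @export
sample_cases <- function(n, p, clf, ref, seed) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  check_open_prob(p)
  stopifnot(inherits(clf, "classifier_profile"),
            inherits(ref, "reference_profile"))
  if (ref$error_structure == "correlated") check_correlated_feasible(clf, ref)
  n <- as.integer(n)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  truth_pos <- stats::runif(n) < p
  clf_correct <- stats::runif(n) < ifelse(truth_pos, clf$recall, clf$specificity)
  clf_pos <- ifelse(truth_pos, clf_correct, !clf_correct)

  if (ref$error_structure %in% c("gold", "independent")) {
    ref_correct <- stats::runif(n) <
      ifelse(truth_pos, ref$recall, ref$specificity)
  } else {
    # conditional error prob on classifier-error cases; 0 when the
    # classifier is perfect on a class (then rr/sr = 1 by feasibility)
    cond_pos <- if (clf$recall < 1) (1 - ref$recall) / (1 - clf$recall) else 0
    cond_neg <- if (clf$specificity < 1) (1 - ref$specificity) / (1 - clf$specificity) else 0
    err_prob <- ifelse(clf_correct, 0, ifelse(truth_pos, cond_pos, cond_neg))
    ref_correct <- stats::runif(n) >= err_prob
  }
  ref_pos <- ifelse(truth_pos, ref_correct, !ref_correct)

  lab <- function(x) factor(ifelse(x, "pos", "neg"), levels = c("pos", "neg"))
  structure(
    list(
      records = tibble::tibble(truth = lab(truth_pos),
                               clf_label = lab(clf_pos),
                               ref_label = lab(ref_pos)),
      seed = as.integer(seed), n = n, p = p, clf = clf, ref = ref
    ),
    class = "case_sample"
  )
}

#' @export
print.case_sample <- function(x, ...) {
  cat(sprintf("<case_sample n=%d, p=%g, ref errors=%s, seed=%d>\n",
              x$n, x$p, x$ref$error_structure, x$seed))
  invisible(x)
}

#' Cross-tabulate a case sample
#'
#' Counts classifier labels against reference labels (the observable
#' table an accuracy assessment actually sees — the truth column is
#' ignored). Set `against = "truth"` for the audit table against the
#' true classes instead.
#'
#' @param sample A [sample_cases()] result, non-empty.
#' @param against `"reference"` (default) or `"truth"`.
#' @return A [confusion_matrix()] of integer counts; provenance is
#'   `"apparent"` against an imperfect reference, `"true"` against truth
#'   or a gold reference.
#' @export
crosstab <- function(sample, against = c("reference", "truth")) {
  against <- match.arg(against)
  stopifnot(inherits(sample, "case_sample"))
  rec <- sample$records
  if (nrow(rec) == 0) stop("empty sample", call. = FALSE)
  col <- if (against == "truth") rec$truth else rec$ref_label
  clf_pos <- rec$clf_label == "pos"
  col_pos <- col == "pos"
  prov <- if (against == "truth" || sample$ref$error_structure == "gold")
    "true" else "apparent"
  confusion_matrix(
    tp = sum(clf_pos & col_pos),
    fp = sum(clf_pos & !col_pos),
    fn = sum(!clf_pos & col_pos),
    tn = sum(!clf_pos & !col_pos),
    provenance = prov
  )
}

#' Monte-Carlo check of a closed-form apparent matrix
#'
#' Draws `n` cases, cross-tabulates them against the reference, and
#' compares the empirical cell proportions (and derived metrics) with
#' the closed-form matrix from the corresponding forward model. Each
#' cell gets a z-score \eqn{(\hat q - q) / \sqrt{q(1-q)/n}}; the check
#' passes iff every |z| is at most `tolerance_se`.
#'
#' @param p,clf,ref As in [sample_cases()].
#' @param n Number of cases; at least 10^4 recommended.
#' @param seed Integer seed.
#' @param tolerance_se Allowed |z| per cell (default 4).
#' @return Object of class `mc_report`: list with `expected` and
#'   `observed` matrices, per-cell `z` scores, `metrics` (closed-form vs
#'   empirical side by side) and `pass`.
#' @export
mc_check <- function(p, clf, ref, n = 1e6, seed = 1, tolerance_se = 4) {
  expected <- apparent_matrix(p, clf, ref)
  smp <- sample_cases(n, p, clf, ref, seed)
  observed <- crosstab(smp)
  cells <- c("tp", "fp", "fn", "tn")
  q <- vapply(cells, function(cl) expected[[cl]], numeric(1))
  q_hat <- vapply(cells, function(cl) observed[[cl]] / n, numeric(1))
  se <- sqrt(q * (1 - q) / n)
  z <- ifelse(se == 0, ifelse(q_hat == q, 0, Inf), (q_hat - q) / se)
  metrics <- tibble::tibble(
    metric = metric_names(),
    closed_form = unlist(metric_set(expected), use.names = FALSE),
    empirical = unlist(metric_set(observed), use.names = FALSE)
  )
  structure(
    list(expected = expected, observed = observed, n = n,
         z = z, tolerance_se = tolerance_se, metrics = metrics,
         pass = all(abs(z) <= tolerance_se)),
    class = "mc_report"
  )
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("<mc_report n=%g, %s>\n", x$n,
              if (x$pass) "PASS" else "FAIL"))
  cat("  per-cell z-scores (tolerance ", x$tolerance_se, "):\n", sep = "")
  print(round(x$z, 2))
  invisible(x)
}

#' Export a case sample to CSV
#'
#' Columns `truth,ref_label,clf_label` with values `pos`/`neg`.
#'
#' @param sample A [sample_cases()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_case_sample <- function(sample, path) {
  stopifnot(inherits(sample, "case_sample"))
  utils::write.csv(
    sample$records[, c("truth", "ref_label", "clf_label")],
    path, row.names = FALSE
  )
  invisible(path)
}
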