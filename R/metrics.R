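#' @keywords internal
#' Safe ratio: zero denominator yields NA_real_ (the undefined sentinel),
#' never an error, so prevalence sweeps over degenerate corners never abort.
safe_div <- function(num, den) {
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (den == 0) return(NA_real_)
  num / den
}

#' Basic per-class rates of a confusion matrix
#'
#' Recall (sensitivity, producer's accuracy), precision (positive
#' predictive value, user's accuracy), specificity (true negative rate)
#' and negative predictive value. Any zero denominator returns `NA`
#' rather than raising, so that degenerate matrices (e.g. an empty
#' classifier-positive row) propagate a sentinel instead of aborting.
#'
#' @param m A [confusion_matrix()].
#' @return Named list with `recall`, `precision`, `specificity`, `npv`;
#'   each a probability or `NA`.
#' @examples
#' rate_metrics(confusion_matrix(90, 170, 90, 650))
#' @export
rate_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  list(
    recall      = safe_div(m$tp, m$tp + m$fn),
    precision   = safe_div(m$tp, m$tp + m$fp),
    specificity = safe_div(m$tn, m$tn + m$fp),
    npv         = safe_div(m$tn, m$tn + m$fn)
  )
}

#' Composite accuracy metrics
#'
#' Overall accuracy `(tp + tn) / n`, Youden's J (true skill statistic,
#' `recall + specificity - 1`), the F1 score `2 tp / (2 tp + fn + fp)`,
#' and the Matthews correlation coefficient
#' `(tp * tn - fp * fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' MCC is the phi (Pearson) correlation between the classifier and
#' reference label vectors; it is `NA` whenever a marginal is zero.
#'
#' @param m A [confusion_matrix()].
#' @return Named list with `accuracy`, `youden_j`, `f1`, `mcc`; each a
#'   real value or `NA`.
#' @export
composite_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  r <- rate_metrics(m)
  youden_j <- if (is.na(r$recall) || is.na(r$specificity)) NA_real_ else
    r$recall + r$specificity - 1
  marg <- c(m$tp + m$fp, m$tp + m$fn, m$tn + m$fp, m$tn + m$fn)
  mcc <- if (any(marg == 0)) NA_real_ else
    (m$tp * m$tn - m$fp * m$fn) / sqrt(prod(marg))
  list(
    accuracy = safe_div(m$tp + m$tn, m$n),
    youden_j = youden_j,
    f1       = safe_div(2 * m$tp, 2 * m$tp + m$fn + m$fp),
    mcc      = mcc
  )
}

#' Likelihood ratios
#'
#' `lr_pos = recall / (1 - specificity)` and
#' `lr_neg = (1 - recall) / specificity`. A perfect specificity gives
#' `lr_pos = Inf`; a zero specificity gives `lr_neg = Inf`. An undefined
#' recall or specificity propagates `NA`. Values of 1 indicate a
#' classification with no discriminating ability.
#'
#' @param m A [confusion_matrix()].
#' @return Named list with `lr_pos`, `lr_neg`; non-negative reals, `Inf`,
#'   or `NA`.
#' @export
likelihood_ratios <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  r <- rate_metrics(m)
  lr_one <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) return(Inf)
    num / den
  }
  list(
    lr_pos = lr_one(r$recall, 1 - r$specificity),
    lr_neg = lr_one(1 - r$recall, r$specificity)
  )
}

#' Canonical metric names
#'
#' The eleven metrics plus prevalence, in the fixed serialisation order.
#' @return Character vector.
#' @export
metric_names <- function() {
  c("accuracy", "recall", "precision", "specificity", "npv",
    "youden_j", "f1", "mcc", "lr_pos", "lr_neg", "prevalence")
}

#' Full metric set of a confusion matrix
#'
#' Computes all eleven accuracy metrics plus the prevalence of the
#' reference-positive class from one matrix. Undefined metrics are `NA`;
#' likelihood ratios may be `Inf`.
#'
#' @param m A [confusion_matrix()] with positive total.
#' @return An object of class `metric_set`: a named list in the order of
#'   [metric_names()].
#' @examples
#' ms <- metric_set(confusion_matrix(170, 90, 10, 730))
#' round(ms$precision, 2)  # 0.65
#' @export
metric_set <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$n <= 0) stop("metric set undefined for a zero-total matrix", call. = FALSE)
  out <- c(
    composite_metrics(m)["accuracy"],
    rate_metrics(m),
    composite_metrics(m)[c("youden_j", "f1", "mcc")],
    likelihood_ratios(m),
    list(prevalence = prevalence_of(m))
  )
  structure(out[metric_names()], class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  cat("<metric_set>\n")
  vals <- vapply(x, function(v) {
    if (is.na(v)) "NA" else if (is.infinite(v)) "Inf" else
      formatC(v, digits = digits, format = "f")
  }, character(1))
  for (nm in names(vals)) cat(sprintf("  %-12s %s\n", nm, vals[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(lapply(unclass(x), identity))
}

#' Serialise a metric set
#'
#' CSV writes undefined metrics as empty fields and infinities as `"inf"`;
#' JSON writes `null` and `"inf"` respectively.
#'
#' @param x A [metric_set()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metric_set <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "metric_set"))
  if (format == "csv") {
    vals <- vapply(x, function(v) {
      if (is.na(v)) "" else if (is.infinite(v)) "inf" else
        format(v, digits = 15)
    }, character(1))
    writeLines(c(paste(names(vals), collapse = ","),
                 paste(vals, collapse = ",")), path)
  } else {
    obj <- lapply(unclass(x), function(v) {
      if (is.na(v)) NULL else if (is.infinite(v)) "inf" else v
    })
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}
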