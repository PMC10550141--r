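#' Binary confusion matrix
#'
#' Container for the four cells of a 2 x 2 confusion matrix in the fixed
#' orientation used throughout the package: **columns are the reference
#' labels, rows are the classifier labels**. So `tp` is
#' classifier-positive and reference-positive, `fp` classifier-positive
#' and reference-negative, `fn` classifier-negative and
#' reference-positive, `tn` classifier-negative and reference-negative.
#'
#' Cells are non-negative reals, not integers: the closed-form error
#' models produce fractional expected counts (e.g. 793.8 cases at
#' prevalence 0.99 and N = 1000). Rounding happens only at display time
#' or when counts come from an actual finite sample.
#'
#' @param tp,fp,fn,tn Non-negative cell masses (proportions or counts).
#' @param provenance Either `"true"` (computed against an error-free
#'   gold-standard reference) or `"apparent"` (against an imperfect
#'   reference). A bookkeeping flag; it does not change any computation.
#' @return An object of class `confusion_matrix`: a list with elements
#'   `tp`, `fp`, `fn`, `tn`, `n` (the cell sum) and `provenance`.
#' @examples
#' m <- confusion_matrix(90, 170, 90, 650)
#' prevalence_of(m)
#' @export
confusion_matrix <- function(tp, fp, fn, tn, provenance = c("true", "apparent")) {
  provenance <- match.arg(provenance)
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells))) {
    stop("confusion matrix cells must be finite numbers", call. = FALSE)
  }
  if (any(cells < 0)) {
    stop("confusion matrix cells must be non-negative", call. = FALSE)
  }
  # store as doubles: integer cells overflow in MCC's marginal products
  tp <- as.double(tp); fp <- as.double(fp)
  fn <- as.double(fn); tn <- as.double(tn)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
         provenance = provenance),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<confusion_matrix (%s), N = %s>\n", x$provenance,
              format(x$n, digits = max(digits, 4))))
  tab <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
                dimnames = list(classifier = c("pos", "neg"),
                                reference = c("pos", "neg")))
  print(round(tab, digits))
  invisible(x)
}

#' @export
as.data.frame.confusion_matrix <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n,
             provenance = x$provenance)
}

#' Rescale a confusion matrix to a new total
#'
#' Multiplies every cell by `n / current total`. Typically used to turn a
#' proportion-space matrix (total mass 1) into expected counts at sample
#' size `n`. Expected counts are real-valued; no rounding is applied.
#'
#' @param m A [confusion_matrix()].
#' @param n New positive total.
#' @return A `confusion_matrix` with cell sum `n`.
#' @export
scale_matrix <- function(m, n) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!is.finite(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (m$n <= 0) stop("cannot rescale a zero-total matrix", call. = FALSE)
  k <- n / m$n
  confusion_matrix(m$tp * k, m$fp * k, m$fn * k, m$tn * k,
                   provenance = m$provenance)
}

#' Prevalence of the reference-positive class
#'
#' The proportion of reference-positive cases, `(tp + fn) / n`. For an
#' apparent matrix this is the *apparent* prevalence, which can differ
#' substantially from the true prevalence that generated it.
#'
#' @param m A [confusion_matrix()] with positive total.
#' @return A probability in \[0, 1\].
#' @export
prevalence_of <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$n <= 0) stop("prevalence undefined for a zero-total matrix", call. = FALSE)
  (m$tp + m$fn) / m$n
}
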