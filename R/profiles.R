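#' Classifier quality profile
#'
#' Per-class correctness rates of the classification under evaluation:
#' its true recall (probability a truly positive case is labelled
#' positive) and true specificity (probability a truly negative case is
#' labelled negative).
#'
#' @param recall,specificity Probabilities in \[0, 1\].
#' @return Object of class `classifier_profile`.
#' @export
classifier_profile <- function(recall, specificity) {
  check_prob(recall, "recall")
  check_prob(specificity, "specificity")
  structure(list(recall = recall, specificity = specificity),
            class = "classifier_profile")
}

#' Reference standard profile
#'
#' Per-class correctness rates of the reference standard a classification
#' is scored against, plus the structure of its errors relative to the
#' classifier's:
#' \describe{
#'   \item{gold}{error-free (`recall = specificity = 1` enforced);}
#'   \item{independent}{reference mistakes occur regardless of whether
#'     the classifier erred on the case (conditional independence);}
#'   \item{correlated}{reference mistakes land only on cases the
#'     classifier also mislabelled (maximal conditional dependence).}
#' }
#'
#' @param recall,specificity Probabilities in \[0, 1\].
#' @param error_structure One of `"gold"`, `"independent"`, `"correlated"`.
#' @return Object of class `reference_profile`.
#' @export
reference_profile <- function(recall, specificity,
                              error_structure = c("gold", "independent", "correlated")) {
  error_structure <- match.arg(error_structure)
  check_prob(recall, "recall")
  check_prob(specificity, "specificity")
  if (error_structure == "gold" && (recall != 1 || specificity != 1)) {
    stop("a gold reference must have recall = specificity = 1", call. = FALSE)
  }
  structure(list(recall = recall, specificity = specificity,
                 error_structure = error_structure),
            class = "reference_profile")
}

#' A gold-standard (error-free) reference profile
#' @return `reference_profile(1, 1, "gold")`
#' @export
gold_reference <- function() reference_profile(1, 1, "gold")

#' @export
print.classifier_profile <- function(x, ...) {
  cat(sprintf("<classifier_profile recall=%g specificity=%g>\n",
              x$recall, x$specificity))
  invisible(x)
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile recall=%g specificity=%g errors=%s>\n",
              x$recall, x$specificity, x$error_structure))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_open_prob <- function(p, name = "prevalence") {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    stop(sprintf("%s must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(p)
}
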