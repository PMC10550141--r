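#' Define a sweep scenario
#'
#' Bundles a classifier profile, a reference profile, a prevalence grid
#' and a display sample size under a label.
#'
#' @param label Unique scenario label.
#' @param clf A [classifier_profile()].
#' @param ref A [reference_profile()].
#' @param grid Strictly increasing vector of prevalences in (0, 1);
#'   defaults to [prevalence_grid()].
#' @param n Positive sample size used when scaling matrices to counts.
#' @return Object of class `scenario`.
#' @export
scenario <- function(label, clf, ref, grid = prevalence_grid(), n = 1000) {
  stopifnot(is.character(label), length(label) == 1,
            inherits(clf, "classifier_profile"),
            inherits(ref, "reference_profile"))
  if (length(grid) < 1 || any(grid <= 0) || any(grid >= 1) ||
      is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing with all values in (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (ref$error_structure == "correlated") check_correlated_feasible(clf, ref)
  structure(list(label = label, clf = clf, ref = ref, grid = grid, n = n),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': clf %g/%g vs ref %g/%g (%s), %d grid points, n=%g>\n",
              x$label, x$clf$recall, x$clf$specificity,
              x$ref$recall, x$ref$specificity, x$ref$error_structure,
              length(x$grid), x$n))
  invisible(x)
}

#' Standard prevalence grid
#'
#' Prevalence from 0.05 to 0.95 in 0.05 increments, with endpoints 0.01
#' and 0.99 replacing 0 and 1 (the extremes are avoided because several
#' metrics degenerate there): 21 points in all. Constructed from integer
#' hundredths so equality comparisons are exact.
#'
#' @return Numeric vector of length 21, strictly increasing.
#' @export
prevalence_grid <- function() {
  c(1L, seq(5L, 95L, by = 5L), 99L) / 100
}

#' Built-in scenario set
#'
#' The standard sweep: a good classifier (recall = specificity = 0.8,
#' J = 0.6) evaluated against imperfect references containing 2%
#' (0.98/0.98), 10% (0.90/0.90) and 18% (0.82/0.82) error, each under
#' independent and under correlated error structures (6 scenarios), plus
#' a coin-tossing classifier (0.5/0.5, J = 0) evaluated against a 30%
#' correlated-error reference (0.7/0.7). All use the standard 21-point
#' grid and n = 1000.
#'
#' @return List of 7 [scenario()] objects, named by label.
#' @export
standard_scenarios <- function() {
  good <- classifier_profile(0.8, 0.8)
  coin <- classifier_profile(0.5, 0.5)
  mk <- function(label, clf, err, structure) {
    q <- 1 - err
    scenario(label, clf, reference_profile(q, q, structure))
  }
  sc <- list(
    mk("ind02",  good, 0.02, "independent"),
    mk("ind10",  good, 0.10, "independent"),
    mk("ind18",  good, 0.18, "independent"),
    mk("corr02", good, 0.02, "correlated"),
    mk("corr10", good, 0.10, "correlated"),
    mk("corr18", good, 0.18, "correlated"),
    mk("coin_corr30", coin, 0.30, "correlated")
  )
  names(sc) <- vapply(sc, `[[`, character(1), "label")
  sc
}

sweep_columns <- function() {
  c("scenario", "p", "provenance", "tp", "fp", "fn", "tn",
    "accuracy", "recall", "precision", "specificity", "npv",
    "youden_j", "f1", "mcc", "lr_pos", "lr_neg", "prevalence_apparent")
}

sweep_row <- function(label, p, m, n, role) {
  ms <- metric_set(m)
  counts <- scale_matrix(m, n)
  tibble::tibble(
    scenario = label, p = p, provenance = role,
    tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
    accuracy = ms$accuracy, recall = ms$recall, precision = ms$precision,
    specificity = ms$specificity, npv = ms$npv, youden_j = ms$youden_j,
    f1 = ms$f1, mcc = ms$mcc, lr_pos = ms$lr_pos, lr_neg = ms$lr_neg,
    prevalence_apparent = ms$prevalence
  )
}

#' Run a prevalence sweep
#'
#' For every scenario and every grid point, computes the true confusion
#' matrix (gold-standard reference) and the apparent matrix under the
#' scenario's imperfect reference, with the full metric set for each.
#' Entirely deterministic: no randomness is involved.
#'
#' @param scenarios A [scenario()] or list of them (e.g.
#'   [standard_scenarios()]).
#' @return A tibble with one `"true"` row and one `"apparent"` row per
#'   (scenario, grid point). Cells `tp`..`tn` are expected counts at the
#'   scenario's `n`; `prevalence_apparent` is the prevalence of that
#'   row's own matrix (equal to `p` on true rows).
#' @examples
#' tab <- run_sweep(standard_scenarios())
#' nrow(tab)  # 7 * 21 * 2 = 294
#' @export
run_sweep <- function(scenarios) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0,
            all(vapply(scenarios, inherits, logical(1), "scenario")))
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique", call. = FALSE)
  rows <- lapply(scenarios, function(sc) {
    per_p <- lapply(sc$grid, function(p) {
      tr <- tryCatch(true_matrix(p, sc$clf), error = function(e) {
        stop(sprintf("scenario '%s', p = %g: %s", sc$label, p, conditionMessage(e)),
             call. = FALSE)
      })
      ap <- tryCatch(apparent_matrix(p, sc$clf, sc$ref), error = function(e) {
        stop(sprintf("scenario '%s', p = %g: %s", sc$label, p, conditionMessage(e)),
             call. = FALSE)
      })
      dplyr::bind_rows(sweep_row(sc$label, p, tr, sc$n, "true"),
                       sweep_row(sc$label, p, ap, sc$n, "apparent"))
    })
    dplyr::bind_rows(per_p)
  })
  out <- dplyr::bind_rows(rows)
  out[, sweep_columns()]
}

#' Per-scenario extrema of an apparent metric
#'
#' Summarises the apparent rows of a sweep table: per scenario, the
#' minimum and maximum of the chosen metric over the grid, the
#' prevalence at which the maximum occurs, and how many grid points were
#' excluded because the metric was undefined there.
#'
#' @param table A sweep table from [run_sweep()].
#' @param metric One of [metric_names()] (with `prevalence` addressed as
#'   `prevalence_apparent`).
#' @return A tibble with columns `scenario`, `min`, `max`, `p_at_max`,
#'   `n_undefined`.
#' @export
summarize_extrema <- function(table, metric) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("sweep table is empty", call. = FALSE)
  }
  valid <- setdiff(sweep_columns(),
                   c("scenario", "p", "provenance", "tp", "fp", "fn", "tn"))
  if (!is.character(metric) || length(metric) != 1 || !metric %in% valid) {
    stop("unknown metric; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  table |>
    dplyr::filter(.data$provenance == "apparent") |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_undefined = sum(is.na(.data[[metric]])),
      min = if (all(is.na(.data[[metric]]))) NA_real_ else
        min(.data[[metric]], na.rm = TRUE),
      max = if (all(is.na(.data[[metric]]))) NA_real_ else
        max(.data[[metric]], na.rm = TRUE),
      p_at_max = if (all(is.na(.data[[metric]]))) NA_real_ else
        .data$p[which.max(.data[[metric]])],
      .groups = "drop"
    ) |>
    dplyr::select("scenario", "min", "max", "p_at_max", "n_undefined")
}

#' Write a sweep table to CSV
#'
#' Undefined metrics become empty fields, infinities `"Inf"`.
#'
#' @param table Sweep table from [run_sweep()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
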