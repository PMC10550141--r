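# Independent oracles used across the suite.

# Phi (Pearson) correlation of the two binary label vectors obtained by
# expanding an integer-count matrix into per-case labels. Brute-force
# cross-check for MCC; intentionally avoids the package's own formula.
phi_oracle <- function(tp, fp, fn, tn) {
  clf <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  ref <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  suppressWarnings(stats::cor(clf, ref))
}

# small lattice of model parameters used by property tests
param_lattice <- function() {
  expand.grid(
    p = c(0.01, 0.1, 0.3, 0.5, 0.7, 0.99),
    rc = c(0.55, 0.8, 0.95),
    sc = c(0.6, 0.8),
    rr = c(0.82, 0.9, 0.98),
    sr = c(0.85, 0.95),
    KEEP.OUT.ATTRS = FALSE
  )
}

cells_of <- function(m) c(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn)

# build a case_sample object from explicit label triples ("pos"/"neg")
manual_sample <- function(truth, clf_label, ref_label,
                          structure_ = "independent") {
  lab <- function(x) factor(x, levels = c("pos", "neg"))
  structure(
    list(
      records = tibble::tibble(truth = lab(truth), clf_label = lab(clf_label),
                               ref_label = lab(ref_label)),
      seed = 0L, n = length(truth), p = 0.5,
      clf = classifier_profile(0.8, 0.8),
      ref = reference_profile(0.9, 0.9, structure_)
    ),
    class = "case_sample"
  )
}
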