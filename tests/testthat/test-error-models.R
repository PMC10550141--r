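good <- classifier_profile(0.8, 0.8)
ref_ind_10 <- reference_profile(0.9, 0.9, "independent")
ref_cor_10 <- reference_profile(0.9, 0.9, "correlated")

test_that("true matrix follows prevalence x classifier-quality products", {
  m <- true_matrix(0.1, good)
  expect_equal(cells_of(m), c(tp = 0.08, fp = 0.18, fn = 0.02, tn = 0.72))
  expect_equal(m$n, 1)
  expect_equal(prevalence_of(m), 0.1)

  expect_equal(cells_of(true_matrix(0.5, classifier_profile(1, 1))),
               c(tp = 0.5, fp = 0, fn = 0, tn = 0.5))
  m3 <- true_matrix(0.3, classifier_profile(0.9, 0.7))
  expect_equal(cells_of(m3), c(tp = 0.27, fp = 0.21, fn = 0.03, tn = 0.49))
  expect_equal(sum(cells_of(m3)), 1)

  expect_error(true_matrix(0, good), "strictly inside")
  expect_error(true_matrix(1, good), "strictly inside")
})

test_that("independent-error model reproduces the redistributed worked matrix", {
  m <- scale_matrix(apparent_matrix_independent(0.1, good, ref_ind_10), 1000)
  expect_equal(cells_of(m), c(tp = 90, fp = 170, fn = 90, tn = 650))
  expect_equal(m$provenance, "apparent")

  # gold reference collapses to the true matrix
  for (p in c(0.05, 0.35, 0.8)) {
    expect_equal(cells_of(apparent_matrix_independent(p, good, gold_reference())),
                 cells_of(true_matrix(p, good)))
  }
  expect_error(apparent_matrix_independent(0.1, good, ref_cor_10), "independent")
})

test_that("correlated-error model reproduces the relabelled worked matrix", {
  m <- scale_matrix(apparent_matrix_correlated(0.1, good, ref_cor_10), 1000)
  expect_equal(cells_of(m), c(tp = 170, fp = 90, fn = 10, tn = 730))

  m2 <- apparent_matrix_correlated(0.5, good,
                                   reference_profile(0.82, 0.82, "correlated"))
  expect_equal(cells_of(m2), c(tp = 0.49, fp = 0.01, fn = 0.01, tn = 0.49))
  expect_equal(composite_metrics(m2)$mcc, 0.96)

  expect_equal(cells_of(apparent_matrix_correlated(0.3, good, gold_reference())),
               cells_of(true_matrix(0.3, good)))

  # infeasible relabelling names the violated inequality
  expect_error(
    apparent_matrix_correlated(0.1, good,
                               reference_profile(0.7, 0.9, "correlated")),
    "recall_r >= recall_c")
  expect_error(
    apparent_matrix_correlated(0.1, good,
                               reference_profile(0.9, 0.7, "correlated")),
    "spec_r >= spec_c")
})

test_that("apparent prevalence is the reference-positive marginal under both structures", {
  expect_equal(apparent_prevalence(0.1, ref_ind_10), 0.18)
  expect_equal(apparent_prevalence(0.3, gold_reference()), 0.3)
  p_low <- apparent_prevalence(0.01, reference_profile(0.82, 0.82, "independent"))
  expect_equal(p_low, 0.1864)
  expect_gt(p_low / 0.01, 18)

  for (p in c(0.05, 0.4, 0.85)) {
    ind <- prevalence_of(apparent_matrix_independent(p, good, ref_ind_10))
    cor <- prevalence_of(apparent_matrix_correlated(p, good, ref_cor_10))
    expect_equal(ind, apparent_prevalence(p, ref_ind_10), tolerance = 1e-12)
    expect_equal(cor, ind, tolerance = 1e-12)
  }
})

test_that("transition prevalences locate the sign change of apparent bias", {
  expect_equal(transition_prevalence(ref_ind_10, "precision"), 0.5)
  ref_as <- reference_profile(0.95, 0.85, "independent")
  expect_equal(transition_prevalence(ref_as, "precision"), 0.75)
  expect_equal(transition_prevalence(ref_as, "npv"), 0.25)
  expect_error(transition_prevalence(gold_reference(), "precision"),
               "no transition")

  # prevalence transition is the fixed point of the apparent-prevalence map
  t_prev <- transition_prevalence(ref_ind_10, "prevalence")
  expect_equal(t_prev, 0.5)
  expect_equal(apparent_prevalence(t_prev, ref_ind_10), t_prev)
})

test_that("correction inverts the independent forward model", {
  res <- correct_independent(confusion_matrix(90, 170, 90, 650, "apparent"),
                             ref_ind_10)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$recall, 0.8, tolerance = 1e-12)
  expect_equal(res$specificity, 0.8, tolerance = 1e-12)
  expect_false(res$clamped)

  # gold reference: correction returns the matrix's own prevalence and rates
  m <- confusion_matrix(27, 21, 3, 49, "apparent")
  res_g <- correct_independent(m, gold_reference())
  expect_equal(res_g$p, prevalence_of(m))
  expect_equal(res_g$recall, rate_metrics(m)$recall)
  expect_equal(res_g$specificity, rate_metrics(m)$specificity)

  # boundary: apparent prevalence equal to the reference false-positive rate
  # recovers p = 0, leaving classifier rates undefined and flagged
  ref82 <- reference_profile(0.82, 0.82, "independent")
  m_bound <- confusion_matrix(0.09, 0.09, 0.09, 0.73, "apparent")
  expect_equal(prevalence_of(m_bound), 0.18)
  expect_warning(res_b <- correct_independent(m_bound, ref82), "clamped")
  expect_equal(res_b$p, 0)
  expect_true(res_b$clamped)
  expect_true(is.na(res_b$recall))

  expect_error(
    correct_independent(m, reference_profile(0.3, 0.7, "independent")),
    "not invertible")
})

test_that("forward models conserve row marginals and total mass over a lattice", {
  lat <- param_lattice()
  for (i in seq_len(nrow(lat))) {
    with(lat[i, ], {
      clf <- classifier_profile(rc, sc)
      tm <- true_matrix(p, clf)
      ai <- apparent_matrix_independent(p, clf,
              reference_profile(rr, sr, "independent"))
      expect_equal(sum(cells_of(ai)), 1, tolerance = 1e-12)
      expect_true(all(cells_of(ai) >= 0))
      expect_equal(ai$tp + ai$fp, tm$tp + tm$fp, tolerance = 1e-12)
      expect_equal(ai$fn + ai$tn, tm$fn + tm$tn, tolerance = 1e-12)
      if (rr >= rc && sr >= sc) {
        ac <- apparent_matrix_correlated(p, clf,
                reference_profile(rr, sr, "correlated"))
        expect_equal(sum(cells_of(ac)), 1, tolerance = 1e-12)
        expect_true(all(cells_of(ac) >= -1e-15))
        expect_equal(ac$tp + ac$fp, tm$tp + tm$fp, tolerance = 1e-12)
        expect_equal(ac$fn + ac$tn, tm$fn + tm$tn, tolerance = 1e-12)
        expect_equal(prevalence_of(ac), prevalence_of(ai), tolerance = 1e-12)
      }
    })
  }
})

test_that("recall, specificity and J from a gold reference equal the profile at every prevalence", {
  clf <- classifier_profile(0.9, 0.7)
  for (p in prevalence_grid()) {
    r <- rate_metrics(true_matrix(p, clf))
    expect_equal(r$recall, 0.9, tolerance = 1e-12)
    expect_equal(r$specificity, 0.7, tolerance = 1e-12)
    expect_equal(composite_metrics(true_matrix(p, clf))$youden_j, 0.6,
                 tolerance = 1e-12)
  }
})

test_that("round trip: correction recovers generating parameters to 1e-10", {
  lat <- param_lattice()
  for (i in seq_len(nrow(lat))) {
    with(lat[i, ], {
      clf <- classifier_profile(rc, sc)
      ref <- reference_profile(rr, sr, "independent")
      res <- correct_independent(apparent_matrix_independent(p, clf, ref), ref)
      expect_equal(res$p, p, tolerance = 1e-10)
      expect_equal(res$recall, rc, tolerance = 1e-10)
      expect_equal(res$specificity, sc, tolerance = 1e-10)
      expect_false(res$clamped)
    })
  }
})
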