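test_that("single-comparison Dunnett p-value is the univariate tail", {
  expect_equal(dunnett_pvalue(1.959964), 0.025, tolerance = 1e-6)
  expect_equal(dunnett_pvalue(0), 0.5)
  expect_equal(dunnett_pvalue(2, df = 10), pt(2, 10, lower.tail = FALSE))
})

test_that("joint Dunnett p-values match a numerical-integration oracle", {
  # frozen from the 1-D conditional-integration oracle: the classical
  # two-comparison one-sided critical value 2.2121 at corr 0.5 gives p 0.025
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(dunnett_pvalue(c(2.2121, 0.3), C), 0.0250022, tolerance = 1e-5)
  # the p-value depends on the statistics only through their maximum
  expect_equal(dunnett_pvalue(c(2.2121, 2.2121), C),
               dunnett_pvalue(c(2.2121, -1), C))
  for (case in list(c(1.5, 0.3), c(2.5, 0.7), c(0, 0.5), c(-1, 0.2))) {
    Cr <- matrix(c(1, case[2], case[2], 1), 2)
    expect_equal(dunnett_pvalue(c(case[1], case[1]), Cr),
                 1 - bvn_max_below(case[1], case[2]), tolerance = 1e-6)
  }
})

test_that("perfect-correlation limit collapses to the univariate test", {
  # the limit gap and the quadrature error are each O(1e-4) this close to
  # singularity, so the comparison is at 1e-3
  C <- matrix(c(1, 1 - 1e-6, 1 - 1e-6, 1), 2)
  expect_lt(abs(dunnett_pvalue(c(1.7, 1.7), C) -
                  pnorm(1.7, lower.tail = FALSE)), 1e-3)
  # monotone approach from above: higher correlation shrinks the joint
  # p-value towards the univariate tail, never below it
  ps <- vapply(c(0.5, 0.9, 0.99, 1 - 1e-6), function(r)
    dunnett_pvalue(c(1.7, 1.7), matrix(c(1, r, r, 1), 2)), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= pnorm(1.7, lower.tail = FALSE) - 1e-3))
})

test_that("Dunnett p-value rejects malformed input", {
  expect_error(dunnett_pvalue(numeric(0)), "empty")
  expect_error(dunnett_pvalue(c(1, 2), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(dunnett_pvalue(c(1, 2), matrix(c(1, 0.2, 0.6, 1), 2)),
               "symmetric")
  expect_error(dunnett_pvalue(c(1, 2)), "correlation matrix")
})

test_that("inverse-normal combination behaves per its closed form", {
  expect_equal(combine_inverse_normal(0.5, 0.5), 0.5)
  expect_equal(combine_inverse_normal(0.025, 0.025), 0.0027873,
               tolerance = 1e-5)
  expect_equal(combine_inverse_normal(0.3, 1), 1)
  expect_equal(combine_inverse_normal(1e-12, 1), 1)
  # symmetric in the (p, w) pairs
  expect_equal(combine_inverse_normal(0.1, 0.7, 0.6, 0.8),
               combine_inverse_normal(0.7, 0.1, 0.8, 0.6))
  # monotone in each argument
  grid <- seq(0.05, 0.95, by = 0.15)
  p <- vapply(grid, combine_inverse_normal, numeric(1), p2 = 0.3)
  expect_true(all(diff(p) > 0))
  expect_error(combine_inverse_normal(0, 0.5), "p-values")
  expect_error(combine_inverse_normal(0.5, 0.5, w1 = 1, w2 = 1), "weights")
})

test_that("Fisher combination matches the chi-square tail", {
  expect_equal(combine_fisher(1, 1), 1)
  # frozen oracle: 1 - F_chisq4(-2 ln 0.01) = 0.0560517
  expect_equal(combine_fisher(0.1, 0.1), 0.0560517, tolerance = 1e-6)
  p <- vapply(seq(0.05, 0.95, by = 0.15), combine_fisher, numeric(1),
              p2 = 0.3)
  expect_true(all(diff(p) > 0))
  expect_error(combine_fisher(-0.1, 0.5), "p-values")
})

test_that("closed test rejects exactly per the closure-tree enumeration", {
  # K = 2, arm 1 selected; both stage-wise statistics strongly significant,
  # so H_{12} and H_1 are rejected but H_2 has no stage-2 data and stays
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit1 <- make_fit(beta = c(4, 3.9), tau = c(1, 1), corr = C)
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_top(1))
  expect_equal(sel$selected, 1L)
  fit2 <- make_fit(beta = 4, tau = 1, arms = 1, scope = "stage2")
  ct <- closed_test(fit1, fit2, sel, alpha = 0.025)
  h <- ct$hypotheses
  expect_true(h$reject[h$S == "1,2"])
  expect_true(h$reject[h$S == "1"])
  expect_false(h$reject[h$S == "2"])
  expect_equal(h$p_combined[h$S == "2"], 1)   # untestable: p2 treated as 1
  expect_true(is.na(h$p2[h$S == "2"]))
  expect_equal(ct$elementary$reject, c(TRUE, FALSE))
})

test_that("uninformative stage-wise p-values reject nothing", {
  fit1 <- make_fit(beta = c(-5, -6), tau = c(1, 1),
                   corr = matrix(c(1, 0.5, 0.5, 1), 2))
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_top(1))
  fit2 <- make_fit(beta = -5, tau = 1, arms = 1)
  ct <- closed_test(fit1, fit2, sel, alpha = 0.5)
  expect_false(any(ct$hypotheses$reject))
  expect_false(any(ct$elementary$reject))
})

test_that("futility stop tests nothing and errors are explicit", {
  fit1 <- make_fit(beta = c(0.1, 0.2), tau = c(1, 1),
                   corr = matrix(c(1, 0.5, 0.5, 1), 2))
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_threshold(Inf))
  ct <- closed_test(fit1, NULL, sel)
  expect_false(any(ct$elementary$reject))
  expect_true(all(ct$hypotheses$p_combined == 1))

  sel2 <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                     select_top(1))
  expect_error(closed_test(fit1, NULL, sel2), "stage-2 fit is required")
})

test_that("closure is monotone on simulated replications", {
  set.seed(31)
  scs <- list(tiny_scenario(mu_Y = c(0, 0.2, 0.3)),
              inhance_scenario(J = 30))
  for (sc in scs) {
    for (r in 1:15) {
      tr <- fit_trial(sc, adjustment = c(1, 2))
      ct <- closed_test(tr$fit1, tr$fit2, tr$selection, alpha = 0.1,
                        weights = sc$stage_weights)
      h <- ct$hypotheses
      expect_true(all(h$p1 >= 0 & h$p1 <= 1))
      expect_true(all(h$p_combined >= 0 & h$p_combined <= 1))
      members <- strsplit(h$S, ",")
      for (k in ct$elementary$arm[ct$elementary$reject]) {
        inS <- vapply(members, function(s) as.character(k) %in% s,
                      logical(1))
        expect_true(all(h$reject[inS]))     # every H_S containing k rejected
      }
      if (any(ct$elementary$reject))
        expect_true(h$reject[which.max(nchar(h$S))])  # global intersection
    }
  }
})
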