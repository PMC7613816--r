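test_that("a single intervention leaves the conditional mean untruncated", {
  # K = 1: the ranking event imposes no constraint, so c1 = +Inf, c2 = -Inf
  set.seed(41)
  sc <- amad_scenario(K = 1, J = 30, mu_Y = c(0, 0.2), rho = c(0.1, 0.6))
  tr <- fit_trial(sc)
  b <- build_sufficient_stats(tr$fit1, tr$fit2, tr$selection, 1)
  expect_equal(b$c1, Inf)
  expect_equal(b$c2, -Inf)
  # untruncated conditional mean tau2^2 Z / (tau1^2 + tau2^2)
  expect_equal(umvcue(b), b$tau2_sq * b$Z[1] / (b$tau1_sq + b$tau2_sq))
  expect_equal(umvcue(b), b$m)
})

test_that("hand-specified two-arm bundle reproduces the worked solution", {
  # unit variances, diagonal V, betahat1 = (1, 0), betahat2_s = 0.5:
  # Z_{s,s} = 1.5, m = 0.75, eta = 1/sqrt(2), single upper bound c1 = 1.5
  fit1 <- make_fit(beta = c(1, 0), tau = c(1, 1), corr = diag(2))
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_top(1))
  fit2 <- make_fit(beta = 0.5, tau = 1, arms = 1, scope = "stage2")
  b <- build_sufficient_stats(fit1, fit2, sel, 1)
  expect_equal(b$Z[b$rank_position], 1.5)
  expect_equal(b$m, 0.75)
  expect_equal(b$eta, 1 / sqrt(2))
  expect_equal(b$c1, 1.5)               # exactly one finite bound
  expect_equal(b$c2, -Inf)
  u <- umvcue(b)
  expect_equal(u, 0.5621354, tolerance = 1e-6)     # frozen truncated-mean value
  expect_equal(umvcue_numeric(b), u, tolerance = 1e-6)
  set.seed(42)
  mc <- umvcue_mc(b, n_draws = 2e5)
  expect_lt(abs(mc$estimate - u), 3 * mc$se)
})

test_that("quadrature and Monte-Carlo agree with half-normal closed forms", {
  fit1 <- make_fit(beta = c(1, 0), tau = c(1, 1), corr = diag(2))
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_top(1))
  fit2 <- make_fit(beta = 0.5, tau = 1, arms = 1)
  b <- build_sufficient_stats(fit1, fit2, sel, 1)
  b$m <- 0; b$eta <- 1
  # whole line: the full-support mean
  expect_equal(umvcue_numeric(b, -Inf, Inf), 0, tolerance = 1e-10)
  # half line [0, Inf): mean of the standard half-normal, sqrt(2/pi)
  expect_equal(umvcue_numeric(b, 0, Inf), sqrt(2 / pi), tolerance = 1e-8)
  set.seed(43)
  mc <- umvcue_mc(b, n_draws = 2e5, lower = 0, upper = Inf)
  expect_lt(abs(mc$estimate - sqrt(2 / pi)), 3 * mc$se)
  mc2 <- umvcue_mc(b, n_draws = 1e5, lower = -Inf, upper = Inf)
  expect_lt(abs(mc2$estimate - 0), 3 * mc2$se)
})

test_that("closed form, quadrature and Rao-Blackwell oracle agree on simulated bundles", {
  set.seed(44)
  cases <- c(replicate(12, tiny_scenario(J = 30,
                                         mu_Y = c(0, runif(1, -0.2, 0.4),
                                                  runif(1, -0.2, 0.4)),
                                         rho = c(0.1, 0.6)),
                       simplify = FALSE),
             replicate(4, inhance_scenario(J = 30), simplify = FALSE))
  for (sc in cases) {
    tr <- fit_trial(sc, adjustment = c(1, 2))
    for (s in tr$selection$selected) {
      b <- build_sufficient_stats(tr$fit1, tr$fit2, tr$selection, s)
      # the observed stage-2 estimate is always inside its own selection region
      expect_true(b$beta2_s >= b$c2 && b$beta2_s <= b$c1)
      u <- umvcue(b)
      expect_equal(umvcue_numeric(b), u, tolerance = 1e-6)
      mc <- umvcue_mc(b, n_draws = 1e5)
      expect_lt(abs(mc$estimate - u), 3 * mc$se + 1e-12)
    }
  }
})

test_that("stage-2 estimator given Z is normal with the stated slope and spread", {
  # sufficient-statistic level simulation with known variances: jointly,
  # (betahat2_s, Z_s) are bivariate normal, so regressing betahat2_s on Z_s
  # gives slope tau2^2/(tau1^2+tau2^2) and residual variance
  # eta^2 = tau2^4/(tau1^2+tau2^2) - the conditional law the UMVCUE truncates
  set.seed(45)
  tau1sq <- 0.02; tau2sq <- 0.03
  n <- 4e4
  b1 <- rnorm(n, 0, sqrt(tau1sq))
  b2 <- rnorm(n, 0, sqrt(tau2sq))
  Z <- b1 + (tau1sq / tau2sq) * b2
  fit <- lm(b2 ~ Z)
  slope <- tau2sq / (tau1sq + tau2sq)
  eta2 <- tau2sq^2 / (tau1sq + tau2sq)
  expect_equal(unname(coef(fit)[2]), slope,
               tolerance = 3 * summary(fit)$coefficients[2, 2] / slope)
  expect_equal(summary(fit)$sigma^2, eta2, tolerance = 0.05)
  # and conditioning on the selection event truncates exactly that normal:
  # the kept stage-2 draws stay inside [c2, c1] by construction, which the
  # simulated-bundle block above asserts on real fits
})

test_that("bundle construction rejects inconsistent requests", {
  set.seed(46)
  tr <- fit_trial(tiny_scenario())
  not_sel <- setdiff(1:2, tr$selection$selected)
  expect_error(build_sufficient_stats(tr$fit1, tr$fit2, tr$selection, not_sel),
               "not selected")
  b <- build_sufficient_stats(tr$fit1, tr$fit2, tr$selection,
                              tr$selection$selected)
  b$c2 <- 1; b$c1 <- 0
  expect_error(umvcue(b), "c1 < c2")
  expect_error(umvcue_mc(b, n_draws = 100), "at least 1e4")
  # region so deep in the tail that no unconditional draw can land in it
  b$c2 <- b$m + 50 * b$eta; b$c1 <- b$m + 51 * b$eta
  expect_error(umvcue_mc(b, n_draws = 1e4), "no draws")
})

test_that("threshold-rule bundles route through the general region", {
  set.seed(47)
  sc <- tiny_scenario(mu_Y = c(0, 0.3, 0.4),
                      selection_rule = select_threshold(0))
  d1 <- simulate_stage(sc, 1)
  fit1 <- fit_model(d1, c(1, 2))
  sel <- select_treatments(fit1, select_threshold(0))
  if (length(sel$selected)) {
    d2 <- simulate_stage(sc, 2, c(0, sel$selected))
    fit2 <- fit_model(d2, c(1, 2))
    for (s in sel$selected) {
      b <- build_sufficient_stats(fit1, fit2, sel, s)
      expect_true(b$beta2_s >= b$c2 && b$beta2_s <= b$c1)
      expect_equal(umvcue_numeric(b), umvcue(b), tolerance = 1e-6)
    }
  }
})

test_that("far-tail truncation stays finite and honours its bounds", {
  fit1 <- make_fit(beta = c(1, 0), tau = c(1, 1), corr = diag(2))
  sel <- apply_rule(rank_treatments(fit1), comparison_stats(fit1),
                    select_top(1))
  fit2 <- make_fit(beta = 0.5, tau = 1, arms = 1)
  b <- build_sufficient_stats(fit1, fit2, sel, 1)
  b$m <- 0; b$eta <- 1
  for (lo in c(8, 12, 20, 40)) {
    b$c2 <- lo; b$c1 <- lo + 2
    b$W1 <- b$c1; b$W2 <- b$c2
    u <- umvcue(b)
    expect_true(is.finite(u))
    expect_true(u > lo && u < lo + 2)
    # Mills-ratio behaviour: the conditional mean hugs the lower bound
    expect_lt(u - lo, 1 / lo + 0.01)
  }
  b$c2 <- -30; b$c1 <- -28
  b$W1 <- b$c1; b$W2 <- b$c2
  u <- umvcue(b)
  expect_true(u > -30 && u < -28)
})

test_that("the estimator table assembles all four estimators per selected arm", {
  set.seed(48)
  sc <- inhance_scenario(J = 40)
  tr <- fit_trial(sc, adjustment = c(1, 2))
  est <- all_estimates(tr$fit1, tr$fit2, tr$pooled, tr$selection)
  expect_equal(nrow(est), 2)                       # top-2 rule
  expect_setequal(est$arm, tr$selection$selected)
  expect_true(all(c("stage1", "stage2", "overall", "umvcue",
                    "overall_lower", "overall_upper") %in% names(est)))
  expect_true(all(is.finite(unlist(est))))
  # pooled estimate sits between the stage-wise estimates (balanced,
  # unadjusted case)
  tru <- fit_trial(sc, adjustment = integer(0))
  estu <- all_estimates(tru$fit1, tru$fit2, tru$pooled, tru$selection)
  expect_true(all(estu$overall >= pmin(estu$stage1, estu$stage2) &
                  estu$overall <= pmax(estu$stage1, estu$stage2)))
})
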