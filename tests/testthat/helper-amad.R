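# shared fixtures, all built in code

# small scenario: fast to simulate, same structure as the benchmark grid
tiny_scenario <- function(K = 2, J = 30, mu_Y = c(0, 0, 0.22),
                          rho = c(0.1, 0.6), ...) {
  amad_scenario(K = K, J = J, mu_Y = mu_Y, rho = rho, ...)
}

# synthetic amad_fit with prescribed treatment-contrast statistics, for unit
# tests that need exact control over t-statistics and covariances
make_fit <- function(beta, tau, corr = diag(length(beta)),
                     arms = seq_along(beta), adjustment_set = integer(0),
                     df = 1e9, scope = "stage1") {
  tau2 <- tau^2
  V <- corr * outer(tau, tau)
  structure(list(coefficients = c("(Intercept)" = 0), beta = stats::setNames(beta, arms),
                 gamma = numeric(0), sigma2 = 1, df = df,
                 n = df + length(beta) + 1,
                 G = V, V = V, tau2 = stats::setNames(tau2, arms),
                 tau = stats::setNames(tau, arms),
                 tstat = stats::setNames(beta / tau, arms),
                 corr = corr, arms = as.integer(arms),
                 adjustment_set = adjustment_set, scope = scope),
            class = "amad_fit")
}

# simulate one complete two-stage trial and return its fits + selection
fit_trial <- function(scenario, adjustment = scenario$adjustment_set,
                      rule = scenario$selection_rule) {
  d1 <- simulate_stage(scenario, 1)
  fit1 <- fit_model(d1, adjustment)
  sel <- select_treatments(fit1, rule)
  d2 <- simulate_stage(scenario, 2, c(0, sel$selected))
  list(fit1 = fit1, fit2 = fit_model(d2, adjustment),
       pooled = fit_model(rbind(d1, d2), adjustment), selection = sel,
       d1 = d1, d2 = d2)
}

# bivariate normal orthant probability by 1-D conditional integration;
# independent oracle for the Dunnett probabilities (does not use mvtnorm)
bvn_max_below <- function(c_, rho) {
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((c_ - rho * z) / sqrt(1 - rho^2)),
    -Inf, c_, rel.tol = 1e-12)$value
}
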