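# Treatment-effect estimators after interim selection.
#
# For a selected arm s the complete sufficient statistics are
#   Z_{i,s} = betahat_i^{(1)} + (V_{i,s}/tau_{(2),s}^2) * betahat_s^{(2)},
# and conditionally on them the stage-2 estimator betahat_s^{(2)} is
# N(m_s, eta_s^2) with
#   m_s   = tau_{(2),s}^2 * Z_{s,s} / (tau_{(1),s}^2 + tau_{(2),s}^2),
#   eta_s = tau_{(2),s}^2 / sqrt(tau_{(1),s}^2 + tau_{(2),s}^2),
# truncated to the interval [c2, c1] carved out by the selection event (each
# ranking or threshold inequality is linear in betahat_s^{(2)} once the Z's
# are held fixed). The UMVCUE is the mean of that truncated normal; its
# closed form is the standard truncated-normal mean identity with
# standardized bounds W_l = (c_l - m_s)/eta_s.

#' Sufficient-statistic bundle for a selected arm
#'
#' Assembles everything the conditional (UMVCUE) computation needs from the
#' two stage-wise fits: stage-wise estimates and variances, cross-arm stage-1
#' covariances, the combined statistics Z, the conditional mean/SD, and the
#' truncation bounds implied by the realized selection event. Arms are
#' relabelled into the realized ranking order before the bounds are formed;
#' empty constraint sets give \code{c1 = +Inf} / \code{c2 = -Inf}.
#'
#' For top-k rules the conditioning event is the full observed ranking of all
#' K stage-1 statistics; for threshold rules it is the set of per-arm
#' threshold crossings.
#'
#' @param fit1 stage-1 [fit_model()] over all arms.
#' @param fit2 stage-2 [fit_model()] over control + selected arms.
#' @param selection the realized \code{"amad_selection"}.
#' @param s the selected arm of interest.
#' @return An object of class \code{"amad_suffstats"}.
#' @export
build_sufficient_stats <- function(fit1, fit2, selection, s) {
  stopifnot(inherits(fit1, "amad_fit"), inherits(fit2, "amad_fit"),
            inherits(selection, "amad_selection"))
  s <- as.integer(s)
  if (!s %in% selection$selected) stop("arm ", s, " was not selected")
  ranking <- selection$ranking
  K <- length(ranking)
  i1 <- match(ranking, fit1$arms)           # ranked order
  if (anyNA(i1)) stop("selection is inconsistent with the stage-1 fit")
  i2s <- match(s, fit2$arms)
  if (is.na(i2s)) stop("arm ", s, " absent from the stage-2 fit")

  beta1 <- unname(fit1$beta[i1])
  tau1 <- unname(fit1$tau[i1])              # stage-1 SDs, ranked
  rs <- match(s, ranking)                   # position of s in the ranking
  V <- unname(fit1$V[i1, i1[rs]])           # V_{i,s}, ranked
  tau1s2 <- tau1[rs]^2
  tau2s2 <- unname(fit2$tau2[i2s])
  if (tau1s2 <= 0 || tau2s2 <= 0) stop("degenerate stage-wise variance")
  beta2s <- unname(fit2$beta[i2s])

  Z <- beta1 + (V / tau2s2) * beta2s        # Z_{s,s} = beta1_s + (tau1^2/tau2^2) beta2_s
  m <- tau2s2 * Z[rs] / (tau1s2 + tau2s2)
  eta <- tau2s2 / sqrt(tau1s2 + tau2s2)

  rule <- selection$rule
  if (rule$type == "top_k") {
    # consecutive ranking inequalities: t_(i) >= t_(i+1), each linear in y
    upper <- numeric(0); lower <- numeric(0)
    for (i in seq_len(K - 1L)) {
      num <- tau1[i + 1L] * Z[i] - tau1[i] * Z[i + 1L]
      den <- tau1[i + 1L] * V[i] - tau1[i] * V[i + 1L]
      if (den > 0) upper <- c(upper, tau2s2 * num / den)
      else if (den < 0) lower <- c(lower, tau2s2 * num / den)
    }
  } else {
    # threshold crossings: t_i > cutoff for selected arms, <= for the rest
    cut <- rule$cutoff
    upper <- numeric(0); lower <- numeric(0)
    for (i in seq_len(K)) {
      num <- tau2s2 * (Z[i] - cut * tau1[i])
      sel_i <- ranking[i] %in% selection$selected
      if (V[i] > 0) {
        if (sel_i) upper <- c(upper, num / V[i]) else lower <- c(lower, num / V[i])
      } else if (V[i] < 0) {
        if (sel_i) lower <- c(lower, num / V[i]) else upper <- c(upper, num / V[i])
      }
    }
  }
  c1 <- if (length(upper)) min(upper) else Inf
  c2 <- if (length(lower)) max(lower) else -Inf

  structure(list(s = s, rank_position = rs, ranking = ranking,
                 beta1 = beta1, tau1 = tau1, V = V, Z = Z,
                 beta1_s = beta1[rs], beta2_s = beta2s,
                 tau1_sq = tau1s2, tau2_sq = tau2s2,
                 m = m, eta = eta, c1 = c1, c2 = c2,
                 W1 = (c1 - m) / eta, W2 = (c2 - m) / eta,
                 rule = rule),
            class = "amad_suffstats")
}

#' @export
print.amad_suffstats <- function(x, ...) {
  cat("Sufficient statistics for selected arm ", x$s,
      " (rank ", x$rank_position, ")\n", sep = "")
  cat("  beta1_s = ", format(x$beta1_s), ", beta2_s = ", format(x$beta2_s),
      ", tau1^2 = ", format(x$tau1_sq), ", tau2^2 = ", format(x$tau2_sq),
      "\n  conditional N(m, eta^2): m = ", format(x$m),
      ", eta = ", format(x$eta),
      "\n  truncation: [", format(x$c2), ", ", format(x$c1), "]\n", sep = "")
  invisible(x)
}

# Mean of N(m, s^2) truncated to [lo, hi], stable far into either tail.
# Log-space evaluation of both phi and Phi differences keeps the Mills-type
# ratio finite when the interval carries essentially no mass.
.truncnorm_mean <- function(m, s, lo, hi) {
  a <- (lo - m) / s
  b <- (hi - m) / s
  if (a > b) stop("empty truncation interval")
  if (a == -Inf && b == Inf) return(m)
  logphi <- function(x) if (is.finite(x)) -0.5 * x^2 - 0.9189385332046727 else -Inf
  logdiff <- function(hi_l, lo_l) {
    # log(exp(hi_l) - exp(lo_l)) with hi_l >= lo_l
    if (lo_l == -Inf) return(hi_l)
    d <- lo_l - hi_l
    if (d > -1e-12) return(-Inf)
    hi_l + log1p(-exp(d))
  }
  if (b <= 0) {
    logZ <- logdiff(stats::pnorm(b, log.p = TRUE), stats::pnorm(a, log.p = TRUE))
  } else if (a >= 0) {
    logZ <- logdiff(stats::pnorm(a, lower.tail = FALSE, log.p = TRUE),
                    stats::pnorm(b, lower.tail = FALSE, log.p = TRUE))
  } else {
    logZ <- log(stats::pnorm(b) - stats::pnorm(a))
  }
  if (logZ == -Inf) stop("truncation interval carries no probability mass")
  m + s * (exp(logphi(a) - logZ) - exp(logphi(b) - logZ))
}

#' Conditionally unbiased estimator (UMVCUE), closed form
#'
#' The minimum-variance estimator of the selected arm's treatment effect that
#' is unbiased conditional on the realized selection event. It equals the
#' conditional mean
#' \deqn{\hat U_s = m_s - \eta_s \frac{\phi(W_1) - \phi(W_2)}{\Phi(W_1) -
#'   \Phi(W_2)}}
#' of a normal with mean \eqn{m_s} and SD \eqn{\eta_s} truncated to
#' \eqn{[c_2, c_1]}, evaluated in tail-stable log form. Valid whenever the
#' selection event restricts the stage-2 estimator to an interval (which is
#' the case for ranking-based and threshold rules).
#'
#' @param bundle an [build_sufficient_stats()] result.
#' @return The point estimate \eqn{\hat U_s}.
#' @export
umvcue <- function(bundle) {
  stopifnot(inherits(bundle, "amad_suffstats"))
  if (bundle$c1 < bundle$c2)
    stop("inconsistent bundle: c1 < c2 (empty selection region)")
  .truncnorm_mean(bundle$m, bundle$eta, bundle$c2, bundle$c1)
}

#' Conditionally unbiased estimator by adaptive quadrature
#'
#' Evaluates the defining ratio of integrals
#' \deqn{\hat U_s = \int_A y\,\varphi_{m_s,\eta_s}(y)\,dy \Big/
#'   \int_A \varphi_{m_s,\eta_s}(y)\,dy}
#' over the selection region A for the stage-2 estimator, by adaptive
#' quadrature. This is the general-rule route (any interval region) and the
#' independent numerical check of the closed form.
#'
#' @param bundle an [build_sufficient_stats()] result.
#' @param lower,upper region bounds; default the bundle's \code{c2}/\code{c1}.
#' @param rel.tol relative quadrature tolerance.
#' @return The point estimate \eqn{\hat U_s}.
#' @export
umvcue_numeric <- function(bundle, lower = bundle$c2, upper = bundle$c1,
                           rel.tol = 1e-10) {
  stopifnot(inherits(bundle, "amad_suffstats"))
  if (lower > upper) stop("empty selection region")
  m <- bundle$m; eta <- bundle$eta
  a <- (lower - m) / eta; b <- (upper - m) / eta
  den <- stats::integrate(stats::dnorm, a, b, rel.tol = rel.tol)$value
  if (den < 1e-300)
    stop("selection region carries negligible probability mass")
  num <- stats::integrate(function(t) t * stats::dnorm(t), a, b,
                          rel.tol = rel.tol)$value
  m + eta * num / den
}

#' Monte-Carlo (Rao-Blackwell) oracle for the conditional estimator
#'
#' Draws from the unconditional \eqn{N(m_s, \eta_s^2)}, keeps the draws
#' falling in the selection region, and averages. Used to validate the closed
#' form and the quadrature; uses the current RNG state.
#'
#' @inheritParams umvcue_numeric
#' @param n_draws number of draws (at least 1e4).
#' @return List with \code{estimate}, \code{se} (Monte-Carlo standard error)
#'   and \code{n_accepted}.
#' @export
umvcue_mc <- function(bundle, n_draws = 1e5, lower = bundle$c2,
                      upper = bundle$c1) {
  stopifnot(inherits(bundle, "amad_suffstats"))
  if (n_draws < 1e4) stop("'n_draws' must be at least 1e4")
  y <- stats::rnorm(n_draws, bundle$m, bundle$eta)
  y <- y[y >= lower & y <= upper]
  if (!length(y)) stop("no draws fell inside the selection region")
  list(estimate = mean(y), se = stats::sd(y) / sqrt(length(y)),
       n_accepted = length(y))
}

#' All treatment-effect estimators for the selected arms
#'
#' Assembles, per selected arm, the stage-1, stage-2 and overall (pooled-fit)
#' OLS estimators with their standard Wald intervals, and the UMVCUE point
#' estimate. No interval is attached to the UMVCUE: there is no established
#' valid construction for it.
#'
#' @param fit1 stage-1 fit, \code{fit2} stage-2 fit, \code{pooled_fit} fit to
#'   both stages pooled.
#' @param fit2,pooled_fit see above.
#' @param selection the realized \code{"amad_selection"}.
#' @param level coverage of the Wald intervals.
#' @return An object of class \code{"amad_estimates"}: a data frame with one
#'   row per selected arm and columns \code{arm}, \code{stage1}, \code{stage2},
#'   \code{overall}, \code{umvcue} plus interval bounds
#'   \code{<estimator>_lower}/\code{_upper} for the first three.
#' @export
all_estimates <- function(fit1, fit2, pooled_fit, selection, level = 0.95) {
  stopifnot(inherits(selection, "amad_selection"))
  sel <- selection$selected
  if (!length(sel)) stop("no arms were selected")
  one <- function(s) {
    ci1 <- wald_interval(fit1, s, level)
    ci2 <- wald_interval(fit2, s, level)
    cio <- wald_interval(pooled_fit, s, level)
    u <- umvcue(build_sufficient_stats(fit1, fit2, selection, s))
    c(arm = s,
      stage1 = unname(fit1$beta[match(s, fit1$arms)]),
      stage1_lower = ci1[[1L]], stage1_upper = ci1[[2L]],
      stage2 = unname(fit2$beta[match(s, fit2$arms)]),
      stage2_lower = ci2[[1L]], stage2_upper = ci2[[2L]],
      overall = unname(pooled_fit$beta[match(s, pooled_fit$arms)]),
      overall_lower = cio[[1L]], overall_upper = cio[[2L]],
      umvcue = u)
  }
  tab <- do.call(rbind, lapply(sel, one))
  out <- .quickdf(as.list(as.data.frame(tab)))
  class(out) <- c("amad_estimates", "data.frame")
  attr(out, "level") <- level
  out
}

#' @export
print.amad_estimates <- function(x, digits = 3, ...) {
  cat("Treatment-effect estimates for selected arm(s) (",
      100 * attr(x, "level"), "% Wald intervals)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    fmt <- function(e, l, u) sprintf("%.*f (%.*f, %.*f)", digits, e,
                                     digits, l, digits, u)
    cat("arm ", r$arm,
        ": stage1 ", fmt(r$stage1, r$stage1_lower, r$stage1_upper),
        "  stage2 ", fmt(r$stage2, r$stage2_lower, r$stage2_upper),
        "  overall ", fmt(r$overall, r$overall_lower, r$overall_upper),
        "  UMVCUE ", sprintf("%.*f", digits, r$umvcue), "\n", sep = "")
  }
  invisible(x)
}
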