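# Front-end: analyse one completed two-stage adaptive multi-arm trial.

#' Analyse a two-stage adaptive multi-arm trial
#'
#' Fits the covariate-adjusted analysis model to the stage-1, stage-2 and
#' pooled data, recomputes the interim selection from the stage-1 fit, runs
#' the closed test with inverse-normal combination, and assembles all
#' treatment-effect estimators (stage-1, stage-2, overall, UMVCUE) for the
#' selected arms.
#'
#' If the arms present in the stage-2 data differ from what the recomputed
#' selection implies (e.g. the trial deviated from the pre-specified rule), a
#' warning is issued and the analysis conditions on the observed selected
#' set.
#'
#' @param data data frame with columns \code{stage} (1/2), \code{arm}
#'   (0 = control), covariates \code{X1, ...}, and outcome \code{Y}.
#' @param adjustment integer indices of covariates to adjust for (the same
#'   set is used for selection and final analysis).
#' @param rule selection rule, see [select_top()] / [select_threshold()].
#' @param alpha one-sided significance level.
#' @param weights inverse-normal stage weights; default
#'   \eqn{w_t = \sqrt{n_t/(n_1+n_2)}} from the realized stage sizes.
#' @param level coverage of the Wald intervals.
#' @return An object of class \code{"amad"} with components \code{fit1},
#'   \code{fit2}, \code{pooled}, \code{selection}, \code{test},
#'   \code{estimates}.
#' @examples
#' sc <- amad_scenario(K = 2, J = 30, mu_Y = c(0, 0.2, 0.4), rho = c(0.1, 0.6))
#' set.seed(7)
#' trial <- simulate(sc)[[1]]
#' fit <- amad(trial, adjustment = c(1, 2))
#' fit
#' @export
amad <- function(data, adjustment = integer(0), rule = select_top(1L),
                 alpha = 0.025, weights = NULL, level = 0.95) {
  if (!all(c("stage", "arm", "Y") %in% names(data)))
    stop("'data' must have columns stage, arm, Y")
  d1 <- data[data$stage == 1, , drop = FALSE]
  d2 <- data[data$stage == 2, , drop = FALSE]
  if (!nrow(d1)) stop("no stage-1 records")
  fit1 <- fit_model(d1, adjustment)
  .check_rule(rule, length(fit1$arms))
  selection <- select_treatments(fit1, rule)

  observed <- sort(setdiff(unique(d2$arm), 0))
  if (nrow(d2) && !setequal(observed, selection$selected)) {
    warning("stage-2 arms {", paste(observed, collapse = ","),
            "} differ from the recomputed selection {",
            paste(selection$selected, collapse = ","),
            "}; conditioning on the observed selected set")
    selection$selected <- as.integer(observed)
    selection$none_selected <- length(observed) == 0L
  }

  if (is.null(weights)) {
    w1 <- sqrt(nrow(d1) / (nrow(d1) + nrow(d2)))
    weights <- c(w1, sqrt(1 - w1^2))
  }

  fit2 <- pooled <- NULL
  estimates <- NULL
  if (length(selection$selected)) {
    if (!nrow(d2)) stop("arms were selected but there are no stage-2 records")
    fit2 <- fit_model(d2, adjustment)
    pooled <- fit_model(data, adjustment)
    estimates <- all_estimates(fit1, fit2, pooled, selection, level)
  }
  test <- closed_test(fit1, fit2, selection, alpha, weights)

  structure(list(call = match.call(), fit1 = fit1, fit2 = fit2,
                 pooled = pooled, selection = selection, test = test,
                 estimates = estimates, adjustment = adjustment,
                 alpha = alpha, weights = weights, level = level),
            class = "amad")
}

#' @export
print.amad <- function(x, ...) {
  cat("Two-stage adaptive multi-arm analysis",
      " (adjustment set {", paste(x$adjustment, collapse = ","), "})\n",
      sep = "")
  print(x$selection)
  rej <- x$test$elementary$arm[x$test$elementary$reject]
  cat("rejected hypotheses:",
      if (length(rej)) paste0("H0", rej, collapse = ", ") else "none", "\n")
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' @export
summary.amad <- function(object, ...) {
  structure(list(object = object), class = "summary.amad")
}

#' @export
print.summary.amad <- function(x, ...) {
  o <- x$object
  print(o$selection)
  print(o$test)
  if (!is.null(o$estimates)) print(o$estimates)
  invisible(x)
}

#' @export
coef.amad <- function(object, estimator = c("overall", "stage1", "stage2",
                                            "umvcue"), ...) {
  estimator <- match.arg(estimator)
  if (is.null(object$estimates)) return(numeric(0))
  out <- object$estimates[[estimator]]
  names(out) <- object$estimates$arm
  out
}

#' @export
confint.amad <- function(object, parm, level = NULL, ...) {
  if (is.null(object$pooled)) stop("no pooled fit (nothing selected)")
  level <- if (is.null(level)) object$level else level
  arms <- if (missing(parm)) object$estimates$arm else parm
  out <- t(vapply(arms, function(a) wald_interval(object$pooled, a, level),
                  numeric(2L)))
  rownames(out) <- paste0("arm", arms)
  out
}

#' @export
plot.amad <- function(x, ...) {
  est <- x$estimates
  if (is.null(est)) stop("nothing selected; no estimates to plot")
  ests <- c("stage1", "stage2", "overall", "umvcue")
  k <- nrow(est)
  ypos <- rev(seq_len(k * 4L))
  vals <- unlist(est[ests])
  lo <- c(est$stage1_lower, est$stage2_lower, est$overall_lower,
          rep(NA, k))
  hi <- c(est$stage1_upper, est$stage2_upper, est$overall_upper,
          rep(NA, k))
  vals <- as.numeric(t(matrix(vals, nrow = k)))
  lo <- as.numeric(t(matrix(lo, nrow = k)))
  hi <- as.numeric(t(matrix(hi, nrow = k)))
  labs <- as.vector(t(outer(est$arm, ests,
                            function(a, e) paste0("arm", a, ":", e))))
  rng <- range(c(vals, lo, hi), na.rm = TRUE)
  graphics::plot(vals, ypos, xlim = rng, yaxt = "n", xlab = "estimate",
                 ylab = "", pch = 19, ...)
  graphics::axis(2, at = ypos, labels = labs, las = 1, cex.axis = 0.7)
  graphics::segments(lo, ypos, hi, ypos)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Simulate complete two-stage trials from a scenario
#'
#' Each simulated trial runs stage 1 on all arms, performs interim selection
#' with the scenario's rule and adjustment set, then runs stage 2 on the
#' control plus the selected arms.
#'
#' @param object an [amad_scenario()].
#' @param nsim number of trials.
#' @param seed optional seed passed to \code{\link{set.seed}}.
#' @param ... unused.
#' @return A list of \code{nsim} data frames in the standard
#'   \code{stage, arm, X..., Y} layout.
#' @export
simulate.amad_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    d1 <- simulate_stage(object, 1L)
    fit1 <- fit_model(d1, object$adjustment_set)
    sel <- select_treatments(fit1, object$selection_rule)
    if (sel$none_selected) return(d1)
    d2 <- simulate_stage(object, 2L, c(0L, sel$selected))
    rbind(d1, d2)
  })
}
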