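# Covariate-adjusted linear model fits.
#
# The analysis model is
#   Y_jk = alpha0 + sum_k beta_k I(T_j = k) + gamma' X_jk + eps_jk,
# fitted by OLS with indicator coding against the control arm. Everything
# downstream (selection, Dunnett p-values, the UMVCUE) is driven by the
# treatment-contrast block of the inverse Gram matrix: tau_k^2 =
# sigmahat^2 * G_kk is the squared standard error of betahat_k and
# V_is = sigmahat^2 * G_is the covariance between contrasts.

#' Fit the covariate-adjusted analysis model by OLS
#'
#' @param data data frame with columns \code{stage}, \code{arm},
#'   \code{X1, ...} and \code{Y}; may hold one stage or pooled data.
#' @param adjustment_set integer indices of the covariates to adjust for;
#'   \code{integer(0)} for the unadjusted model.
#' @param arms optional integer vector of arms that must be present; an arm
#'   with zero records triggers an explicit error naming it.
#' @return An object of class \code{"amad_fit"} with components
#'   \code{coefficients} (full OLS vector), \code{beta} (treatment contrasts,
#'   named by arm), \code{sigma2}, \code{df}, \code{G} (treatment block of the
#'   inverse Gram matrix), \code{V = sigma2 * G}, \code{tau2}, \code{tau},
#'   \code{tstat}, \code{corr} (contrast correlation matrix), \code{arms},
#'   \code{scope} (\code{"stage1"}, \code{"stage2"} or \code{"pooled"}) and
#'   \code{n}.
#' @examples
#' d <- data.frame(stage = 1, arm = c(0, 0, 1, 1), Y = c(0, 2, 1, 3))
#' fit <- fit_model(d)
#' fit$beta   # 1
#' fit$sigma2 # 2
#' @export
fit_model <- function(data, adjustment_set = integer(0), arms = NULL) {
  if (!all(c("stage", "arm", "Y") %in% names(data)))
    stop("'data' must have columns stage, arm, Y")
  present <- sort(unique(data$arm))
  if (!0 %in% present) stop("control arm 0 has zero records")
  if (!is.null(arms)) {
    missing_arms <- setdiff(as.integer(arms), present)
    if (length(missing_arms))
      stop("arm(s) with zero records: ", paste(missing_arms, collapse = ", "))
  }
  trt <- present[present != 0]
  Kf <- length(trt)
  adjustment_set <- as.integer(adjustment_set)
  xn <- if (length(adjustment_set)) paste0("X", adjustment_set) else character(0)
  if (!all(xn %in% names(data)))
    stop("unknown covariate(s) in adjustment set: ",
         paste(setdiff(xn, names(data)), collapse = ", "))

  y <- data$Y
  n <- length(y)
  X <- matrix(1, nrow = n, ncol = 1L + Kf + length(xn))
  for (i in seq_len(Kf)) X[, 1L + i] <- as.numeric(data$arm == trt[i])
  for (j in seq_along(xn)) X[, 1L + Kf + j] <- data[[xn[j]]]
  colnames(X) <- c("(Intercept)", if (Kf) paste0("arm", trt), xn)

  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch))
    stop("design matrix is rank deficient (constant or aliased column)")
  Ginv <- chol2inv(ch)
  coefs <- drop(Ginv %*% crossprod(X, y))
  names(coefs) <- colnames(X)
  df <- n - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom")
  rss <- sum((y - drop(X %*% coefs))^2)
  sigma2 <- rss / df

  ti <- 1L + seq_len(Kf)
  G <- Ginv[ti, ti, drop = FALSE]
  V <- sigma2 * G
  tau2 <- diag(V)
  dimnames(G) <- dimnames(V) <- list(trt, trt)
  beta <- coefs[ti]
  names(beta) <- names(tau2) <- trt
  stg <- unique(data$stage)
  scope <- if (length(stg) > 1L) "pooled" else paste0("stage", stg)

  structure(list(coefficients = coefs, beta = beta,
                 gamma = coefs[seq.int(2L + Kf, length.out = length(xn))],
                 sigma2 = sigma2, df = df, n = n,
                 G = G, V = V, tau2 = tau2, tau = sqrt(tau2),
                 tstat = beta / sqrt(tau2),
                 corr = G / sqrt(outer(diag(G), diag(G))),
                 arms = as.integer(trt), adjustment_set = adjustment_set,
                 scope = scope),
            class = "amad_fit")
}

#' @export
print.amad_fit <- function(x, ...) {
  cat("Covariate-adjusted OLS fit (", x$scope, "), n = ", x$n,
      ", df = ", x$df, ", sigma2 = ", format(x$sigma2, digits = 4), "\n",
      sep = "")
  print(comparison_stats(x))
  invisible(x)
}

#' @export
coef.amad_fit <- function(object, ...) object$coefficients

#' @export
vcov.amad_fit <- function(object, ...) object$V

#' Per-arm treatment comparison statistics
#'
#' @param fit an [fit_model()] result.
#' @return Data frame with one row per fitted intervention arm (ordered by arm
#'   index): \code{arm}, \code{estimate} (\eqn{\hat\beta_k}), \code{se}
#'   (\eqn{\tau_k}) and \code{statistic} (\eqn{t_k = \hat\beta_k/\tau_k}).
#' @export
comparison_stats <- function(fit) {
  stopifnot(inherits(fit, "amad_fit"))
  .quickdf(list(arm = fit$arms, estimate = unname(fit$beta),
                se = unname(fit$tau), statistic = unname(fit$tstat)))
}

#' Wald confidence interval for a treatment contrast
#'
#' \eqn{\hat\beta_k \pm t_{df,(1+level)/2}\,\tau_k} with the Student-t
#' quantile at the fit's residual degrees of freedom.
#'
#' @param fit an [fit_model()] result.
#' @param arm intervention arm index.
#' @param level coverage level in (0, 1).
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
wald_interval <- function(fit, arm, level = 0.95) {
  stopifnot(inherits(fit, "amad_fit"))
  if (!(level > 0 && level < 1)) stop("'level' must lie in (0, 1)")
  i <- match(as.integer(arm), fit$arms)
  if (is.na(i)) stop("unknown arm: ", arm)
  q <- stats::qt((1 + level) / 2, df = fit$df)
  ci <- fit$beta[i] + c(-1, 1) * q * fit$tau[i]
  names(ci) <- c("lower", "upper")
  ci
}
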