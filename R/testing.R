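# Strong familywise error control: Dunnett stage-wise p-values for every
# intersection hypothesis, combined across stages by a pre-specified
# combination function, with rejection decisions taken by the closure
# principle.
#
# Stage-wise statistics are t-statistics (estimated sigma) but the joint
# Dunnett probability is evaluated under the multivariate normal with the
# plug-in contrast correlation from the realized design: with ~100 subjects
# per arm the residual df are large enough that the normal and multivariate-t
# versions are practically indistinguishable.

#' One-sided Dunnett p-value for an intersection hypothesis
#'
#' Computes \eqn{p = 1 - P(\max_k Z_k \le \max_k t_k)} under the central
#' multivariate normal with the given contrast correlation matrix. With a
#' single arm this is exactly the univariate one-sided tail. The correlation
#' matrix is the one implied by the fit's inverse Gram matrix,
#' \eqn{corr_{ij} = G_{ij}/\sqrt{G_{ii}G_{jj}}} (see
#' \code{\link{fit_model}}'s \code{corr} component).
#'
#' @param t_obs observed statistics for the arms in the intersection.
#' @param corr their correlation matrix (unit diagonal, positive definite);
#'   ignored for a single arm.
#' @param df residual degrees of freedom; only honoured univariately, where
#'   \code{df < Inf} uses the Student-t tail. The joint probability always
#'   uses the normal kernel (evaluated with a deterministic quadrature rule).
#' @return One-sided p-value in \[0, 1\].
#' @examples
#' dunnett_pvalue(1.959964) # 0.025
#' @export
dunnett_pvalue <- function(t_obs, corr = NULL, df = Inf) {
  m <- length(t_obs)
  if (m == 0L) stop("empty intersection")
  if (anyNA(t_obs)) stop("missing statistics")
  if (m == 1L)
    return(if (is.finite(df)) stats::pt(t_obs, df, lower.tail = FALSE)
           else stats::pnorm(t_obs, lower.tail = FALSE))
  if (is.null(corr) || !is.matrix(corr) || !all(dim(corr) == m))
    stop("'corr' must be an m x m correlation matrix")
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8))
    stop("'corr' must be symmetric with unit diagonal")
  ok <- tryCatch({ chol(corr); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'corr' is not positive definite")
  .dunnett_p(t_obs, corr)
}

# hot path: correlation matrix comes from a fit and is already valid
.dunnett_p <- function(t_obs, corr) {
  m <- length(t_obs)
  if (m == 1L) return(stats::pnorm(t_obs, lower.tail = FALSE))
  pr <- mvtnorm::pmvnorm(upper = rep(max(t_obs), m), corr = corr,
                         algorithm = mvtnorm::Miwa(steps = 128))
  min(max(1 - as.numeric(pr), 0), 1)
}

#' Weighted inverse-normal combination of stage-wise p-values
#'
#' \eqn{p = 1 - \Phi(w_1\Phi^{-1}(1-p_1) + w_2\Phi^{-1}(1-p_2))}. Monotone
#' non-decreasing in each argument; a stage-wise p-value of 1 forces a
#' combined p-value of 1.
#'
#' @param p1,p2 stage-wise p-values in (0, 1\].
#' @param w1,w2 pre-specified weights with \eqn{w_1^2 + w_2^2 = 1}; default
#'   \eqn{1/\sqrt 2} each (equal stage sample sizes).
#' @return Combined p-value.
#' @examples
#' combine_inverse_normal(0.025, 0.025) # ~0.00279
#' @export
combine_inverse_normal <- function(p1, p2, w1 = 1 / sqrt(2),
                                   w2 = sqrt(1 - w1^2)) {
  .check_p(p1); .check_p(p2)
  if (abs(w1^2 + w2^2 - 1) > 1e-8)
    stop("weights must satisfy w1^2 + w2^2 = 1")
  z <- w1 * stats::qnorm(p1, lower.tail = FALSE) +
    w2 * stats::qnorm(p2, lower.tail = FALSE)
  if (is.nan(z)) stop("degenerate combination of boundary p-values")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Fisher product combination of stage-wise p-values
#'
#' \eqn{p} is the upper tail of \eqn{\chi^2_4} at \eqn{-2(\ln p_1 + \ln p_2)},
#' computed in log space so that very small inputs do not underflow.
#'
#' @inheritParams combine_inverse_normal
#' @return Combined p-value.
#' @export
combine_fisher <- function(p1, p2) {
  .check_p(p1); .check_p(p2)
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

.check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("stage-wise p-values must lie in (0, 1]")
  invisible(p)
}

#' Closed test over all intersection hypotheses
#'
#' Tests every non-empty subset S of the elementary one-sided null hypotheses
#' H0k: mu_k <= 0. The stage-1 p-value of H_S is the Dunnett p-value over all
#' arms in S from the stage-1 fit; the stage-2 p-value uses only the arms of S
#' that continued to stage 2 (from the stage-2 fit). The two are merged with
#' the weighted inverse-normal combination at level \code{alpha}. When S
#' contains no selected arm there is no stage-2 information and the combined
#' test cannot reject (the stage-2 p-value is set to 1, which forces a
#' combined p-value of 1); a deselected intervention can therefore never be
#' claimed effective. Elementary rejections follow the closure principle:
#' H0k is rejected iff every H_S with k in S is rejected.
#'
#' @param fit1 stage-1 [fit_model()] over all arms.
#' @param fit2 stage-2 [fit_model()] over control + selected arms, or
#'   \code{NULL} when nothing was selected (futility).
#' @param selection an \code{"amad_selection"} derived from \code{fit1}.
#' @param alpha one-sided significance level.
#' @param weights inverse-normal stage weights \code{c(w1, w2)}.
#' @return An object of class \code{"amad_closed_test"}: \code{hypotheses}
#'   (one row per subset S with \code{S}, \code{p1}, \code{p2} (NA when
#'   untestable), \code{p_combined}, \code{reject}) and \code{elementary}
#'   (per-arm rejection flags).
#' @export
closed_test <- function(fit1, fit2, selection, alpha = 0.025,
                        weights = c(1, 1) / sqrt(2)) {
  if (!inherits(fit1, "amad_fit") || !inherits(selection, "amad_selection"))
    stop("'fit1' must be an amad_fit and 'selection' an amad_selection")
  selected <- selection$selected
  if (length(selected) && is.null(fit2))
    stop("stage-2 fit is required when arms were selected")
  if (!is.null(fit2)) {
    if (!inherits(fit2, "amad_fit")) stop("'fit2' must be an amad_fit")
    if (!identical(sort(fit1$adjustment_set), sort(fit2$adjustment_set)))
      stop("stage-1 and stage-2 fits must share the adjustment set")
  }
  arms <- fit1$arms
  K <- length(arms)
  nS <- 2L^K - 1L
  bits <- bitwShiftL(1L, seq_len(K) - 1L)
  w1 <- weights[1L]; w2 <- weights[2L]
  if (abs(w1^2 + w2^2 - 1) > 1e-8)
    stop("weights must satisfy w1^2 + w2^2 = 1")
  sel_idx <- match(selected, arms)
  i2_of <- match(arms, if (is.null(fit2)) integer(0) else fit2$arms)
  lab <- character(nS); p1 <- p2 <- pc <- numeric(nS)
  membership <- matrix(FALSE, nS, K)
  for (b in seq_len(nS)) {
    i1 <- which(bitwAnd(b, bits) > 0L)
    membership[b, i1] <- TRUE
    lab[b] <- paste(arms[i1], collapse = ",")
    p1[b] <- .dunnett_p(fit1$tstat[i1], fit1$corr[i1, i1, drop = FALSE])
    i1s <- i1[i1 %in% sel_idx]
    if (length(i1s)) {
      i2 <- i2_of[i1s]
      p2[b] <- .dunnett_p(fit2$tstat[i2], fit2$corr[i2, i2, drop = FALSE])
    } else p2[b] <- NA_real_
    z <- w1 * stats::qnorm(p1[b], lower.tail = FALSE) +
      w2 * stats::qnorm(if (is.na(p2[b])) 1 else p2[b], lower.tail = FALSE)
    # conflicting infinite evidence (p = 0 vs p = 1): conservative no-reject
    pc[b] <- if (is.nan(z)) 1 else stats::pnorm(z, lower.tail = FALSE)
  }
  rej <- pc <= alpha
  elem <- vapply(seq_len(K), function(i) all(rej[membership[, i]]),
                 logical(1L))
  structure(list(
    hypotheses = .quickdf(list(S = lab, p1 = p1, p2 = p2, p_combined = pc,
                               reject = rej)),
    elementary = .quickdf(list(arm = arms, reject = elem)),
    alpha = alpha, weights = weights, selected = selected),
    class = "amad_closed_test")
}

#' @export
print.amad_closed_test <- function(x, digits = 4, ...) {
  cat("Closed test (inverse-normal combination, one-sided alpha = ",
      format(x$alpha), ")\n", sep = "")
  h <- x$hypotheses
  h$p1 <- signif(h$p1, digits); h$p2 <- signif(h$p2, digits)
  h$p_combined <- signif(h$p_combined, digits)
  print(h)
  rej <- x$elementary$arm[x$elementary$reject]
  cat("rejected elementary hypotheses:",
      if (length(rej)) paste0("H0", rej, collapse = ", ") else "none", "\n")
  invisible(x)
}
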