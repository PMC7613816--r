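# Trial scenarios and the joint covariate/outcome data-generating model.
#
# A scenario fixes everything needed to simulate and analyse one two-stage
# adaptive multi-arm trial: K active arms plus control (arm 0), J subjects per
# arm per stage, per-arm means/variances of the covariates and outcome, the
# covariate-outcome correlations, the interim selection rule, the covariate
# adjustment set for analysis, the one-sided significance level and the
# combination-test stage weights.

#' Joint covariance matrix of covariates and outcome for one arm
#'
#' Builds the \eqn{(p+1) \times (p+1)} covariance matrix over
#' \eqn{(X_1, \ldots, X_p, Y)} in which the covariates are mutually
#' uncorrelated and covariate \eqn{X_j} has correlation \eqn{\rho_j} with the
#' outcome \eqn{Y}, so the only non-zero off-diagonal entries are
#' \eqn{\rho_j \sigma_{X_j} \sigma_Y}.
#'
#' @param rho numeric vector of covariate-outcome correlations, each in
#'   (-1, 1). May have length 0 (no covariates).
#' @param sigma2 numeric vector of variances, ordered
#'   \eqn{(\sigma^2_{X_1}, \ldots, \sigma^2_{X_p}, \sigma^2_Y)}; length
#'   \code{length(rho) + 1}.
#' @param arm optional arm label used in error messages.
#' @return A symmetric positive-definite matrix with dimnames
#'   \code{X1, ..., Xp, Y}.
#' @examples
#' joint_covariance(c(0.1, 0.6), c(1, 1, 1))
#' @export
joint_covariance <- function(rho, sigma2, arm = NULL) {
  p <- length(rho)
  if (length(sigma2) != p + 1L)
    stop("'sigma2' must have length length(rho) + 1 (covariates then outcome)")
  if (any(sigma2 <= 0))
    stop("all variances must be positive", .arm_msg(arm))
  if (any(abs(rho) >= 1))
    stop("correlations must lie strictly within (-1, 1)", .arm_msg(arm))
  sd <- sqrt(sigma2)
  S <- diag(sigma2, p + 1L)
  if (p > 0L) {
    S[seq_len(p), p + 1L] <- rho * sd[seq_len(p)] * sd[p + 1L]
    S[p + 1L, seq_len(p)] <- S[seq_len(p), p + 1L]
  }
  dimnames(S) <- rep(list(c(if (p > 0L) paste0("X", seq_len(p)), "Y")), 2L)
  # covariates are mutually independent, so positive definiteness reduces to
  # sum(rho^2) < 1; check via chol so unequal variances are covered too
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("implied joint covariance matrix is not positive definite",
         " (sum of squared covariate-outcome correlations must be < 1)",
         .arm_msg(arm))
  S
}

.arm_msg <- function(arm) if (is.null(arm)) "" else paste0(" for arm ", arm)

#' Define a two-stage adaptive multi-arm trial scenario
#'
#' @param K number of active intervention arms (control is arm 0 and implicit).
#' @param J subjects per arm per stage.
#' @param mu_Y outcome means, length \code{K + 1} (control first).
#' @param mu_X covariate means: a length-\code{p} vector shared by all arms, or
#'   a \code{(K+1) x p} matrix of per-arm means.
#' @param sigma2 variances of \eqn{(X_1, \ldots, X_p, Y)}: a length
#'   \code{p + 1} vector shared by all arms, or a \code{(K+1) x (p+1)} matrix.
#' @param rho covariate-outcome correlations: length-\code{p} vector or
#'   \code{(K+1) x p} matrix.
#' @param n_covariates number of baseline covariates \eqn{p \ge 0}; defaults to
#'   the length implied by \code{rho}.
#' @param selection_rule a rule from [select_top()] or [select_threshold()].
#' @param adjustment_set integer indices of the covariates entering the
#'   analysis model (default: all of them).
#' @param alpha one-sided significance level of the combination test.
#' @param stage_weights inverse-normal combination weights \eqn{(w_1, w_2)}
#'   with \eqn{w_1^2 + w_2^2 = 1}; default \eqn{1/\sqrt{2}} each (equal stage
#'   sizes).
#' @param arm_labels optional character labels, control first.
#' @param label optional scenario label used in printing and grid output.
#' @return An object of class \code{"amad_scenario"}.
#' @examples
#' sc <- amad_scenario(K = 2, J = 100, mu_Y = c(0, 0, 0.22), rho = c(0.1, 0.6))
#' sc
#' @export
amad_scenario <- function(K, J, mu_Y,
                          mu_X = rep(0.5, n_covariates),
                          sigma2 = rep(1, n_covariates + 1L),
                          rho = c(0, 0),
                          n_covariates = NULL,
                          selection_rule = select_top(1L),
                          adjustment_set = seq_len(n_covariates),
                          alpha = 0.025,
                          stage_weights = c(1, 1) / sqrt(2),
                          arm_labels = NULL,
                          label = NULL) {
  K <- as.integer(K); J <- as.integer(J)
  if (K < 1L) stop("'K' must be at least 1")
  if (is.null(n_covariates))
    n_covariates <- if (is.matrix(rho)) ncol(rho) else length(rho)
  p <- as.integer(n_covariates)
  A <- K + 1L

  to_mat <- function(x, nc, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(A, nc)))
        stop("'", what, "' matrix must be (K+1) x ", nc)
      x
    } else {
      if (length(x) != nc)
        stop("'", what, "' must have length ", nc, " or be a (K+1) x ", nc,
             " matrix")
      matrix(x, nrow = A, ncol = nc, byrow = TRUE)
    }
  }
  mu_X <- to_mat(if (p == 0L) numeric(0) else mu_X, p, "mu_X")
  sigma2 <- to_mat(sigma2, p + 1L, "sigma2")
  rho <- to_mat(if (p == 0L) numeric(0) else rho, p, "rho")
  if (length(mu_Y) != A) stop("'mu_Y' must have length K + 1")
  if (J < p + K + 2L)
    stop("'J' too small: need J >= n_covariates + K + 2 for an identifiable ",
         "fit with positive residual degrees of freedom")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (length(stage_weights) != 2L ||
      abs(sum(stage_weights^2) - 1) > 1e-8)
    stop("'stage_weights' must be two weights with w1^2 + w2^2 = 1")
  .check_rule(selection_rule, K)
  adjustment_set <- as.integer(adjustment_set)
  if (length(adjustment_set) && (any(adjustment_set < 1L) ||
                                 any(adjustment_set > p)))
    stop("'adjustment_set' must index covariates 1..", p)
  if (is.null(arm_labels))
    arm_labels <- c("control", paste0("T", seq_len(K)))
  if (length(arm_labels) != A) stop("'arm_labels' must have length K + 1")

  # per-arm joint covariance and its Cholesky factor, validated on construction
  Sigma <- chol_Sigma <- vector("list", A)
  for (a in seq_len(A)) {
    Sigma[[a]] <- joint_covariance(rho[a, ], sigma2[a, ], arm = a - 1L)
    chol_Sigma[[a]] <- chol(Sigma[[a]])
  }

  structure(list(K = K, J = J, n_covariates = p,
                 arm_labels = arm_labels, mu_Y = as.numeric(mu_Y),
                 mu_X = mu_X, sigma2 = sigma2, rho = rho,
                 selection_rule = selection_rule,
                 adjustment_set = adjustment_set,
                 alpha = alpha, stage_weights = as.numeric(stage_weights),
                 label = label, Sigma = Sigma, chol_Sigma = chol_Sigma),
            class = "amad_scenario")
}

#' @export
print.amad_scenario <- function(x, ...) {
  cat("Two-stage adaptive multi-arm scenario",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  arms: control + ", x$K, " interventions, J = ", x$J,
      " per arm per stage\n", sep = "")
  cat("  outcome means: ", paste(format(x$mu_Y), collapse = ", "), "\n",
      sep = "")
  if (x$n_covariates > 0L)
    cat("  covariate-outcome correlations (arm 0): ",
        paste(format(x$rho[1L, ]), collapse = ", "), "\n", sep = "")
  r <- x$selection_rule
  cat("  selection: ", if (r$type == "top_k") paste0("top-", r$k)
      else paste0("threshold t > ", format(r$cutoff)),
      "; adjustment set: {",
      paste(x$adjustment_set, collapse = ","), "}; one-sided alpha = ",
      format(x$alpha), "\n", sep = "")
  invisible(x)
}

#' Simulate subject-level data for one stage of a trial
#'
#' Draws \code{J} independent \eqn{(X_1, \ldots, X_p, Y)} vectors per active
#' arm from the arm's joint multivariate-normal distribution (covariates and
#' outcome drawn jointly). Uses the current RNG state; call
#' \code{\link{set.seed}} beforehand for reproducibility.
#'
#' @param scenario an [amad_scenario()].
#' @param stage 1 or 2.
#' @param active_arms integer arm indices to simulate, including the control
#'   (arm 0). Defaults to all arms for stage 1; required for stage 2, where it
#'   would normally be the control plus the selected arms.
#' @param J optional per-arm sample-size override (e.g. for moment checks).
#' @return A data frame with columns \code{stage}, \code{arm},
#'   \code{X1, ..., Xp}, \code{Y} and \code{J} rows per active arm.
#' @examples
#' sc <- amad_scenario(K = 2, J = 10, mu_Y = c(0, 0, 0.22), rho = c(0.1, 0.6))
#' set.seed(1)
#' head(simulate_stage(sc, 1))
#' @export
simulate_stage <- function(scenario, stage, active_arms = NULL, J = NULL) {
  stopifnot(inherits(scenario, "amad_scenario"))
  if (!stage %in% c(1L, 2L)) stop("'stage' must be 1 or 2")
  if (is.null(active_arms)) {
    if (stage == 2L)
      stop("stage-2 simulation requires 'active_arms' (control + selected)")
    active_arms <- 0:scenario$K
  }
  if (inherits(active_arms, "amad_selection"))
    active_arms <- c(0L, active_arms$selected)
  active_arms <- sort(unique(as.integer(active_arms)))
  if (length(active_arms) == 0L) stop("'active_arms' is empty")
  if (any(active_arms < 0L) || any(active_arms > scenario$K))
    stop("unknown arm(s): ",
         paste(setdiff(active_arms, 0:scenario$K), collapse = ", "))
  if (!0L %in% active_arms)
    stop("'active_arms' must include the control arm 0")
  J <- if (is.null(J)) scenario$J else as.integer(J)
  p <- scenario$n_covariates
  na <- length(active_arms)
  out <- matrix(0, nrow = J * na, ncol = p + 1L)
  arm_col <- integer(J * na)
  for (i in seq_len(na)) {
    a <- active_arms[i] + 1L
    mu <- c(scenario$mu_X[a, ], scenario$mu_Y[a])
    z <- matrix(stats::rnorm(J * (p + 1L)), nrow = J) %*%
      scenario$chol_Sigma[[a]]
    rows <- (i - 1L) * J + seq_len(J)
    out[rows, ] <- sweep(z, 2L, mu, "+")
    arm_col[rows] <- active_arms[i]
  }
  cols <- c(list(stage = rep.int(as.integer(stage), J * na), arm = arm_col),
            if (p > 0L) lapply(seq_len(p), function(j) out[, j]),
            list(Y = out[, p + 1L]))
  names(cols) <- c("stage", "arm", if (p > 0L) paste0("X", seq_len(p)), "Y")
  .quickdf(cols)
}

#' Catalogue of the benchmark simulation scenarios
#'
#' Returns the grid of four data-generating mechanisms crossed with five
#' treatment-effect configurations used throughout the package's operating
#' characteristic studies: K = 2 interventions, J = 100 per arm per stage,
#' one-sided alpha 0.025, top-1 selection, covariate means 0.5 and unit
#' variances. The DGMs differ in the covariate-outcome correlations
#' (DGM1 \code{(0, 0)}, DGM2 \code{(0, 0.2)}, DGM3 \code{(0.2, 0.2)},
#' DGM4 \code{(0.1, 0.6)}); the configurations differ in the outcome means
#' (\code{Null} (0,0,0), \code{LFC50} (0,0,0.22), \code{LFC80} (0,0,0.304),
#' \code{STEP50} (0,0.11,0.22), \code{STEP80} (0,0.152,0.304)).
#'
#' @return A nested named list: \code{scenario_grid()$DGM4$STEP80} etc., each
#'   entry an [amad_scenario()].
#' @export
scenario_grid <- function() {
  rhos <- list(DGM1 = c(0, 0), DGM2 = c(0, 0.2),
               DGM3 = c(0.2, 0.2), DGM4 = c(0.1, 0.6))
  mus <- list(Null   = c(0, 0, 0),
              LFC50  = c(0, 0, 0.22),
              LFC80  = c(0, 0, 0.304),
              STEP50 = c(0, 0.11, 0.22),
              STEP80 = c(0, 0.152, 0.304))
  lapply(names(rhos), function(d) {
    out <- lapply(names(mus), function(cf)
      amad_scenario(K = 2L, J = 100L, mu_Y = mus[[cf]], rho = rhos[[d]],
                    selection_rule = select_top(1L),
                    label = paste0(d, ":", cf)))
    names(out) <- names(mus)
    out
  }) -> grid
  names(grid) <- names(rhos)
  grid
}

#' Four-arm scenario based on published COPD bronchodilator trial summaries
#'
#' A preset with K = 3 interventions against placebo and top-2 selection,
#' parameterised by arm-level summary statistics reported for a seamless
#' phase IIb/IIIa COPD study: trough FEV1 (L) as outcome and baseline FEV1 (L)
#' and bronchodilator reversibility (%) as covariates. Outcome means are
#' (1.28, 1.46, 1.46, 1.42) for placebo, indacaterol 150, indacaterol 300 and
#' tiotropium; standard deviations are 0.375 (FEV1), 0.504 (baseline FEV1) and
#' 16.63 (reversibility).
#'
#' The source summaries do not report covariate-outcome correlations, so they
#' must be supplied; the default \code{rho = c(0.7, 0.2)} takes a strong
#' baseline/follow-up correlation for lung function and a weak positive one
#' for reversibility, typical of COPD bronchodilator trials.
#'
#' @param rho covariate-outcome correlations for (baseline FEV1,
#'   reversibility), shared by all arms.
#' @param J subjects per arm per stage.
#' @return An [amad_scenario()] with \code{K = 3} and top-2 selection.
#' @export
inhance_scenario <- function(rho = c(0.7, 0.2), J = 100L) {
  amad_scenario(
    K = 3L, J = J,
    mu_Y = c(1.28, 1.46, 1.46, 1.42),
    mu_X = matrix(c(1.52, 15.6,
                    1.53, 15.2,
                    1.45, 15.6,
                    1.51, 15.5), nrow = 4L, byrow = TRUE),
    sigma2 = c(0.504^2, 16.63^2, 0.375^2),
    rho = rho,
    selection_rule = select_top(2L),
    arm_labels = c("placebo", "indacaterol150", "indacaterol300",
                   "tiotropium"),
    label = "INHANCE-based")
}

#' Standard covariate-adjustment analysis approaches
#'
#' The four modelling approaches compared throughout: no adjustment, adjust
#' for X1 only, for X2 only, and for both covariates.
#'
#' @return Named list of adjustment sets (integer covariate indices).
#' @export
adjustment_approaches <- function() {
  list(unadjusted = integer(0), adj_X1 = 1L, adj_X2 = 2L, adj_both = c(1L, 2L))
}

# minimal-overhead data.frame constructor for hot paths
.quickdf <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}
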