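# Replication engine: simulate many trials, analyse each under several
# covariate-adjustment approaches, and summarise operating characteristics.

#' Run one replication of a two-stage adaptive trial
#'
#' Simulates stage-1 data once, then for every adjustment approach fits the
#' stage-1 model, applies the selection rule and (for the realized selected
#' set) simulates stage-2 data, fits the stage-2 and pooled models, runs the
#' closed test and computes all estimators. All approaches analyse the same
#' stage-1 data; approaches whose selected sets coincide also share the same
#' stage-2 data (different selections imply different stage-2 trials, so those
#' are simulated independently).
#'
#' Uses the current RNG state; seed it for reproducibility.
#'
#' @param scenario an [amad_scenario()].
#' @param approaches named list of adjustment sets (integer covariate
#'   indices), e.g. [adjustment_approaches()].
#' @param rule,alpha,weights analysis settings; default from the scenario.
#' @return An object of class \code{"amad_replication"}: the shared
#'   \code{stage1} data, \code{stage2} data per distinct selected set, and per
#'   approach the \code{selection}, closed-\code{test} result and
#'   \code{estimates}.
#' @export
run_replication <- function(scenario, approaches = adjustment_approaches(),
                            rule = scenario$selection_rule,
                            alpha = scenario$alpha,
                            weights = scenario$stage_weights) {
  stopifnot(inherits(scenario, "amad_scenario"))
  if (!length(approaches)) stop("'approaches' is empty")
  if (is.null(names(approaches)))
    names(approaches) <- paste0("approach", seq_along(approaches))
  d1 <- simulate_stage(scenario, 1L)
  stage2 <- list()
  out <- vector("list", length(approaches))
  names(out) <- names(approaches)
  for (a in names(approaches)) {
    adj <- approaches[[a]]
    fit1 <- fit_model(d1, adj)
    sel <- select_treatments(fit1, rule)
    fit2 <- pooled <- NULL
    est <- NULL
    if (!sel$none_selected) {
      key <- paste(sort(sel$selected), collapse = ",")
      if (is.null(stage2[[key]]))
        stage2[[key]] <- simulate_stage(scenario, 2L, c(0L, sel$selected))
      d2 <- stage2[[key]]
      fit2 <- fit_model(d2, adj)
      pooled <- fit_model(rbind(d1, d2), adj)
      est <- all_estimates(fit1, fit2, pooled, sel)
    }
    test <- closed_test(fit1, fit2, sel, alpha, weights)
    out[[a]] <- list(selection = sel, test = test, estimates = est)
  }
  structure(list(stage1 = d1, stage2 = stage2, approaches = out,
                 label = scenario$label),
            class = "amad_replication")
}

# one numeric vector per replication: per approach, selection membership,
# disagreement with the reference approach, rejection flags, and
# selected-arm estimator errors
.estimators <- c("stage1", "stage2", "overall", "umvcue")

.measure_names <- function(K, approach_names) {
  per <- c(paste0("sel_", seq_len(K)), "disagree", "none_selected",
           paste0("rej_", seq_len(K)), paste0("err_", .estimators))
  as.vector(vapply(approach_names, function(a) paste0(a, ".", per),
                   character(length(per))))
}

.replication_measures <- function(rec, truth, K) {
  apps <- rec$approaches
  ref <- if ("unadjusted" %in% names(apps)) "unadjusted" else names(apps)[1L]
  ref_sel <- sort(apps[[ref]]$selection$selected)
  unlist(lapply(apps, function(x) {
    sel <- x$selection$selected
    elem <- x$test$elementary
    rej <- as.numeric(elem$reject[match(seq_len(K), elem$arm)])
    errs <- rep(NA_real_, 4L)
    if (!is.null(x$estimates)) {
      tr <- truth[x$estimates$arm]
      errs <- vapply(.estimators, function(e)
        mean(x$estimates[[e]] - tr), numeric(1L))
    }
    c(as.numeric(seq_len(K) %in% sel),
      as.numeric(!setequal(sort(sel), ref_sel)),
      as.numeric(x$selection$none_selected), rej, errs)
  }), use.names = FALSE)
}

#' Summarise operating characteristics over replications
#'
#' Computes, per adjustment approach: per-arm selection frequencies, the
#' disagreement rate with the unadjusted (reference) approach, the
#' probability of rejecting at least one hypothesis, the familywise error
#' rate (probability of rejecting at least one *true* null, i.e. an arm with
#' true effect <= 0), per-arm marginal rejection probabilities, and bias /
#' MSE of the stage-1, stage-2, overall and UMVCUE estimators for the
#' realized selected arm, each with its Monte-Carlo standard error. Bias and
#' MSE are unconditional over selection: each replication contributes the
#' selected arm's estimation error against that arm's true effect.
#'
#' @param records list of [run_replication()] results.
#' @param truth true treatment effects \eqn{\beta_1, \ldots, \beta_K}
#'   (intervention minus control outcome means).
#' @return Data frame with one row per approach.
#' @export
summarize_replications <- function(records, truth) {
  if (!length(records)) stop("no replication records")
  K <- length(truth)
  approach_names <- names(records[[1L]]$approaches)
  mat <- t(vapply(records, .replication_measures, truth = truth, K = K,
                  FUN.VALUE = numeric(length(.measure_names(K, approach_names)))))
  colnames(mat) <- .measure_names(K, approach_names)
  .summarize_measures(mat, approach_names, K, truth)
}

.summarize_measures <- function(mat, approach_names, K, truth) {
  n <- nrow(mat)
  rows <- lapply(approach_names, function(a) {
    g <- function(col) mat[, paste0(a, ".", col)]
    pm <- function(x) {                       # proportion with MC-SE
      p <- mean(x, na.rm = TRUE)
      c(p, sqrt(p * (1 - p) / sum(!is.na(x))))
    }
    out <- list(approach = a, n_reps = n)
    for (k in seq_len(K)) {
      v <- pm(g(paste0("sel_", k)))
      out[[paste0("sel_freq_", k)]] <- v[1L]
      out[[paste0("sel_freq_", k, "_se")]] <- v[2L]
    }
    v <- pm(g("disagree"))
    out$disagreement <- v[1L]; out$disagreement_se <- v[2L]
    rej <- vapply(seq_len(K), function(k) g(paste0("rej_", k)),
                  numeric(n))
    any_rej <- as.numeric(rowSums(rej) > 0)
    v <- pm(any_rej)
    out$p_reject_any <- v[1L]; out$p_reject_any_se <- v[2L]
    nulls <- which(truth <= 0)
    if (length(nulls)) {
      any_true <- as.numeric(rowSums(rej[, nulls, drop = FALSE]) > 0)
      v <- pm(any_true)
      out$fwer <- v[1L]; out$fwer_se <- v[2L]
    } else {
      out$fwer <- NA_real_; out$fwer_se <- NA_real_
    }
    for (k in seq_len(K)) {
      v <- pm(rej[, k])
      out[[paste0("reject_", k)]] <- v[1L]
      out[[paste0("reject_", k, "_se")]] <- v[2L]
    }
    for (e in .estimators) {
      err <- g(paste0("err_", e))
      err <- err[!is.na(err)]
      m <- length(err)
      out[[paste0("bias_", e)]] <- mean(err)
      out[[paste0("bias_", e, "_se")]] <- stats::sd(err) / sqrt(m)
      sq <- err^2
      out[[paste0("mse_", e)]] <- mean(sq)
      out[[paste0("mse_", e, "_se")]] <- stats::sd(sq) / sqrt(m)
    }
    .quickdf(out)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo confidence interval for a nominal error rate
#'
#' The 95% interval \eqn{\alpha \pm 1.959964\sqrt{\alpha(1-\alpha)/n}} for an
#' empirical rejection proportion at its nominal value, clipped to \[0, 1\].
#'
#' @param alpha nominal rate in (0, 1).
#' @param n_reps number of replications.
#' @return \code{c(lower, upper)}.
#' @examples
#' fwer_interval(0.025, 1e5) # c(0.02403, 0.02597) to 5 digits
#' @export
fwer_interval <- function(alpha, n_reps) {
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  if (any(alpha < 0 | alpha > 1)) stop("'alpha' must lie in [0, 1]")
  half <- stats::qnorm(0.975) * sqrt(alpha * (1 - alpha) / n_reps)
  c(lower = max(0, alpha - half), upper = min(1, alpha + half))
}

#' Replicated simulation study over a scenario grid
#'
#' Runs \code{n_reps} independent replications of every scenario, analysing
#' each under all adjustment approaches, and returns the summarised operating
#' characteristics. Every replication runs on its own pre-assigned RNG
#' substream (L'Ecuyer-CMRG spawned from \code{seed}), so results are
#' reproducible and identical for any worker count.
#'
#' @param scenarios an [amad_scenario()] or a named list of them.
#' @param n_reps replications per scenario (>= 1).
#' @param approaches named list of adjustment sets.
#' @param seed integer root seed.
#' @param workers number of forked workers for \code{parallel::mclapply}.
#' @return Data frame with one row per (scenario, approach); the per-
#'   replication measure matrices are attached as \code{attr(,"measures")}
#'   (a named list). Replications that fail are dropped with a warning
#'   listing their ids.
#' @export
run_grid <- function(scenarios, n_reps, approaches = adjustment_approaches(),
                     seed = 1L, workers = 1L) {
  if (inherits(scenarios, "amad_scenario")) {
    nm <- if (is.null(scenarios$label)) "scenario" else scenarios$label
    scenarios <- stats::setNames(list(scenarios), nm)
  }
  if (n_reps < 1L) stop("'n_reps' must be at least 1")
  if (is.null(names(scenarios))) stop("'scenarios' must be named")
  summaries <- list()
  measures <- list()
  for (nm in names(scenarios)) .with_preserved_rng(function() {
    sc <- scenarios[[nm]]
    truth <- sc$mu_Y[-1L] - sc$mu_Y[1L]
    K <- sc$K
    cols <- .measure_names(K, names(approaches))
    streams <- .rng_streams(seed, n_reps)
    run_one <- function(r) {
      assign(".Random.seed", streams[[r]], envir = globalenv())
      tryCatch(.replication_measures(
        run_replication(sc, approaches), truth, K),
        error = function(e) rep(NA_real_, length(cols)))
    }
    res <- if (workers > 1L)
      parallel::mclapply(seq_len(n_reps), run_one, mc.cores = workers)
    else lapply(seq_len(n_reps), run_one)
    mat <- do.call(rbind, res)
    colnames(mat) <- cols
    failed <- which(apply(is.na(mat), 1L, all))
    if (length(failed)) {
      warning("scenario ", nm, ": ", length(failed),
              " replication(s) failed: ids ",
              paste(utils::head(failed, 10L), collapse = ", "),
              if (length(failed) > 10L) ", ...")
      mat <- mat[-failed, , drop = FALSE]
    }
    s <- .summarize_measures(mat, names(approaches), K, truth)
    s <- cbind(.quickdf(list(scenario = rep(nm, nrow(s)))), s)
    summaries[[nm]] <<- s
    measures[[nm]] <<- mat
  })
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  attr(out, "measures") <- measures
  out
}

# pre-assigned per-replication L'Ecuyer-CMRG substreams (caller is
# responsible for saving/restoring the session RNG state)
.rng_streams <- function(seed, n) {
  genv <- globalenv()
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = genv, inherits = FALSE)
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# evaluate fn() with the session RNG kind and state restored afterwards
.with_preserved_rng <- function(fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old_seed <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had) assign(".Random.seed", old_seed, envir = genv)
  })
  fn()
}
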