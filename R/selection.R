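# Interim treatment selection on stage-1 covariate-adjusted statistics.

#' Selection rules
#'
#' \code{select_top(k)} continues the k highest-ranked interventions (by
#' stage-1 t-statistic); \code{select_threshold(cutoff)} continues every
#' intervention whose stage-1 t-statistic exceeds \code{cutoff} and flags the
#' trial as stopped for futility when none does.
#'
#' @param k number of interventions to continue.
#' @param cutoff real threshold on the t-statistic.
#' @return A rule descriptor of class \code{"amad_rule"}.
#' @export
select_top <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  structure(list(type = "top_k", k = k), class = "amad_rule")
}

#' @rdname select_top
#' @export
select_threshold <- function(cutoff) {
  structure(list(type = "threshold", cutoff = as.numeric(cutoff)),
            class = "amad_rule")
}

.check_rule <- function(rule, K) {
  if (!inherits(rule, "amad_rule")) stop("invalid selection rule")
  if (rule$type == "top_k" && rule$k > K)
    stop("top-k rule with k = ", rule$k, " exceeds the number of arms K = ", K)
  invisible(rule)
}

#' Rank interventions by their stage-1 t-statistics
#'
#' Arms are ordered by decreasing \eqn{t_k = \hat\beta_k/\tau_k}; exact ties
#' are broken by the lower arm index (a measure-zero event for continuous
#' data, fixed deterministically for reproducibility).
#'
#' @param stats an [fit_model()] result or a data frame with columns
#'   \code{arm}, \code{estimate}, \code{se}.
#' @return Integer vector of arm indices, best first.
#' @export
rank_treatments <- function(stats) {
  if (inherits(stats, "amad_fit")) {
    if (any(stats$tau <= 0)) stop("non-positive standard error")
    return(stats$arms[order(-stats$tstat, stats$arms)])
  }
  stats <- .as_stats(stats)
  if (any(stats$se <= 0)) stop("non-positive standard error")
  t <- stats$estimate / stats$se
  stats$arm[order(-t, stats$arm)]
}

.as_stats <- function(stats) {
  if (inherits(stats, "amad_fit")) stats <- comparison_stats(stats)
  if (!all(c("arm", "estimate", "se") %in% names(stats)))
    stop("'stats' must be an amad_fit or have columns arm, estimate, se")
  if (!"statistic" %in% names(stats))
    stats$statistic <- stats$estimate / stats$se
  stats
}

#' Apply a pre-specified selection rule
#'
#' @param ranking integer arm ranking from [rank_treatments()].
#' @param stats the statistics used for ranking (fit or data frame).
#' @param rule an \code{"amad_rule"} from [select_top()] or
#'   [select_threshold()].
#' @return An object of class \code{"amad_selection"}: \code{ranking},
#'   \code{selected} (arm subset continuing to stage 2, control implicit;
#'   empty with \code{none_selected = TRUE} when a threshold rule selects
#'   nothing), \code{rule} and \code{statistics}.
#' @export
apply_rule <- function(ranking, stats, rule) {
  stats <- .as_stats(stats)
  .check_rule(rule, length(ranking))
  if (rule$type == "top_k") {
    selected <- ranking[seq_len(rule$k)]
  } else {
    t <- stats$statistic[match(ranking, stats$arm)]
    selected <- ranking[t > rule$cutoff]
  }
  structure(list(ranking = as.integer(ranking),
                 selected = as.integer(selected),
                 none_selected = length(selected) == 0L,
                 rule = rule, statistics = stats),
            class = "amad_selection")
}

#' Select treatments from a stage-1 fit
#'
#' Convenience wrapper: rank by covariate-adjusted t-statistic and apply the
#' rule. The same adjustment set should be used here as in the final
#' analysis.
#'
#' @param fit stage-1 [fit_model()] result.
#' @param rule an \code{"amad_rule"}.
#' @return An \code{"amad_selection"}.
#' @export
select_treatments <- function(fit, rule) {
  apply_rule(rank_treatments(fit), fit, rule)
}

#' @export
print.amad_selection <- function(x, ...) {
  cat("Interim selection (",
      if (x$rule$type == "top_k") paste0("top-", x$rule$k)
      else paste0("t > ", format(x$rule$cutoff)), ")\n", sep = "")
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  if (x$none_selected)
    cat("  no arm selected: trial stops for futility\n")
  else
    cat("  selected:", paste(x$selected, collapse = ", "),
        "(+ control)\n")
  invisible(x)
}
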