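# Plain-text I/O: subject-level datasets as CSV with a `stage,arm,X...,Y`
# header, scenario configurations as YAML key/value files. Numeric values are
# written with 15 significant digits so write-then-read round-trips are
# lossless at double precision for practical purposes.

#' Read / write subject-level trial data
#'
#' Datasets are comma-separated with a header row \code{stage,arm,X1,...,Y};
#' arm 0 is the control by convention.
#'
#' @param data data frame in the standard layout.
#' @param path file path.
#' @return \code{read_trial_data} returns the data frame;
#'   \code{write_trial_data} returns \code{path} invisibly.
#' @export
write_trial_data <- function(data, path) {
  if (!all(c("stage", "arm", "Y") %in% names(data)))
    stop("'data' must have columns stage, arm, Y")
  num <- vapply(data, is.double, logical(1L))
  out <- data
  out[num] <- lapply(data[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  need <- c("stage", "arm", "Y")
  if (!all(need %in% names(d)))
    stop("malformed dataset: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Read / write a scenario configuration
#'
#' Scenarios serialise to a YAML key/value file mirroring the
#' [amad_scenario()] fields; per-arm parameter matrices are stored row-wise
#' (one row per arm, control first).
#'
#' @param scenario an [amad_scenario()].
#' @param path file path.
#' @return \code{read_scenario} returns the reconstructed
#'   [amad_scenario()]; \code{write_scenario} returns \code{path} invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "amad_scenario"))
  rule <- scenario$selection_rule
  x <- list(K = scenario$K, J = scenario$J,
            n_covariates = scenario$n_covariates,
            arm_labels = as.list(scenario$arm_labels),
            mu_Y = as.list(scenario$mu_Y),
            mu_X = apply(scenario$mu_X, 1L, as.list, simplify = FALSE),
            sigma2 = apply(scenario$sigma2, 1L, as.list, simplify = FALSE),
            rho = apply(scenario$rho, 1L, as.list, simplify = FALSE),
            selection_rule = unclass(rule),
            adjustment_set = as.list(scenario$adjustment_set),
            alpha = scenario$alpha,
            stage_weights = as.list(scenario$stage_weights),
            label = scenario$label)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  x <- yaml::read_yaml(path)
  need <- c("K", "J", "mu_Y", "selection_rule", "alpha")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed scenario configuration: missing field(s) ",
         paste(miss, collapse = ", "))
  p <- x$n_covariates
  rows <- function(f) {
    if (is.null(x[[f]])) return(NULL)
    do.call(rbind, lapply(x[[f]], function(r) as.numeric(unlist(r))))
  }
  rule <- x$selection_rule
  rule <- if (identical(rule$type, "top_k")) select_top(rule$k)
  else if (identical(rule$type, "threshold")) select_threshold(rule$cutoff)
  else stop("malformed scenario configuration: unknown selection_rule type")
  amad_scenario(K = x$K, J = x$J, mu_Y = as.numeric(unlist(x$mu_Y)),
                mu_X = if (p > 0L) rows("mu_X") else matrix(0, x$K + 1L, 0L),
                sigma2 = rows("sigma2"),
                rho = if (p > 0L) rows("rho") else matrix(0, x$K + 1L, 0L),
                n_covariates = p,
                selection_rule = rule,
                adjustment_set = as.integer(unlist(x$adjustment_set)),
                alpha = x$alpha,
                stage_weights = as.numeric(unlist(x$stage_weights)),
                arm_labels = as.character(unlist(x$arm_labels)),
                label = x$label)
}

#' Export a closed-test result as delimited text
#'
#' One row per intersection hypothesis with columns
#' \code{S,p1,p2,p_combined,reject}, followed by a separate elementary
#' summary written to \code{<path>} with suffix \code{_elementary}.
#'
#' @param test an \code{"amad_closed_test"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_test_result <- function(test, path) {
  stopifnot(inherits(test, "amad_closed_test"))
  h <- test$hypotheses
  h$p1 <- sprintf("%.15g", h$p1)
  h$p2 <- ifelse(is.na(h$p2), "NA", sprintf("%.15g", h$p2))
  h$p_combined <- sprintf("%.15g", h$p_combined)
  utils::write.csv(h, path, row.names = FALSE, quote = TRUE)
  e <- test$elementary
  utils::write.csv(e, sub("(\\.[^.]*)?$", "_elementary\\1", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
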