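#' Tertile risk groups from the combined prognostic index
#'
#' Cutpoints are the empirical 1/3 and 2/3 quantiles (type-7 linear
#' interpolation) of the TRAINING combined prognostic index; subjects are
#' assigned low / medium / high with boundary subjects going to the lower
#' group. The same cutpoints trichotomise any test-set PI. Published
#' cutpoints can be supplied directly via `cutpoints`.
#'
#' @param training_pi combined PI of the training cohort.
#' @param test_pi optional test-cohort PI to trichotomise with the training
#'   cutpoints.
#' @param cutpoints optional length-2 numeric vector overriding the
#'   quantile-derived cutpoints.
#' @return object of class `risk_grouping`: `cutpoints`, `training` (factor
#'   low/medium/high), `test` (or NULL), per-group counts.
#' @export
derive_groups <- function(training_pi, test_pi = NULL, cutpoints = NULL) {
  stopifnot(length(training_pi) >= 1)
  if (is.null(cutpoints))
    cutpoints <- unname(stats::quantile(training_pi, c(1, 2) / 3, type = 7))
  if (diff(cutpoints) <= 0) stop_micoxpen("degenerate cutpoints")
  assign_group <- function(p)
    factor(ifelse(p <= cutpoints[1], "low",
                  ifelse(p <= cutpoints[2], "medium", "high")),
           levels = c("low", "medium", "high"))
  training <- assign_group(training_pi)
  test <- if (!is.null(test_pi)) assign_group(test_pi)
  structure(list(cutpoints = cutpoints, training = training, test = test,
                 training_n = table(training),
                 test_n = if (!is.null(test)) table(test)),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("Risk groups: cutpoints %.4g / %.4g\n",
              x$cutpoints[1], x$cutpoints[2]))
  cat("  training:", paste(sprintf("%s %d", names(x$training_n), x$training_n),
                           collapse = ", "), "\n")
  if (!is.null(x$test))
    cat("  test:    ", paste(sprintf("%s %d", names(x$test_n), x$test_n),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Kaplan-Meier curves by risk group
#'
#' Product-limit estimate with Greenwood 95% CIs within each risk group.
#'
#' @param groups factor of group assignments (e.g. `risk_grouping$training`).
#' @param time,event outcome.
#' @return object of class `km_by_group`: `curves` data frame (`group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`), per-group `n`
#'   and event counts, and the underlying `survfit`.
#' @export
km_by_group <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) == 0 || any(table(groups) == 0))
    stop_micoxpen("empty risk group")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups,
                          conf.type = "log")
  strata_lab <- if (is.null(sf$strata)) levels(groups)[1]
                else sub("^groups=", "", names(sf$strata))
  grp <- if (is.null(sf$strata)) rep(strata_lab, length(sf$time))
         else rep(strata_lab, sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       lower = sf$lower, upper = sf$upper)
  counts <- data.frame(group = levels(groups),
                       n = as.integer(table(groups)),
                       events = as.integer(tapply(event, groups, sum)))
  structure(list(curves = curves, counts = counts, survfit = sf),
            class = "km_by_group")
}

#' @export
print.km_by_group <- function(x, ...) {
  cat("Kaplan-Meier by risk group\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write KM curve tables as TSV
#' @param x a `km_by_group`.
#' @param path output path.
#' @export
write_km_table <- function(x, path) {
  utils::write.table(x$curves, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plot KM curves by risk group
#' @param x a `km_by_group`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.km_by_group <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_micoxpen("ggplot2 is required for plotting")
  ggplot2::ggplot(x$curves,
                  ggplot2::aes(time, surv, colour = group)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = lower), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = upper), linetype = "dotted") +
    ggplot2::labs(x = "Months", y = "Overall survival") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}
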