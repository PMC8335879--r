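#' Scaled rankits by Bloom's approximation
#'
#' `z_i = sqrt(pi/8) * qnorm((i - 3/8) / (n + 1/4))` for i = 1..n: the
#' expected standard-normal order statistics, scaled by `(8/pi)^(-1/2)` so
#' that the slope of a Cox regression on them (the D-statistic) is
#' interpretable as a log hazard ratio between prognostic halves.
#'
#' @param n number of subjects (>= 1).
#' @return strictly increasing, antisymmetric numeric vector of length n.
#' @export
bloom_rankits <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  sqrt(pi / 8) * stats::qnorm((i - 3 / 8) / (n + 1 / 4))
}

#' Prognostic-separation D-statistic
#'
#' Steps: order subjects by prognostic index; assign the scaled rankits by
#' rank (smallest rankit to the smallest PI; tied PIs receive the mid-rankit
#' at their average rank); regress overall survival on the rankits in a Cox
#' model. D is the rankit coefficient, with its model-based variance. D is
#' invariant to strictly increasing transformations of the PI.
#'
#' @param pi_ per-subject prognostic index (finite).
#' @param time,event outcome (>= 1 event).
#' @return list: `d`, `variance`, `n`.
#' @export
d_statistic <- function(pi_, time, event) {
  stopifnot(all(is.finite(pi_)))
  if (sum(event) < 1) stop_micoxpen("no events in the data")
  n <- length(pi_)
  if (length(unique(pi_)) == 1)
    stop_micoxpen("all prognostic indices tied; D undefined")
  r <- rank(pi_, ties.method = "average")
  z <- sqrt(pi / 8) * stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  fit <- survival::coxph(survival::Surv(time, event) ~ z)
  list(d = unname(fit$coefficients), variance = unname(stats::vcov(fit)[1, 1]),
       n = n)
}

#' Combined D-statistic across imputations
#'
#' One D-statistic per imputed dataset, pooled by Rubin's rules.
#'
#' @param pi_list list of m per-imputation prognostic-index vectors.
#' @param time,event outcome (identical across imputations).
#' @return object of class `d_stat_result`: `per_imputation` data frame,
#'   `combined`, `within`, `between`, `total`, `ci`.
#' @export
combined_d <- function(pi_list, time, event) {
  m <- length(pi_list)
  if (m < 2) stop_micoxpen("combined_d needs m >= 2 imputations")
  per <- lapply(pi_list, d_statistic, time = time, event = event)
  d <- vapply(per, `[[`, 0, "d")
  v <- vapply(per, `[[`, 0, "variance")
  p <- pool(d, v)
  structure(list(per_imputation = data.frame(imputation = seq_len(m),
                                             d = d, variance = v),
                 combined = p$estimate, within = p$within,
                 between = p$between, total = p$total, ci = p$ci, m = m),
            class = "d_stat_result")
}

#' @export
print.d_stat_result <- function(x, ...) {
  cat(sprintf("Combined D-statistic %.3f (95%% CI %.3f to %.3f)\n",
              x$combined, x$ci[1], x$ci[2]))
  cat(sprintf("  within-imputation variance %.3g, between %.3g, m = %d\n",
              x$within, x$between, x$m))
  invisible(x)
}

#' Calibration of predicted survival probabilities
#'
#' Splits subjects into risk groups by the deciles of the predicted
#' probabilities (empirical type-7 quantiles; boundary subjects go to the
#' lower group); group predicted probability = median of the predictions in
#' the group; group observed probability = Kaplan-Meier estimate at the
#' horizon with Greenwood 95% CI. Groups with nobody still at risk before the
#' horizon are reported as unavailable (NA).
#'
#' @param pred per-subject predicted survival probabilities at the horizon.
#' @param time,event outcome.
#' @param t horizon (same unit as `time`).
#' @param groups target number of risk groups (default 10; ties in the
#'   predictions can force fewer).
#' @return object of class `calibration_result`: data frame `table` (`group`,
#'   `n`, `predicted`, `observed`, `lower`, `upper`) plus `t`.
#' @export
calibration <- function(pred, time, event, t, groups = 10) {
  stopifnot(length(pred) == length(time), t >= 0)
  if (t > max(time)) stop_micoxpen("horizon beyond maximum follow-up")
  breaks <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = groups + 1),
                                   type = 7))
  grp <- if (length(breaks) > 2)
    cut(pred, breaks, include.lowest = TRUE, right = TRUE)
  else factor(rep(1, length(pred)))
  lev <- levels(grp)
  tab <- data.frame(group = seq_along(lev), n = NA_integer_,
                    predicted = NA_real_, observed = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (g in seq_along(lev)) {
    sel <- grp == lev[g]
    tab$n[g] <- sum(sel)
    tab$predicted[g] <- stats::median(pred[sel])
    if (t == 0) { tab$observed[g] <- tab$lower[g] <- tab$upper[g] <- 1; next }
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1,
                            conf.type = "log")
    # curve unavailable at t if follow-up in the group ends (censored) earlier
    if (max(time[sel]) < t && min(sf$surv) > 0) next
    s <- summary(sf, times = t, extend = TRUE)
    tab$observed[g] <- s$surv
    tab$lower[g] <- s$lower
    tab$upper[g] <- s$upper
  }
  structure(list(table = tab, t = t), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration at t = %.3g (%d groups)\n", x$t, nrow(x$table)))
  print(x$table, digits = 3)
  invisible(x)
}

#' Calibration slope from one calibration table
#'
#' Ordinary least squares of the group predicted probabilities (response) on
#' the group observed probabilities (regressor). Slope 1 under perfect
#' calibration; values above 1 indicate predictions more dispersed than the
#' observed probabilities.
#'
#' @param result a `calibration_result` (or its `table`).
#' @return the OLS slope.
#' @export
calibration_slope <- function(result) {
  tab <- if (inherits(result, "calibration_result")) result$table else result
  ok <- !is.na(tab$observed) & !is.na(tab$predicted)
  if (sum(ok) < 2)
    stop_micoxpen("need >= 2 risk groups with an observed probability")
  unname(stats::coef(stats::lm(predicted ~ observed, data = tab[ok, ]))[2])
}

#' Pool calibration slopes across imputations
#'
#' Rubin point-estimate pooling (the mean of the m slopes). No confidence
#' interval is reported: with only ten group points per regression, interval
#' estimates would be unreliable.
#'
#' @param slopes numeric vector of per-imputation slopes.
#' @return the pooled slope.
#' @export
pool_calibration_slopes <- function(slopes) mean(slopes)

#' Schoenfeld residuals at fixed coefficients
#'
#' Unscaled (also called weighted) Schoenfeld residuals: for each event, the
#' subject's covariate value minus the risk-weighted mean of that covariate
#' over the risk set, evaluated at the supplied coefficients. Used in
#' preference to the scaled version, which requires inverting a
#' variance-covariance matrix that can be singular when it comes from
#' bootstrap resampling of a penalised model.
#'
#' @param x design matrix.
#' @param time,event outcome.
#' @param coef coefficient vector (e.g. a penalised fit's).
#' @return matrix with one row per event (ordered by event time) and one
#'   column per design column; attribute `time` holds the event times.
#' @export
schoenfeld_residuals <- function(x, time, event, coef) {
  x <- as.matrix(x)
  lp <- drop(x %*% coef)
  w <- exp(lp)
  ev_idx <- which(event == 1)
  ev_idx <- ev_idx[order(time[ev_idx])]
  res <- matrix(NA_real_, length(ev_idx), ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (k in seq_along(ev_idx)) {
    i <- ev_idx[k]
    at_risk <- time >= time[i]
    xbar <- colSums(x[at_risk, , drop = FALSE] * w[at_risk]) / sum(w[at_risk])
    res[k, ] <- x[i, ] - xbar
  }
  attr(res, "time") <- time[ev_idx]
  res
}

#' Proportional-hazards check across imputations
#'
#' Within each imputed dataset, the unscaled Schoenfeld residuals of each
#' covariate are regressed on event time in a linear model; proportional
#' hazards for the covariate is concluded if the slope is not significantly
#' different from zero at the 5% level. A covariate's overall verdict is
#' "violated" if any imputation's test is significant.
#'
#' @param designs list of m design matrices.
#' @param coef_matrix m x p coefficient matrix (or list of fits).
#' @param time,event outcome.
#' @param alpha significance level (default 0.05).
#' @return object of class `ph_check_result`: `tests` (data frame:
#'   imputation, term, slope, p), `verdict` (named character vector).
#' @export
ph_check <- function(designs, coef_matrix, time, event, alpha = 0.05) {
  if (is.list(coef_matrix) && !is.matrix(coef_matrix))
    coef_matrix <- t(vapply(coef_matrix, `[[`,
                            numeric(ncol(designs[[1]])), "coef"))
  if (sum(event) < 3)
    stop_micoxpen("need >= 3 events for the Schoenfeld residual regression")
  m <- length(designs)
  rows <- list()
  for (i in seq_len(m)) {
    res <- schoenfeld_residuals(designs[[i]], time, event, coef_matrix[i, ])
    et <- attr(res, "time")
    for (j in colnames(res)) {
      sm <- summary(stats::lm(res[, j] ~ et))
      rows[[paste(i, j)]] <- data.frame(
        imputation = i, term = j,
        slope = sm$coefficients[2, 1], p = sm$coefficients[2, 4])
    }
  }
  tests <- do.call(rbind, rows); rownames(tests) <- NULL
  verdict <- vapply(unique(tests$term), function(j)
    if (any(tests$p[tests$term == j] < alpha)) "violated" else "ok", "")
  structure(list(tests = tests, verdict = verdict, alpha = alpha),
            class = "ph_check_result")
}

#' @export
print.ph_check_result <- function(x, ...) {
  cat("Proportional-hazards check (unscaled Schoenfeld residuals on time)\n")
  for (j in names(x$verdict)) {
    p <- x$tests$p[x$tests$term == j]
    cat(sprintf("  %-12s min p = %.3f over %d imputation(s): %s\n",
                j, min(p), length(p), x$verdict[[j]]))
  }
  invisible(x)
}

#' Uno's censoring-robust concordance at a horizon
#'
#' Inverse-probability-of-censoring-weighted concordance restricted to
#' comparable pairs whose earlier time is an event before `tau`. Pair (i, j)
#' with `event_i = 1`, `T_i < T_j`, `T_i < tau` receives weight
#' `1 / G(T_i-)^2`, where G is the Kaplan-Meier estimate of the censoring
#' distribution; the pair is concordant when the earlier subject has the
#' larger prognostic index (ties in PI count 1/2).
#'
#' @param pi_ per-subject prognostic index.
#' @param time,event outcome.
#' @param tau horizon (> 0).
#' @return concordance in `[0, 1]`.
#' @export
uno_c <- function(pi_, time, event, tau) {
  stopifnot(tau > 0, length(pi_) == length(time))
  sfG <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G_minus <- function(t) vapply(t, function(ti) {
    j <- sum(sfG$time < ti)
    if (j == 0) 1 else sfG$surv[j]
  }, 0)
  anchors <- which(event == 1 & time < tau)
  if (!length(anchors)) stop_micoxpen("no events before tau")
  g <- G_minus(time[anchors])
  if (any(g <= 0)) stop_micoxpen("censoring survival reaches 0 before tau")
  w <- 1 / g^2
  num <- 0; den <- 0
  for (k in seq_along(anchors)) {
    i <- anchors[k]
    later <- time > time[i]
    nlater <- sum(later)
    if (!nlater) next
    conc <- sum(pi_[i] > pi_[later]) + 0.5 * sum(pi_[i] == pi_[later])
    num <- num + w[k] * conc
    den <- den + w[k] * nlater
  }
  if (den == 0) stop_micoxpen("no comparable pairs before tau")
  num / den
}
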