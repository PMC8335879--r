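# Cox partial-likelihood machinery. Unpenalised fits delegate to
# survival::coxph (Efron ties by default); penalised fits to glmnet's
# coordinate descent. The LASSO penalty follows glmnet's per-observation
# scaling: the objective maximised is l(beta)/n - lambda * sum(|beta_i|).

surv_y <- function(time, event) survival::Surv(time, event)

check_survival_inputs <- function(x, time, event) {
  if (sum(event) < 1) stop_micoxpen("no events in the data")
  if (!all(is.finite(x))) stop_micoxpen("non-finite design values")
  stopifnot(length(time) == nrow(x), length(event) == nrow(x))
}

# Smallest lambda (glmnet scaling) with an all-zero solution: the maximum
# absolute per-observation score of the null Cox partial likelihood.
cox_lambda_max <- function(x, time, event) {
  n <- nrow(x)
  ord <- order(time)
  xs <- x[ord, , drop = FALSE]; ev <- event[ord]; tt <- time[ord]
  # gradient at beta = 0 (Breslow): sum over events of (x_i - riskset mean)
  csum <- apply(xs[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  nrisk <- n:1
  # handle ties: risk set = subjects with time >= t_i
  first_ge <- match(tt, tt)   # index of first subject with each time value
  grad <- colSums((xs - csum[first_ge, , drop = FALSE] /
                     nrisk[first_ge])[ev == 1, , drop = FALSE])
  max(abs(grad)) / n
}

# Decreasing lambda path ending at `lambda`, for single-lambda extraction
# (glmnet's path-wise fits are more stable than a cold single-lambda call).
lambda_path_to <- function(x, time, event, lambda, length_out = 30) {
  lmax <- cox_lambda_max(x, time, event)
  if (lambda >= lmax) return(sort(unique(c(lmax * 1.0001, lambda)), decreasing = TRUE))
  lo <- max(lambda, 1e-8)
  path <- exp(seq(log(lmax), log(lo), length.out = length_out))
  sort(unique(c(path[path > lambda], lambda)), decreasing = TRUE)
}

#' Fit a (penalised) Cox proportional hazards model
#'
#' At `lambda = 0`, the unpenalised partial-likelihood MLE via Newton-Raphson
#' (`survival::coxph`), with model-based variances. At `lambda > 0`, the LASSO
#' solution maximising `l(beta)/n - lambda * sum(|beta_i|)` by coordinate
#' descent (`glmnet`), with some coefficients exactly zero. Either way the
#' Breslow baseline cumulative hazard at the fitted coefficients is attached.
#'
#' @param x design matrix (see [build_design()]); columns are penalised as-is,
#'   no internal standardisation.
#' @param time,event survival outcome (time > 0, event 0/1).
#' @param lambda penalty, >= 0 (glmnet per-observation scaling).
#' @param ties tie handling for the unpenalised fit: `"efron"` (default) or
#'   `"breslow"`.
#' @return object of class `cox_fit` (`lambda = 0`: elements `coef`, `var`,
#'   `loglik`, `baseline`) or `penalized_cox_fit` (elements `coef` with exact
#'   zeros, `lambda`, `selected`, `baseline`).
#' @export
fit_cox <- function(x, time, event, lambda = 0, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  check_survival_inputs(x, time, event)
  if (lambda == 0) {
    df <- as.data.frame(x)
    df$.time <- time; df$.event <- event
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", setdiff(names(df), c(".time", ".event"))),
            collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = ties)
    if (anyNA(fit$coefficients))
      stop_micoxpen("singular design in unpenalised Cox fit")
    beta <- stats::setNames(as.numeric(fit$coefficients), colnames(x))
    structure(list(coef = beta, var = stats::vcov(fit),
                   loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                   lambda = 0, ties = ties,
                   baseline = breslow_baseline(x, time, event, beta)),
              class = "cox_fit")
  } else {
    path <- lambda_path_to(x, time, event, lambda)
    # glmnet requires >= 2 columns; pad single-column designs with a null
    # column that can never be selected
    xg <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
    g <- glmnet::glmnet(xg, surv_y(time, event), family = "cox",
                        lambda = path, standardize = FALSE, thresh = 1e-10)
    j <- which.min(abs(g$lambda - lambda))
    beta_all <- if (abs(g$lambda[j] - lambda) <= 1e-8 * max(lambda, 1))
      as.numeric(g$beta[, j])
    else
      as.numeric(suppressWarnings(glmnet::coef.glmnet(g, s = lambda)))
    beta <- stats::setNames(beta_all[seq_len(ncol(x))], colnames(x))
    structure(list(coef = beta, lambda = lambda, lambda_path = path,
                   selected = colnames(x)[beta != 0], ties = ties,
                   baseline = breslow_baseline(x, time, event, beta)),
              class = "penalized_cox_fit")
  }
}

#' Breslow baseline cumulative hazard
#'
#' `Lambda0(t) = sum over event times t_j <= t of d_j / sum_{risk set}
#' exp(linear predictor)` evaluated at fixed coefficients.
#'
#' @param x design matrix.
#' @param time,event outcome.
#' @param coef coefficient vector.
#' @return data frame `time`, `cumhaz` at the distinct event times.
#' @export
breslow_baseline <- function(x, time, event, coef) {
  lp <- drop(as.matrix(x) %*% coef)
  et <- sort(unique(time[event == 1]))
  risk <- exp(lp)
  denom <- vapply(et, function(t) sum(risk[time >= t]), 0)
  d <- vapply(et, function(t) sum(event[time == t]), 0)
  data.frame(time = et, cumhaz = cumsum(d / denom))
}

# Step-function lookup of a baseline cumulative hazard table.
cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[idx + 1]
}

#' Predicted survival probabilities
#'
#' `S(t | x) = exp(-Lambda0(t) * exp(PI))` with `PI = x' beta` and the fit's
#' Breslow baseline. Horizons beyond the last event time extrapolate flat
#' (with a warning).
#'
#' @param fit a `cox_fit` / `penalized_cox_fit`, or any list with elements
#'   `coef` and `baseline`.
#' @param newx design matrix for the subjects to score (same columns and
#'   standardisation as the training design).
#' @param t horizon (same time unit as training).
#' @return vector of probabilities in (0, 1].
#' @export
predict_survival <- function(fit, newx, t) {
  stopifnot(length(t) == 1, t >= 0)
  if (t > max(fit$baseline$time))
    warning("horizon beyond last event time; extrapolating flat")
  pi_ <- drop(as.matrix(newx) %*% fit$coef)
  exp(-cumhaz_at(fit$baseline, t) * exp(pi_))
}

# Event-stratified fold assignment: events and censored subjects are each
# spread evenly across folds so no fold is event-free.
make_folds <- function(event, nfolds) {
  foldid <- integer(length(event))
  for (grp in list(which(event == 1), which(event == 0))) {
    if (!length(grp)) next
    foldid[grp] <- sample(rep_len(seq_len(nfolds), length(grp)))
  }
  foldid
}

#' Cross-validated penalty selection
#'
#' Selects the lambda minimising the cross-validated partial-likelihood
#' deviance over a fixed decreasing sequence, with event-stratified folds
#' (the Simon et al. coordinate-descent Cox CV, as implemented by
#' `glmnet::cv.glmnet`).
#'
#' @param x,time,event training data.
#' @param lambda_seq strictly decreasing penalty sequence.
#' @param nfolds number of folds (>= 3; default 10).
#' @param seed fold-assignment seed.
#' @return the optimal lambda (a value of `lambda_seq`).
#' @export
cv_lambda <- function(x, time, event, lambda_seq, nfolds = 10, seed = 1) {
  stopifnot(nfolds >= 3)
  if (length(lambda_seq) == 1) return(lambda_seq)
  stopifnot(all(diff(lambda_seq) < 0))
  x <- as.matrix(x)
  check_survival_inputs(x, time, event)
  if (ncol(x) == 1) x <- cbind(x, .pad = 0)
  for (attempt in 1:3) {
    foldid <- with_seed(child_seed(seed, attempt - 1),
                        make_folds(event, nfolds))
    cvfit <- tryCatch(
      glmnet::cv.glmnet(x, surv_y(time, event), family = "cox",
                        lambda = lambda_seq, foldid = foldid,
                        standardize = FALSE, type.measure = "deviance"),
      error = function(e) NULL)
    if (!is.null(cvfit)) return(cvfit$lambda.min)
  }
  stop_micoxpen("cross-validation failed after fold re-randomisation")
}

#' Shared penalty across imputed datasets
#'
#' The lambda sequence is generated once, from the first imputed dataset
#' (glmnet's 100-point log-spaced path from lambda_max down to
#' 0.001 * lambda_max), and reused for the cross-validation in every imputed
#' dataset. The shared penalty `lambda_star` is the arithmetic mean of the m
#' per-imputation optima; using one penalty across imputations reduces the
#' variability of variable selection.
#'
#' @param designs list of m design matrices (one per imputed dataset).
#' @param time,event outcome (identical across imputations).
#' @param nfolds CV folds (default 10).
#' @param seed root seed for fold assignment (per-imputation child streams).
#' @return object of class `lambda_star`: `optima` (m values), `mean`, `sd`,
#'   `sequence`.
#' @export
lambda_star <- function(designs, time, event, nfolds = 10, seed = 1) {
  stopifnot(length(designs) >= 1)
  x1 <- as.matrix(designs[[1]])
  g1 <- glmnet::glmnet(x1, surv_y(time, event), family = "cox",
                       nlambda = 100, lambda.min.ratio = 0.001,
                       standardize = FALSE)
  seq_ <- g1$lambda
  # one fold assignment shared by every imputation: the subjects are the
  # same rows in each completed dataset, so a common split removes spurious
  # between-imputation CV noise
  fold_seed <- child_seed(seed, 1)
  optima <- vapply(seq_along(designs), function(i)
    cv_lambda(designs[[i]], time, event, seq_, nfolds, seed = fold_seed), 0)
  structure(list(optima = optima, mean = mean(optima),
                 sd = if (length(optima) > 1) stats::sd(optima) else 0,
                 sequence = seq_),
            class = "lambda_star")
}

#' @export
print.lambda_star <- function(x, ...) {
  cat(sprintf("lambda* = %.5g (SD %.3g over %d imputations)\n",
              x$mean, x$sd, length(x$optima)))
  invisible(x)
}

#' Bootstrap standard errors for penalised coefficients
#'
#' Penalised-model coefficients have no usable model-based standard errors,
#' so within each completed dataset B bootstrap resamples are refitted at the
#' fixed shared penalty; the SE of each coefficient is its sample SD over the
#' B refits (coefficients shrunk to zero enter as zero). Resamples without
#' events are redrawn (up to 5 times each).
#'
#' @param x,time,event completed training data.
#' @param lambda fixed penalty (the shared `lambda_star`).
#' @param B resamples (>= 2; default 100).
#' @param seed resampling seed.
#' @return list with `se` (named vector) and `coefs` (B x p matrix).
#' @export
bootstrap_se <- function(x, time, event, lambda, B = 100, seed = 1) {
  stopifnot(B >= 2)
  x <- as.matrix(x)
  n <- nrow(x)
  coefs <- with_seed(seed, {
    out <- matrix(NA_real_, B, ncol(x), dimnames = list(NULL, colnames(x)))
    for (b in seq_len(B)) {
      for (try in 1:5) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) >= 1) break
        if (try == 5) stop_micoxpen("bootstrap resample without events")
      }
      fit <- fit_cox(x[idx, , drop = FALSE], time[idx], event[idx], lambda)
      out[b, ] <- fit$coef
    }
    out
  })
  list(se = apply(coefs, 2, stats::sd), coefs = coefs)
}

#' Univariate Cox regressions across imputed datasets
#'
#' Regresses overall survival on each proposed prognostic factor alone (all
#' of an ordinal factor's contrast columns jointly), unpenalised, within each
#' imputed dataset; coefficients are pooled by Rubin's rules with model-based
#' variances and reported with Wald 95% CIs.
#'
#' @param designs list of m design matrices.
#' @param time,event outcome.
#' @return data frame: design column, pooled coefficient, SE, CI bounds,
#'   hazard ratio.
#' @export
univariate_cox <- function(designs, time, event) {
  src <- attr(designs[[1]], "source")
  vars <- unique(src)
  m <- length(designs)
  rows <- list()
  for (v in vars) {
    cols <- names(src)[src == v]
    est <- matrix(NA_real_, m, length(cols), dimnames = list(NULL, cols))
    vr <- est
    for (i in seq_len(m)) {
      f <- fit_cox(designs[[i]][, cols, drop = FALSE], time, event, lambda = 0)
      est[i, ] <- f$coef
      vr[i, ] <- diag(as.matrix(f$var))
    }
    for (j in seq_along(cols)) {
      p <- if (m > 1) pool(est[, j], vr[, j])
           else list(estimate = est[1, j], se = sqrt(vr[1, j]),
                     ci = est[1, j] + c(-1, 1) * 1.96 * sqrt(vr[1, j]))
      rows[[cols[j]]] <- data.frame(
        variable = v, term = cols[j], coef = p$estimate, se = p$se,
        ci_low = p$ci[1], ci_high = p$ci[2], hr = exp(p$estimate))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
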