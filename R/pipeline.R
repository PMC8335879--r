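# End-to-end model building: transform -> impute -> standardise -> shared
# penalty by CV -> penalised fits -> bootstrap SEs -> Rubin pooling.

#' Build a prognostic model from incomplete training data
#'
#' Runs the full model-building process: apply the pre-specified covariate
#' transformations, impute missing covariates by chained equations (m chosen
#' by the 25% rule unless given), standardise the continuous predictors
#' within each completed dataset (mean / population SD), select one shared
#' LASSO penalty by cross-validation (mean of the per-imputation optima over
#' a common lambda sequence), fit the penalised Cox model in every completed
#' dataset at that penalty, derive bootstrap coefficient SEs, and pool by
#' Rubin's rules.
#'
#' @param td a [trial_dataset()] (raw scale, with missingness).
#' @param m number of imputations (NULL = [choose_m()] rule).
#' @param iterations chained-equation cycles (default 5).
#' @param donors PMM donor count (default 5).
#' @param nfolds CV folds for penalty selection (default 10).
#' @param B_se bootstrap resamples for coefficient SEs (default 100; 0 skips
#'   them, leaving pooled point estimates only).
#' @param seed root seed; imputation, folds and bootstrap use derived
#'   child streams.
#' @return object of class `mi_cox_model`: the incomplete data, imputed
#'   stack, per-imputation designs / standardisation params / fits, shared
#'   penalty (`lambda_star`), pooled model (`pooled`), pooled
#'   standardisation parameters and combined prognostic index.
#' @export
build_model <- function(td, m = NULL, iterations = 5, donors = 5,
                        nfolds = 10, B_se = 100, seed = 1) {
  stopifnot(inherits(td, "trial_dataset"))
  tdt <- apply_transforms(td)
  msum <- summarize_missingness(tdt)
  if (is.null(m)) m <- choose_m(msum)
  spec <- if (max(msum$per_variable$percent) > 0)
    imputation_spec(tdt, m = max(m, 2), iterations = iterations,
                    donors = donors, seed = child_seed(seed, 1))
  else NULL
  stack <- if (is.null(spec)) {
    structure(list(datasets = rep(list(tdt), max(m, 1)), spec = NULL,
                   seeds = integer(0)), class = "imputed_stack")
  } else impute(tdt, spec)
  fit_stack(stack, td_raw = td, nfolds = nfolds, B_se = B_se, seed = seed,
            missing_summary = msum)
}

#' Fit the penalised model on an existing imputed stack
#'
#' The second half of [build_model()], usable when the imputed stack was
#' produced (or re-loaded) separately.
#'
#' @param stack an `imputed_stack` (transformed scale).
#' @param td_raw optional original incomplete dataset to carry in the result.
#' @param nfolds,B_se,seed see [build_model()].
#' @param missing_summary optional precomputed [summarize_missingness()].
#' @return an `mi_cox_model`.
#' @export
fit_stack <- function(stack, td_raw = NULL, nfolds = 10, B_se = 100, seed = 1,
                      missing_summary = NULL) {
  m <- n_imputations(stack)
  sch <- stack$datasets[[1]]$schema
  time <- stack$datasets[[1]]$data[[time_name(sch)]]
  event <- stack$datasets[[1]]$data[[event_name(sch)]]
  std_params <- lapply(stack$datasets, compute_standardization)
  designs <- lapply(seq_len(m), function(i)
    build_design(stack$datasets[[i]], std_params[[i]]))
  if (m >= 2) {
    ls <- lambda_star(designs, time, event, nfolds = nfolds,
                      seed = child_seed(seed, 2))
  } else {
    x1 <- designs[[1]]
    g1 <- glmnet::glmnet(x1, surv_y(time, event), family = "cox",
                         nlambda = 100, lambda.min.ratio = 0.001,
                         standardize = FALSE)
    opt <- cv_lambda(x1, time, event, g1$lambda, nfolds,
                     seed = child_seed(seed, 2))
    ls <- structure(list(optima = opt, mean = opt, sd = 0,
                         sequence = g1$lambda), class = "lambda_star")
  }
  fits <- lapply(designs, fit_cox, time = time, event = event,
                 lambda = ls$mean)
  boot <- if (B_se >= 2) lapply(seq_len(m), function(i)
    bootstrap_se(designs[[i]], time, event, ls$mean, B = B_se,
                 seed = child_seed(seed, 100 + i)))
  else NULL
  pooled_std <- pool_standardization(std_params)
  pooled <- if (m >= 2) pool_model(fits, boot, std_params = pooled_std)
  else {
    p <- structure(list(coef_matrix = matrix(fits[[1]]$coef, 1,
                                             dimnames = list(NULL, names(fits[[1]]$coef))),
                        pooled = NULL, coef = fits[[1]]$coef,
                        inclusion = as.integer(fits[[1]]$coef != 0),
                        lambda = ls$mean, m = 1L,
                        baseline = fits[[1]]$baseline,
                        std_params = pooled_std),
                   class = "pooled_cox_model")
    p
  }
  combined_pi <- pool_prognostic_index(designs, pooled$coef_matrix)
  structure(list(data = td_raw, stack = stack, designs = designs,
                 std_params = std_params, pooled_std = pooled_std,
                 lambda_star = ls, fits = fits, boot = boot,
                 pooled = pooled, combined_pi = combined_pi,
                 time = time, event = event, schema = sch,
                 missing_summary = missing_summary,
                 config = list(nfolds = nfolds, B_se = B_se, seed = seed,
                               m = m)),
            class = "mi_cox_model")
}

#' @export
print.mi_cox_model <- function(x, ...) {
  cat(sprintf("Multiply imputed penalised Cox model (n = %d, m = %d)\n",
              length(x$time), x$config$m))
  print(x$lambda_star)
  print(x$pooled)
  invisible(x)
}

# 60 days in months; the package's time unit is months throughout.
months_60d <- 60 * 12 / 365.25

#' Default assessment horizons (months): 60 days and 1 year
#' @return named numeric vector of horizons in months.
#' @export
default_horizons <- function() c(`60d` = months_60d, `1y` = 12)

#' Assess a fitted model: discrimination, calibration, PH check, Uno's C
#'
#' Within each imputed dataset, the prognostic index and predicted survival
#' probabilities come from that dataset's own fitted model (its coefficients
#' and Breslow baseline). Discrimination is the combined (Rubin-pooled)
#' D-statistic; calibration is decile predicted-vs-KM-observed tables with
#' pooled calibration slopes per horizon; Uno's C is summarised across
#' imputations by median and IQR; the proportional-hazards assumption is
#' checked by regressing unscaled Schoenfeld residuals on event time.
#'
#' @param model an `mi_cox_model`.
#' @param horizons named vector of horizons in months (default 60 days and
#'   1 year).
#' @param groups calibration risk groups (default 10).
#' @return object of class `model_assessment`: `d` (a `d_stat_result`),
#'   `calibration` (per horizon: per-imputation tables, slopes, pooled
#'   slope), `uno` (per horizon: per-imputation values, median, IQR), `ph`.
#' @export
assess_model <- function(model, horizons = default_horizons(), groups = 10) {
  m <- model$config$m
  time <- model$time; event <- model$event
  pis <- lapply(seq_len(m), function(i)
    drop(model$designs[[i]] %*% model$fits[[i]]$coef))
  d <- if (m >= 2) combined_d(pis, time, event)
       else { ds <- d_statistic(pis[[1]], time, event)
              structure(list(per_imputation = data.frame(imputation = 1,
                                                         d = ds$d,
                                                         variance = ds$variance),
                             combined = ds$d, within = ds$variance,
                             between = 0, total = ds$variance,
                             ci = ds$d + c(-1, 1) * 1.96 * sqrt(ds$variance),
                             m = 1L), class = "d_stat_result") }
  cal <- lapply(horizons, function(t) {
    tables <- lapply(seq_len(m), function(i) {
      pred <- predict_survival(model$fits[[i]], model$designs[[i]], t)
      calibration(pred, time, event, t, groups = groups)
    })
    slopes <- vapply(tables, calibration_slope, 0)
    list(tables = tables, slopes = slopes,
         pooled_slope = pool_calibration_slopes(slopes))
  })
  uno <- lapply(horizons, function(t) {
    vals <- vapply(pis, uno_c, 0, time = time, event = event, tau = t)
    list(values = vals, median = stats::median(vals),
         iqr = stats::quantile(vals, c(0.25, 0.75), names = FALSE))
  })
  ph <- ph_check(model$designs, model$fits, time, event)
  structure(list(d = d, calibration = cal, uno = uno, ph = ph,
                 horizons = horizons),
            class = "model_assessment")
}

#' @export
print.model_assessment <- function(x, ...) {
  print(x$d)
  for (h in names(x$horizons)) {
    cat(sprintf("Horizon %s: pooled calibration slope %.3f; Uno's C median %.3f (IQR %.3f-%.3f)\n",
                h, x$calibration[[h]]$pooled_slope, x$uno[[h]]$median,
                x$uno[[h]]$iqr[1], x$uno[[h]]$iqr[2]))
  }
  print(x$ph)
  invisible(x)
}
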