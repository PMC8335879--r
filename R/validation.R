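# Optimism-corrected bootstrap internal validation with nested re-imputation,
# and complete-case / imputed external validation.

# term -> source variable map for a schema's design columns
design_source <- function(sch) {
  src <- character(0)
  for (v in sch[predictor_names(sch)]) {
    if (v$kind == "continuous") src[v$name] <- v$name
    else {
      cm <- ordinal_contrasts(v$levels)
      for (j in colnames(cm)) src[paste0(v$name, j)] <- v$name
    }
  }
  src
}

#' Variables retained in the pooled model
#'
#' Source variables of the design columns with nonzero pooled coefficient --
#' the variable set a new subject must have recorded for the model to be
#' applied.
#'
#' @param model an `mi_cox_model` or `pooled_cox_model`.
#' @param sch the dataset schema (taken from the model when available).
#' @return character vector of variable names.
#' @export
selected_variables <- function(model, sch = NULL) {
  pooled <- if (inherits(model, "mi_cox_model")) model$pooled else model
  sch <- sch %||% model$schema
  src <- design_source(sch)
  unique(unname(src[names(pooled$coef)[pooled$coef != 0]]))
}

new_validation_report <- function(measure, apparent, optimism, B, seed,
                                  skipped = 0) {
  mo <- if (length(optimism)) mean(optimism) else 0
  structure(list(measure = measure, apparent = apparent,
                 optimism = optimism, mean_optimism = mo,
                 sd_optimism = if (length(optimism) > 1) stats::sd(optimism) else NA_real_,
                 corrected = apparent - mo,
                 B = B, B_effective = length(optimism),
                 skipped = skipped, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Internal validation (%s): apparent %.3f, mean optimism %.3f (SD %.3f, B = %d), corrected %.3f\n",
              x$measure, x$apparent, x$mean_optimism, x$sd_optimism,
              x$B_effective, x$corrected))
  if (x$skipped > 0)
    cat(sprintf("  %d replicate(s) skipped after repeated failures\n", x$skipped))
  invisible(x)
}

#' Write a validation report as TSV
#' @param reports list of `validation_report`s (or one).
#' @param path output path.
#' @export
write_validation_report <- function(reports, path) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, function(x)
    data.frame(measure = x$measure, apparent = x$apparent,
               mean_optimism = x$mean_optimism, sd_optimism = x$sd_optimism,
               corrected = x$corrected, B = x$B_effective, seed = x$seed)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pooled (mean) calibration slope of predictions from a single coefficient
# vector + baseline applied across a list of designs, against one outcome.
slopes_from_model <- function(coef, baseline, designs, time, event, t,
                              groups = 10) {
  vapply(designs, function(X) {
    pred <- predict_survival(list(coef = coef, baseline = baseline), X, t)
    calibration_slope(calibration(pred, time, event, t, groups = groups))
  }, 0)
}

#' Bootstrap internal validation with nested re-imputation
#'
#' For each of B replicates: (I) resample n subjects with replacement from
#' the INCOMPLETE training data; (II) repeat the entire model-building
#' process on the resample, including imputation; (III) Rubin-combine into a
#' sample model and sample performance (D-statistic, and calibration slope
#' per horizon); (IV) apply the sample model's pooled coefficients to the m
#' imputed datasets of the ORIGINAL run (as standardised in the original
#' run); (V) Rubin-combine into the internal-validation performance;
#' (VI) optimism = sample performance - internal-validation performance.
#' The corrected performance is the apparent performance minus the mean
#' optimism over replicates. Replicates that fail (no events, degenerate
#' fits, all-zero models) are redrawn up to 5 times, then skipped and
#' counted.
#'
#' @param model an `mi_cox_model` built from the incomplete data (must carry
#'   `data`).
#' @param B bootstrap replicates (default 100; 0 returns
#'   corrected = apparent).
#' @param seed replicate-resampling seed.
#' @param horizons calibration horizons (months).
#' @param apparent optional precomputed [assess_model()] result.
#' @param groups calibration risk groups.
#' @return list of `validation_report`s: `$d` plus `$slope_<horizon>` per
#'   horizon.
#' @export
internal_validate <- function(model, B = 100, seed = 1,
                              horizons = default_horizons(),
                              apparent = NULL, groups = 10) {
  stopifnot(inherits(model, "mi_cox_model"))
  if (is.null(model$data))
    stop_micoxpen("internal validation needs the original incomplete dataset")
  if (is.null(apparent)) apparent <- assess_model(model, horizons, groups)
  app_d <- apparent$d$combined
  app_slopes <- vapply(apparent$calibration, `[[`, 0, "pooled_slope")
  if (B == 0) {
    out <- c(list(d = new_validation_report("D-statistic", app_d, numeric(0), 0, seed)),
             stats::setNames(lapply(names(horizons), function(h)
               new_validation_report(paste0("calibration slope ", h),
                                     app_slopes[[h]], numeric(0), 0, seed)),
               paste0("slope_", names(horizons))))
    return(out)
  }
  n <- length(model$time)
  m <- model$config$m
  opt_d <- rep(NA_real_, B)
  opt_slope <- matrix(NA_real_, B, length(horizons),
                      dimnames = list(NULL, names(horizons)))
  skipped <- 0
  for (b in seq_len(B)) {
    done <- FALSE
    for (attempt in 1:5) {
      rep_seed <- child_seed(seed, 7919 * b + attempt)
      res <- tryCatch({
        idx <- with_seed(rep_seed, sample.int(n, n, replace = TRUE))
        sample_td <- trial_dataset(model$data$data[idx, , drop = FALSE],
                                   model$schema)
        sm <- build_model(sample_td, m = m,
                          nfolds = model$config$nfolds, B_se = 0,
                          seed = child_seed(rep_seed, 3))
        st <- sm$time; se <- sm$event
        pis_s <- lapply(seq_len(m), function(i)
          drop(sm$designs[[i]] %*% sm$fits[[i]]$coef))
        sample_d <- if (m >= 2) combined_d(pis_s, st, se)$combined
                    else d_statistic(pis_s[[1]], st, se)$d
        pis_o <- lapply(model$designs, function(X)
          drop(X %*% sm$pooled$coef))
        internal_d <- if (m >= 2) combined_d(pis_o, model$time, model$event)$combined
                      else d_statistic(pis_o[[1]], model$time, model$event)$d
        sl <- vapply(seq_along(horizons), function(hi) {
          t <- horizons[[hi]]
          s_sample <- mean(vapply(seq_len(m), function(i) {
            pred <- predict_survival(sm$fits[[i]], sm$designs[[i]], t)
            calibration_slope(calibration(pred, st, se, t, groups = groups))
          }, 0))
          s_internal <- mean(slopes_from_model(sm$pooled$coef,
                                               sm$pooled$baseline,
                                               model$designs, model$time,
                                               model$event, t, groups))
          s_sample - s_internal
        }, 0)
        list(d = sample_d - internal_d, slope = sl)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        opt_d[b] <- res$d
        opt_slope[b, ] <- res$slope
        done <- TRUE
        break
      }
    }
    if (!done) skipped <- skipped + 1
  }
  ok <- !is.na(opt_d)
  out <- list(d = new_validation_report("D-statistic", app_d, opt_d[ok],
                                        B, seed, skipped))
  for (h in names(horizons))
    out[[paste0("slope_", h)]] <-
      new_validation_report(paste0("calibration slope ", h),
                            app_slopes[[h]], opt_slope[ok, h], B, seed,
                            skipped)
  out
}

#' Complete-case external validation
#'
#' Applies the pooled training model to a test dataset the way it would be
#' used in clinic: only subjects with every model variable recorded are
#' eligible; the training transformations and the Rubin-pooled training
#' standardisation constants are applied; the prognostic index uses the
#' pooled coefficients. Reports the D-statistic, Uno's C and calibration
#' (decile tables against the pooled training baseline, plus slopes) at each
#' horizon.
#'
#' @param model a fitted `mi_cox_model` (or a `pooled_cox_model` with
#'   standardisation parameters, plus `sch`).
#' @param test_td the test `trial_dataset` (raw scale, may have missingness).
#' @param horizons horizons in months.
#' @param groups calibration risk groups.
#' @param sch schema when `model` is a bare `pooled_cox_model`.
#' @return object of class `external_validation`: `n_eligible`, `d` (with
#'   variance and CI), `uno`, `calibration` (per horizon: table + slope),
#'   `pi`, `eligible` row index.
#' @export
external_validate <- function(model, test_td, horizons = default_horizons(),
                              groups = 10, sch = NULL) {
  pooled <- if (inherits(model, "mi_cox_model")) model$pooled else model
  sch <- sch %||% model$schema
  vars <- selected_variables(pooled, sch)
  keep <- rep(TRUE, n_subjects(test_td))
  for (v in vars) keep <- keep & !is.na(test_td$data[[v]])
  if (!any(keep)) stop_micoxpen("zero eligible complete cases in test data")
  sub <- trial_dataset(test_td$data[keep, , drop = FALSE], test_td$schema)
  # non-model predictors may still be missing; fill with observed medians /
  # modes so the design can be built (their coefficients are zero, so the
  # fill never enters the prognostic index)
  for (v in setdiff(predictor_names(sub$schema), vars)) {
    x <- sub$data[[v]]
    if (!anyNA(x)) next
    fill <- if (is.factor(x)) names(which.max(table(x)))
            else stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- fill
    sub$data[[v]] <- x
  }
  sub <- apply_transforms(sub)
  X <- build_design(sub, pooled$std_params)
  pi_ <- drop(X %*% pooled$coef)
  time <- sub$data[[time_name(sch)]]
  event <- sub$data[[event_name(sch)]]
  ds <- d_statistic(pi_, time, event)
  cal <- lapply(horizons, function(t) {
    pred <- predict_survival(list(coef = pooled$coef,
                                  baseline = pooled$baseline), X, t)
    res <- calibration(pred, time, event, t, groups = groups)
    list(table = res, slope = calibration_slope(res))
  })
  uno <- lapply(horizons, function(t) uno_c(pi_, time, event, tau = t))
  structure(list(n_eligible = sum(keep), eligible = which(keep),
                 d = list(d = ds$d, variance = ds$variance,
                          ci = ds$d + c(-1, 1) * 1.96 * sqrt(ds$variance)),
                 uno = uno, calibration = cal, pi = pi_,
                 horizons = horizons),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("External validation: %d eligible complete cases\n", x$n_eligible))
  cat(sprintf("  D-statistic %.3f (95%% CI %.3f to %.3f)\n",
              x$d$d, x$d$ci[1], x$d$ci[2]))
  for (h in names(x$horizons))
    cat(sprintf("  %s: Uno's C %.3f, calibration slope %.3f\n",
                h, x$uno[[h]], x$calibration[[h]]$slope))
  invisible(x)
}

#' External validation with an imputed test dataset
#'
#' Sensitivity analysis: missing test-set covariates are multiply imputed
#' with the same imputation model structure as training; the single pooled
#' training model is applied within each completed test dataset; the
#' D-statistics and calibration slopes are Rubin-combined.
#'
#' @param model a fitted `mi_cox_model`.
#' @param test_td test `trial_dataset` (raw scale).
#' @param m imputations for the test data (default 10).
#' @param seed imputation seed.
#' @param horizons,groups as in [external_validate()].
#' @return list: `d` (a `d_stat_result`), per-horizon pooled calibration
#'   slopes, `m`.
#' @export
external_validate_imputed <- function(model, test_td, m = 10, seed = 1,
                                      horizons = default_horizons(),
                                      groups = 10) {
  pooled <- model$pooled
  tdt <- apply_transforms(test_td)
  msum <- summarize_missingness(tdt)
  stack <- if (max(msum$per_variable$percent) > 0)
    impute(tdt, imputation_spec(tdt, m = m, seed = seed))
  else structure(list(datasets = rep(list(tdt), m), spec = NULL,
                      seeds = integer(0)), class = "imputed_stack")
  designs <- lapply(stack$datasets, build_design, params = pooled$std_params)
  time <- tdt$data[[time_name(tdt$schema)]]
  event <- tdt$data[[event_name(tdt$schema)]]
  pis <- lapply(designs, function(X) drop(X %*% pooled$coef))
  d <- combined_d(pis, time, event)
  slopes <- lapply(horizons, function(t)
    pool_calibration_slopes(slopes_from_model(pooled$coef, pooled$baseline,
                                              designs, time, event, t,
                                              groups)))
  uno <- lapply(horizons, function(t) {
    vals <- vapply(pis, uno_c, 0, time = time, event = event, tau = t)
    list(median = stats::median(vals),
         iqr = stats::quantile(vals, c(0.25, 0.75), names = FALSE))
  })
  list(d = d, slopes = slopes, uno = uno, m = m, stack = stack)
}
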