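#' Choose the number of imputed datasets
#'
#' Pre-specified rule: if no predictor has more than `threshold` percent
#' missing, use 10 imputed datasets; otherwise the rule of thumb applies and
#' m equals the percentage of incomplete cases, rounded up. Fully observed
#' data need no imputation (m = 1, pass-through).
#'
#' @param summary a [summarize_missingness()] result.
#' @param threshold percent, in (0, 100); default 25.
#' @return integer m.
#' @export
choose_m <- function(summary, threshold = 25) {
  stopifnot(inherits(summary, "missing_pattern_summary"),
            threshold > 0, threshold < 100)
  max_pct <- max(summary$per_variable$percent)
  if (max_pct == 0) return(1L)
  if (max_pct <= threshold) return(10L)
  as.integer(ceiling(100 - summary$complete_percent))
}

#' Specify a chained-equations imputation
#'
#' Builds the imputation specification for a dataset: visit order from least
#' to most missing (ties broken by schema order), per-variable conditional
#' model (Bayesian linear regression + predictive mean matching for
#' continuous, cumulative-logit proportional odds for ordinal), and predictor
#' sets. Each target's imputation model uses the remaining predictors, the
#' auxiliary variables (e.g. sex), and the survival outcome -- time in months
#' plus the event indicator by default, or the Nelson-Aalen cumulative-hazard
#' estimate behind a flag. The randomised treatment arm is excluded.
#'
#' @param td a `trial_dataset` (transformed scale).
#' @param m number of imputed datasets (>= 2; see [choose_m()]).
#' @param iterations chained-equation cycles per dataset (default 5).
#' @param donors PMM donor pool size k (default 5).
#' @param seed integer root seed; imputation d uses a derived child stream.
#' @param survival_covariate `"months"` or `"nelson_aalen"`.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(td, m = 10, iterations = 5, donors = 5, seed = 1,
                            survival_covariate = c("months", "nelson_aalen")) {
  stopifnot(inherits(td, "trial_dataset"), m >= 2, iterations >= 1, donors >= 1)
  survival_covariate <- match.arg(survival_covariate)
  preds <- predictor_names(td$schema)
  nmiss <- vapply(preds, function(v) sum(is.na(td$data[[v]])), 0L)
  targets <- preds[nmiss > 0]
  visit <- targets[order(nmiss[targets], match(targets, preds))]
  method <- vapply(visit, function(v)
    if (td$schema[[v]]$kind == "continuous") "pmm_linear" else "ordinal_logit",
    "")
  predictors <- lapply(visit, function(v)
    c(setdiff(preds, v), auxiliary_names(td$schema)))
  names(predictors) <- visit
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors = as.integer(donors), seed = as.integer(seed),
                 visit = visit, method = method, predictors = predictors,
                 survival_covariate = survival_covariate),
            class = "imputation_spec")
}

# Numeric design frame for the conditional imputation models: continuous
# variables as-is, ordinal variables as orthonormal polynomial contrast
# columns, plus the survival covariate(s).
imp_design <- function(df, sch, vars, surv_cols) {
  cols <- list()
  for (v in vars) {
    spec <- sch[[v]]
    if (spec$kind == "continuous") cols[[v]] <- df[[v]]
    else {
      cm <- ordinal_contrasts(spec$levels)
      idx <- as.integer(df[[v]])
      for (j in seq_len(ncol(cm)))
        cols[[paste0(v, colnames(cm)[j])]] <- cm[idx, j]
    }
  }
  for (nm in names(surv_cols)) cols[[nm]] <- surv_cols[[nm]]
  as.data.frame(cols, check.names = FALSE)
}

# Bayesian linear regression draw + type-1 predictive mean matching.
# Proper imputation: sigma^2 and beta are drawn from their large-sample
# posterior so Rubin's between-imputation variance is valid; each missing
# cell receives an observed donor value, so imputations stay in the observed
# support.
draw_pmm <- function(y, ry, X, donors) {
  Xo <- X[ry, , drop = FALSE]; yo <- y[ry]
  p <- ncol(Xo)
  xtx <- crossprod(Xo)
  ridge <- diag(p) * 1e-5 * mean(diag(xtx))   # numerical stabiliser
  V <- solve(xtx + ridge)
  betahat <- V %*% crossprod(Xo, yo)
  resid <- yo - drop(Xo %*% betahat)
  df <- max(length(yo) - p, 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, df)
  Vs <- (V + t(V)) / 2
  beta_star <- betahat + t(chol(Vs)) %*% stats::rnorm(p) * sqrt(sigma2_star)
  yhat_obs <- drop(Xo %*% betahat)
  yhat_mis <- drop(X[!ry, , drop = FALSE] %*% beta_star)
  k <- min(donors, length(yo))
  idx <- vapply(yhat_mis, function(z) {
    nearest <- order(abs(yhat_obs - z))[seq_len(k)]
    nearest[sample.int(k, 1)]
  }, 0L)
  yo[idx]
}

# Proportional-odds (cumulative logit) draw for an ordinal target: fit on the
# observed rows, perturb the parameters with a draw from their approximate
# normal posterior, and sample each missing cell from the predicted category
# distribution (not the modal category, preserving variability).
draw_ordinal <- function(y, ry, X, var_name, cycle) {
  lev_all <- levels(y)
  yo <- droplevels(y[ry])
  obs_lev <- levels(yo)
  nmis <- sum(!ry)
  if (length(obs_lev) < 2)
    return(factor(rep(obs_lev, nmis), levels = lev_all, ordered = TRUE))
  dat <- data.frame(X[ry, , drop = FALSE], check.names = TRUE)
  dat$.y <- yo
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ ., data = dat, method = "logistic",
                                Hess = TRUE)),
    error = function(e)
      stop_micoxpen("ordinal imputation model failed for '%s' (cycle %d): %s",
                    var_name, cycle, conditionMessage(e)))
  theta <- c(fit$coefficients, fit$zeta)
  Vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(Vc) && all(is.finite(Vc)))
    theta <- MASS::mvrnorm(1, theta, (Vc + t(Vc)) / 2)
  nb <- length(fit$coefficients)
  beta <- theta[seq_len(nb)]
  zeta <- sort(theta[-seq_len(nb)])
  Xm <- as.matrix(data.frame(X[!ry, , drop = FALSE], check.names = TRUE))
  eta <- if (nb) drop(Xm %*% beta) else rep(0, nmis)
  cum <- stats::plogis(outer(zeta, eta, "-"))        # P(Y <= j | x)
  probs <- apply(rbind(cum, 1), 2, function(p) pmax(diff(c(0, p)), 0))
  probs <- matrix(probs, nrow = length(obs_lev))
  picks <- apply(probs, 2, function(p) sample.int(length(p), 1, prob = p))
  factor(obs_lev[picks], levels = lev_all, ordered = TRUE)
}

#' Impute missing covariates by chained equations
#'
#' Produces m completed copies of the dataset. Within each copy, missing cells
#' are initialised by random draws from the observed marginals, then the
#' conditional models are cycled in the visit order for the specified number
#' of iterations. Observed cells are never touched, so they are identical
#' across the m copies.
#'
#' @param td a `trial_dataset` on the transformed scale (see
#'   [apply_transforms()]).
#' @param spec an [imputation_spec()]; defaults to the spec built from `td`
#'   with m chosen by [choose_m()].
#' @return object of class `imputed_stack`: list with `datasets` (m completed
#'   `trial_dataset`s), `spec`, and per-dataset `seeds`.
#' @export
impute <- function(td, spec = NULL) {
  stopifnot(inherits(td, "trial_dataset"))
  if (is.null(spec)) {
    m <- choose_m(summarize_missingness(td))
    spec <- if (m >= 2) imputation_spec(td, m = m) else NULL
  }
  if (is.null(spec) || length(spec$visit) == 0) {
    m <- if (is.null(spec)) 1L else spec$m
    return(structure(list(datasets = rep(list(td), m), spec = spec,
                          seeds = integer(0)),
                     class = "imputed_stack"))
  }
  sch <- td$schema
  tn <- time_name(sch); en <- event_name(sch)
  surv_cols <- if (spec$survival_covariate == "months")
    stats::setNames(list(td$data[[tn]], td$data[[en]]), c(tn, en))
  else
    list(nelson_aalen = nelson_aalen(td$data[[tn]], td$data[[en]]),
         event = td$data[[en]])
  ry_list <- lapply(spec$visit, function(v) !is.na(td$data[[v]]))
  names(ry_list) <- spec$visit
  seeds <- vapply(seq_len(spec$m), function(d) child_seed(spec$seed, d), 0L)
  datasets <- vector("list", spec$m)
  for (d in seq_len(spec$m)) {
    datasets[[d]] <- with_seed(seeds[d], {
      df <- td$data
      for (v in spec$visit) {                  # marginal initialisation
        ry <- ry_list[[v]]
        df[[v]][!ry] <- sample(df[[v]][ry], sum(!ry), replace = TRUE)
      }
      for (cycle in seq_len(spec$iterations)) {
        for (v in spec$visit) {
          ry <- ry_list[[v]]
          X <- imp_design(df, sch, spec$predictors[[v]], surv_cols)
          if (spec$method[[v]] == "pmm_linear") {
            Xi <- cbind(`(Intercept)` = 1, as.matrix(X))
            df[[v]][!ry] <- draw_pmm(df[[v]], ry, Xi, spec$donors)
          } else {
            df[[v]][!ry] <- draw_ordinal(df[[v]], ry, X, v, cycle)
          }
        }
      }
      out <- td; out$data <- df; out
    })
  }
  structure(list(datasets = datasets, spec = spec, seeds = seeds),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d completed datasets", length(x$datasets)))
  if (!is.null(x$spec))
    cat(sprintf(" (%d cycles, PMM donors = %d, seed = %d)",
                x$spec$iterations, x$spec$donors, x$spec$seed))
  cat("\n")
  invisible(x)
}

n_imputations <- function(stack) length(stack$datasets)

# Nelson-Aalen estimate of the cumulative hazard at each subject's own time;
# optional survival covariate for the imputation models.
nelson_aalen <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  H <- cumsum(sf$n.event / sf$n.risk)
  idx <- findInterval(time, sf$time)
  c(0, H)[idx + 1]
}

#' Export an imputed stack in long format
#'
#' One CSV with an imputation-index column `.imp` (1..m), plus a JSON metadata
#' file with the spec and seeds.
#'
#' @param stack an `imputed_stack`.
#' @param path output CSV path; metadata written alongside as
#'   `<path>.meta.json`.
#' @export
write_stack <- function(stack, path) {
  long <- do.call(rbind, lapply(seq_along(stack$datasets), function(d) {
    df <- stack$datasets[[d]]$data
    for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
    cbind(.imp = d, df)
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  meta <- list(m = n_imputations(stack), seeds = stack$seeds,
               spec = stack$spec[c("m", "iterations", "donors", "seed",
                                   "visit", "survival_covariate")])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a long-format imputed stack
#'
#' @param path CSV written by [write_stack()].
#' @param sch the dataset schema.
#' @return an `imputed_stack` (spec metadata reloaded from the sidecar file if
#'   present).
#' @export
read_stack <- function(path, sch) {
  long <- utils::read.csv(path, colClasses = "character", na.strings = "",
                          check.names = FALSE)
  datasets <- lapply(split(long, as.integer(long$.imp)), function(df)
    trial_dataset(df[setdiff(names(df), ".imp")], sch))
  names(datasets) <- NULL
  meta_path <- paste0(path, ".meta.json")
  seeds <- integer(0)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    seeds <- as.integer(meta$seeds)
  }
  structure(list(datasets = datasets, spec = NULL, seeds = seeds),
            class = "imputed_stack")
}
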