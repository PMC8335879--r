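#' Rubin's rules for m multiply imputed estimates
#'
#' Pooled point estimate = mean; within-imputation variance W = mean of the
#' variances; between-imputation variance B = sample variance of the
#' estimates (divisor m - 1); total variance T = W + (1 + 1/m) B; 95% CI from
#' the standard normal reference.
#'
#' @param estimates numeric vector of m per-imputation estimates (m >= 2).
#' @param variances numeric vector of m per-imputation variances (>= 0).
#' @return object of class `pooled_estimate`: `estimate`, `within`, `between`,
#'   `total`, `se`, `m`, `ci`.
#' @export
pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop_micoxpen("Rubin's rules need m >= 2 estimates")
  stopifnot(length(variances) == m, all(variances >= 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  structure(list(estimate = qbar, within = W, between = B, total = Tv,
                 se = sqrt(Tv), m = m,
                 ci = qbar + c(-1, 1) * stats::qnorm(0.975) * sqrt(Tv)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (95%% CI %.4g to %.4g; W %.3g, B %.3g, m %d)\n",
              x$estimate, x$ci[1], x$ci[2], x$within, x$between, x$m))
  invisible(x)
}

#' Pool m penalised Cox fits into a prognostic model
#'
#' Columns shrunk to zero in a given imputation's fit contribute zero to both
#' the estimate and the bootstrap variance for that imputation; the Rubin
#' denominator stays m throughout, representing that penalisation occurred in
#' some but not all imputed datasets. Variables with pooled coefficient
#' exactly zero (never selected) are flagged excluded from the reported model.
#'
#' @param fits list of m `penalized_cox_fit`s sharing design columns and
#'   penalty.
#' @param boot list of m [bootstrap_se()] results (or NULL for point
#'   estimates only).
#' @param std_params optional pooled `standardization_params` to travel with
#'   the model.
#' @return object of class `pooled_cox_model`: coefficient matrix, per-column
#'   `pooled_estimate`s, pooled coefficient vector, inclusion counts, pooled
#'   Breslow baseline, `lambda`.
#' @export
pool_model <- function(fits, boot = NULL, std_params = NULL) {
  m <- length(fits)
  cols <- names(fits[[1]]$coef)
  for (f in fits)
    if (!identical(names(f$coef), cols))
      stop_micoxpen("mismatched design columns across fits")
  coef_mat <- do.call(rbind, lapply(fits, `[[`, "coef"))
  se_mat <- if (is.null(boot)) matrix(0, m, length(cols))
            else do.call(rbind, lapply(boot, `[[`, "se"))
  # unselected columns carry zero estimate and zero bootstrap variance
  se_mat[coef_mat == 0] <- 0
  pooled <- lapply(seq_along(cols), function(j)
    pool(coef_mat[, j], se_mat[, j]^2))
  names(pooled) <- cols
  coef_pooled <- vapply(pooled, `[[`, 0, "estimate")
  inclusion <- colSums(coef_mat != 0)
  baselines <- lapply(fits, `[[`, "baseline")
  bl <- baselines[[1]]
  bl$cumhaz <- rowMeans(vapply(baselines, `[[`, bl$cumhaz, "cumhaz"))
  structure(list(coef_matrix = coef_mat, pooled = pooled,
                 coef = coef_pooled, inclusion = inclusion,
                 lambda = fits[[1]]$lambda, m = m,
                 baseline = bl, std_params = std_params),
            class = "pooled_cox_model")
}

#' @export
print.pooled_cox_model <- function(x, ...) {
  cat(sprintf("Pooled penalised Cox model (m = %d, lambda = %.5g)\n",
              x$m, x$lambda))
  tab <- model_table(x)
  if (!nrow(tab)) { cat("  (all coefficients penalised to zero)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %2d/%-2d  %8.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
                tab$term[i], tab$inclusion[i], x$m, tab$coef[i], tab$se[i],
                tab$ci_low[i], tab$ci_high[i]))
  invisible(x)
}

#' Reported model table
#'
#' The machine-readable final model: one row per design column with nonzero
#' pooled coefficient (never-selected columns are omitted from the report).
#'
#' @param model a `pooled_cox_model`.
#' @return data frame: `term`, `inclusion`, `coef`, `se`, `ci_low`, `ci_high`,
#'   `hr`.
#' @export
model_table <- function(model) {
  keep <- names(model$coef)[model$coef != 0]
  rows <- lapply(keep, function(nm) {
    p <- model$pooled[[nm]]
    data.frame(term = nm, inclusion = model$inclusion[[nm]],
               coef = p$estimate, se = p$se,
               ci_low = p$ci[1], ci_high = p$ci[2], hr = exp(p$estimate))
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(term = character(0), inclusion = integer(0),
                         coef = numeric(0), se = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         hr = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write the pooled model table as TSV
#' @param model a `pooled_cox_model`.
#' @param path output path.
#' @export
write_model_table <- function(model, path) {
  utils::write.table(model_table(model), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Combined prognostic index across imputations
#'
#' Each subject's linear predictor is computed within every (completed
#' dataset, fitted model) pair and averaged over the m pairs -- Rubin
#' point-estimate pooling at the subject level.
#'
#' @param designs list of m design matrices (same subjects, same order).
#' @param coef_matrix m x p coefficient matrix (or a list of fits).
#' @return numeric vector: combined PI per subject.
#' @export
pool_prognostic_index <- function(designs, coef_matrix) {
  if (is.list(coef_matrix) && !is.matrix(coef_matrix))
    coef_matrix <- t(vapply(coef_matrix, `[[`,
                            numeric(ncol(designs[[1]])), "coef"))
  m <- length(designs)
  stopifnot(nrow(coef_matrix) == m)
  ns <- vapply(designs, nrow, 0L)
  if (length(unique(ns)) != 1)
    stop_micoxpen("subject mismatch across imputations")
  pis <- vapply(seq_len(m), function(i)
    drop(as.matrix(designs[[i]]) %*% coef_matrix[i, ]), numeric(ns[1]))
  if (is.null(dim(pis))) pis <- matrix(pis, nrow = ns[1])
  rowMeans(pis)
}

#' Export a pooled model as JSON
#'
#' Everything needed to score new data without refitting: coefficient names
#' and values, penalty, pooled standardisation constants, and the pooled
#' baseline cumulative-hazard table.
#'
#' @param model a `pooled_cox_model`.
#' @param path output JSON path.
#' @export
export_model <- function(model, path) {
  obj <- list(
    coef = as.list(model$coef),
    inclusion = as.list(model$inclusion),
    lambda = model$lambda, m = model$m,
    standardization = if (!is.null(model$std_params))
      as.data.frame(model$std_params) else NULL,
    baseline = model$baseline)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-load an exported model
#' @param path JSON written by [export_model()].
#' @return a `pooled_cox_model` (scoring fields only).
#' @export
import_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- NULL
  if (!is.null(obj$standardization))
    std <- structure(obj$standardization,
                     class = c("standardization_params", "data.frame"),
                     provenance = "pooled_across_imputations")
  structure(list(coef = unlist(obj$coef),
                 inclusion = unlist(obj$inclusion),
                 lambda = obj$lambda, m = obj$m,
                 coef_matrix = NULL, pooled = NULL,
                 baseline = obj$baseline, std_params = std),
            class = "pooled_cox_model")
}
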