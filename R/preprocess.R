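#' Apply the pre-specified covariate transformations
#'
#' Replaces each continuous predictor by its declared transform (`log` or
#' `log1p`); missing cells stay missing. Transformation is pre-specified per
#' variable in the schema (chosen from histogram review of skewness, e.g.
#' `log` for LDH and `log1p` for CRP) and is applied before imputation so the
#' conditional imputation models work on the analysis scale.
#'
#' @param td a [trial_dataset()].
#' @return the transformed `trial_dataset` (flagged so the transform is not
#'   applied twice).
#' @export
apply_transforms <- function(td) {
  stopifnot(inherits(td, "trial_dataset"))
  if (isTRUE(attr(td, "transformed"))) return(td)
  for (v in td$schema) {
    if (v$transform == "none") next
    x <- td$data[[v$name]]
    obs <- !is.na(x)
    if (v$transform == "log") {
      if (any(x[obs] <= 0))
        stop_micoxpen("non-positive value in '%s' under log transform", v$name)
      x[obs] <- log(x[obs])
    } else if (v$transform == "log1p") {
      if (any(x[obs] <= -1))
        stop_micoxpen("value <= -1 in '%s' under log1p transform", v$name)
      x[obs] <- log1p(x[obs])
    }
    td$data[[v$name]] <- x
  }
  attr(td, "transformed") <- TRUE
  td
}

# Invert the declared transforms (observed values only); used in tests to
# check that apply_transforms is a bijection.
invert_transforms <- function(td) {
  for (v in td$schema) {
    if (v$transform == "none") next
    x <- td$data[[v$name]]
    obs <- !is.na(x)
    x[obs] <- if (v$transform == "log") exp(x[obs]) else expm1(x[obs])
    td$data[[v$name]] <- x
  }
  attr(td, "transformed") <- NULL
  td
}

#' Compute standardisation parameters
#'
#' For each continuous predictor flagged `standardize`, the mean and the
#' population standard deviation (divisor n, not n - 1) of the completed
#' column. Run after imputation, within each completed dataset, so that
#' continuous variables are penalised equally in the LASSO.
#'
#' @param td a completed `trial_dataset` (no missing values in the flagged
#'   columns).
#' @param provenance `"single_dataset"` or `"pooled_across_imputations"`.
#' @return object of class `standardization_params`: data frame with columns
#'   `variable`, `mean`, `sd`.
#' @export
compute_standardization <- function(td, provenance = "single_dataset") {
  vars <- Filter(function(v) isTRUE(v$standardize), td$schema)
  out <- data.frame(variable = vapply(vars, `[[`, "", "name"),
                    mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
  n <- n_subjects(td)
  for (i in seq_len(nrow(out))) {
    x <- td$data[[out$variable[i]]]
    if (anyNA(x))
      stop_micoxpen("missing values in '%s'; standardise after imputation",
                    out$variable[i])
    m <- mean(x)
    s <- sqrt(sum((x - m)^2) / n)
    if (s == 0) stop_micoxpen("constant column '%s'", out$variable[i])
    out$mean[i] <- m; out$sd[i] <- s
  }
  rownames(out) <- NULL
  structure(out, class = c("standardization_params", "data.frame"),
            provenance = provenance)
}

#' Standardise continuous predictors
#'
#' `x_s = (x - mean) / sd` with the supplied parameters (which may come from
#' another dataset, e.g. pooled training parameters applied to a test set).
#' Ordinal variables are untouched.
#'
#' @param td a `trial_dataset`.
#' @param params a `standardization_params`.
#' @return standardised `trial_dataset`.
#' @export
standardize <- function(td, params) {
  flagged <- names(Filter(function(v) isTRUE(v$standardize), td$schema))
  missing_par <- setdiff(flagged, params$variable)
  if (length(missing_par))
    stop_micoxpen("no standardisation parameters for: %s",
                  paste(missing_par, collapse = ", "))
  for (v in flagged) {
    i <- match(v, params$variable)
    td$data[[v]] <- (td$data[[v]] - params$mean[i]) / params$sd[i]
  }
  td
}

#' Pool standardisation parameters across imputations
#'
#' Rubin point-estimate pooling of the per-imputation means and population
#' SDs (the simple mean), used to standardise external data.
#'
#' @param params_list list of `standardization_params`, one per imputation.
#' @return pooled `standardization_params`.
#' @export
pool_standardization <- function(params_list) {
  out <- params_list[[1]]
  out$mean <- rowMeans(vapply(params_list, `[[`, out$mean, "mean"))
  out$sd <- rowMeans(vapply(params_list, `[[`, out$sd, "sd"))
  attr(out, "provenance") <- "pooled_across_imputations"
  out
}

#' Orthonormal polynomial contrast basis for an ordinal variable
#'
#' k - 1 orthogonal polynomial contrast columns (linear, quadratic, ...) over
#' equally spaced, equally weighted level scores, each of unit length and
#' summing to zero -- the convention of standard statistical software.
#'
#' @param levels ordered level labels (or an integer k >= 2).
#' @return k x (k-1) matrix; rows named by level, columns `.L`, `.Q`, `.C`,
#'   `^4`, ...
#' @export
ordinal_contrasts <- function(levels) {
  k <- if (length(levels) == 1 && is.numeric(levels)) as.integer(levels)
       else length(levels)
  if (k < 2) stop_micoxpen("need >= 2 levels for a contrast basis")
  cm <- stats::contr.poly(k)
  if (length(levels) > 1) rownames(cm) <- as.character(levels)
  colnames(cm) <- c(".L", ".Q", ".C", paste0("^", 4:98))[seq_len(k - 1)]
  cm
}

#' Build the model design matrix
#'
#' Continuous predictors enter as single (optionally standardised) columns;
#' each ordinal predictor with k declared levels contributes its k - 1
#' orthonormal polynomial contrast columns, named `var.L`, `var.Q`, ...
#'
#' @param td a completed `trial_dataset` (transformed scale).
#' @param params optional `standardization_params`; if supplied, flagged
#'   continuous predictors are standardised with it.
#' @return numeric matrix, one row per subject, with attribute `source`
#'   mapping each column to its schema variable.
#' @export
build_design <- function(td, params = NULL) {
  if (!is.null(params)) td <- standardize(td, params)
  cols <- list(); src <- character(0)
  for (v in td$schema[predictor_names(td$schema)]) {
    x <- td$data[[v$name]]
    if (anyNA(x))
      stop_micoxpen("missing values in '%s'; impute before building a design",
                    v$name)
    if (v$kind == "continuous") {
      cols[[v$name]] <- x
      src <- c(src, v$name)
    } else {
      cm <- ordinal_contrasts(v$levels)
      idx <- as.integer(x)
      for (j in seq_len(ncol(cm))) {
        nm <- paste0(v$name, colnames(cm)[j])
        cols[[nm]] <- cm[idx, j]
        src <- c(src, v$name)
      }
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "source") <- stats::setNames(src, colnames(X))
  X
}

#' Pairwise covariate comparison plots
#'
#' Review plots for the correlation screen: scatter for two continuous
#' variables, stacked bars for two ordinal variables, box plots for mixed
#' pairs. Produced for human review; no automated exclusion is applied, since
#' dropping one of a highly correlated pair is a clinical-utility judgement.
#'
#' @param td a `trial_dataset`.
#' @param dir optional directory; if given, one PNG per pair is written.
#' @return (invisibly) a named list of ggplot objects.
#' @export
plot_pairwise <- function(td, dir = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_micoxpen("ggplot2 is required for plot_pairwise()")
  preds <- predictor_names(td$schema)
  plots <- list()
  for (i in seq_along(preds)) for (j in seq_along(preds)) {
    if (i >= j) next
    a <- td$schema[[preds[i]]]; b <- td$schema[[preds[j]]]
    df <- td$data[c(a$name, b$name)]
    df <- df[stats::complete.cases(df), ]
    nm <- paste(a$name, b$name, sep = "_vs_")
    aes2 <- ggplot2::aes(.data[[a$name]], .data[[b$name]])
    p <- if (a$kind == "continuous" && b$kind == "continuous") {
      ggplot2::ggplot(df, aes2) + ggplot2::geom_point(alpha = 0.3)
    } else if (a$kind == "ordinal" && b$kind == "ordinal") {
      ggplot2::ggplot(df, ggplot2::aes(.data[[a$name]], fill = .data[[b$name]])) +
        ggplot2::geom_bar(position = "stack")
    } else {
      ord <- if (a$kind == "ordinal") a$name else b$name
      cont <- setdiff(c(a$name, b$name), ord)
      ggplot2::ggplot(df, ggplot2::aes(.data[[ord]], .data[[cont]])) +
        ggplot2::geom_boxplot()
    }
    plots[[nm]] <- p + ggplot2::theme_minimal()
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), p,
                      width = 5, height = 4, dpi = 120)
    }
  }
  invisible(plots)
}
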