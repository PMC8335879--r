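#' Declare a dataset variable
#'
#' A `variable_spec` describes one column of a subject-level survival table:
#' its measurement type, any pre-specified transformation, the ordered level
#' set for ordinal variables, whether it is standardised before penalised
#' fitting, and its role in the modelling pipeline.
#'
#' @param name column name in the CSV / data frame.
#' @param kind `"continuous"` or `"ordinal"`.
#' @param role one of `"predictor"`, `"auxiliary"`, `"outcome_time"`,
#'   `"outcome_event"`, `"treatment"`, `"id"`.
#' @param transform `"none"`, `"log"` or `"log1p"`; continuous variables only.
#' @param levels ordered character vector of levels (ordinal variables only,
#'   at least 2).
#' @param standardize logical; standardise after imputation? Only meaningful
#'   for continuous predictors. Ordinal variables are never standardised:
#'   their polynomial contrasts already live on a comparable scale.
#' @return an object of class `variable_spec`.
#' @seealso [trial_schema()] for the default myeloma-style schema.
#' @export
variable_spec <- function(name,
                          kind = c("continuous", "ordinal"),
                          role = c("predictor", "auxiliary", "outcome_time",
                                   "outcome_event", "treatment", "id"),
                          transform = c("none", "log", "log1p"),
                          levels = NULL,
                          standardize = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  transform <- match.arg(transform)
  if (kind == "ordinal") {
    if (is.null(levels) || length(levels) < 2)
      stop_micoxpen("ordinal variable '%s' needs >= 2 ordered levels", name)
    if (transform != "none")
      stop_micoxpen("transform '%s' not allowed for ordinal variable '%s'",
                    transform, name)
    levels <- as.character(levels)
  } else {
    levels <- NULL
  }
  if (is.null(standardize))
    standardize <- kind == "continuous" && role == "predictor"
  if (standardize && kind != "continuous")
    stop_micoxpen("only continuous variables can be standardised ('%s')", name)
  structure(list(name = name, kind = kind, role = role, transform = transform,
                 levels = levels, standardize = standardize),
            class = "variable_spec")
}

#' Assemble a dataset schema
#'
#' @param ... `variable_spec` objects.
#' @return object of class `trial_schema` (a named list of specs).
#' @details Exactly one `outcome_time` and one `outcome_event` spec are
#'   required; at most one `id` and one `treatment`.
#' @export
schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  stopifnot(all(vapply(specs, inherits, TRUE, "variable_spec")))
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs)))
    stop_micoxpen("duplicate variable names in schema")
  roles <- vapply(specs, `[[`, "", "role")
  if (sum(roles == "outcome_time") != 1 || sum(roles == "outcome_event") != 1)
    stop_micoxpen("schema needs exactly one outcome_time and one outcome_event")
  if (sum(roles == "id") > 1 || sum(roles == "treatment") > 1)
    stop_micoxpen("schema allows at most one id and one treatment variable")
  structure(specs, class = "trial_schema")
}

schema_roles <- function(sch) vapply(sch, `[[`, "", "role")

#' @export
print.trial_schema <- function(x, ...) {
  cat("Dataset schema (", length(x), " variables)\n", sep = "")
  for (v in x) {
    extra <- if (v$kind == "ordinal")
      paste0(" levels=", paste(v$levels, collapse = "<"))
    else if (v$transform != "none") paste0(" transform=", v$transform) else ""
    cat(sprintf("  %-12s %-10s %-13s%s\n", v$name, v$kind, v$role, extra))
  }
  invisible(x)
}

# Names of variables by role/kind
predictor_names <- function(sch) names(sch)[schema_roles(sch) == "predictor"]
auxiliary_names <- function(sch) names(sch)[schema_roles(sch) == "auxiliary"]
time_name  <- function(sch) names(sch)[schema_roles(sch) == "outcome_time"]
event_name <- function(sch) names(sch)[schema_roles(sch) == "outcome_event"]
id_name    <- function(sch) { nm <- names(sch)[schema_roles(sch) == "id"]
  if (length(nm)) nm else NULL }

#' Default schema: the six myeloma prognostic factors
#'
#' The standard schema used throughout the package examples: overall survival
#' in months with a death indicator, and the six routinely collected candidate
#' prognostic factors considered for newly diagnosed transplant-ineligible
#' multiple myeloma -- age (continuous), WHO performance status (ordinal 0-4),
#' lactate dehydrogenase (LDH, log-transformed), C-reactive protein (CRP,
#' log(1+x)-transformed), the lymphocyte to white-blood-cell ratio and
#' International Staging System stage (ordinal I-III) -- plus sex as an
#' auxiliary imputation variable and a randomised treatment arm that is
#' deliberately excluded from imputation and modelling.
#'
#' @return a `trial_schema`.
#' @export
trial_schema <- function() {
  schema(
    variable_spec("id", "continuous", role = "id"),
    variable_spec("os_months", "continuous", role = "outcome_time"),
    variable_spec("os_event", "continuous", role = "outcome_event"),
    variable_spec("age", "continuous", role = "predictor"),
    variable_spec("who_ps", "ordinal", role = "predictor",
                  levels = c("0", "1", "2", "3", "4")),
    variable_spec("ldh", "continuous", role = "predictor", transform = "log"),
    variable_spec("crp", "continuous", role = "predictor", transform = "log1p"),
    variable_spec("lw_ratio", "continuous", role = "predictor"),
    variable_spec("iss", "ordinal", role = "predictor",
                  levels = c("I", "II", "III")),
    variable_spec("sex", "continuous", role = "auxiliary", standardize = FALSE),
    variable_spec("treatment", "continuous", role = "treatment",
                  standardize = FALSE)
  )
}

#' Construct a typed trial dataset
#'
#' Validates a data frame against a schema: survival times strictly positive,
#' event indicator binary, ordinal values within their declared level sets, and
#' missingness confined to predictor columns.
#'
#' @param df data frame with one row per subject.
#' @param sch a `trial_schema`.
#' @return object of class `trial_dataset` with elements `data` (typed data
#'   frame; ordinal columns as ordered factors) and `schema`.
#' @export
trial_dataset <- function(df, sch) {
  stopifnot(inherits(sch, "trial_schema"), is.data.frame(df))
  if (nrow(df) < 1) stop_micoxpen("dataset needs at least one row")
  missing_cols <- setdiff(names(sch), names(df))
  if (length(missing_cols))
    stop_micoxpen("missing required column(s): %s",
                  paste(missing_cols, collapse = ", "))
  df <- df[names(sch)]
  for (v in sch) {
    col <- df[[v$name]]
    if (v$kind == "ordinal") {
      col <- as.character(col)
      bad <- !is.na(col) & !(col %in% v$levels)
      if (any(bad))
        stop_micoxpen("unknown level '%s' for ordinal variable '%s'",
                      col[which(bad)[1]], v$name)
      df[[v$name]] <- factor(col, levels = v$levels, ordered = TRUE)
    } else {
      df[[v$name]] <- suppressWarnings(as.numeric(col))
      if (any(!is.na(col) & is.na(df[[v$name]])))
        stop_micoxpen("non-numeric value in continuous variable '%s'", v$name)
    }
  }
  tn <- time_name(sch); en <- event_name(sch)
  if (anyNA(df[[tn]]) || any(df[[tn]] <= 0))
    stop_micoxpen("non-positive or missing survival time")
  ev <- df[[en]]
  if (anyNA(ev) || !all(ev %in% c(0, 1)))
    stop_micoxpen("non-binary event indicator")
  non_pred <- setdiff(names(sch), predictor_names(sch))
  for (nm in non_pred)
    if (anyNA(df[[nm]]))
      stop_micoxpen("missing values only allowed in predictors (found in '%s')",
                    nm)
  structure(list(data = df, schema = sch), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  ev <- x$data[[event_name(x$schema)]]
  cat(sprintf("Trial dataset: %d subjects, %d events (%.1f%%)\n",
              nrow(x$data), sum(ev), 100 * mean(ev)))
  nmiss <- vapply(predictor_names(x$schema),
                  function(v) sum(is.na(x$data[[v]])), 0L)
  if (any(nmiss > 0)) {
    cat("Missing predictor values:\n")
    for (v in names(nmiss)[nmiss > 0])
      cat(sprintf("  %-10s %d\n", v, nmiss[[v]]))
  } else cat("No missing predictor values\n")
  invisible(x)
}

n_subjects <- function(td) nrow(td$data)

#' Read a trial dataset from CSV
#'
#' @param path CSV file with a header row matching the schema names.
#' @param sch a `trial_schema`.
#' @param na character vector of missing-value sentinels.
#' @return a `trial_dataset`.
#' @export
read_dataset <- function(path, sch, na = c("", "NA")) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = na, check.names = FALSE)
  trial_dataset(df, sch)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_dataset()]: values and missingness masks round-trip.
#'
#' @param td a `trial_dataset`.
#' @param path output CSV path.
#' @export
write_dataset <- function(td, path) {
  df <- td$data
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
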