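#' Summarise the missing-data pattern of a dataset
#'
#' Every subject is assigned to exactly one pattern: the set of predictor
#' variables missing for that subject (the empty set is the "complete cases"
#' pattern). Per-variable missing totals are the sums of the counts of all
#' patterns containing the variable. Percentages are of the full sample size,
#' rounded half-up to two decimals as in clinical summary tables.
#'
#' @param td a [trial_dataset()].
#' @return object of class `missing_pattern_summary` with elements
#'   `patterns` (data frame: `pattern`, `variables` list-column, `n`,
#'   `percent`, sorted by descending count then pattern label),
#'   `per_variable` (data frame: `variable`, `n_missing`, `percent`),
#'   `complete_cases`, `complete_percent`, and `n`.
#' @export
summarize_missingness <- function(td) {
  stopifnot(inherits(td, "trial_dataset"))
  preds <- predictor_names(td$schema)
  n <- n_subjects(td)
  miss <- vapply(preds, function(v) is.na(td$data[[v]]), logical(n))
  if (n == 1) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, preds))
  key <- apply(miss, 1, function(r) paste(preds[r], collapse = " and "))
  key[key == ""] <- "complete cases"
  tab <- table(key)
  pat <- data.frame(pattern = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  pat$variables <- lapply(pat$pattern, function(p)
    if (p == "complete cases") character(0) else strsplit(p, " and ", fixed = TRUE)[[1]])
  pat$percent <- round_half_up(100 * pat$n / n, 2)
  pat <- pat[order(-pat$n, pat$pattern), c("pattern", "variables", "n", "percent")]
  rownames(pat) <- NULL
  per_var <- data.frame(
    variable = preds,
    n_missing = vapply(preds, function(v)
      sum(pat$n[vapply(pat$variables, function(s) v %in% s, TRUE)]), 0L),
    stringsAsFactors = FALSE
  )
  per_var$percent <- round_half_up(100 * per_var$n_missing / n, 2)
  rownames(per_var) <- NULL
  cc <- sum(pat$n[pat$pattern == "complete cases"])
  structure(list(patterns = pat, per_variable = per_var,
                 complete_cases = cc,
                 complete_percent = round_half_up(100 * cc / n, 2),
                 n = n),
            class = "missing_pattern_summary")
}

#' @export
print.missing_pattern_summary <- function(x, ...) {
  cat(sprintf("Missing data patterns (n = %d)\n", x$n))
  for (i in seq_len(nrow(x$patterns)))
    cat(sprintf("  %-45s %5d (%.2f)\n", x$patterns$pattern[i],
                x$patterns$n[i], x$patterns$percent[i]))
  cat("Per-variable missing:\n")
  for (i in seq_len(nrow(x$per_variable)))
    cat(sprintf("  %-12s %5d (%.2f)\n", x$per_variable$variable[i],
                x$per_variable$n_missing[i], x$per_variable$percent[i]))
  invisible(x)
}

#' Write a missingness report as TSV
#'
#' @param x a `missing_pattern_summary`.
#' @param path output TSV path (columns: pattern, n, percent).
#' @export
write_missingness_report <- function(x, path) {
  out <- x$patterns[c("pattern", "n", "percent")]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count subjects complete on a set of variables
#'
#' The eligibility rule of complete-case external validation: a subject is
#' eligible if none of `required_vars` is missing.
#'
#' @param td a `trial_dataset`.
#' @param required_vars character vector of predictor names.
#' @return integer count.
#' @export
count_eligible_complete_cases <- function(td, required_vars) {
  preds <- predictor_names(td$schema)
  bad <- setdiff(required_vars, preds)
  if (length(bad))
    stop_micoxpen("unknown variable(s): %s", paste(bad, collapse = ", "))
  keep <- rep(TRUE, n_subjects(td))
  for (v in required_vars) keep <- keep & !is.na(td$data[[v]])
  sum(keep)
}

#' Published missing-data pattern tables for the myeloma trial cohorts
#'
#' The pattern-by-pattern missingness counts reported for the Myeloma XI
#' transplant-ineligible cohort (training, n = 1852) and the Myeloma IX
#' transplant-ineligible cohort (test, n = 849). The subject-level trial data
#' are not public; these published summary counts are shipped as plain-text
#' data so the package's missingness arithmetic can be exercised against them.
#'
#' @param which `"training"` (Myeloma XI) or `"test"` (Myeloma IX).
#' @return data frame with columns `pattern` (semicolon-separated missing
#'   variable names, empty string for complete cases) and `n`.
#' @export
myeloma_missing_patterns <- function(which = c("training", "test")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("myeloma_", which, "_missing_patterns.tsv"),
                      package = "micoxpen", mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "integer"))
}

#' Reconstruct a dataset realising a published pattern table
#'
#' Builds a dummy `trial_dataset` whose missingness mask reproduces the given
#' pattern counts exactly (covariate values are placeholders). Used to run the
#' package's missingness summaries on published pattern tables.
#'
#' @param patterns data frame with columns `pattern` (semicolon-separated
#'   missing variable names, `""` = complete) and `n`.
#' @param sch schema; defaults to [trial_schema()].
#' @return a `trial_dataset`.
#' @export
dataset_from_patterns <- function(patterns, sch = trial_schema()) {
  n <- sum(patterns$n)
  filler <- list(age = 70, who_ps = "1", ldh = 250, crp = 5,
                 lw_ratio = 0.2, iss = "II")
  df <- data.frame(id = seq_len(n), os_months = seq_len(n) / 2,
                   os_event = rep_len(c(1, 0), n), sex = 1, treatment = 0)
  for (v in predictor_names(sch)) df[[v]] <- rep(filler[[v]] %||% 1, n)
  row <- 1L
  for (i in seq_len(nrow(patterns))) {
    vars <- strsplit(patterns$pattern[i], ";", fixed = TRUE)[[1]]
    idx <- row:(row + patterns$n[i] - 1L)
    for (v in vars) df[[v]][idx] <- NA
    row <- row + patterns$n[i]
  }
  trial_dataset(df, sch)
}
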