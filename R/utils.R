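# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding used in missingness and model tables: 0.005 rounds to
#' 0.01 rather than to the even digit (the convention of clinical summary
#' tables), unlike base [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a given seed, restoring the caller's RNG state afterwards so
# that seeded package functions do not perturb the user's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation so each component (imputation stream,
# CV folds, bootstrap, simulation) gets its own reproducible stream from one
# root seed. Kept below 2^31 - 1.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 10007) %% 2147483629)
}

# djb2 string hash, used to stamp run manifests with a config fingerprint.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_micoxpen <- function(...) stop(sprintf(...), call. = FALSE)
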