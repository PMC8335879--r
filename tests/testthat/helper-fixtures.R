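# Shared fixtures and independent brute-force oracles.

# A compact schema for unit tests that do not need all six myeloma covariates.
mini_schema <- function() {
  schema(
    variable_spec("id", "continuous", role = "id"),
    variable_spec("time", "continuous", role = "outcome_time"),
    variable_spec("event", "continuous", role = "outcome_event"),
    variable_spec("x", "continuous"),
    variable_spec("grade", "ordinal", levels = c("I", "II", "III")),
    variable_spec("z", "continuous", transform = "log"),
    variable_spec("sex", "continuous", role = "auxiliary",
                  standardize = FALSE)
  )
}

mini_df <- function(n = 8, seed = 1) {
  micoxpen:::with_seed(seed, data.frame(
    id = seq_len(n),
    time = round(rexp(n, 0.05) + 0.5, 2),
    event = rbinom(n, 1, 0.6),
    x = rnorm(n, 10, 2),
    grade = sample(c("I", "II", "III"), n, replace = TRUE),
    z = rlnorm(n, 2, 0.5),
    sex = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE))
}

# Fast small synthetic run (shared by several files; built once).
fast_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_trial(synthetic_config(n = 350, seed = 404))
      cache <<- list(gen = g,
                     model = build_model(g$data, m = 3, B_se = 10, seed = 77))
    }
    cache
  }
})

# Brute-force log partial likelihood for a single covariate (Breslow form;
# exact for tie-free data).
log_plik_1d <- function(beta, x, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

# Exhaustive Harrell concordance by pair counting (censoring-aware).
harrell_brute <- function(pi_, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      num <- num + (pi_[i] > pi_[j]) + 0.5 * (pi_[i] == pi_[j])
    }
  }
  num / den
}

# Exhaustive IPCW (Uno) concordance by explicit double loop.
uno_brute <- function(pi_, time, event, tau) {
  sfG <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gm <- function(t) { j <- sum(sfG$time < t); if (j == 0) 1 else sfG$surv[j] }
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < tau && time[i] < time[j]) {
      w <- 1 / Gm(time[i])^2
      den <- den + w
      num <- num + w * ((pi_[i] > pi_[j]) + 0.5 * (pi_[i] == pi_[j]))
    }
  }
  num / den
}

# Gram-Schmidt orthonormalisation of {s, s^2, ...} (centred) over equally
# spaced scores: independent construction of the polynomial contrast basis.
gram_schmidt_contrasts <- function(k) {
  s <- seq_len(k)
  basis <- sapply(seq_len(k - 1), function(p) s^p)
  basis <- sweep(basis, 2, colMeans(basis))
  out <- matrix(0, k, k - 1)
  for (j in seq_len(k - 1)) {
    v <- basis[, j]
    if (j > 1) for (l in seq_len(j - 1))
      v <- v - sum(v * out[, l]) * out[, l]
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
}
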