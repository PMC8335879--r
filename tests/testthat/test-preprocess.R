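test_that("declared transforms are applied once, keep NA, and invert exactly", {
  df <- mini_df(10, seed = 5)
  df$z[3] <- NA
  td <- trial_dataset(df, mini_schema())
  tt <- apply_transforms(td)
  expect_equal(tt$data$z[-3], log(df$z[-3]))
  expect_true(is.na(tt$data$z[3]))
  expect_identical(apply_transforms(tt)$data$z, tt$data$z)  # idempotent
  back <- micoxpen:::invert_transforms(tt)
  expect_equal(back$data$z, df$z, tolerance = 1e-12)
})

test_that("log transform rejects non-positive values; log1p handles zero", {
  df <- mini_df(5)
  df$z[1] <- 0
  expect_error(apply_transforms(trial_dataset(df, mini_schema())),
               "non-positive value in 'z'")
  expect_equal(log1p(0), 0)  # boundary of the CRP transform domain
  sch <- schema(
    variable_spec("time", role = "outcome_time"),
    variable_spec("event", role = "outcome_event"),
    variable_spec("w", "continuous", transform = "log1p"))
  td <- trial_dataset(data.frame(time = 1:3, event = c(1, 0, 1),
                                 w = c(0, 1, exp(1) - 1)), sch)
  expect_equal(apply_transforms(td)$data$w, c(0, log(2), 1))
})

test_that("standardisation uses the population SD and centres exactly", {
  sch <- schema(variable_spec("time", role = "outcome_time"),
                variable_spec("event", role = "outcome_event"),
                variable_spec("x", "continuous"))
  td <- trial_dataset(data.frame(time = 1:3, event = c(1, 1, 0), x = 1:3), sch)
  p <- compute_standardization(td)
  expect_equal(p$mean, 2)
  expect_equal(p$sd, sqrt(2 / 3))   # divisor n, not n - 1
  std <- standardize(td, p)
  expect_equal(std$data$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  td_const <- trial_dataset(data.frame(time = 1:3, event = c(1, 1, 0),
                                       x = c(5, 5, 5)), sch)
  expect_error(compute_standardization(td_const), "constant column")
})

test_that("standardisation parameters match an independent two-pass computation", {
  micoxpen:::with_seed(88, {
    x <- rnorm(1000, 10, 4)
    sch <- schema(variable_spec("time", role = "outcome_time"),
                  variable_spec("event", role = "outcome_event"),
                  variable_spec("x", "continuous"))
    td <- trial_dataset(data.frame(time = rep(1, 1000),
                                   event = rep(1, 1000), x = x), sch)
    p <- compute_standardization(td)
    expect_equal(p$mean, sum(x) / 1000, tolerance = 1e-12)
    expect_equal(p$sd, sqrt(sum((x - sum(x) / 1000)^2) / 1000),
                 tolerance = 1e-12)
    z <- standardize(td, p)$data$x
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  })
})

test_that("identity parameters leave data unchanged; foreign parameters decentre", {
  df <- mini_df(20, seed = 9)
  td <- trial_dataset(df, mini_schema())
  ident <- compute_standardization(td)
  ident$mean[] <- 0; ident$sd[] <- 1
  expect_equal(standardize(td, ident)$data$x, df$x)
  foreign <- compute_standardization(td)
  foreign$mean[] <- foreign$mean + 5
  expect_gt(abs(mean(standardize(td, foreign)$data$x)), 1)
})

test_that("polynomial contrast basis matches Gram-Schmidt construction", {
  for (k in 2:6) {
    cm <- ordinal_contrasts(k)
    gs <- gram_schmidt_contrasts(k)
    # columns agree up to sign
    for (j in seq_len(k - 1)) {
      agree <- max(abs(cm[, j] - gs[, j]))
      flip  <- max(abs(cm[, j] + gs[, j]))
      expect_lt(min(agree, flip), 1e-10)
    }
    expect_lt(max(abs(crossprod(cm) - diag(k - 1))), 1e-12)  # orthonormal
    expect_lt(max(abs(colSums(cm))), 1e-12)                  # zero-sum
  }
  expect_equal(ordinal_contrasts(3)[, 1], c(-1, 0, 1) / sqrt(2),
               ignore_attr = TRUE)
  expect_equal(ordinal_contrasts(3)[, 2], c(1, -2, 1) / sqrt(6),
               ignore_attr = TRUE)
  expect_equal(ordinal_contrasts(2)[, 1], c(-1, 1) / sqrt(2),
               ignore_attr = TRUE)
})

test_that("design matrix expands ordinals and records column sources", {
  df <- mini_df(15, seed = 2)
  td <- apply_transforms(trial_dataset(df, mini_schema()))
  X <- build_design(td, compute_standardization(td))
  expect_equal(colnames(X), c("x", "grade.L", "grade.Q", "z"))
  src <- attr(X, "source")
  expect_equal(unname(src[c("grade.L", "grade.Q")]), c("grade", "grade"))
  expect_equal(mean(X[, "x"]), 0, tolerance = 1e-10)
  # ordinal columns are contrast scores, never standardised
  expect_true(all(X[, "grade.L"] %in% ordinal_contrasts(3)[, 1]))
  # missing predictor refuses a design
  df$x[1] <- NA
  expect_error(build_design(trial_dataset(df, mini_schema())),
               "impute before building")
})

test_that("pooled standardisation parameters are the simple mean", {
  df <- mini_df(10, seed = 4)
  td <- trial_dataset(df, mini_schema())
  p1 <- compute_standardization(td)
  p2 <- p1; p2$mean <- p2$mean + 1; p2$sd <- p2$sd * 2
  pooled <- pool_standardization(list(p1, p2))
  expect_equal(pooled$mean, p1$mean + 0.5)
  expect_equal(pooled$sd, p1$sd * 1.5)
  expect_equal(attr(pooled, "provenance"), "pooled_across_imputations")
})
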