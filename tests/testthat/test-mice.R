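# Fixture: one continuous and one ordinal variable masked MCAR, with strong
# linear structure so the mask-and-recover checks are informative.
mice_fixture <- function(n = 500, seed = 21, mask = 0.2) {
  micoxpen:::with_seed(seed, {
    u <- rnorm(n)
    x <- 10 + 2 * u + rnorm(n, 0, 0.7)          # R^2 about 0.9
    grade_p <- plogis(outer(c(-1, 1), u, "-"))  # ordered by u
    grade <- apply(rbind(grade_p, 1), 2, function(p)
      sample(c("I", "II", "III"), 1, prob = pmax(diff(c(0, p)), 0)))
    df <- data.frame(id = 1:n, time = rexp(n, 0.05) + 0.1,
                     event = rbinom(n, 1, 0.5), x = x, grade = grade,
                     z = exp(u + 3), sex = rbinom(n, 1, 0.5),
                     stringsAsFactors = FALSE)
    full <- df
    df$x[sample(n, round(mask * n))] <- NA
    df$grade[sample(n, round(mask * n))] <- NA
    list(masked = trial_dataset(df, mini_schema()),
         full = trial_dataset(full, mini_schema()))
  })
}

test_that("the 25% rule selects m and the rule of thumb takes over above it", {
  td <- dataset_from_patterns(myeloma_missing_patterns("training"))
  s <- summarize_missingness(td)
  expect_equal(choose_m(s), 10L)   # max per-variable 22.46% <= 25%
  s2 <- s
  s2$per_variable$percent[3] <- 30
  s2$complete_percent <- 58.8      # 41.2% incomplete
  expect_equal(choose_m(s2), 42L)  # ceiling(41.2)
  s3 <- s
  s3$per_variable$percent[] <- 0
  expect_equal(choose_m(s3), 1L)
})

test_that("visit order runs least to most missing with schema-order ties", {
  fx <- mice_fixture(120, seed = 31, mask = 0.1)
  df <- fx$masked$data
  df$z[1:60] <- NA                        # most missing
  td <- trial_dataset(df, mini_schema())
  spec <- imputation_spec(td, m = 3)
  nm <- vapply(spec$visit, function(v) sum(is.na(td$data[[v]])), 0L)
  expect_true(all(diff(nm) >= 0))
  expect_equal(spec$visit[length(spec$visit)], "z")
  # predictors of each target: other predictors + auxiliary sex (outcome
  # enters separately); treatment never appears
  expect_false("treatment" %in% unlist(spec$predictors))
  expect_true(all(vapply(spec$predictors, function(p) "sex" %in% p, TRUE)))
})

test_that("fully observed data pass through imputation unchanged", {
  fx <- mice_fixture(80, seed = 41, mask = 0)
  st <- impute(fx$full)
  expect_equal(micoxpen:::n_imputations(st), 1L)
  expect_identical(st$datasets[[1]]$data, fx$full$data)
})

test_that("observed cells are identical across imputations and PMM respects donors", {
  fx <- mice_fixture(300, seed = 51)
  st <- impute(fx$masked, imputation_spec(fx$masked, m = 4, seed = 9))
  obs_x <- !is.na(fx$masked$data$x)
  obs_g <- !is.na(fx$masked$data$grade)
  for (d in 1:4) {
    expect_identical(st$datasets[[d]]$data$x[obs_x],
                     fx$masked$data$x[obs_x])
    expect_identical(st$datasets[[d]]$data$grade[obs_g],
                     fx$masked$data$grade[obs_g])
    expect_false(anyNA(st$datasets[[d]]$data$x))
    # PMM donor property: imputed values drawn from the observed support
    expect_true(all(st$datasets[[d]]$data$x[!obs_x] %in%
                      fx$masked$data$x[obs_x]))
  }
})

test_that("identical seed and spec reproduce the stack exactly", {
  fx <- mice_fixture(200, seed = 61)
  s1 <- impute(fx$masked, imputation_spec(fx$masked, m = 3, seed = 123))
  s2 <- impute(fx$masked, imputation_spec(fx$masked, m = 3, seed = 123))
  expect_identical(lapply(s1$datasets, `[[`, "data"),
                   lapply(s2$datasets, `[[`, "data"))
  s3 <- impute(fx$masked, imputation_spec(fx$masked, m = 3, seed = 124))
  expect_false(identical(s1$datasets[[1]]$data$x, s3$datasets[[1]]$data$x))
})

test_that("MCAR-masked continuous and ordinal values are recovered in distribution", {
  fx <- mice_fixture(500, seed = 71)
  st <- impute(fx$masked, imputation_spec(fx$masked, m = 5, seed = 5))
  full_mean <- mean(fx$full$data$x)
  comp_means <- vapply(st$datasets, function(d) mean(d$data$x), 0)
  # Monte-Carlo tolerance: a few SEs of the full-data mean
  expect_lt(abs(mean(comp_means) - full_mean),
            4 * sd(fx$full$data$x) / sqrt(500))
  full_freq <- prop.table(table(fx$full$data$grade))
  comp_freq <- rowMeans(vapply(st$datasets, function(d)
    prop.table(table(d$data$grade)), full_freq))
  expect_lt(max(abs(comp_freq - full_freq)),
            4 * sqrt(0.25 / 500) + 0.02)  # binomial tolerance
})

test_that("long-format stack export round-trips", {
  fx <- mice_fixture(100, seed = 81)
  st <- impute(fx$masked, imputation_spec(fx$masked, m = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stack(st, path)
  st2 <- read_stack(path, mini_schema())
  expect_equal(micoxpen:::n_imputations(st2), 3L)
  expect_equal(st2$datasets[[2]]$data$x, st$datasets[[2]]$data$x,
               tolerance = 1e-9)
  expect_equal(st2$seeds, st$seeds)
})
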