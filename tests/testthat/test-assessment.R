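test_that("Bloom rankits: boundary values, antisymmetry and large-n spread", {
  expect_equal(bloom_rankits(1), 0)
  z3 <- bloom_rankits(3)
  expect_equal(z3[2], 0)
  expect_equal(z3[3], sqrt(pi / 8) * qnorm(2.625 / 3.25), tolerance = 1e-12)
  expect_equal(z3[3], 0.5449, tolerance = 1e-3)   # table arithmetic
  for (n in c(10, 101, 10000)) {
    z <- bloom_rankits(n)
    expect_true(all(diff(z) > 0))
    expect_lt(max(abs(z + rev(z))), 1e-12)        # antisymmetry
  }
  expect_equal(sd(bloom_rankits(1000)), sqrt(pi / 8), tolerance = 0.02 * sqrt(pi / 8))
})

test_that("D-statistic equals an independently coded Cox-on-rankits fit", {
  time <- c(5, 8, 2, 11, 3, 9)
  event <- c(1, 1, 1, 0, 1, 1)
  pi_ <- c(0.3, -1.2, 0.8, -0.4, 1.5, 0.1)
  d <- d_statistic(pi_, time, event)
  # independent route: explicit rankit assignment then a direct coxph call
  z <- sqrt(pi / 8) * qnorm((rank(pi_) - 3 / 8) / (6 + 1 / 4))
  ref <- survival::coxph(survival::Surv(time, event) ~ z)
  expect_equal(d$d, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(d$variance, unname(vcov(ref)[1, 1]), tolerance = 1e-8)
})

test_that("D is invariant under strictly increasing transforms of the PI", {
  micoxpen:::with_seed(71, {
    n <- 120
    pi_ <- rnorm(n)
    time <- rexp(n, exp(pi_))
    event <- rbinom(n, 1, 0.8)
    d0 <- d_statistic(pi_, time, event)$d
    for (f in list(exp, function(p) p^3 + 2 * p, function(p) rank(p)))
      expect_equal(d_statistic(f(pi_), time, event)$d, d0, tolerance = 1e-10)
    expect_error(d_statistic(rep(1, n), time, event), "tied")
  })
})

test_that("combined D pools per-imputation statistics by Rubin's rules", {
  micoxpen:::with_seed(73, {
    n <- 150
    pi1 <- rnorm(n); pi2 <- pi1 + rnorm(n, 0, 0.1)
    time <- rexp(n, exp(pi1)); event <- rbinom(n, 1, 0.8)
    res <- combined_d(list(pi1, pi2), time, event)
    expect_equal(res$combined, mean(res$per_imputation$d))
    expect_equal(res$within, mean(res$per_imputation$variance),
                 tolerance = 1e-12)
    # identical imputations: zero between-imputation variance
    res2 <- combined_d(list(pi1, pi1), time, event)
    expect_equal(res2$between, 0)
    expect_equal(mean(c(0.8, 0.9)), 0.85)   # the pooling arithmetic itself
  })
})

test_that("calibration: degenerate predictions collapse to the overall KM", {
  micoxpen:::with_seed(79, {
    n <- 300
    time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
    pred <- rep(0.5, n)
    res <- calibration(pred, time, event, t = 5)
    expect_equal(nrow(res$table), 1)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(res$table$observed,
                 summary(sf, times = 5)$surv, tolerance = 1e-12)
    # t = 0 boundary: everyone survives
    res0 <- calibration(runif(n), time, event, t = 0)
    expect_true(all(res0$table$observed == 1))
    expect_error(calibration(runif(n), time, event, t = max(time) + 1),
                 "beyond maximum follow-up")
  })
})

test_that("a perfectly calibrated model stays within the group confidence bands", {
  micoxpen:::with_seed(83, {
    n <- 5000
    pi_ <- rnorm(n, 0, 0.8)
    rate <- 0.05 * exp(pi_)
    time <- rexp(n, rate)
    cens <- runif(n, 5, 60)
    obs_t <- pmin(time, cens); event <- as.integer(time <= cens)
    t_star <- 12
    pred <- exp(-0.05 * t_star * exp(pi_))       # the true S(t | x)
    res <- calibration(pred, obs_t, event, t = t_star)
    expect_gte(sum(res$table$predicted >= res$table$lower &
                     res$table$predicted <= res$table$upper), 8)
  })
})

test_that("calibration slope recovers identity and affine relationships", {
  tab <- data.frame(observed = seq(0.1, 1, 0.1))
  tab$predicted <- tab$observed
  expect_equal(calibration_slope(tab), 1, tolerance = 1e-12)
  tab$predicted <- 2 * tab$observed - 0.3
  expect_equal(calibration_slope(tab), 2, tolerance = 1e-12)
  expect_error(calibration_slope(data.frame(observed = 0.5, predicted = 0.4)),
               ">= 2 risk groups")
  micoxpen:::with_seed(89, {
    slopes <- rnorm(10)
    expect_equal(pool_calibration_slopes(slopes), mean(slopes),
                 tolerance = 1e-12)
  })
})

test_that("hand-rolled Schoenfeld residuals match the survival package", {
  micoxpen:::with_seed(97, {
    n <- 80
    x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
    time <- rexp(n, exp(0.5 * x[, 1])) + seq_len(n) * 1e-8
    event <- rbinom(n, 1, 0.7)
    fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
    ref <- residuals(fit, type = "schoenfeld")
    mine <- schoenfeld_residuals(x, time, event, coef(fit))
    expect_equal(unname(mine), unname(ref), tolerance = 1e-6,
                 ignore_attr = TRUE)
  })
})

test_that("PH check keeps size under proportional hazards and flags reversal", {
  micoxpen:::with_seed(101, {
    n <- 600
    rejections <- 0; reps <- 60
    for (r in seq_len(reps)) {
      x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
      time <- rexp(n, 0.1 * exp(0.5 * x[, 1]))
      event <- as.integer(time <= runif(n, 5, 40))
      time <- pmin(time, runif(n, 5, 40))
      beta <- coef(survival::coxph(survival::Surv(time, event) ~ x))
      res <- ph_check(list(x), rbind(beta), time, event)
      if (res$verdict[["x"]] == "violated") rejections <- rejections + 1
    }
    expect_lt(abs(rejections / reps - 0.05), 0.08)
    # strong reversal of the effect at the median time: high power
    hits <- 0; reps2 <- 20
    for (r in seq_len(reps2)) {
      x <- rnorm(n)
      t1 <- rexp(n, 0.2 * exp(1.5 * x))          # early: positive effect
      t2 <- 3 + rexp(n, 0.2 * exp(-1.5 * x))     # late: reversed
      time <- ifelse(t1 < 3, t1, t2)
      event <- rep(1, n)
      xm <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
      beta <- coef(survival::coxph(survival::Surv(time, event) ~ xm))
      res <- ph_check(list(xm), rbind(beta), time, event)
      if (res$verdict[["x"]] == "violated") hits <- hits + 1
    }
    expect_gte(hits / reps2, 0.9)
  })
  # degenerate guard: residuals exist, regression refused
  x <- matrix(c(1, 0, 1, 0), 4, 1, dimnames = list(NULL, "x"))
  expect_silent(schoenfeld_residuals(x, 1:4, c(1, 1, 0, 0), 0.2))
  expect_error(ph_check(list(x), rbind(0.2), 1:4, c(1, 1, 0, 0)),
               ">= 3 events")
})

test_that("Uno's C matches exhaustive weighted pair counting on small data", {
  time <- c(2, 4, 5, 7, 9)
  event <- c(1, 0, 1, 1, 0)
  pi_ <- c(1.0, 0.2, 0.8, -0.5, -1.0)
  expect_equal(uno_c(pi_, time, event, tau = 8),
               uno_brute(pi_, time, event, tau = 8), tolerance = 1e-12)
  # perfect anti-concordance with time, no censoring
  t2 <- 1:6
  expect_equal(uno_c(-(1:6), t2, rep(1, 6), tau = 10), 1)
})

test_that("without censoring Uno's C reduces to Harrell's C", {
  micoxpen:::with_seed(103, {
    n <- 60
    pi_ <- rnorm(n)
    time <- rexp(n, exp(pi_))
    event <- rep(1, n)
    tau <- max(time) + 1
    expect_equal(uno_c(pi_, time, event, tau),
                 harrell_brute(pi_, time, event), tolerance = 1e-12)
    # cross-check against the survival package's concordance
    cfit <- survival::concordance(survival::Surv(time, event) ~ pi_,
                                  reverse = TRUE)
    expect_equal(uno_c(pi_, time, event, tau), unname(cfit$concordance),
                 tolerance = 1e-10)
  })
})

test_that("random prognostic indices give chance-level concordance", {
  micoxpen:::with_seed(107, {
    n <- 2500
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.8)
    pi_ <- rnorm(n)
    expect_lt(abs(uno_c(pi_, time, event, tau = 15) - 0.5), 0.04)
  })
})
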