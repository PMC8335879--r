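toy_cox <- function() {
  # interleaved groups so the partial-likelihood maximum is finite
  list(x = matrix(c(1, 0, 1, 0, 1, 0), ncol = 1,
                  dimnames = list(NULL, "x")),
       time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
}

test_that("unpenalised fit maximises the explicit partial likelihood", {
  d <- toy_cox()
  fit <- fit_cox(d$x, d$time, d$event, lambda = 0)
  brute <- optimize(function(b) log_plik_1d(b, d$x[, 1], d$time, d$event),
                    c(-6, 6), maximum = TRUE)
  expect_equal(unname(fit$coef), brute$maximum, tolerance = 1e-5)
  expect_gte(fit$loglik, fit$loglik_null)
  # sign symmetry
  fit_neg <- fit_cox(-d$x, d$time, d$event, lambda = 0)
  expect_equal(unname(fit_neg$coef), -unname(fit$coef), tolerance = 1e-8)
})

test_that("lambda = 0 fit agrees with an independent coordinate-descent solver", {
  micoxpen:::with_seed(17, {
    for (r in 1:20) {
      n <- 60
      x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
      time <- rexp(n, exp(0.5 * x[, 1] - 0.3 * x[, 2]))
      time <- time + seq_len(n) * 1e-9        # break ties
      event <- rbinom(n, 1, 0.8)
      if (sum(event) < 5) next
      mine <- fit_cox(x, time, event, lambda = 0, ties = "breslow")
      lmax <- micoxpen:::cox_lambda_max(x, time, event)
      g <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                          lambda = exp(seq(log(lmax), log(lmax * 1e-7),
                                           length.out = 60)),
                          standardize = FALSE, thresh = 1e-12)
      expect_equal(unname(mine$coef), unname(g$beta[, ncol(g$beta)]),
                   tolerance = 1e-4)
    }
  })
})

test_that("full shrinkage at large lambda and monotone sparsity along the path", {
  micoxpen:::with_seed(23, {
    n <- 150
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    time <- rexp(n, exp(x[, 1]))
    event <- rbinom(n, 1, 0.7)
    lmax <- micoxpen:::cox_lambda_max(x, time, event)
    fit_big <- fit_cox(x, time, event, lambda = 10 * lmax)
    expect_true(all(fit_big$coef == 0))
    lams <- exp(seq(log(lmax * 0.9), log(lmax * 0.002), length.out = 12))
    nnz <- vapply(lams, function(l)
      sum(fit_cox(x, time, event, lambda = l)$coef != 0), 0L)
    expect_true(all(diff(nnz) >= 0))  # sparsity non-increasing in lambda
  })
})

test_that("cross-validation keeps a strong predictor and drops pure noise", {
  micoxpen:::with_seed(29, {
    n <- 400
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, c("strong", paste0("noise", 1:4))))
    time <- rexp(n, 0.1 * exp(x[, "strong"]))
    event <- rep(1, n)
    g <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                        nlambda = 60, lambda.min.ratio = 0.01,
                        standardize = FALSE)
    opt <- cv_lambda(x, time, event, g$lambda, nfolds = 5, seed = 1)
    fit <- fit_cox(x, time, event, opt)
    expect_true("strong" %in% fit$selected)
    expect_equal(cv_lambda(x, time, event, 0.05), 0.05)  # degenerate sequence
  })
})

test_that("near-null predictors are mostly shrunk away at the cross-validated optimum", {
  micoxpen:::with_seed(31, {
    hits <- 0; empty <- 0; runs <- 50
    for (r in seq_len(runs)) {
      n <- 400
      x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
      time <- rexp(n, 0.1)
      event <- rbinom(n, 1, 0.7)
      g <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                          nlambda = 100, lambda.min.ratio = 0.001,
                          standardize = FALSE)
      opt <- cv_lambda(x, time, event, g$lambda, nfolds = 10, seed = r)
      fit <- fit_cox(x, time, event, opt)
      nnz <- sum(fit$coef != 0)
      if (nnz <= 1) hits <- hits + 1
      if (nnz == 0) empty <- empty + 1
    }
    # the deviance-minimising rule keeps occasional noise columns, but the
    # modal outcome is the empty model at or near lambda_max
    expect_gte(hits / runs, 0.75)
    expect_gte(empty / runs, 0.4)   # empty model is the modal outcome
  })
})

test_that("shared penalty is the mean of per-imputation optima on one sequence", {
  micoxpen:::with_seed(37, {
    n <- 250
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
    time <- rexp(n, 0.1 * exp(0.8 * x[, 1]))
    event <- rbinom(n, 1, 0.8)
    designs <- list(x, x, x)  # identical imputations
    ls1 <- lambda_star(designs, time, event, nfolds = 5, seed = 3)
    expect_equal(ls1$sd, 0)
    expect_equal(ls1$mean, ls1$optima[1])
    ls2 <- lambda_star(designs, time, event, nfolds = 5, seed = 3)
    expect_identical(ls1$optima, ls2$optima)   # seeding contract
    expect_gte(length(ls1$sequence), 50)
    expect_true(all(diff(ls1$sequence) < 0))
  })
  expect_equal(mean(c(0.05, 0.06)), 0.055)     # the lambda* pooling rule
})

test_that("bootstrap SEs: degenerate cases give zero, realistic case tracks model SE", {
  micoxpen:::with_seed(43, {
    n <- 300
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
    time <- rexp(n, 0.1 * exp(0.8 * x[, 1]))
    event <- rep(1, n)
    lmax <- micoxpen:::cox_lambda_max(x, time, event)
    bs_big <- bootstrap_se(x, time, event, lambda = 10 * lmax, B = 5, seed = 1)
    expect_true(all(bs_big$coefs == 0))
    expect_equal(unname(bs_big$se), 0)
    bs <- bootstrap_se(x, time, event, lambda = lmax * 0.001, B = 100, seed = 2)
    model_se <- sqrt(diag(fit_cox(x, time, event, 0)$var))
    expect_lt(abs(bs$se[["x"]] - model_se) / model_se, 0.3)
  })
})

test_that("predicted survival has the correct boundary and monotonicity behaviour", {
  micoxpen:::with_seed(47, {
    n <- 400
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
    time <- rexp(n, 0.2 * exp(0.8 * x[, 1]))
    event <- rep(1, n)
    fit <- fit_cox(x, time, event, lambda = 0)
    newx <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "x"))
    expect_equal(predict_survival(fit, newx, 0), rep(1, 3))
    s5 <- predict_survival(fit, newx, 5)
    s9 <- predict_survival(fit, newx, 9)
    expect_true(all(s9 <= s5))                    # non-increasing in t
    expect_true(all(diff(s5) < 0))                # decreasing in PI
    # baseline subject: S(t) = exp(-Lambda0(t))
    x0 <- matrix(0, 1, 1, dimnames = list(NULL, "x"))
    bl <- fit$baseline
    t_star <- bl$time[20]
    expect_equal(predict_survival(fit, x0, t_star),
                 exp(-bl$cumhaz[20]), tolerance = 1e-12)
    expect_warning(predict_survival(fit, x0, max(time) + 1),
                   "extrapolating flat")
  })
})

test_that("null-model predictions recover the exponential survival curve", {
  micoxpen:::with_seed(53, {
    n <- 4000; rate <- 0.1
    time <- rexp(n, rate)
    event <- rep(1, n)
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
    lmax <- micoxpen:::cox_lambda_max(x, time, event)
    fit <- fit_cox(x, time, event, lambda = 2 * lmax)   # all zero: null model
    expect_true(all(fit$coef == 0))
    for (t in c(2, 5, 10))
      expect_equal(predict_survival(fit, x[1, , drop = FALSE], t)[[1]],
                   exp(-rate * t), tolerance = 0.05)
  })
})

test_that("univariate pooled fits carry Wald intervals per factor", {
  fm <- fast_model()
  mod <- fm$model
  uni <- univariate_cox(mod$designs, mod$time, mod$event)
  expect_true(all(c("age", "who_ps", "iss") %in% uni$variable))
  expect_true(all(uni$ci_low < uni$coef & uni$coef < uni$ci_high))
  age <- uni[uni$term == "age", ]
  expect_gt(age$coef, 0)  # older patients at higher hazard by construction
})

test_that("fits refuse event-free data", {
  x <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "x"))
  expect_error(fit_cox(x, 1:10, rep(0, 10), 0), "no events")
})
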