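test_that("species_dataset enforces binary occurrence and zero-forest policy", {
  cells <- data.frame(cell_id = c("a", "b", "c", "d"),
                      pfc = c(10, 0, 40, 80), rlps = c(50, NA, 90, 100),
                      occurrence = c(0, 1, 1, 0))
  d <- species_dataset("x", "herb", cells)
  expect_equal(nrow(d$cells), 3)
  expect_equal(d$n_dropped_zero_forest, 1)
  d2 <- species_dataset("x", "herb", cells, zero_forest_policy = "impute-zero")
  expect_equal(nrow(d2$cells), 4)
  expect_equal(d2$cells$rlps[2], 0)
  cells$occurrence[1] <- 2
  expect_error(species_dataset("x", "herb", cells), "binary")
})

test_that("logistic fit recovers known coefficients and flags degeneracy", {
  d <- make_dataset(n = 2000, beta = c(-3, 0.05, 0.02), seed = 21)
  fit <- fit_logistic(d)
  expect_true(fit$converged)
  se <- sqrt(diag(stats::vcov(fit$glm)))
  expect_lt(abs(fit$beta0 - (-3)), 3 * se[1])
  expect_lt(abs(fit$beta1 - 0.05), 3 * se[2])
  expect_lt(abs(fit$beta2 - 0.02), 3 * se[3])
  expect_gte(fit$loglik_full, fit$loglik_null)

  # no-signal truth: slopes near zero
  d0 <- make_dataset(n = 2000, beta = c(0, 0, 0), seed = 22)
  fit0 <- fit_logistic(d0)
  se0 <- sqrt(diag(stats::vcov(fit0$glm)))
  expect_lt(abs(fit0$beta1), 3 * se0[2])
  expect_lt(abs(fit0$beta2), 3 * se0[3])

  # single-class outcome
  dall <- make_dataset(n = 500, beta = c(50, 0, 0), seed = 23)
  expect_error(fit_logistic(dall), "degenerate outcome")
})

test_that("coefficient bias is small on average across repeated fits", {
  truth <- c(-3, 0.05, 0.02)
  reps <- t(vapply(1:40, function(i) {
    f <- fit_logistic(make_dataset(n = 2000, beta = truth, seed = 400 + i))
    c(f$beta0, f$beta1, f$beta2, sqrt(diag(stats::vcov(f$glm))))
  }, numeric(6)))
  bias <- colMeans(reps[, 1:3]) - truth
  mean_se <- colMeans(reps[, 4:6])
  expect_true(all(abs(bias) < mean_se))
})

test_that("predicted probability is the inverse logit of the linear predictor", {
  flat <- list(beta0 = 0, beta1 = 0, beta2 = 0)
  expect_equal(predict_p(flat, 42, 87), 0.5)
  f <- list(beta0 = 0, beta1 = 0.05, beta2 = 0)
  expect_equal(predict_p(f, 75, 100), exp(3.75) / (1 + exp(3.75)))
  expect_equal(predict_p(f, 75, 100), 0.97702, tolerance = 1e-5)
  # logistic symmetry under coefficient negation
  fneg <- list(beta0 = -1.3, beta1 = -0.02, beta2 = 0.01)
  fpos <- list(beta0 = 1.3, beta1 = 0.02, beta2 = -0.01)
  expect_equal(predict_p(fneg, 33, 70) + predict_p(fpos, 33, 70), 1)
})

test_that("McFadden rho2 matches its definition and grows with signal", {
  d <- make_dataset(n = 1500, beta = c(-3, 0.06, 0.02), seed = 31)
  fit <- fit_logistic(d)
  expect_equal(mcfadden_rho2(fit), 1 - fit$loglik_full / fit$loglik_null,
               tolerance = 1e-10)
  rho <- vapply(c(0.01, 0.04, 0.08), function(b1) {
    mcfadden_rho2(fit_logistic(make_dataset(1500, c(-1.5, b1, 0), seed = 77)))
  }, numeric(1))
  expect_true(all(diff(rho) > 0))
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(auc(c(.1, .2, .8, .9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(auc(c(.1, .2), c(1, 1)), "both outcome classes")
})

test_that("AUC is invariant to monotone transforms and flips on reversal", {
  set.seed(6)
  scores <- runif(50); labels <- rbinom(50, 1, 0.4)
  a <- auc(scores, labels)
  expect_equal(auc(qlogis(scores), labels), a)
  expect_equal(auc(scores^3, labels), a)
  expect_equal(auc(-scores, labels), 1 - a)
})

test_that("two-predictor VIF follows the closed form 1/(1-r^2)", {
  x <- c(-2, -1, 0, 1, 2)
  y <- c(0, 0, 0, 0, 0) + c(1, -1, 1, -1, 1)  # r = 0 with x
  expect_equal(vif_two_predictor(x, y), 1, tolerance = 1e-12)
  set.seed(8)
  a <- rnorm(4000)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(4000)
  expect_equal(vif_two_predictor(a, b), 1 / (1 - cor(a, b)^2))
  z <- rnorm(200)
  w <- 0.999 * scale(z)[, 1] + sqrt(1 - 0.999^2) * scale(rnorm(200))[, 1]
  expect_gt(vif_two_predictor(scale(z)[, 1], w), 100)
  expect_error(vif_two_predictor(rep(1, 10), rnorm(10)), "constant")
})

test_that("likelihood-ratio p-values are uniform when predictors carry no signal", {
  pvals <- vapply(1:500, function(i) {
    d <- make_dataset(n = 200, beta = c(0, 0, 0), seed = 9000 + i)
    gof_report(fit_logistic(d), d)$chi2_p
  }, numeric(1))
  counts <- table(cut(pvals, seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  expect_true(all(pvals >= 0 & pvals <= 1))
})

test_that("model screen applies all criteria and reports violations", {
  expect_true(screen_model(1e-5, rho2 = 0.22, auc = 0.81,
                           prevalence = 0.385)$pass)
  r1 <- screen_model(1e-5, rho2 = 0.16, auc = 0.73, prevalence = 0.534)
  expect_false(r1$pass)
  expect_length(r1$reasons, 1)
  expect_match(r1$reasons, "rho2")
  r2 <- screen_model(1e-5, rho2 = 0.07, auc = 0.68)
  expect_false(r2$pass)
  expect_length(r2$reasons, 2)
  # boundary: 0.20 and 0.70 pass (inclusive operators)
  expect_true(screen_model(0.01, rho2 = 0.20, auc = 0.70)$pass)
  # prevalence bounds are strict
  expect_false(screen_model(0.01, rho2 = 0.3, auc = 0.8,
                            prevalence = 0.70)$pass)
})

test_that("gof report is internally consistent and cross-checks with pROC", {
  d <- make_dataset(n = 1200, beta = c(-3.2, 0.06, 0.025), seed = 41)
  fit <- fit_logistic(d)
  rep <- gof_report(fit, d)
  expect_equal(rep$chi2_stat, 2 * (fit$loglik_full - fit$loglik_null))
  expect_equal(rep$chi2_p,
               pchisq(rep$chi2_stat, df = 2, lower.tail = FALSE))
  skip_if_not_installed("pROC")
  scores <- predict_p(fit, d$cells$pfc, d$cells$rlps)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(d$cells$occurrence, scores,
                                             quiet = TRUE)))
  expect_equal(rep$auc, proc_auc, tolerance = 1e-10)
})
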