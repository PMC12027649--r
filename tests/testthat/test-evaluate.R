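# Logistic evaluation, AUC, DeLong, correlations, model selection.

test_that("logistic regression matches the hand-rolled Newton oracle", {
  set.seed(19)
  n <- 30
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  fit <- logistic_regression(y, x)
  oracle <- newton_logistic(y, x)
  expect_lt(max(abs(fit$coefficients$estimate - oracle$beta)), 1e-8)
  expect_lt(max(abs(fit$coefficients$se - oracle$se)), 1e-8)
  expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-8)
})

test_that("an antisymmetric toy gives a zero intercept", {
  # mirror symmetry (x, y) -> (-x, 1 - y) maps the data onto itself, so
  # the (finite) MLE intercept is exactly zero
  fit <- logistic_regression(c(0, 1, 0, 1), c(-2, -1, 1, 2))
  expect_lt(abs(fit$coefficients$estimate[1]), 1e-6)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(20)
  ps <- replicate(200, {
    y <- rbinom(200, 1, 0.5)
    x <- rnorm(200)
    fit <- logistic_regression(y, x)
    fit$coefficients$p[2]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("perfect separation is flagged but the AUC survives", {
  y <- rep(c(0, 1), each = 10)
  x <- c(rnorm(10, -4), rnorm(10, 4))
  suppressWarnings(expect_warning(fit <- logistic_regression(y, x),
                                  "separation"))
  expect_true(fit$separation)
  expect_equal(roc_auc(x, y), 1)
})

test_that("roc_auc equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(22)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(40), 1))  # ties likely
    expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with pROC", {
  set.seed(23)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150) + y
  ours <- delong_ci(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-10)
})

test_that("DeLong endpoints agree with a stratified bootstrap", {
  set.seed(24)
  y <- rep(c(0, 1), each = 100)
  s <- rnorm(200) + 0.8 * y
  dl <- delong_ci(s, y)
  boot <- boot_auc_ci(s, y, B = 2000, seed = 25)
  expect_lt(abs(dl$ci_low - boot[1]), 0.02)
  expect_lt(abs(dl$ci_high - boot[2]), 0.02)
})

test_that("DeLong degenerates and reflects correctly", {
  y <- rep(c(0, 1), each = 5)
  s <- c(1:5, 11:15)
  dl <- delong_ci(s, y)
  expect_equal(dl$auc, 1)
  expect_equal(dl$variance, 0)
  expect_equal(c(dl$ci_low, dl$ci_high), c(1, 1))
  # swapping labels maps AUC -> 1 - AUC and reflects the interval
  set.seed(26)
  y2 <- rbinom(80, 1, 0.5); s2 <- rnorm(80) + 0.5 * y2
  a <- delong_ci(s2, y2); b <- delong_ci(s2, 1 - y2)
  expect_equal(b$auc, 1 - a$auc, tolerance = 1e-12)
  expect_equal(b$ci_low, 1 - a$ci_high, tolerance = 1e-12)
  expect_equal(b$ci_high, 1 - a$ci_low, tolerance = 1e-12)
})

test_that("DeLong 95% CI covers the null AUC at nominal rate", {
  set.seed(27)
  cover <- 0
  for (i in 1:500) {
    y <- rep(c(0, 1), each = 100)
    s <- rnorm(200)
    dl <- delong_ci(s, y)
    cover <- cover + (dl$ci_low <= 0.5 && dl$ci_high >= 0.5)
  }
  expect_gte(cover / 500, 0.93)
  expect_lte(cover / 500, 0.97)
})

test_that("correlation matrix matches the covariance formula", {
  set.seed(28)
  v <- list(a = rnorm(30), b = rnorm(30))
  v$c <- -v$a
  r <- correlation_matrix(v)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "c"], -1, tolerance = 1e-12)
  manual <- sum((v$a - mean(v$a)) * (v$b - mean(v$b))) /
    sqrt(sum((v$a - mean(v$a))^2) * sum((v$b - mean(v$b))^2))
  expect_equal(r["a", "b"], manual, tolerance = 1e-12)
  v$z <- rep(1, 30)
  expect_warning(r2 <- correlation_matrix(v), "zero-variance")
  expect_true(is.na(r2["a", "z"]))
  expect_equal(r2["z", "z"], 1)
})

test_that("best-model selection honours significance before AUC", {
  res <- data.frame(method = c("MOA", "MOMENT"), threshold = c(0.01, 0.05),
                    n_probes = c(100L, 200L), AUC = c(0.62, 0.66),
                    p_mrs = c(0.01, 0.30), stringsAsFactors = FALSE)
  expect_equal(select_best_model(res)$AUC, 0.62)

  res_only_excluded <- data.frame(method = "MOA", threshold = c(1e-4, 1e-5),
                                  n_probes = c(5L, 2L), AUC = c(0.7, 0.8),
                                  p_mrs = c(0.01, 0.01))
  expect_error(select_best_model(res_only_excluded), "all models excluded")

  res_ns <- data.frame(method = c("MOA", "MOA"), threshold = c(0.01, 0.1),
                       n_probes = c(10L, 50L), AUC = c(0.51, 0.58),
                       p_mrs = c(0.4, 0.6))
  expect_equal(select_best_model(res_ns)$AUC, 0.58)

  # ties: fewer probes, then method name
  res_tie <- data.frame(method = c("MOMENT", "MOA"), threshold = c(0.1, 0.1),
                        n_probes = c(50L, 50L), AUC = c(0.6, 0.6),
                        p_mrs = c(0.01, 0.01))
  expect_equal(select_best_model(res_tie)$method, "MOA")
})

test_that("nested logistic deviances are monotone in-sample", {
  set.seed(29)
  n <- 120
  mrs <- rnorm(n); prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * mrs + 0.4 * prs))
  d_mrs <- logistic_regression(y, data.frame(MRS = mrs))$deviance
  d_prs <- logistic_regression(y, data.frame(PRS = prs))$deviance
  d_both <- logistic_regression(y, data.frame(MRS = mrs, PRS = prs))$deviance
  expect_lte(d_both, min(d_mrs, d_prs) + 1e-8)
})
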