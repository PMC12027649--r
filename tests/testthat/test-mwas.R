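# Association scans: OLS baseline, MOA, MOMENT, thresholds.

scan_fixture <- function(n = 300, m = 400, seed = 11, share = 0.5) {
  sim <- simulate_orm_phenotype(n, m, share, seed = seed)
  Z <- standardize_probes(sim$beta)
  list(Z = Z, y = sim$y, X = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
       orm = compute_relationship_matrix(Z, "ORM"),
       ann = random_annotation(colnames(Z), seed = seed))
}

test_that("a probe equal to the centred phenotype is a perfect predictor", {
  set.seed(2)
  n <- 100
  y <- rnorm(n)
  z <- (y - mean(y)) / sqrt(sum((y - mean(y))^2) / n)
  Z <- cbind(matrix(rnorm(n * 5), n, 5), z)
  colnames(Z) <- paste0("p", 1:6); rownames(Z) <- paste0("s", 1:n)
  Z <- standardize_probes(Z)
  res <- ols_scan(Z, y, matrix(1, n, 1))
  expect_lt(res$p[6], 1e-10)
  expect_equal(res$effect[6], sqrt(sum((y - mean(y))^2) / n), tolerance = 1e-8)
})

test_that("OLS coefficients match the dense normal-equations oracle", {
  set.seed(14)
  n <- 50
  X <- cbind(1, matrix(rnorm(n * 4), n, 4))
  colnames(X) <- c("intercept", paste0("c", 1:3), "c4")
  Z <- standardize_probes(matrix(rnorm(n * 20), n, 20,
                                 dimnames = list(NULL, paste0("p", 1:20))))
  y <- rnorm(n)
  res <- ols_scan(Z, y, X)
  for (j in c(1, 7, 20)) {
    M <- cbind(X, Z[, j])
    bj <- solve(crossprod(M), crossprod(M, y))[ncol(M)]
    expect_equal(res$effect[j], unname(bj), tolerance = 1e-10)
  }
  # Wald contract: p equals the two-sided normal tail of effect/se
  expect_equal(res$p, 2 * pnorm(-abs(res$effect / res$se)), tolerance = 1e-10)
})

test_that("MOA with the methylome variance forced to zero equals OLS", {
  fx <- scan_fixture(n = 150, m = 200, seed = 21)
  qrX <- qr(fx$X)
  s0 <- sum(qr.resid(qrX, fx$y)^2) / (150 - 1)
  moa <- moa_scan(fx$Z, fx$y, fx$X, fx$orm, variances = c(0, s0))
  ols <- ols_scan(fx$Z, fx$y, fx$X)
  expect_lt(max(abs(moa$p - ols$p)), 1e-8)
  expect_lt(max(abs(moa$effect - ols$effect)), 1e-10)
})

test_that("MOA deflates polygenic inflation that OLS carries", {
  fx <- scan_fixture(n = 500, m = 2000, seed = 201, share = 0.8)
  ols <- ols_scan(fx$Z, fx$y, fx$X)
  moa <- moa_scan(fx$Z, fx$y, fx$X, fx$orm)
  expect_gt(inflation_factor(ols$p), 1.2)
  lam <- inflation_factor(moa$p)
  expect_gte(lam, 0.9); expect_lte(lam, 1.1)
  expect_equal(moa$p, 2 * pnorm(-abs(moa$effect / moa$se)), tolerance = 1e-10)
})

test_that("a planted 5%-variance probe tops the MOA scan in >= 18/20 seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 600; m <- 400
    beta <- make_probe_fixture(n, m, seed = 300 + s, noise_sd = 0.1)
    Z <- standardize_probes(beta)
    y <- sqrt(0.05) * Z[, 7] + rnorm(n, 0, sqrt(0.95))
    orm <- compute_relationship_matrix(Z, "ORM")
    moa <- moa_scan(Z, y, matrix(1, n, 1), orm)
    hits <- hits + (which.min(moa$p) == 7)
  }
  expect_gte(hits, 18)
})

test_that("the 50 kb exclusion window is fully closed on the same chromosome", {
  ann <- data.frame(probe_id = c("target", "near", "far", "other_chr"),
                    chrom = c("1", "1", "1", "2"),
                    pos = c(100000L, 149999L, 150001L, 100000L),
                    stringsAsFactors = FALSE)
  excl <- moment_exclusion_set(ann, "target", half_width = 50000)
  expect_setequal(excl, c("target", "near"))
})

test_that("with an empty strong group MOMENT degenerates to MOA", {
  fx <- scan_fixture(n = 150, m = 200, seed = 23, share = 0)
  moa <- moa_scan(fx$Z, fx$y, fx$X, fx$orm, fx$ann)
  mm <- moment_scan(fx$Z, fx$y, fx$X, fx$ann, group1_threshold = 1e-300)
  expect_true(mm$grouping$degenerate)
  expect_lt(max(abs(mm$assoc$p - moa$p)), 1e-8)
  expect_lt(max(abs(mm$assoc$effect - moa$effect)), 1e-8)
  expect_equal(unique(mm$grouping$groups$group), 2L)
})

test_that("MOMENT effects track MOA on a polygenic cohort", {
  fx <- scan_fixture(n = 300, m = 600, seed = 25, share = 0.5)
  moa <- moa_scan(fx$Z, fx$y, fx$X, fx$orm, fx$ann)
  mm <- moment_scan(fx$Z, fx$y, fx$X, fx$ann, group1_threshold = 0.01)
  expect_gt(cor(mm$assoc$effect, moa$effect), 0.9)
  # grouping partitions the probe set
  expect_setequal(mm$grouping$groups$probe_id, colnames(fx$Z))
  expect_true(all(mm$grouping$groups$group %in% 1:2))
  expect_equal(mm$assoc$p, 2 * pnorm(-abs(mm$assoc$effect / mm$assoc$se)),
               tolerance = 1e-10)
})

test_that("scans are deterministic given identical inputs", {
  fx <- scan_fixture(n = 120, m = 150, seed = 27)
  expect_identical(moa_scan(fx$Z, fx$y, fx$X, fx$orm),
                   moa_scan(fx$Z, fx$y, fx$X, fx$orm))
  expect_identical(moment_scan(fx$Z, fx$y, fx$X, fx$ann, group1_threshold = 0.01),
                   moment_scan(fx$Z, fx$y, fx$X, fx$ann, group1_threshold = 0.01))
})

test_that("bonferroni_threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(762651, 0.05), 3), 6.56e-8)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 0.0025)
  expect_error(bonferroni_threshold(0, 0.05))
  expect_error(bonferroni_threshold(10, 1))
})
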