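# m-values, standardization, PCA, covariate screening, surrogate variables.

test_that("beta_to_m is the base-2 logit with clipping and antisymmetry", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)  # log2(0.8/0.2)
  b <- c(0.1, 0.3, 0.42, 0.77)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  expect_warning(m1 <- beta_to_m(c(0, 1)), "clipped")
  expect_true(all(is.finite(m1)))
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(grid)) > 0))
})

test_that("standardize_probes gives mean 0, population variance 1, idempotence", {
  x <- matrix(c(0.2, 0.4, 0.6), 3, 1, dimnames = list(NULL, "p1"))
  z <- standardize_probes(x)
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  z2 <- standardize_probes(z)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-12)

  beta <- make_probe_fixture(20, 10, seed = 1)
  zz <- standardize_probes(beta)
  expect_equal(unname(colMeans(zz)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(colSums(zz^2) / nrow(zz)), rep(1, 10), tolerance = 1e-12)

  beta_const <- cbind(beta, const = rep(0.5, 20))
  expect_warning(zc <- standardize_probes(beta_const), "zero-variance")
  expect_equal(attr(zc, "dropped"), "const")
  expect_error(standardize_probes(matrix(0.5, 5, 3,
                                         dimnames = list(NULL, letters[1:3]))),
               "zero variance")
})

test_that("pca_scores matches a dense covariance eigendecomposition", {
  set.seed(4)
  x <- matrix(rnorm(200), 10, 20)
  k <- 5
  res <- pca_scores(x, k)
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(crossprod(xc), symmetric = TRUE)
  oracle_scores <- xc %*% eg$vectors[, 1:k]
  for (j in 1:k)  # agreement up to sign
    expect_lt(min(max(abs(res$scores[, j] - oracle_scores[, j])),
                  max(abs(res$scores[, j] + oracle_scores[, j]))), 1e-8)
  expect_true(all(diff(res$var_frac) <= 1e-12))
  expect_lt(max(abs(crossprod(res$scores)[upper.tri(diag(k))])), 1e-8)
  # deterministic sign convention
  res2 <- pca_scores(x, k)
  expect_identical(res$scores, res2$scores)
  for (j in 1:k) {
    nz <- which(abs(res$loadings[, j]) > 1e-12)[1]
    expect_gt(res$loadings[nz, j], 0)
  }
})

test_that("rank-1 matrix puts all variance on PC1", {
  u <- rnorm(12); v <- rnorm(6)
  x <- outer(u, v)
  res <- suppressWarnings(pca_scores(x, 3))
  expect_equal(res$var_frac[1], 1, tolerance = 1e-12)
  expect_true(all(res$zero_variance >= 2))
})

test_that("covariate screen picks the right test per covariate type", {
  # 2x2 with expected cells < 5 -> Fisher, p = 1/3 by direct enumeration
  samples <- data.frame(sample_id = paste0("s", 1:4), status = c(0, 0, 1, 1),
                        grp = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(8), 4, 2)
  rep1 <- covariate_screen(samples, pcs, covariates = "grp")
  expect_equal(rep1$status_tests$test, "fisher")
  expect_equal(rep1$status_tests$p, 1 / 3, tolerance = 1e-12)

  # identical age values in the two groups -> t = 0, p = 1
  samples2 <- data.frame(sample_id = paste0("s", 1:8),
                         status = rep(c(0, 1), each = 4),
                         age = rep(c(30, 35, 40, 45), 2))
  rep2 <- covariate_screen(samples2, matrix(rnorm(16), 8, 2),
                           covariates = "age")
  expect_equal(rep2$status_tests$statistic, 0)
  expect_equal(rep2$status_tests$p, 1)

  # perfectly balanced 2x3 table with big cells -> chi-squared 0, p = 1
  samples3 <- data.frame(sample_id = paste0("s", 1:60),
                         status = rep(c(0, 1), each = 30),
                         grp = rep(rep(c("A", "B", "C"), each = 10), 2))
  rep3 <- covariate_screen(samples3, matrix(rnorm(120), 60, 2),
                           covariates = "grp")
  expect_equal(rep3$status_tests$test, "chisq")
  expect_equal(rep3$status_tests$statistic, 0)
  expect_equal(rep3$status_tests$p, 1)

  # single-level covariate is skipped with a note
  samples3$one <- "x"
  expect_message(rep4 <- covariate_screen(samples3, matrix(rnorm(120), 60, 2),
                                          covariates = c("grp", "one")),
                 "single level")
  expect_equal(nrow(rep4$status_tests), 1)
  # PC tests present and in (0, 1]
  expect_true(all(rep4$pc_tests$p > 0 & rep4$pc_tests$p <= 1))
})

test_that("surrogate variables recover a planted batch factor", {
  set.seed(5)
  n <- 120; p <- 800
  status <- rep(0:1, each = n / 2)
  batch <- rep(c(0, 1), times = n / 2)
  beta <- make_probe_fixture(n, p, seed = 5, noise_sd = 0.04)
  beta <- pmin(pmax(beta + outer(batch, rnorm(p, 0, 0.05)), 1e-3), 1 - 1e-3)
  sv <- estimate_svs(beta_to_m(beta), status, seed = 2)
  expect_gte(sv$q, 1)
  expect_gt(abs(cor(sv$sv[, 1], batch)), 0.9)
  # construction invariants: zero mean, unit norm, orthogonal
  expect_equal(unname(colMeans(sv$sv)), rep(0, sv$q), tolerance = 1e-8)
  expect_equal(unname(colSums(sv$sv^2)), rep(1, sv$q), tolerance = 1e-8)
  if (sv$q > 1)
    expect_lt(max(abs(crossprod(sv$sv)[upper.tri(diag(sv$q))])), 1e-8)
})

test_that("pure-noise residuals yield at most a couple of SVs", {
  set.seed(9)
  n <- 100; p <- 1000
  status <- rep(0:1, each = n / 2)
  beta <- make_probe_fixture(n, p, seed = 9, noise_sd = 0.04)
  sv <- suppressMessages(estimate_svs(beta_to_m(beta), status, seed = 3))
  expect_lte(sv$q, 2)
})

test_that("residualize is idempotent and zeroes SV-aligned columns", {
  set.seed(6)
  n <- 50
  sv_mat <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  svs <- structure(list(sv = sv_mat, q = 2L), class = "surrogate_variables")
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 3] <- sv_mat[, 1]
  adj <- residualize(x, svs)
  expect_lt(max(abs(adj[, 3])), 1e-10)
  expect_lt(max(abs(residualize(adj, svs) - adj)), 1e-10)
  expect_lt(max(abs(cor(adj[, -3], sv_mat))), 1e-8)
  # empty SV set: plain column centering
  empty <- structure(list(sv = matrix(numeric(0), n, 0), q = 0L),
                     class = "surrogate_variables")
  expect_equal(residualize(x, empty), sweep(x, 2, colMeans(x)))
})
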