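# Cohort generator: parameter validation, determinism, planted structure.

test_that("parameter validation rejects inconsistent settings", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(case_fraction = 1.2), "case_fraction")
  expect_error(sim_params(beta_shift_range = c(0.1, 0.6)), "beta_shift_range")
  expect_error(sim_params(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(sim_params(n_probes = 50, n_differential_probes = 40,
                          n_mqtl_probes = 20), "exceeds")
  expect_error(sim_params(h2_snp_liability = 1.3), "h2_snp_liability")
  expect_error(sim_params(var_meth_nongenetic = 0, n_differential_probes = 10),
               "variance shares")
})

test_that("null generator yields uniform per-probe t-test p-values", {
  params <- sim_params(n_samples = 300, n_probes = 2000, n_variants = 100,
                       n_differential_probes = 0, n_mqtl_probes = 0,
                       batch_effect_sd = 0, seed = 11)
  cohort <- simulate_cohort(params)
  y <- cohort$samples$status
  beta <- cohort$meth$beta
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(beta[y == 1, ]); m0 <- colMeans(beta[y == 0, ])
  v1 <- apply(beta[y == 1, ], 2, var); v0 <- apply(beta[y == 0, ], 2, var)
  tstat <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  df <- (v1 / n1 + v0 / n0)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("case counts and status variance match the design fraction", {
  cohort <- simulate_cohort(sim_params(n_samples = 908, n_probes = 50,
                                       n_variants = 100,
                                       n_differential_probes = 5,
                                       n_mqtl_probes = 5, seed = 3))
  n_cases <- sum(cohort$samples$status)
  expect_gte(n_cases, qbinom(0.005, 908, 0.65))
  expect_lte(n_cases, qbinom(0.995, 908, 0.65))
  expect_equal(var(cohort$samples$status), 0.65 * 0.35, tolerance = 0.02 / 0.2275)
})

test_that("identical params and seed give identical cohorts; seeds differ", {
  p <- sim_params(n_samples = 60, n_probes = 40, n_variants = 30, seed = 1,
                  n_differential_probes = 5, n_mqtl_probes = 5)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1, c2)
  p2 <- p; p2$seed <- 2L
  c3 <- simulate_cohort(p2)
  expect_false(identical(c1$meth$beta, c3$meth$beta))
  expect_false(identical(c1$geno$dosage, c3$geno$dosage))
})

test_that("emitted matrices satisfy the generator invariants", {
  params <- sim_params(n_samples = 900, n_probes = 400, n_variants = 200,
                       seed = 7)
  cohort <- simulate_cohort(params)
  beta <- cohort$meth$beta
  expect_true(all(beta >= 0.001 & beta <= 0.999))
  expect_true(all(cohort$geno$dosage %in% 0:2))
  af <- colMeans(cohort$geno$dosage) / 2
  expect_true(all(pmin(af, 1 - af) >= 0.03))
  # truth bookkeeping: ids exist, shifts inside the declared range
  tr <- cohort$truth
  expect_true(all(tr$differential_probes$probe_id %in% colnames(beta)))
  expect_true(all(tr$mqtl_map$probe_id %in% colnames(beta)))
  expect_true(all(tr$mqtl_map$variant_id %in% colnames(cohort$geno$dosage)))
  expect_true(all(tr$differential_probes$shift >= params$beta_shift_range[1] &
                    tr$differential_probes$shift <= params$beta_shift_range[2]))
  # observed case-control difference close to the recorded shift
  y <- cohort$samples$status
  obs <- colMeans(beta[y == 1, tr$differential_probes$probe_id]) -
    colMeans(beta[y == 0, tr$differential_probes$probe_id])
  expect_true(all(abs(obs - tr$differential_probes$shift) < 0.02))
})

test_that("zero-noise PRS weights recover the genetic liability exactly", {
  cohort <- simulate_cohort(sim_params(n_samples = 500, n_probes = 20,
                                       n_variants = 2000,
                                       n_differential_probes = 2,
                                       n_mqtl_probes = 2, seed = 5))
  w0 <- simulate_prs_weights(cohort$geno, cohort$truth, noise_sd = 0, seed = 9)
  prs <- compute_prs(w0, cohort$geno)
  expect_equal(cor(prs$score, cohort$truth$genetic_liability), 1,
               tolerance = 1e-12)
  # infinite-noise limit: correlation with liability washes out
  wbig <- simulate_prs_weights(cohort$geno, cohort$truth, noise_sd = 1e4,
                               seed = 9)
  prs_big <- compute_prs(wbig, cohort$geno)
  expect_lt(abs(cor(prs_big$score, cohort$truth$liability)), 0.1)
})

test_that("PRS weight files round-trip unchanged", {
  cohort <- simulate_cohort(sim_params(n_samples = 40, n_probes = 10,
                                       n_variants = 50,
                                       n_differential_probes = 1,
                                       n_mqtl_probes = 1, seed = 2))
  w <- simulate_prs_weights(cohort$geno, cohort$truth, noise_sd = 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_weights(w, path)
  w2 <- read_score_weights(path)
  expect_equal(w2$feature_id, w$feature_id)
  expect_equal(w2$effect_allele, w$effect_allele)
  expect_equal(w2$weight, w$weight, tolerance = 1e-12)
})

test_that("a non-heritable trait gives an uninformative zero-noise PRS", {
  cohort <- simulate_cohort(sim_params(n_samples = 400, n_probes = 20,
                                       n_variants = 300,
                                       n_differential_probes = 2,
                                       n_mqtl_probes = 2,
                                       h2_snp_liability = 0, seed = 6))
  w0 <- simulate_prs_weights(cohort$geno, cohort$truth, noise_sd = 0, seed = 1)
  prs <- compute_prs(w0, cohort$geno)
  auc <- roc_auc(prs$score, cohort$samples$status)
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)
})

test_that("known-share phenotype simulator hits its variance target", {
  sim <- simulate_orm_phenotype(200, 500, 0.5, seed = 12)
  expect_equal(sim$realized_share, 0.5, tolerance = 0.1)
  expect_true(all(sim$beta >= 0.001 & sim$beta <= 0.999))
  sim0 <- simulate_orm_phenotype(200, 500, 0, seed = 12)
  expect_equal(sim0$realized_share, 0)
})
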