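# Synthetic cohort generator.
#
# Emulates the structure of a multi-institution endometrial methylation
# case-control study: ~900 samples from four recruiting institutions, a
# case fraction of about 0.65, case-control beta differences in the
# 0.03-0.08 range, mQTL-coupled probes, per-institution batch offsets, and
# common-variant dosages driving a liability-threshold disease model. All
# planted parameters are recorded so downstream recovery tests can compare
# estimates against ground truth.

#' Simulation parameters for a synthetic cohort
#'
#' Constructs and validates the parameter set consumed by
#' [simulate_cohort()]. Defaults mirror the structure of the study design
#' the package targets: 908 samples across four institutions with sampling
#' proportions 9/33/17/41%, case fraction 0.65, planted case-control beta
#' shifts drawn from \[0.03, 0.08\], and variants with MAF in \[0.05, 0.5\].
#'
#' @param n_samples number of samples.
#' @param n_probes number of methylation probes.
#' @param n_variants number of common variants.
#' @param case_fraction expected fraction of cases (liability-threshold cut).
#' @param institutions named numeric vector of institution sampling
#'   proportions (must sum to 1).
#' @param h2_snp_liability proportion of liability variance explained by the
#'   variants.
#' @param var_meth_nongenetic fraction of the disease-linked methylation
#'   factor's variance attributable to case-control status; at 1 the factor
#'   is exactly the 0/1 status.
#' @param n_differential_probes number of probes given a case-control mean
#'   beta shift.
#' @param beta_shift_range interval the true shifts are drawn from.
#' @param n_mqtl_probes number of probes coupled to a variant's dosage.
#' @param mqtl_effect_sd sd (beta scale per dosage unit) of mQTL effects.
#' @param batch_effect_sd sd of per-institution, per-probe beta offsets.
#' @param probe_noise_sd sd of i.i.d. per-sample beta noise.
#' @param maf_range interval variant minor-allele frequencies are drawn from.
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical cohorts.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 908L,
                       n_probes = 2000L,
                       n_variants = 1000L,
                       case_fraction = 0.65,
                       institutions = c(CIR = 0.09, IMB = 0.33,
                                        Oxford = 0.17, UCSF = 0.41),
                       h2_snp_liability = 0.25,
                       var_meth_nongenetic = 0.8,
                       n_differential_probes = 50L,
                       beta_shift_range = c(0.03, 0.08),
                       n_mqtl_probes = 50L,
                       mqtl_effect_sd = 0.02,
                       batch_effect_sd = 0.01,
                       probe_noise_sd = 0.08,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  .assert(.is_count(n_samples) && n_samples >= 2, "n_samples must be a count >= 2")
  .assert(.is_count(n_probes) && n_probes >= 1, "n_probes must be a positive count")
  .assert(.is_count(n_variants) && n_variants >= 1, "n_variants must be a positive count")
  .assert(.is_prop(case_fraction), "case_fraction must be in [0,1]")
  .assert(length(institutions) >= 1 && all(institutions >= 0) &&
            abs(sum(institutions) - 1) < 1e-8 && !is.null(names(institutions)),
          "institutions must be a named vector of proportions summing to 1")
  .assert(.is_prop(h2_snp_liability), "h2_snp_liability must be in [0,1]")
  .assert(.is_prop(var_meth_nongenetic), "var_meth_nongenetic must be in [0,1]")
  .assert(h2_snp_liability <= 1 && var_meth_nongenetic <= 1,
          "variance shares exceed 1")
  .assert(.is_count(n_differential_probes), "n_differential_probes must be a count")
  .assert(.is_count(n_mqtl_probes), "n_mqtl_probes must be a count")
  .assert(n_differential_probes + n_mqtl_probes <= n_probes,
          "n_differential_probes + n_mqtl_probes exceeds n_probes")
  .assert(length(beta_shift_range) == 2 && all(beta_shift_range >= 0) &&
            all(beta_shift_range <= 0.5) && diff(beta_shift_range) >= 0,
          "beta_shift_range must be an interval within [0, 0.5]")
  .assert(length(maf_range) == 2 && maf_range[1] >= 0.05 && maf_range[2] <= 0.5 &&
            diff(maf_range) >= 0, "maf_range must be an interval within [0.05, 0.5]")
  .assert(mqtl_effect_sd >= 0 && batch_effect_sd >= 0 && probe_noise_sd >= 0,
          "sd parameters must be non-negative")
  .assert(.is_count(abs(seed)), "seed must be an integer")
  if (n_differential_probes > 0 && var_meth_nongenetic == 0)
    stop("var_meth_nongenetic = 0 leaves no status share for the planted ",
         "differential signal; variance shares inconsistent", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_variants = as.integer(n_variants), case_fraction = case_fraction,
    institutions = institutions, h2_snp_liability = h2_snp_liability,
    var_meth_nongenetic = var_meth_nongenetic,
    n_differential_probes = as.integer(n_differential_probes),
    beta_shift_range = beta_shift_range,
    n_mqtl_probes = as.integer(n_mqtl_probes),
    mqtl_effect_sd = mqtl_effect_sd, batch_effect_sd = batch_effect_sd,
    probe_noise_sd = probe_noise_sd, maf_range = maf_range,
    seed = as.integer(seed)), class = "sim_params")
}

#' Simulate a multi-institution methylation + genotype cohort
#'
#' Draws dosages per variant from Binomial(2, MAF), builds a liability from
#' variant effects plus Gaussian noise (variant share =
#' `h2_snp_liability`), thresholds it at the `1 - case_fraction` empirical
#' quantile to set case-control status, and then layers methylation signal:
#' differential probes receive a mean beta shift for cases through a
#' non-genetic disease factor, mQTL probes receive dosage-proportional
#' shifts, and every probe receives institution offsets and i.i.d. noise.
#' Betas are clipped to \[0.001, 0.999\] so the m-value transform stays
#' finite.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `mrs_cohort` with elements `meth`
#'   ([meth_matrix()]), `geno` ([geno_matrix()]), `samples` (sample table
#'   data frame) and `truth` (recorded ground-truth parameters).
#' @export
simulate_cohort <- function(params) {
  .assert(inherits(params, "sim_params"), "params must be a sim_params object")
  set.seed(params$seed)
  n <- params$n_samples; p <- params$n_probes; m <- params$n_variants

  sample_ids <- sprintf("S%04d", seq_len(n))
  probe_ids <- sprintf("cg%06d", seq_len(p))
  variant_ids <- sprintf("var%06d", seq_len(m))

  institution <- sample(names(params$institutions), n, replace = TRUE,
                        prob = params$institutions)

  # genotypes ------------------------------------------------------------
  maf <- runif(m, params$maf_range[1], params$maf_range[2])
  dosage <- vapply(seq_len(m), function(j) rbinom(n, 2L, maf[j]), numeric(n))
  dimnames(dosage) <- list(sample_ids, variant_ids)
  # alt drawn from non-complementary bases so weights are never
  # strand-ambiguous (A/T, C/G pairs are avoided by construction)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), c(r, comp[[r]])), 1L), character(1))
  alleles <- cbind(ref, unname(alt))

  # liability-threshold disease model ------------------------------------
  h2 <- params$h2_snp_liability
  b_raw <- rnorm(m)
  g_raw <- drop(dosage %*% b_raw)
  if (h2 > 0 && var(g_raw) > 0) {
    s <- sqrt(h2 / var(g_raw))
    w_true <- b_raw * s
    g <- g_raw * s
  } else {
    w_true <- numeric(m)
    g <- numeric(n)
  }
  liability <- g + rnorm(n, 0, sqrt(max(1 - h2, 0)))
  status <- as.integer(liability > quantile(liability, 1 - params$case_fraction))

  # methylation ----------------------------------------------------------
  mu <- runif(p, 0.1, 0.9)
  beta <- matrix(rep(mu, each = n), n, p) +
    matrix(rnorm(n * p, 0, params$probe_noise_sd), n, p)

  idx <- sample.int(p)
  diff_idx <- if (params$n_differential_probes > 0)
    sort(idx[seq_len(params$n_differential_probes)]) else integer(0)
  mqtl_idx <- if (params$n_mqtl_probes > 0)
    sort(idx[params$n_differential_probes + seq_len(params$n_mqtl_probes)]) else integer(0)

  v <- params$var_meth_nongenetic
  shifts <- numeric(0)
  if (length(diff_idx)) {
    # mid-range baselines keep the planted shift clear of the [0,1]
    # clipping bounds, so the case-control difference is fully expressed
    mu_diff <- runif(length(diff_idx), 0.15, 0.70)
    beta[, diff_idx] <- beta[, diff_idx] +
      rep(mu_diff - mu[diff_idx], each = n)
    mu[diff_idx] <- mu_diff
    shifts <- runif(length(diff_idx), params$beta_shift_range[1],
                    params$beta_shift_range[2])
    disease_factor <- status
    if (v < 1) {
      jitter_sd <- sqrt(max(var(status), 1e-12) * (1 - v) / v)
      disease_factor <- status + rnorm(n, 0, jitter_sd)
    }
    beta[, diff_idx] <- beta[, diff_idx] + outer(disease_factor, shifts)
  }

  mqtl_var <- integer(0); mqtl_eff <- numeric(0)
  if (length(mqtl_idx)) {
    mqtl_var <- sample.int(m, length(mqtl_idx), replace = length(mqtl_idx) > m)
    mqtl_eff <- rnorm(length(mqtl_idx), 0, params$mqtl_effect_sd)
    for (k in seq_along(mqtl_idx)) {
      d <- dosage[, mqtl_var[k]]
      beta[, mqtl_idx[k]] <- beta[, mqtl_idx[k]] + mqtl_eff[k] * (d - mean(d))
    }
  }

  batch <- matrix(rnorm(length(params$institutions) * p, 0, params$batch_effect_sd),
                  length(params$institutions), p,
                  dimnames = list(names(params$institutions), NULL))
  beta <- beta + batch[institution, , drop = FALSE]
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sample_ids, probe_ids)

  annotation <- data.frame(
    probe_id = probe_ids,
    chrom = sample(as.character(1:22), p, replace = TRUE),
    pos = sample.int(2.8e8, p, replace = TRUE),
    gene = NA_character_, stringsAsFactors = FALSE)

  # sample covariates -----------------------------------------------------
  # cases younger by 2.8 years on average; cycle phase and ancestry drawn
  # with study-like marginal proportions, independent of status
  age <- round(ifelse(status == 1, rnorm(n, 34.2, 7), rnorm(n, 37.0, 7)), 1)
  age <- pmin(pmax(age, 18), 55)
  phases <- c("proliferative", "secretory-undefined", "early-secretory",
              "mid-secretory", "late-secretory", "menstrual")
  cycle_phase <- sample(phases, n, replace = TRUE,
                        prob = c(0.483, 0.023, 0.123, 0.212, 0.109, 0.050))
  ancestries <- c("European", "African", "EastAsian", "American", "ADMIX",
                  "SouthAsian")
  ancestry <- sample(ancestries, n, replace = TRUE,
                     prob = c(0.687, 0.051, 0.079, 0.055, 0.080, 0.048))

  samples <- data.frame(sample_id = sample_ids, status = status, age = age,
                        institution = institution, cycle_phase = cycle_phase,
                        ancestry = ancestry, stringsAsFactors = FALSE)

  truth <- list(
    differential_probes = data.frame(
      probe_id = probe_ids[diff_idx],
      shift = if (length(diff_idx)) shifts else numeric(0),
      stringsAsFactors = FALSE),
    mqtl_map = data.frame(
      variant_id = variant_ids[mqtl_var],
      probe_id = probe_ids[mqtl_idx],
      effect = mqtl_eff, stringsAsFactors = FALSE),
    variant_weights = data.frame(
      feature_id = variant_ids,
      effect_allele = alleles[, 2],
      weight = w_true, stringsAsFactors = FALSE),
    batch_offsets = batch,
    liability = liability,
    genetic_liability = g)

  variants <- data.frame(variant_id = variant_ids,
                         chrom = sample(as.character(1:22), m, replace = TRUE),
                         pos = sample.int(2.8e8, m, replace = TRUE),
                         ref = alleles[, 1], alt = alleles[, 2],
                         stringsAsFactors = FALSE)

  structure(list(meth = meth_matrix(beta, annotation),
                 geno = geno_matrix(dosage, variants, maf_warn = FALSE),
                 samples = samples, truth = truth, params = params),
            class = "mrs_cohort")
}

#' @export
print.mrs_cohort <- function(x, ...) {
  cat(sprintf("mrs_cohort: %d samples (%d cases), %d probes, %d variants, %d institutions\n",
              nrow(x$samples), sum(x$samples$status == 1), ncol(x$meth$beta),
              ncol(x$geno$dosage), length(unique(x$samples$institution))))
  invisible(x)
}

#' Synthetic external variant weights for a polygenic score
#'
#' Produces allele-oriented variant weights by adding Gaussian noise to the
#' cohort's true liability effects, emulating an external GWAS-derived
#' weight file of variable quality. At `noise_sd = 0` a score built from
#' these weights equals the true genetic liability up to an affine
#' transform.
#'
#' @param geno a [geno_matrix()] (used for the variant catalogue).
#' @param truth the `truth` element of a simulated cohort.
#' @param noise_sd sd of the Gaussian noise added to each true weight.
#' @param seed integer seed.
#' @return an [effect_weights()] object with effect alleles.
#' @export
simulate_prs_weights <- function(geno, truth, noise_sd, seed = 1L) {
  .assert(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(as.integer(seed))
  tw <- truth$variant_weights
  .assert(all(tw$feature_id %in% geno$variants$variant_id),
          "truth weights refer to variants absent from the genotype matrix")
  effect_weights(data.frame(
    feature_id = tw$feature_id,
    effect_allele = tw$effect_allele,
    weight = tw$weight + rnorm(nrow(tw), 0, noise_sd),
    stringsAsFactors = FALSE), source = "external-synthetic")
}

#' Simulate a cohort with a known observed-scale methylation variance share
#'
#' Builds a probe matrix of independent betas and a continuous phenotype
#' `y = g + e` where `g` is a sum of planted per-probe effects scaled so the
#' methylation component carries `orm_share` of the phenotypic variance.
#' Used for REML parameter-recovery checks where the ground truth must be
#' on the observed scale of `y` itself.
#'
#' @param n,m samples and probes.
#' @param orm_share target proportion of var(y) carried by the probe signal.
#' @param seed integer seed.
#' @return list with `beta` (n x m beta matrix), `y`, and `realized_share`
#'   (the realized var(g)/var(y)).
#' @export
simulate_orm_phenotype <- function(n, m, orm_share, seed = 1L) {
  .assert(.is_prop(orm_share), "orm_share must be in [0,1]")
  set.seed(as.integer(seed))
  mu <- runif(m, 0.2, 0.8)
  beta <- matrix(rep(mu, each = n), n, m) + matrix(rnorm(n * m, 0, 0.05), n, m)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sprintf("S%04d", seq_len(n)), sprintf("cg%06d", seq_len(m)))
  Z <- scale(beta) * sqrt(n / (n - 1))  # population-sd standardization
  b <- rnorm(m)
  g <- drop(Z %*% b)
  if (orm_share > 0 && var(g) > 0) g <- g * sqrt(orm_share / var(g)) else g <- g * 0
  y <- g + rnorm(n, 0, sqrt(max(1 - orm_share, 1e-12)))
  list(beta = beta, y = y,
       realized_share = var(g) / var(y))
}
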