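# Leave-one-institution-out (LOIO) MRS development and evaluation.
#
# For each split one institution is the test set and the rest train. Scans
# (MOA, MOMENT) and BLUP run on training samples with training covariates;
# weights are built per method x threshold; MRS is computed on the test
# samples; PRS comes from an external (or synthetic) weight file; three
# logistic models (MRS, MRS+PRS, PRS) are evaluated per model spec with
# AUCs, DeLong CIs and Wald p-values. Genetic PCs are computed once on the
# full analysed cohort (a documented, deliberate leakage caveat matching
# standard practice); surrogate variables are estimated separately within
# training and test sets so no phenotype information crosses the split.

#' Pipeline configuration
#'
#' @param cohort an `mrs_cohort` (in-memory) or NULL to load from `paths`.
#' @param paths named list (beta, genotype, sample, annotation) of input
#'   files, used when `cohort` is NULL.
#' @param methods scan/weight methods to run, subset of MOA, MOMENT, BLUP.
#' @param thresholds p-value grid for probe selection (BLUP ignores it).
#' @param covariates sample-table columns used as training fixed effects.
#' @param n_genetic_pcs genetic PCs included as covariates (computed once
#'   on the full cohort).
#' @param sv_in_covariates include training surrogate variables as fixed
#'   covariates in the scans (default) ...
#' @param sv_preresidualize ... or instead residualize the training beta
#'   matrix on them before standardization.
#' @param mrs_standardize score MRS on train-standardized betas instead of
#'   raw betas.
#' @param prs_weights an [effect_weights()] object or weight-file path;
#'   NULL generates synthetic external weights from the cohort truth.
#' @param prs_noise_mult noise sd for synthetic PRS weights, as a multiple
#'   of the true-weight sd.
#' @param group1_threshold,share_cap,batch_frac,half_width MOMENT controls
#'   (see [moment_scan()]).
#' @param sv_nperm,sv_qmax surrogate-variable controls.
#' @param alpha family-wise error rate for the Bonferroni threshold report.
#' @param seed master seed; every random stage derives from it.
#' @return object of class `mrs_config`.
#' @export
mrs_config <- function(cohort = NULL, paths = NULL,
                       methods = c("MOA", "MOMENT", "BLUP"),
                       thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5),
                       covariates = c("age", "institution", "cycle_phase"),
                       n_genetic_pcs = 11L,
                       sv_in_covariates = TRUE,
                       sv_preresidualize = FALSE,
                       mrs_standardize = FALSE,
                       prs_weights = NULL,
                       prs_noise_mult = 1,
                       group1_threshold = NULL, share_cap = 0.5,
                       batch_frac = 0.1, half_width = 50000,
                       sv_nperm = 20L, sv_qmax = 10L,
                       alpha = 0.05, seed = 1L) {
  .assert(length(methods) >= 1 && all(methods %in% c("MOA", "MOMENT", "BLUP")),
          "methods must be a non-empty subset of MOA, MOMENT, BLUP")
  .assert(all(thresholds > 0 & thresholds <= 1), "thresholds must lie in (0,1]")
  structure(list(cohort = cohort, paths = paths, methods = methods,
                 thresholds = sort(thresholds), covariates = covariates,
                 n_genetic_pcs = as.integer(n_genetic_pcs),
                 sv_in_covariates = sv_in_covariates,
                 sv_preresidualize = sv_preresidualize,
                 mrs_standardize = mrs_standardize,
                 prs_weights = prs_weights, prs_noise_mult = prs_noise_mult,
                 group1_threshold = group1_threshold, share_cap = share_cap,
                 batch_frac = batch_frac, half_width = half_width,
                 sv_nperm = as.integer(sv_nperm), sv_qmax = as.integer(sv_qmax),
                 alpha = alpha, seed = as.integer(seed)),
            class = "mrs_config")
}

#' Leave-one-institution-out split plan
#'
#' One split per institution: that institution's samples form the test
#' set, all others train. Splits partition the analysed samples.
#'
#' @param samples sample table with `sample_id` and `institution`.
#' @return list of `split_plan` objects (label, train/test institutions and
#'   sample ids).
#' @export
make_loio_splits <- function(samples) {
  insts <- sort(unique(samples$institution))
  .assert(length(insts) >= 2, "need at least 2 institutions for LOIO splits")
  lapply(insts, function(inst) {
    test_ids <- samples$sample_id[samples$institution == inst]
    if (length(test_ids) < 10)
      warning("institution ", inst, " has fewer than 10 samples", call. = FALSE)
    structure(list(label = inst,
                   train_institutions = setdiff(insts, inst),
                   test_institution = inst,
                   train_ids = samples$sample_id[samples$institution != inst],
                   test_ids = test_ids), class = "split_plan")
  })
}

#' Build a full-rank covariate matrix
#'
#' Intercept, continuous covariates as-is, categorical covariates as
#' treatment indicators. Menstrual-phase subcategories with fewer than
#' `collapse_min` samples are collapsed into their parent phase
#' (proliferative/secretory); any remaining level below the minimum merges
#' into the largest level. Single-level factors are dropped, and aliased
#' indicator columns are removed (with a message) so the result has full
#' column rank.
#'
#' @param samples sample table rows for the modelled samples.
#' @param genetic_pcs optional n x k PC score matrix (same sample order).
#' @param svs optional surrogate variables (object or matrix).
#' @param include sample-table columns to use.
#' @param collapse_min minimum per-level count before collapsing.
#' @return numeric covariate matrix with intercept.
#' @export
build_covariate_matrix <- function(samples, genetic_pcs = NULL, svs = NULL,
                                   include = c("age", "institution",
                                               "cycle_phase"),
                                   collapse_min = 3L) {
  n <- nrow(samples)
  X <- matrix(1, n, 1, dimnames = list(samples$sample_id, "intercept"))
  for (cv in include) {
    x <- samples[[cv]]
    if (is.numeric(x)) {
      X <- cbind(X, x)
      colnames(X)[ncol(X)] <- cv
    } else {
      if (cv == "cycle_phase") x <- .collapse_phases(x, collapse_min)
      xf <- droplevels(factor(x))
      if (nlevels(xf) < 2) {
        message("covariate '", cv, "' single-valued; omitted")
        next
      }
      mm <- model.matrix(~xf)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, ".", levels(xf)[-1])
      X <- cbind(X, mm)
    }
  }
  X <- as.matrix(X)
  if (!is.null(genetic_pcs)) {
    gp <- as.matrix(genetic_pcs)
    colnames(gp) <- paste0("gPC", seq_len(ncol(gp)))
    X <- cbind(X, gp)
  }
  if (!is.null(svs)) {
    sv <- if (inherits(svs, "surrogate_variables")) svs$sv else svs
    if (!is.null(sv) && ncol(sv) > 0) X <- cbind(X, sv)
  }
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    message("dropping aliased covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  X
}

.collapse_phases <- function(x, collapse_min) {
  parents <- c("early-secretory" = "secretory", "mid-secretory" = "secretory",
               "late-secretory" = "secretory",
               "secretory-undefined" = "secretory",
               "early-proliferative" = "proliferative",
               "mid-proliferative" = "proliferative",
               "late-proliferative" = "proliferative")
  tab <- table(x)
  small <- names(tab)[tab < collapse_min]
  for (lev in small) {
    if (lev %in% names(parents)) x[x == lev] <- parents[lev]
  }
  tab <- table(x)
  small <- names(tab)[tab < collapse_min]
  if (length(small) > 0) {
    biggest <- names(which.max(table(x[!x %in% small])))
    x[x %in% small] <- biggest
  }
  x
}

.get_cohort <- function(config) {
  if (!is.null(config$cohort)) return(config$cohort)
  .assert(!is.null(config$paths), "config needs either a cohort or input paths")
  load_cohort(config$paths$beta, config$paths$genotype, config$paths$sample,
              config$paths$annotation)
}

.get_prs_weights <- function(config, cohort) {
  pw <- config$prs_weights
  if (is.null(pw)) {
    .assert(!is.null(cohort$truth),
            "synthetic PRS weights need a cohort with recorded truth")
    noise_sd <- config$prs_noise_mult * sd(cohort$truth$variant_weights$weight)
    return(simulate_prs_weights(cohort$geno, cohort$truth, noise_sd,
                                seed = config$seed))
  }
  if (is.character(pw)) return(read_score_weights(pw))
  pw
}

#' Subset a cohort to a set of sample ids
#' @param cohort cohort list with `meth`, `geno`, `samples`.
#' @param ids sample ids to keep (order preserved from the sample table).
#' @export
subset_cohort <- function(cohort, ids) {
  samples <- cohort$samples[cohort$samples$sample_id %in% ids, , drop = FALSE]
  ord <- samples$sample_id
  out <- cohort
  out$samples <- samples
  out$meth <- meth_matrix(cohort$meth$beta[ord, , drop = FALSE],
                          cohort$meth$annotation)
  out$geno <- geno_matrix(cohort$geno$dosage[ord, , drop = FALSE],
                          cohort$geno$variants, maf_warn = FALSE)
  out
}

#' Run the leave-one-institution-out MRS pipeline
#'
#' Executes the full experiment described in the package vignette: per
#' split, training-set surrogate variables, null REML, MOA/MOMENT scans
#' and BLUP effects with training covariates (age, institution, cycle
#' phase, genetic PCs, SVs), probe selection over the threshold grid, MRS
#' on the held-out institution, PRS from the external weight file, and the
#' three logistic classification models with AUC/DeLong/Wald statistics.
#' Fully deterministic given the config seed. Splits in which training or
#' test samples lack one of the classes are skipped with a warning.
#'
#' @param config an [mrs_config()].
#' @return list of class `mrs_pipeline_result`: `results` (long data
#'   frame), `best` (best MRS model per split), `effect_correlations` and
#'   `mrs_correlations` (per split), `splits`, `artifacts` (per-split scan
#'   and weight objects), `config`.
#' @export
run_mrs_pipeline <- function(config) {
  .assert(inherits(config, "mrs_config"), "config must be an mrs_config")
  set.seed(config$seed)
  cohort <- .get_cohort(config)
  known <- !is.na(cohort$samples$status)
  if (any(!known)) {
    message(sum(!known), " sample(s) with unknown status excluded")
    cohort <- subset_cohort(cohort, cohort$samples$sample_id[known])
  }
  samples <- cohort$samples
  prs_weights <- .get_prs_weights(config, cohort)

  # genetic PCs once on the full analysed cohort
  gpcs <- NULL
  if (config$n_genetic_pcs > 0) {
    Zg <- standardize_probes(cohort$geno$dosage)
    k <- min(config$n_genetic_pcs, nrow(Zg) - 1L, ncol(Zg))
    gpcs <- pca_scores(Zg, k)$scores
  }

  splits <- make_loio_splits(samples)
  rows <- list(); best <- list(); eff_cor <- list(); mrs_cor <- list()
  artifacts <- list()

  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    tr <- match(sp$train_ids, samples$sample_id)
    te <- match(sp$test_ids, samples$sample_id)
    y_tr <- samples$status[tr]
    y_te <- samples$status[te]
    if (length(unique(y_tr)) < 2 || length(unique(y_te)) < 2) {
      warning("split ", sp$label, " lacks a class in train or test; skipped",
              call. = FALSE)
      next
    }
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("pipeline failed at stage '%s' (split %s): %s",
                     what, sp$label, conditionMessage(e)), call. = FALSE))
    }

    beta_tr <- cohort$meth$beta[tr, , drop = FALSE]
    beta_te <- cohort$meth$beta[te, , drop = FALSE]

    svs_tr <- stage("sva-train",
                    estimate_svs(beta_to_m(beta_tr), y_tr, n_perm = config$sv_nperm,
                                 q_max = config$sv_qmax, seed = config$seed + si))
    # test-side SVs estimated for completeness/reporting; MRS itself uses
    # raw betas by default
    svs_te <- stage("sva-test",
                    estimate_svs(beta_to_m(beta_te), y_te, n_perm = config$sv_nperm,
                                 q_max = config$sv_qmax,
                                 seed = config$seed + 1000L + si))

    if (config$sv_preresidualize && svs_tr$q > 0)
      beta_tr <- residualize(beta_tr, svs_tr)
    Z_tr <- stage("standardize", standardize_probes(beta_tr))
    ann <- cohort$meth$annotation[cohort$meth$annotation$probe_id %in%
                                    colnames(Z_tr), , drop = FALSE]

    X_tr <- stage("covariates", build_covariate_matrix(
      samples[tr, , drop = FALSE],
      genetic_pcs = if (is.null(gpcs)) NULL else gpcs[tr, , drop = FALSE],
      svs = if (config$sv_in_covariates && !config$sv_preresidualize) svs_tr else NULL,
      include = config$covariates))

    orm_tr <- stage("orm", compute_relationship_matrix(Z_tr, "ORM"))
    est <- stage("null-reml",
                 fit_variance_components(y_tr, list(orm_tr), X_tr))

    scans <- list()
    if ("MOA" %in% config$methods)
      scans$MOA <- stage("moa", moa_scan(Z_tr, y_tr, X_tr, orm_tr, ann,
                                         variances = est$components$variance))
    moment_grouping <- NULL
    if ("MOMENT" %in% config$methods) {
      mres <- stage("moment", moment_scan(
        Z_tr, y_tr, X_tr, ann,
        group1_threshold = config$group1_threshold,
        share_cap = config$share_cap, batch_frac = config$batch_frac,
        half_width = config$half_width))
      scans$MOMENT <- mres$assoc
      moment_grouping <- mres$grouping
    }
    blup_w <- NULL
    if ("BLUP" %in% config$methods) {
      mmfit <- stage("blup-predict",
                     predict_individual_effects(y_tr, list(orm_tr), X_tr, est))
      blup_w <- stage("blup-probe", blup_probe_effects(mmfit, Z_tr))
    }

    # weight sets per model spec
    specs <- list()
    for (mth in intersect(c("MOA", "MOMENT"), config$methods)) {
      for (tau in config$thresholds) {
        w <- suppressWarnings(select_probes_by_threshold(scans[[mth]], tau))
        specs[[paste(mth, tau, sep = "_")]] <-
          list(method = mth, threshold = tau, weights = w)
      }
    }
    if ("BLUP" %in% config$methods)
      specs[["BLUP_all"]] <- list(method = "BLUP", threshold = NA_real_,
                                  weights = blup_w)

    prs <- stage("prs", compute_prs(prs_weights, subset_cohort(cohort, sp$test_ids)$geno))
    prs_fit <- logistic_regression(y_te, data.frame(PRS = prs$score))
    prs_auc <- delong_ci(prs$score, y_te)
    p_prs_only <- prs_fit$coefficients$p[prs_fit$coefficients$term == "PRS"]

    mrs_scores <- list()
    for (spec_name in names(specs)) {
      spec <- specs[[spec_name]]
      empty <- nrow(spec$weights) == 0
      na_row <- function(model) data.frame(
        test_set = sp$label, method = spec$method, threshold = spec$threshold,
        n_probes = 0L, model = model, AUC = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_mrs = NA_real_, p_prs = NA_real_,
        deviance = NA_real_, stringsAsFactors = FALSE)
      if (empty) {
        rows[[paste(sp$label, spec_name, "MRS")]] <- na_row("MRS")
        rows[[paste(sp$label, spec_name, "MRS+PRS")]] <- na_row("MRS+PRS")
        prs_row <- na_row("PRS")
        prs_row$n_probes <- attr(prs, "n_used")
        prs_row$AUC <- prs_auc$auc; prs_row$ci_low <- prs_auc$ci_low
        prs_row$ci_high <- prs_auc$ci_high; prs_row$p_prs <- p_prs_only
        prs_row$deviance <- prs_fit$deviance
        rows[[paste(sp$label, spec_name, "PRS")]] <- prs_row
        next
      }
      mrs <- stage("mrs", compute_mrs(
        spec$weights, beta_te, standardize = config$mrs_standardize,
        center = attr(Z_tr, "center"), scale = attr(Z_tr, "scale")))
      mrs_scores[[spec_name]] <- mrs$score
      n_used <- attr(mrs, "n_used")

      fit1 <- logistic_regression(y_te, data.frame(MRS = mrs$score))
      ci1 <- delong_ci(mrs$score, y_te)
      p_mrs1 <- fit1$coefficients$p[fit1$coefficients$term == "MRS"]
      rows[[paste(sp$label, spec_name, "MRS")]] <- data.frame(
        test_set = sp$label, method = spec$method, threshold = spec$threshold,
        n_probes = n_used, model = "MRS", AUC = ci1$auc, ci_low = ci1$ci_low,
        ci_high = ci1$ci_high, p_mrs = p_mrs1, p_prs = NA_real_,
        deviance = fit1$deviance, stringsAsFactors = FALSE)

      fit2 <- logistic_regression(y_te, data.frame(MRS = mrs$score,
                                                   PRS = prs$score))
      ci2 <- delong_ci(fit2$fitted, y_te)
      cf2 <- fit2$coefficients
      rows[[paste(sp$label, spec_name, "MRS+PRS")]] <- data.frame(
        test_set = sp$label, method = spec$method, threshold = spec$threshold,
        n_probes = n_used, model = "MRS+PRS", AUC = ci2$auc,
        ci_low = ci2$ci_low, ci_high = ci2$ci_high,
        p_mrs = cf2$p[cf2$term == "MRS"], p_prs = cf2$p[cf2$term == "PRS"],
        deviance = fit2$deviance, stringsAsFactors = FALSE)

      rows[[paste(sp$label, spec_name, "PRS")]] <- data.frame(
        test_set = sp$label, method = spec$method, threshold = spec$threshold,
        n_probes = attr(prs, "n_used"), model = "PRS", AUC = prs_auc$auc,
        ci_low = prs_auc$ci_low, ci_high = prs_auc$ci_high,
        p_mrs = NA_real_, p_prs = p_prs_only, deviance = prs_fit$deviance,
        stringsAsFactors = FALSE)
    }

    # cross-method effect-size and cross-model score correlations
    eff <- list()
    if (!is.null(scans$MOA)) eff$MOA <- scans$MOA$effect
    if (!is.null(scans$MOMENT)) eff$MOMENT <- scans$MOMENT$effect
    if (!is.null(blup_w)) eff$BLUP <- blup_w$weight[match(
      if (length(eff)) scans[[1]]$probe_id else blup_w$feature_id,
      blup_w$feature_id)]
    if (length(eff) >= 2) eff_cor[[sp$label]] <- correlation_matrix(eff)
    if (length(mrs_scores) >= 2)
      mrs_cor[[sp$label]] <- suppressWarnings(correlation_matrix(mrs_scores))

    split_rows <- do.call(rbind, rows[grep(paste0("^", sp$label, " "), names(rows))])
    mrs_rows <- split_rows[split_rows$model == "MRS" & !is.na(split_rows$AUC), ,
                           drop = FALSE]
    if (nrow(mrs_rows) > 0) {
      bm <- tryCatch(select_best_model(mrs_rows), error = function(e) NULL)
      if (!is.null(bm)) best[[sp$label]] <- bm
    }

    artifacts[[sp$label]] <- list(scans = scans, blup = blup_w,
                                  svs_train = svs_tr, svs_test = svs_te,
                                  reml = est, moment_grouping = moment_grouping,
                                  weights = lapply(specs, `[[`, "weights"))
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 best = if (length(best)) do.call(rbind, best) else NULL,
                 effect_correlations = eff_cor, mrs_correlations = mrs_cor,
                 splits = splits, artifacts = artifacts, config = config),
            class = "mrs_pipeline_result")
}

#' @export
print.mrs_pipeline_result <- function(x, ...) {
  cat(sprintf("LOIO MRS pipeline: %d splits, %d result rows\n",
              length(x$splits), nrow(x$results)))
  if (!is.null(x$best)) {
    cat("best MRS model per test set:\n")
    print(x$best[, c("test_set", "method", "threshold", "n_probes", "AUC",
                     "p_mrs")], row.names = FALSE)
  }
  invisible(x)
}

#' Re-run the pipeline restricted to one ancestry
#'
#' Filters the sample table to the given ancestry label and re-runs
#' [run_mrs_pipeline()]; output schema is identical. Splits that lose a
#' class are skipped with a warning (as in the main run).
#'
#' @param config an [mrs_config()].
#' @param ancestry ancestry label to keep.
#' @return an `mrs_pipeline_result`.
#' @export
ancestry_subset <- function(config, ancestry) {
  cohort <- .get_cohort(config)
  keep <- cohort$samples$ancestry == ancestry
  .assert(any(keep), "ancestry label '%s' absent from the cohort", ancestry)
  sub <- subset_cohort(cohort, cohort$samples$sample_id[keep])
  .assert(length(unique(sub$samples$institution)) >= 2,
          "fewer than 2 institutions remain after ancestry filtering")
  config$cohort <- sub
  config$paths <- NULL
  run_mrs_pipeline(config)
}
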