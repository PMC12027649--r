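# Per-probe association scans.
#
# All scans test the standardized probe as a fixed effect, so effects are
# per 1 SD of the probe. Reported p-values are two-sided normal (Wald)
# tails of effect/SE. The mixed scans use the P3D approximation: variance
# components are estimated once under the null model (no target fixed
# effect) and the covariance matrix is held fixed across per-probe GLS
# tests.

.scan_annotation <- function(probe_ids, annotation) {
  if (is.null(annotation))
    return(data.frame(chrom = NA_character_, pos = NA_integer_)[rep(1, length(probe_ids)), ])
  idx <- match(probe_ids, annotation$probe_id)
  data.frame(chrom = annotation$chrom[idx], pos = annotation$pos[idx])
}

.assoc_table <- function(probe_ids, b, se, method, annotation) {
  ann <- .scan_annotation(probe_ids, annotation)
  z <- b / se
  data.frame(probe_id = probe_ids, chrom = ann$chrom, pos = ann$pos,
             effect = b, se = se, p = 2 * pnorm(-abs(z)), method = method,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-probe ordinary least squares scan
#'
#' Regresses the phenotype on covariates plus each standardized probe in
#' turn. The Wald SE uses the covariate-only residual variance (the exact
#' `sigma2_u = 0` limit of the mixed-model scan), so OLS and mixed scans
#' share the same test convention; coefficients equal textbook OLS.
#'
#' @param std_probes standardized samples x probes matrix.
#' @param y phenotype vector.
#' @param covariates full-rank covariate matrix including intercept.
#' @param annotation optional probe annotation (probe_id, chrom, pos).
#' @return data frame of per-probe associations (probe_id, chrom, pos,
#'   effect, se, p, method).
#' @export
ols_scan <- function(std_probes, y, covariates, annotation = NULL) {
  X <- .check_covariates(as.matrix(covariates), length(y))
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RW <- qr.resid(qrX, std_probes)
  sigma2_0 <- sum(ry^2) / (length(y) - qrX$rank)
  ww <- colSums(RW^2)
  b <- drop(crossprod(RW, ry)) / ww
  se <- sqrt(sigma2_0 / ww)
  .assoc_table(colnames(std_probes), b, se, "OLS", annotation)
}

#' Mixed-linear-model omic association scan (single random component)
#'
#' Fits the null model `y = C beta + W u + e` once by REML (u captured
#' through the omics relationship matrix), then tests each standardized
#' probe as a fixed effect by GLS with the null covariance held fixed
#' (P3D). The target probe remains part of the genome-wide random term,
#' which costs a small, uniform shrinkage of large effects but keeps the
#' scan a single pass.
#'
#' @inheritParams ols_scan
#' @param orm the [relationship_matrix] built from the same standardized
#'   probes.
#' @param variances optional length-2 numeric `(sigma2_u, sigma2_e)`
#'   overriding the REML estimates (diagnostics, e.g. forcing
#'   `sigma2_u = 0` reproduces [ols_scan()]).
#' @return data frame of per-probe associations.
#' @export
moa_scan <- function(std_probes, y, covariates, orm, annotation = NULL,
                     variances = NULL) {
  X <- .check_covariates(as.matrix(covariates), length(y))
  if (is.null(variances)) {
    est <- fit_variance_components(y, list(orm), X)
    if (!est$converged)
      stop("null-model REML did not converge; fall back to ols_scan()",
           call. = FALSE)
    variances <- est$components$variance
  }
  A <- if (inherits(orm, "relationship_matrix")) orm$values else orm
  # GLS in the error-contrast space: P = K (K'VK)^{-1} K'
  cs <- .contrast_space(X, y, list(A))
  nk <- length(cs$yk)
  V <- variances[1] * cs$At[[1]] + diag(variances[2], nk)
  Vinv <- chol2inv(chol(V))
  Wk <- crossprod(cs$K, std_probes)
  Py <- drop(Vinv %*% cs$yk)
  PW <- Vinv %*% Wk
  den <- colSums(Wk * PW)
  b <- drop(crossprod(Wk, Py)) / den
  se <- sqrt(1 / den)
  .assoc_table(colnames(std_probes), b, se, "MOA", annotation)
}

#' Probes excluded from the random terms for a given target
#'
#' The exclusion window is fully closed: probes on the same chromosome with
#' `|pos - pos_target| <= half_width` (the target itself included) are
#' removed from the random-effect components when the target is tested.
#' Probes on other chromosomes are never excluded.
#'
#' @param annotation data frame with probe_id, chrom, pos.
#' @param target_probe probe_id of the target.
#' @param half_width window half-width in bases (default 50,000).
#' @return character vector of excluded probe ids.
#' @export
moment_exclusion_set <- function(annotation, target_probe, half_width = 50000) {
  i <- match(target_probe, annotation$probe_id)
  .assert(!is.na(i), "target probe not found in annotation")
  same <- annotation$chrom == annotation$chrom[i] &
    abs(annotation$pos - annotation$pos[i]) <= half_width
  annotation$probe_id[same]
}

#' Multi-component mixed-model scan with target-region exclusion
#'
#' MOMENT-style scan: (i) an initial OLS scan ranks probes; (ii) probes
#' with initial p below `group1_threshold` form a strong-effect component,
#' the rest a background component; (iii) a stepwise reduction moves the
#' weakest strong-group probes (largest initial p, in batches of
#' `batch_frac` of the group) to the background while the strong
#' component's REML variance share exceeds `share_cap` or REML fails;
#' (iv) when each probe is tested, all probes within `half_width` bases on
#' the same chromosome (the target included) are removed from the random
#' components via a low-rank covariance downdate; (v) variance components
#' are estimated once for the final grouping (P3D) and each probe is tested
#' by GLS. If no probe passes `group1_threshold` the model degenerates to
#' the single-component [moa_scan()].
#'
#' @inheritParams ols_scan
#' @param annotation probe annotation (probe_id, chrom, pos); required.
#' @param group1_threshold initial-scan p-value cut for the strong group;
#'   default is the Bonferroni threshold at the scan size.
#' @param share_cap maximum allowed variance share of the strong component.
#' @param batch_frac fraction of the strong group demoted per stepwise
#'   round.
#' @param half_width exclusion window half-width in bases.
#' @return list with `assoc` (association data frame) and `grouping`
#'   (probe_grouping object: probe/group assignment, initial p-values,
#'   window).
#' @export
moment_scan <- function(std_probes, y, covariates, annotation,
                        group1_threshold = NULL, share_cap = 0.5,
                        batch_frac = 0.1, half_width = 50000) {
  .assert(!is.null(annotation), "moment_scan requires probe annotation")
  probe_ids <- colnames(std_probes)
  .assert(all(probe_ids %in% annotation$probe_id),
          "annotation missing scanned probes")
  X <- .check_covariates(as.matrix(covariates), length(y))
  m <- ncol(std_probes)
  n <- length(y)
  if (is.null(group1_threshold)) group1_threshold <- bonferroni_threshold(m, 0.05)

  init <- ols_scan(std_probes, y, X, annotation)
  in_g1 <- init$p < group1_threshold

  grouping_df <- function(g1) data.frame(probe_id = probe_ids,
                                         group = ifelse(g1, 1L, 2L),
                                         initial_p = init$p,
                                         stringsAsFactors = FALSE)

  if (!any(in_g1)) {
    orm <- compute_relationship_matrix(std_probes, "ORM")
    assoc <- moa_scan(std_probes, y, X, orm, annotation)
    assoc$method <- "MOMENT"
    grouping <- structure(list(groups = grouping_df(rep(FALSE, m)),
                               group1_threshold = group1_threshold,
                               half_width = half_width, degenerate = TRUE),
                          class = "probe_grouping")
    return(list(assoc = assoc, grouping = grouping))
  }

  fit_grouping <- function(g1) {
    if (!any(!g1)) stop("grouping leaves the background group empty", call. = FALSE)
    A1 <- compute_relationship_matrix(std_probes[, g1, drop = FALSE], "ORM")
    A2 <- compute_relationship_matrix(std_probes[, !g1, drop = FALSE], "ORM")
    est <- tryCatch(suppressWarnings(
      fit_variance_components(y, list(A1, A2), X)), error = function(e) NULL)
    list(A1 = A1, A2 = A2, est = est)
  }

  repeat {
    fit <- fit_grouping(in_g1)
    ok <- !is.null(fit$est) && fit$est$converged
    share1 <- if (ok) fit$est$components$proportion[1] else NA_real_
    if (ok && share1 <= share_cap) break
    # demote the weakest strong-group probes (largest initial p)
    g1_idx <- which(in_g1)
    if (length(g1_idx) == 0) break
    n_move <- max(1L, ceiling(batch_frac * length(g1_idx)))
    demote <- g1_idx[order(init$p[g1_idx], decreasing = TRUE)][seq_len(n_move)]
    in_g1[demote] <- FALSE
    if (!any(in_g1)) {
      orm <- compute_relationship_matrix(std_probes, "ORM")
      assoc <- moa_scan(std_probes, y, X, orm, annotation)
      assoc$method <- "MOMENT"
      grouping <- structure(list(groups = grouping_df(in_g1),
                                 group1_threshold = group1_threshold,
                                 half_width = half_width, degenerate = TRUE),
                            class = "probe_grouping")
      return(list(assoc = assoc, grouping = grouping))
    }
  }

  sig <- fit$est$components$variance  # (group1, group2, residual)
  m1 <- sum(in_g1); m2 <- m - m1
  # error-contrast space: P = K (K'VK)^{-1} K', so per-target GLS needs
  # only the downdated inverse of K'VK
  cs <- .contrast_space(X, y, list(fit$A1$values, fit$A2$values))
  nk <- length(cs$yk)
  V <- sig[1] * cs$At[[1]] + sig[2] * cs$At[[2]] + diag(sig[3], nk)
  Vinv <- chol2inv(chol(V))
  Wk <- crossprod(cs$K, std_probes)
  ViW <- Vinv %*% Wk
  Viy <- drop(Vinv %*% cs$yk)

  # per-column contribution of probe j to V: (sig_g / m_g) z_j z_j'
  col_load <- ifelse(in_g1, sig[1] / m1, sig[2] / m2)

  ann_idx <- match(probe_ids, annotation$probe_id)
  chrom <- annotation$chrom[ann_idx]
  pos <- annotation$pos[ann_idx]

  b <- se <- numeric(m)
  for (i in seq_len(m)) {
    excl <- which(chrom == chrom[i] & abs(pos - pos[i]) <= half_width &
                    col_load > 1e-14)
    w <- Wk[, i]
    Viw <- ViW[, i]
    if (length(excl) > 0) {
      U <- Wk[, excl, drop = FALSE]
      ViU <- ViW[, excl, drop = FALSE]
      # Woodbury downdate: (V - U D U')^{-1} = Vinv + ViU (D^{-1} - U'ViU)^{-1} U'Vi
      Mmat <- diag(1 / col_load[excl], length(excl)) - crossprod(U, ViU)
      Minv <- tryCatch(solve(Mmat), error = function(e) NULL)
      if (!is.null(Minv)) {
        Vtw <- Viw + drop(ViU %*% (Minv %*% crossprod(U, Viw)))
        Vty <- Viy + drop(ViU %*% (Minv %*% crossprod(U, Viy)))
      } else {  # downdate not PD (numerical edge); fall back to no exclusion
        Vtw <- Viw; Vty <- Viy
      }
    } else {
      Vtw <- Viw; Vty <- Viy
    }
    wPy <- sum(w * Vty)
    wPw <- sum(w * Vtw)
    b[i] <- wPy / wPw
    se[i] <- sqrt(1 / wPw)
  }

  assoc <- .assoc_table(probe_ids, b, se, "MOMENT", annotation)
  grouping <- structure(list(groups = grouping_df(in_g1),
                             group1_threshold = group1_threshold,
                             half_width = half_width, degenerate = FALSE,
                             variance_estimate = fit$est),
                        class = "probe_grouping")
  list(assoc = assoc, grouping = grouping)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate, in (0,1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  .assert(.is_count(n_tests) && n_tests >= 1, "n_tests must be a count >= 1")
  .assert(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  alpha / n_tests
}
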