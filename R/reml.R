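# Multi-component restricted maximum likelihood (average-information REML
# with EM fallback) for variance partitioning of a phenotype across
# relationship matrices, plus BLUP of individual-level component effects.
#
# Model: y ~ N(X beta, sum_k sigma2_k A_k + sigma2_e I). Binary phenotypes
# are analysed on the observed 0/1 scale; no liability transformation is
# applied to the estimates.

.as_matrix_list <- function(matrices) {
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  .assert(is.list(matrices) && length(matrices) >= 1,
          "matrices must be a (list of) relationship_matrix")
  matrices
}

.check_covariates <- function(X, n) {
  .assert(is.matrix(X) && nrow(X) == n, "covariate matrix dimension mismatch")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is singular; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X
}

# REML is maximized in the error-contrast space: with K an orthonormal
# basis of the orthogonal complement of col(X), the projection matrix
# satisfies P = K (K'VK)^{-1} K', so working with yk = K'y and
# Ak_t = K'A_kK removes the fixed-effect directions (including the
# all-ones null vector every centred relationship matrix carries) and
# keeps the likelihood numerically stable near the residual-variance
# boundary. The reported log-likelihood is shifted by -log|X'X|/2 to the
# classical (log|V| + log|X'V^{-1}X| + y'Py) convention.

.contrast_space <- function(X, y, A_list) {
  n <- length(y)
  qrX <- qr(X)
  K <- qr.Q(qrX, complete = TRUE)[, -(seq_len(qrX$rank)), drop = FALSE]
  R <- qr.R(qrX)
  logdet_xtx <- 2 * sum(log(abs(diag(R))))
  list(yk = drop(crossprod(K, y)),
       At = lapply(A_list, function(A) crossprod(K, A %*% K)),
       K = K, const = -0.5 * logdet_xtx)
}

# one REML evaluation in contrast space; NULL if K'VK is not (numerically
# safely) positive definite
.reml_state <- function(sig, cs) {
  nk <- length(cs$yk)
  V <- diag(sig[length(sig)], nk)
  for (k in seq_along(cs$At)) V <- V + sig[k] * cs$At[[k]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  dc <- diag(cholV)
  if (min(dc)^2 < 1e-13 * mean(diag(V))) return(NULL)
  Vinv <- chol2inv(cholV)
  Py <- drop(Vinv %*% cs$yk)
  logl <- -0.5 * (2 * sum(log(dc)) + sum(cs$yk * Py)) + cs$const
  if (!is.finite(logl)) return(NULL)
  list(sig = sig, P = Vinv, Py = Py, logl = logl)
}

.reml_derivs <- function(state, cs) {
  K <- length(cs$At) + 1L
  APy <- vector("list", K)
  trPA <- numeric(K)
  for (k in seq_along(cs$At)) {
    APy[[k]] <- drop(cs$At[[k]] %*% state$Py)
    trPA[k] <- sum(state$P * cs$At[[k]])
  }
  APy[[K]] <- state$Py
  trPA[K] <- sum(diag(state$P))
  yPAPy <- vapply(APy, function(a) sum(a * state$Py), numeric(1))
  score <- -0.5 * (trPA - yPAPy)
  AI <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in k:K) {
    AI[k, l] <- AI[l, k] <- 0.5 * sum(APy[[k]] * (state$P %*% APy[[l]]))
  }
  list(score = score, AI = AI, trPA = trPA, yPAPy = yPAPy)
}

#' Fit variance components by AI-REML with EM fallback
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X beta, sum_k sigma2_k A_k + sigma2_e I)` by average-information
#' updates, falling back to expectation-maximization steps when an AI step
#' fails to increase the restricted log-likelihood. Variances are
#' constrained non-negative by projection onto a small positive floor.
#' Standard errors come from the inverse AI matrix; proportion SEs use a
#' first-order delta method and are approximate. Convergence is declared
#' when the restricted log-likelihood changes by less than `tol` (default
#' 1e-8) or after `max_iter` iterations (non-convergence is flagged, last
#' iterate returned).
#'
#' @param y numeric phenotype vector (binary traits on the observed 0/1
#'   scale).
#' @param matrices a [relationship_matrix] or list of them.
#' @param covariates numeric covariate matrix including an intercept; a
#'   singular matrix is fatal and names the aliased columns.
#' @param max_iter,tol iteration controls.
#' @param verbose print per-iteration log-likelihoods.
#' @return object of class `variance_estimate` with per-component variances,
#'   SEs, proportions of phenotypic variance, restricted log-likelihood,
#'   convergence and identifiability flags.
#' @export
fit_variance_components <- function(y, matrices, covariates, max_iter = 100L,
                                    tol = 1e-8, verbose = FALSE) {
  matrices <- .as_matrix_list(matrices)
  n <- length(y)
  A_list <- lapply(matrices, function(mm) {
    if (inherits(mm, "relationship_matrix")) mm$values else mm
  })
  for (A in A_list) .assert(nrow(A) == n, "relationship matrix dimension mismatch")
  X <- .check_covariates(as.matrix(covariates), n)
  K <- length(A_list) + 1L
  .assert(n > ncol(X) + K, "too few samples for the number of covariates/components")

  vary <- var(y)
  floor_val <- 1e-8 * vary
  sig <- rep(vary / K, K)

  cs <- .contrast_space(X, y, A_list)
  state <- .reml_state(sig, cs)
  .assert(!is.null(state), "initial variance matrix not positive definite")
  converged <- FALSE
  iter <- 0L
  derivs <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    derivs <- .reml_derivs(state, cs)
    # EM update (guaranteed uphill direction, slow); used for the first
    # step and as fallback when the AI step fails
    em_sig <- pmax(sig + sig^2 * (derivs$yPAPy - derivs$trPA) / n, floor_val)
    accepted <- NULL
    if (iter > 1L) {
      delta <- tryCatch(solve(derivs$AI, derivs$score), error = function(e) NULL)
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:12) {
          cand <- pmax(sig + step * delta, floor_val)
          st <- .reml_state(cand, cs)
          if (!is.null(st) && st$logl >= state$logl - 1e-12) {
            accepted <- st
            break
          }
          step <- step / 2
        }
      }
    }
    if (is.null(accepted)) {
      st <- .reml_state(em_sig, cs)
      if (is.null(st)) break  # cannot evaluate; keep last iterate
      accepted <- st
    }
    dlog <- accepted$logl - state$logl
    sig <- accepted$sig
    state <- accepted
    if (verbose) message(sprintf("iter %d logL %.8f", iter, state$logl))
    if (abs(dlog) < tol) {
      converged <- TRUE
      break
    }
  }
  derivs <- .reml_derivs(state, cs)

  AI <- derivs$AI
  ev <- eigen(AI, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.eps)
  identifiable <- is.finite(cond) && cond < 1e8
  C <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(C)) {  # pseudo-inverse for flat directions
    e <- eigen(AI, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(e$values)
    C <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  }
  se <- sqrt(pmax(diag(C), 0))

  sigma_p <- sum(sig)
  sigma_p_se <- sqrt(max(sum(C), 0))
  prop <- sig / sigma_p
  prop_se <- vapply(seq_len(K), function(k) {
    g <- -sig[k] / sigma_p^2 * rep(1, K)
    g[k] <- g[k] + 1 / sigma_p
    sqrt(max(drop(t(g) %*% C %*% g), 0))
  }, numeric(1))

  labels <- vapply(seq_along(matrices), function(k) {
    mm <- matrices[[k]]
    if (inherits(mm, "relationship_matrix")) mm$kind else paste0("K", k)
  }, character(1))
  labels <- make.unique(c(labels, "residual"))

  if (!identifiable)
    warning("variance components weakly identified (AI condition number ",
            format(cond, digits = 3), ")", call. = FALSE)
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations; ",
            "last iterate returned", call. = FALSE)

  structure(list(
    components = data.frame(component = labels, variance = sig, se = se,
                            proportion = prop, proportion_se = prop_se,
                            stringsAsFactors = FALSE),
    sigma_p = sigma_p, sigma_p_se = sigma_p_se,
    loglik = state$logl, n_iter = iter, converged = converged,
    identifiable = identifiable, condition_number = cond,
    var_y = vary), class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("REML variance components (logL %.4f, %d iterations%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  df <- x$components
  df$variance <- sprintf("%.5f (%.5f)", df$variance, df$se)
  df$proportion <- sprintf("%.4f (%.4f)", df$proportion, df$proportion_se)
  print(df[, c("component", "variance", "proportion")], row.names = FALSE)
  cat(sprintf("phenotypic variance: %.5f (%.5f)\n", x$sigma_p, x$sigma_p_se))
  invisible(x)
}

#' Restricted log-likelihood at fixed variances
#'
#' Evaluates the restricted log-likelihood of the variance-component model
#' at a given variance vector (components in the order of `matrices`, with
#' the residual variance last). Used for profiling and external checks.
#'
#' @inheritParams fit_variance_components
#' @param variances numeric vector of length `length(matrices) + 1`.
#' @return the restricted log-likelihood (or `-Inf` if V is not PD).
#' @export
reml_loglik <- function(y, matrices, covariates, variances) {
  matrices <- .as_matrix_list(matrices)
  A_list <- lapply(matrices, function(mm)
    if (inherits(mm, "relationship_matrix")) mm$values else mm)
  X <- as.matrix(covariates)
  cs <- .contrast_space(X, y, A_list)
  st <- .reml_state(variances, cs)
  if (is.null(st)) return(-Inf)
  st$logl
}

#' Predict individual-level random effects (BLUP) from a REML fit
#'
#' Computes GLS fixed effects and, per component,
#' `u_k = sigma2_k A_k V^{-1} (y - X beta)`. The decomposition
#' `y = X beta + sum_k u_k + e` holds exactly by construction.
#'
#' @inheritParams fit_variance_components
#' @param estimate a converged [fit_variance_components()] result.
#' @return object of class `mixed_model_fit` with `beta` (estimates and
#'   SEs), `u` (list of per-component n-vectors), `residuals`, and the
#'   `estimate` used.
#' @export
predict_individual_effects <- function(y, matrices, covariates, estimate) {
  .assert(inherits(estimate, "variance_estimate"), "estimate must be a variance_estimate")
  matrices <- .as_matrix_list(matrices)
  A_list <- lapply(matrices, function(mm)
    if (inherits(mm, "relationship_matrix")) mm$values else mm)
  X <- .check_covariates(as.matrix(covariates), length(y))
  sig <- estimate$components$variance
  n <- length(y)
  V <- diag(sig[length(sig)], n)
  for (k in seq_along(A_list)) V <- V + sig[k] * A_list[[k]]
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-12 * max(diag(V)))
    stop(sprintf("V is numerically singular (smallest eigenvalue %.3e)", ev_min),
         call. = FALSE)
  cholV <- chol(V)
  Vinv <- chol2inv(cholV)
  ViX <- Vinv %*% X
  XtViX_inv <- solve(crossprod(X, ViX))
  beta_hat <- drop(XtViX_inv %*% crossprod(ViX, y))
  r <- drop(y - X %*% beta_hat)
  Vir <- drop(Vinv %*% r)
  u <- lapply(seq_along(A_list), function(k) sig[k] * drop(A_list[[k]] %*% Vir))
  names(u) <- estimate$components$component[seq_along(A_list)]
  e_hat <- sig[length(sig)] * Vir
  structure(list(
    beta = data.frame(term = colnames(X) %||% paste0("b", seq_along(beta_hat)),
                      estimate = beta_hat,
                      se = sqrt(diag(XtViX_inv)), stringsAsFactors = FALSE),
    u = u, residuals = e_hat, fitted_fixed = drop(X %*% beta_hat),
    estimate = estimate), class = "mixed_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the five-model variance-partition ladder
#'
#' Convenience wrapper fitting the standard model sequence on a cohort:
#' (1) ORM alone; (2) GRM alone; (3) ORM + GRM; (4) SV-adjusted ORM + GRM;
#' (5) SV-adjusted ORM + GRM with age, institution and menstrual-phase
#' fixed covariates. SV adjustment residualizes the beta matrix on
#' surrogate variables before ORM construction (not via fixed effects).
#'
#' @param cohort an `mrs_cohort` (or list with `meth`, `geno`, `samples`).
#' @param sv_seed seed for the surrogate-variable permutation null.
#' @return named list of [fit_variance_components()] results.
#' @export
variance_ladder <- function(cohort, sv_seed = 1L) {
  y <- cohort$samples$status
  n <- length(y)
  Z_o <- standardize_probes(cohort$meth$beta)
  orm <- compute_relationship_matrix(Z_o, "ORM")
  Z_g <- standardize_probes(cohort$geno$dosage)
  grm <- compute_relationship_matrix(Z_g, "GRM")
  svs <- estimate_svs(beta_to_m(cohort$meth$beta), y, seed = sv_seed)
  beta_adj <- residualize(cohort$meth$beta, svs)
  orm_adj <- compute_relationship_matrix(standardize_probes(beta_adj), "ORM")
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X5 <- build_covariate_matrix(cohort$samples, genetic_pcs = NULL,
                               svs = NULL, include = c("age", "institution",
                                                       "cycle_phase"))
  list(
    orm = fit_variance_components(y, list(orm), X0),
    grm = fit_variance_components(y, list(grm), X0),
    orm_grm = fit_variance_components(y, list(orm, grm), X0),
    orm_adj_grm = fit_variance_components(y, list(orm_adj, grm), X0),
    orm_adj_grm_cov = fit_variance_components(y, list(orm_adj, grm), X5))
}

#' Write a variance-partition report
#'
#' Long-format TSV with one row per model and component: model, component,
#' variance, se, proportion, proportion_se, phenotypic variance and its SE,
#' log-likelihood, and the plain sum of non-residual proportions (the
#' "combined share" convention) alongside each model's own normalization.
#'
#' @param ladder named list of `variance_estimate` objects.
#' @param path output TSV path.
#' @export
write_variance_report <- function(ladder, path) {
  rows <- lapply(names(ladder), function(nm) {
    ve <- ladder[[nm]]
    df <- ve$components
    nonres <- df$component != "residual"
    data.frame(model = nm, component = df$component,
               variance = df$variance, se = df$se,
               proportion = df$proportion, proportion_se = df$proportion_se,
               combined_share = sum(df$proportion[nonres]),
               sigma_p = ve$sigma_p, sigma_p_se = ve$sigma_p_se,
               loglik = ve$loglik, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
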