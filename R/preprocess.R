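# Pre-modelling transformations: m-values, probe standardization, PCA,
# covariate screening, surrogate variables, residualization.

#' Beta to m-value transform
#'
#' Base-2 logit, `m = log2(beta / (1 - beta))`. Values at or beyond 0/1 are
#' clipped to `[1e-6, 1 - 1e-6]` with a warning so the transform stays
#' finite; strictly increasing in beta.
#'
#' @param beta numeric vector or matrix of beta values.
#' @return m-values with the same shape.
#' @export
beta_to_m <- function(beta) {
  eps <- 1e-6
  n_clip <- sum(beta <= 0 | beta >= 1)
  if (n_clip > 0) {
    warning(n_clip, " beta value(s) at 0/1 clipped to [1e-6, 1-1e-6]",
            call. = FALSE)
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' Standardize probes to mean 0 and population variance 1
#'
#' Uses the divide-by-n (population) standard deviation so relationship
#' matrices built from the output have diagonals averaging exactly 1.
#' Zero-variance probes are dropped with a warning listing them.
#'
#' @param x numeric samples x features matrix, no missing values.
#' @return standardized matrix with attributes `center`, `scale` (per kept
#'   feature) and `dropped` (ids of constant features).
#' @export
standardize_probes <- function(x) {
  .assert(is.matrix(x) && !anyNA(x), "x must be a complete numeric matrix")
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sds <- sqrt(colSums(xc^2) / n)
  drop_idx <- which(sds == 0)
  if (length(drop_idx) == ncol(x))
    stop("all features have zero variance", call. = FALSE)
  dropped <- colnames(x)[drop_idx]
  if (length(drop_idx) > 0) {
    warning(length(drop_idx), " zero-variance feature(s) dropped", call. = FALSE)
    xc <- xc[, -drop_idx, drop = FALSE]
    sds <- sds[-drop_idx]
    ctr <- ctr[-drop_idx]
  }
  z <- sweep(xc, 2, sds, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  attr(z, "dropped") <- dropped
  z
}

#' Principal-component scores of a column-centered matrix
#'
#' Scores are projections onto the top-k right singular directions of the
#' column-centered matrix. The sign of each component is fixed so its first
#' nonzero loading is positive, making output deterministic.
#'
#' @param x numeric samples x features matrix.
#' @param k number of components, `k <= min(n, p)`.
#' @return list with `scores` (n x k), `loadings` (p x k), `var_frac`
#'   (fraction of total variance per component) and `zero_variance`
#'   (indices of requested components beyond the matrix rank).
#' @export
pca_scores <- function(x, k) {
  .assert(is.matrix(x), "x must be a matrix")
  .assert(k >= 1 && k <= min(dim(x)), "k must be in [1, min(n, p)]")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  # sign convention: first nonzero loading positive
  for (j in seq_len(k)) {
    nz <- which(abs(sv$v[, j]) > 1e-12)[1]
    if (!is.na(nz) && sv$v[nz, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(d, k, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(sv$d^2)
  zero_var <- which(d^2 / max(tot, .Machine$double.eps) < 1e-14)
  if (length(zero_var) > 0)
    warning("component(s) beyond matrix rank returned with zero variance: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  list(scores = scores, loadings = sv$v,
       var_frac = if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k),
       zero_variance = zero_var)
}

#' Screen covariates against case-control status and methylation PCs
#'
#' Continuous covariates are tested against status with a two-sided Welch
#' t-test; categorical covariates with a chi-squared test (no continuity
#' correction), switching to Fisher's exact test when any expected cell
#' count is below 5. Each methylation PC is tested against categorical
#' covariates by one-way ANOVA and against continuous covariates by a
#' simple-regression F-test. Covariates with p < 0.05 against status are
#' flagged. Up to the top 15 PCs are screened.
#'
#' @param samples sample table with a 0/1 `status` column.
#' @param dnam_pcs numeric matrix of methylation PC scores (n x k).
#' @param covariates character vector of sample-table columns to screen.
#' @return list of class `screen_report` with data frames `status_tests`
#'   and `pc_tests`.
#' @export
covariate_screen <- function(samples, dnam_pcs,
                             covariates = c("age", "institution",
                                            "cycle_phase", "ancestry")) {
  .assert(!anyNA(samples$status), "status must be known for all samples")
  status <- factor(samples$status, levels = c(0, 1))
  k <- min(15L, ncol(dnam_pcs))

  status_rows <- list(); pc_rows <- list(); notes <- character(0)
  for (cv in covariates) {
    x <- samples[[cv]]
    if (is.numeric(x)) {
      tt <- t.test(x ~ status)  # Welch by default
      status_rows[[cv]] <- data.frame(covariate = cv, test = "welch-t",
                                      statistic = unname(tt$statistic),
                                      p = tt$p.value)
      for (j in seq_len(k)) {
        fit <- lm(dnam_pcs[, j] ~ x)
        a <- anova(fit)
        pc_rows[[paste(cv, j)]] <- data.frame(
          pc = j, covariate = cv, test = "lm-F",
          p = a$`Pr(>F)`[1])
      }
    } else {
      xf <- factor(x)
      if (nlevels(droplevels(xf)) < 2) {
        notes <- c(notes, sprintf("covariate '%s' has a single level; skipped", cv))
        next
      }
      tab <- table(xf, status)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        status_rows[[cv]] <- data.frame(covariate = cv, test = "fisher",
                                        statistic = NA_real_, p = ft$p.value)
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        status_rows[[cv]] <- data.frame(covariate = cv, test = "chisq",
                                        statistic = unname(ct$statistic),
                                        p = ct$p.value)
      }
      for (j in seq_len(k)) {
        a <- anova(aov(dnam_pcs[, j] ~ xf))
        pc_rows[[paste(cv, j)]] <- data.frame(
          pc = j, covariate = cv, test = "anova-F", p = a$`Pr(>F)`[1])
      }
    }
  }
  st <- do.call(rbind, status_rows)
  rownames(st) <- NULL
  st$flagged <- st$p < 0.05
  pc <- do.call(rbind, pc_rows)
  if (!is.null(pc)) rownames(pc) <- NULL
  if (length(notes)) message(paste(notes, collapse = "\n"))
  structure(list(status_tests = st, pc_tests = pc, notes = notes),
            class = "screen_report")
}

#' Estimate surrogate variables from status-adjusted methylation residuals
#'
#' Residualizes each probe's m-values on case-control status (full model:
#' intercept + status; null model: intercept), estimates the number of
#' surrogate variables q by comparing the residual matrix's leading singular
#' values to the 95th percentile of `n_perm` column-permutation nulls, and
#' returns the top-q left singular vectors refined by one reweighting pass
#' (probes are reweighted by how much of their residual variance the current
#' SVs explain). Columns are zero-mean, unit-norm and mutually orthogonal.
#'
#' @param mvalues numeric samples x probes matrix of m-values.
#' @param status 0/1 vector.
#' @param n_perm number of permutation nulls for the rank estimate.
#' @param q_max maximum number of SVs returned.
#' @param seed seed for the permutation null (SV estimation is otherwise
#'   deterministic).
#' @return list of class `surrogate_variables` with `sv` (n x q matrix,
#'   possibly 0 columns) and `q`.
#' @export
estimate_svs <- function(mvalues, status, n_perm = 20L, q_max = 10L, seed = 1L) {
  .assert(is.matrix(mvalues) && !anyNA(mvalues), "mvalues must be complete")
  .assert(length(status) == nrow(mvalues), "status length mismatch")
  .assert(min(table(status)) >= 3, "need at least 3 samples per status group")
  n <- nrow(mvalues)

  X <- cbind(1, status)
  qrX <- qr(X)
  R <- qr.resid(qrX, mvalues)

  q_max <- min(q_max, n - ncol(X), ncol(R))
  d_obs <- svd(R, nu = 0, nv = 0)$d

  # permutation null for the leading singular value: permute each column
  # independently, killing cross-probe structure while keeping margins
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  null_max <- vapply(seq_len(n_perm), function(b) {
    Rp <- apply(R, 2, sample)
    Rp <- qr.resid(qrX, Rp)  # permuted columns re-residualized on the design
    .top_singular_value(Rp)
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  thr <- quantile(null_max, 0.95, names = FALSE)
  q <- min(sum(d_obs > thr), q_max)
  if (q == 0) {
    message("no surrogate variables above the permutation null; returning none")
    sv <- matrix(numeric(0), n, 0)
    rownames(sv) <- rownames(mvalues)
    return(structure(list(sv = sv, q = 0L, threshold = thr),
                     class = "surrogate_variables"))
  }

  u <- svd(R, nu = q, nv = 0)$u
  # one reweighting pass: emphasize probes whose residual variation the
  # current SVs capture, then recompute the basis on the weighted matrix
  fitted <- u %*% crossprod(u, R)
  r2 <- colSums(fitted^2) / pmax(colSums(R^2), .Machine$double.eps)
  u <- svd(sweep(R, 2, sqrt(r2), "*"), nu = q, nv = 0)$u
  u <- qr.Q(qr(u))[, seq_len(q), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(q)) {
    i0 <- which.max(abs(u[, j]))
    if (u[i0, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- rownames(mvalues)
  colnames(u) <- paste0("SV", seq_len(q))
  structure(list(sv = u, q = as.integer(q), threshold = thr),
            class = "surrogate_variables")
}

.top_singular_value <- function(x, iter = 100L, tol = 1e-8) {
  v <- rnorm(ncol(x))
  v <- v / sqrt(sum(v^2))
  s <- s_old <- 0
  for (i in seq_len(iter)) {
    w <- crossprod(x, x %*% v)  # X'X v
    v <- w / sqrt(sum(w^2))
    s <- sqrt(sum((x %*% v)^2))
    if (abs(s - s_old) < tol * max(s, 1)) break
    s_old <- s
  }
  s
}

#' Residualize a matrix on surrogate variables
#'
#' Replaces each column by the residuals of its least-squares projection on
#' an intercept plus the SVs; with an empty SV set this is column centering.
#' Adjusted columns have zero correlation with every SV.
#'
#' @param x numeric samples x features matrix.
#' @param svs a `surrogate_variables` object or a numeric matrix of SVs.
#' @return adjusted matrix of the same shape.
#' @export
residualize <- function(x, svs) {
  sv <- if (inherits(svs, "surrogate_variables")) svs$sv else svs
  .assert(is.matrix(x), "x must be a matrix")
  if (is.null(sv) || ncol(sv) == 0) return(sweep(x, 2, colMeans(x)))
  .assert(nrow(sv) == nrow(x), "sample dimension mismatch between x and SVs")
  if (!is.null(rownames(sv)) && !is.null(rownames(x)))
    .assert(identical(rownames(sv), rownames(x)), "sample id order mismatch")
  qr.resid(qr(cbind(1, sv)), x)
}
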