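# Logistic-model evaluation of risk scores: AUC, DeLong confidence
# intervals, Wald p-values, correlations, best-model selection.

#' Logistic regression with Wald tests
#'
#' Thin wrapper around `stats::glm(binomial)` (IRLS to a deviance change
#' below 1e-10 or 50 iterations) reporting coefficients, SEs, Wald
#' p-values, fitted probabilities and deviance. Perfect separation is
#' flagged (diverging coefficients with vanishing deviance); the AUC of the
#' raw score remains usable even then.
#'
#' @param y 0/1 outcome with at least two of each class.
#' @param predictors numeric vector, matrix or data frame of predictors
#'   (no intercept column; one is added).
#' @return list of class `logistic_fit`: `coefficients` data frame (term,
#'   estimate, se, z, p), `fitted`, `deviance`, `null_deviance`,
#'   `converged`, `separation`.
#' @export
logistic_regression <- function(y, predictors) {
  .assert(all(y %in% c(0, 1)), "y must be 0/1")
  .assert(sum(y == 0) >= 2 && sum(y == 1) >= 2, "need >= 2 of each class")
  Xd <- as.data.frame(predictors)
  if (is.null(names(predictors)) && ncol(Xd) == 1) names(Xd) <- "x"
  dat <- cbind(data.frame(.y = y), Xd)
  fit <- glm(.y ~ ., data = dat, family = binomial(),
             control = glm.control(epsilon = 1e-12, maxit = 50))
  sm <- summary(fit)$coefficients
  # diverging coefficients with vanishing deviance signal separation; the
  # deviance criterion is the operative one (glm stops before |beta|
  # grows arbitrarily)
  separation <- fit$deviance < 1e-6 &&
    max(abs(coef(fit)[-1]), 0, na.rm = TRUE) > 10
  if (separation)
    warning("perfect separation detected; Wald p-values unusable", call. = FALSE)
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], z = sm[, 3], p = sm[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    fitted = unname(fit$fitted.values), deviance = fit$deviance,
    null_deviance = fit$null.deviance, converged = fit$converged,
    separation = separation), class = "logistic_fit")
}

#' Area under the ROC curve (rank form)
#'
#' `AUC = (# case-control pairs with score_case > score_control + half the
#' ties) / (n_case * n_control)`, computed from midranks.
#'
#' @param scores numeric score vector.
#' @param y 0/1 class labels (both classes present).
#' @return the AUC.
#' @export
roc_auc <- function(scores, y) {
  .assert(length(scores) == length(y), "length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  .assert(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance from DeLong structural components: per case the
#' mean placement against all controls, per control the mean placement
#' against all cases; `var = var(V10)/n1 + var(V01)/n0`. The Wald interval
#' `AUC +/- z * sd` is returned untruncated. Zero variance away from AUC of
#' 0/1 is reported as-is with a warning.
#'
#' @param scores numeric score vector.
#' @param y 0/1 labels.
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `variance`.
#' @export
delong_ci <- function(scores, y, level = 0.95) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  .assert(n1 > 0 && n0 > 0, "both classes must be present")
  cases <- scores[y == 1]; controls <- scores[y == 0]
  # placement values via midranks (O(n log n))
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_case <- rank(cases, ties.method = "average")
  r_ctrl <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_case) / n0              # P(score_ctrl < case)
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_ctrl) / n1     # P(score_case > ctrl)
  auc <- mean(v10)
  variance <- var(v10) / n1 + var(v01) / n0
  if (variance == 0 && auc > 0 && auc < 1)
    warning("zero DeLong variance with non-degenerate AUC", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, ci_low = auc - z * sqrt(variance),
       ci_high = auc + z * sqrt(variance), variance = variance)
}

#' Pearson correlation matrix of score/effect vectors
#'
#' @param vectors named list (or data frame) of equal-length numeric
#'   vectors; zero-variance vectors yield NA entries with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  mat <- as.matrix(as.data.frame(vectors))
  lens <- apply(mat, 2, length)
  .assert(length(unique(lens)) == 1, "vectors must have equal length")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0))
    warning("zero-variance vector(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  r <- suppressWarnings(cor(mat))
  diag(r) <- 1
  r
}

#' Select the best MRS model from an evaluation table
#'
#' Applies, in order: (1) models at thresholds 1e-4 and 1e-5 are excluded
#' (their low probe counts give unstable scores); (2) among remaining
#' models with a significant MRS association (p_mrs < 0.05 in the MRS-only
#' fit), the highest AUC wins; (3) if none is significant, the highest AUC
#' overall wins. Ties break by fewer probes, then lexicographic method
#' name.
#'
#' @param results data frame of MRS-model rows (one per method x threshold)
#'   with columns method, threshold, n_probes, AUC, p_mrs.
#' @return the selected row.
#' @export
select_best_model <- function(results) {
  drop_thr <- !is.na(results$threshold) &
    (abs(results$threshold - 1e-4) < 1e-12 | abs(results$threshold - 1e-5) < 1e-12)
  res <- results[!drop_thr, , drop = FALSE]
  .assert(nrow(res) > 0, "all models excluded")
  pick <- function(df) {
    ord <- order(-df$AUC, df$n_probes, df$method)
    df[ord[1], , drop = FALSE]
  }
  sig <- res[!is.na(res$p_mrs) & res$p_mrs < 0.05, , drop = FALSE]
  if (nrow(sig) > 0) pick(sig) else pick(res)
}
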