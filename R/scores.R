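# Risk-score computation on test samples.

#' Compute a methylation risk score
#'
#' `MRS_i = sum_k w_k m_ik` over the intersection of weight probes and test
#' probes, using raw beta values (not m-values, not re-standardized).
#' Weight probes absent from the test matrix are dropped and counted.
#' Because scan weights are per standardized probe, applying them to raw
#' betas rescales each term by that probe's training SD; for
#' approximately-equal-variance probes this changes scale, not ranking. Set
#' `standardize = TRUE` to score on betas standardized with the supplied
#' center/scale instead.
#'
#' @param weights an [effect_weights()] object.
#' @param test_meth a [meth_matrix()] (or samples x probes beta matrix).
#' @param standardize score on standardized betas.
#' @param center,scale per-probe center/scale (named vectors from the
#'   training [standardize_probes()]) when `standardize = TRUE`.
#' @return object of class `risk_score`: data frame sample_id, score, with
#'   provenance attributes (kind, method, threshold, n_used, n_dropped).
#' @export
compute_mrs <- function(weights, test_meth, standardize = FALSE,
                        center = NULL, scale = NULL) {
  .assert(nrow(weights) > 0, "empty weight set")
  beta <- if (inherits(test_meth, "meth_matrix")) test_meth$beta else test_meth
  common <- intersect(weights$feature_id, colnames(beta))
  .assert(length(common) > 0, "no weight probes present in the test matrix")
  n_dropped <- nrow(weights) - length(common)
  if (n_dropped > 0)
    message(n_dropped, " weight probe(s) absent from test matrix; dropped")
  w <- weights$weight[match(common, weights$feature_id)]
  mat <- beta[, common, drop = FALSE]
  if (standardize) {
    .assert(!is.null(center) && !is.null(scale), "standardize needs center/scale")
    mat <- sweep(sweep(mat, 2, center[common]), 2, scale[common], "/")
  }
  score <- drop(mat %*% w)
  structure(data.frame(sample_id = rownames(beta), score = score,
                       stringsAsFactors = FALSE),
            kind = "MRS", method = attr(weights, "source"),
            threshold = attr(weights, "threshold"),
            n_used = length(common), n_dropped = n_dropped,
            class = c("risk_score", "data.frame"))
}

#' Compute a polygenic risk score from allele-oriented weights
#'
#' Per variant, the dosage is oriented to the weight's effect allele: if
#' the effect allele is the alt allele the dosage is used as is; if it is
#' the ref allele, `2 - dosage`; if it matches neither, the variant is
#' skipped and counted. The score is the plain weighted sum (no mean-score
#' rescaling; AUC is invariant to it). Strand-ambiguous (A/T, C/G) weights
#' are not reconciled: synthetic weights are strand-consistent by
#' construction and real data must be pre-harmonized (a warning notes
#' ambiguous pairs).
#'
#' @param weights an [effect_weights()] object carrying `effect_allele`.
#' @param test_geno a [geno_matrix()].
#' @return a `risk_score` object of kind "PRS".
#' @export
compute_prs <- function(weights, test_geno) {
  .assert("effect_allele" %in% names(weights),
          "PRS weights must carry an effect_allele column")
  v <- test_geno$variants
  idx <- match(weights$feature_id, v$variant_id)
  present <- !is.na(idx)
  amb <- present & ((v$ref[idx] == "A" & v$alt[idx] == "T") |
                      (v$ref[idx] == "T" & v$alt[idx] == "A") |
                      (v$ref[idx] == "C" & v$alt[idx] == "G") |
                      (v$ref[idx] == "G" & v$alt[idx] == "C"))
  if (any(amb))
    warning(sum(amb), " strand-ambiguous variant(s) scored as-is; ",
            "pre-harmonize real data", call. = FALSE)
  ea <- weights$effect_allele
  use_alt <- present & ea == v$alt[idx]
  use_ref <- present & !use_alt & ea == v$ref[idx]
  matched <- use_alt | use_ref
  .assert(any(matched), "no weight variant matched the test genotypes")
  n_dropped <- nrow(weights) - sum(matched)
  if (n_dropped > 0)
    message(n_dropped, " weight variant(s) unmatched (absent or allele ",
            "mismatch); dropped")
  score <- numeric(nrow(test_geno$dosage))
  if (any(use_alt))
    score <- score + drop(test_geno$dosage[, idx[use_alt], drop = FALSE] %*%
                            weights$weight[use_alt])
  if (any(use_ref))
    score <- score + drop((2 - test_geno$dosage[, idx[use_ref], drop = FALSE]) %*%
                            weights$weight[use_ref])
  structure(data.frame(sample_id = rownames(test_geno$dosage), score = score,
                       stringsAsFactors = FALSE),
            kind = "PRS", method = attr(weights, "source"),
            threshold = attr(weights, "threshold"),
            n_used = sum(matched), n_dropped = n_dropped,
            class = c("risk_score", "data.frame"))
}
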