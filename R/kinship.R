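# Omics (ORM) and genomic (GRM) relationship matrices.

#' Compute a relationship matrix from standardized features
#'
#' `A = Z Z' / m` where `Z` is the samples x features matrix standardized by
#' [standardize_probes()] (population sd), so the diagonal of `A` averages
#' exactly 1 and `trace(A) = n`. The same scheme is used for methylation
#' (ORM) and dosage (GRM) features: downstream variance components are
#' invariant to a global rescaling of `A` combined with re-estimated
#' variances, so fixing one convention is sufficient.
#'
#' @param std_features standardized samples x features matrix.
#' @param kind "ORM" or "GRM".
#' @return object of class `relationship_matrix`: list with `values`
#'   (n x n), `sample_ids`, `kind`, `n_features`.
#' @export
compute_relationship_matrix <- function(std_features, kind = c("ORM", "GRM")) {
  kind <- match.arg(kind)
  .assert(is.matrix(std_features), "std_features must be a matrix")
  m <- ncol(std_features)
  .assert(m > 0, "no features left after zero-variance drops")
  A <- tcrossprod(std_features) / m
  ids <- rownames(std_features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(list(values = A, sample_ids = ids, kind = kind, n_features = m),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s: %d samples, %d features, mean diagonal %.4f\n",
              x$kind, length(x$sample_ids), x$n_features,
              mean(diag(x$values))))
  invisible(x)
}
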