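# Turning scan output or BLUP fits into score weights.

#' Back-solve per-probe effects from individual-level BLUPs
#'
#' Given the individual-level joint probe effect `u` (the ORM component of
#' a [predict_individual_effects()] fit) and the standardized probe matrix
#' `Z` the ORM was built from, recovers per-probe weights
#' `b = Z' A^+ u / m` with `A = Z Z' / m` (Moore-Penrose pseudo-inverse,
#' tolerance `1e-10` of the largest eigenvalue, for rank deficiency). Every
#' probe receives a weight; `Z b` reproduces the projection of `u` onto the
#' column space of `Z`. Equivalent to ridge regression of the adjusted
#' phenotype on `Z` with penalty `lambda = m sigma2_e / sigma2_u`.
#'
#' @param fit a `mixed_model_fit` whose `u` list carries an ORM component.
#' @param std_probes the standardized samples x probes matrix `Z` the ORM
#'   was computed from.
#' @param component which component of `fit$u` holds the probe effect
#'   (default: the first).
#' @return an [effect_weights()] object tagged "BLUP" with one weight per
#'   probe.
#' @export
blup_probe_effects <- function(fit, std_probes, component = 1L) {
  .assert(inherits(fit, "mixed_model_fit"), "fit must be a mixed_model_fit")
  u <- fit$u[[component]]
  .assert(!is.null(u), "fit has no random component %s", component)
  .assert(length(u) == nrow(std_probes),
          "dimension mismatch between u and std_probes")
  m <- ncol(std_probes)
  A <- tcrossprod(std_probes) / m
  e <- eigen(A, symmetric = TRUE)
  tol <- 1e-10 * max(e$values)
  pos <- e$values > tol
  Aplus_u <- e$vectors[, pos, drop = FALSE] %*%
    (crossprod(e$vectors[, pos, drop = FALSE], u) / e$values[pos])
  b <- drop(crossprod(std_probes, Aplus_u)) / m
  effect_weights(data.frame(feature_id = colnames(std_probes), weight = b,
                            stringsAsFactors = FALSE), source = "BLUP")
}

#' Select scan probes by p-value threshold
#'
#' Retains probes with `p < tau` (strict inequality: a probe whose p-value
#' equals `tau` is excluded) and returns their scan effects as score
#' weights. The BLUP path bypasses this selection (all probes are used).
#'
#' @param assocs association data frame from a scan.
#' @param tau p-value threshold in (0, 1\].
#' @return an [effect_weights()] object; empty (with a warning) when no
#'   probe passes.
#' @export
select_probes_by_threshold <- function(assocs, tau) {
  .assert(is.numeric(tau) && tau > 0 && tau <= 1, "tau must be in (0,1]")
  keep <- assocs$p < tau
  if (!any(keep))
    warning("no probes pass threshold ", tau, "; empty weight set returned",
            call. = FALSE)
  effect_weights(data.frame(feature_id = assocs$probe_id[keep],
                            weight = assocs$effect[keep],
                            stringsAsFactors = FALSE),
                 source = assocs$method[1] %||% "scan", threshold = tau)
}
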