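# Independent oracles used across the suite. These deliberately use naive,
# transparent formulations (dense solves, double loops, enumeration) and
# never call the package code paths they check.

# brute-force AUC over all case-control pairs
brute_auc <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# hand-rolled Newton-Raphson on the exact binomial log-likelihood
newton_logistic <- function(y, X, max_iter = 100, tol = 1e-12) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta,
       se = sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu)))))),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# stratified bootstrap CI for the AUC
boot_auc_ci <- function(scores, y, B = 2000, level = 0.95, seed = 1) {
  set.seed(seed)
  i1 <- which(y == 1); i0 <- which(y == 0)
  aucs <- replicate(B, {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    methrisk::roc_auc(scores[idx], y[idx])
  })
  quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

# dense Henderson mixed-model equations for y = X b + u + e,
# u ~ N(0, s2u * A), e ~ N(0, s2e * I)
mme_solve <- function(y, X, A, s2u, s2e) {
  n <- length(y)
  Ainv <- solve(A)
  lhs <- rbind(cbind(crossprod(X) / s2e, t(X) / s2e),
               cbind(X / s2e, diag(n) / s2e + Ainv / s2u))
  rhs <- c(crossprod(X, y) / s2e, y / s2e)
  sol <- solve(lhs, rhs)
  list(beta = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

# dense restricted log-likelihood, written independently of the package
# internals (determinant() + solve() instead of Cholesky identities)
dense_reml_loglik <- function(y, A, X, s2u, s2e) {
  V <- s2u * A + diag(s2e, length(y))
  Vinv <- solve(V)
  XtViX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtViX) %*% t(X) %*% Vinv
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y))
}

# genomic inflation factor (median-based)
inflation_factor <- function(p) {
  median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

# small standardized-probe fixture: independent beta-like probes
make_probe_fixture <- function(n, m, seed, noise_sd = 0.1) {
  set.seed(seed)
  mu <- runif(m, 0.2, 0.8)
  beta <- matrix(rep(mu, each = n), n, m) + matrix(rnorm(n * m, 0, noise_sd), n, m)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sprintf("s%03d", seq_len(n)), sprintf("cg%05d", seq_len(m)))
  beta
}

random_annotation <- function(probe_ids, seed = 1) {
  set.seed(seed)
  data.frame(probe_id = probe_ids,
             chrom = sample(as.character(1:22), length(probe_ids), TRUE),
             pos = sample.int(2.8e8, length(probe_ids), replace = TRUE),
             stringsAsFactors = FALSE)
}
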