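# Brute-force oracles, computed by routes independent of the package's
# chol/backsolve implementation.

# dense model covariance assembled directly from the grouping maps
oracle_V <- function(design, Cm, theta) {
  n <- design$n_obs
  Zs <- outer(design$species, seq_len(design$n_species), "==") * 1
  Zt <- outer(design$study, seq_len(design$n_studies), "==") * 1
  theta[["phylo"]] * Zs %*% Cm %*% t(Zs) +
    theta[["species"]] * Zs %*% t(Zs) +
    theta[["study"]] * Zt %*% t(Zt) +
    theta[["unit"]] * diag(n) +
    diag(design$v, n)
}

# REML loglik as the multivariate-normal log density of an orthonormal
# basis of error contrasts K'y, K spanning the null space of X'
oracle_reml_loglik <- function(design, Cm, theta) {
  V <- oracle_V(design, Cm, theta)
  X <- design$X
  K <- qr.Q(qr(X), complete = TRUE)[, -(seq_len(ncol(X))), drop = FALSE]
  W <- t(K) %*% V %*% K
  yk <- drop(t(K) %*% design$y)
  m <- length(yk)
  ld <- determinant(W, logarithm = TRUE)$modulus[1]
  -0.5 * (m * log(2 * pi) + ld + drop(t(yk) %*% solve(W, yk)))
}

# GLS coefficients by direct inversion
oracle_gls_beta <- function(design, Cm, theta) {
  V <- oracle_V(design, Cm, theta)
  X <- design$X
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% design$y))
}
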