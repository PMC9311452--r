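# Shared fixtures and dense oracles.  The oracles go through base R dense
# linear algebra on the assembled (I-H), R blocks or the full covariance --
# independent of the tree-structured computation paths they check.

toy_locs <- function(n, q = 2L, seed = 1) {
  set.seed(seed)
  expanded_locs(cbind(runif(n), runif(n)), sample(seq_len(q), n, TRUE), q = q)
}

random_params <- function(q = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov_params(sigma1 = runif(q, -2, 2), sigma2 = runif(q, 0.3, 1.5),
             phi_i = runif(q, 0.5, 4),
             delta = {
               d <- matrix(0, q, q)
               d[lower.tri(d)] <- runif(q * (q - 1) / 2, 0.1, 2)
               d + t(d)
             },
             alpha = runif(1, 0.5, 2), beta_cov = runif(1, 0.5, 2),
             phi = runif(1, 1, 8))
}

# Dense (I - H) and blockdiag R from the node factors.
dense_HR <- function(dag, fac) {
  n <- length(dag$eta)
  H <- matrix(0, n, n)
  R <- matrix(0, n, n)
  for (i in seq_along(dag$level)) {
    li <- dag$node_locs[[i]]
    pl <- unlist(dag$node_locs[dag$parents[[i]]])
    if (length(pl) > 0) H[li, pl] <- fac[[i]]$H
    R[li, li] <- fac[[i]]$R
  }
  list(H = H, R = R)
}

dense_precision_oracle <- function(dag, fac) {
  hr <- dense_HR(dag, fac)
  n <- nrow(hr$H)
  t(diag(n) - hr$H) %*% solve(hr$R) %*% (diag(n) - hr$H)
}

dense_ctilde_oracle <- function(dag, fac) {
  solve(dense_precision_oracle(dag, fac))
}

dense_logdens_oracle <- function(w, dag, fac) {
  Q <- dense_precision_oracle(dag, fac)
  n <- length(w)
  as.numeric(-0.5 * (n * log(2 * pi) - determinant(Q)$modulus +
                       t(w) %*% Q %*% w))
}

# Gaussian KL(N(0, C) || N(0, Ct)) in nats.
gauss_kl <- function(C, Ct) {
  k <- nrow(C)
  0.5 * (sum(diag(solve(Ct, C))) - k +
           as.numeric(determinant(Ct)$modulus - determinant(C)$modulus))
}

# Build a small dag and return it with factors and a parameter draw.
toy_fixture <- function(n = 24, M = 2, depth = M, per_level = 4,
                        branching = 2, seed = 1, q = 2L, ...) {
  locs <- toy_locs(n, q = q, seed = seed)
  th <- random_params(q = q, seed = seed + 100)
  dag <- spamtree_dag(locs, M = M, depth = depth,
                      per_level_size = per_level, branching = branching, ...)
  list(locs = locs, th = th, dag = dag,
       fac = node_conditionals(dag, th))
}
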