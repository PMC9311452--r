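# Block factorisation (I - L)' D (I - L), block triangular inversion, and
# the integrated likelihood, all against dense oracles on toy instances.

dense_of <- function(bc, dag) {
  n <- length(dag$eta)
  Ld <- bm_dense(bc$L, symmetric = FALSE)
  Dd <- matrix(0, n, n)
  for (k in seq_along(bc$D)) {
    Dd[dag$node_locs[[k]], dag$node_locs[[k]]] <- bc$D[[k]]
  }
  t(diag(n) - Ld) %*% Dd %*% (diag(n) - Ld)
}

test_that("identity factorises trivially", {
  fx <- toy_fixture(16, M = 2, depth = 2, per_level = 4, seed = 101)
  blocks <- list()
  for (i in seq_along(fx$dag$level)) {
    blocks[[treedgp:::bm_key(i, i)]] <- diag(length(fx$dag$node_locs[[i]]))
  }
  bc <- block_cholesky(block_matrix(fx$dag, blocks))
  expect_true(all(vapply(seq_along(bc$D), function(k)
    isTRUE(all.equal(bc$D[[k]], diag(length(fx$dag$node_locs[[k]])))),
    logical(1))))
  expect_true(all(vapply(bc$L$blocks, function(b) max(abs(b)) < 1e-12,
                         logical(1))))
  B <- block_tri_inverse(bc$L)
  expect_equal(bm_dense(B, symmetric = FALSE), diag(16))
})

test_that("the treed precision factorises and reconstructs exactly", {
  for (cfg in list(c(2, 2), c(3, 1), c(3, 3))) {
    fx <- toy_fixture(24, M = cfg[1], depth = cfg[2], per_level = 3,
                      seed = 110 + cfg[2])
    Lam <- precision_block_matrix(fx$dag, fx$fac)
    bc <- block_cholesky(Lam)
    expect_lt(max(abs(dense_of(bc, fx$dag) - bm_dense(Lam))) /
                max(abs(bm_dense(Lam))), 1e-8)
    # D blocks are PD
    for (k in seq_along(bc$D)) {
      expect_gt(min(eigen(bc$D[[k]], symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
    # L shares H's sparsity pattern: blocks only at (node, parent)
    for (key in names(bc$L$blocks)) {
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      expect_true(ij[2] %in% fx$dag$parents[[ij[1]]])
    }
    # adding a block-diagonal matrix keeps the pattern factorisable
    ed <- runif(24, 0.2, 3)
    Lam2 <- precision_block_matrix(fx$dag, fx$fac, extra_diag = ed)
    bc2 <- block_cholesky(Lam2)
    expect_lt(max(abs(dense_of(bc2, fx$dag) - bm_dense(Lam2))) /
                max(abs(bm_dense(Lam2))), 1e-8)
  }
})

test_that("block triangular inversion matches the dense inverse", {
  fx <- toy_fixture(21, M = 3, depth = 3, per_level = 3, seed = 121)
  # random conforming strictly-lower L with H's pattern
  set.seed(122)
  blocks <- list()
  for (i in seq_along(fx$dag$level)) {
    for (j in fx$dag$parents[[i]]) {
      blocks[[treedgp:::bm_key(i, j)]] <-
        matrix(rnorm(length(fx$dag$node_locs[[i]]) *
                       length(fx$dag$node_locs[[j]]), sd = 0.4),
               length(fx$dag$node_locs[[i]]),
               length(fx$dag$node_locs[[j]]))
    }
  }
  L <- block_matrix(fx$dag, blocks)
  B <- block_tri_inverse(L)
  n <- 21
  Ld <- bm_dense(L, symmetric = FALSE)
  Bd <- bm_dense(B, symmetric = FALSE)
  expect_lt(max(abs((diag(n) - Ld) %*% Bd - diag(n))), 1e-10)
  expect_equal(Bd, solve(diag(n) - Ld), tolerance = 1e-9)
  # block lower triangular: entries only on ancestor pairs
  for (key in names(B$blocks)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    expect_true(ij[2] <= ij[1])
  }
})

test_that("non-conforming inputs are rejected, not densified", {
  fx <- toy_fixture(18, M = 2, depth = 2, per_level = 4, seed = 131)
  Lam <- precision_block_matrix(fx$dag, fx$fac)
  # inject a block between two structurally-independent leaves
  leaves <- which(fx$dag$kind == "leaf")
  if (length(leaves) >= 2) {
    i <- leaves[2]; j <- leaves[1]
    Lam$blocks[[treedgp:::bm_key(i, j)]] <-
      matrix(0.5, length(fx$dag$node_locs[[i]]),
             length(fx$dag$node_locs[[j]]))
    expect_error(block_cholesky(Lam), "pattern")
  }
})

test_that("integrated likelihood equals the dense marginal likelihood", {
  set.seed(141)
  n <- 36
  locs <- toy_locs(n, seed = 141)
  th <- random_params(seed = 241)
  y <- rnorm(n, 0.4)
  obs <- runif(n) < 0.75
  dat <- spamtree_data(locs$coords, locs$var, ifelse(obs, y, NA),
                       X = cbind(1, locs$coords[, 1]))
  tau2 <- c(0.25, 0.6)
  beta <- c(0.3, -0.2)
  for (cfg in list(c(1, 1), c(2, 2), c(3, 1))) {
    dag <- spamtree_dag(dat$locs, M = cfg[1], depth = cfg[2],
                        per_level_size = if (cfg[1] == 1) n else 5,
                        branching = 2, candidates = which(obs))
    fac <- node_conditionals(dag, th)
    got <- integrated_likelihood(dat, beta, tau2, th, dag, fac)
    Ct <- dense_ctilde_oracle(dag, fac)
    S <- Ct[obs, obs] + diag(tau2[locs$var[obs]])
    r <- y[obs] - (cbind(1, locs$coords[, 1]) %*% beta)[obs]
    want <- -0.5 * (sum(obs) * log(2 * pi) + determinant(S)$modulus +
                      t(r) %*% solve(S, r))
    expect_equal(got, as.numeric(want), tolerance = 1e-8)
  }
})

test_that("huge nuggets wash out the latent field", {
  set.seed(151)
  n <- 20
  locs <- toy_locs(n, seed = 151)
  th <- random_params(seed = 251)
  y <- rnorm(n)
  dat <- spamtree_data(locs$coords, locs$var, y)
  dag <- spamtree_dag(locs, M = 2, depth = 2, per_level_size = 4,
                      branching = 2)
  tau2 <- c(1e8, 1e8)
  got <- integrated_likelihood(dat, NULL, tau2, th, dag)
  want <- sum(dnorm(y, 0, sqrt(1e8), log = TRUE))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("integrated likelihood is invariant to within-level node order", {
  # two identical trees built from the same partition, with the node ids of
  # two same-level branches swapped by relabelling
  fx <- toy_fixture(24, M = 2, depth = 2, per_level = 4, seed = 161)
  dag <- fx$dag
  lvl <- which(dag$level == 1 & dag$kind == "branch")
  expect_gte(length(lvl), 2)
  perm <- seq_along(dag$level)
  perm[lvl[1]] <- lvl[2]
  perm[lvl[2]] <- lvl[1]
  inv <- order(perm)
  dag2 <- dag
  dag2$level <- dag$level[perm]
  dag2$kind <- dag$kind[perm]
  dag2$node_locs <- dag$node_locs[perm]
  dag2$tile_parent <- ifelse(is.na(dag$tile_parent[perm]), NA,
                             inv[dag$tile_parent[perm]])
  dag2$parents <- lapply(dag$parents[perm], function(p) sort(inv[p]))
  dag2$children <- lapply(dag$children[perm], function(p) sort(inv[p]))
  dag2$eta <- inv[dag$eta]
  dag2$cache <- new.env(parent = emptyenv())
  expect_true(validate_dag(dag2))
  set.seed(2)
  y <- rnorm(24)
  dat <- spamtree_data(fx$locs$coords, fx$locs$var, y)
  tau2 <- c(0.5, 0.5)
  expect_equal(integrated_likelihood(dat, NULL, tau2, fx$th, dag),
               integrated_likelihood(dat, NULL, tau2, fx$th, dag2),
               tolerance = 1e-9)
})
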