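# Gibbs sampler components: full conditionals against dense oracles,
# reproducibility, and posterior prediction.

test_that("fixed-effect conditional has the stated moments", {
  set.seed(301)
  n <- 12
  locs <- toy_locs(n, seed = 301)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, 1)
  dat <- spamtree_data(locs$coords, locs$var, y, X = X)
  w <- rnorm(n)
  tau2 <- c(0.4, 0.8)
  prior <- prior_spec(2, v_beta = 4)
  dinv <- 1 / tau2[locs$var]
  prec <- diag(1 / 4, 2) + crossprod(X * sqrt(dinv))
  mu <- solve(prec, crossprod(X, dinv * (y - w)))
  U <- chol(prec)
  set.seed(9)
  draw <- sample_beta(dat, w, tau2, prior)
  set.seed(9)
  want <- as.numeric(mu + backsolve(U, rnorm(2)))
  expect_equal(draw, want, tolerance = 1e-10)
  # flat-prior limit: mean is the GLS estimate
  priorf <- prior_spec(2, v_beta = 1e8)
  gls <- solve(crossprod(X * sqrt(dinv)), crossprod(X, dinv * (y - w)))
  set.seed(11); d1 <- sample_beta(dat, w, tau2, priorf)
  set.seed(11)
  Uf <- chol(diag(1e-8, 2) + crossprod(X * sqrt(dinv)))
  expect_equal(d1, as.numeric(gls + backsolve(Uf, rnorm(2))),
               tolerance = 1e-6)
  # determinism under a seed
  set.seed(13); a <- sample_beta(dat, w, tau2, prior)
  set.seed(13); b <- sample_beta(dat, w, tau2, prior)
  expect_identical(a, b)
})

test_that("nugget conditional parameters follow the residuals", {
  set.seed(311)
  n <- 40
  locs <- toy_locs(n, seed = 311)
  prior <- prior_spec(2, a_tau = 3, b_tau = 2)
  # zero residuals: posterior reduces to IG(a + N/2, b)
  w <- rnorm(n)
  dat0 <- spamtree_data(locs$coords, locs$var, w)
  n1 <- sum(locs$var == 1)
  set.seed(5); d <- sample_tau2(dat0, NULL, w, prior)
  set.seed(5)
  want1 <- 1 / rgamma(1, 3 + n1 / 2, rate = 2)
  expect_equal(d[1], want1)
  # constant residuals c: rate b + N c^2 / 2
  cshift <- 0.7
  datc <- spamtree_data(locs$coords, locs$var, w + cshift)
  set.seed(6); dc <- sample_tau2(datc, NULL, w, prior)
  set.seed(6)
  expect_equal(dc[1], 1 / rgamma(1, 3 + n1 / 2, rate = 2 + n1 * cshift^2 / 2))
  # an outcome with no observations draws from the prior
  y2 <- ifelse(locs$var == 2, NA, w)
  dat2 <- spamtree_data(locs$coords, locs$var, y2)
  set.seed(7)
  d2 <- sample_tau2(dat2, NULL, w, prior)
  expect_true(d2[2] > 0)
  # consistency: the posterior mean concentrates at the truth
  set.seed(317)
  nbig <- 1e4
  locsb <- expanded_locs(cbind(runif(nbig), runif(nbig)),
                         rep(1L, nbig), q = 1)
  wb <- rnorm(nbig)
  yb <- wb + rnorm(nbig, sd = sqrt(0.3))
  datb <- spamtree_data(locsb$coords, locsb$var, yb)
  draws <- replicate(50, sample_tau2(datb, NULL, wb, prior_spec(1)))
  expect_lt(abs(mean(draws) - 0.3), 0.03)
})

test_that("latent full conditionals match dense joint conditioning", {
  set.seed(321)
  n <- 26
  locs <- toy_locs(n, seed = 321)
  th <- random_params(seed = 421)
  y <- rnorm(n)
  obs <- runif(n) < 0.6
  # a node with every outcome missing and no children reduces to the prior
  dat <- spamtree_data(locs$coords, locs$var, ifelse(obs, y, NA))
  tau2 <- c(0.3, 0.7)
  for (d in c(1, 3)) {
    dag <- spamtree_dag(locs, M = 3, depth = d, per_level_size = 3,
                        branching = 2, candidates = which(obs))
    fac <- node_conditionals(dag, th)
    Q <- dense_precision_oracle(dag, fac)
    w <- rnorm(n)
    dinv <- ifelse(obs, 1 / tau2[locs$var], 0)
    for (i in c(1, 2, length(dag$level))) {
      li <- dag$node_locs[[i]]
      set.seed(77)
      draw <- sample_w_node(i, dag, fac, dat, w, NULL, tau2)
      P <- Q[li, li] + diag(dinv[li], length(li))
      b <- -Q[li, -li, drop = FALSE] %*% w[-li] +
        ifelse(obs[li], dinv[li] * y[li], 0)
      U <- chol(P)
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      set.seed(77)
      want <- as.numeric(mu + backsolve(U, rnorm(length(li))))
      expect_equal(draw, want, tolerance = 1e-8)
    }
    # a leaf whose outcomes are all missing and without children: the full
    # conditional is the prior conditional N(H w_par, R)
    leaf <- which(dag$kind == "leaf")[1]
    li <- dag$node_locs[[leaf]]
    dat_miss <- spamtree_data(locs$coords, locs$var,
                              replace(ifelse(obs, y, NA), li, NA))
    set.seed(78)
    draw <- sample_w_node(leaf, dag, fac, dat_miss, w, NULL, tau2)
    pl <- treedgp:::parent_locs(dag, leaf)
    mu <- as.numeric(fac[[leaf]]$H %*% w[pl])
    set.seed(78)
    want <- mu + as.numeric(backsolve(chol(fac[[leaf]]$Rinv),
                                      rnorm(length(li))))
    expect_equal(draw, want, tolerance = 1e-7)
  }
})

test_that("full-loading rows condition on all latent processes at a site", {
  set.seed(331)
  ns <- 14
  sites <- cbind(runif(ns), runif(ns))
  Z <- cbind(rnorm(ns), rnorm(ns))
  y <- rnorm(ns)
  dat <- spamtree_data(sites, rep(1L, ns), y, Z = Z, q = 2)
  expect_false(dat$diagonal)
  expect_equal(length(dat$locs), 2 * ns)
  th <- random_params(seed = 431)
  dag <- spamtree_dag(dat$locs, M = 2, depth = 2, per_level_size = 5,
                      branching = 2,
                      candidates = treedgp:::reference_candidates(dat))
  fac <- node_conditionals(dag, th)
  Q <- dense_precision_oracle(dag, fac)
  tau2 <- c(0.5, 0.5)
  w <- rnorm(2 * ns)
  # dense oracle: A maps w to observed rows
  A <- matrix(0, ns, 2 * ns)
  for (r in seq_len(ns)) A[r, dat$row_w[[r]]$w_idx] <- dat$row_w[[r]]$coef
  dinv <- 1 / tau2[dat$outcome]
  for (i in c(1, length(dag$level))) {
    li <- dag$node_locs[[i]]
    P <- Q[li, li] + crossprod(A[, li] * sqrt(dinv))
    b <- -Q[li, -li, drop = FALSE] %*% w[-li] +
      crossprod(A[, li], dinv * (y - A[, -li] %*% w[-li]))
    U <- chol(P)
    mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
    set.seed(79)
    draw <- sample_w_node(i, dag, fac, dat, w, NULL, tau2)
    set.seed(79)
    want <- as.numeric(mu + backsolve(U, rnorm(length(li))))
    expect_equal(draw, want, tolerance = 1e-8)
  }
})

test_that("identical-density proposals are always accepted", {
  set.seed(341)
  st <- ram_step(z = c(0, 0), logpost = function(z) 0, ld = 0,
                 S = diag(0.5, 2), iter = 1, adapt = FALSE)
  expect_true(st$accepted)
  expect_equal(st$alpha, 1)
})

test_that("theta updates move the chain and respect the box", {
  fx <- toy_fixture(20, M = 2, depth = 2, per_level = 4, seed = 351)
  prior <- prior_spec(2)
  set.seed(352)
  w <- rnorm(20)
  params <- fx$th
  rs <- NULL
  acc <- 0
  for (k in 1:30) {
    up <- update_theta(w, fx$dag, params, prior, ram_state = rs)
    params <- up$params
    rs <- up$ram_state
    acc <- acc + up$accepted
    x <- flatten_params(params)
    expect_true(all(x >= prior$theta$lower - 1e-12))
    expect_true(all(x <= prior$theta$upper + 1e-12))
  }
  expect_gt(acc, 0)
})

test_that("zero-iteration runs return the initial state", {
  set.seed(361)
  n <- 16
  locs <- toy_locs(n, seed = 361)
  y <- rnorm(n)
  dat <- spamtree_data(locs$coords, locs$var, y)
  dag <- spamtree_dag(locs, M = 1, depth = 1, per_level_size = n)
  fit <- run_gibbs(dat, dag, prior_spec(2),
                   mcmc_config(n_iter = 0, seed = 1, init = "median"))
  expect_equal(nrow(fit$theta), 1)
  expect_equal(fit$w[1, ], rep(0, n))
  expect_equal(fit$tau2[1, ], c(1, 1))
})

test_that("fixed seeds reproduce chains exactly", {
  set.seed(371)
  n <- 30
  locs <- toy_locs(n, seed = 371)
  y <- rnorm(n)
  dat <- spamtree_data(locs$coords, locs$var, ifelse(runif(n) < 0.8, y, NA))
  dag <- spamtree_dag(locs, M = 2, depth = 2, per_level_size = 5,
                      branching = 2)
  mc <- mcmc_config(n_iter = 60, burn = 20, thin = 1, seed = 99)
  f1 <- run_gibbs(dat, dag, prior_spec(2), mc)
  f2 <- run_gibbs(dat, dag, prior_spec(2), mc)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$tau2, f2$tau2)
})

test_that("conjugate posterior of beta is recovered with theta fixed", {
  set.seed(381)
  n <- 20
  locs <- expanded_locs(cbind(runif(n), runif(n)), rep(1L, n), q = 1)
  th <- cov_params(1.2, 0.5, 2, matrix(0, 1, 1), 1, 1, 3)
  C <- cov_matrix(locs, params = th, jitter = 0)
  tau2 <- 0.3
  beta_true <- 1.5
  X <- matrix(1, n, 1)
  y <- as.numeric(X %*% beta_true + t(chol(C)) %*% rnorm(n) +
                    rnorm(n, sd = sqrt(tau2)))
  dat <- spamtree_data(locs$coords, locs$var, y, X = X)
  dag <- spamtree_dag(locs, M = 1, depth = 1, per_level_size = n)
  v_beta <- 25
  fit <- run_gibbs(dat, dag, prior_spec(1, v_beta = v_beta),
                   mcmc_config(n_iter = 20000, burn = 2000, thin = 2,
                               seed = 4, fix_theta = th, fix_tau2 = tau2,
                               keep_w = FALSE))
  S <- C + diag(tau2, n)
  prec <- 1 / v_beta + t(X) %*% solve(S, X)
  mu <- solve(prec, t(X) %*% solve(S, y))
  post_mean <- mean(fit$beta)
  post_sd <- sqrt(1 / prec)
  # Monte-Carlo tolerance: a few standard errors of a correlated chain
  expect_lt(abs(post_mean - mu), 4 * post_sd / sqrt(200))
})

test_that("within-level node relabelling leaves the posterior unchanged", {
  set.seed(391)
  n <- 40
  locs <- toy_locs(n, seed = 391)
  y <- rnorm(n)
  dat <- spamtree_data(locs$coords, locs$var, ifelse(runif(n) < 0.8, y, NA))
  dag <- spamtree_dag(locs, M = 2, depth = 2, per_level_size = 6,
                      branching = 2)
  lvl <- which(dag$level == 1 & dag$kind == "branch")
  perm <- seq_along(dag$level)
  perm[lvl[1]] <- lvl[2]; perm[lvl[2]] <- lvl[1]
  inv <- order(perm)
  dag2 <- dag
  dag2$level <- dag$level[perm]; dag2$kind <- dag$kind[perm]
  dag2$node_locs <- dag$node_locs[perm]
  dag2$tile_parent <- ifelse(is.na(dag$tile_parent[perm]), NA,
                             inv[dag$tile_parent[perm]])
  dag2$parents <- lapply(dag$parents[perm], function(p) sort(inv[p]))
  dag2$children <- lapply(dag$children[perm], function(p) sort(inv[p]))
  dag2$eta <- inv[dag$eta]
  dag2$cache <- new.env(parent = emptyenv())
  mc <- mcmc_config(n_iter = 800, burn = 200, thin = 1, seed = 17,
                    fix_theta = random_params(seed = 392))
  f1 <- run_gibbs(dat, dag, prior_spec(2), mc)
  f2 <- run_gibbs(dat, dag2, prior_spec(2), mc)
  # same model, different within-level update order: marginal moments agree
  loc_probe <- which(!dat$observed)[1]
  m1 <- f1$w[, loc_probe]; m2 <- f2$w[, loc_probe]
  expect_lt(abs(mean(m1) - mean(m2)) / sd(m1), 0.35)
  # subsample to near-independent draws before the distribution comparison
  keep <- seq(1, length(m1), by = 10)
  ks <- suppressWarnings(ks.test(m1[keep], m2[keep]))
  expect_gt(ks$p.value, 0.01)
})

test_that("prediction draws follow the posterior and kriging geometry", {
  set.seed(401)
  n <- 50
  locs <- toy_locs(n, seed = 401)
  # a long-range field, so that kriging variance is visibly reduced near
  # the data and saturates only far outside it
  th <- cov_params(c(1.5, -1), c(0.5, 0.5), c(0.8, 1.2), 0.5, 1, 1, 1.5)
  C <- cov_matrix(locs, params = th)
  w_true <- as.numeric(t(chol(C)) %*% rnorm(n))
  y <- w_true + rnorm(n, sd = 0.3)
  obs <- runif(n) < 0.7
  dat <- spamtree_data(locs$coords, locs$var, ifelse(obs, y, NA))
  dag <- spamtree_dag(locs, M = 2, depth = 2, per_level_size = 8,
                      branching = 2, candidates = which(obs))
  fit <- run_gibbs(dat, dag, prior_spec(2),
                   mcmc_config(n_iter = 1000, burn = 200, thin = 1, seed = 7))
  pred <- predict(fit)
  expect_equal(nrow(pred), n)
  # in-sample branch: predictive mean tracks the posterior mean of w
  wbar <- colMeans(fit$w)
  expect_gt(cor(pred$mean, wbar), 0.99)
  expect_true(all(pred$lwr <= pred$mean & pred$mean <= pred$upr))
  # out-of-tree predictions: intervals widen with distance from the data
  transect <- cbind(seq(0.5, 3, length.out = 6), 0.5)
  ndf <- data.frame(x = transect[, 1], y = transect[, 2], outcome = 1L)
  pr <- predict(fit, newdata = ndf)
  widths <- pr$upr - pr$lwr
  expect_gt(widths[6], widths[1])
  expect_gt(mean(widths[5:6]), 1.05 * widths[1])
})
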