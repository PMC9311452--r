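# Gibbs sampler for the latent treed Gaussian process regression:
# full conditionals for the fixed effects, nuggets and latent field, with
# robust-adaptive-Metropolis updates of the covariance parameters.

row_fitted_w <- function(data, w) {
  if (data$diagonal) {
    data$z * w
  } else {
    vapply(seq_len(data$n_rows), function(i) {
      rw <- data$row_w[[i]]
      sum(rw$coef * w[rw$w_idx])
    }, numeric(1))
  }
}

v_beta_matrix <- function(prior, p) {
  if (is.matrix(prior$v_beta)) prior$v_beta else diag(prior$v_beta, p)
}

#' Sample the fixed effects from their full conditional
#'
#' Gaussian with covariance \eqn{(V_\beta^{-1} + X' D_n^{-1} X)^{-1}} and
#' mean \eqn{\Sigma^* X' D_n^{-1} (y - Zw)}, over the observed rows.
#'
#' @param data a [spamtree_data()] object with a design matrix `X`.
#' @param w current latent field.
#' @param tau2 current nuggets (length q).
#' @param prior a [prior_spec()].
#' @return A draw of beta.
#' @export
sample_beta <- function(data, w, tau2, prior) {
  if (is.null(data$X)) stop("data has no fixed-effect design")
  obs <- data$observed
  X <- data$X[obs, , drop = FALSE]
  dinv <- 1 / tau2[data$outcome[obs]]
  r <- data$y[obs] - row_fitted_w(data, w)[obs]
  p <- ncol(X)
  prec <- chol2inv(chol(v_beta_matrix(prior, p))) + crossprod(X * sqrt(dinv))
  U <- chol(prec)
  mu <- backsolve(U, backsolve(U, crossprod(X, dinv * r), transpose = TRUE))
  as.numeric(mu + backsolve(U, stats::rnorm(p)))
}

#' Sample the nuggets from their full conditionals
#'
#' Per outcome j, inverse-gamma with shape \eqn{a_\tau + N_j/2} and rate
#' \eqn{b_\tau + E_j'E_j/2} where \eqn{E_j} are the observed residuals.
#' Outcomes with no observations fall back to a prior draw.
#'
#' @param data a [spamtree_data()].
#' @param beta current fixed effects (`NULL` when there are none).
#' @param w current latent field.
#' @param prior a [prior_spec()].
#' @return Length-q vector of nugget draws.
#' @export
sample_tau2 <- function(data, beta, w, prior) {
  fit <- row_fitted_w(data, w)
  if (!is.null(data$X) && !is.null(beta)) fit <- fit + data$X %*% beta
  r <- data$y - fit
  out <- numeric(data$q)
  for (j in seq_len(data$q)) {
    sel <- data$observed & data$outcome == j
    nj <- sum(sel)
    if (nj == 0L) {
      out[j] <- 1 / stats::rgamma(1, prior$a_tau, rate = prior$b_tau)
    } else {
      out[j] <- 1 / stats::rgamma(1, prior$a_tau + nj / 2,
                                  rate = prior$b_tau + 0.5 * sum(r[sel]^2))
    }
  }
  out
}

# Column offset of parent node `p` inside node i's H
parent_offset <- function(dag, i, p) {
  ps <- dag$parents[[i]]
  pos <- match(p, ps)
  if (is.na(pos)) stop("node ", p, " is not a parent of node ", i)
  if (pos == 1L) 0L else sum(lengths(dag$node_locs[ps[seq_len(pos - 1L)]]))
}

#' Sample one node of the latent field from its full conditional
#'
#' Reference implementation of the per-node full conditional
#' \eqn{N(\mu_i, \Sigma_i)} with
#' \eqn{\Sigma_i^{-1} = Z_i' \tilde D_i^{-1} Z_i + R_i^{-1} + F_i^c} where
#' the child messages are \eqn{F_i^c = \sum_{j \in Ch[i]} H_{i\to j}'
#' R_j^{-1} H_{i\to j}} and \eqn{m_i^c = \sum_j H_{i\to j}' R_j^{-1}
#' \tilde w_j}, \eqn{\tilde w_j = w_j - H_{\setminus i\to j}
#' w_{[\setminus i \to j]}}.  Unobserved outcomes contribute nothing (the
#' zero-filled noise convention).  Supports full loading matrices; the
#' compiled sweep used by [run_gibbs()] covers the diagonal-loading case.
#'
#' @param i node id.
#' @param dag a `treed_dag`.
#' @param factors output of [node_conditionals()].
#' @param data a [spamtree_data()].
#' @param w current latent field (updated values of other nodes are read).
#' @param beta current fixed effects (or `NULL`).
#' @param tau2 current nuggets.
#' @return The new draw for `w` restricted to node i's locations.
#' @export
sample_w_node <- function(i, dag, factors, data, w, beta, tau2) {
  locs_i <- dag$node_locs[[i]]
  n_i <- length(locs_i)
  f <- factors[[i]]
  P <- f$Rinv
  pl <- parent_locs(dag, i)
  b <- if (length(pl) > 0) f$Rinv %*% (f$H %*% w[pl]) else numeric(n_i)

  # data terms
  xb <- if (!is.null(data$X) && !is.null(beta)) as.numeric(data$X %*% beta)
        else rep(0, data$n_rows)
  if (data$diagonal) {
    rows <- locs_i[data$observed[locs_i]]
    for (r in rows) {
      k <- match(r, locs_i)
      di <- 1 / tau2[data$outcome[r]]
      P[k, k] <- P[k, k] + data$z[r]^2 * di
      b[k] <- b[k] + data$z[r] * di * (data$y[r] - xb[r])
    }
  } else {
    inset <- logical(length(w))
    inset[locs_i] <- TRUE
    for (r in which(data$observed)) {
      rw <- data$row_w[[r]]
      hit <- inset[rw$w_idx]
      if (!any(hit)) next
      a <- numeric(n_i)
      a[match(rw$w_idx[hit], locs_i)] <- rw$coef[hit]
      ytil <- data$y[r] - xb[r] -
        sum(rw$coef[!hit] * w[rw$w_idx[!hit]])
      di <- 1 / tau2[data$outcome[r]]
      P <- P + di * tcrossprod(a)
      b <- b + di * a * ytil
    }
  }

  # child messages
  for (cid in dag$children[[i]]) {
    fc <- factors[[cid]]
    off <- parent_offset(dag, cid, i)
    Hic <- fc$H[, off + seq_len(n_i), drop = FALSE]
    plc <- parent_locs(dag, cid)
    wtil <- w[dag$node_locs[[cid]]] - fc$H %*% w[plc] + Hic %*% w[locs_i]
    RinvH <- fc$Rinv %*% Hic
    P <- P + crossprod(Hic, RinvH)
    b <- b + crossprod(RinvH, wtil)
  }
  P <- 0.5 * (P + t(P))
  U <- chol(P)
  mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
  as.numeric(mu + backsolve(U, stats::rnorm(n_i)))
}

#' One Metropolis update of the covariance parameters
#'
#' Joint robust-adaptive-Metropolis step on the transformed parameter
#' vector, targeting either `p(w | theta)` (default, evaluated through the
#' treed factorisation) or the integrated likelihood `p(y | beta, theta,
#' tau)` (experimental).  The prior is flat on the transformed scale inside
#' its box; proposals outside the box are auto-rejected.
#'
#' @param w current latent field.
#' @param dag a `treed_dag`.
#' @param params current [cov_params()].
#' @param prior a [prior_spec()].
#' @param ram_state list with `S` (lower-triangular scale) and `iter`;
#'   `NULL` initialises `S = 0.1 I`.
#' @param adapt adapt the proposal scale this step?
#' @param route `"conditional"` or `"integrated"`.
#' @param data,beta,tau2 required for the integrated route.
#' @return List with `params`, `accepted`, `ram_state`.
#' @export
update_theta <- function(w, dag, params, prior, ram_state = NULL,
                         adapt = TRUE, route = c("conditional", "integrated"),
                         data = NULL, beta = NULL, tau2 = NULL) {
  route <- match.arg(route)
  tp <- prior$theta
  q <- dag$q
  z <- theta_to_z(params, tp)
  if (is.null(ram_state)) ram_state <- list(S = diag(0.1, length(z)), iter = 0L)
  ram_state$iter <- ram_state$iter + 1L
  logpost <- if (route == "conditional") {
    function(zz) log_density_w(w, dag, z_to_theta(zz, tp, q))
  } else {
    function(zz) integrated_likelihood(data, beta, tau2,
                                       z_to_theta(zz, tp, q), dag)
  }
  st <- ram_step(z, logpost, logpost(z), ram_state$S, iter = ram_state$iter,
                 adapt = adapt, z_lower = tp$z_lower, z_upper = tp$z_upper)
  ram_state$S <- st$S
  list(params = z_to_theta(st$z, tp, q), accepted = st$accepted,
       ram_state = ram_state)
}

#' MCMC configuration
#'
#' @param n_iter total Gibbs sweeps.
#' @param burn burn-in sweeps discarded (adaptation is frozen afterwards).
#' @param thin thinning interval for stored draws.
#' @param seed RNG seed for the whole run.
#' @param theta_update `"conditional"` (default) or `"integrated"`
#'   (experimental) likelihood for the covariance-parameter step.
#' @param init `"moments"` (default) starts the covariance parameters and
#'   nuggets at cheap method-of-moments values computed from the observed
#'   data (empirical variances split between the shared and independent
#'   components, spatial decay matched to the nearest-neighbour empirical
#'   correlation, cross-correlation sign for the shared scales);
#'   `"median"` starts at the prior medians.  Both starts are
#'   deterministic.
#' @param fix_theta optional [cov_params()] to hold fixed (no theta step).
#' @param fix_tau2 optional length-q nugget vector to hold fixed (no nugget
#'   step); useful for conjugate diagnostics.
#' @param interweave_tau add an ancillary (interweaving) Metropolis move for
#'   each nugget after its conjugate draw: holding the standardised
#'   residuals fixed, `tau` and the observed-location field move together
#'   against the treed prior density.  Dramatically improves nugget mixing
#'   when the nugget is small relative to the field's conditional
#'   variance; the conjugate draw alone then moves the nugget only
#'   diffusively.
#' @param keep_w store thinned draws of the latent field?
#' @param s0 initial RAM proposal scale.
#' @return A list of settings for [run_gibbs()].
#' @export
mcmc_config <- function(n_iter = 1000L, burn = floor(n_iter / 2), thin = 1L,
                        seed = 1L, theta_update = "conditional",
                        init = c("moments", "median"),
                        fix_theta = NULL, fix_tau2 = NULL,
                        interweave_tau = TRUE, keep_w = TRUE,
                        s0 = 0.1) {
  list(n_iter = as.integer(n_iter), burn = as.integer(burn),
       thin = as.integer(thin), seed = as.integer(seed),
       theta_update = theta_update, init = match.arg(init),
       fix_theta = fix_theta, fix_tau2 = fix_tau2,
       interweave_tau = interweave_tau, keep_w = keep_w, s0 = s0)
}

# Deterministic method-of-moments starting values: split each outcome's
# empirical variance between the shared and independent process components,
# take the shared-scale signs from the empirical cross-correlation, match
# the spatial decays to the nearest-neighbour empirical correlation of the
# densest outcome, and start the nuggets at a small fraction of the
# variance.  Everything is clipped into the prior box.
moments_init <- function(data, tp, q) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  v <- vapply(seq_len(q), function(j) {
    yj <- data$y[data$observed & data$outcome == j]
    if (length(yj) > 2) stats::var(yj) else 1
  }, numeric(1))
  # nearest-neighbour correlation of the densest outcome
  jd <- which.max(tabulate(data$outcome[data$observed], q))
  sel <- which(data$observed & data$outcome == jd)
  rho <- 0.5
  d_nn <- 0.05
  if (length(sel) > 20) {
    Xs <- data$locs$coords[sel, , drop = FALSE]
    ys <- data$y[sel] - mean(data$y[sel])
    nn <- vapply(seq_along(sel), function(i) {
      d2 <- (Xs[, 1] - Xs[i, 1])^2 + (Xs[, 2] - Xs[i, 2])^2
      d2[i] <- Inf
      which.min(d2)
    }, integer(1))
    d_nn <- stats::median(sqrt((Xs[, 1] - Xs[nn, 1])^2 +
                               (Xs[, 2] - Xs[nn, 2])^2))
    rho <- clip(mean(ys * ys[nn]) / stats::var(ys), 0.02, 0.98)
  }
  phi0 <- -log(rho) / max(d_nn, 1e-6)
  # cross-correlation sign from co-located / nearby outcome pairs
  sgn <- rep(1, q)
  if (q >= 2) {
    s1 <- which(data$observed & data$outcome == 1L)
    for (j in 2:q) {
      sj <- which(data$observed & data$outcome == j)
      if (length(s1) > 5 && length(sj) > 5) {
        Xj <- data$locs$coords[sj, , drop = FALSE]
        X1 <- data$locs$coords[s1, , drop = FALSE]
        near <- vapply(seq_along(sj), function(i) {
          which.min((X1[, 1] - Xj[i, 1])^2 + (X1[, 2] - Xj[i, 2])^2)
        }, integer(1))
        cc <- stats::cor(data$y[sj], data$y[s1][near])
        if (is.finite(cc) && cc < 0) sgn[j] <- -1
      }
    }
  }
  x <- flatten_params(cov_params(
    sigma1 = sgn * sqrt(0.45 * v), sigma2 = sqrt(0.5 * v),
    phi_i = rep(phi0, q),
    delta = matrix(as.numeric(row(diag(q)) != col(diag(q))), q, q),
    alpha = 1, beta_cov = 1, phi = phi0))
  x <- clip(x, tp$lower, tp$upper)
  list(theta = unflatten_params(x, q),
       tau2 = pmax(0.05 * v, 1e-4))
}

#' Run the Gibbs sampler
#'
#' Full sweep order: the latent field node-by-node in level order (nodes
#' within a level are conditionally independent given the other levels, so
#' any within-level order yields the same kernel), then the fixed effects,
#' the nuggets, and a joint RAM Metropolis step for the covariance
#' parameters.  Initial state: `w = 0`, `beta = 0`, `tau2 = 1`, covariance
#' parameters at their prior medians.
#'
#' @param data a [spamtree_data()].
#' @param dag a `treed_dag` over `data$locs`.
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @return A `spamtree_fit` with chains for `beta`, `tau2`, `theta` (natural
#'   scale), optionally `w`, the theta acceptance trace and the RAM scale
#'   diagonal trace.
#' @export
run_gibbs <- function(data, dag, prior, mcmc = mcmc_config()) {
  stopifnot(length(dag$eta) == length(data$locs))
  set.seed(mcmc$seed)
  q <- data$q
  tp <- prior$theta
  n_w <- length(data$locs)
  p <- if (is.null(data$X)) 0L else ncol(data$X)

  fixed <- !is.null(mcmc$fix_theta)
  mom <- if (identical(mcmc$init, "moments")) moments_init(data, tp, q)
         else NULL
  theta <- if (fixed) mcmc$fix_theta
           else if (!is.null(mom)) mom$theta
           else z_to_theta(ifelse(tp$transform == "log", log(tp$init),
                                  tp$init), tp, q)
  z <- pmin(pmax(theta_to_z(theta, tp), tp$z_lower), tp$z_upper)
  theta <- if (fixed) theta else z_to_theta(z, tp, q)
  ptr <- dag_ptr(dag)
  .dag_factors_update(ptr, unclass(theta), FALSE)
  fac <- if (data$diagonal) NULL else .dag_factors_list(ptr, FALSE)

  # latent field starts at the observed data under the moments start (the
  # nugget-free varying-intercept fit), at zero otherwise
  w <- rep(0, n_w)
  if (!is.null(mom) && data$diagonal) {
    obs0 <- data$observed & data$z != 0
    w[obs0] <- data$y[obs0] / data$z[obs0]
  }
  beta <- rep(0, p)
  tau2 <- if (!is.null(mcmc$fix_tau2)) mcmc$fix_tau2
          else if (!is.null(mom)) mom$tau2
          else rep(1, q)
  S <- diag(mcmc$s0, length(z))

  n_save <- if (mcmc$n_iter == 0L) 1L else
    max(0L, (mcmc$n_iter - mcmc$burn) %/% mcmc$thin)
  theta_chain <- matrix(NA_real_, n_save, length(z),
                        dimnames = list(NULL, tp$names))
  tau2_chain <- matrix(NA_real_, n_save, q)
  beta_chain <- if (p > 0) matrix(NA_real_, n_save, p) else NULL
  w_chain <- if (isTRUE(mcmc$keep_w)) matrix(NA_real_, n_save, n_w) else NULL
  accept <- logical(mcmc$n_iter)
  s_diag <- matrix(NA_real_, n_save, length(z))
  save_i <- 0L

  record <- function(k) {
    theta_chain[k, ] <<- flatten_params(theta)
    tau2_chain[k, ] <<- tau2
    if (p > 0) beta_chain[k, ] <<- beta
    if (!is.null(w_chain)) w_chain[k, ] <<- w
    s_diag[k, ] <<- diag(S)
  }
  if (mcmc$n_iter == 0L) record(1L)

  use_integrated <- identical(mcmc$theta_update, "integrated")
  for (it in seq_len(mcmc$n_iter)) {
    # latent field
    if (data$diagonal) {
      ytilde <- numeric(n_w)
      dinv <- numeric(n_w)
      obs <- data$observed
      xb <- if (p > 0) as.numeric(data$X %*% beta) else 0
      ytilde[obs] <- data$y[obs] - (if (p > 0) xb[obs] else 0)
      dinv[obs] <- 1 / tau2[data$outcome[obs]]
      w <- .dag_w_sweep(ptr, w, ytilde, dinv, data$z)
    } else {
      for (i in seq_along(dag$level)) {
        w[dag$node_locs[[i]]] <- sample_w_node(i, dag, fac, data, w, beta,
                                               tau2)
      }
    }
    # fixed effects and nuggets
    if (p > 0) beta <- sample_beta(data, w, tau2, prior)
    if (is.null(mcmc$fix_tau2)) {
      tau2 <- sample_tau2(data, beta, w, prior)
      ld_state <- NULL
      if (isTRUE(mcmc$interweave_tau) && data$diagonal) {
        # ancillary move: u = (y - x'b - z w)/tau fixed, tau and the
        # observed-location field move together; target is the treed prior
        # density of w times the inverse-gamma prior (log-scale proposal)
        xb <- if (p > 0) as.numeric(data$X %*% beta) else 0
        ld_cur <- .dag_log_density(ptr, w, FALSE)
        lpri <- function(t2) -prior$a_tau * log(t2) - prior$b_tau / t2
        for (j in seq_len(q)) {
          sel <- data$observed & data$outcome == j & data$z != 0
          if (!any(sel)) next
          yt <- (data$y[sel] - (if (p > 0) xb[sel] else 0)) / data$z[sel]
          u <- (yt - w[sel]) / sqrt(tau2[j])
          zp <- log(tau2[j]) + stats::rnorm(1, 0, 0.4)
          wprop <- w
          wprop[sel] <- yt - exp(zp / 2) * u
          ldp <- .dag_log_density(ptr, wprop, FALSE)
          la <- (ldp + lpri(exp(zp))) - (ld_cur + lpri(tau2[j]))
          if (log(stats::runif(1)) < la) {
            w <- wprop
            tau2[j] <- exp(zp)
            ld_cur <- ldp
          }
        }
        ld_state <- ld_cur
      }
    } else {
      ld_state <- NULL
    }
    # covariance parameters
    if (!fixed) {
      if (use_integrated) {
        logpost <- function(zz) {
          integrated_likelihood(data, beta, tau2, z_to_theta(zz, tp, q), dag)
        }
        ld <- logpost(z)
        st <- ram_step(z, logpost, ld, S, iter = it,
                       adapt = it <= mcmc$burn,
                       z_lower = tp$z_lower, z_upper = tp$z_upper)
        if (st$accepted) {
          z <- st$z
          theta <- z_to_theta(z, tp, q)
          .dag_factors_update(ptr, unclass(theta), FALSE)
          if (!data$diagonal) fac <- .dag_factors_list(ptr, FALSE)
        }
      } else {
        ld <- if (!is.null(ld_state)) ld_state
              else .dag_log_density(ptr, w, FALSE)
        logpost <- function(zz) {
          .dag_factors_update(ptr, unclass(z_to_theta(zz, tp, q)), TRUE)
          .dag_log_density(ptr, w, TRUE)
        }
        st <- ram_step(z, logpost, ld, S, iter = it,
                       adapt = it <= mcmc$burn,
                       z_lower = tp$z_lower, z_upper = tp$z_upper)
        if (st$accepted) {
          .dag_swap_slots(ptr)
          z <- st$z
          theta <- z_to_theta(z, tp, q)
          if (!data$diagonal) fac <- .dag_factors_list(ptr, FALSE)
        }
      }
      S <- st$S
      accept[it] <- st$accepted
    }
    if (!all(is.finite(w)) || !all(is.finite(tau2))) {
      stop("sampler diverged (non-finite state) at iteration ", it)
    }
    if (it > mcmc$burn && (it - mcmc$burn) %% mcmc$thin == 0L) {
      save_i <- save_i + 1L
      record(save_i)
    }
  }

  structure(list(theta = theta_chain, tau2 = tau2_chain, beta = beta_chain,
                 w = w_chain, accept = accept, ram_s_diag = s_diag,
                 dag = dag, data = data, prior = prior, mcmc = mcmc),
            class = "spamtree_fit")
}

#' @export
print.spamtree_fit <- function(x, ...) {
  cat(sprintf(paste0("<spamtree_fit> %d sweeps (%d saved), theta acceptance ",
                     "%.3f\n"), x$mcmc$n_iter, nrow(x$theta),
              mean(x$accept)))
  invisible(x)
}

#' Convenience wrapper: build the tree and run the sampler
#'
#' @param data a [spamtree_data()].
#' @param tree list of tree settings passed to [spamtree_dag()] (`M`,
#'   `depth`, `per_level_size`, `branching`, `n_roots`, `root_bias_var`,
#'   `same_variable_first`, `all_outcomes_colocated`, `granularity`).
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @return A `spamtree_fit`.
#' @export
spamtree_fit <- function(data, tree, prior = prior_spec(data$q),
                         mcmc = mcmc_config()) {
  dag <- do.call(spamtree_dag, c(list(locs = data$locs,
                                      candidates = reference_candidates(data)),
                                 tree))
  run_gibbs(data, dag, prior, mcmc)
}

#' Posterior predictive summaries
#'
#' For rows of the fitted data (`newdata = NULL`) every saved posterior draw
#' yields `y* = X beta + Z w + e`, `e ~ N(0, tau_j^2)`; for new
#' out-of-tree locations the latent value is first drawn from its
#' cherry-picked leaf conditional `N(H_l w_{[j]}, R_l)` per draw.  Summaries
#' are the predictive mean and the central 95% interval.
#'
#' @param object a `spamtree_fit` (needs stored `w` draws).
#' @param newdata optional data frame with columns `x`, `y`, `outcome` for
#'   new locations (treated as unobserved).
#' @param same_variable_first passed to the cherry-picking search for new
#'   locations.
#' @param level interval coverage level.
#' @param ... unused.
#' @return Data frame with `mean`, `lwr`, `upr` per row.
#' @export
predict.spamtree_fit <- function(object, newdata = NULL,
                                 same_variable_first = FALSE, level = 0.95,
                                 ...) {
  if (is.null(object$w)) stop("fit was run with keep_w = FALSE")
  a <- (1 - level) / 2
  nd <- nrow(object$theta)
  data <- object$data
  p <- if (is.null(data$X)) 0L else ncol(data$X)
  if (is.null(newdata)) {
    n <- data$n_rows
    draws <- matrix(NA_real_, nd, n)
    for (s in seq_len(nd)) {
      wfit <- row_fitted_w(data, object$w[s, ])
      if (p > 0) wfit <- wfit + as.numeric(data$X %*% object$beta[s, ])
      draws[s, ] <- wfit +
        stats::rnorm(n, 0, sqrt(object$tau2[s, data$outcome]))
    }
    out <- data.frame(x = data$locs$coords[, 1], y = data$locs$coords[, 2],
                      outcome = data$outcome, observed = data$observed)
    # for full-loading data the rows are the observation rows, not locations
    if (!data$diagonal) {
      out <- data.frame(outcome = data$outcome, observed = data$observed)
    }
  } else {
    dag <- object$dag
    coords <- as.matrix(newdata[, c("x", "y")])
    var <- as.integer(newdata$outcome)
    n <- nrow(coords)
    term <- assign_terminal(dag, coords, var, same_variable_first)
    draws <- matrix(NA_real_, nd, n)
    for (t in unique(term)) {
      sel <- which(term == t)
      path <- leaf_parent_path(dag, t)
      pl <- as.integer(unlist(dag$node_locs[path]))
      par_sub <- subset_locs(dag$locs, pl)
      new_sub <- expanded_locs(coords[sel, , drop = FALSE], var[sel],
                               q = dag$q)
      for (s in seq_len(nd)) {
        th <- unflatten_params(object$theta[s, ], dag$q)
        Cpar <- cov_matrix(par_sub, params = th)
        Clp <- cov_matrix(new_sub, par_sub, params = th)
        H <- Clp %*% chol2inv(chol(Cpar))
        mu <- as.numeric(H %*% object$w[s, pl])
        v <- pmax(cross_cov(new_sub, new_sub, th) - rowSums(H * Clp), 1e-12)
        wl <- stats::rnorm(length(sel), mu, sqrt(v))
        draws[s, sel] <- wl +
          stats::rnorm(length(sel), 0, sqrt(object$tau2[s, var[sel]]))
      }
    }
    out <- data.frame(x = coords[, 1], y = coords[, 2], outcome = var)
  }
  out$mean <- colMeans(draws)
  out$lwr <- apply(draws, 2, stats::quantile, probs = a)
  out$upr <- apply(draws, 2, stats::quantile, probs = 1 - a)
  out
}
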