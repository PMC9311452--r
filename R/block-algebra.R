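# Block-sparse factorisation utilities for matrices conforming to the treed
# DAG: any symmetric PD matrix with the precision's block-sparsity pattern
# can be written (I - L)' D (I - L) with L sharing H's pattern and D block
# diagonal, with no external sparse-matrix library.

bm_key <- function(i, j) paste0(i, "|", j)

#' Block matrix conforming to a treed DAG
#'
#' Light-weight container for symmetric block matrices with the precision's
#' sparsity pattern: only the diagonal blocks and the (node, parent) blocks
#' are stored (one triangle, keyed by node pair).
#'
#' @param dag a `treed_dag`.
#' @param blocks named list of matrices with names `"i|j"`, `i >= j` in
#'   canonical order.
#' @return A `block_matrix` object.
#' @export
block_matrix <- function(dag, blocks) {
  structure(list(dag = dag, blocks = blocks), class = "block_matrix")
}

bm_get <- function(bm, i, j) {
  b <- bm$blocks[[bm_key(i, j)]]
  if (!is.null(b)) return(b)
  b <- bm$blocks[[bm_key(j, i)]]
  if (!is.null(b)) return(t(b))
  NULL
}

#' Dense view of a block matrix (small problems)
#'
#' @param bm a [block_matrix()].
#' @param symmetric reflect stored blocks to the opposite triangle?
#' @return Dense matrix ordered by expanded-location id.
#' @export
bm_dense <- function(bm, symmetric = TRUE) {
  dag <- bm$dag
  n <- length(dag$eta)
  out <- matrix(0, n, n)
  for (key in names(bm$blocks)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    ri <- dag$node_locs[[ij[1]]]
    cj <- dag$node_locs[[ij[2]]]
    out[ri, cj] <- bm$blocks[[key]]
    if (symmetric && ij[1] != ij[2]) out[cj, ri] <- t(bm$blocks[[key]])
  }
  out
}

#' The treed precision as a block matrix, with optional diagonal additions
#'
#' Builds \eqn{\Lambda = \tilde C^{-1} + \Sigma^{-1}} in block form, where
#' \eqn{\Sigma^{-1}} is a nonnegative diagonal supplied per expanded
#' location (zero where absent) — the matrix whose factorisation yields the
#' integrated likelihood.
#'
#' @param dag a `treed_dag`.
#' @param factors output of [node_conditionals()].
#' @param extra_diag optional numeric vector (length = number of locations)
#'   added to the diagonal.
#' @return A [block_matrix()].
#' @export
precision_block_matrix <- function(dag, factors, extra_diag = NULL) {
  blocks <- list()
  m <- length(dag$level)
  for (i in seq_len(m)) {
    blk <- precision_block(dag, factors, i, i)
    if (!is.null(extra_diag)) {
      diag(blk) <- diag(blk) + extra_diag[dag$node_locs[[i]]]
    }
    blocks[[bm_key(i, i)]] <- blk
    for (j in dag$parents[[i]]) {
      blocks[[bm_key(i, j)]] <- precision_block(dag, factors, i, j)
    }
  }
  block_matrix(dag, blocks)
}

#' Block Cholesky-type decomposition conforming to the treed DAG
#'
#' Writes a symmetric positive-definite `Lambda` with the precision's block
#' pattern as \eqn{\Lambda = (I - L)' D (I - L)} where `L` is strictly block
#' lower triangular with H's sparsity pattern (nonzero block `(k, j)` only
#' for `j` a parent of `k`) and `D` is block diagonal PD.  Implemented as a
#' reverse-ordered block elimination: walking nodes from the leaves up,
#' \eqn{D_k} is the current (k, k) block, \eqn{L_{kj} = -D_k^{-1}
#' \Lambda^{(k)}_{kj}}, and the parent pairs receive the downdate
#' \eqn{\Lambda_{jj'} \leftarrow \Lambda_{jj'} - L_{kj}' D_k L_{kj'}}.
#' For trees built by [build_tree()] all downdates stay inside the pattern;
#' a nonzero block outside it raises an error (the input does not conform).
#'
#' @param Lambda a [block_matrix()] (e.g. from [precision_block_matrix()]).
#' @return List with `L` (a `block_matrix` holding blocks `(k, parent)`)
#'   and `D` (list of diagonal blocks, one per node).
#' @export
block_cholesky <- function(Lambda) {
  dag <- Lambda$dag
  m <- length(dag$level)
  work <- new.env(parent = emptyenv())
  for (key in names(Lambda$blocks)) assign(key, Lambda$blocks[[key]], work)
  getw <- function(i, j) {
    b <- get0(bm_key(i, j), envir = work)
    if (is.null(b)) {
      b <- get0(bm_key(j, i), envir = work)
      if (!is.null(b)) b <- t(b)
    }
    b
  }
  Lb <- list()
  Db <- vector("list", m)
  for (k in m:1) {
    Dk <- getw(k, k)
    if (is.null(Dk)) stop("missing diagonal block for node ", k)
    Uk <- tryCatch(chol(Dk), error = function(e) {
      stop("block (", k, ",", k, ") not positive definite during elimination")
    })
    Db[[k]] <- 0.5 * (Dk + t(Dk))
    ps <- dag$parents[[k]]
    # any stored off-diagonal block of row k outside the parent set means
    # the input does not conform to the DAG
    for (j in seq_len(k - 1L)) {
      if (!(j %in% ps)) {
        stray <- getw(k, j)
        if (!is.null(stray) && any(abs(stray) > 1e-10)) {
          stop("fill-in outside the H pattern at block (", k, ",", j, ")")
        }
      }
    }
    Lrow <- vector("list", length(ps))
    for (a in seq_along(ps)) {
      blk <- getw(k, ps[a])
      if (is.null(blk)) blk <- matrix(0, nrow(Dk),
                                      length(dag$node_locs[[ps[a]]]))
      Lrow[[a]] <- -backsolve(Uk, backsolve(Uk, blk, transpose = TRUE))
      Lb[[bm_key(k, ps[a])]] <- Lrow[[a]]
    }
    for (a in seq_along(ps)) for (b2 in seq_along(ps)) {
      if (ps[a] < ps[b2]) next
      upd <- crossprod(Lrow[[a]], Db[[k]] %*% Lrow[[b2]])
      key <- bm_key(ps[a], ps[b2])
      old <- get0(key, envir = work)
      if (is.null(old)) {
        if (max(abs(upd)) <= 1e-10) next
        if (ps[a] != ps[b2]) {
          # the pair must already be in the pattern (ancestor-related)
          stop("fill-in outside the H pattern at block (", ps[a], ",",
               ps[b2], ")")
        }
        old <- matrix(0, nrow(upd), ncol(upd))
      }
      assign(key, old - upd, envir = work)
    }
  }
  list(L = block_matrix(dag, Lb), D = Db)
}

#' Block inverse of (I - L) by forward substitution
#'
#' `L` must be strictly block lower triangular in canonical (level-
#' ascending) order; the inverse is again block lower triangular, with
#' blocks accumulating along ancestor paths:
#' \eqn{B_{ij} = \delta_{ij} I + \sum_{k \in Pa[i]} L_{ik} B_{kj}}.
#'
#' @param L a `block_matrix` with H's pattern (from [block_cholesky()]).
#' @return A `block_matrix` holding the blocks of \eqn{(I - L)^{-1}}.
#' @export
block_tri_inverse <- function(L) {
  dag <- L$dag
  m <- length(dag$level)
  rows <- vector("list", m)
  out <- list()
  for (i in seq_len(m)) {
    n_i <- length(dag$node_locs[[i]])
    acc <- list()
    acc[[as.character(i)]] <- diag(1, n_i)
    for (k in dag$parents[[i]]) {
      Lik <- L$blocks[[bm_key(i, k)]]
      if (is.null(Lik)) next
      for (jname in names(rows[[k]])) {
        contrib <- Lik %*% rows[[k]][[jname]]
        if (is.null(acc[[jname]])) acc[[jname]] <- contrib
        else acc[[jname]] <- acc[[jname]] + contrib
      }
    }
    rows[[i]] <- acc
    for (jname in names(acc)) out[[bm_key(i, as.integer(jname))]] <- acc[[jname]]
  }
  block_matrix(dag, out)
}

# Solve Lambda x = b given the block factorisation (I-L)' D (I-L):
# x = (I-L)^{-1} D^{-1} (I-L)^{-T} b, using the block triangular inverse.
solve_block_ldl <- function(fac, b) {
  dag <- fac$L$dag
  B <- block_tri_inverse(fac$L)
  n <- length(dag$eta)
  # y = (I-L)^{-T} b ; z = D^{-1} y ; x = (I-L)^{-1} z
  dense_apply <- function(bm, v, transpose = FALSE) {
    outv <- numeric(n)
    for (key in names(bm$blocks)) {
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      ri <- dag$node_locs[[ij[1]]]
      cj <- dag$node_locs[[ij[2]]]
      if (!transpose) {
        outv[ri] <- outv[ri] + as.numeric(bm$blocks[[key]] %*% v[cj])
      } else {
        outv[cj] <- outv[cj] + as.numeric(crossprod(bm$blocks[[key]], v[ri]))
      }
    }
    outv
  }
  y <- dense_apply(B, b, transpose = TRUE)
  z <- numeric(n)
  for (k in seq_along(fac$D)) {
    idx <- dag$node_locs[[k]]
    z[idx] <- solve(fac$D[[k]], y[idx])
  }
  dense_apply(B, z)
}

#' Integrated (marginal) log-likelihood of the observed outcomes
#'
#' Evaluates \eqn{\log N(y \mid X\beta, Z \tilde C Z' + D_n)} with the
#' latent field integrated out, through the block factorisation of
#' \eqn{\Lambda = \tilde C^{-1} + Z' D_n^{-1} Z} (matrix-inversion-lemma
#' route) — no dense covariance over all observations is ever formed.
#' Requires diagonal loadings (each observed row loads one latent
#' location).
#'
#' @param data a [spamtree_data()] with diagonal loadings.
#' @param beta fixed effects (or `NULL`).
#' @param tau2 nuggets (length q).
#' @param params a [cov_params()].
#' @param dag a `treed_dag` over `data$locs`.
#' @param factors optional precomputed [node_conditionals()].
#' @return Scalar log-likelihood.
#' @export
integrated_likelihood <- function(data, beta, tau2, params, dag,
                                  factors = NULL) {
  if (!data$diagonal) {
    stop("integrated likelihood requires diagonal loadings")
  }
  if (is.null(factors)) factors <- node_conditionals(dag, params)
  obs <- data$observed
  n_obs <- sum(obs)
  if (n_obs == 0L) stop("no observed outcomes")
  r <- data$y
  if (!is.null(data$X) && !is.null(beta)) {
    r <- r - as.numeric(data$X %*% beta)
  }
  r[!obs] <- 0
  dinv <- numeric(length(r))
  dinv[obs] <- 1 / tau2[data$outcome[obs]]
  zd <- data$z^2 * dinv
  Lambda <- precision_block_matrix(dag, factors, extra_diag = zd)
  fac <- block_cholesky(Lambda)
  logdet_Lambda <- sum(vapply(fac$D, function(D) {
    2 * sum(log(diag(chol(D))))
  }, numeric(1)))
  logdet_Ctilde <- sum(vapply(factors, `[[`, numeric(1), "logdetR"))
  logdet_Dn <- sum(log(tau2[data$outcome[obs]]))
  b <- data$z * dinv * r
  quad <- sum(dinv * r^2) - sum(b * solve_block_ldl(fac, b))
  -0.5 * (n_obs * log(2 * pi) + logdet_Dn + logdet_Ctilde + logdet_Lambda +
            quad)
}
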