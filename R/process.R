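# Gaussian treed-DAG process: per-node conditional factors, joint density,
# block precision algebra.  The numerical core lives in compiled code; the
# functions here expose it on the package's R objects and implement the
# block-level operations used for analysis and testing.

# Build (or reuse) the packed C++ representation of a dag.
dag_ptr <- function(dag) {
  cache <- dag$cache
  if (!is.null(cache$ptr)) return(cache$ptr)
  m <- length(dag$level)
  prec_mode <- integer(m)
  for (i in seq_len(m)) {
    ps <- dag$parents[[i]]
    if (length(ps) == 0L) {
      prec_mode[i] <- 0L
    } else if (length(ps) == 1L) {
      prec_mode[i] <- 1L
    } else {
      p <- ps[length(ps)]
      prec_mode[i] <- if (identical(ps[-length(ps)], dag$parents[[p]])) 2L else 3L
    }
  }
  cache$ptr <- .dag_pack_build(dag$locs$coords, dag$locs$var,
                               dag$node_locs, dag$parents, dag$children,
                               dag$level, prec_mode)
  cache$ptr
}

# Ids of the parent locations of node i, in block (level-ascending) order.
parent_locs <- function(dag, i) {
  as.integer(unlist(dag$node_locs[dag$parents[[i]]]))
}

#' Per-node Gaussian conditional factors
#'
#' For every node computes the conditional-mean operator
#' \eqn{H_j = C_{j,[j]} C_{[j]}^{-1}} and residual covariance
#' \eqn{R_j = C_j - C_{j,[j]} C_{[j]}^{-1} C_{[j],j}} under the base
#' cross-covariance, caching the parent precision \eqn{C_{[j]}^{-1}}.
#' Parent precisions are obtained level-by-level: reused from the parent for
#' single root parents, assembled by the recursive two-block identity when
#' the parent set nests (see [recursive_parent_precision()]), and by direct
#' factorisation otherwise.
#'
#' @param dag a `treed_dag`.
#' @param params a [cov_params()] object.
#' @return A list (one entry per node, canonical order) with components `H`,
#'   `R`, `Rinv`, `parent_precision`, `logdetR`.
#' @export
node_conditionals <- function(dag, params) {
  ptr <- dag_ptr(dag)
  .dag_factors_update(ptr, unclass(params), FALSE)
  .dag_factors_list(ptr, FALSE)
}

#' Recursive parent-precision update
#'
#' When `Pa[v_j] = {v_i}, Pa[v_i]` (a nested parent set), the precision of
#' the stacked parent vector follows from the parent's own factors without
#' inverting the larger covariance:
#' \deqn{C_{[j]}^{-1} = \begin{pmatrix} C_{[i]}^{-1} + H_i' R_i^{-1} H_i &
#'  -H_i' R_i^{-1} \\ -R_i^{-1} H_i & R_i^{-1} \end{pmatrix}.}
#'
#' @param C_parent_inv precision of `w_{[i]}` (0 x 0 matrix for a root).
#' @param H_i,R_i conditional factors of node `v_i`.
#' @return The precision of `(w_{[i]}, w_i)`.
#' @export
recursive_parent_precision <- function(C_parent_inv, H_i, R_i) {
  Rinv <- chol2inv(chol(R_i))
  J <- nrow(C_parent_inv)
  if (J == 0L) return(Rinv)
  if (ncol(H_i) != J) stop("H_i has ", ncol(H_i), " columns but C_parent_inv is ",
                           J, " x ", J)
  RiH <- Rinv %*% H_i
  rbind(cbind(C_parent_inv + crossprod(H_i, RiH), -t(RiH)),
        cbind(-RiH, Rinv))
}

#' Joint log-density of the latent field
#'
#' Evaluates \eqn{\log \tilde p(w_S) + \log \tilde p(w_U | w_S) = \sum_i \log
#' N(w_i \mid H_i w_{[i]}, R_i)} over all branch and leaf nodes, i.e. the
#' density of \eqn{N(0, \tilde C)} where \eqn{\tilde C^{-1} = (I-H)' R^{-1}
#' (I-H)}.  `w` must be ordered by expanded-location id (the canonical
#' within-node order is by location id).
#'
#' @param w numeric vector over all expanded locations in the dag.
#' @param dag a `treed_dag`.
#' @param params a [cov_params()] object.
#' @return Scalar log-density.
#' @export
log_density_w <- function(w, dag, params) {
  if (length(w) != length(dag$eta)) stop("length(w) must match the dag")
  ptr <- dag_ptr(dag)
  .dag_factors_update(ptr, unclass(params), FALSE)
  .dag_log_density(ptr, as.numeric(w), FALSE)
}

# Selector-minus-H block: I_{ki} - H_{i->k}, of size n_k x n_i
sel_minus_H <- function(dag, factors, k, i) {
  n_k <- length(dag$node_locs[[k]])
  n_i <- length(dag$node_locs[[i]])
  out <- matrix(0, n_k, n_i)
  if (k == i) diag(out) <- 1
  ps <- dag$parents[[k]]
  pos <- match(i, ps)
  if (!is.na(pos)) {
    sizes <- lengths(dag$node_locs[ps])
    off <- if (pos == 1L) 0L else sum(sizes[seq_len(pos - 1L)])
    out <- out - factors[[k]]$H[, off + seq_len(n_i), drop = FALSE]
  }
  out
}

#' Block of the treed precision matrix
#'
#' The (i, j) block of \eqn{\tilde C^{-1}} is structurally zero when the
#' common-descendant set \eqn{cd(v_i, v_j)} is empty, and otherwise equals
#' \deqn{\sum_{v_k \in cd(v_i,v_j)} (I_{ki} - H_{i\to k})' R_k^{-1}
#'  (I_{kj} - H_{j\to k}).}
#'
#' @param dag a `treed_dag`.
#' @param factors output of [node_conditionals()].
#' @param i,j node ids.
#' @return The block matrix, or `NULL` for a structural zero.
#' @export
precision_block <- function(dag, factors, i, j) {
  cd <- common_descendants(dag, i, j)
  if (length(cd) == 0L) return(NULL)
  n_i <- length(dag$node_locs[[i]])
  n_j <- length(dag$node_locs[[j]])
  out <- matrix(0, n_i, n_j)
  for (k in cd) {
    out <- out + crossprod(sel_minus_H(dag, factors, k, i),
                           factors[[k]]$Rinv %*% sel_minus_H(dag, factors, k, j))
  }
  out
}

#' Assemble the dense precision matrix (small problems)
#'
#' Assembles \eqn{\tilde C^{-1}} from [precision_block()]s into a dense
#' matrix ordered by expanded-location id.  Intended for toy instances and
#' diagnostics; the sampler never forms this matrix.
#'
#' @inheritParams precision_block
#' @return Dense precision matrix.
#' @export
assemble_precision <- function(dag, factors) {
  n <- length(dag$eta)
  out <- matrix(0, n, n)
  m <- length(dag$level)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    blk <- precision_block(dag, factors, i, j)
    if (!is.null(blk)) {
      out[dag$node_locs[[i]], dag$node_locs[[j]]] <- blk
    }
  }
  out
}

#' Number of nonzero elements of the treed precision
#'
#' \eqn{nnz(\tilde C^{-1}) = \sum_i (2 n_i J_i + n_i^2)} over all nodes,
#' counting the diagonal blocks and both triangles of every node-parent
#' block.
#'
#' @param dag a `treed_dag`.
#' @return Integer count.
#' @export
nnz_precision <- function(dag) {
  n_i <- lengths(dag$node_locs)
  J_i <- vapply(seq_along(dag$level), function(i) {
    sum(lengths(dag$node_locs[dag$parents[[i]]]))
  }, numeric(1))
  sum(2 * n_i * J_i + n_i^2)
}

#' Analytic floating-point-operation count of a density evaluation
#'
#' Counts the leading-order flops of one [log_density_w()] pass (covariance
#' assembly, parent-precision recursion, Cholesky factorisations, quadratic
#' forms) from the block sizes alone.  Used to verify the O(n N_s^2) cost
#' scaling without relying on wall clocks.
#'
#' @param dag a `treed_dag`.
#' @return Total flop count (double).
#' @export
flop_count <- function(dag) {
  total <- 0
  for (i in seq_along(dag$level)) {
    n <- length(dag$node_locs[[i]])
    J <- sum(lengths(dag$node_locs[dag$parents[[i]]]))
    total <- total +
      n^2 + n * J +            # covariance blocks
      2 * n * J^2 + n^2 * J +  # H = C_{j,[j]} C_{[j]}^{-1}, R update
      n^3 / 3 +                # Cholesky of R
      n^2 +                    # triangular solve in the quadratic form
      (if (J > 0) {
        p <- dag$parents[[i]][length(dag$parents[[i]])]
        np <- length(dag$node_locs[[p]])
        (J - np)^2 * np + np^2 * (J - np)  # recursive precision assembly
      } else 0)
  }
  total
}
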