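# Covariance function induced by the treed process between any two
# expanded locations already assigned to nodes: a path sum through shared
# conditioning sets when the two nodes' parent sets interact, and a product
# of conditional-expectation operators along shortest paths from the
# concestor otherwise.

# Residual kernel attached to node s along a conditioning path: the base
# covariance conditioned on s's parent set when s lies above the depth band
# (level > M - depth), and the raw base covariance when s sits at the
# path-start level M - depth (its own parent, if any, is below the band and
# plays no role in the decomposition).
node_kernel <- function(dag, params, s, ids_a, ids_b, condition_on_parents) {
  A <- subset_locs(dag$locs, ids_a)
  B <- subset_locs(dag$locs, ids_b)
  Cab <- .cov_block_arma(A$coords, A$var, B$coords, B$var, unclass(params))
  if (!condition_on_parents || length(dag$parents[[s]]) == 0L) return(Cab)
  pl <- parent_locs(dag, s)
  P <- subset_locs(dag$locs, pl)
  Cap <- .cov_block_arma(A$coords, A$var, P$coords, P$var, unclass(params))
  Cpb <- .cov_block_arma(P$coords, P$var, B$coords, B$var, unclass(params))
  Cpp <- cov_matrix(P, params = params)
  Cab - Cap %*% solve(Cpp, Cpb)
}

#' Covariance induced by the treed process
#'
#' Computes `Cov(w(l1), w(l2))` under the standalone treed process for two
#' expanded locations already assigned to nodes of the DAG.  When the two
#' nodes' conditioning sets interact (shared parents, or one node parent of
#' the other, or the same node) the covariance is a sum over the shared
#' conditioning path of projected residual kernels, plus the own residual
#' kernel for locations in a common node; with full depth this is the only
#' regime.  When the parent sets are disjoint the covariance is the product
#' of conditional-expectation operators along the shortest paths from the
#' concestor.  Nodes in disjoint trees are structurally independent: the
#' value 0 is returned with attribute `independent = TRUE`.
#'
#' @param dag a `treed_dag`.
#' @param params a [cov_params()].
#' @param id1,id2 expanded-location ids (in the dag).
#' @return Scalar covariance (with attribute `independent` when structural).
#' @export
induced_cov <- function(dag, params, id1, id2) {
  v_i <- dag$eta[id1]
  v_j <- dag$eta[id2]
  M_delta <- dag$M - dag$depth
  Pa_i <- dag$parents[[v_i]]
  Pa_j <- dag$parents[[v_j]]
  own <- 0
  shared <- NULL
  if (v_i == v_j) {
    shared <- Pa_i
    own <- node_kernel(dag, params, v_i, id1, id2, TRUE)[1, 1]
  } else if (v_i %in% Pa_j) {
    shared <- c(intersect(Pa_i, Pa_j), v_i)
  } else if (v_j %in% Pa_i) {
    shared <- c(intersect(Pa_i, Pa_j), v_j)
  } else if (length(intersect(Pa_i, Pa_j)) > 0L) {
    shared <- intersect(Pa_i, Pa_j)
  }
  if (!is.null(shared)) {
    total <- own
    for (s in shared) {
      cond <- dag$level[s] > M_delta
      sl <- dag$node_locs[[s]]
      Kls <- node_kernel(dag, params, s, id1, sl, cond)
      Kss <- node_kernel(dag, params, s, sl, sl, cond)
      diag(Kss) <- diag(Kss) + 1e-9 * mean(diag(Kss))
      Ksl <- node_kernel(dag, params, s, sl, id2, cond)
      total <- total + as.numeric(Kls %*% solve(Kss, Ksl))
    }
    return(total)
  }
  # disjoint parent sets: product along shortest paths from the concestor
  z <- tryCatch(concestor(dag, v_i, v_j), error = function(e) NA_integer_)
  if (is.na(z)) {
    return(structure(0, independent = TRUE))
  }
  zl <- dag$node_locs[[z]]
  Z <- subset_locs(dag$locs, zl)
  Cz <- cov_matrix(Z, params = params)
  chain_to <- function(target) {
    path <- shortest_path(dag, z, target)
    A <- diag(1, length(zl))
    if (length(path) > 1L) {
      for (h in 2:length(path)) {
        Sh <- subset_locs(dag$locs, dag$node_locs[[path[h]]])
        Sp <- subset_locs(dag$locs, dag$node_locs[[path[h - 1L]]])
        Chp <- .cov_block_arma(Sh$coords, Sh$var, Sp$coords, Sp$var,
                               unclass(params))
        Cpp <- cov_matrix(Sp, params = params)
        A <- Chp %*% solve(Cpp, A)
      }
    }
    A
  }
  Ai <- chain_to(v_i)
  Aj <- chain_to(v_j)
  blk <- Ai %*% Cz %*% t(Aj)
  blk[match(id1, dag$node_locs[[v_i]]), match(id2, dag$node_locs[[v_j]])]
}
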