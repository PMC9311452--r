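# Treed DAG construction: recursive kd partition of the reference set,
# branch structure with configurable depth, and the cherry-picking map that
# attaches every non-reference location to a leaf.

# Split a set of point ids into k tiles by recursive median cuts on
# alternating axes.  Deterministic: the largest tile is split next (ties by
# creation order), points are ordered by (coordinate, id) before the cut.
kd_split <- function(ids, coords, k, axis0 = 1L) {
  parts <- list(list(ids = ids, axis = axis0))
  while (length(parts) < k) {
    sizes <- vapply(parts, function(p) length(p$ids), integer(1))
    if (max(sizes) < 2L) break
    i <- which.max(sizes)
    p <- parts[[i]]
    ax <- p$axis
    ord <- order(coords[p$ids, ax], p$ids)
    cut <- ceiling(length(p$ids) / 2)
    nxt <- if (ax == 1L) 2L else 1L
    left <- list(ids = p$ids[ord[seq_len(cut)]], axis = nxt)
    right <- list(ids = p$ids[ord[-seq_len(cut)]], axis = nxt)
    parts <- append(parts[-i], list(left, right), after = i - 1L)
  }
  lapply(parts, `[[`, "ids")
}

# Space-filling subsample of k points from a tile: greedy farthest-point with
# an optional retention-priority weight for one variable (root bias).  The
# first pick is the point nearest the tile centroid (restricted to the biased
# variable when present); ties break on the lowest id.
retain_spacefill <- function(ids, coords, var, k, bias_var = NULL,
                             bias_weight = 5) {
  n <- length(ids)
  if (n <= k) return(ids[order(var[ids], ids)])
  X <- coords[ids, , drop = FALSE]
  w <- rep(1, n)
  if (!is.null(bias_var)) w[var[ids] == bias_var] <- bias_weight
  cen <- colMeans(X)
  d0 <- sqrt(colSums((t(X) - cen)^2))
  first_pool <- if (!is.null(bias_var) && any(w > 1)) which(w > 1) else seq_len(n)
  f <- first_pool[order(d0[first_pool], ids[first_pool])[1L]]
  sel <- integer(k)
  sel[1L] <- f
  mind <- sqrt(colSums((t(X) - X[f, ])^2))
  for (s in seq_len(k - 1L)) {
    score <- mind * w
    score[sel[seq_len(s)]] <- -Inf
    cand <- which(score == max(score))
    pick <- cand[order(ids[cand])[1L]]
    sel[s + 1L] <- pick
    mind <- pmin(mind, sqrt(colSums((t(X) - X[pick, ])^2)))
  }
  keep <- ids[sel]
  keep[order(var[keep], keep)]
}

#' Partition a reference set into level-wise subsets
#'
#' Splits the candidate reference locations into a nested tiling (recursive
#' axis-aligned median cuts, alternating axes) with `n_roots *
#' branching^(r)` tiles at tree level `r`, and retains `per_level_size[r+1]`
#' locations per tile as that tile's reference subset via a greedy
#' space-filling subsample.  The remainder of each tile is passed to its
#' children; whatever is left after the last branch level goes to the
#' non-reference set.  When `root_bias_var` is set, locations of that
#' variable receive a retention-priority weight so that sparsely observed
#' outcomes populate near-root subsets.
#'
#' @param locs an [expanded_locs()] object.
#' @param M number of branch levels (levels `0..M-1`).
#' @param per_level_size integer (recycled to length M): reference locations
#'   retained per tile and level.
#' @param branching number of child tiles per tile (>= 2).
#' @param n_roots number of root tiles (level 0); > 1 yields a forest of
#'   independent trees (independent-partitioning models).
#' @param root_bias_var optional variable index to favour near the root.
#' @param bias_weight retention-priority multiplier for `root_bias_var`.
#' @param candidates optional integer ids of locations eligible as reference
#'   (defaults to all); the rest can only enter the non-reference set.
#' @return A list with per-level tiles (`levels`), the leftover location ids
#'   (`leftover`), and bookkeeping used by [build_tree()].
#' @export
partition_reference <- function(locs, M, per_level_size, branching = 2L,
                                n_roots = 1L, root_bias_var = NULL,
                                bias_weight = 5, candidates = NULL) {
  stopifnot(M >= 1L, branching >= 2L || n_roots > 1L)
  per_level_size <- rep_len(as.integer(per_level_size), M)
  if (any(per_level_size < 1L)) stop("per_level_size must be >= 1")
  if (is.null(candidates)) candidates <- seq_len(length(locs))
  if (length(candidates) == 0L) stop("no candidate reference locations")
  coords <- locs$coords
  var <- locs$var

  levels <- vector("list", M)
  current <- lapply(kd_split(candidates, coords, n_roots, axis0 = 1L),
                    function(ids) list(ids = ids, parent = NA_integer_))
  for (r in seq_len(M)) {
    keep <- vapply(current, function(t) length(t$ids) > 0L, logical(1))
    if (!all(keep)) {
      message(sprintf("level %d: dropping %d empty tile(s)", r - 1L,
                      sum(!keep)))
      current <- current[keep]
    }
    if (length(current) == 0L) stop("reference partition ran out of points")
    tiles <- vector("list", length(current))
    nxt <- list()
    for (ti in seq_along(current)) {
      ids <- current[[ti]]$ids
      ret <- retain_spacefill(ids, coords, var, per_level_size[r],
                              bias_var = root_bias_var,
                              bias_weight = bias_weight)
      rest <- setdiff(ids, ret)
      tiles[[ti]] <- list(ids = ret, parent = current[[ti]]$parent)
      if (r < M) {
        axis0 <- if (r %% 2L == 1L) 2L else 1L
        for (part in kd_split(rest, coords, branching, axis0 = axis0)) {
          nxt[[length(nxt) + 1L]] <- list(ids = part, parent = ti)
        }
      } else {
        nxt[[length(nxt) + 1L]] <- list(ids = rest, parent = ti)
      }
    }
    levels[[r]] <- tiles
    current <- nxt
  }
  leftover <- sort(unlist(lapply(current, `[[`, "ids")))
  structure(list(levels = levels, leftover = leftover, M = as.integer(M),
                 branching = as.integer(branching),
                 n_roots = as.integer(n_roots), locs = locs),
            class = "reference_partition")
}

#' Build the branch structure of a treed DAG
#'
#' Creates the branch nodes of the DAG from a reference partition.  With
#' depth `delta`, a node at level `r <= M - delta` has the single parent
#' given by its parent tile, while a node at level `r > M - delta` conditions
#' on its full chain of tile ancestors from level `M - delta` through
#' `r - 1` (nested parent sets).  `delta = M` gives fully nested conditioning;
#' `delta = 1` single parents throughout.
#'
#' @param partition a [partition_reference()] result.
#' @param depth tree depth `delta` in `1..M`.
#' @return A `treed_dag` object containing branches only; leaves are added by
#'   [cherry_pick()].
#' @export
build_tree <- function(partition, depth) {
  M <- partition$M
  if (depth < 1L || depth > M) stop("depth must lie in 1..M")
  M_delta <- M - depth

  level <- integer(0)
  node_locs <- list()
  tile_parent <- integer(0)  # node id of the parent tile's node
  idx <- vector("list", M)   # tile index -> node id per level
  nid <- 0L
  for (r in seq_len(M)) {
    idx[[r]] <- integer(length(partition$levels[[r]]))
    for (ti in seq_along(partition$levels[[r]])) {
      tile <- partition$levels[[r]][[ti]]
      nid <- nid + 1L
      level[nid] <- r - 1L
      node_locs[[nid]] <- tile$ids
      tile_parent[nid] <- if (r == 1L) NA_integer_ else idx[[r - 1L]][tile$parent]
      idx[[r]][ti] <- nid
    }
  }
  m <- nid
  parents <- vector("list", m)
  for (i in seq_len(m)) {
    r <- level[i]
    if (r == 0L) {
      parents[[i]] <- integer(0)
    } else if (r <= M_delta) {
      parents[[i]] <- tile_parent[i]
    } else {
      chain <- integer(0)
      a <- tile_parent[i]
      while (!is.na(a) && level[a] >= M_delta) {
        chain <- c(a, chain)
        a <- tile_parent[a]
      }
      parents[[i]] <- chain
    }
  }
  children <- vector("list", m)
  for (i in seq_len(m)) children[[i]] <- integer(0)
  for (i in seq_len(m)) for (p in parents[[i]]) {
    children[[p]] <- c(children[[p]], i)
  }
  n <- length(partition$locs)
  eta <- rep(NA_integer_, n)
  for (i in seq_len(m)) eta[node_locs[[i]]] <- i
  dag <- structure(list(
    M = M, depth = as.integer(depth), q = partition$locs$q,
    locs = partition$locs,
    level = level, kind = rep("branch", m),
    parents = parents, children = children,
    node_locs = node_locs, tile_parent = tile_parent,
    eta = eta, is_reference = !is.na(eta),
    leftover = partition$leftover,
    cache = new.env(parent = emptyenv())
  ), class = "treed_dag")
  dag
}

#' Terminal branches of a treed DAG
#'
#' Branch nodes all of whose children are leaves (or that have no children):
#' the anchors for cherry-picked conditioning sets.
#'
#' @param dag a `treed_dag`.
#' @return Integer node ids.
#' @export
terminal_branches <- function(dag) {
  which(vapply(seq_along(dag$level), function(i) {
    dag$kind[i] == "branch" &&
      (length(dag$children[[i]]) == 0L ||
         all(dag$kind[dag$children[[i]]] == "leaf"))
  }, logical(1)))
}

# Parent set of a leaf hanging below terminal branch t: the path of ancestors
# of t at levels >= M - depth, followed by t itself (level-ascending).
leaf_parent_path <- function(dag, t) {
  M_delta <- dag$M - dag$depth
  chain <- t
  a <- dag$tile_parent[t]
  while (!is.na(a) && dag$level[a] >= M_delta) {
    chain <- c(a, chain)
    a <- dag$tile_parent[a]
  }
  chain
}

# Resolve, for arbitrary query points, the terminal branch containing the
# nearest reference location (Euclidean distance on the spatial
# coordinates), optionally searching same-variable references first.
# Ties break on the lowest node id, then the lowest location id.
assign_terminal <- function(dag, coords, var, same_variable_first = FALSE) {
  term <- terminal_branches(dag)
  if (length(term) == 0L) stop("dag has no terminal branch")
  cand_loc <- unlist(dag$node_locs[term])
  cand_node <- rep(term, lengths(dag$node_locs[term]))
  if (length(cand_loc) == 0L) stop("empty reference set in terminal branches")
  ordc <- order(cand_node, cand_loc)
  cand_loc <- cand_loc[ordc]
  cand_node <- cand_node[ordc]
  X <- dag$locs$coords
  vr <- dag$locs$var

  nearest <- function(Xu, keep) {
    cl <- cand_loc[keep]
    cn <- cand_node[keep]
    Xc <- X[cl, , drop = FALSE]
    D2 <- outer(rowSums(Xu^2), rep(1, nrow(Xc))) - 2 * Xu %*% t(Xc) +
      outer(rep(1, nrow(Xu)), rowSums(Xc^2))
    D2[D2 < 0] <- 0
    vapply(seq_len(nrow(Xu)), function(k) {
      d <- D2[k, ]
      hit <- which(d <= min(d) + 1e-12)
      cn[hit[order(cn[hit], cl[hit])[1L]]]
    }, integer(1))
  }

  assigned <- integer(nrow(coords))
  if (same_variable_first) {
    for (v in sort(unique(var))) {
      sel <- which(var == v)
      keep <- vr[cand_loc] == v
      if (!any(keep)) keep <- rep(TRUE, length(cand_loc))
      assigned[sel] <- nearest(coords[sel, , drop = FALSE], keep)
    }
  } else {
    assigned <- nearest(coords, rep(TRUE, length(cand_loc)))
  }
  assigned
}

#' Cherry-pick non-reference locations onto leaves
#'
#' Each non-reference location is assigned to a leaf whose parent set is the
#' conditioning path of the terminal branch containing its nearest reference
#' location (Euclidean distance on the spatial coordinates).  With
#' `same_variable_first`, the nearest-reference search is restricted to
#' reference locations of the location's own variable, falling back to all
#' variables when none exist; this forces every conditioning set to include
#' at least one realisation of the same variable.  Leaves are materialised
#' one per terminal branch actually used (so the number of leaves equals the
#' number of used terminal anchors), or one per location when
#' `granularity = "location"`.
#'
#' @param dag a `treed_dag` with branches only (from [build_tree()]).
#' @param ids integer ids of the non-reference locations to assign; defaults
#'   to every location not in the reference set.
#' @param same_variable_first restrict the nearest-reference search to the
#'   same variable first.
#' @param granularity `"terminal"` (one leaf per used terminal branch) or
#'   `"location"` (one leaf per location, conditionally independent given the
#'   shared path).
#' @return The `treed_dag` with leaf nodes appended and `eta` completed.
#' @export
cherry_pick <- function(dag, ids = NULL,
                        same_variable_first = FALSE,
                        granularity = c("terminal", "location")) {
  granularity <- match.arg(granularity)
  if (is.null(ids)) ids <- which(is.na(dag$eta))
  if (length(ids) == 0L) return(dag)
  assigned <- assign_terminal(dag, dag$locs$coords[ids, , drop = FALSE],
                              dag$locs$var[ids], same_variable_first)

  m <- length(dag$level)
  add_leaf <- function(dag, locs_ids, t) {
    nid <- length(dag$level) + 1L
    dag$level[nid] <- dag$M
    dag$kind[nid] <- "leaf"
    dag$node_locs[[nid]] <- locs_ids
    dag$parents[[nid]] <- leaf_parent_path(dag, t)
    dag$children[[nid]] <- integer(0)
    dag$tile_parent[nid] <- t
    for (p in dag$parents[[nid]]) {
      dag$children[[p]] <- c(dag$children[[p]], nid)
    }
    dag$eta[locs_ids] <- nid
    dag
  }
  vr_all <- dag$locs$var
  if (granularity == "terminal") {
    for (t in sort(unique(assigned))) {
      sel <- ids[assigned == t]
      dag <- add_leaf(dag, sel[order(vr_all[sel], sel)], t)
    }
  } else {
    ord <- order(assigned, ids)
    for (k in ord) dag <- add_leaf(dag, ids[k], assigned[k])
  }
  dag$cache <- new.env(parent = emptyenv())
  dag
}

#' Build a complete spatial multivariate treed DAG
#'
#' Convenience wrapper: partitions the reference candidates, builds the
#' branch structure at the requested depth, and cherry-picks all remaining
#' locations onto leaves.
#'
#' @inheritParams partition_reference
#' @inheritParams build_tree
#' @inheritParams cherry_pick
#' @param all_outcomes_colocated when `TRUE`, the partition operates on
#'   unique spatial sites and a retained site contributes all its variables
#'   to the reference subset, so the tree never separates co-located
#'   variables.
#' @return A `treed_dag` with complete `eta`.
#' @export
spamtree_dag <- function(locs, M, depth = M, per_level_size, branching = 2L,
                         n_roots = 1L, root_bias_var = NULL, bias_weight = 5,
                         same_variable_first = FALSE,
                         all_outcomes_colocated = FALSE,
                         granularity = c("terminal", "location"),
                         candidates = NULL) {
  granularity <- match.arg(granularity)
  if (all_outcomes_colocated) {
    if (is.null(candidates)) candidates <- seq_len(length(locs))
    key <- paste(locs$coords[, 1], locs$coords[, 2], sep = "\r")
    site <- match(key, unique(key))
    # one pseudo-candidate per site (its lowest candidate id)
    site_rep <- vapply(split(candidates, site[candidates]), min, numeric(1))
    part <- partition_reference(locs, M, per_level_size, branching, n_roots,
                                root_bias_var, bias_weight,
                                candidates = as.integer(site_rep))
    # expand each retained representative to all locations at the site
    for (r in seq_along(part$levels)) {
      for (ti in seq_along(part$levels[[r]])) {
        sids <- site[part$levels[[r]][[ti]]$ids]
        part$levels[[r]][[ti]]$ids <- sort(which(site %in% sids))
      }
    }
    part$leftover <- sort(setdiff(seq_len(length(locs)),
                                  unlist(lapply(part$levels, function(l) {
                                    unlist(lapply(l, `[[`, "ids"))
                                  }))))
  } else {
    part <- partition_reference(locs, M, per_level_size, branching, n_roots,
                                root_bias_var, bias_weight,
                                candidates = candidates)
  }
  dag <- build_tree(part, depth)
  dag <- cherry_pick(dag, same_variable_first = same_variable_first,
                     granularity = granularity)
  validate_dag(dag)
  dag
}

#' @export
print.treed_dag <- function(x, ...) {
  nb <- sum(x$kind == "branch")
  nl <- sum(x$kind == "leaf")
  cat(sprintf(paste0("<treed_dag> M = %d, depth = %d, %d branches, ",
                     "%d leaves, %d reference / %d total locations\n"),
              x$M, x$depth, nb, nl, sum(x$is_reference), length(x$eta)))
  invisible(x)
}

#' Validate the structural invariants of a treed DAG
#'
#' Checks acyclicity (every parent at a strictly lower level, topological
#' order), the parent-count rules implied by the depth, the disjointness and
#' coverage of the reference subsets and leaf partition, and that every
#' location maps to exactly one node.
#'
#' @param dag a `treed_dag`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_dag <- function(dag) {
  m <- length(dag$level)
  M_delta <- dag$M - dag$depth
  for (i in seq_len(m)) {
    ps <- dag$parents[[i]]
    if (any(dag$level[ps] >= dag$level[i])) {
      stop("parent at level >= child level: cycle risk at node ", i)
    }
    if (any(ps >= i)) stop("canonical order violated at node ", i)
    r <- dag$level[i]
    if (dag$kind[i] == "branch") {
      if (r == 0L && length(ps) != 0L) stop("root with parents")
      if (r > 0L && r <= M_delta && length(ps) != 1L) {
        stop("node below the depth band must have one parent")
      }
      if (r > M_delta && length(ps) > 0L) {
        want <- seq(M_delta, r - 1L)
        if (!identical(as.integer(sort(dag$level[ps])), as.integer(want))) {
          stop("nested parent path broken at node ", i)
        }
      }
    }
    if (dag$kind[i] == "leaf" && length(dag$children[[i]]) > 0L) {
      stop("leaf with children")
    }
  }
  if (anyNA(dag$eta)) stop("some locations are not assigned to any node")
  all_ids <- sort(as.integer(unlist(dag$node_locs)))
  if (!identical(all_ids, seq_along(dag$eta))) {
    stop("node location sets do not partition the locations")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Graph queries
# ---------------------------------------------------------------------------

#' Graph queries on a treed DAG
#'
#' `common_descendants()` returns \eqn{cd(v_i, v_j) = (\{v_i\} \cup
#' Ch[v_i]) \cap (\{v_j\} \cup Ch[v_j])}, the set governing which precision
#' blocks are structurally nonzero.  `concestor()` returns the last common
#' ancestor of two nodes (deepest node lying on both ancestor paths,
#' including the nodes themselves), erroring for nodes in disjoint trees.
#' `shortest_path()`/`longest_path()` return directed paths following child
#' edges.
#'
#' @param dag a `treed_dag`.
#' @param i,j node ids.
#' @return Integer node ids (a set or a path).
#' @export
common_descendants <- function(dag, i, j) {
  sort(intersect(c(i, dag$children[[i]]), c(j, dag$children[[j]])))
}

ancestor_set <- function(dag, i) {
  out <- integer(0)
  frontier <- dag$parents[[i]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier]))
  }
  sort(out)
}

#' @rdname common_descendants
#' @export
concestor <- function(dag, i, j) {
  pi_ <- c(i, ancestor_set(dag, i))
  pj <- c(j, ancestor_set(dag, j))
  common <- intersect(pi_, pj)
  if (length(common) == 0L) {
    stop("nodes ", i, " and ", j, " lie in disjoint trees: concestor undefined",
         call. = FALSE)
  }
  common[which.max(dag$level[common])]
}

#' @rdname common_descendants
#' @export
shortest_path <- function(dag, i, j) {
  if (i == j) return(i)
  # BFS over child edges from i
  prev <- rep(NA_integer_, length(dag$level))
  frontier <- i
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (f in frontier) for (c in dag$children[[f]]) {
      if (is.na(prev[c])) {
        prev[c] <- f
        if (c == j) {
          path <- j
          while (path[1L] != i) path <- c(prev[path[1L]], path)
          return(path)
        }
        nxt <- c(nxt, c)
      }
    }
    frontier <- nxt
  }
  stop("no directed path from ", i, " to ", j)
}

#' @rdname common_descendants
#' @export
longest_path <- function(dag, i, j) {
  if (i == j) return(i)
  best <- NULL
  walk <- function(path) {
    tip <- path[length(path)]
    if (tip == j) {
      if (is.null(best) || length(path) > length(best)) best <<- path
      return()
    }
    for (c in dag$children[[tip]]) walk(c(path, c))
  }
  walk(i)
  if (is.null(best)) stop("no directed path from ", i, " to ", j)
  best
}

#' Write a treed DAG as plain text
#'
#' Writes an edge list (`child_id parent_id level kind`, one row per edge,
#' parentless roots with parent 0) followed by the location-assignment table
#' (`location_id node_id`).
#'
#' @param dag a `treed_dag`.
#' @param file path or connection.
#' @export
write_dag <- function(dag, file) {
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  writeLines("# child_id parent_id level kind", con)
  for (i in seq_along(dag$level)) {
    ps <- dag$parents[[i]]
    if (length(ps) == 0L) ps <- 0L
    for (p in ps) {
      writeLines(sprintf("%d %d %d %s", i, p, dag$level[i], dag$kind[i]), con)
    }
  }
  writeLines("# location_id node_id", con)
  writeLines(sprintf("%d %d", seq_along(dag$eta), dag$eta), con)
  invisible(file)
}
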