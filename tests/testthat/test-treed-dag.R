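# Tree construction, reference partitioning, cherry picking, graph queries.

grid_locs <- function(side, q = 1L) {
  s <- seq(0, 1, length.out = side)
  g <- as.matrix(expand.grid(s, s))
  expanded_locs(g[rep(seq_len(nrow(g)), q), , drop = FALSE],
                rep(seq_len(q), each = nrow(g)), q = q)
}

test_that("reference partition sizes follow the level budget", {
  locs <- grid_locs(4)  # 16 points
  p1 <- partition_reference(locs, M = 1, per_level_size = 16, branching = 2)
  expect_length(p1$levels[[1]], 1)
  expect_setequal(p1$levels[[1]][[1]]$ids, 1:16)
  expect_length(p1$leftover, 0)

  p2 <- partition_reference(locs, M = 2, per_level_size = c(4, 3),
                            branching = 2)
  expect_equal(length(p2$levels[[1]][[1]]$ids), 4)
  expect_length(p2$levels[[2]], 2)
  expect_equal(lengths(lapply(p2$levels[[2]], `[[`, "ids")), c(3L, 3L))
  expect_length(p2$leftover, 6)
  # disjoint subsets covering everything
  all_ids <- c(unlist(lapply(unlist(p2$levels, recursive = FALSE),
                             `[[`, "ids")), p2$leftover)
  expect_setequal(all_ids, 1:16)
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("root bias preferentially retains the sparse variable at the root", {
  set.seed(42)
  n <- 400
  vr <- ifelse(runif(n) < 0.1, 2L, 1L)
  locs <- expanded_locs(cbind(runif(n), runif(n)), vr, q = 2)
  p <- partition_reference(locs, M = 2, per_level_size = 30, branching = 2,
                           root_bias_var = 2L)
  root_ids <- p$levels[[1]][[1]]$ids
  frac_root <- mean(locs$var[root_ids] == 2)
  expect_gt(frac_root, mean(vr == 2))
})

test_that("depth controls the parent structure", {
  locs <- grid_locs(8)
  part <- partition_reference(locs, M = 4, per_level_size = 4, branching = 2)
  d1 <- build_tree(part, depth = 1)
  for (i in seq_along(d1$level)) {
    expect_length(d1$parents[[i]], if (d1$level[i] == 0) 0 else 1)
  }
  d4 <- build_tree(part, depth = 4)
  for (i in seq_along(d4$level)) {
    ps <- d4$parents[[i]]
    expect_length(ps, d4$level[i])
    # fully nested: parent sets of parents are subsets
    for (p in ps) expect_true(all(d4$parents[[p]] %in% ps))
  }
  expect_error(build_tree(part, depth = 5), "depth")
  expect_error(build_tree(part, depth = 0), "depth")
  # M = 1: parentless roots only
  p1 <- partition_reference(locs, M = 1, per_level_size = 10, branching = 2)
  t1 <- build_tree(p1, 1)
  expect_true(all(lengths(t1$parents) == 0))
})

test_that("cherry picking matches an exhaustive nearest-reference search", {
  set.seed(7)
  locs <- toy_locs(60, seed = 7)
  dag <- spamtree_dag(locs, M = 2, depth = 2, per_level_size = 6,
                      branching = 2)
  term <- terminal_branches(dag)
  u_ids <- which(!dag$is_reference)
  expect_gt(length(u_ids), 0)
  cand <- unlist(dag$node_locs[term])
  cand_node <- rep(term, lengths(dag$node_locs[term]))
  for (u in u_ids[1:10]) {
    d <- sqrt(colSums((t(locs$coords[cand, , drop = FALSE]) -
                         locs$coords[u, ])^2))
    best <- cand_node[which.min(d)]
    leaf <- dag$eta[u]
    expect_equal(dag$tile_parent[leaf], best)
  }
  # a location coincident with a reference point maps to that terminal
  r <- dag$node_locs[[term[1]]][1]
  t_hit <- treedgp:::assign_terminal(dag, locs$coords[r, , drop = FALSE],
                                     locs$var[r])
  expect_equal(t_hit, term[1])
})

test_that("same-variable-first cherry picking finds a same-variable parent", {
  # two clusters: terminal A holds only variable-1 references near the
  # query; terminal B holds the query's variable farther away
  coords <- rbind(c(0.1, 0.1), c(0.12, 0.1), c(0.9, 0.9), c(0.88, 0.9),
                  c(0.15, 0.12))
  vr <- c(1L, 1L, 2L, 2L, 2L)
  locs <- expanded_locs(coords, vr, q = 2)
  dag <- spamtree_dag(locs, M = 1, depth = 1, per_level_size = 2, n_roots = 2,
                      candidates = 1:4, same_variable_first = TRUE)
  leaf <- dag$eta[5]
  parents_locs <- unlist(dag$node_locs[dag$parents[[leaf]]])
  expect_true(any(locs$var[parents_locs] == 2))
  # without the filter the nearest reference is variable 1
  dag2 <- spamtree_dag(locs, M = 1, depth = 1, per_level_size = 2,
                       n_roots = 2, candidates = 1:4,
                       same_variable_first = FALSE)
  parents2 <- unlist(dag2$node_locs[dag2$parents[[dag2$eta[5]]]])
  expect_true(all(locs$var[parents2] == 1))
})

test_that("graph queries match brute-force enumeration", {
  fx <- toy_fixture(40, M = 3, depth = 2, per_level = 3, seed = 11)
  dag <- fx$dag
  m <- length(dag$level)
  anc <- function(i) {
    out <- integer(0); front <- dag$parents[[i]]
    while (length(front)) {
      out <- union(out, front)
      front <- unique(unlist(dag$parents[front]))
    }
    out
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    cd <- common_descendants(dag, i, j)
    brute <- intersect(union(i, which(vapply(seq_len(m), function(k)
      i %in% dag$parents[[k]], logical(1)))),
      union(j, which(vapply(seq_len(m), function(k)
        j %in% dag$parents[[k]], logical(1)))))
    expect_setequal(cd, brute)
  }
  # cd(v, v) always contains v
  for (i in seq_len(m)) expect_true(i %in% common_descendants(dag, i, i))
  # concestor = deepest common node on the two ancestor paths
  for (i in seq_len(m)) for (j in seq_len(m)) {
    common <- intersect(c(i, anc(i)), c(j, anc(j)))
    if (length(common) == 0) {
      expect_error(concestor(dag, i, j), "disjoint")
    } else {
      expect_equal(concestor(dag, i, j),
                   common[which.max(dag$level[common])])
    }
  }
  # delta = 1: cd(child, parent) is the child alone
  d1 <- toy_fixture(40, M = 3, depth = 1, per_level = 3, seed = 11)$dag
  for (i in seq_along(d1$level)) {
    for (p in d1$parents[[i]]) {
      expect_setequal(common_descendants(d1, i, p), i)
    }
  }
})

test_that("fixed colorings are valid for full depth and depth one", {
  blanket <- function(dag, i) {
    kids <- dag$children[[i]]
    co <- unique(unlist(dag$parents[kids]))
    sort(setdiff(union(union(dag$parents[[i]], kids), co), i))
  }
  fx <- toy_fixture(50, M = 3, depth = 3, per_level = 4, seed = 13)
  for (i in seq_along(fx$dag$level)) {
    expect_false(any(fx$dag$level[blanket(fx$dag, i)] == fx$dag$level[i]))
  }
  d1 <- toy_fixture(50, M = 3, depth = 1, per_level = 4, seed = 13)$dag
  for (i in seq_along(d1$level)) {
    expect_false(any(d1$level[blanket(d1, i)] %% 2 == d1$level[i] %% 2))
  }
})

test_that("every location maps to exactly one node and the dag validates", {
  for (cfg in list(c(2, 1), c(3, 2), c(3, 3))) {
    fx <- toy_fixture(45, M = cfg[1], depth = cfg[2], per_level = 3,
                      seed = cfg[1] * 10 + cfg[2])
    expect_true(validate_dag(fx$dag))
    expect_false(anyNA(fx$dag$eta))
    expect_setequal(unlist(fx$dag$node_locs), seq_len(45))
    # eta restricted to a reference subset is constant
    for (i in which(fx$dag$kind == "branch")) {
      expect_true(all(fx$dag$eta[fx$dag$node_locs[[i]]] == i))
    }
    # acyclicity: canonical order is a topological order
    for (i in seq_along(fx$dag$level)) {
      expect_true(all(fx$dag$parents[[i]] < i))
    }
  }
})

test_that("dag dump format is a parseable edge list plus assignment table", {
  fx <- toy_fixture(30, M = 2, depth = 2, per_level = 4, seed = 5)
  f <- tempfile()
  write_dag(fx$dag, f)
  lines <- readLines(f)
  split_at <- which(lines == "# location_id node_id")
  edges <- read.table(text = lines[2:(split_at - 1)],
                      col.names = c("child", "parent", "level", "kind"))
  expect_true(all(edges$parent < edges$child | edges$parent == 0))
  assign_tab <- read.table(text = lines[(split_at + 1):length(lines)],
                           col.names = c("loc", "node"))
  expect_equal(assign_tab$node, fx$dag$eta)
})
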