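test_that("tanimoto coefficient on hand-checked sets", {
  expect_equal(tanimoto(c("a", "b"), c("a", "b")), 1)
  expect_equal(tanimoto(c("a", "b"), c("c", "d")), 0)
  expect_equal(tanimoto(c("t1", "t2", "t3"), c("t2", "t3", "t4")), 0.5)
  expect_error(tanimoto(character(), "a"), "empty")
})

test_that("tanimoto is symmetric, 1 on identity, 0 iff disjoint", {
  set.seed(42)
  universe <- sprintf("t%d", 1:12)
  for (i in 1:25) {
    a <- sample(universe, sample(1:8, 1))
    b <- sample(universe, sample(1:8, 1))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, a), 1)
    expect_identical(tanimoto(a, b) == 0, length(intersect(a, b)) == 0)
  }
})

test_that("planted support clusters are recovered at a separating threshold", {
  ps <- generate_supports(3, per_cluster = 4, universe = 40,
                          within_sim = 0.8, between_sim = 0.2, seed = 11)
  cl <- cluster_invariants(ps$invariants, threshold = 0.65)
  expect_equal(length(cl$clusters), 3)
  truth <- split(rownames(ps$invariants$vectors),
                 ps$labels_in_invariant_order)
  expect_identical(partition_signature(cl$clusters),
                   partition_signature(truth))
  ## identical supports collapse to one cluster
  one <- generate_supports(1, per_cluster = 3, universe = 20, seed = 2)
  expect_equal(length(cluster_invariants(one$invariants, 0.65)$clusters), 1)
})

test_that("clustering is a partition and cluster count is monotone in the threshold", {
  cm <- build_core_model()
  ti <- classify_trivial(minimal_t_invariants(cm$net))
  ids <- rownames(ti$vectors)[!ti$trivial]
  prev <- NULL
  for (th in c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95)) {
    cl <- cluster_invariants(ti, threshold = th)
    members <- unlist(cl$clusters, use.names = FALSE)
    expect_setequal(members, ids)         # exhaustive
    expect_equal(anyDuplicated(members), 0)  # disjoint
    if (!is.null(prev)) expect_gte(length(cl$clusters), prev)
    prev <- length(cl$clusters)
  }
  expect_error(cluster_invariants(ti, threshold = 0), "threshold")
})

test_that("both clustering modes are deterministic and agree on planted data", {
  ps <- generate_supports(3, per_cluster = 3, universe = 40, seed = 5)
  for (mode in c("dendrogram", "pairwise")) {
    c1 <- cluster_invariants(ps$invariants, 0.65, mode = mode)
    c2 <- cluster_invariants(ps$invariants, 0.65, mode = mode)
    expect_identical(c1$clusters, c2$clusters)
    expect_equal(length(c1$clusters), 3)
  }
})

test_that("mcts groups transitions by identical invariant membership", {
  ## supports {a,b,c} and {a,b,d}: one non-trivial class {a,b}
  v <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1))
  colnames(v) <- c("a", "b", "c", "d")
  invs <- invariant_set(v, colnames(v), "T")
  invs$trivial <- c(FALSE, FALSE)
  part <- mcts(invs)
  expect_equal(length(part$sets), 1)
  expect_setequal(part$sets$M1, c("a", "b"))
  expect_setequal(part$singletons, c("c", "d"))

  ## a single invariant: one class equal to its whole support
  one <- invariant_set(matrix(c(1, 1, 1), 1), c("x", "y", "z"), "T")
  one$trivial <- FALSE
  p1 <- mcts(one)
  expect_setequal(p1$sets$M1, c("x", "y", "z"))
})

test_that("mcts classes match a brute-force pattern-grouping oracle", {
  for (s in c(1, 4, 9)) {
    pn <- generate_net(3, 4, n_bridges = 2, read_arcs = 1, seed = s,
                       grunwald_safe = TRUE)
    ti <- classify_trivial(minimal_t_invariants(pn$net))
    part <- mcts(ti)
    ## oracle: group by membership pattern column-by-column
    v <- ti$vectors[!ti$trivial, , drop = FALSE] > 0
    pat <- apply(v, 2, paste, collapse = "|")
    oracle <- split(colnames(v), pat)
    oracle <- oracle[vapply(oracle, function(g) any(v[, g[1]]), logical(1))]
    oracle_big <- oracle[lengths(oracle) >= 2]
    expect_identical(partition_signature(part$sets),
                     partition_signature(oracle_big))
    ## classes are disjoint and pattern-equal within class
    all_members <- unlist(part$sets)
    expect_equal(anyDuplicated(all_members), 0)
    for (g in part$sets) {
      expect_equal(length(unique(pat[g])), 1)
    }
    ## maximality: merging two distinct classes breaks pattern equality
    if (length(part$sets) >= 2) {
      expect_false(pat[part$sets[[1]][1]] == pat[part$sets[[2]][1]])
    }
    ## every class lies entirely inside or outside each support
    for (g in part$sets) {
      inside <- rowSums(v[, g, drop = FALSE]) # per invariant
      expect_true(all(inside == 0 | inside == length(g)))
    }
  }
})

test_that("a shared common core across clusters comes back as one MCTS", {
  ps <- generate_supports(2, per_cluster = 3, universe = 40, seed = 8,
                          common_core = 4)
  invs <- ps$invariants
  invs$trivial <- rep(FALSE, nrow(invs$vectors))
  part <- mcts(invs)
  shared <- Reduce(intersect, ps$supports)
  hit <- vapply(part$sets, function(g) setequal(g, shared), logical(1))
  expect_true(any(hit))
})

test_that("coverage table counts invariants containing whole sets", {
  v <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1))
  colnames(v) <- c("a", "b", "c", "d")
  invs <- invariant_set(v, colnames(v), "T")
  invs$trivial <- c(FALSE, FALSE)
  part <- mcts(invs)
  cl <- cluster_invariants(invs, threshold = 0.4)
  tab <- coverage_table(invs, part, cl)
  ## the {a,b} class is in both invariants; c and d in one each
  expect_equal(tab$count[tab$set == "M1"], 2)
  expect_equal(tab$count[tab$set == "c"], 1)
  expect_true(all(tab$count <= nrow(v)))
  expect_true(all(c("C1") %in% colnames(tab)))
})
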