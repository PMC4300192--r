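test_that("thresholding q-values reproduces the enumerated 3-gene network", {
  # packed order: (B,A), (C,A), (C,B)
  stats <- stats_with_q(c(0.01, 0.20, 0.04), gene_ids = c("A", "B", "C"))
  net <- build_adjacency(stats, tau = 0.05)
  expected <- matrix(c(0, 1, 0,
                       1, 0, 1,
                       0, 1, 0), 3, 3, byrow = TRUE)
  expect_equal(unname(net$adjacency), expected)
  expect_identical(net$connectivity, c(1L, 2L, 1L))
})

test_that("tau boundaries give the complete and the q=0 graph", {
  set.seed(3)
  q <- runif(15)          # k = 6
  q[c(2, 9)] <- 0
  stats <- stats_with_q(q)
  full <- build_adjacency(stats, tau = 1)
  expect_identical(full$connectivity, rep(5L, 6))
  none <- build_adjacency(stats, tau = 0)
  expect_identical(sum(none$adjacency) / 2, 2)   # only the exact zeros
  expect_error(build_adjacency(stats, tau = 1.5), "\\[0, 1\\]")
})

test_that("adjacency is symmetric, hollow, and conserves the degree sum", {
  for (seed in 1:5) {
    set.seed(seed)
    stats <- stats_with_q(runif(45), gene_ids = sprintf("g%02d", 1:10))
    net <- build_adjacency(stats, tau = 0.4)
    expect_identical(net$adjacency, t(net$adjacency))
    expect_identical(unname(diag(net$adjacency)), rep(0, 10))
    expect_identical(sum(net$connectivity), as.integer(sum(net$adjacency)))
    expect_identical(sum(net$connectivity) %% 2L, 0L)  # = 2|E|
  }
})

test_that("raising tau never removes an edge", {
  set.seed(12)
  stats <- stats_with_q(runif(190))
  taus <- sort(runif(6))
  prev <- build_adjacency(stats, tau = taus[1])$adjacency
  for (tau in taus[-1]) {
    cur <- build_adjacency(stats, tau = tau)$adjacency
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("pruning removes exactly the zero-connectivity genes", {
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- 1                   # single edge A-B
  net <- net_from_adjacency(a, gene_ids = LETTERS[1:5])
  pruned <- prune_isolated(net)
  expect_identical(pruned$gene_ids, c("A", "B"))
  expect_identical(pruned$original_index, 1:2)
  expect_identical(attr(pruned, "removed_gene_ids"), c("C", "D", "E"))
  expect_true(all(pruned$connectivity >= 1L))

  # no isolated nodes -> identity
  k3 <- net_from_adjacency(1 - diag(3))
  expect_identical(prune_isolated(k3)$adjacency, k3$adjacency)

  empty <- net_from_adjacency(matrix(0, 4, 4))
  expect_error(prune_isolated(empty), "larger tau")
})

test_that("topological overlap matches the hand-derived small graphs", {
  # triangle: every off-diagonal s = (1+1)/(2+2-1-1) = 1
  k3 <- net_from_adjacency(1 - diag(3))
  s3 <- topological_similarity(k3)$s
  expect_equal(unname(s3), matrix(1, 3, 3))

  # path A-B-C: s(A,C) = (1+0)/(1+1-1-0) = 1, s(A,B) = (0+1)/(1+2-0-1) = 0.5
  ap <- matrix(0, 3, 3)
  ap[1, 2] <- ap[2, 1] <- ap[2, 3] <- ap[3, 2] <- 1
  sp <- topological_similarity(net_from_adjacency(ap))$s
  expect_equal(sp[1, 3], 1)
  expect_equal(sp[1, 2], 0.5)
  expect_equal(sp[2, 3], 0.5)

  # single edge: s = (0+1)/(1+1-0-1) = 1
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(topological_similarity(net_from_adjacency(a2))$s),
               matrix(1, 2, 2))
})

test_that("matrix-product shared-neighbor counts equal the brute force", {
  for (seed in 1:10) {
    k <- sample(10:60, 1)
    a <- rand_adjacency(k, runif(1, 0.1, 0.5), seed = seed)
    a[1, ] <- a[, 1] <- 0; a[1, 2] <- a[2, 1] <- 1   # keep node 1 connected
    net <- net_from_adjacency(a)
    if (any(net$connectivity == 0)) net <- prune_isolated(net)
    sim <- topological_similarity(net)
    expect_identical(sim$h, h_brute(net$adjacency))
  }
})

test_that("similarity invariants hold on random pruned networks", {
  for (seed in 21:25) {
    net <- prune_isolated(net_from_adjacency(rand_adjacency(40, 0.15, seed)))
    sim <- topological_similarity(net)
    k <- sim$k
    off <- !diag(TRUE, k)
    expect_identical(sim$s, t(sim$s))
    expect_identical(unname(diag(sim$s)), rep(1, k))
    expect_true(all(sim$s >= 0 & sim$s <= 1))
    # Eq-style denominator stays >= 1 off-diagonal on pruned networks
    denom <- outer(sim$connectivity, sim$connectivity, "+") -
      sim$h - net$adjacency
    expect_true(all(denom[off] >= 1))
    # nodes with identical neighbor sets score exactly 1
    same <- which(off & sim$s == 1, arr.ind = TRUE)
    for (r in seq_len(nrow(same))) {
      i <- same[r, 1]; j <- same[r, 2]
      ni <- net$adjacency[i, -c(i, j)]
      nj <- net$adjacency[j, -c(i, j)]
      expect_identical(ni, nj)
    }
  }
})

test_that("unpruned input to the similarity step is a hard error", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  expect_error(topological_similarity(net_from_adjacency(a)),
               "prune_isolated")
})
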