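test_that("connected components become the initial communities", {
  empty <- makeAdj(matrix(0, 5, 5))
  p <- connectedComponents(empty)
  expect_equal(nCommunities(p), 5L)
  expect_equal(unname(communitySizes(p)), rep(1L, 5))
  expect_false(any(indivisibleFlags(p)))

  complete <- makeAdj(1 - diag(4))
  expect_equal(nCommunities(connectedComponents(complete)), 1L)

  twoTriangles <- adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                       c(4, 5), c(4, 6), c(5, 6)))
  p2 <- connectedComponents(twoTriangles)
  expect_equal(nCommunities(p2), 2L)
  expect_equal(unname(communitySizes(p2)), c(3L, 3L))
  # BFS oracle: same components
  expect_true(samePartition(unname(communityLabels(p2)),
                            c(1, 1, 1, 2, 2, 2)))
  # no edge crosses labels
  lab <- unname(communityLabels(p2))
  A <- adjacencyValues(twoTriangles)
  expect_true(all(A[outer(lab, lab, `!=`)] == 0))
})

test_that("modularity reproduces hand-computed values", {
  part <- function(A, lab) new("CommunityPartition",
                               labels = as.integer(lab),
                               indivisible = rep(TRUE, max(lab)),
                               channelIds = channelIds(A))
  complete <- makeAdj(1 - diag(4))
  expect_equal(modularityScore(complete, part(complete, rep(1, 4))), 0)

  twoTriangles <- adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                       c(4, 5), c(4, 6), c(5, 6)))
  expect_equal(modularityScore(twoTriangles,
                               part(twoTriangles, c(1, 1, 1, 2, 2, 2))),
               0.5)

  bridge <- bridgeGraph()
  expect_equal(modularityScore(bridge, part(bridge, c(1, 1, 1, 2, 2, 2))),
               5 / 14)

  edgeless <- makeAdj(matrix(0, 3, 3))
  expect_warning(q <- modularityScore(edgeless, part(edgeless, 1:3)),
                 "edgeless")
  expect_equal(q, 0)
})

test_that("modularity agrees with igraph and the brute-force oracle", {
  set.seed(101)
  for (rep in 1:5) {
    A <- randomAdj(10, 0.35)
    if (countEdges(A) == 0) next
    lab <- sample(1:3, 10, replace = TRUE)
    lab <- match(lab, unique(lab))  # contiguous
    p <- new("CommunityPartition", labels = as.integer(lab),
             indivisible = rep(TRUE, max(lab)), channelIds = channelIds(A))
    q <- modularityScore(A, p)
    expect_equal(q, bruteModularity(adjacencyValues(A), lab),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(adjacencyValues(A),
                                             mode = "undirected")
    expect_equal(q, igraph::modularity(g, lab), tolerance = 1e-12)
  }
})

test_that("generalized modularity matrices have zero row sums", {
  set.seed(111)
  for (rep in 1:5) {
    A <- randomAdj(12, 0.3)
    if (countEdges(A) == 0) next
    M <- generalizedModularityMatrix(A, 1:12)
    expect_lt(max(abs(rowSums(M@values))), 1e-12)
    sub <- sort(sample(1:12, 5))
    Msub <- generalizedModularityMatrix(A, sub)
    expect_lt(max(abs(rowSums(Msub@values))), 1e-12)
  }
  # single-node subset is a 1x1 zero matrix
  bridge <- bridgeGraph()
  expect_equal(generalizedModularityMatrix(bridge, 3)@values,
               matrix(0, 1, 1))
  expect_error(generalizedModularityMatrix(makeAdj(matrix(0, 3, 3)), 1:3),
               "edgeless")
  expect_error(generalizedModularityMatrix(bridge, integer(0)),
               "non-empty")
})

test_that("subset modularity matrix matches entry-by-entry hand evaluation", {
  bridge <- bridgeGraph()
  A <- adjacencyValues(bridge)
  deg <- rowSums(A)
  m <- 7
  sub <- 1:3  # one triangle of the bridge graph
  expected <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    expected[i, j] <- A[sub[i], sub[j]] - deg[sub[i]] * deg[sub[j]] / (2 * m)
  for (i in 1:3)
    expected[i, i] <- expected[i, i] - sum(
      A[sub[i], sub] - deg[sub[i]] * deg[sub] / (2 * m))
  got <- generalizedModularityMatrix(bridge, sub)@values
  expect_equal(unname(got), expected, tolerance = 1e-14)
})

test_that("leading-eigenvector split separates planted halves", {
  # 1x1 zero matrix: lambda 0, no split
  one <- generalizedModularityMatrix(bridgeGraph(), 2)
  sp <- leadingEigenvectorSplit(one)
  expect_equal(sp$lambdaMax, 0)
  expect_equal(sp$membership, 1L)

  # two disjoint triangles, full-graph matrix
  twoTriangles <- adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                       c(4, 5), c(4, 6), c(5, 6)))
  M <- generalizedModularityMatrix(twoTriangles, 1:6)
  sp <- leadingEigenvectorSplit(M)
  expect_gt(sp$lambdaMax, 0)
  expect_true(samePartition(sp$membership, c(1, 1, 1, 2, 2, 2)))
  # brute force: the sign pattern maximizing s' M s is the triangle split
  best <- NULL; bestVal <- -Inf
  for (bits in 0:63) {
    s <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, 1, -1)
    v <- drop(t(s) %*% M@values %*% s)
    if (v > bestVal) { bestVal <- v; best <- s }
  }
  expect_true(samePartition(ifelse(best > 0, 1, 2), sp$membership))

  # bridge graph: split separates the two triangles
  spB <- leadingEigenvectorSplit(
    generalizedModularityMatrix(bridgeGraph(), 1:6))
  expect_true(samePartition(spB$membership, c(1, 1, 1, 2, 2, 2)))
})

test_that("detectCommunities recovers planted structure deterministically", {
  # empty graph: all singletons, all indivisible
  p <- detectCommunities(makeAdj(matrix(0, 4, 4)))
  expect_equal(nCommunities(p), 4L)
  expect_true(all(indivisibleFlags(p)))

  # two 5-cliques joined by one edge
  clique <- function(off) {
    es <- list()
    for (i in 1:4) for (j in (i + 1):5) es <- c(es, list(off + c(i, j)))
    es
  }
  A <- adjFromEdges(10, c(clique(0), clique(5), list(c(5, 6))))
  p <- detectCommunities(A)
  lab <- unname(communityLabels(p))
  expect_true(samePartition(lab, rep(1:2, each = 5)))
  expect_true(all(indivisibleFlags(p)))

  # its modularity equals the best bipartition found exhaustively
  q <- modularityScore(A, p)
  bestQ <- -Inf
  for (bits in 0:511) {
    s <- c(0, ifelse(bitwAnd(bits, 2^(0:8)) > 0, 1, 0))
    labs <- s + 1
    if (length(unique(labs)) < 2) next
    bestQ <- max(bestQ, bruteModularity(adjacencyValues(A), labs))
  }
  expect_equal(q, bestQ, tolerance = 1e-12)

  # determinism
  p2 <- detectCommunities(A)
  expect_identical(communityLabels(p), communityLabels(p2))
})

test_that("splits never decrease modularity below the initial partition", {
  set.seed(131)
  for (rep in 1:6) {
    A <- randomAdj(12, 0.25)
    if (countEdges(A) == 0) next
    q0 <- suppressWarnings(modularityScore(A, connectedComponents(A)))
    q1 <- suppressWarnings(modularityScore(A, detectCommunities(A)))
    expect_gte(q1, q0 - 1e-9)
  }
})

test_that("detected partitions are near the exhaustive optimum on small graphs", {
  set.seed(141)
  for (rep in 1:4) {
    A <- randomAdj(8, 0.35)
    if (countEdges(A) == 0) next
    p <- detectCommunities(A)
    q <- suppressWarnings(modularityScore(A, p))
    bestQ <- max(vapply(enumeratePartitions(8, 4), function(lab)
      bruteModularity(adjacencyValues(A), lab), 0))
    expect_gte(q, bestQ - 0.05)
  }
})

test_that("communities never span connected components", {
  set.seed(151)
  for (rep in 1:5) {
    A <- randomAdj(14, 0.12)
    comp <- unname(communityLabels(connectedComponents(A)))
    lab <- unname(communityLabels(detectCommunities(A)))
    # every detected community lies inside one component
    for (c in unique(lab))
      expect_length(unique(comp[lab == c]), 1)
  }
})

test_that("community summaries count sizes under a parameterized cutoff", {
  mkPart <- function(sizes) {
    lab <- rep(seq_along(sizes), sizes)
    new("CommunityPartition", labels = as.integer(lab),
        indivisible = rep(TRUE, length(sizes)),
        channelIds = paste0("c", seq_along(lab)))
  }
  s <- communitySummary(mkPart(c(3, 3, 3)))
  expect_equal(s$nC, 3)
  expect_equal(s$nLarge, 3)

  s2 <- communitySummary(mkPart(rep(1, 5)))
  expect_equal(s2$nC, 5)
  expect_equal(s2$nLarge, 0)

  # multi-member reading (>= 2) vs strict "greater than two" (>= 3)
  s3 <- communitySummary(mkPart(c(1, 1, 2, 3, 4)))
  expect_equal(s3$nLarge, 3)
  s4 <- communitySummary(mkPart(c(1, 1, 2, 3, 4)), minSize = 3)
  expect_equal(s4$nLarge, 2)
  expect_equal(as.integer(s3$sizeHistogram), c(2L, 1L, 1L, 1L))
})

test_that("detection matches igraph's leading-eigenvector on the benchmark graph", {
  ds <- generateBenchmark(smallBenchCfg(4))
  S <- pearsonSimilarity(winsorize(ds))
  sw <- selectThreshold(qgpSweep(S, candidateThresholds()), S)
  A <- applyThreshold(S, sw@tS)
  mine <- unname(communityLabels(detectCommunities(A)))
  g <- igraph::graph_from_adjacency_matrix(adjacencyValues(A),
                                           mode = "undirected")
  ref <- igraph::membership(igraph::cluster_leading_eigen(g))
  expect_true(samePartition(mine, as.integer(ref)))
})
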