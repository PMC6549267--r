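## Independent brute-force oracles and small fixture builders. These are
## deliberately naive (triple enumeration, BFS, exhaustive search) and
## share no code with the package implementation.

## Wrap a plain 0/1 matrix as an AdjacencyMatrix.
makeAdj <- function(mat, ids = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(mat)))
  new("AdjacencyMatrix", values = mat, channelIds = ids,
      threshold = NA_real_)
}

## Adjacency matrix from an edge list on n nodes.
adjFromEdges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  makeAdj(A)
}

## Erdos-Renyi style random adjacency matrix.
randomAdj <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A <- A + t(A)
  makeAdj(A)
}

## Two triangles {1,2,3} and {4,5,6} joined by the bridge edge (3,4).
bridgeGraph <- function() {
  adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 3),
                       c(4, 5), c(4, 6), c(5, 6), c(3, 4)))
}

## Full-grid MSIDataset from an intensity matrix (pixels in y-major
## order, x fastest), grid width m.
makeDataset <- function(D, m, n) {
  stopifnot(nrow(D) == m * n)
  MSIDataset(D, as.matrix(expand.grid(x = seq_len(m), y = seq_len(n))),
             mzValues = 100 * seq_len(ncol(D)))
}

## Average local clustering coefficient by triple enumeration.
bruteClustering <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_len(a - 1))
      if (adj[nb[a], nb[b]] == 1) links <- links + 1
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

## Global efficiency from BFS all-pairs distances; disconnected pairs
## contribute zero.
bruteEfficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  total <- 0
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in which(adj[v, ] == 1))
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    fin <- is.finite(d[-s]) & d[-s] > 0
    total <- total + sum(1 / d[-s][fin])
  }
  total / (n * (n - 1))
}

## Newman modularity computed directly from the definition.
bruteModularity <- function(adj, labels) {
  m <- sum(adj[upper.tri(adj)])
  deg <- rowSums(adj)
  sum(vapply(unique(labels), function(c) {
    nodes <- which(labels == c)
    sum(adj[nodes, nodes]) / (2 * m) - (sum(deg[nodes]) / (2 * m))^2
  }, 0))
}

## TRUE iff two labelings describe the same partition (up to renaming).
samePartition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

## All set partitions of n elements into at most maxBlocks blocks,
## as restricted growth strings.
enumeratePartitions <- function(n, maxBlocks = n) {
  out <- list()
  recurse <- function(prefix, used) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(min(used + 1, maxBlocks)))
      recurse(c(prefix, b), max(used, b))
  }
  recurse(integer(0), 0L)
  out
}

## Leading eigenpair of a symmetric 2x2 matrix by the quadratic formula.
eigen2x2 <- function(a, b, c) {
  disc <- sqrt((a - c)^2 + 4 * b^2)
  lambda <- (a + c + disc) / 2
  if (abs(b) < 1e-300) {
    u <- if (a >= c) c(1, 0) else c(0, 1)
  } else {
    u <- c(b, lambda - a)
    u <- u / sqrt(sum(u^2))
  }
  list(lambda = lambda, u = u)
}

## Small, fast benchmark configuration used throughout the unit tests
## (same geometry rules as the default, scaled down).
smallBenchCfg <- function(seed = 1L) {
  BenchmarkConfig(gridShape = c(60L, 55L), baseSigma = 7, seed = seed)
}
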