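## Community detection: leading-eigenvector modularity method with
## connected-component initialization, lambda <= 0 stop criterion and
## "indivisible" labeling.

.newPartition <- function(groups, indivisible, channelIds) {
  ## groups: list of integer node-index vectors; relabeled contiguously
  ## by smallest member so results are order-independent.
  ord <- order(vapply(groups, min, 0L))
  groups <- groups[ord]
  indivisible <- indivisible[ord]
  labels <- integer(sum(lengths(groups)))
  for (i in seq_along(groups)) labels[groups[[i]]] <- i
  new("CommunityPartition", labels = labels,
      indivisible = indivisible, channelIds = channelIds)
}

#' Connected components as the initial partition
#'
#' The classical leading-eigenvector method initializes all nodes in one
#' community; thresholded MSI colocalization graphs are routinely
#' disconnected, so the method here starts from the connected components
#' instead: each component becomes one (not yet indivisible) community,
#' and no later split can merge across components.
#'
#' @param A an [AdjacencyMatrix-class].
#' @return a [CommunityPartition-class] with `indivisible` all FALSE.
#' @export
connectedComponents <- function(A) {
  stopifnot(is(A, "AdjacencyMatrix"))
  if (nrow(A@values) == 0L)
    return(new("CommunityPartition", labels = integer(0),
               indivisible = logical(0), channelIds = A@channelIds))
  comp <- igraph::components(.asIgraph(A))
  groups <- split(seq_along(comp$membership), comp$membership)
  .newPartition(unname(lapply(groups, as.integer)),
                rep(FALSE, length(groups)), A@channelIds)
}

#' @export
setMethod("communityLabels", "CommunityPartition", function(object) {
  stats::setNames(object@labels, object@channelIds)
})

#' @export
setMethod("nCommunities", "CommunityPartition", function(object) {
  if (length(object@labels) == 0L) 0L else max(object@labels)
})

#' @export
setMethod("communitySizes", "CommunityPartition", function(object) {
  tabulate(object@labels, nbins = nCommunities(object))
})

#' @export
setMethod("indivisibleFlags", "CommunityPartition", function(object)
  object@indivisible)

setMethod("show", "CommunityPartition", function(object) {
  sz <- communitySizes(object)
  cat(sprintf("CommunityPartition: %d nodes in %d communities\n",
              length(object@labels), nCommunities(object)))
  if (length(sz))
    cat("  sizes:", paste(sort(sz, decreasing = TRUE), collapse = ", "),
        "\n")
})

#' Modularity of a partition
#'
#' `Q = sum_c [ intraEdges_c / m - (degreeSum_c / (2 m))^2 ]` with `m`
#' the total number of edges. Defined as 0 (with a warning) on an
#' edgeless graph.
#'
#' @param A an [AdjacencyMatrix-class].
#' @param partition a [CommunityPartition-class] over the same nodes.
#' @return numeric modularity Q.
#' @export
modularityScore <- function(A, partition) {
  stopifnot(is(A, "AdjacencyMatrix"), is(partition, "CommunityPartition"))
  if (length(partition@labels) != nrow(A@values))
    stop("partition does not match the graph")
  m <- countEdges(A)
  if (m == 0L) {
    warning("modularity of an edgeless graph is defined as 0")
    return(0)
  }
  lab <- partition@labels
  deg <- rowSums(A@values)
  Q <- 0
  for (c in seq_len(nCommunities(partition))) {
    nodes <- which(lab == c)
    intra <- sum(A@values[nodes, nodes, drop = FALSE]) / 2
    Q <- Q + intra / m - (sum(deg[nodes]) / (2 * m))^2
  }
  Q
}

#' Generalized modularity matrix of a node subset
#'
#' Newman's formulation for splitting a community `g` in place:
#' `B_ij = A_ij - k_i k_j / (2 m)` restricted to `g`, with the diagonal
#' correction `B^(g)_ij = B_ij - delta_ij * sum_{k in g} B_ik`. Degrees
#' `k_i` and the edge count `m` are taken from the full graph, so a
#' split of `g` is judged against the whole network's null model; the
#' correction makes every row sum to zero, which is what turns "no
#' division" into the eigenvalue-zero case.
#'
#' @param A an [AdjacencyMatrix-class] with at least one edge.
#' @param subset integer node indices (non-empty).
#' @return a [ModularityMatrix-class].
#' @export
generalizedModularityMatrix <- function(A, subset) {
  stopifnot(is(A, "AdjacencyMatrix"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (any(subset < 1L) || any(subset > nrow(A@values)))
    stop("subset indices out of range")
  m <- countEdges(A)
  if (m == 0L) stop("modularity matrix undefined for an edgeless graph")
  deg <- rowSums(A@values)
  B <- A@values[subset, subset, drop = FALSE] -
    outer(deg[subset], deg[subset]) / (2 * m)
  diag(B) <- diag(B) - rowSums(B)
  new("ModularityMatrix", values = B, subset = subset)
}

#' Leading-eigenvector bipartition of a community
#'
#' Computes the leading eigenpair of a (generalized) modularity matrix
#' with a dense symmetric solver and splits the nodes by eigenvector
#' sign: `u_i >= 0` stays in the community, `u_i < 0` founds the new
#' one. The eigenvector sign is canonicalized (its largest-magnitude
#' component is made positive) so the result does not depend on solver
#' sign conventions.
#'
#' @param M a [ModularityMatrix-class].
#' @return list with `membership` (integer 1/2 per subset node, 1 = the
#'   `u_i >= 0` side) and `lambdaMax` (leading eigenvalue).
#' @export
leadingEigenvectorSplit <- function(M) {
  stopifnot(is(M, "ModularityMatrix"))
  V <- M@values
  if (nrow(V) == 1L)
    return(list(membership = 1L, lambdaMax = V[1L, 1L]))
  eig <- eigen(V, symmetric = TRUE)
  lambdaMax <- eig$values[1L]
  u <- eig$vectors[, 1L]
  pivot <- which.max(abs(u))
  if (u[pivot] < 0) u <- -u
  list(membership = ifelse(u >= 0, 1L, 2L), lambdaMax = lambdaMax)
}

#' Detect molecular communities
#'
#' The modified leading-eigenvector method: initialize with connected
#' components; then repeatedly, for any divisible community, build its
#' generalized modularity matrix, compute the leading eigenpair, and
#' split by eigenvector sign if the leading eigenvalue exceeds `tol`.
#' A community whose eigenvalue is `<= tol`, or whose split would leave
#' one side empty (an all-one-sign eigenvector: "the best division is no
#' division"), is marked indivisible. The procedure stops when every
#' community is indivisible. `tol` is the numerical stand-in for the
#' exact "lambda = 0" stop criterion.
#'
#' @param A an [AdjacencyMatrix-class].
#' @param tol numerical zero for the leading eigenvalue (default 1e-10).
#' @param verifyGain if TRUE, additionally reject splits that do not
#'   strictly increase modularity (off by default; the plain eigenvalue
#'   criterion is the documented procedure).
#' @return a [CommunityPartition-class] with all communities flagged
#'   indivisible and labels contiguous from 1.
#' @examples
#' S <- pearsonSimilarity(generateBenchmark(BenchmarkConfig(
#'   gridShape = c(60, 55), baseSigma = 7, seed = 1)))
#' A <- applyThreshold(S, 0.6)
#' detectCommunities(A)
#' @export
detectCommunities <- function(A, tol = 1e-10, verifyGain = FALSE) {
  stopifnot(is(A, "AdjacencyMatrix"))
  n <- nrow(A@values)
  if (n == 0L)
    return(new("CommunityPartition", labels = integer(0),
               indivisible = logical(0), channelIds = A@channelIds))
  init <- connectedComponents(A)
  queue <- unname(split(seq_len(n), init@labels))
  final <- list()
  while (length(queue)) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(g) == 1L) {
      final <- c(final, list(g))
      next
    }
    M <- generalizedModularityMatrix(A, g)
    sp <- leadingEigenvectorSplit(M)
    side1 <- g[sp$membership == 1L]
    side2 <- g[sp$membership == 2L]
    accept <- sp$lambdaMax > tol && length(side1) > 0L && length(side2) > 0L
    if (accept && verifyGain) {
      before <- sum(M@values) / (2 * countEdges(A))  # zero by construction
      gain <- (sum(M@values[sp$membership == 1L, sp$membership == 1L]) +
               sum(M@values[sp$membership == 2L, sp$membership == 2L])) /
        (2 * countEdges(A))
      accept <- gain > before + tol
    }
    if (accept) {
      queue <- c(queue, list(side1), list(side2))
    } else {
      final <- c(final, list(g))
    }
  }
  .newPartition(final, rep(TRUE, length(final)), A@channelIds)
}

#' Community size summary
#'
#' Reports the number of communities, the number of "large" communities,
#' and the size histogram. The size cutoff is a parameter: the default
#' `minSize = 2` counts every multi-member community (any (n)-community
#' with n > 1); `minSize = 3` reproduces a strict "size greater than
#' two" reading.
#'
#' @param partition a [CommunityPartition-class].
#' @param minSize smallest size counted as a large community.
#' @return list with `nC`, `nLarge`, and `sizeHistogram` (a table of
#'   community sizes).
#' @export
communitySummary <- function(partition, minSize = 2L) {
  stopifnot(is(partition, "CommunityPartition"))
  sz <- communitySizes(partition)
  list(nC = nCommunities(partition),
       nLarge = sum(sz >= minSize),
       sizeHistogram = table(size = sz))
}

#' Export a partition as a two-column CSV
#'
#' @param partition a [CommunityPartition-class].
#' @param path output file.
#' @export
exportPartitionCSV <- function(partition, path) {
  stopifnot(is(partition, "CommunityPartition"))
  data.table::fwrite(data.table::data.table(
    channel_id = partition@channelIds,
    community_id = partition@labels), path)
  invisible(path)
}
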