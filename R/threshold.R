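## Threshold selection: sweep candidate thresholds, score each candidate
## graph with quantitative graph properties (QGPs), baseline against the
## normalized edge count, weight by PCA, and pick the candidate whose
## projection is maximal.

#' Candidate threshold grid
#'
#' Arithmetic sequence from `tmin` to `tmax` with step `tdelta`; the
#' endpoint is included when it is reachable within `1e-9`. The default
#' grid for Pearson similarities is `-1, -0.9, ..., 1` (21 candidates).
#'
#' @param tmin,tmax interval of candidate thresholds (`tmin < tmax`).
#' @param tdelta positive step size; smaller steps buy resolution at the
#'   price of sweep time.
#' @return numeric vector of candidates.
#' @export
candidateThresholds <- function(tmin = -1, tmax = 1, tdelta = 0.1) {
  if (!is.numeric(tdelta) || tdelta <= 0)
    stop("tdelta must be positive")
  if (tmin >= tmax) stop("tmin must be smaller than tmax")
  nSteps <- floor((tmax - tmin) / tdelta + 1e-9)
  tmin + tdelta * (0:nSteps)
}

#' Threshold a similarity matrix into an adjacency matrix
#'
#' Edge `(i, j)` survives iff `S[i, j] >= t` (only strictly smaller
#' similarities are dropped, so ties at exactly `t` are kept); the
#' diagonal is forced to zero.
#'
#' @param S a [SimilarityMatrix-class].
#' @param t threshold.
#' @return an [AdjacencyMatrix-class] defining graph G.
#' @export
applyThreshold <- function(S, t) {
  stopifnot(is(S, "SimilarityMatrix"), is.numeric(t), length(t) == 1L)
  A <- (S@values >= t) * 1
  diag(A) <- 0
  new("AdjacencyMatrix", values = A, channelIds = S@channelIds,
      threshold = t)
}

#' @export
setMethod("adjacencyValues", "AdjacencyMatrix", function(object)
  object@values)

#' @export
setMethod("channelIds", "AdjacencyMatrix", function(object)
  object@channelIds)

#' @export
setMethod("chosenThreshold", "AdjacencyMatrix", function(object)
  object@threshold)

setMethod("show", "AdjacencyMatrix", function(object) {
  cat(sprintf("AdjacencyMatrix: %d nodes, %d edges",
              nrow(object@values), countEdges(object)))
  if (!is.na(object@threshold))
    cat(sprintf(" (threshold %.4g)", object@threshold))
  cat("\n")
})

.asIgraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A@values, mode = "undirected",
                                      diag = FALSE)
}

#' Number of edges of a graph
#'
#' @param A an [AdjacencyMatrix-class].
#' @return integer upper-triangle sum `N_E`.
#' @export
countEdges <- function(A) {
  stopifnot(is(A, "AdjacencyMatrix"))
  as.integer(sum(A@values[upper.tri(A@values)]))
}

#' Average clustering coefficient (zeta)
#'
#' Mean over all nodes of the local clustering coefficient (fraction of a
#' node's neighbor pairs that are themselves connected); nodes of degree
#' < 2 contribute 0. A segregation measure: high when the graph decomposes
#' into dense subgraphs.
#'
#' @param A an [AdjacencyMatrix-class].
#' @return numeric in `[0, 1]`.
#' @export
avgClusteringCoeff <- function(A) {
  stopifnot(is(A, "AdjacencyMatrix"))
  if (nrow(A@values) == 0L) return(0)
  local <- igraph::transitivity(.asIgraph(A), type = "local",
                                isolates = "zero")
  mean(local)
}

#' Global efficiency (xi)
#'
#' Average inverse shortest-path length over all ordered node pairs,
#' `1/(N_V (N_V - 1)) * sum_{i != j} 1 / d_ij`; disconnected pairs
#' contribute 0. An integration measure: high when everything is close
#' to everything.
#'
#' @param A an [AdjacencyMatrix-class].
#' @return numeric in `[0, 1]`; defined as 0 for fewer than 2 nodes.
#' @export
globalEfficiency <- function(A) {
  stopifnot(is(A, "AdjacencyMatrix"))
  if (nrow(A@values) < 2L) return(0)
  if (countEdges(A) == 0L) return(0)
  igraph::global_efficiency(.asIgraph(A))
}

#' Sweep candidate thresholds and record raw QGPs
#'
#' Builds `A(t_i)` for each candidate and records the edge count, average
#' clustering coefficient and global efficiency, aligned with the
#' candidate vector.
#'
#' @param S a [SimilarityMatrix-class].
#' @param candidates non-empty numeric vector (see
#'   [candidateThresholds()]).
#' @return a partially filled [ThresholdSweep-class] (raw vectors only).
#' @export
qgpSweep <- function(S, candidates = candidateThresholds()) {
  stopifnot(is(S, "SimilarityMatrix"))
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  k <- length(candidates)
  nE <- numeric(k); zeta <- numeric(k); xi <- numeric(k)
  for (i in seq_len(k)) {
    A <- applyThreshold(S, candidates[i])
    nE[i] <- countEdges(A)
    zeta[i] <- avgClusteringCoeff(A)
    xi[i] <- globalEfficiency(A)
  }
  new("ThresholdSweep", candidates = as.numeric(candidates),
      nERaw = nE, zetaRaw = zeta, xiRaw = xi)
}

## Min-max normalization to [0, 1]; a constant vector maps to all zeros.
.minmax <- function(v) {
  r <- range(v)
  if (r[2L] - r[1L] == 0) return(rep(0, length(v)))
  (v - r[1L]) / (r[2L] - r[1L])
}

#' Select the edge-reduction threshold from a QGP sweep
#'
#' Completes a [ThresholdSweep-class]: min-max normalizes the three raw
#' QGP vectors to `[0, 1]`, baselines the clustering coefficient and
#' global efficiency by subtracting the normalized edge count (so the
#' structural measures no longer scale with sheer edge mass), assembles
#' `X = [eta_zeta, eta_xi]`, and projects `X` onto the leading
#' eigenvector of the covariance of the centered `X` (PCA weighting; the
#' clustering coefficient varies more and therefore dominates the
#' weighting). The selected threshold `t_S` is the candidate maximizing
#' the projection; at ties the smallest candidate wins, retaining more
#' edges.
#'
#' The eigenvector sign is fixed so its `eta_zeta` component is
#' nonnegative; the opposite orientation would minimize instead of
#' maximize the weighted objective, so the fix is load-bearing. When the
#' baselined vectors are constant (zero covariance) the weighting falls
#' back to equal weights `(1, 1)/sqrt(2)` with a warning.
#'
#' Because the similarity values rarely coincide with grid candidates,
#' the completed sweep also records `effectiveMinWeight`, the smallest
#' similarity among surviving edges at `t_S` — the tightest threshold
#' that would produce the same graph (equal to `t_S` when no edge
#' survives).
#'
#' @param sweep a [ThresholdSweep-class] from [qgpSweep()] (>= 2
#'   candidates).
#' @param S the [SimilarityMatrix-class] the sweep was computed from
#'   (used for `effectiveMinWeight`).
#' @return the completed [ThresholdSweep-class].
#' @export
selectThreshold <- function(sweep, S) {
  stopifnot(is(sweep, "ThresholdSweep"), is(S, "SimilarityMatrix"))
  k <- length(sweep@candidates)
  if (k < 2L) stop("need at least 2 candidates to select a threshold")
  if (length(sweep@nERaw) != k) stop("sweep is missing its raw QGP vectors")
  nEBase <- .minmax(sweep@nERaw)
  etaZeta <- .minmax(sweep@zetaRaw) - nEBase
  etaXi <- .minmax(sweep@xiRaw) - nEBase
  X <- cbind(etaZeta, etaXi)
  C <- stats::cov(X)   # covariance of the centered X equals cov(X)
  if (max(abs(C)) < 1e-15) {
    warning("baselined QGP vectors are constant; falling back to ",
            "equal weighting")
    u0 <- c(1, 1) / sqrt(2)
  } else {
    eig <- eigen(C, symmetric = TRUE)
    u0 <- eig$vectors[, 1L]
    if (u0[1L] < 0 || (u0[1L] == 0 && u0[2L] < 0)) u0 <- -u0
  }
  y <- as.numeric(X %*% u0)   # uncentered projection; argmax unaffected
  chosen <- which.max(y)      # first index attaining the maximum
  tS <- sweep@candidates[chosen]
  A <- applyThreshold(S, tS)
  surviving <- S@values[A@values == 1]
  emw <- if (length(surviving)) min(surviving) else tS
  new("ThresholdSweep", candidates = sweep@candidates,
      nERaw = sweep@nERaw, zetaRaw = sweep@zetaRaw, xiRaw = sweep@xiRaw,
      nEBase = nEBase, etaZeta = etaZeta, etaXi = etaXi,
      projection = y, chosenIndex = as.integer(chosen), tS = tS,
      effectiveMinWeight = emw)
}

#' @export
setMethod("chosenThreshold", "ThresholdSweep", function(object) object@tS)

setMethod("show", "ThresholdSweep", function(object) {
  cat(sprintf("ThresholdSweep: %d candidates in [%.3g, %.3g]\n",
              length(object@candidates), min(object@candidates),
              max(object@candidates)))
  if (!is.na(object@chosenIndex))
    cat(sprintf("  selected t_S = %.4g (effective min edge weight %.4g)\n",
                object@tS, object@effectiveMinWeight))
  else cat("  (threshold not yet selected)\n")
})

#' Sweep report table
#'
#' @param x a [ThresholdSweep-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with one row per candidate: `candidate`, `nE`,
#'   `zeta`, `xi`, `etaZeta`, `etaXi`, `y`, `chosen`.
#' @export
as.data.frame.ThresholdSweep <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  k <- length(x@candidates)
  pad <- function(v) if (length(v) == k) v else rep(NA_real_, k)
  data.frame(candidate = x@candidates, nE = x@nERaw, zeta = x@zetaRaw,
             xi = x@xiRaw, etaZeta = pad(x@etaZeta), etaXi = pad(x@etaXi),
             y = pad(x@projection),
             chosen = seq_len(k) == (x@chosenIndex %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Export the sweep report as CSV
#'
#' @param sweep a [ThresholdSweep-class].
#' @param path output file.
#' @export
exportSweepCSV <- function(sweep, path) {
  data.table::fwrite(as.data.frame(sweep), path)
  invisible(path)
}
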