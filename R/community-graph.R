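## The collapsed community graph G' with community and hybrid edges,
## plus the edge-reduction summary statistic.

#' Build the community graph G'
#'
#' Collapses each community to one node. Every edge of the underlying
#' graph is classified by the expansion state of its endpoints'
#' communities:
#' * both endpoints in the same community: materialized as an m/z-edge
#'   only when that community is expanded (collapsed communities hide
#'   their internal structure);
#' * different communities, neither expanded: one community edge
#'   (deduplicated) between the two collapsed nodes;
#' * different communities, exactly one expanded: a hybrid edge from the
#'   expanded side's m/z-node to the other community's collapsed node;
#' * different communities, both expanded: an m/z-edge between the two
#'   m/z-nodes.
#'
#' @param A an [AdjacencyMatrix-class].
#' @param partition a [CommunityPartition-class] consistent with `A`.
#' @param expanded integer ids of expanded communities (default none).
#' @return a [CommunityGraph-class].
#' @export
buildCommunityGraph <- function(A, partition, expanded = integer(0)) {
  stopifnot(is(A, "AdjacencyMatrix"), is(partition, "CommunityPartition"))
  if (length(partition@labels) != nrow(A@values))
    stop("partition does not match the graph")
  nC <- nCommunities(partition)
  expanded <- as.integer(expanded)
  if (length(expanded) && (any(expanded < 1L) || any(expanded > nC)))
    stop("expanded refers to unknown community ids")
  lab <- partition@labels
  members <- unname(split(seq_along(lab), lab))
  edges <- which(upper.tri(A@values) & A@values == 1, arr.ind = TRUE)
  emptyPairs <- matrix(integer(0), 0L, 2L)
  commEdges <- emptyPairs; mzEdges <- emptyPairs; hybEdges <- emptyPairs
  isExp <- seq_len(nC) %in% expanded
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      ci <- lab[i]; cj <- lab[j]
      if (ci == cj) {
        if (isExp[ci]) mzEdges <- rbind(mzEdges, c(i, j))
      } else if (!isExp[ci] && !isExp[cj]) {
        commEdges <- rbind(commEdges, c(min(ci, cj), max(ci, cj)))
      } else if (isExp[ci] && isExp[cj]) {
        mzEdges <- rbind(mzEdges, c(i, j))
      } else if (isExp[ci]) {
        hybEdges <- rbind(hybEdges, c(i, cj))
      } else {
        hybEdges <- rbind(hybEdges, c(j, ci))
      }
    }
    commEdges <- unique(commEdges)
    hybEdges <- unique(hybEdges)
  }
  storage.mode(commEdges) <- "integer"
  storage.mode(mzEdges) <- "integer"
  storage.mode(hybEdges) <- "integer"
  mzNodes <- if (length(expanded))
    sort(unlist(members[expanded], use.names = FALSE)) else integer(0)
  new("CommunityGraph",
      communityMembers = lapply(members, as.integer),
      communityEdges = commEdges, expanded = sort(unique(expanded)),
      mzNodes = as.integer(mzNodes), mzEdges = mzEdges,
      hybridEdges = hybEdges, channelIds = A@channelIds)
}

setMethod("show", "CommunityGraph", function(object) {
  cat(sprintf(paste0("CommunityGraph: %d community nodes, %d community ",
                     "edges, %d expanded\n"),
              length(object@communityMembers),
              nrow(object@communityEdges), length(object@expanded)))
  if (length(object@expanded))
    cat(sprintf("  %d m/z-nodes, %d m/z-edges, %d hybrid edges\n",
                length(object@mzNodes), nrow(object@mzEdges),
                nrow(object@hybridEdges)))
})

#' Edge reduction achieved by thresholding
#'
#' Percentage of the complete graph's `n (n - 1) / 2` edges that the
#' thresholded graph dropped, rounded to 3 decimal places (the printed
#' precision used in reports).
#'
#' @param nNodes number of nodes (>= 2).
#' @param nEdges number of surviving edges, between 0 and
#'   `nNodes (nNodes - 1) / 2`.
#' @return numeric percentage in `[0, 100]`.
#' @examples
#' edgeReductionPercent(101, 789)   # 84.376
#' edgeReductionPercent(106, 2371)  # 57.394
#' @export
edgeReductionPercent <- function(nNodes, nEdges) {
  if (!is.numeric(nNodes) || nNodes < 2)
    stop("nNodes must be at least 2")
  total <- nNodes * (nNodes - 1) / 2
  if (!is.numeric(nEdges) || nEdges < 0 || nEdges > total)
    stop("nEdges must lie in [0, nNodes*(nNodes-1)/2]")
  round(100 * (1 - nEdges / total), 3)
}
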