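## S4 class definitions and validity rules for the msinet data model.

#' MSIDataset: a pixel-by-channel MSI data cube
#'
#' Holds the intensity matrix `D` (`N_P` measured pixels by `N_V`
#' m/z-channels) together with the integer pixel grid coordinates, the
#' m/z value of every channel, and the extent of the pixel grid. Only
#' measured pixels are stored; unmeasured grid cells are simply absent
#' rows (never sentinel values), so partial tissue coverage is the normal
#' case, not an error.
#'
#' Coordinates are 1-based: `1 <= x <= gridShape[1]` (x is the column of
#' the rendered image, i.e. width) and `1 <= y <= gridShape[2]` (height).
#'
#' @slot intensities numeric matrix, `N_P` rows x `N_V` columns; finite,
#'   nonnegative.
#' @slot coords integer matrix, `N_P` rows x 2 columns (`x`, `y`); no
#'   duplicate coordinate pairs; all within `gridShape`.
#' @slot mzValues numeric, length `N_V`, strictly increasing (Da).
#' @slot channelIds character, length `N_V`, unique labels.
#' @slot gridShape integer, length 2: `c(m, n)` = (width, height).
#'
#' @seealso [MSIDataset()] for the user-facing constructor.
#' @exportClass MSIDataset
setClass("MSIDataset",
  representation(
    intensities = "matrix",
    coords      = "matrix",
    mzValues    = "numeric",
    channelIds  = "character",
    gridShape   = "integer"
  )
)

setValidity("MSIDataset", function(object) {
  D  <- object@intensities
  xy <- object@coords
  msgs <- character(0)
  if (!is.numeric(D)) msgs <- c(msgs, "intensities must be numeric")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msgs <- c(msgs, "gridShape must be two positive integers (m, n)")
  if (nrow(xy) != nrow(D))
    msgs <- c(msgs, "coords must have one row per intensity row")
  if (ncol(xy) != 2L)
    msgs <- c(msgs, "coords must have two columns (x, y)")
  if (length(object@mzValues) != ncol(D))
    msgs <- c(msgs, "mzValues length must equal the number of channels")
  if (length(object@channelIds) != ncol(D))
    msgs <- c(msgs, "channelIds length must equal the number of channels")
  if (anyDuplicated(object@channelIds))
    msgs <- c(msgs, "channelIds must be unique")
  if (length(object@mzValues) > 1L && any(diff(object@mzValues) <= 0))
    msgs <- c(msgs, "mzValues must be strictly increasing")
  if (length(D) && (!all(is.finite(D)) || any(D < 0)))
    msgs <- c(msgs, "intensities must be finite and nonnegative")
  if (nrow(xy)) {
    if (!all(is.finite(xy)))
      msgs <- c(msgs, "coords must be finite integers")
    else {
      m <- object@gridShape[1L]; n <- object@gridShape[2L]
      if (any(xy[, 1L] < 1L | xy[, 1L] > m | xy[, 2L] < 1L | xy[, 2L] > n))
        msgs <- c(msgs, "all coords must lie within gridShape (1-based)")
      if (anyDuplicated(xy))
        msgs <- c(msgs, "duplicate pixel coordinates are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' IntensityImage: one rendered m/z-image (or aggregate map)
#'
#' A full-grid raster of one channel (or a per-pixel aggregate of several),
#' with a mask flagging which grid cells were actually measured. Values are
#' indexed `values[x, y]`; unmeasured cells carry 0 with `mask` FALSE.
#'
#' @slot values numeric `m x n` matrix.
#' @slot mask logical `m x n` matrix, TRUE where measured.
#' @slot label character scalar (typically the m/z value).
#' @exportClass IntensityImage
setClass("IntensityImage",
  representation(values = "matrix", mask = "matrix", label = "character")
)

setValidity("IntensityImage", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(!is.finite(object@values[object@mask])))
    return("values must be finite on measured pixels")
  if (length(object@values) && any(object@values[!object@mask] != 0))
    return("unmeasured pixels must carry the background value 0")
  TRUE
})

#' SimilarityMatrix: pairwise m/z-image similarities
#'
#' Symmetric `N_V x N_V` matrix of Pearson correlations `w_ij` between
#' channel pixel vectors, clamped to `[-1, 1]` with unit diagonal.
#'
#' @slot values numeric symmetric matrix in `[-1, 1]`, diagonal 1.
#' @slot channelIds character labels matching the dataset.
#' @slot measure character, the similarity measure used.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(values = "matrix", channelIds = "character",
                 measure = "character")
)

setValidity("SimilarityMatrix", function(object) {
  V <- object@values
  if (nrow(V) != ncol(V)) return("values must be square")
  if (length(object@channelIds) != nrow(V))
    return("channelIds length must match matrix dimension")
  if (!all(is.finite(V))) return("similarities must be finite")
  if (any(abs(V - t(V)) > 0)) return("similarity matrix must be symmetric")
  if (any(V < -1 | V > 1)) return("similarities must lie in [-1, 1]")
  if (any(diag(V) != 1)) return("diagonal must be 1")
  TRUE
})

#' AdjacencyMatrix: the thresholded colocalization graph
#'
#' Binary, symmetric, zero-diagonal `N_V x N_V` matrix defining the
#' undirected, unweighted graph G whose nodes are m/z-images.
#'
#' @slot values numeric 0/1 symmetric matrix with zero diagonal.
#' @slot channelIds character labels.
#' @slot threshold numeric scalar, the threshold that produced the graph
#'   (`NA` when constructed directly).
#' @exportClass AdjacencyMatrix
setClass("AdjacencyMatrix",
  representation(values = "matrix", channelIds = "character",
                 threshold = "numeric")
)

setValidity("AdjacencyMatrix", function(object) {
  V <- object@values
  if (nrow(V) != ncol(V)) return("values must be square")
  if (length(object@channelIds) != nrow(V))
    return("channelIds length must match matrix dimension")
  if (!all(V %in% c(0, 1))) return("entries must be 0 or 1")
  if (!identical(V, t(V))) return("adjacency matrix must be symmetric")
  if (any(diag(V) != 0)) return("diagonal must be 0 (no self-loops)")
  TRUE
})

#' ThresholdSweep: candidate thresholds and their graph properties
#'
#' Records, per candidate threshold, the raw quantitative graph properties
#' (edge count, average clustering coefficient zeta, global efficiency xi),
#' their min-max normalized and baselined versions, the PCA projection y,
#' and the selected threshold. Raw slots are filled by [qgpSweep()]; the
#' remaining slots by [selectThreshold()].
#'
#' @slot candidates numeric vector of candidate thresholds.
#' @slot nERaw,zetaRaw,xiRaw numeric, raw QGP values per candidate.
#' @slot nEBase numeric, edge counts min-max normalized to `[0, 1]`.
#' @slot etaZeta,etaXi numeric, baselined (normalized QGP minus `nEBase`).
#' @slot projection numeric, projection of `[etaZeta, etaXi]` on the
#'   leading PCA component.
#' @slot chosenIndex integer, index of the selected candidate (`NA` until
#'   selection).
#' @slot tS numeric, the selected threshold.
#' @slot effectiveMinWeight numeric, smallest similarity among surviving
#'   edges at `tS` (equals `tS` when no edge survives).
#' @exportClass ThresholdSweep
setClass("ThresholdSweep",
  representation(
    candidates = "numeric",
    nERaw = "numeric", zetaRaw = "numeric", xiRaw = "numeric",
    nEBase = "numeric", etaZeta = "numeric", etaXi = "numeric",
    projection = "numeric",
    chosenIndex = "integer", tS = "numeric",
    effectiveMinWeight = "numeric"
  ),
  prototype(chosenIndex = NA_integer_, tS = NA_real_,
            effectiveMinWeight = NA_real_)
)

setValidity("ThresholdSweep", function(object) {
  k <- length(object@candidates)
  raw <- list(object@nERaw, object@zetaRaw, object@xiRaw)
  if (any(vapply(raw, length, 0L) != k))
    return("raw QGP vectors must align with candidates")
  filled <- list(object@nEBase, object@etaZeta, object@etaXi,
                 object@projection)
  if (any(!vapply(filled, length, 0L) %in% c(0L, k)))
    return("derived vectors must be empty or aligned with candidates")
  if (!is.na(object@chosenIndex)) {
    if (object@chosenIndex < 1L || object@chosenIndex > k)
      return("chosenIndex out of range")
    if (length(object@projection) == k &&
        object@projection[object@chosenIndex] < max(object@projection))
      return("chosenIndex must maximize the projection")
    if (!isTRUE(all.equal(object@tS, object@candidates[object@chosenIndex])))
      return("tS must equal candidates[chosenIndex]")
  }
  TRUE
})

#' CommunityPartition: node-to-community assignment
#'
#' Community labels are contiguous integers starting at 1; the
#' `indivisible` flag records, per community, whether the leading
#' eigenvector method declared it unsplittable (always TRUE in a final
#' result, FALSE for the connected-component initialization).
#'
#' @slot labels integer vector, one community id per node.
#' @slot indivisible logical vector, one flag per community.
#' @slot channelIds character node labels.
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  representation(labels = "integer", indivisible = "logical",
                 channelIds = "character")
)

setValidity("CommunityPartition", function(object) {
  lab <- object@labels
  if (length(object@channelIds) != length(lab))
    return("channelIds length must match labels")
  if (length(lab) == 0L) {
    if (length(object@indivisible) != 0L)
      return("empty partition must have no community flags")
    return(TRUE)
  }
  k <- max(lab)
  if (any(lab < 1L) || !all(seq_len(k) %in% lab))
    return("labels must be contiguous integers 1..N_C with no empty community")
  if (length(object@indivisible) != k)
    return("indivisible must have one flag per community")
  TRUE
})

#' ModularityMatrix: generalized modularity matrix of a node subset
#'
#' Newman's generalized modularity matrix `B^(g)` over a community `g`,
#' with degrees and edge count taken from the full graph and the diagonal
#' correction that makes every row sum to zero.
#'
#' @slot values numeric symmetric matrix, rows summing to 0.
#' @slot subset integer indices of the nodes (into the full graph).
#' @exportClass ModularityMatrix
setClass("ModularityMatrix",
  representation(values = "matrix", subset = "integer")
)

setValidity("ModularityMatrix", function(object) {
  V <- object@values
  if (nrow(V) != ncol(V)) return("values must be square")
  if (length(object@subset) != nrow(V))
    return("subset length must match matrix dimension")
  if (max(abs(V - t(V))) > 1e-9) return("modularity matrix must be symmetric")
  if (length(V) && max(abs(rowSums(V))) > 1e-8)
    return("rows of a generalized modularity matrix must sum to 0")
  TRUE
})

#' CommunityMap: per-pixel aggregate image of one community
#'
#' @slot image an [IntensityImage-class] holding the aggregate.
#' @slot communityId integer id of the community.
#' @slot mode character, `"max"` (maximum projection) or `"average"`.
#' @slot members integer channel indices aggregated.
#' @exportClass CommunityMap
setClass("CommunityMap",
  representation(image = "IntensityImage", communityId = "integer",
                 mode = "character", members = "integer")
)

setValidity("CommunityMap", function(object) {
  if (!object@mode %in% c("max", "average"))
    return("mode must be 'max' or 'average'")
  if (length(object@members) == 0L)
    return("a community map needs at least one member channel")
  TRUE
})

#' CommunityGraph: the collapsed graph G' for interactive viewers
#'
#' Communities collapse to single nodes; a community edge joins two
#' collapsed nodes iff any graph edge joins their members. Expanding a
#' community materializes its m/z-nodes and intra-community edges; its
#' edges to unexpanded communities become hybrid (m/z-node to community
#' node) edges, and edges between two expanded communities stay at the
#' m/z level.
#'
#' @slot communityMembers list of integer vectors (channel indices per
#'   community, indexed by community id).
#' @slot communityEdges integer 2-column matrix of community id pairs.
#' @slot expanded integer ids of expanded communities.
#' @slot mzNodes integer channel indices materialized by expansion.
#' @slot mzEdges integer 2-column matrix of channel index pairs.
#' @slot hybridEdges integer 2-column matrix (channel index, community id).
#' @slot channelIds character channel labels.
#' @exportClass CommunityGraph
setClass("CommunityGraph",
  representation(
    communityMembers = "list",
    communityEdges = "matrix",
    expanded = "integer",
    mzNodes = "integer",
    mzEdges = "matrix",
    hybridEdges = "matrix",
    channelIds = "character"
  )
)

setValidity("CommunityGraph", function(object) {
  nC <- length(object@communityMembers)
  if (length(object@expanded) &&
      (any(object@expanded < 1L) || any(object@expanded > nC)))
    return("expanded refers to unknown community ids")
  for (nm in c("communityEdges", "mzEdges", "hybridEdges"))
    if (ncol(slot(object, nm)) != 2L)
      return(sprintf("%s must have two columns", nm))
  if (length(object@communityEdges) &&
      any(object@communityEdges > nC | object@communityEdges < 1L))
    return("communityEdges refer to unknown community ids")
  TRUE
})

#' BenchmarkConfig: parameters of the synthetic nine-Gaussian benchmark
#'
#' See [generateBenchmark()] for the meaning of each parameter and
#' the methods vignette for how the defaults were chosen.
#'
#' @slot gridShape integer (width, height) of the pixel grid.
#' @slot nGroups,perGroup integer layout of channels into groups.
#' @slot baseSigma numeric base standard deviation in pixels.
#' @slot amplitudeBase,amplitudeStep numeric peak amplitudes.
#' @slot positionJitter numeric half-width (px) of the uniform center jitter.
#' @slot sigmaJitterFrac numeric relative jitter of the x/y sigmas.
#' @slot rotationRange numeric length-2 interval of rotation angles (rad).
#' @slot groupLayout numeric matrix of group centers (one row per group),
#'   or a 0-row matrix to use the default triangle layout.
#' @slot noiseSd numeric sd of optional additive Gaussian noise (default 0).
#' @slot seed integer RNG seed.
#' @exportClass BenchmarkConfig
setClass("BenchmarkConfig",
  representation(
    gridShape = "integer", nGroups = "integer", perGroup = "integer",
    baseSigma = "numeric", amplitudeBase = "numeric",
    amplitudeStep = "numeric", positionJitter = "numeric",
    sigmaJitterFrac = "numeric", rotationRange = "numeric",
    groupLayout = "matrix", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("BenchmarkConfig", function(object) {
  if (length(object@gridShape) != 2L || any(object@gridShape < 8L))
    return("gridShape must be two integers >= 8")
  if (object@nGroups < 1L || object@perGroup < 1L)
    return("nGroups and perGroup must be positive")
  if (object@baseSigma <= 0) return("baseSigma must be positive")
  if (object@sigmaJitterFrac < 0 || object@sigmaJitterFrac >= 1)
    return("sigmaJitterFrac must lie in [0, 1)")
  if (length(object@rotationRange) != 2L ||
      diff(object@rotationRange) < 0)
    return("rotationRange must be an increasing length-2 interval")
  ctr <- benchmarkCenters(object)
  m <- object@gridShape[1L]; n <- object@gridShape[2L]
  if (any(ctr[, 1L] < 1 | ctr[, 1L] > m | ctr[, 2L] < 1 | ctr[, 2L] > n))
    return("group centers must lie inside the grid")
  if (nrow(ctr) > 1L) {
    dd <- as.matrix(stats::dist(ctr))
    if (max(dd) > 4 * object@baseSigma)
      return("group footprints must pairwise overlap (centers too far apart)")
  }
  TRUE
})

#' PipelineResult: all artifacts of one pipeline run
#'
#' @slot dataset the preprocessed (winsorized) [MSIDataset-class].
#' @slot similarity the [SimilarityMatrix-class].
#' @slot sweep the completed [ThresholdSweep-class].
#' @slot adjacency the [AdjacencyMatrix-class] at the selected threshold.
#' @slot partition the final [CommunityPartition-class].
#' @slot maps list of [CommunityMap-class], one per community.
#' @slot communityGraph the collapsed [CommunityGraph-class].
#' @slot report named list of run summary values (config, seed, tS,
#'   effectiveMinWeight, nEdges, nC, nC2plus, edgeReductionPercent, sizes).
#' @exportClass PipelineResult
setClass("PipelineResult",
  representation(
    dataset = "MSIDataset",
    similarity = "SimilarityMatrix",
    sweep = "ThresholdSweep",
    adjacency = "AdjacencyMatrix",
    partition = "CommunityPartition",
    maps = "list",
    communityGraph = "CommunityGraph",
    report = "list"
  )
)
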