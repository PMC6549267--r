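## End-to-end pipeline runner and viewer export.

#' Pipeline configuration
#'
#' @param tmin,tmax,tdelta candidate threshold grid (see
#'   [candidateThresholds()]).
#' @param winsorize logical; apply the upper-quantile clipping
#'   preprocessing step first.
#' @param upperQuantile winsorizing quantile.
#' @param mapMode community map aggregation, `"max"` or `"average"`.
#' @param pcaComponents three component indices for the PCA RGB map
#'   (computed only when the dataset has >= 3 channels).
#' @return named list of validated settings.
#' @export
pipelineConfig <- function(tmin = -1, tmax = 1, tdelta = 0.1,
                           winsorize = TRUE, upperQuantile = 0.99,
                           mapMode = c("max", "average"),
                           pcaComponents = 1:3) {
  list(tmin = tmin, tmax = tmax, tdelta = tdelta,
       winsorize = isTRUE(winsorize), upperQuantile = upperQuantile,
       mapMode = match.arg(mapMode),
       pcaComponents = as.integer(pcaComponents))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full colocalization-network pipeline
#'
#' Executes, in order: winsorizing preprocessing, Pearson similarity,
#' QGP threshold sweep and selection, adjacency thresholding, community
#' detection, community maps and the collapsed community graph. All
#' intermediate artifacts are retained in the returned
#' [PipelineResult-class]; `report(result)`-style access goes through
#' the `@report` slot, a plain list suitable for serialization. The run
#' is deterministic: identical inputs yield identical results.
#'
#' @param ds an [MSIDataset-class].
#' @param config a list from [pipelineConfig()].
#' @return a [PipelineResult-class].
#' @examples
#' ds <- generateBenchmark(BenchmarkConfig(gridShape = c(60, 55),
#'                                         baseSigma = 7, seed = 3))
#' res <- runPipeline(ds)
#' res@report$nC
#' @export
runPipeline <- function(ds, config = pipelineConfig()) {
  stopifnot(is(ds, "MSIDataset"))
  pre <- if (config$winsorize)
    .stage("winsorize", winsorize(ds, config$upperQuantile)) else ds
  S <- .stage("similarity", pearsonSimilarity(pre))
  cand <- .stage("candidates",
                 candidateThresholds(config$tmin, config$tmax, config$tdelta))
  sweep <- .stage("qgp-sweep", qgpSweep(S, cand))
  sweep <- .stage("threshold-selection", selectThreshold(sweep, S))
  A <- .stage("thresholding", applyThreshold(S, sweep@tS))
  part <- .stage("community-detection", detectCommunities(A))
  maps <- .stage("community-maps", {
    lapply(seq_len(nCommunities(part)), function(c)
      communityMap(pre, which(part@labels == c), config$mapMode,
                   communityId = c))
  })
  cg <- .stage("community-graph", buildCommunityGraph(A, part))
  summ <- communitySummary(part)
  report <- list(
    config = config,
    nPixels = nPixels(ds), nChannels = nChannels(ds),
    tS = sweep@tS, effectiveMinWeight = sweep@effectiveMinWeight,
    nEdges = countEdges(A),
    edgeReductionPercent = if (nChannels(ds) >= 2)
      edgeReductionPercent(nChannels(ds), countEdges(A)) else NA_real_,
    nC = summ$nC, nC2plus = summ$nLarge,
    sizes = as.integer(communitySizes(part))
  )
  new("PipelineResult", dataset = pre, similarity = S, sweep = sweep,
      adjacency = A, partition = part, maps = maps, communityGraph = cg,
      report = report)
}

setMethod("show", "PipelineResult", function(object) {
  r <- object@report
  cat("PipelineResult\n")
  cat(sprintf("  %d pixels x %d channels\n", r$nPixels, r$nChannels))
  cat(sprintf("  t_S = %.4g (effective min edge weight %.4g)\n",
              r$tS, r$effectiveMinWeight))
  cat(sprintf("  %d edges (%.3f%% reduction), %d communities (%d multi-member)\n",
              r$nEdges, r$edgeReductionPercent, r$nC, r$nC2plus))
})

#' Export pipeline results for an interactive viewer
#'
#' Writes one JSON document (schema `msinet-viewer/1`) describing the
#' community graph — community nodes with member channel lists and m/z
#' values, community/hybrid/m-z edges, the selected threshold — plus a
#' reference to one PNG community map per community, written alongside
#' the JSON as `<stem>-community-<id>.png` (min-max rescaled for
#' contrast, row = y, column = x, origin top-left).
#'
#' @param result a [PipelineResult-class].
#' @param path output JSON file path.
#' @param writeImages logical; write the PNG maps (default TRUE).
#' @return the JSON path, invisibly.
#' @seealso [validateViewerExport()]
#' @export
exportViewerJSON <- function(result, path, writeImages = TRUE) {
  stopifnot(is(result, "PipelineResult"))
  part <- result@partition
  ds <- result@dataset
  cg <- result@communityGraph
  stem <- sub("\\.json$", "", basename(path))
  dir <- dirname(path)
  communities <- lapply(seq_len(nCommunities(part)), function(c) {
    mem <- which(part@labels == c)
    mapFile <- sprintf("%s-community-%d.png", stem, c)
    if (writeImages) {
      img <- rescaleImage(result@maps[[c]]@image)
      png::writePNG(t(img@values), file.path(dir, mapFile))
    }
    list(id = c,
         indivisible = part@indivisible[c],
         members = lapply(mem, function(i)
           list(channel = channelIds(ds)[i], mz = mzValues(ds)[i])),
         map = mapFile,
         map_mode = result@maps[[c]]@mode)
  })
  doc <- list(
    schema = "msinet-viewer/1",
    grid_shape = gridShape(ds),
    threshold = result@report$tS,
    effective_min_weight = result@report$effectiveMinWeight,
    n_edges = result@report$nEdges,
    communities = communities,
    community_edges = .edgeList(cg@communityEdges),
    hybrid_edges = .edgeList(cg@hybridEdges),
    mz_edges = .edgeList(cg@mzEdges),
    expanded = as.list(cg@expanded)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.edgeList <- function(mat) {
  if (nrow(mat) == 0L) return(list())
  lapply(seq_len(nrow(mat)), function(r) as.integer(mat[r, ]))
}

#' Validate a viewer export against the shipped schema
#'
#' Structural validation of a `msinet-viewer/1` document: required
#' top-level and per-community keys (as listed in the shipped schema
#' file `inst/extdata/viewer-schema.json`), edge arity, and internal
#' consistency of community ids.
#'
#' @param path path to a JSON file written by [exportViewerJSON()].
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validateViewerExport <- function(path) {
  doc <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(
    system.file("extdata", "viewer-schema.json", package = "msinet"))
  for (key in unlist(schema$required))
    if (is.null(doc[[key]])) stop("missing required key: ", key)
  if (!identical(doc$schema, schema$id))
    stop("unexpected schema tag: ", doc$schema)
  nC <- length(doc$communities)
  for (com in doc$communities)
    for (key in unlist(schema$community_required))
      if (is.null(com[[key]])) stop("community missing key: ", key)
  for (e in c(doc$community_edges, doc$hybrid_edges, doc$mz_edges))
    if (length(e) != 2L) stop("edges must be pairs")
  for (e in doc$community_edges)
    if (any(unlist(e) < 1) || any(unlist(e) > nC))
      stop("community edge refers to unknown community")
  invisible(TRUE)
}
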