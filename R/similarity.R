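## Pairwise image similarity: Pearson correlation of m/z-image pixel
## vectors over the measured pixels only.

#' Pairwise Pearson similarity of m/z-images
#'
#' Computes the `N_V x N_V` similarity matrix `S` with
#' `w_ij = cov(p_i, p_j) / (sd(p_i) * sd(p_j))`, the Pearson correlation
#' of channel pixel vectors over the `N_P` measured pixels. The rendered
#' grid (with its zero-padded unmeasured cells) is never used: similarity
#' is a property of the measured pixel vectors.
#'
#' A zero-variance channel carries no lateral structure; its
#' off-diagonal similarities are defined as 0 (diagonal stays 1) and a
#' warning is emitted, so such channels end up as isolated nodes instead
#' of joining communities through NaN propagation. Entries are clamped to
#' `[-1, 1]` against floating-point overshoot.
#'
#' @param ds an [MSIDataset-class] with at least 2 pixels and 2 channels.
#' @param measure similarity measure identifier; only `"pearson"` is
#'   implemented (`"cosine"` and `"mutual_information"` are reserved and
#'   raise a not-implemented error).
#' @return a [SimilarityMatrix-class].
#' @export
pearsonSimilarity <- function(ds, measure = "pearson") {
  stopifnot(is(ds, "MSIDataset"))
  if (!measure %in% c("pearson", "cosine", "mutual_information"))
    stop("unknown similarity measure: ", measure)
  if (measure != "pearson")
    stop("similarity measure '", measure, "' is not implemented")
  if (nChannels(ds) < 2L) stop("need at least 2 channels")
  if (nPixels(ds) < 2L) stop("need at least 2 measured pixels")
  D <- intensityMatrix(ds)
  sds <- apply(D, 2L, stats::sd)
  degenerate <- sds == 0
  S <- suppressWarnings(stats::cor(D))
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance channel(s); their ",
            "similarities are set to 0")
    S[degenerate, ] <- 0
    S[, degenerate] <- 0
  }
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(channelIds(ds), channelIds(ds))
  new("SimilarityMatrix", values = S, channelIds = channelIds(ds),
      measure = measure)
}

#' @export
setMethod("similarityValues", "SimilarityMatrix", function(object)
  object@values)

#' @export
setMethod("channelIds", "SimilarityMatrix", function(object)
  object@channelIds)

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("SimilarityMatrix (%s): %d channels, %d pairs\n",
              object@measure, nrow(object@values), length(v)))
  if (length(v))
    cat(sprintf("  pairwise range: [%.4f, %.4f]\n", min(v), max(v)))
})

#' Histogram of pairwise similarities
#'
#' Bins the upper-triangle (`i < j`) similarity values over `[-1, 1]`
#' into `bins` equal-width bins; the total count is `N_V (N_V - 1) / 2`.
#'
#' @param S a [SimilarityMatrix-class].
#' @param bins number of bins (>= 1).
#' @return data.frame with columns `binStart`, `binEnd`, `count`.
#' @export
similarityHistogram <- function(S, bins = 20L) {
  stopifnot(is(S, "SimilarityMatrix"))
  if (bins < 1L) stop("bins must be >= 1")
  v <- S@values[upper.tri(S@values)]
  edges <- seq(-1, 1, length.out = bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(binStart = edges[-(bins + 1L)], binEnd = edges[-1L],
             count = tabulate(idx, nbins = bins))
}

#' Export a similarity matrix as a square CSV table
#'
#' Channel ids form the header row and the first column.
#'
#' @param S a [SimilarityMatrix-class].
#' @param path output file.
#' @export
exportSimilarityCSV <- function(S, path) {
  stopifnot(is(S, "SimilarityMatrix"))
  tab <- data.table::data.table(channel = S@channelIds)
  V <- S@values
  for (j in seq_along(S@channelIds)) tab[[S@channelIds[j]]] <- V[, j]
  data.table::fwrite(tab, path)
  invisible(path)
}
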