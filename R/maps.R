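## Community maps, single-mass-map rescaling and the PCA RGB overview map.

#' Community map: per-pixel aggregate of member m/z-images
#'
#' In maximum projection mode (`mode = "max"`) each pixel shows the
#' maximal member intensity — the total area covered by the community.
#' In averaging mode the pixel shows the mean member intensity —
#' emphasizing the quantity of signal coverage. The average map never
#' exceeds the maximum map pixelwise.
#'
#' @param ds an [MSIDataset-class].
#' @param members non-empty integer channel indices of one community.
#' @param mode `"max"` or `"average"`.
#' @param communityId integer id recorded in the result.
#' @return a [CommunityMap-class].
#' @export
communityMap <- function(ds, members, mode = c("max", "average"),
                         communityId = NA_integer_) {
  stopifnot(is(ds, "MSIDataset"))
  mode <- match.arg(mode)
  members <- as.integer(members)
  if (length(members) == 0L) stop("member set must be non-empty")
  if (any(members < 1L | members > nChannels(ds)))
    stop("member channel index out of range")
  D <- intensityMatrix(ds)[, members, drop = FALSE]
  agg <- if (mode == "max") apply(D, 1L, max) else rowMeans(D)
  m <- gridShape(ds)[1L]; n <- gridShape(ds)[2L]
  vals <- matrix(0, m, n); mask <- matrix(FALSE, m, n)
  xy <- pixelCoords(ds)
  vals[xy] <- agg
  mask[xy] <- TRUE
  img <- new("IntensityImage", values = vals, mask = mask,
             label = sprintf("community %s (%s)",
                             ifelse(is.na(communityId), "?", communityId),
                             mode))
  new("CommunityMap", image = img, communityId = as.integer(communityId),
      mode = mode, members = members)
}

#' Rescale an image to maximum contrast
#'
#' Min-max rescales the measured pixels to `[0, 1]` so weak mass signals
#' become visible; a constant image maps to all zeros. Unmeasured pixels
#' stay 0. Idempotent after the first application.
#'
#' @param img an [IntensityImage-class].
#' @return an [IntensityImage-class] with values in `[0, 1]`.
#' @export
rescaleImage <- function(img) {
  stopifnot(is(img, "IntensityImage"))
  vals <- img@values
  v <- vals[img@mask]
  if (length(v)) {
    r <- range(v)
    vals[img@mask] <- if (r[2L] - r[1L] == 0) 0 else (v - r[1L]) / (r[2L] - r[1L])
  }
  new("IntensityImage", values = vals, mask = img@mask, label = img@label)
}

#' PCA RGB overview map
#'
#' Mean-centers the intensity matrix over pixels, projects every pixel
#' onto three selected principal components of the channel covariance
#' (eigenvalues in decreasing order), min-max rescales each projection
#' to `[0, 1]` and assigns them to the red, green and blue channels.
#' The default uses the three most informative components (`1:3`);
#' passing e.g. `2:4` selects the second to fourth instead. Plain
#' covariance PCA on the (winsorized) data is used; no additional
#' squaring or image thresholding variants are applied.
#'
#' @param ds an [MSIDataset-class] with at least 3 channels.
#' @param components integer vector of three component indices (1-based).
#' @return numeric array `m x n x 3` with values in `[0, 1]`; unmeasured
#'   pixels are 0 in all three channels.
#' @export
pcaRGBMap <- function(ds, components = 1:3) {
  stopifnot(is(ds, "MSIDataset"))
  if (nChannels(ds) < 3L) stop("PCA RGB map needs at least 3 channels")
  components <- as.integer(components)
  if (length(components) != 3L)
    stop("components must name exactly three principal components")
  if (any(components < 1L | components > nChannels(ds)))
    stop("component index out of range")
  pr <- stats::prcomp(intensityMatrix(ds), center = TRUE, scale. = FALSE)
  scores <- pr$x[, components, drop = FALSE]
  m <- gridShape(ds)[1L]; n <- gridShape(ds)[2L]
  out <- array(0, dim = c(m, n, 3L))
  xy <- pixelCoords(ds)
  for (ch in 1:3) {
    v <- scores[, ch]
    r <- range(v)
    v <- if (r[2L] - r[1L] < 1e-12) rep(0, length(v)) else (v - r[1L]) / (r[2L] - r[1L])
    plane <- matrix(0, m, n)
    plane[xy] <- v
    out[, , ch] <- plane
  }
  out
}
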