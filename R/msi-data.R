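## MSIDataset construction, accessors, native-format I/O, image rendering
## and winsorizing.

#' Construct an MSIDataset
#'
#' @param intensities numeric matrix, `N_P` pixels x `N_V` channels;
#'   finite and nonnegative.
#' @param coords integer matrix or data.frame with columns `x`, `y`
#'   (1-based grid positions), one row per pixel.
#' @param mzValues numeric vector of channel m/z values, strictly
#'   increasing.
#' @param channelIds optional character channel labels; defaults to
#'   `"mz_<value>"`.
#' @param gridShape integer `c(m, n)` grid extent (width, height);
#'   defaults to the bounding box of `coords`.
#' @return a validated [MSIDataset-class].
#' @examples
#' ds <- MSIDataset(matrix(1:6, 3, 2), cbind(x = 1:3, y = rep(1L, 3)),
#'                  mzValues = c(100, 200))
#' nPixels(ds)
#' @export
MSIDataset <- function(intensities, coords, mzValues,
                       channelIds = NULL, gridShape = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (is.null(gridShape)) {
    gridShape <- if (nrow(coords)) c(max(coords[, 1L]), max(coords[, 2L]))
                 else c(1L, 1L)
  }
  if (is.null(channelIds))
    channelIds <- paste0("mz_", format(mzValues, trim = TRUE))
  colnames(intensities) <- channelIds
  new("MSIDataset", intensities = intensities, coords = coords,
      mzValues = as.numeric(mzValues), channelIds = as.character(channelIds),
      gridShape = as.integer(gridShape))
}

#' @describeIn MSIDataset the `N_P x N_V` intensity matrix.
#' @param object an `MSIDataset`.
#' @export
setMethod("intensityMatrix", "MSIDataset", function(object) object@intensities)

#' @describeIn MSIDataset the pixel coordinate matrix (columns `x`, `y`).
#' @export
setMethod("pixelCoords", "MSIDataset", function(object) object@coords)

#' @describeIn MSIDataset channel m/z values.
#' @export
setMethod("mzValues", "MSIDataset", function(object) object@mzValues)

#' @describeIn MSIDataset channel labels.
#' @export
setMethod("channelIds", "MSIDataset", function(object) object@channelIds)

#' @describeIn MSIDataset grid extent `c(m, n)`.
#' @export
setMethod("gridShape", "MSIDataset", function(object) object@gridShape)

#' @describeIn MSIDataset number of measured pixels `N_P`.
#' @export
setMethod("nPixels", "MSIDataset", function(object) nrow(object@intensities))

#' @describeIn MSIDataset number of m/z-channels `N_V`.
#' @export
setMethod("nChannels", "MSIDataset", function(object) ncol(object@intensities))

setMethod("show", "MSIDataset", function(object) {
  cat(sprintf("MSIDataset: %d pixels x %d m/z-channels on a %d x %d grid\n",
              nPixels(object), nChannels(object),
              object@gridShape[1L], object@gridShape[2L]))
  if (nChannels(object))
    cat(sprintf("  m/z range: %.4g .. %.4g\n",
                min(object@mzValues), max(object@mzValues)))
})

#' @export
setMethod("imageValues", "IntensityImage", function(object) object@values)

#' @export
setMethod("imageMask", "IntensityImage", function(object) object@mask)

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage '%s': %d x %d, %d measured pixels\n",
              object@label, nrow(object@values), ncol(object@values),
              sum(object@mask)))
})

## ---------------------------------------------------------------------
## Native on-disk format: <stem>.json header + <stem>.csv table.
##
## Header (JSON): format tag, grid_shape [m, n], mz_values, channel_ids,
## n_pixels, table file name. Table (CSV): columns x, y, then one column
## per channel in header order. Numeric cells are written with 17
## significant digits so doubles round-trip exactly.
## ---------------------------------------------------------------------

.nativePaths <- function(path) {
  stem <- sub("\\.json$", "", path)
  list(header = paste0(stem, ".json"), table = paste0(stem, ".csv"))
}

#' Write an MSIDataset in the native format
#'
#' The native format is a two-file pair: a JSON header
#' (`<stem>.json`: grid shape, m/z values, channel ids) and a CSV table
#' (`<stem>.csv`: columns `x`, `y`, then one intensity column per channel,
#' in header order). Intensities are serialized with 17 significant
#' digits, so [readMSI()] recovers them exactly.
#'
#' @param ds a valid [MSIDataset-class].
#' @param path output stem (with or without a `.json` extension); the
#'   two files `<stem>.json` and `<stem>.csv` are written.
#' @return the header path, invisibly.
#' @seealso [readMSI()]
#' @export
writeMSI <- function(ds, path) {
  stopifnot(is(ds, "MSIDataset"))
  validObject(ds)
  p <- .nativePaths(path)
  header <- list(
    format = "msinet-native/1",
    grid_shape = gridShape(ds),
    mz_values = mzValues(ds),
    channel_ids = channelIds(ds),
    n_pixels = nPixels(ds),
    table = basename(p$table)
  )
  jsonlite::write_json(header, p$header, auto_unbox = TRUE, digits = NA)
  tab <- data.table::data.table(x = pixelCoords(ds)[, 1L],
                                y = pixelCoords(ds)[, 2L])
  D <- intensityMatrix(ds)
  for (j in seq_len(ncol(D)))
    tab[[channelIds(ds)[j]]] <- sprintf("%.17g", D[, j])
  data.table::fwrite(tab, p$table, quote = FALSE)
  invisible(p$header)
}

#' Read an MSIDataset
#'
#' @param path for `format = "native"`, the stem or header path written
#'   by [writeMSI()].
#' @param format input format. Only the package's native format is
#'   implemented; `"imzml"` is reserved as an ingestion interface and
#'   raises a not-implemented error (convert imzML externally, e.g. with
#'   pyimzML, and save in the native format).
#' @return a validated [MSIDataset-class]; channel order as in the file.
#' @export
readMSI <- function(path, format = c("native", "imzml")) {
  format <- match.arg(format)
  if (format == "imzml")
    stop("imzML ingestion is not implemented; convert to the native ",
         "format (see ?writeMSI)")
  p <- .nativePaths(path)
  if (!file.exists(p$header)) stop("header file not found: ", p$header)
  header <- tryCatch(jsonlite::read_json(p$header, simplifyVector = TRUE),
                     error = function(e)
                       stop("unparseable native header: ", conditionMessage(e)))
  if (!identical(header$format, "msinet-native/1"))
    stop("not a msinet native header (missing format tag)")
  tablePath <- file.path(dirname(p$header), header$table)
  if (!file.exists(tablePath)) stop("table file not found: ", tablePath)
  nCh <- length(header$mz_values)
  tab <- as.data.frame(data.table::fread(
    tablePath, header = TRUE,
    colClasses = list(integer = 1:2, numeric = 2L + seq_len(nCh))))
  expected <- c("x", "y", header$channel_ids)
  if (!identical(names(tab), as.character(expected)))
    stop("native table columns do not match the header ",
         "(expected x, y, then channels in header order)")
  D <- as.matrix(tab[, 2L + seq_len(nCh), drop = FALSE])
  if (nrow(tab) == 0L) D <- matrix(numeric(0), 0L, nCh)
  ds <- MSIDataset(D, as.matrix(tab[, 1:2, drop = FALSE]),
                   mzValues = header$mz_values,
                   channelIds = header$channel_ids,
                   gridShape = as.integer(header$grid_shape))
  validObject(ds)
  ds
}

## ---------------------------------------------------------------------

#' Render one m/z-image
#'
#' Places the channel's pixel vector onto the full grid. Unmeasured grid
#' cells get value 0 and mask FALSE; the total intensity of the image
#' equals the channel column sum.
#'
#' @param ds an [MSIDataset-class].
#' @param channel channel index (1-based) or channel id.
#' @return an [IntensityImage-class].
#' @export
renderImage <- function(ds, channel) {
  stopifnot(is(ds, "MSIDataset"))
  if (is.character(channel)) {
    channel <- match(channel, channelIds(ds))
    if (is.na(channel)) stop("unknown channel id")
  }
  if (length(channel) != 1L || is.na(channel) ||
      channel < 1L || channel > nChannels(ds))
    stop("channel index out of range [1, ", nChannels(ds), "]")
  m <- gridShape(ds)[1L]; n <- gridShape(ds)[2L]
  vals <- matrix(0, m, n)
  mask <- matrix(FALSE, m, n)
  xy <- pixelCoords(ds)
  vals[xy] <- intensityMatrix(ds)[, channel]
  mask[xy] <- TRUE
  new("IntensityImage", values = vals, mask = mask,
      label = channelIds(ds)[channel])
}

#' @describeIn winsorize clip, per channel, every intensity above the
#'   upper quantile down to that quantile. The quantile is the classic
#'   winsorization bound: the smallest order statistic whose empirical
#'   CDF reaches `upperQuantile` (inverse-ECDF estimator), which makes
#'   the operation exactly idempotent.
#' @return an [MSIDataset-class] of identical shape.
#' @export
setMethod("winsorize", "MSIDataset", function(object, upperQuantile = 0.99) {
  if (nPixels(object) == 0L)
    stop("cannot winsorize an empty dataset")
  if (!is.numeric(upperQuantile) || upperQuantile <= 0 || upperQuantile > 1)
    stop("upperQuantile must lie in (0, 1]")
  D <- intensityMatrix(object)
  for (j in seq_len(ncol(D))) {
    q <- stats::quantile(D[, j], probs = upperQuantile, type = 1,
                         names = FALSE)
    D[D[, j] > q, j] <- q
  }
  MSIDataset(D, pixelCoords(object), mzValues(object),
             channelIds(object), gridShape(object))
})
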