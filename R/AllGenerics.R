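## Generics for accessors shared across the msinet classes.

#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))

#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))

#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))

#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @export
setGeneric("similarityValues", function(object) standardGeneric("similarityValues"))

#' @export
setGeneric("adjacencyValues", function(object) standardGeneric("adjacencyValues"))

#' @export
setGeneric("communityLabels", function(object) standardGeneric("communityLabels"))

#' @export
setGeneric("communitySizes", function(object) standardGeneric("communitySizes"))

#' @export
setGeneric("nCommunities", function(object) standardGeneric("nCommunities"))

#' @export
setGeneric("indivisibleFlags", function(object) standardGeneric("indivisibleFlags"))

#' @export
setGeneric("chosenThreshold", function(object) standardGeneric("chosenThreshold"))

#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))

#' @export
setGeneric("imageMask", function(object) standardGeneric("imageMask"))

#' Winsorize channel intensities
#'
#' @param object an [MSIDataset-class].
#' @param upperQuantile upper clipping quantile in `(0, 1]`.
#' @export
setGeneric("winsorize", function(object, upperQuantile = 0.99)
  standardGeneric("winsorize"))
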