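## Synthetic nine-Gaussian benchmark: a 9 x 205 x 190 MSI toy data cube
## of localized 2-D Gaussian m/z-images in three mutually overlapping
## groups of three.

#' Benchmark configuration
#'
#' Builds a [BenchmarkConfig-class] describing the synthetic data cube:
#' `nGroups * perGroup` channels on a fully measured `gridShape` grid,
#' each channel a rotated anisotropic 2-D Gaussian. Channels of one group
#' share a group center; each channel is individually distorted by a
#' uniform position jitter, independent relative jitters of its x- and
#' y-sigma, and a random rotation. Group centers default to the vertices
#' of an equilateral triangle centered in the grid with side length
#' `2.2 * baseSigma`, which guarantees all three pairwise overlaps.
#'
#' @param gridShape integer `c(m, n)` grid (width, height).
#' @param nGroups,perGroup number of groups and channels per group.
#' @param baseSigma base Gaussian sd in pixels.
#' @param amplitudeBase,amplitudeStep channel `j` of a group gets peak
#'   amplitude `amplitudeBase + amplitudeStep * (j - 1)` ("slightly
#'   different amplitude"); amplitude does not affect Pearson similarity.
#' @param positionJitter centers are jittered by U(-positionJitter,
#'   positionJitter) px per axis.
#' @param sigmaJitterFrac x- and y-sigma are independently scaled by
#'   `1 + U(-f, f)`.
#' @param rotationRange rotation angle drawn uniformly from this interval
#'   (radians).
#' @param groupLayout optional numeric matrix of group centers (one row
#'   per group, columns x, y); 0-row matrix selects the default layout.
#' @param noiseSd sd of optional additive Gaussian noise (truncated at 0);
#'   default 0, i.e. noise-free images.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated [BenchmarkConfig-class].
#' @export
BenchmarkConfig <- function(gridShape = c(205L, 190L), nGroups = 3L,
                            perGroup = 3L, baseSigma = 22,
                            amplitudeBase = 1.0, amplitudeStep = 0.1,
                            positionJitter = 5, sigmaJitterFrac = 0.1,
                            rotationRange = c(0, pi),
                            groupLayout = matrix(numeric(0), 0L, 2L),
                            noiseSd = 0, seed = 1L) {
  new("BenchmarkConfig",
      gridShape = as.integer(gridShape), nGroups = as.integer(nGroups),
      perGroup = as.integer(perGroup), baseSigma = baseSigma,
      amplitudeBase = amplitudeBase, amplitudeStep = amplitudeStep,
      positionJitter = positionJitter, sigmaJitterFrac = sigmaJitterFrac,
      rotationRange = as.numeric(rotationRange),
      groupLayout = groupLayout, noiseSd = noiseSd, seed = as.integer(seed))
}

## Group centers: user-supplied layout, or nGroups points equally spaced
## on the circumcircle of an equilateral triangle with side 2.2*baseSigma,
## centered in the grid, starting at angle pi/2.
benchmarkCenters <- function(cfg) {
  if (nrow(cfg@groupLayout) > 0L) {
    if (nrow(cfg@groupLayout) != cfg@nGroups)
      stop("groupLayout must have one row per group")
    return(cfg@groupLayout)
  }
  m <- cfg@gridShape[1L]; n <- cfg@gridShape[2L]
  side <- 2.2 * cfg@baseSigma
  radius <- side / sqrt(3)
  ang <- pi / 2 + 2 * pi * (seq_len(cfg@nGroups) - 1L) / max(cfg@nGroups, 1L)
  cbind(x = (m + 1) / 2 + radius * cos(ang),
        y = (n + 1) / 2 + radius * sin(ang))
}

## Evaluate then restore the global RNG state, so generation is
## reproducible without clobbering the caller's random stream.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the synthetic nine-Gaussian benchmark data cube
#'
#' Produces an [MSIDataset-class] with `nGroups * perGroup` channels on a
#' fully measured grid (default 9 channels on 205 x 190 = 38950 pixels).
#' Channel `j` belongs to group `ceiling(j / perGroup)` and is a rotated
#' anisotropic Gaussian at its group's (jittered) center.
#'
#' Random draws are consumed in a fixed documented order — for each
#' channel in turn: x-jitter, y-jitter, x-sigma factor, y-sigma factor,
#' rotation angle; then, only if `noiseSd > 0`, one noise matrix — so the
#' output is fully reproducible given `cfg@seed`.
#'
#' @param cfg a [BenchmarkConfig-class] (default configuration if omitted).
#' @return an [MSIDataset-class]; synthetic m/z values are assigned as
#'   an arbitrary increasing ladder starting at 100 Da.
#' @examples
#' ds <- generateBenchmark(BenchmarkConfig(gridShape = c(60, 55),
#'                                         baseSigma = 7, seed = 42))
#' nChannels(ds)
#' @export
generateBenchmark <- function(cfg = BenchmarkConfig()) {
  validObject(cfg)
  m <- cfg@gridShape[1L]; n <- cfg@gridShape[2L]
  nV <- cfg@nGroups * cfg@perGroup
  centers <- benchmarkCenters(cfg)
  xy <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(n)))
  D <- .withSeed(cfg@seed, {
    D <- matrix(0, nrow(xy), nV)
    for (j in seq_len(nV)) {
      g <- (j - 1L) %/% cfg@perGroup + 1L
      cx <- centers[g, 1L] + runif(1, -cfg@positionJitter, cfg@positionJitter)
      cy <- centers[g, 2L] + runif(1, -cfg@positionJitter, cfg@positionJitter)
      sx <- cfg@baseSigma *
        (1 + runif(1, -cfg@sigmaJitterFrac, cfg@sigmaJitterFrac))
      sy <- cfg@baseSigma *
        (1 + runif(1, -cfg@sigmaJitterFrac, cfg@sigmaJitterFrac))
      th <- runif(1, cfg@rotationRange[1L], cfg@rotationRange[2L])
      amp <- cfg@amplitudeBase +
        cfg@amplitudeStep * ((j - 1L) %% cfg@perGroup)
      a <- cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2)
      b <- -sin(2 * th) / (4 * sx^2) + sin(2 * th) / (4 * sy^2)
      cc <- sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2)
      dx <- xy[, 1L] - cx
      dy <- xy[, 2L] - cy
      D[, j] <- amp * exp(-(a * dx^2 + 2 * b * dx * dy + cc * dy^2))
    }
    if (cfg@noiseSd > 0)
      D <- pmax(D + matrix(rnorm(length(D), sd = cfg@noiseSd),
                           nrow(D), ncol(D)), 0)
    D
  })
  MSIDataset(D, xy, mzValues = 100 + 50 * (seq_len(nV) - 1L),
             channelIds = sprintf("I%d", seq_len(nV) - 1L),
             gridShape = cfg@gridShape)
}

#' Ground-truth grouping of the benchmark channels
#'
#' @param cfg a [BenchmarkConfig-class].
#' @return integer vector of length `nGroups * perGroup`: group label
#'   (1-based) of each channel; for the defaults,
#'   `{1,1,1,2,2,2,3,3,3}` over channels 1..9.
#' @export
benchmarkGroundTruth <- function(cfg = BenchmarkConfig()) {
  validObject(cfg)
  rep(seq_len(cfg@nGroups), each = cfg@perGroup)
}
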