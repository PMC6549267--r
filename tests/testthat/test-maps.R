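test_that("community maps aggregate member images as stated", {
  # single-member community: map equals the channel image
  set.seed(161)
  ds <- makeDataset(matrix(rexp(20 * 3), 20, 3), 4, 5)
  m1 <- communityMap(ds, 2, "max")
  expect_equal(imageValues(m1@image), imageValues(renderImage(ds, 2)))
  m2 <- communityMap(ds, 2, "average")
  expect_equal(imageValues(m2@image), imageValues(renderImage(ds, 2)))

  # two constant images (3 and 5 everywhere)
  const <- makeDataset(cbind(rep(3, 20), rep(5, 20)), 4, 5)
  expect_true(all(imageValues(communityMap(const, 1:2, "max")@image) == 5))
  expect_true(all(imageValues(communityMap(const, 1:2, "average")@image) == 4))

  expect_error(communityMap(ds, integer(0)), "non-empty")
  expect_error(communityMap(ds, 9), "out of range")
})

test_that("average maps never exceed maximum maps; supports match", {
  set.seed(171)
  for (rep in 1:5) {
    ds <- makeDataset(matrix(rexp(30 * 4), 30, 4), 5, 6)
    members <- sort(sample(1:4, 2 + (rep %% 3)))
    mx <- imageValues(communityMap(ds, members, "max")@image)
    av <- imageValues(communityMap(ds, members, "average")@image)
    expect_true(all(av <= mx + 1e-12))
    expect_equal(av > 0, mx > 0)  # same support
  }
})

test_that("benchmark group map covers the union of member footprints", {
  cfg <- smallBenchCfg(12)
  ds <- generateBenchmark(cfg)
  mx <- imageValues(communityMap(ds, 1:3, "max")@image)
  for (ch in 1:3) {
    img <- imageValues(renderImage(ds, ch))
    expect_true(all(mx >= img - 1e-12))
    # wherever a member has substantial signal, so does the map
    expect_true(all(mx[img > 0.5 * max(img)] > 0))
  }
})

test_that("single-mass rescaling maximizes contrast and is idempotent", {
  set.seed(164)
  ds <- makeDataset(cbind(c(2, 6, 10, runif(17, 2, 10)), rep(7, 20)), 4, 5)
  img <- rescaleImage(renderImage(ds, 1))
  v <- imageValues(img)
  expect_equal(range(v[imageMask(img)]), c(0, 1))
  # value 6 on a [2, 10] scale maps to 0.5 (pixel 2 = grid cell (2, 1))
  expect_equal(v[2, 1], 0.5, tolerance = 1e-12)
  # constant image maps to all zeros
  expect_true(all(imageValues(rescaleImage(renderImage(ds, 2))) == 0))
  # idempotent
  expect_equal(imageValues(rescaleImage(img)), v, tolerance = 1e-15)
})

test_that("PCA RGB map has the right shape, range, and degenerate behavior", {
  set.seed(181)
  ds <- makeDataset(matrix(rexp(40 * 5), 40, 5), 5, 8)
  rgb <- pcaRGBMap(ds)
  expect_equal(dim(rgb), c(5, 8, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # alternative component selection (second to fourth)
  rgb2 <- pcaRGBMap(ds, components = 2:4)
  expect_equal(dim(rgb2), c(5, 8, 3))
  expect_false(identical(rgb, rgb2))

  # rank-1 dataset: all variance on PC1, so G and B rescale to zero
  base <- rexp(40)
  r1 <- makeDataset(cbind(base, 2 * base, 0.5 * base), 5, 8)
  rgbR1 <- pcaRGBMap(r1)
  expect_true(all(rgbR1[, , 2] == 0))
  expect_true(all(rgbR1[, , 3] == 0))
  expect_gt(max(rgbR1[, , 1]), 0)

  expect_error(pcaRGBMap(makeDataset(matrix(rexp(20), 10, 2), 2, 5)),
               "3 channels")
  expect_error(pcaRGBMap(ds, components = 1:2), "three")
})

test_that("community graph classifies edges by the expansion rules", {
  # two communities joined by one inter-edge
  A <- adjFromEdges(4, list(c(1, 2), c(3, 4), c(2, 3)))
  p <- new("CommunityPartition", labels = c(1L, 1L, 2L, 2L),
           indivisible = c(TRUE, TRUE), channelIds = channelIds(A))
  cg <- buildCommunityGraph(A, p)
  expect_equal(nrow(cg@communityEdges), 1)
  expect_equal(unname(cg@communityEdges[1, ]), c(1L, 2L))
  expect_equal(nrow(cg@hybridEdges), 0)
  expect_equal(nrow(cg@mzEdges), 0)

  # expanding one side turns the inter-edge into exactly one hybrid edge
  cgE <- buildCommunityGraph(A, p, expanded = 1L)
  expect_equal(nrow(cgE@communityEdges), 0)
  expect_equal(nrow(cgE@hybridEdges), 1)
  expect_equal(unname(cgE@hybridEdges[1, ]), c(2L, 2L))  # node 2 -> community 2
  expect_equal(nrow(cgE@mzEdges), 1)  # intra-edge (1,2) materialized
  expect_equal(cgE@mzNodes, c(1L, 2L))

  # both sides expanded: everything lives at the m/z level
  cgB <- buildCommunityGraph(A, p, expanded = 1:2)
  expect_equal(nrow(cgB@communityEdges), 0)
  expect_equal(nrow(cgB@hybridEdges), 0)
  expect_equal(nrow(cgB@mzEdges), 3)

  expect_error(buildCommunityGraph(A, p, expanded = 5L), "unknown")
})

test_that("community-edge existence matches brute-force classification", {
  set.seed(191)
  for (rep in 1:5) {
    A <- randomAdj(12, 0.25)
    lab <- sample(1:4, 12, replace = TRUE)
    lab <- match(lab, unique(lab))
    p <- new("CommunityPartition", labels = as.integer(lab),
             indivisible = rep(TRUE, max(lab)), channelIds = channelIds(A))
    expanded <- sort(sample(seq_len(max(lab)),
                            size = min(1 + rep %% 2, max(lab))))
    cg <- buildCommunityGraph(A, p, expanded = expanded)

    adj <- adjacencyValues(A)
    expComm <- character(0); expHyb <- character(0); expMz <- character(0)
    for (i in 1:11) for (j in (i + 1):12) {
      if (adj[i, j] != 1) next
      ci <- lab[i]; cj <- lab[j]
      ei <- ci %in% expanded; ej <- cj %in% expanded
      if (ci == cj) {
        if (ei) expMz <- c(expMz, paste(i, j))
      } else if (!ei && !ej) {
        expComm <- c(expComm, paste(min(ci, cj), max(ci, cj)))
      } else if (ei && ej) {
        expMz <- c(expMz, paste(i, j))
      } else if (ei) {
        expHyb <- c(expHyb, paste(i, cj))
      } else {
        expHyb <- c(expHyb, paste(j, ci))
      }
    }
    fmt <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)
    expect_setequal(fmt(cg@communityEdges), unique(expComm))
    expect_setequal(fmt(cg@hybridEdges), unique(expHyb))
    expect_setequal(fmt(cg@mzEdges), expMz)
  }
})

test_that("edge reduction percentages match the published graph sizes", {
  expect_equal(edgeReductionPercent(101, 789), 84.376)
  expect_equal(edgeReductionPercent(106, 2371), 57.394)
  expect_equal(edgeReductionPercent(10, 45), 0)
  expect_error(edgeReductionPercent(1, 0), "at least 2")
  expect_error(edgeReductionPercent(10, 46), "nEdges")
})

test_that("thresholding at -1 keeps the complete graph (zero reduction)", {
  set.seed(201)
  ds <- makeDataset(matrix(rexp(30 * 5), 30, 5), 5, 6)
  S <- pearsonSimilarity(ds)
  A <- applyThreshold(S, -1)
  expect_equal(edgeReductionPercent(5, countEdges(A)), 0)
})

test_that("the pipeline ties the stages together deterministically", {
  # full-size benchmark: three disconnected communities, nine edges
  resFull <- runPipeline(generateBenchmark(BenchmarkConfig(seed = 1)))
  expect_equal(resFull@report$nC, 3)
  expect_equal(resFull@report$nEdges, 9)
  expect_equal(nrow(resFull@communityGraph@communityEdges), 0)
  expect_equal(resFull@report$edgeReductionPercent, 75)

  ds <- generateBenchmark(smallBenchCfg(10))
  res <- runPipeline(ds)
  expect_s4_class(res, "PipelineResult")
  expect_equal(res@report$nC, 3)
  expect_length(res@maps, 3)

  # byte-identical re-run
  res2 <- runPipeline(ds)
  expect_identical(res@report, res2@report)
  expect_identical(communityLabels(res@partition),
                   communityLabels(res2@partition))
  expect_identical(similarityValues(res@similarity),
                   similarityValues(res2@similarity))

  # two identical channels collapse into one 2-community
  twin <- makeDataset(cbind(c(1, 2, 3, 4), c(2, 4, 6, 8)), 2, 2)
  resT <- suppressWarnings(runPipeline(twin,
                                       pipelineConfig(winsorize = FALSE)))
  expect_equal(resT@report$nC, 1)
  expect_equal(resT@report$sizes, 2L)
})

test_that("stage failures identify the failing stage", {
  bad <- makeDataset(matrix(rexp(4), 4, 1), 2, 2)  # one channel only
  expect_error(runPipeline(bad), "stage 'similarity'")
})

test_that("viewer export writes a valid, parse-back-consistent document", {
  ds <- generateBenchmark(smallBenchCfg(10))
  res <- runPipeline(ds)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "result.json")
  exportViewerJSON(res, path)
  expect_true(validateViewerExport(path))

  doc <- jsonlite::read_json(path)
  expect_length(doc$communities, 3)
  # parse-back recovers the edge bookkeeping
  expect_equal(length(doc$community_edges),
               nrow(res@communityGraph@communityEdges))
  expect_equal(doc$n_edges, countEdges(res@adjacency))
  expect_equal(sum(lengths(lapply(doc$communities, `[[`, "members"))), 9)
  # map images written alongside
  for (com in doc$communities)
    expect_true(file.exists(file.path(dir, com$map)))

  # exports are CSV round-trippable
  exportSweepCSV(res@sweep, file.path(dir, "sweep.csv"))
  sw <- read.csv(file.path(dir, "sweep.csv"))
  expect_equal(nrow(sw), 21)
  expect_equal(sum(sw$chosen), 1)
  exportPartitionCSV(res@partition, file.path(dir, "partition.csv"))
  pt <- read.csv(file.path(dir, "partition.csv"))
  expect_equal(nrow(pt), 9)
  expect_true(samePartition(pt$community_id,
                            unname(communityLabels(res@partition))))
  exportSimilarityCSV(res@similarity, file.path(dir, "similarity.csv"))
  sm <- read.csv(file.path(dir, "similarity.csv"), check.names = FALSE)
  expect_equal(as.matrix(sm[, -1]),
               similarityValues(res@similarity), ignore_attr = TRUE)
})
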