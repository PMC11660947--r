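test_that("ROI means are computed over included voxels only", {
  uniform <- fieldFromTensors(replicate(8, diag(c(0.45, 0.3, 1.7)),
                                        simplify = FALSE), 4, 2)
  roi <- squareRoi("projection", "left", c(1, 1), 1)
  rd <- extractRoiDiffusivities(uniform, roi)
  expect_equal(rd@dxx, 0.45)
  expect_equal(rd@dyy, 0.3)
  expect_equal(rd@dzz, 1.7)
  expect_equal(rd@nIncluded + rd@nExcluded, 4L)

  # one outlier voxel carrying Dxx = 10, flagged
  tl <- replicate(4, diag(c(1, 1, 1)), simplify = FALSE)
  tl[[1]] <- diag(c(10, 1, 1))
  field <- fieldFromTensors(tl, 2, 2)
  flags <- array(FALSE, c(2, 2, 1)); flags[1, 1, 1] <- TRUE
  fm <- new("FlagMap", flags = flags, threshold = 1.8)
  adj <- extractRoiDiffusivities(field, roi, fm, mode = "adjusted")
  expect_equal(adj@dxx, 1)
  expect_equal(adj@nExcluded, 1L)
  conv <- extractRoiDiffusivities(field, roi, mode = "conventional")
  expect_equal(conv@dxx, (10 + 3) / 4)

  allFm <- new("FlagMap", flags = array(TRUE, c(2, 2, 1)), threshold = 1.8)
  expect_error(extractRoiDiffusivities(field, roi, allFm, mode = "adjusted"),
               "relocate")
  expect_error(extractRoiDiffusivities(field,
                 squareRoi("projection", "left", c(2, 2), 1)),
               "outside the grid")
})

test_that("the ALPS index is the x-over-transverse diffusivity ratio", {
  expect_equal(alpsIndex(c(dxx = 0.9, dyy = 0.6), c(dxx = 0.9, dzz = 0.6)), 1.5)
  expect_equal(alpsIndex(c(dxx = 0.7, dyy = 0.7), c(dxx = 0.7, dzz = 0.7)), 1)
  expect_equal(alpsIndex(c(dxx = 0.45, dyy = 0.3), c(dxx = 0.36, dzz = 0.24)),
               1.5)
  expect_error(alpsIndex(c(dxx = 1, dyy = -2), c(dxx = 1, dzz = 1)),
               "denominator")
})

test_that("ALPS is invariant to voxel ordering within ROIs", {
  set.seed(9)
  tl <- replicate(8, randomTensor(), simplify = FALSE)
  field <- fieldFromTensors(tl, 4, 2)
  vox <- as.matrix(expand.grid(1:2, 1:2, 1))
  a <- extractRoiDiffusivities(field, roiSpec("projection", "left", vox))
  b <- extractRoiDiffusivities(field,
         roiSpec("projection", "left", vox[c(3, 1, 4, 2), ]))
  expect_equal(a@dxx, b@dxx)
  expect_equal(a@dyy, b@dyy)
})

test_that("true ALPS follows 1 + Dpv/Drad and is scale invariant", {
  expect_equal(trueAlps(0, 0.3), 1)
  expect_equal(trueAlps(0.15, 0.3), 1.5)
  expect_equal(trueAlps(0.3, 0.6), trueAlps(0.15, 0.3))
  expect_error(trueAlps(0.1, 0), "> 0")
  expect_error(trueAlps(-0.1, 0.3), ">= 0")
})

test_that("ALPS from a noiseless axis-aligned phantom reduces to 1 + Dpv/Drad", {
  for (dpv in c(0, 0.15)) {
    ph <- makePhantom(phantomConfig(dpv = dpv))
    res <- analyzePhantom(ph)
    expect_equal(res$alps, rep(trueAlps(dpv, 0.3), 4), tolerance = 1e-10)
  }
  # at Dpv/Drad = 1 the clean-fibre eigenvalue ratio itself reaches 2.0,
  # beyond the 1.8 flag threshold: the conventional index still reduces
  # exactly, while flag-guided relocation rightly refuses (everything is
  # "dark")
  ph <- makePhantom(phantomConfig(dpv = 0.3))
  field <- fitTensorField(ph@dwi, ph@scheme, labels = ph@truth@labels)
  rois <- phantomRois(ph@truth@config@dims)
  conv <- computeAlps(field, rois$left$projection, rois$left$association,
                      mode = "conventional")
  expect_equal(conv$conventional@alps, 2, tolerance = 1e-10)
  flags <- flagCrossing(field)
  expect_error(computeAlps(field, rois$left$projection,
                           rois$left$association, flags, mode = "adjusted"),
               "candidate")
})

test_that("clean-ROI search relocates away from flagged voxels deterministically", {
  # 6 x 4 slab, uniform tensors; flags on the right half
  field <- fieldFromTensors(replicate(24, diag(c(0.45, 0.3, 1.7)),
                                      simplify = FALSE), 6, 4)
  flags <- array(FALSE, c(6, 4, 1))
  seed <- squareRoi("projection", "left", c(3, 2), 1)
  fm <- new("FlagMap", flags = flags, threshold = 1.8)
  expect_equal(roiVoxels(findCleanRoi(field, fm, seed)), roiVoxels(seed))

  # flag the seed's right column; the clean 2x2 one voxel to the left wins
  flags[4, 2:3, 1] <- TRUE
  fm <- new("FlagMap", flags = flags, threshold = 1.8)
  found <- findCleanRoi(field, fm, seed, searchRadius = 2)
  expect_equal(min(roiVoxels(found)[, 1]), 2)
  expect_equal(found@mode, "adjusted")

  # fully flagged window
  flags[, , 1] <- TRUE
  fm <- new("FlagMap", flags = flags, threshold = 1.8)
  expect_error(findCleanRoi(field, fm, seed, searchRadius = 2), "candidate")
})

test_that("clean-ROI search respects tissue labels", {
  field <- fieldFromTensors(replicate(24, diag(c(0.45, 0.3, 1.7)),
                                      simplify = FALSE), 6, 4)
  field@labels[, 1:2, 1] <- 1L   # projection rows
  field@labels[, 3:4, 1] <- 2L   # association rows
  flags <- array(FALSE, c(6, 4, 1))
  flags[2:3, 1:2, 1] <- TRUE     # flag the projection seed
  fm <- new("FlagMap", flags = flags, threshold = 1.8)
  seed <- squareRoi("projection", "left", c(2, 1), 1)
  found <- findCleanRoi(field, fm, seed, searchRadius = 3)
  # must stay in label-1 rows even though label-2 rows are unflagged
  expect_true(all(field@labels[roiVoxels(found)] == 1L))
  expect_true(all(roiVoxels(found)[, 2] <= 2))
})

test_that("conventional and relocated-adjusted ALPS agree on a clean field", {
  ph <- makePhantom(phantomConfig(dpv = 0.15))
  field <- fitTensorField(ph@dwi, ph@scheme, labels = ph@truth@labels)
  flags <- flagCrossing(field)
  rois <- phantomRois(ph@truth@config@dims)
  res <- computeAlps(field, rois$left$projection, rois$left$association,
                     flags, mode = "both")
  expect_equal(res$conventional@alps, res$adjusted@alps, tolerance = 1e-12)
  # exclusion mode agrees too when nothing is flagged
  res2 <- computeAlps(field, rois$left$projection, rois$left$association,
                      flags, mode = "adjusted", adjust = "exclude")
  expect_equal(res2$adjusted@alps, res$conventional@alps, tolerance = 1e-12)
  expect_equal(res2$adjusted@projection@nExcluded, 0L)
})
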