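test_that("synthetic gradient schemes are well-formed and deterministic", {
  sch <- makeScheme()
  expect_equal(length(bValues(sch)), 31L)      # 1 b=0 + 30 weighted
  expect_equal(sum(bValues(sch) == 0), 1L)
  g <- directions(sch)[bValues(sch) > 0, ]
  expect_true(all(abs(sqrt(rowSums(g^2)) - 1) < 1e-8))
  expect_identical(makeScheme(), makeScheme())
  expect_identical(makeScheme(20, seed = 3), makeScheme(20, seed = 3))
  expect_false(identical(directions(makeScheme(20, seed = 3)),
                         directions(makeScheme(20, seed = 4))))
  # repulsion spreads points: smallest pairwise (antipodally folded) angle
  # should be well clear of zero
  cosAng <- pmin(abs(tcrossprod(g)), 1)
  minAngle <- min(acos(cosAng[upper.tri(cosAng)])) * 180 / pi
  expect_gt(minAngle, 10)
})

test_that("noiseless phantoms recover the true ALPS through the pipeline", {
  res <- analyzePhantom(makePhantom(phantomConfig(dpv = 0, fxp = 0)))
  expect_equal(res$alps, rep(1, 4), tolerance = 1e-10)
  res <- analyzePhantom(makePhantom(phantomConfig(dpv = 0.15, drad = 0.3)))
  expect_equal(res$alps, rep(1.5, 4), tolerance = 1e-10)
})

test_that("undetectable crossing inflates the conventional ROI as Eq-5 predicts", {
  # fXp = 0.1 mixtures stay below the flag threshold; the conventional ROI
  # reads the inflated index while a ground-truth clean ROI reads 1.0
  cfg <- phantomConfig(dpv = 0, fxp = 0.1, dxxCross = 1.7)
  ph <- makePhantom(cfg)
  field <- fitTensorField(ph@dwi, ph@scheme, labels = ph@truth@labels)
  rois <- phantomRois(cfg@dims)
  conv <- computeAlps(field, rois$left$projection, rois$left$association,
                      mode = "conventional")
  expect_equal(conv$conventional@alps, 37 / 30, tolerance = 1e-10)
  # clean ROI outside the crossing zone, same slabs (ground truth placement)
  lay <- crossalps:::.phantomLayout(cfg@dims)
  projClean <- squareRoi("projection", "left",
                         c(1, lay$sites[["left.projection"]]$zoneY[1]),
                         lay$slice)
  assocClean <- squareRoi("association", "left",
                          c(1, lay$sites[["left.association"]]$zoneY[1]),
                          lay$slice)
  clean <- computeAlps(field, projClean, assocClean, mode = "conventional")
  expect_equal(clean$conventional@alps, 1, tolerance = 1e-10)
  expect_false(any(flagArray(flagCrossing(field))))
})

test_that("phantom crossing voxels are recorded in the ground truth", {
  cfg <- phantomConfig(fxp = 0.5, fxa = 0.5, dpv = 0)
  ph <- makePhantom(cfg)
  expect_true(any(ph@truth@crossing))
  # lattice pattern: every 2x2 ROI inside the zone holds exactly one
  cfgL <- phantomConfig(fxp = 0.5, fxa = 0.5, crossingPattern = "lattice")
  phL <- makePhantom(cfgL)
  lay <- crossalps:::.phantomLayout(cfgL@dims)
  site <- lay$sites[["right.association"]]
  for (cx in site$zoneX[1:3]) for (cy in site$zoneY[1:3])
    expect_equal(sum(phL@truth@crossing[cx:(cx + 1), cy:(cy + 1), lay$slice]),
                 1L)
})

test_that("flagging separates 90-degree equal mixtures perfectly when noiseless", {
  cfg <- phantomConfig(fxp = 0.5, fxa = 0.5, dpv = 0)
  ph <- makePhantom(cfg)
  field <- fitTensorField(ph@dwi, ph@scheme, labels = ph@truth@labels)
  flags <- flagArray(flagCrossing(field))
  truth <- ph@truth@crossing
  expect_equal(sum(flags & truth), sum(truth))      # sensitivity 1
  expect_equal(sum(flags & !truth), 0L)             # specificity 1
})

test_that("Rician noise has the magnitude-MRI moments and is seed-reproducible", {
  s <- rep(100, 1000)
  expect_identical(addRicianNoise(s, Inf), s)
  n1 <- addRicianNoise(s, 30, s0 = 100, seed = 11)
  n2 <- addRicianNoise(s, 30, s0 = 100, seed = 11)
  expect_identical(n1, n2)
  expect_false(identical(n1, addRicianNoise(s, 30, s0 = 100, seed = 12)))
  # Rayleigh floor: mean magnitude of pure noise is sigma * sqrt(pi/2)
  z <- addRicianNoise(rep(0, 1e5), snr = 30, s0 = 100, seed = 5)
  sigma <- 100 / 30
  expect_equal(mean(z), sigma * sqrt(pi / 2), tolerance = 0.01)
  # caller RNG state untouched when seeded
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(addRicianNoise(s, 30, s0 = 100, seed = 3))
  expect_identical(runif(1), before)
})

test_that("cohorts honour group structure, determinism and couplings", {
  cc <- cohortConfig(seed = 5, hemispheres = "left",
                     groups = data.frame(
                       group = c("HC", "PSP"), n = c(12L, 6L),
                       dpvMean = c(0.129, 0.078), dpvSd = c(0, 0),
                       dradMean = 0.3, dradSd = 0,
                       fxMean = 0, fxSd = 0,
                       scoreMean = c(NA, 37.8), scoreSd = c(NA, 16.3),
                       scoreCor = c(NA, 0.5)))
  rec <- makeCohort(cc)
  expect_equal(nrow(rec), (12 + 6) * 2)     # two modes per subject
  expect_equal(sort(unique(rec$group)), c("HC", "PSP"))
  expect_equal(sum(rec$group == "HC" & rec$mode == "conventional"), 12)
  # zero SDs: all subjects in a group share generating parameters
  expect_equal(length(unique(rec$dpv[rec$group == "HC"])), 1L)
  expect_equal(length(unique(rec$trueAlps[rec$group == "PSP"])), 1L)
  # clinical score present only where configured
  expect_true(all(is.na(rec$clinicalScore[rec$group == "HC"])))
  expect_true(all(is.finite(rec$clinicalScore[rec$group == "PSP"])))
  # determinism
  expect_identical(rec, makeCohort(cc))
  # lower perivascular diffusivity group recovers lower mean ALPS
  adj <- rec[rec$mode == "adjusted", ]
  expect_lt(mean(adj$alps[adj$group == "PSP"]),
            mean(adj$alps[adj$group == "HC"]))
})

test_that("cohort defaults emulate the three-group study layout", {
  cc <- cohortConfig()
  g <- cc@groups
  expect_equal(g$n[match(c("HC", "PD", "PSP"), g$group)], c(41L, 60L, 17L))
  expect_true(all(g$fxMean[match(c("HC", "PD"), g$group)] >
                  g$fxMean[g$group == "PSP"]))
})
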