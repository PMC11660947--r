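test_that("synthesized signals follow the monoexponential tensor model", {
  sch <- axisScheme(s0rows = 2)
  # isotropic tensor: same attenuation in every direction
  s <- synthesizeSignals(diffusionTensor(0.7, 0.7, 0.7), sch, s0 = 1)
  expect_equal(s[bValues(sch) == 0], c(1, 1))
  expect_equal(s[bValues(sch) > 0], rep(exp(-0.7), 6), tolerance = 1e-12)
  # prolate tensor along x, measured along x
  s <- synthesizeSignals(diffusionTensor(1.7, 0.3, 0.3), sch, s0 = 100)
  expect_equal(s[3], 100 * exp(-1.7), tolerance = 1e-12)  # g = (1,0,0)
  expect_equal(s[4], 100 * exp(-0.3), tolerance = 1e-12)  # g = (0,1,0)
  # b = 0 always returns s0 regardless of the tensor
  expect_equal(synthesizeSignals(randomTensor(), sch, s0 = 42)[1], 42)
})

test_that("signal synthesis rejects tensors with negative eigenvalues", {
  expect_error(synthesizeSignals(diffusionTensor(-0.1, 0.3, 0.3), axisScheme()),
               "negative eigenvalue")
})

test_that("log-linear fit round-trips noiseless signals", {
  sch <- makeScheme()
  set.seed(41)
  for (i in 1:30) {
    m <- randomTensor()
    s <- synthesizeSignals(m, sch, s0 = 100)
    fit <- fitTensor(s, sch)
    expect_lt(max(abs(fit@components - tensorFromMatrix(m)@components)), 1e-8)
    expect_equal(attr(fit, "s0"), 100, tolerance = 1e-8)
  }
})

test_that("weighted refit equals the ordinary fit on noiseless data", {
  sch <- makeScheme()
  set.seed(17)
  m <- randomTensor()
  s <- synthesizeSignals(m, sch, s0 = 100)
  expect_equal(fitTensor(s, sch, weighted = TRUE)@components,
               fitTensor(s, sch)@components, tolerance = 1e-10)
  # on noisy data it still returns a sensible tensor near the generator
  sn <- addRicianNoise(s, snr = 40, s0 = 100, seed = 2)
  fw <- fitTensor(sn, sch, weighted = TRUE)
  expect_lt(max(abs(fw@components - tensorFromMatrix(m)@components)), 0.2)
})

test_that("constant signals fit to the zero tensor", {
  sch <- makeScheme()
  fit <- fitTensor(rep(7, length(bValues(sch))), sch)
  expect_equal(unname(fit@components), rep(0, 6), tolerance = 1e-12)
})

test_that("fitted principal direction matches a rotated generator", {
  sch <- makeScheme()
  set.seed(7)
  for (i in 1:10) {
    r <- randomRotation()
    m <- r %*% diag(c(1.7, 0.3, 0.3)) %*% t(r)
    fit <- fitTensor(synthesizeSignals(m, sch, 50), sch)
    e1 <- eigenSystem(fit)@vectors[, 1]
    angle <- acos(min(abs(sum(e1 * r[, 1])), 1)) * 180 / pi
    expect_lt(angle, 0.1)
  }
})

test_that("degenerate gradient schemes are rejected", {
  # 6 directions in one plane cannot determine a tensor
  th <- seq(0, pi, length.out = 7)[-7]
  expect_error(gradientScheme(c(0, rep(1000, 6)),
                              rbind(0, cbind(cos(th), sin(th), 0))),
               "degenerate")
  expect_error(makeScheme(4), "at least 6")
})

test_that("eigen-decomposition is ordered, orthonormal and reconstructive", {
  e <- eigenSystem(diffusionTensor(1.7, 0.3, 0.3))
  expect_equal(e@values, c(1.7, 0.3, 0.3))
  e <- eigenSystem(diffusionTensor(0.3, 1.7, 0.3))
  expect_equal(e@values[1], 1.7)
  expect_equal(abs(e@vectors[, 1]), c(0, 1, 0))
  expect_gte(e@vectors[2, 1], 0)   # sign fix: dominant component positive
  e <- eigenSystem(diffusionTensor(0.7, 0.7, 0.7))
  expect_equal(e@values, rep(0.7, 3))
  set.seed(13)
  for (i in 1:25) {
    m <- randomTensor()
    e <- eigenSystem(m)
    expect_false(is.unsorted(rev(e@values)))
    rec <- e@vectors %*% diag(e@values) %*% t(e@vectors)
    expect_lt(max(abs(rec - m)), 1e-10)
    expect_lt(max(abs(crossprod(e@vectors) - diag(3))), 1e-8)
  }
  expect_error(eigenSystem(diffusionTensor(NaN, 1, 1)), "finite")
})

test_that("FA and MD match their definitions and FA is rotation invariant", {
  sm <- scalarMaps(eigenSystem(diffusionTensor(0.7, 0.7, 0.7)))
  expect_equal(sm$fa, 0)
  expect_equal(sm$md, 0.7)
  sm <- scalarMaps(eigenSystem(diffusionTensor(1.7, 0.3, 0.3)))
  expect_equal(sm$md, (1.7 + 0.3 + 0.3) / 3, tolerance = 1e-12)
  expect_equal(sm$fa, 0.7990222, tolerance = 1e-6)
  expect_equal(scalarMaps(eigenSystem(diffusionTensor(1, 0, 0)))$fa, 1)
  expect_equal(scalarMaps(eigenSystem(diffusionTensor(0, 0, 0)))$fa, 0)
  set.seed(5)
  for (i in 1:10) {
    m <- randomTensor()
    r <- randomRotation()
    a <- scalarMaps(eigenSystem(m))
    b <- scalarMaps(eigenSystem(r %*% m %*% t(r)))
    expect_equal(a$fa, b$fa, tolerance = 1e-10)
    expect_equal(a$md, b$md, tolerance = 1e-10)
    # principal axis co-rotates (up to sign)
    e1 <- eigenSystem(m)@vectors[, 1]
    e1r <- eigenSystem(r %*% m %*% t(r))@vectors[, 1]
    expect_equal(abs(sum(e1r * (r %*% e1))), 1, tolerance = 1e-8)
  }
})

test_that("vectorized field eigenvalues agree with base eigen", {
  set.seed(3)
  tl <- replicate(12, randomTensor() - 0.3 * diag(3), simplify = FALSE)
  field <- fieldFromTensors(tl, 4, 3)
  ev <- crossalps:::.eigvalsSym3(crossalps:::.tensorMatrixAt(
    tensorArray(field), seq_len(12)))
  for (k in 1:12)
    expect_equal(ev[, k], eigen(tl[[k]], symmetric = TRUE,
                                only.values = TRUE)$values,
                 tolerance = 1e-10)
})

test_that("DEC map colours voxels by principal axis weighted by FA", {
  tl <- list(diag(c(0.43, 0.3, 1.7)),   # z fibre -> blue
             diag(c(0.43, 1.7, 0.3)),   # y fibre -> green
             diag(c(1.7, 0.3, 0.3)),    # x fibre -> red
             0.7 * diag(3))             # isotropic -> black
  dec <- decMap(fieldFromTensors(tl, 2, 2))
  blue <- dec[1, 1, 1, ]; green <- dec[2, 1, 1, ]
  red <- dec[1, 2, 1, ]; black <- dec[2, 2, 1, ]
  expect_gt(blue[3], max(blue[1:2]))
  expect_gt(green[2], max(green[c(1, 3)]))
  expect_gt(red[1], max(red[2:3]))
  expect_equal(black, c(0, 0, 0))
  expect_true(all(dec >= 0 & dec <= 1))
})

test_that("whole-field fit recovers the generating field and flags QC issues", {
  cfg <- phantomConfig()
  ph <- makePhantom(cfg)
  field <- fitTensorField(ph@dwi, ph@scheme, mask = ph@mask,
                          labels = ph@truth@labels)
  expect_lt(max(abs(tensorArray(field) - ph@truth@tensors)), 1e-8)
  expect_false(any(field@qc))
  # a voxel with a zero signal gets clamped and QC-flagged
  dwi <- ph@dwi
  dwi[1, 1, 1, 5] <- 0
  field2 <- fitTensorField(dwi, ph@scheme)
  expect_true(field2@qc[1, 1, 1])
  expect_equal(sum(field2@qc), 1)
})
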