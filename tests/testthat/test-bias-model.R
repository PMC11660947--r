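test_that("site diffusivities are exact linear mixtures", {
  # no crossing: fibre-model values
  d <- mixtureDiffusivities(crossingConfig(drad = 0.3, dpv = 0.15))
  expect_equal(unname(d), c(0.45, 0.3, 0.45, 0.3))
  # full replacement at the projection site
  d <- mixtureDiffusivities(crossingConfig(drad = 0.3, fxp = 1,
                                           dxxCross = 1.7, dyyCross = 0.4))
  expect_equal(d[["dxxProj"]], 1.7)
  expect_equal(d[["dyyProj"]], 0.4)
  # partial mixture arithmetic
  d <- mixtureDiffusivities(crossingConfig(drad = 0.3, fxp = 0.1,
                                           dxxCross = 1.7, dyyCross = 0.3))
  expect_equal(d[["dxxProj"]], 0.9 * 0.3 + 0.1 * 1.7)
  expect_equal(d[["dyyProj"]], 0.3)
  expect_error(crossingConfig(drad = 0.3, fxp = 1.2), "0, 1")
})

test_that("apparent ALPS reproduces its closed-form special cases", {
  expect_equal(apparentAlps(crossingConfig(drad = 0.3)), 1)
  cfg <- crossingConfig(drad = 0.3, fxp = 0.1, dxxCross = 1.7)
  expect_equal(apparentAlps(cfg), 37 / 30, tolerance = 1e-12)
  expect_equal(apparentAlps(cfg),
               apparentAlpsClosedForm(1, 0.1, 1.7 / 0.3, "one"),
               tolerance = 1e-14)
  # crossing indistinguishable from the fibres: no bias at any fraction
  cfg <- crossingConfig(drad = 0.3, dpv = 0.12, fxp = 0.4, fxa = 0.2,
                        dxxCross = 0.42)
  expect_equal(apparentAlps(cfg), trueAlps(0.12, 0.3), tolerance = 1e-12)
})

test_that("single-site closed form matches the mixture model to 1e-12", {
  set.seed(2024)
  maxErr <- 0
  for (i in 1:10000) {
    drad <- runif(1, 0.1, 0.8)
    dpv <- runif(1, 0, 0.5)
    fx <- runif(1, 0, 1)
    dxc <- runif(1, 0, 3)
    projSite <- i %% 2 == 0
    cfg <- crossingConfig(drad = drad, dpv = dpv,
                          fxp = if (projSite) fx else 0,
                          fxa = if (projSite) 0 else fx,
                          dxxCross = dxc)
    err <- abs(apparentAlps(cfg) -
               apparentAlpsClosedForm(trueAlps(dpv, drad), fx, dxc / drad,
                                      "one"))
    maxErr <- max(maxErr, err)
  }
  expect_lt(maxErr, 1e-12)
})

test_that("both-site bias is exactly twice the single-site bias", {
  set.seed(77)
  for (i in 1:200) {
    alps <- runif(1, 1, 2); fx <- runif(1, 0.01, 1); r <- runif(1, 0, 8)
    b1 <- apparentAlpsClosedForm(alps, fx, r, "one") - alps
    b2 <- apparentAlpsClosedForm(alps, fx, r, "both") - alps
    expect_equal(b2, 2 * b1, tolerance = 1e-12)
    # Eq-4 route with equal fractions at both sites agrees
    drad <- 0.3
    cfg <- crossingConfig(drad = drad, dpv = drad * (alps - 1),
                          fxp = fx, fxa = fx, dxxCross = r * drad)
    expect_equal(apparentAlps(cfg),
                 apparentAlpsClosedForm(alps, fx, r, "both"),
                 tolerance = 1e-10)
  }
})

test_that("bias sign follows the anisotropy of the crossing fibres", {
  expect_equal(apparentAlpsClosedForm(1.5, 0.3, 1.5), 1.5)   # fixed point
  expect_equal(apparentAlpsClosedForm(1.5, 0, 7), 1.5)       # zero fraction
  expect_gt(apparentAlpsClosedForm(1.2, 0.1, 5), 1.2)        # r > ALPS
  expect_lt(apparentAlpsClosedForm(1.8, 0.1, 1.2), 1.8)      # r < ALPS
})

test_that("apparent ALPS is scale invariant in the diffusivities", {
  cfg1 <- crossingConfig(drad = 0.3, dpv = 0.15, fxp = 0.2, fxa = 0.05,
                         dxxCross = 1.7, dyyCross = 0.5, dzzCross = 0.4)
  cfg2 <- crossingConfig(drad = 0.6, dpv = 0.30, fxp = 0.2, fxa = 0.05,
                         dxxCross = 3.4, dyyCross = 1.0, dzzCross = 0.8)
  expect_equal(apparentAlps(cfg1), apparentAlps(cfg2), tolerance = 1e-12)
})

test_that("bias surfaces are flat at r = ALPS and monotone above it", {
  fx <- seq(0, 0.3, length.out = 7)
  r <- seq(1, 8, length.out = 9)
  s <- biasSurface(fx, r, trueAlps = 1.5)
  expect_equal(unname(s[1, ]), rep(1.5, 9))               # fx = 0 column
  flat <- biasSurface(fx, rGrid = 1.5, trueAlps = 1.5)
  expect_equal(unname(flat[, 1]), rep(1.5, 7))            # r = ALPS slice
  above <- r > 1.5
  expect_true(all(apply(s[, above, drop = FALSE], 2, diff) > 0))
  expect_true(all(t(apply(s[-1, above, drop = FALSE], 1, diff)) > 0))
  # every cell equals the mixture-model evaluation
  for (i in c(2, 5)) for (j in c(3, 8)) {
    cfg <- crossingConfig(drad = 0.3, dpv = 0.3 * 0.5, fxp = fx[i],
                          dxxCross = r[j] * 0.3)
    expect_equal(s[i, j], apparentAlps(cfg), tolerance = 1e-12)
  }
})

test_that("relative bias changes sign at r and can push below the true index", {
  rb <- relativeBiasCurve(c(1, 1.5, 5.667, 7), fx = 0.1, r = 5.667)
  expect_equal(unname(rb[1]), 0.1 / 2 * (5.667 - 1), tolerance = 1e-12)
  expect_equal(unname(rb[1]), 0.2333, tolerance = 1e-3)
  expect_equal(unname(rb[3]), 0)
  expect_lt(rb[4], 0)
  expect_error(relativeBiasCurve(c(0.5, 1)), ">= 1")
})
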