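test_that("SIRT drives the residual down monotonically on consistent data", {
  ds <- smallDataset(n = 32, S = 50, jitter = 0, noise = 0)
  p <- ds$projections
  f <- TomoVolume(array(0, c(32, 32, 32)))
  resid <- numeric(200)
  for (k in 1:200) {
    f <- sirtUpdate(f, p)
    wf <- projData(forwardProject(f, tiltAngles(p)))
    resid[k] <- sqrt(sum((projData(p) - wf)^2))
  }
  expect_true(all(diff(resid) <= 1e-9 * resid[-200]))
  expect_lt(resid[200], 0.05 * resid[1])
})

test_that("SIRT fixed points and localization", {
  # zero data, null init: stays zero
  p0 <- ProjectionStack(array(0, c(8, 8, 4)), c(0, 45, 90, 135))
  f <- TomoVolume(array(0, c(8, 8, 8)))
  f <- sirtUpdate(f, p0)
  expect_true(all(volumeData(f) == 0))

  # one-voxel phantom: reconstruction peaks at the true voxel
  n <- 16
  vol <- array(0, c(n, n, n)); vol[9, 6, 11] <- 1
  p <- forwardProject(TomoVolume(vol), benchmarkAngles(16))
  rec <- reconstruct(p, reconConfig("sirt", nIter = 100))
  expect_equal(arrayInd(which.max(volumeData(rec)), c(n, n, n)),
               matrix(c(9L, 6L, 11L), 1))
})

test_that("MLEM preserves nonnegativity and its exact-data fixed point", {
  ds <- smallDataset(n = 16, S = 12, jitter = 0, noise = 0)
  rec <- reconstruct(ds$projections, reconConfig("mlem", nIter = 30))
  expect_true(all(volumeData(rec) >= 0))

  # constant volume: W f as data makes the update ratio exactly 1
  n <- 12
  fconst <- TomoVolume(array(0.7, c(n, n, n)))
  ang <- benchmarkAngles(10)
  p <- forwardProject(fconst, ang)
  f1 <- mlemUpdate(fconst, p)
  supported <- volumeData(backProject(
    ProjectionStack(array(1, dim(projData(p))), ang))) > 1e-8
  expect_lt(max(abs((volumeData(f1) - volumeData(fconst))[supported])), 1e-8)
})

test_that("MLEM is monotone in the Poisson log-likelihood on exact data", {
  n <- 24
  # uniform disk (cylinder) phantom
  spec <- PhantomSpec(c(n, n, n),
                      data.frame(ax = (n + 1) / 2, y = (n + 1) / 2,
                                 x = (n + 1) / 2, radius = 8, density = 1))
  vol <- makePhantom(spec)
  ang <- benchmarkAngles(20)
  p <- forwardProject(vol, ang)
  meas <- projData(p)
  f <- TomoVolume(array(1, c(n, n, n)))
  ll <- numeric(100)
  for (k in 1:100) {
    f <- mlemUpdate(f, p)
    wf <- pmax(projData(forwardProject(f, ang)), 1e-12)
    ll[k] <- sum(meas * log(wf) - wf)
  }
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-100])))
})

test_that("MLEM clips negative measurements with a logged count", {
  ds <- smallDataset(n = 16, S = 8, jitter = 0, noise = 0)
  img <- projData(ds$projections)
  img[1, 1, 1] <- -5
  p <- ProjectionStack(img, tiltAngles(ds$projections))
  expect_message(reconstruct(p, reconConfig("mlem", nIter = 1)),
                 "clipping 1 negative")
})

test_that("FBP recovers the density of a sphere under dense angles", {
  n <- 48
  spec <- PhantomSpec(c(n, n, n),
                      data.frame(ax = n / 2, y = n / 2, x = n / 2,
                                 radius = 12, density = 1))
  vol <- makePhantom(spec)
  rec <- fbp(forwardProject(vol, benchmarkAngles(720)))
  inside <- volumeData(vol) > 0
  expect_lt(abs(mean(volumeData(rec)[inside]) - 1), 0.05)

  z <- fbp(ProjectionStack(array(0, c(8, 8, 4)), c(0, 45, 90, 135)))
  expect_true(all(volumeData(z) == 0))

  expect_error(fbp(ProjectionStack(array(1, c(8, 8, 1)), 0)),
               "at least 2 angles")
})

test_that("reconstruct dispatches algorithm and initialization correctly", {
  ds <- smallDataset(n = 16, S = 8, jitter = 0, noise = 0)
  p <- ds$projections

  one <- reconstruct(p, reconConfig("sirt", nIter = 1))
  manual <- sirtUpdate(TomoVolume(array(0, c(16, 16, 16))), p)
  expect_equal(volumeData(one), volumeData(manual))

  # MLEM null init is strictly positive (ones), so one update is nonzero
  m1 <- reconstruct(p, reconConfig("mlem", nIter = 1))
  expect_gt(max(volumeData(m1)), 0)

  # FBP-initialized SIRT differs from null-initialized after one update
  s1 <- reconstruct(p, reconConfig("sirt", nIter = 1, init = "fbp"))
  expect_gt(max(abs(volumeData(s1) - volumeData(one))), 1e-6)

  expect_error(reconConfig("gridrec"), "arg")
  expect_error(reconConfig("sirt", nIter = 0), "nIter")
  expect_error(reconConfig("mlem", epsilon = 0), "epsilon")
})
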