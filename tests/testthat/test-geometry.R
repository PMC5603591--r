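test_that("central ray through a centered sphere integrates to its diameter", {
  n <- 64; r <- 20
  cen <- (n + 1) / 2  # voxel-centre coordinates are 1-based
  spec <- PhantomSpec(c(n, n, n),
                      data.frame(ax = cen, y = cen, x = cen,
                                 radius = r, density = 1))
  p <- forwardProject(makePhantom(spec), c(0, 45, 90))
  img <- projData(p)
  # central detector column at the central axial row, every angle
  for (i in 1:3) {
    central <- img[n / 2, n / 2, i]
    expect_lt(abs(central - 2 * r), 1)  # one-voxel discretization tolerance
  }
})

test_that("forward projection of a zero volume is zero and linear", {
  ang <- c(0, 30, 77)
  z <- forwardProject(TomoVolume(array(0, c(8, 8, 8))), ang)
  expect_true(all(projData(z) == 0))

  set.seed(5)
  f1 <- array(rnorm(12^3), c(12, 12, 12))
  f2 <- array(rnorm(12^3), c(12, 12, 12))
  a <- 2.5; b <- -0.7
  lhs <- projData(forwardProject(TomoVolume(a * f1 + b * f2), ang))
  rhs <- a * projData(forwardProject(TomoVolume(f1), ang)) +
         b * projData(forwardProject(TomoVolume(f2), ang))
  expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(rhs)))
})

test_that("projections at theta and theta+180 are column mirrors", {
  n <- 32
  set.seed(9)
  # smooth random volume: heavy Fourier-domain low-pass of white noise
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  k2 <- outer(k^2, rep(1, n)) + outer(rep(1, n), k^2)
  vol <- array(0, c(n, n, n))
  for (a in seq_len(n)) {
    w <- matrix(rnorm(n^2), n, n)
    vol[a, , ] <- Re(fft(fft(w) * exp(-k2 / 18), inverse = TRUE)) / n^2
  }
  thetas <- c(10, 57)
  p1 <- projData(forwardProject(TomoVolume(vol), thetas))
  p2 <- projData(forwardProject(TomoVolume(vol), thetas + 180))
  for (i in seq_along(thetas)) {
    mirrored <- p2[, n:1, i]
    expect_lt(max(abs(p1[, , i] - mirrored)),
              0.02 * max(abs(p1[, , i])))  # interpolation tolerance
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(11)
  n <- 16; ang <- benchmarkAngles(8)
  f <- array(rnorm(n^3), c(n, n, n))
  q <- array(rnorm(n * n * 8), c(n, n, 8))
  wf <- projData(forwardProject(TomoVolume(f), ang))
  wtq <- volumeData(backProject(ProjectionStack(q, ang)))
  ip1 <- sum(wf * q)
  ip2 <- sum(f * wtq)
  expect_lt(abs(ip1 - ip2) / abs(ip1), 1e-5)
})

test_that("back projection of zero is zero; single pixel gives a streak", {
  ang <- c(0, 90)
  z <- backProject(ProjectionStack(array(0, c(6, 6, 2)), ang))
  expect_true(all(volumeData(z) == 0))

  # angle 0: a single detector pixel (row a, column t) spreads uniformly
  # along the in-plane column x = t
  n <- 8
  q <- array(0, c(n, n, 1))
  q[3, 5, 1] <- 1
  b <- volumeData(backProject(ProjectionStack(q, 0)))
  expect_equal(b[3, , 5], rep(1, n))
  b[3, , 5] <- 0
  expect_true(all(b == 0))
})

test_that("axial slices are decoupled through the projector", {
  set.seed(3)
  n <- 16; ang <- c(20, 110)
  vol <- array(rnorm(n^3), c(n, n, n))
  p0 <- projData(forwardProject(TomoVolume(vol), ang))
  vol2 <- vol
  vol2[5, , ] <- vol2[5, , ] + matrix(rnorm(n^2), n, n)
  p1 <- projData(forwardProject(TomoVolume(vol2), ang))
  diff <- abs(p1 - p0)
  expect_gt(max(diff[5, , ]), 0)
  diff[5, , ] <- 0
  expect_equal(max(diff), 0)
})

test_that("non-finite volumes are rejected naming the offending slice", {
  arr <- array(1, c(4, 4, 4))
  vol <- TomoVolume(arr)
  vol@data[2, 1, 1] <- NaN  # bypasses constructor validity
  expect_error(forwardProject(vol, c(0, 90)), "slice\\(s\\): 2")
})

test_that("translateImage: identity, integer round-trip, linearity", {
  img <- smoothTestImage(32)
  expect_identical(translateImage(img, 0, 0), img)

  shifted <- translateImage(img, 3, -5)
  back <- translateImage(shifted, -3, 5)
  interior <- back[6:27, 4:29]
  expect_equal(interior, img[6:27, 4:29], tolerance = 1e-12)

  # linear operator: T(a f + b g) = a T f + b T g
  g <- smoothTestImage(32, sigma = 3)
  lhs <- translateImage(2 * img - 3 * g, 1.3, -0.4)
  rhs <- 2 * translateImage(img, 1.3, -0.4) - 3 * translateImage(g, 1.3, -0.4)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(translateImage(img, NaN, 0), "dh")
})

test_that("sub-pixel translation agrees with the Fourier-shift oracle", {
  img <- smoothTestImage(48)
  got <- translateImage(img, 0.5, 0.5)
  oracle <- fourierShift(img, 0.5, 0.5)
  interior <- 9:40
  err <- max(abs(got[interior, interior] - oracle[interior, interior]))
  expect_lt(err, 0.01 * max(abs(img)))
})

test_that("applyShifts matches per-image translation and validates input", {
  ds <- smallDataset(n = 16, S = 4, jitter = 0)
  p <- ds$projections
  zero <- ShiftSet(rep(0, 4), rep(0, 4))
  expect_equal(projData(applyShifts(p, zero)), projData(p))

  s <- ShiftSet(c(2, -1, 0, 3), c(1, 0, -2, 1))
  shifted <- applyShifts(p, s)
  for (i in 1:4)
    expect_equal(projData(shifted)[, , i],
                 translateImage(projData(p)[, , i], shiftH(s)[i],
                                shiftV(s)[i]))
  # integer shifts round-trip on interior pixels
  back <- applyShifts(shifted, ShiftSet(-shiftH(s), -shiftV(s)))
  expect_equal(projData(back)[5:12, 5:12, ], projData(p)[5:12, 5:12, ],
               tolerance = 1e-12)

  expect_error(applyShifts(p, ShiftSet(1, 1)), "4 projections")
})

test_that("integer translation with zero fill loses only boundary intensity", {
  img <- matrix(1, 10, 10)
  shifted <- translateImage(img, 3, 0)
  # content moved right by 3: three empty columns, total reduced accordingly
  expect_equal(sum(shifted), sum(img) - 3 * 10)
  expect_true(all(shifted[, 1:3] == 0))
})
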