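# Alignment driver behaviour on the reduced benchmark. These use small
# grids (32^3, 24 angles) so the whole file stays fast; the full-scale
# behaviour is exercised in test-acceptance.R.

test_that("already-aligned data stays put: cumulative shifts < 0.5 px", {
  ds <- smallDataset(n = 32, S = 24, jitter = 0, noise = 0)
  cfg <- alignmentConfig(reconConfig("sirt"), registrationConfig(),
                         "joint", totalIters = 15)
  res <- alignJoint(ds$projections, cfg)
  for (s in shiftHistory(res)) {
    expect_lt(max(abs(shiftH(s))), 0.5)
    expect_lt(max(abs(shiftV(s))), 0.5)
  }
})

test_that("sequential with inner=1 reproduces the joint driver exactly", {
  ds <- smallDataset(n = 32, S = 24, jitter = 3.2, noise = 0)
  N <- 8
  cfgJ <- alignmentConfig(reconConfig("sirt"), registrationConfig(),
                          "joint", totalIters = N)
  cfgS <- alignmentConfig(reconConfig("sirt"), registrationConfig(),
                          "sequential", innerIters = 1, outerIters = N)
  resJ <- alignJoint(ds$projections, cfgJ, truth = list(shifts = ds$shifts))
  resS <- alignSequential(ds$projections, cfgS,
                          truth = list(shifts = ds$shifts))
  expect_identical(shiftH(correctionShifts(resJ)),
                   shiftH(correctionShifts(resS)))
  expect_identical(shiftV(correctionShifts(resJ)),
                   shiftV(correctionShifts(resS)))
  expect_identical(volumeData(alignedVolume(resJ)),
                   volumeData(alignedVolume(resS)))
  tj <- convergenceTrace(resJ); ts <- convergenceTrace(resS)
  expect_equal(tj$shiftMseNorm, ts$shiftMseNorm)
})

test_that("one outer loop equals plain reconstruction plus one registration", {
  ds <- smallDataset(n = 32, S = 24, jitter = 3.2, noise = 0)
  cfg <- alignmentConfig(reconConfig("sirt"), registrationConfig(),
                         "sequential", innerIters = 10, outerIters = 1,
                         anchorShifts = FALSE)
  res <- alignSequential(ds$projections, cfg)
  rec <- reconstruct(ds$projections, reconConfig("sirt", nIter = 10))
  reproj <- forwardProject(rec, tiltAngles(ds$projections))
  d <- registerStack(ds$projections, reproj)
  expect_equal(shiftH(correctionShifts(res)), shiftH(d))
  expect_equal(shiftV(correctionShifts(res)), shiftV(d))
  expect_equal(res@nReconUpdates, 10L)
  expect_equal(res@nRegistrations, 1L)
})

test_that("operation counters embody the O(N) vs O(NM) schedules", {
  ds <- smallDataset(n = 16, S = 8, jitter = 1.6, noise = 0)
  N <- 6
  resJ <- alignJoint(ds$projections,
                     alignmentConfig(totalIters = N))
  expect_identical(resJ@nReconUpdates, as.integer(N))
  expect_identical(resJ@nRegistrations, as.integer(N))
  expect_identical(nrow(convergenceTrace(resJ)), as.integer(N))

  inner <- 4L; outer <- 3L
  resS <- alignSequential(ds$projections,
                          alignmentConfig(mode = "sequential",
                                          innerIters = inner,
                                          outerIters = outer))
  expect_identical(resS@nReconUpdates, inner * outer)
  expect_identical(resS@nRegistrations, outer)
})

test_that("axial alignment converges faster than transverse", {
  ds <- smallDataset(n = 32, S = 24, jitter = 3.2, noise = 0)
  res <- alignJoint(ds$projections,
                    alignmentConfig(reconConfig("sirt"),
                                    registrationConfig(), "joint",
                                    totalIters = 30),
                    truth = list(shifts = ds$shifts))
  rel <- successiveRelMse(shiftHistory(res))
  tol <- 1e-4
  firstBelow <- function(x) which(!is.na(x) & x <= tol)[1]
  expect_lte(firstBelow(rel$relV), firstBelow(rel$relH))
})

test_that("estimated shifts track the ground truth up to the global gauge", {
  # a global object translation is unidentifiable: remove the projection-
  # consistent component (dx cos + dy sin transverse; constant axial) and
  # the remaining per-projection error must be well sub-pixel
  ds <- smallDataset(n = 32, S = 24, jitter = 3.2, noise = 0)
  res <- alignJoint(ds$projections,
                    alignmentConfig(totalIters = 40),
                    truth = list(shifts = ds$shifts))
  est <- estimatedShifts(res)
  eh <- shiftH(est) - shiftH(ds$shifts)
  ev <- shiftV(est) - shiftV(ds$shifts)
  th <- tiltAngles(ds$projections) * pi / 180
  ehResid <- resid(lm(eh ~ cos(th) + sin(th)))
  evResid <- ev - mean(ev)
  expect_lt(sd(ehResid), 0.15)
  expect_lt(sd(evResid), 0.15)
  # and the absolute errors are bounded by jitter consensus + scatter
  expect_lt(max(abs(eh)), 2)
  expect_lt(max(abs(ev)), 2)
})

test_that("transverse-only mode never touches the axial axis", {
  ds <- smallDataset(n = 16, S = 8, jitter = 1.6, noise = 0)
  res <- alignJoint(ds$projections,
                    alignmentConfig(totalIters = 5, transverseOnly = TRUE))
  expect_identical(shiftV(correctionShifts(res)), rep(0, 8))
})

test_that("the direct Fourier kernel underperforms SIRT in the joint loop", {
  # a ramp-FBP reconstruction inside the joint loop either trips the
  # divergence guard or aligns distinctly worse than SIRT: its streaking
  # artifacts under 60 angles with large jitter inflate the per-projection
  # registration scatter severalfold
  ds <- smallDataset(n = 64, S = 60, jitter = 6.4, noise = 0,
                     seedJitter = 11, seedNoise = 12)
  th <- tiltAngles(ds$projections) * pi / 180
  gaugeFreeScatter <- function(res) {
    eh <- shiftH(estimatedShifts(res)) - shiftH(ds$shifts)
    sd(resid(lm(eh ~ cos(th) + sin(th))))
  }
  cfgF <- alignmentConfig(reconConfig("fbp"), registrationConfig(),
                          "joint", totalIters = 40)
  outcome <- tryCatch(
    alignJoint(ds$projections, cfgF, truth = list(shifts = ds$shifts)),
    tomojointDivergence = function(e) e)
  if (inherits(outcome, "tomojointDivergence")) {
    expect_match(conditionMessage(outcome), "field")
  } else {
    resS <- alignJoint(ds$projections,
                       alignmentConfig(totalIters = 40),
                       truth = list(shifts = ds$shifts))
    expect_gt(gaugeFreeScatter(outcome), 2 * gaugeFreeScatter(resS))
  }
})

test_that("early stopping on the shift-change tolerance truncates the trace", {
  ds <- smallDataset(n = 32, S = 24, jitter = 3.2, noise = 0)
  res <- alignJoint(ds$projections,
                    alignmentConfig(totalIters = 50, stopTol = 1e-3))
  expect_lt(res@nReconUpdates, 50L)
  expect_identical(nrow(convergenceTrace(res)), res@nReconUpdates)
})
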