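# Reconstruction kernels used inside the alignment loops: SIRT, MLEM and
# ramp-filtered backprojection.

#' Reconstruction configuration
#'
#' @param algorithm \code{"sirt"} (additive, row/column-normalized
#'   simultaneous update), \code{"mlem"} (multiplicative
#'   expectation-maximization update, nonnegativity-preserving) or
#'   \code{"fbp"} (direct ramp-filtered backprojection, non-iterative).
#' @param nIter number of update iterations (ignored by fbp).
#' @param relaxation SIRT relaxation factor lambda (default 1).
#' @param epsilon positivity floor guarding zero forward-projection rays in
#'   the MLEM ratio.
#' @param filter FBP frequency filter; only \code{"ramp"} is provided.
#' @param init initial object estimate: \code{"null"} (zeros for SIRT,
#'   ones for MLEM — a multiplicative update cannot leave zero),
#'   \code{"fbp"} (filtered backprojection of the data) or \code{"volume"}
#'   (a user-supplied [TomoVolume-class] in \code{initVolume}).
#' @param initVolume starting volume when \code{init = "volume"}.
#' @return A classed list.
#' @examples
#' reconConfig("sirt", nIter = 50)
#' @export
reconConfig <- function(algorithm = c("sirt", "mlem", "fbp"), nIter = 1,
                        relaxation = 1, epsilon = 1e-12,
                        filter = "ramp",
                        init = c("null", "fbp", "volume"),
                        initVolume = NULL) {
  algorithm <- match.arg(algorithm)
  init <- match.arg(init)
  filter <- match.arg(filter)
  if (nIter < 1) stop("'nIter' must be >= 1")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (init == "volume" && !is(initVolume, "TomoVolume"))
    stop("init = 'volume' requires a TomoVolume in 'initVolume'")
  structure(list(algorithm = algorithm, nIter = as.integer(nIter),
                 relaxation = relaxation, epsilon = epsilon,
                 filter = filter, init = init, initVolume = initVolume),
            class = "ReconConfig")
}

# Discrete ramp (Ram-Lak) frequency response of length n: the DFT of the
# exact band-limited spatial ramp kernel h(0) = 1/4, h(odd k) =
# -1/(pi k)^2, h(even k) = 0. Using the DFT of the spatial kernel instead
# of |k| directly avoids the DC underestimation of the naive sampled ramp.
.rampFilter <- function(n) {
  h <- numeric(n)
  h[1L] <- 0.25
  odd <- seq(2L, n, by = 2L)                 # 1-based positions of odd lags
  lag <- pmin(odd - 1L, n - (odd - 1L))      # circular symmetric lag
  h[odd] <- -1 / (pi * lag)^2
  2 * Re(fft(h))
}

# Row (ray) and column (voxel) sums of the projector, i.e. W 1 and W^T 1,
# used as the SIRT/MLEM normalizations. Cached by the alignment drivers.
.projNorms <- function(volDim, angles) {
  ones <- array(1, volDim)
  raySum <- .cpp_forward_project(ones, volDim, angles * pi / 180)
  pdim <- dim(raySum)
  onesP <- array(1, pdim)
  voxSum <- .cpp_back_project(onesP, pdim, angles * pi / 180,
                              as.integer(volDim))
  tiny <- 1e-8
  list(raySum = raySum, voxSum = voxSum,
       rayOk = raySum > tiny, voxOk = voxSum > tiny)
}

#' One SIRT update
#'
#' The simultaneous iterative reconstruction technique step
#' \deqn{f \leftarrow f + \lambda \, C \, W^T R \, (p - W f)}
#' with \eqn{R = \mathrm{diag}(1 / W\mathbf{1})} (ray-length
#' normalization) and \eqn{C = \mathrm{diag}(1 / W^T\mathbf{1})}
#' (voxel-coverage normalization); rays and voxels with empty support are
#' left untouched. On consistent (noise-free) data the residual
#' \eqn{\|p - W f\|} decreases monotonically.
#'
#' @param f current [TomoVolume-class] estimate.
#' @param p measured [ProjectionStack-class].
#' @param cfg a [reconConfig()] (uses \code{relaxation}).
#' @param norms precomputed normalizations from repeated calls on the same
#'   geometry (internal caching by the drivers); recomputed when NULL.
#' @param wf optional precomputed forward projection of \code{f}
#'   (a [ProjectionStack-class] or bare array), to avoid recomputing it.
#' @return Updated [TomoVolume-class].
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(16), benchmarkAngles(12),
#'                       jitterModel(0, seed = 1), noiseModel(0, seed = 2))
#' f1 <- sirtUpdate(TomoVolume(array(0, c(16, 16, 16))), ds$projections)
#' @export
sirtUpdate <- function(f, p, cfg = reconConfig("sirt"), norms = NULL,
                       wf = NULL) {
  stopifnot(is(f, "TomoVolume"), is(p, "ProjectionStack"))
  volDim <- dim(f@data)
  pd <- dim(p@images)
  if (volDim[1L] != pd[1L] || volDim[3L] != pd[2L])
    stop("volume grid incompatible with projection stack")
  if (is.null(norms)) norms <- .projNorms(volDim, p@angles)
  if (is.null(wf)) wf <- .cpp_forward_project(f@data, volDim,
                                              p@angles * pi / 180)
  if (is(wf, "ProjectionStack")) wf <- wf@images
  resid <- p@images - wf
  resid[norms$rayOk] <- resid[norms$rayOk] / norms$raySum[norms$rayOk]
  resid[!norms$rayOk] <- 0
  corr <- .cpp_back_project(resid, pd, p@angles * pi / 180,
                            as.integer(volDim))
  corr[norms$voxOk] <- corr[norms$voxOk] / norms$voxSum[norms$voxOk]
  corr[!norms$voxOk] <- 0
  TomoVolume(f@data + cfg$relaxation * corr, f@voxelSize)
}

#' One MLEM update
#'
#' The maximum-likelihood expectation-maximization step
#' \deqn{f \leftarrow f \cdot \frac{W^T (p / \max(W f, \epsilon))}{W^T \mathbf{1}}}
#' Multiplicative, so nonnegativity is preserved and exact data are a
#' fixed point. Negative measured pixels (possible after additive Gaussian
#' noise) are clipped to zero.
#'
#' @inheritParams sirtUpdate
#' @param cfg a [reconConfig()] (uses \code{epsilon}).
#' @return Updated [TomoVolume-class].
#' @export
mlemUpdate <- function(f, p, cfg = reconConfig("mlem"), norms = NULL,
                       wf = NULL) {
  stopifnot(is(f, "TomoVolume"), is(p, "ProjectionStack"))
  volDim <- dim(f@data)
  pd <- dim(p@images)
  if (volDim[1L] != pd[1L] || volDim[3L] != pd[2L])
    stop("volume grid incompatible with projection stack")
  if (any(f@data < 0))
    stop("MLEM requires a nonnegative current estimate")
  if (is.null(norms)) norms <- .projNorms(volDim, p@angles)
  if (is.null(wf)) wf <- .cpp_forward_project(f@data, volDim,
                                              p@angles * pi / 180)
  if (is(wf, "ProjectionStack")) wf <- wf@images
  meas <- p@images
  meas[meas < 0] <- 0
  ratio <- meas / pmax(wf, cfg$epsilon)
  bp <- .cpp_back_project(ratio, pd, p@angles * pi / 180,
                          as.integer(volDim))
  upd <- f@data
  upd[norms$voxOk] <- upd[norms$voxOk] * bp[norms$voxOk] /
    norms$voxSum[norms$voxOk]
  upd[!norms$voxOk] <- 0
  TomoVolume(upd, f@voxelSize)
}

#' Ramp-filtered backprojection (FBP)
#'
#' Direct reconstruction: each projection row is filtered with the ramp
#' \eqn{|k|} in the frequency domain (along the transverse detector axis),
#' the filtered stack is backprojected, and the result is scaled by
#' \eqn{\pi / S}. Deterministic; the representative of the direct
#' Fourier-class methods, which degrade badly under few angles or
#' misalignment.
#'
#' @param p a [ProjectionStack-class] with at least two angles.
#' @param cfg a [reconConfig()] (only \code{filter = "ramp"} supported).
#' @return A [TomoVolume-class].
#' @examples
#' vol <- makePhantom(defaultPhantomSpec(32))
#' rec <- fbp(forwardProject(vol, benchmarkAngles(90)))
#' @export
fbp <- function(p, cfg = reconConfig("fbp")) {
  stopifnot(is(p, "ProjectionStack"))
  pd <- dim(p@images)
  S <- pd[3L]
  if (S < 2L) stop("FBP requires at least 2 angles")
  m2 <- pd[2L]
  filt <- .rampFilter(m2)
  filtered <- p@images
  for (i in seq_len(S)) {
    ft <- mvfft(t(p@images[, , i]))          # fft along detector columns
    filtered[, , i] <- t(Re(mvfft(ft * filt, inverse = TRUE)) / m2)
  }
  bp <- .cpp_back_project(filtered, pd, p@angles * pi / 180,
                          as.integer(c(pd[1L], m2, m2)))
  TomoVolume(bp * pi / (2 * S))
}

#' Run a configured reconstruction
#'
#' Dispatches on \code{cfg$algorithm}: \code{nIter} SIRT or MLEM updates
#' from the configured initialization, or a single FBP pass.
#'
#' @param p a [ProjectionStack-class].
#' @param cfg a [reconConfig()].
#' @return A [TomoVolume-class].
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(16), benchmarkAngles(12),
#'                       jitterModel(0, seed = 1), noiseModel(0, seed = 2))
#' rec <- reconstruct(ds$projections, reconConfig("sirt", nIter = 10))
#' @export
reconstruct <- function(p, cfg = reconConfig()) {
  stopifnot(is(p, "ProjectionStack"), inherits(cfg, "ReconConfig"))
  if (cfg$algorithm == "fbp") return(fbp(p, cfg))
  pd <- dim(p@images)
  volDim <- c(pd[1L], pd[2L], pd[2L])
  f <- .initVolume(cfg, p, volDim)
  norms <- .projNorms(volDim, p@angles)
  if (cfg$algorithm == "mlem") {
    nneg <- sum(p@images < 0)
    if (nneg > 0)
      message(sprintf("MLEM: clipping %d negative pixel(s) to zero", nneg))
  }
  for (k in seq_len(cfg$nIter)) {
    f <- switch(cfg$algorithm,
      sirt = sirtUpdate(f, p, cfg, norms),
      mlem = mlemUpdate(f, p, cfg, norms))
  }
  f
}

.initVolume <- function(cfg, p, volDim) {
  switch(cfg$init,
    null = TomoVolume(array(if (cfg$algorithm == "mlem") 1 else 0, volDim)),
    fbp = {
      f0 <- fbp(p)
      if (cfg$algorithm == "mlem") {
        d <- f0@data
        d[d < cfg$epsilon] <- cfg$epsilon
        f0 <- TomoVolume(d)
      }
      f0
    },
    volume = cfg$initVolume)
}
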