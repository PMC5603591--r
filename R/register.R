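# Sub-pixel rigid-translation registration by phase correlation with
# upsampled-DFT local refinement.

#' Registration configuration
#'
#' @param upsampleFactor integer >= 1; the translation is refined on a
#'   \code{1/upsampleFactor}-pixel grid by a local matrix-multiply DFT
#'   around the integer correlation peak. The default 100 gives a 0.01 px
#'   grid, fine enough for the well-sub-pixel residuals the joint
#'   alignment reaches.
#' @param maxShift optional per-axis clamp in pixels applied to the
#'   returned shifts; NULL disables clamping.
#' @param method \code{"cross"} (default): peak of the FFT cross-power
#'   spectrum without magnitude normalization, i.e. plain cross-correlation
#'   with upsampled-DFT refinement. This is robust when one image is a
#'   blurry early-iteration reprojection whose spectrum has little energy
#'   at high frequencies. \code{"phase"}: fully whitened (unit-magnitude)
#'   cross-power spectrum, giving a sharper, delta-like peak for image
#'   pairs of comparable sharpness, but unreliable when the reference is
#'   strongly low-pass (the whitening lets incoherent high-frequency bins
#'   swamp the peak).
#' @param window \code{"none"} (default) or \code{"hann"} edge apodization
#'   for data with hard frame edges.
#' @return A classed list.
#' @examples
#' registrationConfig(upsampleFactor = 100)
#' @export
registrationConfig <- function(upsampleFactor = 100, maxShift = NULL,
                               method = c("cross", "phase"),
                               window = c("none", "hann")) {
  method <- match.arg(method)
  window <- match.arg(window)
  upsampleFactor <- as.integer(upsampleFactor)
  if (upsampleFactor < 1L) stop("'upsampleFactor' must be >= 1")
  if (!is.null(maxShift)) {
    .assertScalarFinite(maxShift, "maxShift")
    if (maxShift < 0) stop("'maxShift' must be >= 0")
  }
  structure(list(upsampleFactor = upsampleFactor, maxShift = maxShift,
                 method = method, window = window),
            class = "RegistrationConfig")
}

# Signed DFT bin frequencies in natural fft order.
.fftIndex <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Evaluate the inverse-DFT cross-correlation surface of spectrum X on an
# arbitrary real-valued grid (rows x cols) by matrix-multiply DFT.
.upsampledCorr <- function(X, rows, cols) {
  m1 <- nrow(X); m2 <- ncol(X)
  kr <- .fftIndex(m1); kc <- .fftIndex(m2)
  Er <- exp(2i * pi * outer(rows, kr) / m1)   # |rows| x m1
  Ec <- exp(2i * pi * outer(cols, kc) / m2)   # |cols| x m2
  Re(Er %*% X %*% t(Ec))
}

#' Sub-pixel translation between two images
#'
#' Estimates the translation \code{(dh, dv)} such that
#' \code{translateImage(mov, dh, dv)} best matches \code{ref}, from the
#' peak of the inverse-transformed cross-power spectrum (normalized to
#' unit magnitude only for \code{method = "phase"}). The
#' integer peak is refined on a \code{1/upsampleFactor}-pixel grid by
#' evaluating the correlation surface in a ±0.75 px neighbourhood with a
#' local matrix-multiply DFT. Antisymmetric: swapping the arguments
#' negates the result to within the grid precision.
#'
#' @param ref reference image (matrix).
#' @param mov moving image (matrix, same shape).
#' @param cfg a [registrationConfig()].
#' @return Named numeric vector \code{c(dh = , dv = )} in pixels.
#' @examples
#' img <- volumeData(makePhantom(defaultPhantomSpec(32)))[16, , ]
#' phaseCorrelate(img, translateImage(img, 2, -1))  # about (-2, 1)
#' @export
phaseCorrelate <- function(ref, mov, cfg = registrationConfig()) {
  if (!is.matrix(ref) || !is.matrix(mov) || !all(dim(ref) == dim(mov)))
    stop("'ref' and 'mov' must be matrices of equal shape")
  if (sd(ref) == 0 || sd(mov) == 0)
    stop("cannot register constant images (zero spectrum)")
  if (cfg$window == "hann") {
    m1 <- nrow(ref); m2 <- ncol(ref)
    w <- outer(0.5 - 0.5 * cos(2 * pi * seq_len(m1) / (m1 + 1)),
               0.5 - 0.5 * cos(2 * pi * seq_len(m2) / (m2 + 1)))
    ref <- ref * w; mov <- mov * w
  }
  m1 <- nrow(ref); m2 <- ncol(ref)
  X <- fft(ref) * Conj(fft(mov))
  if (cfg$method == "phase") {
    mag <- Mod(X)
    X <- X / pmax(mag, .Machine$double.eps * max(mag))
  }
  cc <- Re(fft(X, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L   # 0-based
  dv <- if (pk[1L] > m1 / 2) pk[1L] - m1 else pk[1L]
  dh <- if (pk[2L] > m2 / 2) pk[2L] - m2 else pk[2L]
  if (cfg$upsampleFactor > 1L) {
    us <- cfg$upsampleFactor
    half <- ceiling(1.5 * us / 2)
    rows <- dv + (-half:half) / us
    cols <- dh + (-half:half) / us
    surf <- .upsampledCorr(X, rows, cols)
    pk2 <- arrayInd(which.max(surf), dim(surf))
    dv <- rows[pk2[1L]]
    dh <- cols[pk2[2L]]
  }
  if (!is.null(cfg$maxShift)) {
    dh <- max(min(dh, cfg$maxShift), -cfg$maxShift)
    dv <- max(min(dv, cfg$maxShift), -cfg$maxShift)
  }
  c(dh = as.numeric(dh), dv = as.numeric(dv))
}

#' Register a measured stack against its reprojection
#'
#' Runs [phaseCorrelate()] per projection with the reprojection as the
#' fixed reference and the measured image as the moving one. The returned
#' [ShiftSet-class] is the translation to apply to each measured image to
#' bring it onto its reprojection (the correction convention used by the
#' alignment drivers).
#'
#' @param measured measured [ProjectionStack-class] (moving).
#' @param reprojected reprojected [ProjectionStack-class] (reference),
#'   same shape and S.
#' @param cfg a [registrationConfig()].
#' @return A [ShiftSet-class] of per-projection corrections.
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(32), benchmarkAngles(12),
#'                       jitterModel(2, seed = 1), noiseModel(0, seed = 2))
#' registerStack(ds$projections, ds$clean)
#' @export
registerStack <- function(measured, reprojected,
                          cfg = registrationConfig()) {
  stopifnot(is(measured, "ProjectionStack"),
            is(reprojected, "ProjectionStack"))
  if (!all(dim(measured@images) == dim(reprojected@images)))
    stop("'measured' and 'reprojected' stacks must have identical shape")
  S <- dim(measured@images)[3L]
  h <- v <- numeric(S)
  for (i in seq_len(S)) {
    d <- phaseCorrelate(reprojected@images[, , i], measured@images[, , i],
                        cfg)
    h[i] <- d[["dh"]]
    v[i] <- d[["dv"]]
  }
  ShiftSet(h, v)
}
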