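# Convergence and quality metrics. All pure functions.

#' Successive relative MSE of a sequence of shift estimates
#'
#' For consecutive estimates \eqn{x_{k-1}, x_k} the per-axis relative MSE
#' is \eqn{\|x_k - x_{k-1}\|^2 / \|x_{k-1}\|^2} (normalized by the
#' previous iterate). A zero-norm previous iterate yields NA for that
#' step rather than an error.
#'
#' @param shiftList list of [ShiftSet-class] estimates (>= 2), e.g.
#'   [shiftHistory()] of an [AlignmentResult-class].
#' @return data.frame with columns \code{step} (2..K), \code{relH},
#'   \code{relV}.
#' @examples
#' successiveRelMse(list(ShiftSet(1, 0), ShiftSet(1.1, 0),
#'                       ShiftSet(1.1, 0)))
#' @export
successiveRelMse <- function(shiftList) {
  if (!is.list(shiftList) || length(shiftList) < 2L)
    stop("need a list of at least two ShiftSet estimates")
  K <- length(shiftList)
  relH <- relV <- rep(NA_real_, K - 1L)
  for (k in 2:K) {
    prev <- shiftList[[k - 1L]]; cur <- shiftList[[k]]
    ph2 <- sum(prev@h^2); pv2 <- sum(prev@v^2)
    relH[k - 1L] <- if (ph2 > 0) sum((cur@h - prev@h)^2) / ph2 else NA_real_
    relV[k - 1L] <- if (pv2 > 0) sum((cur@v - prev@v)^2) / pv2 else NA_real_
  }
  data.frame(step = 2:K, relH = relH, relV = relV)
}

#' Mean squared error between two volumes
#'
#' Mean of squared voxel differences on the raw grid. Optionally a
#' least-squares intensity scale is fitted to the reconstruction first
#' (iterative reconstructions can differ from truth by a global scale);
#' off by default.
#'
#' @param recon reconstructed [TomoVolume-class].
#' @param truth ground-truth [TomoVolume-class] of identical shape.
#' @param fitScale fit a least-squares global intensity scale before
#'   computing the MSE.
#' @return Scalar MSE.
#' @examples
#' v <- makePhantom(defaultPhantomSpec(16))
#' objectMse(v, v)  # 0
#' @export
objectMse <- function(recon, truth, fitScale = FALSE) {
  stopifnot(is(recon, "TomoVolume"), is(truth, "TomoVolume"))
  if (!all(dim(recon@data) == dim(truth@data)))
    stop("volume shapes differ")
  r <- recon@data
  if (fitScale) {
    denom <- sum(r^2)
    if (denom > 0) r <- r * (sum(r * truth@data) / denom)
  }
  mean((r - truth@data)^2)
}

#' First iteration at which a trace metric reaches a threshold
#'
#' @param trace a data.frame (e.g. [convergenceTrace()]) with an
#'   \code{iteration} column.
#' @param metric name of the metric column.
#' @param threshold the level to reach (metric <= threshold).
#' @param sustained if TRUE, require the metric to stay at or below the
#'   threshold for all subsequent recorded values (a plateau, robust to
#'   transient spikes); if FALSE (default) the first crossing counts.
#' @return The iteration index, or NA if the threshold is never reached.
#' @examples
#' tr <- data.frame(iteration = 1:5, err = c(4, 2, 1, 0.5, 0.2))
#' iterationsToThreshold(tr, "err", 1)  # 3
#' @export
iterationsToThreshold <- function(trace, metric, threshold,
                                  sustained = FALSE) {
  if (!metric %in% names(trace))
    stop(sprintf("no metric column '%s' in trace", metric))
  vals <- trace[[metric]]
  ok <- !is.na(vals) & vals <= threshold
  if (sustained) {
    known <- !is.na(vals)
    # below threshold at every later recorded point as well
    failAfter <- rev(cumsum(rev(known & !ok)))
    ok <- ok & failAfter == 0
  }
  idx <- which(ok)
  if (!length(idx)) return(NA_integer_)
  as.integer(trace$iteration[idx[1L]])
}

#' Plot convergence traces
#'
#' Draws the per-axis successive relative MSE of the shift estimates on a
#' log scale against iteration (solid: transverse, dashed: axial), and,
#' when recorded, the object MSE in a second panel. Optionally writes a
#' PNG instead of drawing to the active device.
#'
#' @param result an [AlignmentResult-class].
#' @param file optional PNG path; NULL draws to the current device.
#' @param width,height,res PNG device parameters.
#' @return The trace data.frame used, invisibly.
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(32), benchmarkAngles(20),
#'                       jitterModel(3, seed = 1), noiseModel(0, seed = 2))
#' res <- alignJoint(ds$projections, alignmentConfig(totalIters = 6))
#' plotConvergence(res, file = tempfile(fileext = ".png"))
#' @export
plotConvergence <- function(result, file = NULL, width = 900, height = 450,
                            res = 110) {
  stopifnot(is(result, "AlignmentResult"))
  tr <- convergenceTrace(result)
  reg <- tr[tr$registered & (!is.na(tr$relMseH) | !is.na(tr$relMseV)), ,
            drop = FALSE]
  if (!nrow(reg))
    stop("no registered iterations with convergence metrics to plot")
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  hasObj <- any(!is.na(tr$objectMse))
  if (hasObj) graphics::par(mfrow = c(1, 2))
  eps <- .Machine$double.xmin
  graphics::plot(reg$iteration, pmax(reg$relMseH, eps), type = "l",
                 log = "y", xlab = "iteration",
                 ylab = "successive relative MSE",
                 main = "alignment convergence")
  graphics::lines(reg$iteration, pmax(reg$relMseV, eps), lty = 2)
  graphics::legend("topright", legend = c("transverse", "axial"),
                   lty = c(1, 2), bty = "n")
  if (hasObj) {
    obj <- tr[!is.na(tr$objectMse), ]
    graphics::plot(obj$iteration, obj$objectMse, type = "l", log = "y",
                   xlab = "iteration", ylab = "object MSE",
                   main = "object convergence")
  }
  invisible(tr)
}
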