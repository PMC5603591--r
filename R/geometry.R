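# Parallel-beam projection geometry: the measurement model
#   p_i = T_i(h_i, v_i) W(theta_i) f + e_i
# with W the voxel-driven line-integral operator, W^T its exact matched
# transpose, and T a bilinear real-space translation.

#' Forward projection (the W operator)
#'
#' Computes parallel-beam line integrals of a volume at each tilt angle.
#' The projector is voxel-driven: for every angle, the in-plane grid is
#' sampled on a rotated unit lattice with bilinear interpolation and summed
#' along the ray direction. Axial rows are decoupled: each axial slice of
#' the volume contributes only to the corresponding detector row. The
#' rotation axis passes through the in-plane grid centre, and the detector
#' has as many columns as the volume (\code{m2 = n3}).
#'
#' The operator is linear in the volume, and [backProject()] is its exact
#' matched transpose.
#'
#' @param vol a [TomoVolume-class] (or bare 3D array).
#' @param angles tilt angles in degrees, strictly increasing.
#' @return A [ProjectionStack-class] of \code{n1 x n3 x length(angles)}
#'   line integrals.
#' @examples
#' vol <- makePhantom(defaultPhantomSpec(32))
#' p <- forwardProject(vol, seq(0, 179, by = 6))
#' @seealso [backProject()], [applyShifts()]
#' @export
setGeneric("forwardProject",
           function(vol, angles) standardGeneric("forwardProject"))

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature("TomoVolume", "numeric"),
  function(vol, angles) {
    if (length(angles) < 1L) stop("'angles' must be non-empty")
    d <- vol@data
    if (!all(is.finite(d))) {
      bad <- which(apply(!is.finite(d), 1L, any))
      stop(sprintf("volume contains non-finite values in axial slice(s): %s",
                   paste(bad, collapse = ", ")))
    }
    img <- .cpp_forward_project(d, dim(d), angles * pi / 180)
    ProjectionStack(img, angles)
  })

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature("array", "numeric"),
  function(vol, angles) forwardProject(TomoVolume(vol), angles))

#' Back projection (the W-transpose operator)
#'
#' The exact matched transpose of [forwardProject()] onto a voxel grid:
#' each detector value is spread back along its ray with the same bilinear
#' weights the forward projector used, so that
#' \eqn{\langle Wf, p\rangle = \langle f, W^T p\rangle} holds to machine
#' precision. Used as the adjoint inside the SIRT and MLEM updates.
#'
#' @param p a [ProjectionStack-class].
#' @param volDim target grid \code{c(n1, n2, n3)}; defaults to
#'   \code{c(m1, m2, m2)}. \code{n1} must equal \code{m1} and \code{n3}
#'   must equal \code{m2} (detector columns match in-plane columns).
#' @return A [TomoVolume-class].
#' @examples
#' p <- forwardProject(makePhantom(defaultPhantomSpec(16)), c(0, 90))
#' b <- backProject(p)
#' @export
setGeneric("backProject",
           function(p, volDim = NULL) standardGeneric("backProject"))

#' @rdname backProject
#' @export
setMethod("backProject", "ProjectionStack", function(p, volDim = NULL) {
  d <- dim(p@images)
  if (is.null(volDim)) volDim <- c(d[1L], d[2L], d[2L])
  volDim <- as.integer(volDim)
  if (length(volDim) != 3L || volDim[1L] != d[1L] || volDim[3L] != d[2L])
    stop(sprintf(
      "volume grid %s incompatible with %d x %d detector (need n1 = m1, n3 = m2)",
      paste(volDim, collapse = " x "), d[1L], d[2L]))
  v <- .cpp_back_project(p@images, d, p@angles * pi / 180, volDim)
  TomoVolume(v)
})

#' Sub-pixel image translation (the T operator)
#'
#' Translates a 2D image by \code{(dh, dv)} pixels with bilinear
#' interpolation: \code{out[r, c] = img[r - dv, c - dh]}. Positive
#' \code{dh} moves content toward increasing column index (transverse),
#' positive \code{dv} toward increasing row index (axial). Pixels sampled
#' outside the frame take \code{fill} (zero by default: measured
#' projections are compactly supported, and wrap-around would inject
#' spurious features at the opposite edge for the large shifts handled
#' here). Integer shifts are exact permutations on interior pixels; the
#' operator is linear in the image.
#'
#' @param img numeric matrix.
#' @param dh transverse shift in pixels.
#' @param dv axial shift in pixels.
#' @param fill value for out-of-frame samples.
#' @return The translated matrix.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 4] <- 1
#' which(translateImage(m, 2, 1) == 1, arr.ind = TRUE)  # row 5, col 6
#' @export
translateImage <- function(img, dh, dv, fill = 0) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a numeric matrix")
  if (!all(is.finite(img))) stop("'img' contains non-finite values")
  .assertScalarFinite(dh, "dh")
  .assertScalarFinite(dv, "dv")
  if (dh == 0 && dv == 0) return(img)
  .cpp_translate(img, dh, dv, fill)
}

#' Translate every projection in a stack
#'
#' Applies [translateImage()] per projection: image \code{i} is shifted by
#' \code{(h[i], v[i])}. This is the block-diagonal translation operator
#' \eqn{T(h, v)} of the measurement model.
#'
#' @param p a [ProjectionStack-class].
#' @param s a [ShiftSet-class] with one \code{(h, v)} pair per projection.
#' @param fill out-of-frame fill value.
#' @return A [ProjectionStack-class] with the same angles.
#' @examples
#' p <- forwardProject(makePhantom(defaultPhantomSpec(16)), c(0, 90))
#' applyShifts(p, ShiftSet(h = c(2, -1), v = c(0, 1)))
#' @export
setGeneric("applyShifts",
           function(p, s, fill = 0) standardGeneric("applyShifts"))

#' @rdname applyShifts
#' @export
setMethod("applyShifts", signature("ProjectionStack", "ShiftSet"),
  function(p, s, fill = 0) {
    S <- dim(p@images)[3L]
    if (length(s@h) != S)
      stop(sprintf("ShiftSet has %d entries for %d projections",
                   length(s@h), S))
    out <- p@images
    for (i in seq_len(S)) {
      if (s@h[i] != 0 || s@v[i] != 0)
        out[, , i] <- .cpp_translate(p@images[, , i], s@h[i], s@v[i], fill)
    }
    ProjectionStack(out, p@angles)
  })
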