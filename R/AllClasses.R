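# Central S4 data containers.
#
# Array layout contract (column-major, R-native):
#   TomoVolume@data       : n1 x n2 x n3  (axial slice, in-plane row y,
#                           in-plane column x); the rotation axis passes
#                           through the in-plane grid centre ((n2-1)/2,
#                           (n3-1)/2 in 0-based coordinates).
#   ProjectionStack@images: m1 x m2 x S   (axial detector row, transverse
#                           detector column, projection index).
# Transverse shift h moves image content toward increasing column index,
# axial shift v toward increasing row index.

#' TomoVolume: a 3D object on a voxel grid
#'
#' Container for the 3D object \eqn{f} being reconstructed, stored as an
#' \code{n1 x n2 x n3} array: \code{n1} axial slices along the rotation
#' axis, each an \code{n2 x n3} in-plane image. The rotation axis passes
#' through the in-plane grid centre.
#'
#' @slot data 3D numeric array of voxel values, all finite.
#' @slot voxelSize informational physical voxel edge length (one unit by
#'   default; the geometry itself works in voxel units).
#'
#' @seealso [TomoVolume()], [forwardProject()], [reconstruct()]
#' @export
setClass("TomoVolume",
  representation(data = "array", voxelSize = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), voxelSize = 1)
)

setValidity("TomoVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("'data' must be a 3D array (axial x row x column)")
  if (any(dim(d) < 1L))
    return("all dimensions must be >= 1")
  if (!all(is.finite(d)))
    return("volume contains non-finite values")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("'voxelSize' must be a single positive number")
  TRUE
})

#' Construct a TomoVolume
#'
#' @param data 3D numeric array (axial slices x rows x columns).
#' @param voxelSize physical voxel edge length (informational).
#' @return A [TomoVolume-class] object.
#' @examples
#' vol <- TomoVolume(array(0, c(8, 8, 8)))
#' dim(volumeData(vol))
#' @export
TomoVolume <- function(data, voxelSize = 1) {
  new("TomoVolume", data = data, voxelSize = voxelSize)
}

#' ProjectionStack: tilt-series projection images
#'
#' A stack of S 2D projection images of \code{m1 x m2} pixels with their
#' tilt angles in degrees. Rows (m1) run along the rotation axis (axial),
#' columns (m2) across it (transverse). Stored as an \code{m1 x m2 x S}
#' array.
#'
#' @slot images 3D numeric array, \code{m1 x m2 x S}.
#' @slot angles numeric vector of S tilt angles in degrees, strictly
#'   increasing.
#' @seealso [ProjectionStack()], [applyShifts()], [registerStack()]
#' @export
setClass("ProjectionStack",
  representation(images = "array", angles = "numeric"),
  prototype(images = array(0, c(1, 1, 1)), angles = 0)
)

setValidity("ProjectionStack", function(object) {
  d <- object@images
  if (length(dim(d)) != 3L)
    return("'images' must be a 3D array (row x column x projection)")
  if (dim(d)[3L] != length(object@angles))
    return(sprintf("number of images (%d) != number of angles (%d)",
                   dim(d)[3L], length(object@angles)))
  if (!all(is.finite(object@angles)))
    return("angles must be finite")
  if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
    return("angles must be strictly increasing")
  if (!all(is.finite(d))) {
    bad <- which(apply(!is.finite(d), 3L, any))
    return(sprintf("non-finite pixels in projection(s): %s",
                   paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a ProjectionStack
#'
#' @param images \code{m1 x m2 x S} numeric array, or a list of S matrices.
#' @param angles S tilt angles in degrees, strictly increasing.
#' @return A [ProjectionStack-class] object.
#' @examples
#' p <- ProjectionStack(array(0, c(4, 4, 3)), angles = c(0, 60, 120))
#' nProjections(p)
#' @export
ProjectionStack <- function(images, angles) {
  if (is.list(images))
    images <- array(unlist(images),
                    c(dim(images[[1L]]), length(images)))
  new("ProjectionStack", images = images, angles = as.numeric(angles))
}

#' ShiftSet: per-projection translation errors
#'
#' Transverse (\code{h}, detector columns) and axial (\code{v}, detector
#' rows) translations in pixels, one pair per projection. Positive values
#' move image content toward increasing column/row index.
#'
#' @slot h numeric vector of transverse shifts (pixels).
#' @slot v numeric vector of axial shifts (pixels).
#' @seealso [ShiftSet()], [sampleShifts()], [shiftResiduals()]
#' @export
setClass("ShiftSet",
  representation(h = "numeric", v = "numeric"),
  prototype(h = numeric(0), v = numeric(0))
)

setValidity("ShiftSet", function(object) {
  if (length(object@h) != length(object@v))
    return("'h' and 'v' must have equal length")
  if (!all(is.finite(object@h)) || !all(is.finite(object@v)))
    return("shifts must be finite")
  TRUE
})

#' Construct a ShiftSet
#'
#' @param h transverse shifts in pixels.
#' @param v axial shifts in pixels (same length as \code{h}).
#' @return A [ShiftSet-class] object.
#' @examples
#' s <- ShiftSet(h = c(1, -2), v = c(0.5, 3))
#' shiftH(s)
#' @export
ShiftSet <- function(h, v) new("ShiftSet", h = as.numeric(h), v = as.numeric(v))

#' PhantomSpec: analytic description of a spherical test object
#'
#' The ground-truth object of the simulation benchmark: a set of spheres
#' (centre, radius, density) on an \code{n1 x n2 x n3} voxel grid. Voxel
#' centres sit at integer coordinates \code{1..n} on each axis (R
#' indexing); overlapping spheres add their densities.
#'
#' @slot gridShape integer vector \code{c(n1, n2, n3)}.
#' @slot spheres data.frame with columns \code{ax, y, x} (centre, voxel
#'   units), \code{radius} (voxels) and \code{density}.
#' @seealso [PhantomSpec()], [defaultPhantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spheres = "data.frame"),
  prototype(gridShape = c(1L, 1L, 1L),
            spheres = data.frame(ax = numeric(0), y = numeric(0),
                                 x = numeric(0), radius = numeric(0),
                                 density = numeric(0)))
)

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("'gridShape' must be three positive integers")
  sp <- object@spheres
  need <- c("ax", "y", "x", "radius", "density")
  if (!all(need %in% names(sp)))
    return(sprintf("'spheres' must have columns: %s",
                   paste(need, collapse = ", ")))
  if (nrow(sp) > 0L && any(sp$radius <= 0))
    return("sphere radii must be > 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param gridShape three integers \code{c(n1, n2, n3)}.
#' @param spheres data.frame with columns \code{ax, y, x, radius, density}.
#'   Spheres whose extent crosses the grid boundary are permitted but
#'   flagged with a warning (their protruding voxels are clipped).
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(c(32, 32, 32),
#'                     data.frame(ax = 16, y = 16, x = 16,
#'                                radius = 8, density = 1))
#' @export
PhantomSpec <- function(gridShape, spheres) {
  obj <- new("PhantomSpec", gridShape = as.integer(gridShape),
             spheres = spheres)
  if (nrow(spheres) > 0L) {
    lo <- pmin(spheres$ax - spheres$radius, spheres$y - spheres$radius,
               spheres$x - spheres$radius)
    hi <- pmax(spheres$ax + spheres$radius - gridShape[1L],
               spheres$y + spheres$radius - gridShape[2L],
               spheres$x + spheres$radius - gridShape[3L])
    clipped <- which(lo < 1 | hi > 0)
    if (length(clipped))
      warning(sprintf("sphere(s) %s extend beyond the grid; voxels clipped",
                      paste(clipped, collapse = ", ")))
  }
  obj
}

#' AlignmentResult: output of the alignment drivers
#'
#' Bundles the reconstructed volume, the cumulative per-projection
#' correction (the translation that, applied to each measured image,
#' aligns it with the reconstruction; the estimated jitter is its
#' negation, see [estimatedShifts()]), a per-reconstruction-iteration
#' convergence trace, the history of shift estimates, and operation
#' counters.
#'
#' @slot volume final [TomoVolume-class] reconstruction.
#' @slot shifts [ShiftSet-class], cumulative correction per projection.
#' @slot trace data.frame with one row per reconstruction update:
#'   \code{iteration}, \code{outer}, \code{registered} (logical),
#'   \code{relMseH}, \code{relMseV} (successive relative MSE of the shift
#'   estimates, NA where no registration happened or no previous estimate
#'   exists), \code{residual} (L2 norm of corrected data minus
#'   reprojection), and, when ground truth is supplied, \code{objectMse},
#'   \code{shiftMseH}, \code{shiftMseV}, \code{shiftMseNorm}.
#' @slot shiftHistory list of [ShiftSet-class] correction estimates, one
#'   per registration pass.
#' @slot nReconUpdates integer, reconstruction updates executed.
#' @slot nRegistrations integer, registration passes executed.
#' @slot config the [alignmentConfig()] list used.
#' @seealso [alignJoint()], [alignSequential()]
#' @export
setClass("AlignmentResult",
  representation(volume = "TomoVolume", shifts = "ShiftSet",
                 trace = "data.frame", shiftHistory = "list",
                 nReconUpdates = "integer", nRegistrations = "integer",
                 config = "list")
)

setValidity("AlignmentResult", function(object) {
  if (nrow(object@trace) != object@nReconUpdates)
    return("trace must have one row per reconstruction update")
  TRUE
})

# ---- accessors ----

#' @describeIn TomoVolume-class voxel array accessor.
#' @param object,x a package object.
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname TomoVolume-class
#' @export
setMethod("volumeData", "TomoVolume", function(object) object@data)

#' @describeIn ProjectionStack-class image array accessor (m1 x m2 x S).
#' @export
setGeneric("projData", function(object) standardGeneric("projData"))
#' @rdname ProjectionStack-class
#' @export
setMethod("projData", "ProjectionStack", function(object) object@images)

#' @describeIn ProjectionStack-class tilt angles in degrees.
#' @export
setGeneric("tiltAngles", function(object) standardGeneric("tiltAngles"))
#' @rdname ProjectionStack-class
#' @export
setMethod("tiltAngles", "ProjectionStack", function(object) object@angles)

#' @describeIn ProjectionStack-class number of projections S.
#' @export
setGeneric("nProjections", function(object) standardGeneric("nProjections"))
#' @rdname ProjectionStack-class
#' @export
setMethod("nProjections", "ProjectionStack",
          function(object) dim(object@images)[3L])
#' @rdname ShiftSet-class
#' @export
setMethod("nProjections", "ShiftSet", function(object) length(object@h))

#' @describeIn ShiftSet-class transverse shifts (pixels).
#' @export
setGeneric("shiftH", function(object) standardGeneric("shiftH"))
#' @rdname ShiftSet-class
#' @export
setMethod("shiftH", "ShiftSet", function(object) object@h)

#' @describeIn ShiftSet-class axial shifts (pixels).
#' @export
setGeneric("shiftV", function(object) standardGeneric("shiftV"))
#' @rdname ShiftSet-class
#' @export
setMethod("shiftV", "ShiftSet", function(object) object@v)

#' @describeIn AlignmentResult-class final reconstructed volume.
#' @export
setGeneric("alignedVolume", function(object) standardGeneric("alignedVolume"))
#' @rdname AlignmentResult-class
#' @export
setMethod("alignedVolume", "AlignmentResult", function(object) object@volume)

#' @describeIn AlignmentResult-class cumulative correction per projection.
#' @export
setGeneric("correctionShifts",
           function(object) standardGeneric("correctionShifts"))
#' @rdname AlignmentResult-class
#' @export
setMethod("correctionShifts", "AlignmentResult",
          function(object) object@shifts)

#' @describeIn AlignmentResult-class estimated translation errors (the
#'   negated cumulative correction), directly comparable to the
#'   ground-truth jitter of [simulateDataset()].
#' @export
setGeneric("estimatedShifts",
           function(object) standardGeneric("estimatedShifts"))
#' @rdname AlignmentResult-class
#' @export
setMethod("estimatedShifts", "AlignmentResult", function(object)
  ShiftSet(-object@shifts@h, -object@shifts@v))

#' @describeIn AlignmentResult-class convergence trace data.frame.
#' @export
setGeneric("convergenceTrace",
           function(object) standardGeneric("convergenceTrace"))
#' @rdname AlignmentResult-class
#' @export
setMethod("convergenceTrace", "AlignmentResult",
          function(object) object@trace)

#' @describeIn AlignmentResult-class per-registration shift estimate
#'   history (list of [ShiftSet-class]).
#' @export
setGeneric("shiftHistory", function(object) standardGeneric("shiftHistory"))
#' @rdname AlignmentResult-class
#' @export
setMethod("shiftHistory", "AlignmentResult",
          function(object) object@shiftHistory)

# ---- show methods ----

setMethod("show", "TomoVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("TomoVolume: %d x %d x %d voxels (axial x row x column)\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  value range: [%.4g, %.4g], voxel size %g\n",
              min(object@data), max(object@data), object@voxelSize))
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("ProjectionStack: %d projections of %d x %d pixels\n",
              d[3L], d[1L], d[2L]))
  cat(sprintf("  tilt angles: %.6g to %.6g deg\n",
              object@angles[1L], object@angles[length(object@angles)]))
})

setMethod("show", "ShiftSet", function(object) {
  cat(sprintf("ShiftSet: %d projections\n", length(object@h)))
  if (length(object@h))
    cat(sprintf("  h in [%.3f, %.3f] px, v in [%.3f, %.3f] px\n",
                min(object@h), max(object@h), min(object@v), max(object@v)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d sphere(s) on a %s grid\n",
              nrow(object@spheres),
              paste(object@gridShape, collapse = " x ")))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult (%s/%s): %d recon updates, %d registrations\n",
              object@config$mode %||% "?",
              object@config$recon$algorithm %||% "?",
              object@nReconUpdates, object@nRegistrations))
  if (length(object@shifts@h))
    cat(sprintf("  final correction: |h| <= %.3f px, |v| <= %.3f px\n",
                max(abs(object@shifts@h)), max(abs(object@shifts@v))))
})
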