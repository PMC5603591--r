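# Simulation benchmark: three-sphere phantom, uniform per-projection
# jitter, additive Gaussian noise.

#' Default three-sphere benchmark phantom
#'
#' The benchmark object: three spheres of unit density with radii 0.30n,
#' 0.15n and 0.06n at distinct off-axis positions on an n-cubed grid
#' (n = 100 by default, giving radii 30, 15 and 6 voxels). Positions and
#' radii scale with \code{n} so the benchmark can be run at reduced grid
#' sizes while preserving relative geometry; every sphere stays inside the
#' reconstructable cylinder even after +/-10\% field-of-view jitter. The
#' smallest sphere is only resolvable once the stack is aligned, which is
#' what makes the benchmark diagnostic.
#'
#' @param n grid edge length in voxels.
#' @return A [PhantomSpec-class].
#' @examples
#' defaultPhantomSpec(64)
#' @export
defaultPhantomSpec <- function(n = 100) {
  n <- as.integer(n)
  spheres <- data.frame(
    ax     = n * c(0.45, 0.30, 0.70),
    y      = n * c(0.40, 0.65, 0.55),
    x      = n * c(0.45, 0.60, 0.30),
    radius = n * c(0.30, 0.15, 0.06),
    density = c(1, 1, 1)
  )
  PhantomSpec(c(n, n, n), spheres)
}

#' Rasterize a PhantomSpec to a volume
#'
#' Each voxel takes the sum of the densities of all spheres whose surface
#' encloses the voxel centre (overlapping spheres add). Deterministic.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [TomoVolume-class].
#' @examples
#' vol <- makePhantom(defaultPhantomSpec(32))
#' range(volumeData(vol))
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  gs <- spec@gridShape
  vol <- array(0, gs)
  sp <- spec@spheres
  if (nrow(sp) == 0L) return(TomoVolume(vol))
  ax <- seq_len(gs[1L]); yy <- seq_len(gs[2L]); xx <- seq_len(gs[3L])
  for (k in seq_len(nrow(sp))) {
    r2 <- sp$radius[k]^2
    da2 <- (ax - sp$ax[k])^2
    dy2 <- (yy - sp$y[k])^2
    dx2 <- (xx - sp$x[k])^2
    # outer sum of squared distances, thresholded against r^2
    inside <- outer(outer(da2, dy2, `+`), dx2, `+`) <= r2
    vol <- vol + sp$density[k] * inside
  }
  TomoVolume(vol)
}

#' Jitter model: uniform per-projection translations
#'
#' Random translation errors emulating rotation-stage runout: independent
#' draws from \code{U(-halfWidth, +halfWidth)} pixels on both axes for
#' every projection.
#'
#' @param halfWidth maximum shift magnitude in pixels (default 10, i.e.
#'   10\% of a 100-pixel field of view).
#' @param seed integer seed for reproducible draws, or NULL.
#' @return A classed list used by [sampleShifts()].
#' @examples
#' jm <- jitterModel(10, seed = 1)
#' @export
jitterModel <- function(halfWidth = 10, seed = NULL) {
  .assertScalarFinite(halfWidth, "halfWidth")
  if (halfWidth < 0) stop("'halfWidth' must be >= 0")
  structure(list(halfWidth = halfWidth, seed = seed),
            class = "JitterModel")
}

#' Noise model: additive Gaussian noise
#'
#' Zero-mean Gaussian noise whose standard deviation is a fraction
#' \code{level} of the maximum value of the whole projection stack (the
#' global maximum, so the noise floor is common to all projections).
#'
#' @param level noise standard deviation as a fraction of the stack
#'   maximum; the benchmark uses 0, 0.05, 0.10, 0.20.
#' @param seed integer seed, or NULL.
#' @return A classed list used by [addNoise()].
#' @examples
#' nm <- noiseModel(0.1, seed = 2)
#' @export
noiseModel <- function(level = 0, seed = NULL) {
  .assertScalarFinite(level, "level")
  if (level < 0) stop("'level' must be >= 0")
  structure(list(kind = "gaussian", level = level, seed = seed),
            class = "NoiseModel")
}

#' Draw ground-truth jitter shifts
#'
#' 2S independent uniform draws on \code{(-halfWidth, +halfWidth)}:
#' transverse first, then axial. Reproducible for a fixed seed.
#'
#' @param S number of projections.
#' @param jm a [jitterModel()].
#' @return A [ShiftSet-class] of length S.
#' @examples
#' s <- sampleShifts(100, jitterModel(10, seed = 1))
#' max(abs(shiftH(s)))  # <= 10
#' @export
sampleShifts <- function(S, jm) {
  stopifnot(inherits(jm, "JitterModel"), S >= 1)
  draws <- .withSeed(jm$seed, runif(2L * S, -jm$halfWidth, jm$halfWidth))
  ShiftSet(h = draws[seq_len(S)], v = draws[S + seq_len(S)])
}

#' Add Gaussian noise to a projection stack
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' \code{level * max(stack)} to every pixel. \code{level = 0} returns the
#' stack unchanged (bit-identical). Reproducible for a fixed seed.
#'
#' @param p a [ProjectionStack-class].
#' @param nm a [noiseModel()].
#' @return A [ProjectionStack-class].
#' @examples
#' p <- forwardProject(makePhantom(defaultPhantomSpec(16)), c(0, 90))
#' addNoise(p, noiseModel(0.05, seed = 2))
#' @export
addNoise <- function(p, nm) {
  stopifnot(is(p, "ProjectionStack"), inherits(nm, "NoiseModel"))
  if (nm$level == 0) return(p)
  sigma <- nm$level * max(p@images)
  noise <- .withSeed(nm$seed, rnorm(length(p@images), 0, sigma))
  ProjectionStack(p@images + array(noise, dim(p@images)), p@angles)
}

#' Uniform tilt angles over the half turn
#'
#' \code{S} angles uniformly spaced on \code{[0, 180)} degrees (half-open:
#' 0 and 180 degrees are redundant in parallel beam).
#'
#' @param S number of angles.
#' @return Numeric vector of degrees.
#' @examples
#' benchmarkAngles(100)[1:3]  # 0, 1.8, 3.6
#' @export
benchmarkAngles <- function(S = 100) seq(0, 180, length.out = S + 1)[seq_len(S)]

#' Simulate a complete benchmark dataset
#'
#' Runs the full measurement pipeline: rasterize the phantom, forward
#' project at the given angles, translate every projection by its
#' ground-truth jitter, then add Gaussian noise. The default arguments
#' reproduce the reference benchmark: a 100-cubed three-sphere phantom,
#' 100 projections uniformly over [0, 180) degrees on a 100 x 100
#' detector, jitter uniform in +/-10 px on both axes.
#'
#' Jitter and noise take separate seeds, so the noise level can be varied
#' while holding the jitter realization fixed.
#'
#' @param spec a [PhantomSpec-class].
#' @param angles tilt angles in degrees.
#' @param jm a [jitterModel()].
#' @param nm a [noiseModel()].
#' @return A list with elements \code{projections} (the misaligned, noisy
#'   [ProjectionStack-class]), \code{shifts} (ground-truth
#'   [ShiftSet-class]), \code{volume} (ground-truth [TomoVolume-class])
#'   and \code{clean} (the aligned, noise-free stack).
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(32), benchmarkAngles(30),
#'                       jitterModel(3, seed = 1), noiseModel(0, seed = 2))
#' @export
simulateDataset <- function(spec = defaultPhantomSpec(),
                            angles = benchmarkAngles(100),
                            jm = jitterModel(10, seed = 1),
                            nm = noiseModel(0, seed = 2)) {
  vol <- makePhantom(spec)
  clean <- forwardProject(vol, angles)
  truth <- sampleShifts(length(angles), jm)
  shifted <- applyShifts(clean, truth)
  noisy <- addNoise(shifted, nm)
  list(projections = noisy, shifts = truth, volume = vol, clean = clean)
}
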