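# Dataset I/O: multi-page 32-bit TIFF for image stacks/volumes (with a
# JSON sidecar recording the affine intensity scale), CSV for angles,
# shifts and traces, JSON for manifests and summaries.

# TIFF stores 32-bit samples normalized to [0,1]; the sidecar
# <path>.meta.json records (lo, hi) so values round-trip to ~1e-8
# relative precision.
.writeTiffPages <- function(pages, path) {
  lo <- min(vapply(pages, min, 0))
  hi <- max(vapply(pages, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  norm <- lapply(pages, function(m) (m - lo) / scale)
  suppressWarnings(
    tiff::writeTIFF(norm, path, bits.per.sample = 32L,
                    compression = "deflate"))
  jsonlite::write_json(list(lo = lo, hi = hi,
                            nrow = nrow(pages[[1L]]),
                            ncol = ncol(pages[[1L]]),
                            pages = length(pages)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.readTiffPages <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- if (meta$hi > meta$lo) meta$hi - meta$lo else 1
  lapply(pages, function(m) m * scale + meta$lo)
}

#' Write / read a projection stack as multi-page TIFF + angles CSV
#'
#' One TIFF page per projection (32-bit samples, deflate-compressed, with
#' a \code{.meta.json} sidecar holding the intensity scale) and a sidecar
#' CSV of tilt angles (columns \code{index, angle_deg}).
#'
#' @param p a [ProjectionStack-class].
#' @param tiffPath output TIFF path.
#' @param anglesPath output angles CSV path; defaults to
#'   \code{<tiffPath dir>/angles.csv}.
#' @return \code{writeProjections}: the TIFF path, invisibly.
#' @examples
#' ds <- simulateDataset(defaultPhantomSpec(16), benchmarkAngles(8),
#'                       jitterModel(0, seed = 1), noiseModel(0, seed = 2))
#' td <- tempfile(); dir.create(td)
#' writeProjections(ds$projections, file.path(td, "data.tiff"))
#' p2 <- readProjections(file.path(td, "data.tiff"))
#' @export
writeProjections <- function(p, tiffPath, anglesPath = NULL) {
  stopifnot(is(p, "ProjectionStack"))
  if (is.null(anglesPath))
    anglesPath <- file.path(dirname(tiffPath), "angles.csv")
  S <- nProjections(p)
  pages <- lapply(seq_len(S), function(i) p@images[, , i])
  .writeTiffPages(pages, tiffPath)
  write.csv(data.frame(index = seq_len(S), angle_deg = p@angles),
            anglesPath, row.names = FALSE)
  invisible(tiffPath)
}

#' @rdname writeProjections
#' @return \code{readProjections}: a [ProjectionStack-class].
#' @export
readProjections <- function(tiffPath, anglesPath = NULL) {
  if (is.null(anglesPath))
    anglesPath <- file.path(dirname(tiffPath), "angles.csv")
  if (!file.exists(anglesPath))
    stop(sprintf("no tilt-angle file at '%s'; supply 'anglesPath'",
                 anglesPath))
  pages <- .readTiffPages(tiffPath)
  ang <- read.csv(anglesPath)
  if (!"angle_deg" %in% names(ang))
    stop("angles CSV must have an 'angle_deg' column")
  if (nrow(ang) != length(pages))
    stop(sprintf("%d TIFF pages but %d angles", length(pages), nrow(ang)))
  ProjectionStack(pages, ang$angle_deg)
}

#' Write / read a volume as multi-page TIFF
#'
#' One page per axial slice.
#'
#' @param vol a [TomoVolume-class].
#' @param path TIFF path.
#' @return \code{writeVolume}: the path invisibly; \code{readVolume}: a
#'   [TomoVolume-class].
#' @examples
#' f <- tempfile(fileext = ".tiff")
#' writeVolume(makePhantom(defaultPhantomSpec(16)), f)
#' v <- readVolume(f)
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "TomoVolume"))
  n1 <- dim(vol@data)[1L]
  pages <- lapply(seq_len(n1), function(a) vol@data[a, , ])
  .writeTiffPages(pages, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  pages <- .readTiffPages(path)
  n1 <- length(pages)
  arr <- array(0, c(n1, dim(pages[[1L]])))
  for (a in seq_len(n1)) arr[a, , ] <- pages[[a]]
  TomoVolume(arr)
}

#' Write / read per-projection shifts as CSV
#'
#' Columns: \code{index, angle_deg, h_px, v_px}.
#'
#' @param s a [ShiftSet-class].
#' @param path CSV path.
#' @param angles optional tilt angles (degrees) for the \code{angle_deg}
#'   column; NA when omitted.
#' @return \code{writeShifts}: the path invisibly; \code{readShifts}: a
#'   [ShiftSet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeShifts(ShiftSet(c(1, 2), c(0, -1)), f, angles = c(0, 90))
#' readShifts(f)
#' @export
writeShifts <- function(s, path, angles = NULL) {
  stopifnot(is(s, "ShiftSet"))
  S <- length(s@h)
  write.csv(data.frame(index = seq_len(S),
                       angle_deg = if (is.null(angles)) NA_real_ else angles,
                       h_px = s@h, v_px = s@v),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeShifts
#' @export
readShifts <- function(path) {
  df <- read.csv(path)
  if (!all(c("h_px", "v_px") %in% names(df)))
    stop("shifts CSV must have 'h_px' and 'v_px' columns")
  ShiftSet(df$h_px, df$v_px)
}
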