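#' Parallel-beam scan geometry
#'
#' Bundles the discretisation of the ray transform: projection angles, the
#' detector array, and the image grid. All lengths are in millimetres.
#'
#' @param n_views number of projection angles.
#' @param n_detectors number of detector cells.
#' @param image_rows,image_cols image grid size (pixels).
#' @param pixel_size pixel edge length in mm.
#' @param detector_spacing detector cell pitch in mm.
#' @param angles view angles in radians, strictly increasing over `[0, pi)`.
#'   Defaults to `n_views` equispaced angles starting at 0.
#' @return an object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_views, n_detectors, image_rows, image_cols,
                          pixel_size = 1, detector_spacing = pixel_size,
                          angles = seq(0, pi, length.out = n_views + 1L)[seq_len(n_views)]) {
  stopifnot(n_views >= 1, n_detectors >= 1, image_rows >= 1, image_cols >= 1)
  if (pixel_size <= 0 || detector_spacing <= 0)
    stop("pixel_size and detector_spacing must be positive", call. = FALSE)
  angles <- as.numeric(angles)
  if (length(angles) != n_views) stop("length(angles) must equal n_views", call. = FALSE)
  if (n_views > 1 && any(diff(angles) <= 0))
    stop("angles must be strictly increasing", call. = FALSE)
  structure(
    list(n_views = as.integer(n_views), angles = angles,
         n_detectors = as.integer(n_detectors),
         detector_spacing = detector_spacing,
         image_rows = as.integer(image_rows), image_cols = as.integer(image_cols),
         pixel_size = pixel_size),
    class = "scan_geometry")
}

#' Single-channel sinogram
#'
#' A grid of line integrals (log-transformed, unitless values times mm) of
#' size `n_views x n_detectors`, tied to the geometry that produced it.
#'
#' @param values numeric matrix, `n_views x n_detectors`.
#' @param geometry a [scan_geometry()].
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("sinogram values must be finite", call. = FALSE)
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_detectors)
    stop(sprintf("sinogram is %d x %d but geometry expects %d x %d",
                 nrow(values), ncol(values), geometry$n_views, geometry$n_detectors),
         call. = FALSE)
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' Multi-channel sinogram set
#'
#' The volumetric spectral projection: one sinogram per energy bin, all
#' sharing one scan geometry.
#'
#' @param channels list of [sinogram()] objects.
#' @param channel_windows optional labels for the energy intervals, e.g. an
#'   [energy_windows()] object or a character vector.
#' @return an object of class `sinogram_set`.
#' @export
sinogram_set <- function(channels, channel_windows = NULL) {
  stopifnot(length(channels) >= 1)
  if (!all(vapply(channels, inherits, TRUE, "sinogram")))
    stop("all channels must be sinogram objects", call. = FALSE)
  g0 <- channels[[1L]]$geometry
  same <- vapply(channels, function(s) identical(s$geometry, g0), TRUE)
  if (!all(same)) stop("all channels must share one geometry", call. = FALSE)
  structure(list(channels = channels, channel_windows = channel_windows,
                 geometry = g0),
            class = "sinogram_set")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d views over [%.3f, %.3f) rad, %d detectors (%.3g mm), image %d x %d (%.3g mm px)\n",
              x$n_views, x$angles[1L], x$angles[x$n_views] + diff(range(x$angles)) / max(1L, x$n_views - 1L),
              x$n_detectors, x$detector_spacing, x$image_rows, x$image_cols, x$pixel_size))
  invisible(x)
}

#' @export
print.sinogram_set <- function(x, ...) {
  cat(sprintf("sinogram_set: %d channels, %d views x %d detectors\n",
              length(x$channels), x$geometry$n_views, x$geometry$n_detectors))
  invisible(x)
}

n_channels <- function(sinos) length(sinos$channels)

as_volume <- function(values, channel_labels = NULL) {
  stopifnot(length(dim(values)) == 3L)
  if (!is.null(channel_labels)) dimnames(values)[[3L]] <- channel_labels
  values
}

check_volume <- function(F) {
  if (length(dim(F)) != 3L) stop("expected an M x N x C array", call. = FALSE)
  if (!all(is.finite(F))) stop("volume must be finite", call. = FALSE)
  invisible(F)
}
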