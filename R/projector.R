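#' Forward projection (discrete parallel-beam ray transform)
#'
#' Computes line integrals of an image with Joseph (interpolating) ray
#' weights: each sinogram entry is a length-weighted sum of pixel values
#' along one ray, in value * mm.
#'
#' @param image numeric matrix, `image_rows x image_cols` of the geometry.
#' @param geometry a [scan_geometry()].
#' @return a [sinogram()].
#' @export
forward_project <- function(image, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  image <- as.matrix(image)
  if (nrow(image) != geometry$image_rows || ncol(image) != geometry$image_cols)
    stop(sprintf("image is %d x %d but geometry expects %d x %d",
                 nrow(image), ncol(image), geometry$image_rows, geometry$image_cols),
         call. = FALSE)
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  vals <- cpp_forward_project(image, geometry$pixel_size, geometry$angles,
                              geometry$n_detectors, geometry$detector_spacing)
  sinogram(vals, geometry)
}

#' Backprojection (exact adjoint of the forward projector)
#'
#' Smears sinogram values back into the image grid using the same Joseph
#' weights as [forward_project()], so the pair passes the inner-product
#' adjointness test to rounding error.
#'
#' @param sino a [sinogram()].
#' @return numeric matrix of the geometry's image size.
#' @export
back_project <- function(sino) {
  if (!inherits(sino, "sinogram") || is.null(sino$geometry))
    stop("back_project needs a sinogram with geometry", call. = FALSE)
  g <- sino$geometry
  cpp_back_project(sino$values, g$image_rows, g$image_cols, g$pixel_size,
                   g$angles, g$detector_spacing)
}

# Band-limited ramp filter (spatial-domain Ram-Lak kernel, optionally
# apodised), returned as a length-L real frequency response.
ramp_filter_response <- function(n_detectors, detector_spacing, filter_name) {
  L <- 2^ceiling(log2(max(64L, 2L * n_detectors)))
  h <- numeric(L)
  h[1L] <- 1 / (4 * detector_spacing^2)
  n_odd <- seq(1L, L / 2, by = 2L)
  h[1L + n_odd] <- -1 / (pi^2 * n_odd^2 * detector_spacing^2)
  h[L + 1L - n_odd] <- -1 / (pi^2 * n_odd^2 * detector_spacing^2)
  H <- Re(fft(h))
  fr <- c(0:(L / 2), (L / 2 - 1):1) / (L / 2)  # |freq| / Nyquist
  W <- switch(filter_name,
    "ramp" = , "ram-lak" = rep(1, L),
    "shepp-logan" = ifelse(fr == 0, 1, sin(pi * fr / 2) / (pi * fr / 2)),
    "cosine" = cos(pi * fr / 2),
    "hann" = 0.5 * (1 + cos(pi * fr)),
    "hamming" = 0.54 + 0.46 * cos(pi * fr),
    stop(sprintf("unknown FBP filter '%s'", filter_name), call. = FALSE))
  H * W
}

#' Filtered backprojection
#'
#' Classical FBP inversion of a parallel-beam sinogram whose views cover
#' `[0, pi)`: each view is convolved with a band-limited ramp kernel
#' (optionally apodised) via FFT, then backprojected pixel-driven with
#' angular weight `pi / n_views`.
#'
#' @param sino a [sinogram()].
#' @param filter_name one of `"ram-lak"` (synonym `"ramp"`), `"shepp-logan"`,
#'   `"cosine"`, `"hann"`, `"hamming"`.
#' @return numeric matrix reconstruction.
#' @export
fbp_reconstruct <- function(sino, filter_name = "ram-lak") {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  H <- ramp_filter_response(g$n_detectors, g$detector_spacing, filter_name)
  L <- length(H)
  padded <- matrix(0, L, g$n_views)
  padded[seq_len(g$n_detectors), ] <- t(sino$values)
  filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / L
  fsino <- t(filt[seq_len(g$n_detectors), , drop = FALSE]) * g$detector_spacing
  cpp_pixel_backproject(fsino, g$image_rows, g$image_cols, g$pixel_size,
                        g$angles, g$detector_spacing)
}

#' Precompute SART normalisation weights
#'
#' Row sums (per-ray total weight, the forward projection of a unit image)
#' and column sums (per-pixel total weight, the backprojection of a unit
#' sinogram) used by [sart_update()]. Compute once per geometry when running
#' many sweeps.
#'
#' @param geometry a [scan_geometry()].
#' @return list with `row_sums` (matrix) and `col_sums` (matrix).
#' @export
projection_weights <- function(geometry) {
  ones_img <- matrix(1, geometry$image_rows, geometry$image_cols)
  row_sums <- cpp_forward_project(ones_img, geometry$pixel_size, geometry$angles,
                                  geometry$n_detectors, geometry$detector_spacing)
  ones_sino <- matrix(1, geometry$n_views, geometry$n_detectors)
  col_sums <- cpp_back_project(ones_sino, geometry$image_rows, geometry$image_cols,
                               geometry$pixel_size, geometry$angles,
                               geometry$detector_spacing)
  list(row_sums = row_sums, col_sums = col_sums)
}

#' One SART sweep
#'
#' Simultaneous algebraic reconstruction: one full pass over all views,
#' moving the image toward consistency with the measured sinogram. The
#' residual is normalised by per-ray weight sums, backprojected, and
#' normalised by per-pixel weight sums; rays or pixels with zero total
#' weight are skipped. With consistent data the current solution is a fixed
#' point.
#'
#' @param image current estimate (matrix).
#' @param sino measured [sinogram()].
#' @param relaxation step length in `(0, 1]`.
#' @param nonneg clip negative pixels to zero after the update (attenuation
#'   images are nonnegative).
#' @param weights optional precomputed [projection_weights()].
#' @return updated image matrix.
#' @export
sart_update <- function(image, sino, relaxation = 0.2, nonneg = TRUE,
                        weights = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  if (relaxation <= 0 || relaxation > 1)
    stop("relaxation must be in (0, 1]", call. = FALSE)
  g <- sino$geometry
  if (is.null(weights)) weights <- projection_weights(g)
  resid <- sino$values - cpp_forward_project(as.matrix(image), g$pixel_size,
                                             g$angles, g$n_detectors,
                                             g$detector_spacing)
  rs <- weights$row_sums
  resid <- ifelse(rs > 0, resid / pmax(rs, .Machine$double.xmin), 0)
  delta <- cpp_back_project(resid, g$image_rows, g$image_cols, g$pixel_size,
                            g$angles, g$detector_spacing)
  cs <- weights$col_sums
  delta <- ifelse(cs > 0, delta / pmax(cs, .Machine$double.xmin), 0)
  out <- image + relaxation * delta
  if (nonneg) out[out < 0] <- 0
  out
}

#' Data-fidelity subproblem of the alternating framework
#'
#' Approximately minimises, over the spectral volume `F`,
#' `||P(F) - P||^2 + tau * sum_x (Fc_vol - (a F + b))^2`,
#' by alternating, for each energy channel, one SART sweep with the exact
#' pointwise minimiser of the coupling-plus-proximity term,
#' `F <- (F_sart + tau' a (Fc - b)) / (1 + tau' a^2)`,
#' where `tau' = tau / (1 + tau)` by default. As `tau -> 0` this reduces to
#' plain channel-wise SART.
#'
#' @param F current spectral volume, `M x N x C` array.
#' @param sinos a [sinogram_set()] with `C` channels.
#' @param coeffs list of `C` coefficient fields (each with elements `a`, `b`)
#'   relating channel `i` of `F` to slice `i` of `Fc_vol`; `NULL` together
#'   with `Fc_vol = NULL` runs pure SART sweeps.
#' @param Fc_vol the transformed target volume `F^c` (`M x N x C` array).
#' @param tau coupling weight, must be positive (pass `coeffs = NULL` to
#'   disable coupling entirely).
#' @param n_sweeps number of alternations.
#' @param relaxation,nonneg passed to [sart_update()]; the nonnegativity
#'   projection is applied once per sweep, after the pointwise step.
#' @param coupling_step the pointwise step weight `tau'`; default
#'   `tau / (1 + tau)`.
#' @param weights optional precomputed [projection_weights()].
#' @return updated `M x N x C` array.
#' @export
solve_data_subproblem <- function(F, sinos, coeffs, Fc_vol, tau,
                                  n_sweeps = 10L, relaxation = 0.2,
                                  nonneg = TRUE,
                                  coupling_step = tau / (1 + tau),
                                  weights = NULL) {
  stopifnot(inherits(sinos, "sinogram_set"))
  check_volume(F)
  C <- dim(F)[3L]
  if (C != n_channels(sinos)) stop("channel count mismatch", call. = FALSE)
  couple <- !is.null(coeffs)
  if (couple) {
    if (tau <= 0) stop("tau must be positive", call. = FALSE)
    stopifnot(length(coeffs) == C, identical(dim(Fc_vol), dim(F)))
  }
  if (is.null(weights)) weights <- projection_weights(sinos$geometry)
  for (sweep in seq_len(n_sweeps)) {
    for (ch in seq_len(C)) {
      f_sart <- sart_update(F[, , ch], sinos$channels[[ch]], relaxation,
                            nonneg = FALSE, weights = weights)
      if (couple) {
        a <- coeffs[[ch]]$a; b <- coeffs[[ch]]$b
        f_sart <- (f_sart + coupling_step * a * (Fc_vol[, , ch] - b)) /
          (1 + coupling_step * a^2)
      }
      if (nonneg) f_sart[f_sart < 0] <- 0
      F[, , ch] <- f_sart
    }
  }
  F
}

# Channel-wise data residual ||P(F) - P||^2 over all channels.
data_residual2 <- function(F, sinos) {
  g <- sinos$geometry
  tot <- 0
  for (ch in seq_len(dim(F)[3L])) {
    pf <- cpp_forward_project(F[, , ch], g$pixel_size, g$angles,
                              g$n_detectors, g$detector_spacing)
    tot <- tot + sum((pf - sinos$channels[[ch]]$values)^2)
  }
  tot
}
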