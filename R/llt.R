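# Locally linear transform: per-patch affine fit of a reference channel to
# a target channel (the guided-filter local linear model), followed by
# aggregation of the per-patch coefficients over all patches covering each
# pixel — unweighted (box) or Gaussian-weighted, the refined variant that
# gives the patch centres nearest a pixel more say and so distorts edges
# less.

# Truncated box sum: sum of x over the (2r+1)^2 window clipped to the image.
box_sum <- function(x, r) {
  if (r == 0L) return(x)
  M <- nrow(x); N <- ncol(x)
  cs <- rbind(0, apply(x, 2L, cumsum))
  i1 <- pmax(seq_len(M) - r, 1L); i2 <- pmin(seq_len(M) + r, M)
  x <- cs[i2 + 1L, , drop = FALSE] - cs[i1, , drop = FALSE]
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  j1 <- pmax(seq_len(N) - r, 1L); j2 <- pmin(seq_len(N) + r, N)
  cs[, j2 + 1L, drop = FALSE] - cs[, j1, drop = FALSE]
}

box_count <- function(M, N, r) box_sum(matrix(1, M, N), r)

# Separable windowed convolution with per-pixel renormalisation over
# in-bounds offsets: returns sum_k w(k) x(k) and sum_k w(k) for offsets
# |dx|,|dy| <= r with separable weights w = k1d(dy) * k1d(dx).
sep_weighted_sum <- function(x, k1d, r) {
  M <- nrow(x); N <- ncol(x)
  tmp <- matrix(0, M, N)
  for (d in -r:r) {
    w <- k1d[d + r + 1L]
    src <- seq_len(M) + d
    ok <- src >= 1L & src <= M
    tmp[ok, ] <- tmp[ok, ] + w * x[src[ok], , drop = FALSE]
  }
  out <- matrix(0, M, N)
  for (d in -r:r) {
    w <- k1d[d + r + 1L]
    src <- seq_len(N) + d
    ok <- src >= 1L & src <= N
    out[, ok] <- out[, ok] + w * tmp[, src[ok], drop = FALSE]
  }
  out
}

#' Locally linear transform parameters
#'
#' @param radius patch half-width `r`; the patch is `(2r+1) x (2r+1)`,
#'   truncated at image boundaries.
#' @param eps ridge penalty on the slope (scaled by patch size, i.e. the
#'   penalty enters the per-patch objective once per patch pixel, the
#'   guided-filter convention). `eps = 0` is only exact on patches with
#'   positive guide variance; see `degenerate`.
#' @param mode `"box"` (unweighted aggregation) or `"gaussian"` (the refined
#'   transform).
#' @param sigma Gaussian aggregation width in pixels (gaussian mode);
#'   defaults to `radius / 2`.
#' @param degenerate with `eps = 0` on a zero-variance patch, either
#'   `"fallback"` (slope 0, intercept = patch mean of the target) or
#'   `"error"`.
#' @return object of class `llt_params`.
#' @export
llt_params <- function(radius = 5L, eps = 1e-4, mode = c("gaussian", "box"),
                       sigma = NULL, degenerate = c("fallback", "error")) {
  mode <- match.arg(mode)
  degenerate <- match.arg(degenerate)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  if (is.null(sigma)) sigma <- max(radius / 2, 0.5)
  if (mode == "gaussian" && sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(radius = as.integer(radius), eps = eps, mode = mode,
                 sigma = sigma, degenerate = degenerate),
            class = "llt_params")
}

#' Per-patch affine fit coefficients
#'
#' For every patch centre `k` (every pixel; boundary patches are truncated
#' to in-bounds pixels), fits `target ~ a * guide + b` by ridge regression
#' with the penalty `eps * a^2` counted once per patch pixel, giving the
#' closed form `a = cov_k(guide, target) / (var_k(guide) + eps)`,
#' `b = mean_k(target) - a * mean_k(guide)`.
#'
#' @param guide,target numeric matrices of equal size.
#' @param radius patch half-width.
#' @param eps ridge penalty, `>= 0`.
#' @param degenerate policy for `eps = 0` on zero-variance patches:
#'   `"fallback"` (a = 0, b = patch mean) or `"error"`.
#' @return list with matrices `a` and `b`, indexed by patch centre.
#' @export
patch_coefficients <- function(guide, target, radius, eps,
                               degenerate = c("fallback", "error")) {
  degenerate <- match.arg(degenerate)
  guide <- as.matrix(guide); target <- as.matrix(target)
  if (!identical(dim(guide), dim(target)))
    stop("guide and target must have the same shape", call. = FALSE)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  # Sums formulation of the per-patch normal equations (identical to
  # cov/(var + eps) in exact arithmetic, but exact in floating point on
  # integer/dyadic data): a = (n S_gt - S_g S_t) / (n S_gg - S_g^2 + n^2 eps)
  n <- box_count(nrow(guide), ncol(guide), radius)
  Sg <- box_sum(guide, radius)
  St <- box_sum(target, radius)
  num <- n * box_sum(guide * target, radius) - Sg * St
  den <- pmax(n * box_sum(guide * guide, radius) - Sg^2, 0)  # n^2 * var >= 0
  if (eps == 0) {
    degen <- den <= 1e-12 * max(max(den), .Machine$double.xmin)
    if (any(degen) && degenerate == "error")
      stop("eps = 0 with zero-variance patch(es)", call. = FALSE)
    a <- ifelse(degen, 0, num / ifelse(degen, 1, den))
  } else {
    a <- num / (den + n^2 * eps)
  }
  list(a = a, b = (St - a * Sg) / n)
}

#' Box (unweighted) coefficient aggregation
#'
#' Averages the per-patch coefficients over all patch centres whose patch
#' covers each pixel (with truncated boundary windows this is the truncated
#' box mean), yielding pixel-indexed fields.
#'
#' @param patch_coeffs output of [patch_coefficients()].
#' @param radius the patch half-width used for the fit.
#' @return list with pixel-indexed matrices `a` and `b`.
#' @export
aggregate_box <- function(patch_coeffs, radius) {
  n <- box_count(nrow(patch_coeffs$a), ncol(patch_coeffs$a), radius)
  list(a = box_sum(patch_coeffs$a, radius) / n,
       b = box_sum(patch_coeffs$b, radius) / n)
}

#' Gaussian-weighted coefficient aggregation (refined transform)
#'
#' Replaces the flat average of [aggregate_box()] with radial-basis weights
#' `w(x, k) = exp(-||x - k||^2 / (2 sigma^2))` over the covering patch
#' centres, so the coefficients fitted nearest a pixel dominate. As
#' `sigma -> Inf` this reduces to the box aggregation.
#'
#' @inheritParams aggregate_box
#' @param sigma Gaussian width in pixels, `> 0`.
#' @return list with pixel-indexed matrices `a` and `b`.
#' @export
aggregate_gaussian <- function(patch_coeffs, radius, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (radius == 0L) return(list(a = patch_coeffs$a, b = patch_coeffs$b))
  k1d <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  den <- sep_weighted_sum(matrix(1, nrow(patch_coeffs$a), ncol(patch_coeffs$a)),
                          k1d, radius)
  list(a = sep_weighted_sum(patch_coeffs$a, k1d, radius) / den,
       b = sep_weighted_sum(patch_coeffs$b, k1d, radius) / den)
}

#' Apply a pixel-indexed affine coefficient field
#'
#' @param coeffs list with matrices `a`, `b`.
#' @param guide numeric matrix of the same size.
#' @return `a * guide + b`, elementwise.
#' @export
apply_transform <- function(coeffs, guide) {
  guide <- as.matrix(guide)
  if (!identical(dim(coeffs$a), dim(guide)))
    stop("coefficient and guide shapes differ", call. = FALSE)
  coeffs$a * guide + coeffs$b
}

#' Build the transformed volume for one target channel
#'
#' Re-expresses every channel of the spectral volume as an affine copy of
#' the target channel: for each reference channel `i`, channel `i` is used
#' as the fitting guide, the duplicate extension of the target channel along
#' the spectral axis as the filtering input, and the aggregated coefficients
#' are applied to the guide. Stacking the `C` outputs gives the volume
#' `F^c`, which inherits the target's structures at every slice and is
#' therefore gradient-sparse along the spectral direction — exactly so when
#' the channels are affinely related and `eps = 0`.
#'
#' @param F spectral volume, `M x N x C` array.
#' @param target_channel index `c` in `1..C`.
#' @param params an [llt_params()].
#' @return list with `values` (the `M x N x C` transformed volume),
#'   `target_channel`, and `coeffs` (list of `C` pixel-indexed coefficient
#'   fields, one per reference channel, as used by the data subproblem).
#' @export
build_transformed_volume <- function(F, target_channel, params = llt_params()) {
  check_volume(F)
  C <- dim(F)[3L]
  if (target_channel < 1 || target_channel > C)
    stop("target_channel out of range", call. = FALSE)
  target <- F[, , target_channel]
  out <- array(0, dim(F))
  coeffs <- vector("list", C)
  for (i in seq_len(C)) {
    pc <- patch_coefficients(F[, , i], target, params$radius, params$eps,
                             degenerate = params$degenerate)
    ag <- if (params$mode == "gaussian")
      aggregate_gaussian(pc, params$radius, params$sigma)
    else
      aggregate_box(pc, params$radius)
    coeffs[[i]] <- ag
    out[, , i] <- apply_transform(ag, F[, , i])
  }
  list(values = out, target_channel = as.integer(target_channel), coeffs = coeffs)
}
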