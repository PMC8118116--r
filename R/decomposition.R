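#' Bin-effective decomposition basis
#'
#' Spectrum-weighted per-bin effective attenuation of each basis material:
#' `A[c, m] = sum_{E in w_c} S(E) mu_m(E) / sum_{E in w_c} S(E)`.
#'
#' @param basis a [toy_attenuation_model()] material basis.
#' @param spectrum a [source_spectrum()] on the basis grid.
#' @param windows an [energy_windows()] object; every window must contain at
#'   least one grid point with positive weight.
#' @return object of class `decomposition_basis`: matrix `A`
#'   (channels x materials) and `materials`.
#' @export
effective_basis <- function(basis, spectrum, windows) {
  stopifnot(inherits(basis, "material_basis"),
            inherits(spectrum, "source_spectrum"),
            inherits(windows, "energy_windows"))
  if (!isTRUE(all.equal(spectrum$energies, basis$energies)))
    stop("spectrum and basis must share one energy grid", call. = FALSE)
  members <- window_members(windows, spectrum$energies)
  A <- t(vapply(members, function(idx) {
    w <- spectrum$weights[idx]
    if (sum(w) <= 0) stop("empty (zero-weight) energy window", call. = FALSE)
    colSums(w * basis$mu[idx, , drop = FALSE]) / sum(w)
  }, numeric(length(basis$materials))))
  A <- matrix(A, nrow = length(members),
              dimnames = list(windows$labels, basis$materials))
  structure(list(A = A, materials = basis$materials),
            class = "decomposition_basis")
}

# Nonnegative least squares for a small fixed design matrix A (C x m),
# solved for every pixel at once by enumerating active sets: for each subset
# S of materials, the unconstrained fit restricted to S is computed via a
# precomputed pseudo-inverse, infeasible (negative) solutions are discarded,
# and the feasible fit with the smallest residual wins. Exact for m <= ~6.
nnls_enumerate <- function(A, Y) {
  m <- ncol(A)
  npix <- ncol(Y)
  best_f <- matrix(0, m, npix)
  best_r <- colSums(Y^2)  # empty active set: f = 0
  for (size in seq_len(m)) {
    for (S in utils::combn(m, size, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      pinv <- solve(crossprod(As), t(As))
      fs <- pinv %*% Y
      feas <- colSums(fs < -1e-12) == 0
      if (!any(feas)) next
      r <- colSums((Y - As %*% fs)^2)
      take <- feas & (r < best_r - 1e-15)
      if (any(take)) {
        best_r[take] <- r[take]
        best_f[, take] <- 0
        best_f[S, take] <- pmax(fs[, take, drop = FALSE], 0)
      }
    }
  }
  list(f = best_f, resid2 = best_r)
}

#' Image-domain material decomposition
#'
#' Per-pixel linear basis fit: solves `A f(x) = y(x)` in least squares for
#' every pixel, where `y(x)` is the vector of channel values and `A` the
#' bin-effective basis. `constraint = "nonneg"` solves the nonnegative
#' variant exactly (active-set enumeration over the few basis materials).
#' No sum-to-one constraint is imposed.
#'
#' @param channel_images `M x N x C` array of reconstructed channel images.
#' @param basis a [effective_basis()] object (or a bare matrix `A`).
#' @param constraint `"none"` or `"nonneg"`.
#' @return object of class `fraction_maps`: list `maps` of `M x N` matrices
#'   named by material.
#' @export
decompose <- function(channel_images, basis, constraint = c("none", "nonneg")) {
  constraint <- match.arg(constraint)
  check_volume(channel_images)
  A <- if (inherits(basis, "decomposition_basis")) basis$A else as.matrix(basis)
  mats <- colnames(A) %||% paste0("material", seq_len(ncol(A)))
  d <- dim(channel_images)
  if (d[3L] < ncol(A))
    stop("need at least as many channels as basis materials", call. = FALSE)
  if (nrow(A) != d[3L]) stop("basis rows must match channel count", call. = FALSE)
  if (qr(A)$rank < ncol(A)) stop("basis matrix is rank deficient", call. = FALSE)
  Y <- unfold3(channel_images)  # C x (M*N)
  F <- if (constraint == "none") {
    solve(crossprod(A), t(A) %*% Y)
  } else {
    nnls_enumerate(A, Y)$f
  }
  maps <- lapply(seq_len(ncol(A)), function(m) matrix(F[m, ], d[1L], d[2L]))
  names(maps) <- mats
  structure(list(maps = maps, materials = mats), class = "fraction_maps")
}

#' Circular region-of-interest mask
#'
#' @param M,N grid size.
#' @param center `c(row, col)` in pixels.
#' @param radius radius in pixels.
#' @return logical `M x N` matrix.
#' @export
circular_mask <- function(M, N, center, radius) {
  rows <- matrix(rep(seq_len(M), N), M, N)
  cols <- matrix(rep(seq_len(N), each = M), M, N)
  (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
}

#' ROI mean and standard deviation
#'
#' Sample mean and population standard deviation (divisor `n`) of a map over
#' a mask, the protocol used to score decomposed calibration material.
#'
#' @param map numeric matrix.
#' @param mask logical matrix of the same size with at least one `TRUE`.
#' @return list with `mean`, `std`, `n_pixels`.
#' @export
roi_stats <- function(map, mask) {
  map <- as.matrix(map); mask <- as.matrix(mask)
  if (!identical(dim(map), dim(mask))) stop("shape mismatch", call. = FALSE)
  v <- map[mask]
  if (length(v) == 0L) stop("empty ROI mask", call. = FALSE)
  m <- mean(v)
  list(mean = m, std = sqrt(mean((v - m)^2)), n_pixels = length(v))
}

#' Root-mean-square error
#'
#' @param map,reference numeric arrays of equal shape.
#' @param mask optional logical mask restricting the evaluation.
#' @return nonnegative real.
#' @export
rmse <- function(map, reference, mask = NULL) {
  if (!identical(dim(map) %||% length(map), dim(reference) %||% length(reference)))
    stop("shape mismatch", call. = FALSE)
  d2 <- (map - reference)^2
  if (!is.null(mask)) d2 <- d2[mask]
  sqrt(mean(d2))
}
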