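#' Framework parameters
#'
#' Settings of the alternating reconstruction: regularizer choice and
#' weights, outer iteration count, locally linear transform settings, and
#' data-subproblem constants.
#'
#' @param regularizer `"L1"` (anisotropic gradient TV), `"L0"` (gradient
#'   support count), or `"trace"` (trace norm of the mode-3 unfolding).
#' @param lambda regularisation weight, scalar or one value per channel;
#'   `0` disables regularisation entirely, reducing the method to plain
#'   channel-wise SART.
#' @param tau relaxation weight of the transform-coupling term (`> 0`).
#'   Defaults to `lambda`; note the loop-2 subproblem weight is
#'   `lambda / tau`, so shipped configurations set `tau` explicitly.
#' @param iter_max outer iterations (default 20).
#' @param llt an [llt_params()]; its `mode` is overridden by `variant`.
#' @param variant `"ellt"` (Gaussian-weighted aggregation) or `"llt"` (box
#'   aggregation).
#' @param n_sweeps,relaxation,nonneg data-subproblem constants, see
#'   [solve_data_subproblem()].
#' @param coupling_step pointwise coupling step `tau'`; default
#'   `tau / (1 + tau)`.
#' @param l0 an [l0_solver_params()] shell for the L0 subproblem; its
#'   `lambda` is set per call to `lambda / tau`. Pass `NULL` for defaults.
#' @param z_weight spectral-axis gradient weight.
#' @param channel_update `"spectral_mean"` (average each transformed volume
#'   along the spectral axis — the default) or `"cross_volume"` (average the
#'   c-th slice across the C transformed volumes).
#' @param prox_inner,prox_tol inner iterations / tolerance of the TV prox.
#' @param fbp_filter filter used for the warm-start FBP and FBP baseline.
#' @param seed integer seed recorded with the run (the solver itself is
#'   deterministic).
#' @return object of class `framework_params`.
#' @export
framework_params <- function(regularizer = c("L1", "L0", "trace"),
                             lambda = 1e-3, tau = NULL,
                             iter_max = 20L, llt = llt_params(),
                             variant = c("ellt", "llt"),
                             n_sweeps = 10L, relaxation = 0.2, nonneg = TRUE,
                             coupling_step = NULL,
                             l0 = NULL, z_weight = 1,
                             channel_update = c("spectral_mean", "cross_volume"),
                             prox_inner = 50L, prox_tol = 1e-8,
                             fbp_filter = "ram-lak", seed = 1L) {
  regularizer <- match.arg(regularizer)
  variant <- match.arg(variant)
  channel_update <- match.arg(channel_update)
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (is.null(tau)) tau <- max(lambda)
  if (any(lambda > 0) && tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (iter_max < 1) stop("iter_max must be >= 1", call. = FALSE)
  llt$mode <- if (variant == "ellt") "gaussian" else "box"
  if (is.null(l0)) l0 <- l0_solver_params(lambda = 1)  # lambda set per call
  structure(list(regularizer = regularizer, lambda = lambda, tau = tau,
                 iter_max = as.integer(iter_max), llt = llt, variant = variant,
                 n_sweeps = as.integer(n_sweeps), relaxation = relaxation,
                 nonneg = nonneg,
                 coupling_step = coupling_step %||% (tau / (1 + tau)),
                 l0 = l0, z_weight = z_weight, channel_update = channel_update,
                 prox_inner = as.integer(prox_inner), prox_tol = prox_tol,
                 fbp_filter = fbp_filter, seed = as.integer(seed)),
            class = "framework_params")
}

# Loop-2 subproblem: min lambda * Phi(u) + tau * ||u - g||^2, dispatched to
# the matching prox with effective weight lambda / tau (trace norm prox is
# defined with a 1/2 factor, hence lambda / (2 tau)).
regularizer_subproblem <- function(g, params, lambda_c) {
  w <- lambda_c / params$tau
  out <- switch(params$regularizer,
    L1 = prox_tv_3d(g, weight = w, n_inner = params$prox_inner,
                    tol = params$prox_tol, z_weight = params$z_weight),
    L0 = {
      p <- params$l0; p$lambda <- w
      solve_l0_gradient_3d(g, p, z_weight = params$z_weight)
    },
    trace = svt_mode3(g, threshold = w / 2))
  # prox property: the sub-objective never exceeds its value at g
  sub <- function(u) lambda_c * switch(params$regularizer,
    L1 = tv_value_3d(u, params$z_weight),
    L0 = gradient_support_count(u, params$z_weight),
    trace = trace_norm_mode3(u)) + params$tau * sum((u - g)^2)
  s0 <- sub(g); s1 <- sub(out)
  if (s1 > s0 + 1e-9 * max(1, s0))
    warning("regularizer subproblem did not decrease its objective")
  out
}

regularizer_value <- function(u, params) {
  switch(params$regularizer,
    L1 = tv_value_3d(u, params$z_weight),
    L0 = gradient_support_count(u, params$z_weight),
    trace = trace_norm_mode3(u))
}

#' Objective of the relaxed (unconstrained) model
#'
#' `||P(F) - P||^2 + sum_c [lambda_c Phi(F^c) + tau ||F^c - (a F + b)||^2]`
#' with the configured sparsity measure `Phi`.
#'
#' @param F spectral volume.
#' @param Fc_list list of `C` transformed volumes `F^c`.
#' @param sinos the measured [sinogram_set()].
#' @param coeffs_list list of `C` coefficient sets, each a list of `C`
#'   pixel-indexed fields (as returned by [build_transformed_volume()]).
#' @param params a [framework_params()].
#' @return scalar objective value.
#' @export
objective_value <- function(F, Fc_list, sinos, coeffs_list, params) {
  check_volume(F)
  C <- dim(F)[3L]
  lambda <- rep_len(params$lambda, C)
  tot <- data_residual2(F, sinos)
  for (c in seq_len(C)) {
    pred <- array(0, dim(F))
    for (i in seq_len(C))
      pred[, , i] <- apply_transform(coeffs_list[[c]][[i]], F[, , i])
    tot <- tot + lambda[c] * regularizer_value(Fc_list[[c]], params) +
      params$tau * sum((Fc_list[[c]] - pred)^2)
  }
  tot
}

#' Plain channel-wise SART reconstruction
#'
#' @param sinos a [sinogram_set()].
#' @param n_iterations total sweeps per channel.
#' @param relaxation,nonneg see [sart_update()].
#' @return `M x N x C` array.
#' @export
sart_reconstruct <- function(sinos, n_iterations = 50L, relaxation = 0.2,
                             nonneg = TRUE) {
  g <- sinos$geometry
  C <- n_channels(sinos)
  F <- array(0, c(g$image_rows, g$image_cols, C))
  w <- projection_weights(g)
  for (it in seq_len(n_iterations))
    for (ch in seq_len(C))
      F[, , ch] <- sart_update(F[, , ch], sinos$channels[[ch]], relaxation,
                               nonneg = nonneg, weights = w)
  F
}

#' FBP reconstruction of every channel
#'
#' @param sinos a [sinogram_set()].
#' @param filter_name FBP filter label.
#' @return `M x N x C` array.
#' @export
fbp_volume <- function(sinos, filter_name = "ram-lak") {
  g <- sinos$geometry
  C <- n_channels(sinos)
  F <- array(0, c(g$image_rows, g$image_cols, C))
  for (ch in seq_len(C))
    F[, , ch] <- fbp_reconstruct(sinos$channels[[ch]], filter_name)
  F
}

new_reconstruction_result <- function(volume, objective_trace, residual_trace,
                                      params, method) {
  structure(list(volume = volume, objective_trace = objective_trace,
                 residual_trace = residual_trace, params = params,
                 method = method),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("reconstruction_result: method %s, %d x %d x %d, %d iterations\n",
              x$method, d[1L], d[2L], d[3L], length(x$objective_trace)))
  invisible(x)
}

#' Locally linear transform based spectral CT reconstruction
#'
#' The alternating outer loop: starting from `F = 0`, each outer iteration
#' (1) refits the per-channel transform coefficients and runs the
#' data-fidelity subproblem for every target channel, averaging the `C`
#' candidates; (2) rebuilds the transformed volumes from the averaged
#' estimate and solves the sparsity subproblem for each, with the configured
#' measure; then updates each channel image by averaging its transformed
#' volume along the spectral dimension (or across volumes, per
#' `channel_update`). Because `F = 0` is a degenerate guide for the very
#' first coefficient fit, iteration 0 fits its coefficients on an FBP warm
#' start (the reconstruction itself still starts from zero).
#'
#' With `lambda = 0` the coupling and sparsity layers are inert and the
#' method reduces exactly to plain channel-wise SART.
#'
#' @param sinos a [sinogram_set()].
#' @param params a [framework_params()].
#' @return a `reconstruction_result` with the final volume, per-iteration
#'   objective trace, data-residual trace, and the parameter snapshot.
#' @export
reconstruct <- function(sinos, params = framework_params()) {
  stopifnot(inherits(sinos, "sinogram_set"), inherits(params, "framework_params"))
  g <- sinos$geometry
  C <- n_channels(sinos)
  lambda <- rep_len(params$lambda, C)
  weights <- projection_weights(g)
  F <- array(0, c(g$image_rows, g$image_cols, C))

  if (all(lambda == 0)) {  # regularisation disabled: exact SART degeneration
    resid <- numeric(params$iter_max)
    for (i in seq_len(params$iter_max)) {
      F <- solve_data_subproblem(F, sinos, coeffs = NULL, Fc_vol = NULL,
                                 tau = 1, n_sweeps = params$n_sweeps,
                                 relaxation = params$relaxation,
                                 nonneg = params$nonneg, weights = weights)
      resid[i] <- data_residual2(F, sinos)
    }
    return(new_reconstruction_result(F, resid, resid, params,
                                     paste0(params$variant, "-",
                                            tolower(params$regularizer))))
  }

  warm <- fbp_volume(sinos, params$fbp_filter)
  Fc_list <- vector("list", C)
  coeffs_list <- vector("list", C)
  for (c in seq_len(C)) {
    bt <- build_transformed_volume(warm, c, params$llt)
    Fc_list[[c]] <- bt$values
    coeffs_list[[c]] <- bt$coeffs
  }

  obj_trace <- numeric(params$iter_max)
  resid_trace <- numeric(params$iter_max)
  for (i in seq_len(params$iter_max)) {
    if (i > 1L) {  # refit coupling coefficients on the current volume
      for (c in seq_len(C))
        coeffs_list[[c]] <- build_transformed_volume(F, c, params$llt)$coeffs
    }
    # loop 1: data subproblem per target channel, then average
    F_star <- array(0, dim(F))
    for (c in seq_len(C)) {
      F_star <- F_star + solve_data_subproblem(
        F, sinos, coeffs_list[[c]], Fc_list[[c]], params$tau,
        n_sweeps = params$n_sweeps, relaxation = params$relaxation,
        nonneg = params$nonneg, coupling_step = params$coupling_step,
        weights = weights)
    }
    F_star <- F_star / C

    # loop 2: sparsity subproblem per target channel
    for (c in seq_len(C)) {
      bt <- build_transformed_volume(F_star, c, params$llt)
      Fc_list[[c]] <- regularizer_subproblem(bt$values, params, lambda[c])
      coeffs_list[[c]] <- bt$coeffs
    }

    # channel update
    if (params$channel_update == "spectral_mean") {
      for (c in seq_len(C)) {
        s <- matrix(0, dim(F)[1L], dim(F)[2L])
        for (i2 in seq_len(C)) s <- s + Fc_list[[c]][, , i2]
        F[, , c] <- s / C
      }
    } else {
      for (c in seq_len(C)) {
        s <- matrix(0, dim(F)[1L], dim(F)[2L])
        for (k in seq_len(C)) s <- s + Fc_list[[k]][, , c]
        F[, , c] <- s / C
      }
    }
    if (params$nonneg) F[F < 0] <- 0

    resid_trace[i] <- data_residual2(F, sinos)
    obj_trace[i] <- objective_value(F, Fc_list, sinos, coeffs_list, params)
    if (resid_trace[i] > 10 * min(resid_trace[seq_len(i)]))
      stop(sprintf(paste0("divergence guard: data residual at iteration %d ",
                          "grew 10x over its running minimum (%.4g vs %.4g); ",
                          "reduce lambda/tau or the relaxation"),
                   i, resid_trace[i], min(resid_trace[seq_len(i)])),
           call. = FALSE)
  }
  new_reconstruction_result(F, obj_trace, resid_trace, params,
                            paste0(params$variant, "-", tolower(params$regularizer)))
}

#' Non-transform comparison reconstructions
#'
#' The baseline set: `"fbp"` (filtered backprojection per channel);
#' `"tv2d"` / `"l02d"` (each channel regularised independently, the spectral
#' gradient vacuous); `"tv3d"` / `"l03d"` (the raw channel stack regularised
#' jointly, spectral gradient active); `"tvlr"` (spatial TV plus trace norm
#' of the directly unfolded stack). Iterative baselines alternate the same
#' SART sweeps with the matching subproblem at weight `lambda / tau`.
#'
#' @param sinos a [sinogram_set()].
#' @param which baseline label.
#' @param params a [framework_params()]; `regularizer` is implied by `which`
#'   where applicable.
#' @return a `reconstruction_result`.
#' @export
reconstruct_baselines <- function(sinos,
                                  which = c("fbp", "tv2d", "l02d", "tv3d",
                                            "l03d", "tvlr"),
                                  params = framework_params()) {
  which <- match.arg(which)
  g <- sinos$geometry
  C <- n_channels(sinos)
  if (which == "fbp") {
    F <- fbp_volume(sinos, params$fbp_filter)
    r <- data_residual2(F, sinos)
    return(new_reconstruction_result(F, r, r, params, "fbp"))
  }
  lambda <- rep_len(params$lambda, C)
  weights <- projection_weights(g)
  w2 <- function(c) lambda[c] / params$tau
  p2 <- params
  p2$regularizer <- switch(which, tv2d = , tv3d = , tvlr = "L1",
                           l02d = , l03d = "L0")
  F <- array(0, c(g$image_rows, g$image_cols, C))
  resid <- numeric(params$iter_max)
  for (i in seq_len(params$iter_max)) {
    F <- solve_data_subproblem(F, sinos, coeffs = NULL, Fc_vol = NULL, tau = 1,
                               n_sweeps = params$n_sweeps,
                               relaxation = params$relaxation,
                               nonneg = params$nonneg, weights = weights)
    if (which %in% c("tv2d", "l02d")) {
      for (c in seq_len(C)) {
        u <- array(F[, , c], c(g$image_rows, g$image_cols, 1L))
        F[, , c] <- regularizer_subproblem(u, p2, lambda[c])[, , 1L]
      }
    } else if (which %in% c("tv3d", "l03d")) {
      F <- regularizer_subproblem(F, p2, lambda[1L])
    } else {  # tvlr: spatial TV then spectral trace norm, sequentially
      F <- prox_tv_3d(F, weight = w2(1L), n_inner = params$prox_inner,
                      tol = params$prox_tol, z_weight = 0)
      F <- svt_mode3(F, threshold = w2(1L) / 2)
    }
    if (params$nonneg) F[F < 0] <- 0
    resid[i] <- data_residual2(F, sinos)
  }
  new_reconstruction_result(F, resid, resid, params, which)
}
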