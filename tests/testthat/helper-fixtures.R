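# Shared fixtures and independent oracles, built in code at test time.

# Disk with supersampled (partial-volume) edge: the honest discretisation of
# a uniform disk, free of the aliasing a binary mask introduces.
aa_disk <- function(M, N, center, radius, value, supersample = 4L) {
  img <- matrix(0, M, N)
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  for (oi in off) for (oj in off) {
    d2 <- outer((seq_len(M) + oi - center[1L])^2,
                (seq_len(N) + oj - center[2L])^2, `+`)
    img <- img + (d2 <= radius^2) * value
  }
  img / supersample^2
}

# Per-patch ridge regression by explicit normal equations (the independent
# oracle for patch_coefficients); penalty counted once per patch pixel.
ridge_fit_oracle <- function(guide, target, radius, eps) {
  M <- nrow(guide); N <- ncol(guide)
  a <- matrix(0, M, N); b <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    ii <- max(1, i - radius):min(M, i + radius)
    jj <- max(1, j - radius):min(N, j + radius)
    g <- as.numeric(guide[ii, jj]); t <- as.numeric(target[ii, jj])
    n <- length(g)
    sol <- solve(matrix(c(sum(g^2) + n * eps, sum(g), sum(g), n), 2L),
                 c(sum(g * t), sum(t)))
    a[i, j] <- sol[1L]; b[i, j] <- sol[2L]
  }
  list(a = a, b = b)
}

# Exhaustive 1D Potts oracle: enumerate all contiguous partitions, segment
# means per segment, exact composite energy.
potts_oracle_1d <- function(g, lambda) {
  n <- length(g)
  best <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    starts <- c(1L, bounds + 1L); ends <- c(bounds, n)
    u <- numeric(n)
    for (s in seq_along(starts)) u[starts[s]:ends[s]] <- mean(g[starts[s]:ends[s]])
    e <- lambda * sum(abs(diff(u)) != 0) + sum((u - g)^2)
    if (e < best) best <- e
  }
  best
}

# Dyadic-valued spectral volume with exactly affine-related channels
# (power-of-two slopes/offsets so the locally linear fit is exact in
# floating point); every patch of the base image has positive variance.
affine_dyadic_volume <- function(M = 48L, alphas = c(1, 0.5, 2),
                                 betas = c(0, 0.5, 1)) {
  base <- outer(seq_len(M), seq_len(M), function(i, j) (i + 2 * j) %% 5) +
    outer(seq_len(M), seq_len(M), function(i, j) (3 * i + j) %% 3)
  F <- array(0, c(M, M, length(alphas)))
  for (i in seq_along(alphas)) F[, , i] <- alphas[i] * base + betas[i]
  F
}

# Small noiseless single-material study used by projector/framework tests.
smooth_phantom <- function(M = 64L, sigma = M / 5, value = 0.03) {
  c0 <- (M + 1) / 2
  outer(seq_len(M), seq_len(M),
        function(i, j) value * exp(-((i - c0)^2 + (j - c0)^2) / (2 * sigma^2)))
}

# Tiny 2-bin noisy study for smoke/integration tests.
tiny_config <- function(seed = 7L) {
  cfg <- default_run_config(seed = seed)
  cfg$methods <- c("fbp", "ellt-tv")
  cfg$simulator$rows <- 64L
  cfg$simulator$cols <- 64L
  cfg$simulator$n_views <- 90L
  cfg$simulator$windows <- list(lo = c(30, 70), hi = c(70, 120))
  cfg$framework$iter_max <- 3L
  cfg$framework$n_sweeps <- 4L
  cfg$decomposition$roi <- list(center = c(32, 32), radius = 7)
  cfg
}
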