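test_that("the 3D gradient matches hand enumeration and has an exact adjoint", {
  expect_equal(max(abs(unlist(gradient_3d(array(3, c(4, 5, 2)))))), 0)

  v <- array(c(0, 0, 1, 1), c(2, 2, 1))  # rows [0,1; 0,1]
  g <- gradient_3d(v)
  expect_equal(g$dx[, , 1L], matrix(c(1, 1, 0, 0), 2))
  expect_equal(sum(g$dx != 0), 2L)
  expect_equal(max(abs(g$dy)), 0)
  expect_equal(max(abs(g$dz)), 0)

  set.seed(41)
  for (zw in c(1, 0.5)) {
    v <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
    q <- list(dx = array(rnorm(60), c(4, 5, 3)),
              dy = array(rnorm(60), c(4, 5, 3)),
              dz = array(rnorm(60), c(4, 5, 3)))
    gv <- gradient_3d(v, zw)
    ip1 <- sum(gv$dx * q$dx) + sum(gv$dy * q$dy) + sum(gv$dz * q$dz)
    ip2 <- sum(v * elltct:::gradient_adjoint(q, zw))
    expect_lt(abs(ip1 - ip2), 1e-10)
  }
})

test_that("gradient support count enumerates nonzero positions exactly", {
  expect_equal(gradient_support_count(array(2, c(3, 3, 2))), 0L)

  # single bright interior pixel, identical channels: brute-force enumeration
  C <- 3
  v <- array(0, c(5, 5, C))
  v[3, 3, ] <- 1
  g <- gradient_3d(v)
  brute <- sum(abs(g$dx) + abs(g$dy) + abs(g$dz) != 0)
  expect_equal(gradient_support_count(v), brute)
  expect_equal(brute, 3L * C)  # dz vanishes for identical channels

  set.seed(42)
  v <- array(rnorm(36), c(3, 4, 3))
  expect_equal(gradient_support_count(v + 17.3), gradient_support_count(v))
})

test_that("the anisotropic TV value sums absolute forward differences", {
  expect_equal(tv_value_3d(array(1, c(4, 4, 2))), 0)
  expect_equal(tv_value_3d(array(c(0, 1, 2), c(1, 3, 1))), 2)
  set.seed(43)
  v <- array(rnorm(48), c(4, 4, 3))
  g <- gradient_3d(v, 0.7)
  expect_equal(tv_value_3d(v, 0.7),
               sum(abs(g$dx)) + sum(abs(g$dy)) + sum(abs(g$dz)))
})

test_that("the TV prox has exact limits and matches the 1D closed form", {
  set.seed(44)
  v <- array(rnorm(32), c(4, 4, 2))
  expect_identical(prox_tv_3d(v, 0), v)
  expect_error(prox_tv_3d(v, 1, tol = -1), "tol")

  pm <- prox_tv_3d(v, 1e5, n_inner = 5000L, tol = 1e-14)
  expect_lt(max(abs(pm - mean(v))), 1e-6)

  # two-level signal [0,0,4,4]: the jump shrinks by w/2 (delta = w/4 per side)
  w <- 0.6
  g <- array(c(0, 0, 4, 4), c(4, 1, 1))
  p <- prox_tv_3d(g, w, n_inner = 4000L, tol = 1e-14)
  expect_equal(as.numeric(p), c(w / 4, w / 4, 4 - w / 4, 4 - w / 4),
               tolerance = 1e-6)
  # brute force over two-piece candidates confirms the optimum
  obj <- function(d) w * (4 - 2 * d) + 4 * d^2
  expect_lt(obj(w / 4), min(obj(w / 4 + 0.01), obj(w / 4 - 0.01)))

  tr <- attr(prox_tv_3d(array(rnorm(64), c(4, 4, 4)), 0.5), "objective_trace")
  expect_true(all(diff(tr) <= 0))
})

test_that("TV and SVT proxes are nonexpansive on random pairs", {
  set.seed(45)
  for (k in 1:20) {
    a <- array(rnorm(36), c(4, 3, 3))
    b <- array(rnorm(36), c(4, 3, 3))
    pa <- prox_tv_3d(a, 0.5, n_inner = 400L)
    pb <- prox_tv_3d(b, 0.5, n_inner = 400L)
    expect_lte(sqrt(sum((pa - pb)^2)), sqrt(sum((a - b)^2)) * (1 + 1e-8))
    sa <- svt_mode3(a, 0.8); sb <- svt_mode3(b, 0.8)
    expect_lte(sqrt(sum((sa - sb)^2)), sqrt(sum((a - b)^2)) * (1 + 1e-8))
  }
})

test_that("the gradient L0 solver handles the canonical two-level signals", {
  g <- array(c(0, 0, 5, 5), c(4, 1, 1))
  expect_identical(solve_l0_gradient_3d(g, l0_solver_params(0)),
                   structure(g, energy = 0))
  # lambda = 100: merging wins, the energy-optimal solution is constant 2.5
  out <- solve_l0_gradient_3d(g, l0_solver_params(100))
  expect_equal(as.numeric(out), rep(2.5, 4), tolerance = 1e-9)
  expect_equal(attr(out, "energy"), 25, tolerance = 1e-9)
  # lambda = 1: keeping the jump (energy 1) beats the constant (energy 25)
  out <- solve_l0_gradient_3d(g, l0_solver_params(1))
  expect_equal(as.numeric(out), c(0, 0, 5, 5), tolerance = 1e-9)
  expect_equal(attr(out, "energy"), 1, tolerance = 1e-9)
  expect_error(solve_l0_gradient_3d(array(NaN, c(2, 1, 1)),
                                    l0_solver_params(1)), "finite")
  expect_error(l0_solver_params(1, kappa = 1), "kappa")
  expect_error(l0_solver_params(1, beta0 = 2, beta_max = 1), "beta_max")
})

test_that("L0 solver energy matches the exhaustive oracle on short multi-level signals", {
  set.seed(46)
  for (k in 1:20) {
    n <- sample(4:8, 1L)
    g <- sample(c(0, 2, 5), n, replace = TRUE)
    lambda <- sample(c(0.5, 2, 8, 40), 1L)
    out <- solve_l0_gradient_3d(array(g, c(n, 1, 1)), l0_solver_params(lambda))
    expect_lt(abs(attr(out, "energy") - potts_oracle_1d(g, lambda)), 1e-6)
  }
})

test_that("L0 solver never exceeds the energy of the input or the constant candidate", {
  set.seed(47)
  for (k in 1:8) {
    d <- c(sample(3:6, 1L), sample(3:6, 1L), sample(1:3, 1L))
    g <- array(rnorm(prod(d)), d) + array(rep(rnorm(d[3L]), each = d[1L] * d[2L]), d)
    lambda <- runif(1L, 0.05, 5)
    out <- solve_l0_gradient_3d(g, l0_solver_params(lambda))
    energy <- function(u) lambda * gradient_support_count(u) + sum((u - g)^2)
    e <- attr(out, "energy")
    expect_equal(e, energy(out), tolerance = 1e-10)
    expect_lte(e, energy(g) + 1e-12)
    expect_lte(e, energy(array(mean(g), d)) + 1e-12)
    expect_lte(gradient_support_count(out), gradient_support_count(g))
  }
})

test_that("mode-3 SVT matches a dense SVD oracle and never raises the rank", {
  set.seed(48)
  v <- array(rnorm(48), c(4, 4, 3))
  expect_lt(max(abs(svt_mode3(v, 0) - v)), 1e-10)

  for (k in 1:20) {
    v <- array(rnorm(48), c(4, 4, 3))
    th <- runif(1L, 0, 2)
    out <- svt_mode3(v, th)
    U <- t(matrix(v, 16, 3))
    sv <- svd(U)
    ref <- array(t(sv$u %*% (pmax(sv$d - th, 0) * t(sv$v))), c(4, 4, 3))
    expect_lt(max(abs(out - ref)), 1e-10)
    rk <- function(x) sum(svd(t(matrix(x, 16, 3)))$d > 1e-10)
    expect_lte(rk(out), rk(v))
  }

  # unfolding with singular values (3, 1), threshold 2 -> (1, 0), rank 1
  u1 <- c(1, 0, 0); u2 <- c(0, 1, 0)
  v1 <- rep(1 / 4, 16); v2 <- rep(c(1 / 4, -1 / 4), 8)
  U <- 3 * outer(u1, v1) + 1 * outer(u2, v2)
  vol <- array(t(U), c(4, 4, 3))
  out <- svt_mode3(vol, 2)
  d_out <- svd(t(matrix(out, 16, 3)))$d
  expect_equal(d_out, c(1, 0, 0), tolerance = 1e-10)
})

test_that("the mode-3 trace norm matches closed forms and the SVD oracle", {
  expect_equal(trace_norm_mode3(array(0, c(3, 3, 2))), 0)
  # identical channels, each of unit Frobenius norm -> rank one, sqrt(C)
  ch <- matrix(1 / 4, 4, 4)  # Frobenius norm 1
  vol <- array(rep(ch, 3), c(4, 4, 3))
  expect_equal(trace_norm_mode3(vol), sqrt(3), tolerance = 1e-12)
  set.seed(49)
  v <- array(rnorm(60), c(5, 4, 3))
  expect_equal(trace_norm_mode3(v), sum(svd(t(matrix(v, 20, 3)))$d),
               tolerance = 1e-12)
})
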