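test_that("intensity estimators reproduce hand and closed-form cases", {
  # symmetric soft partition of a constant image
  g <- voxel_grid(array(5, c(2, 3, 3)))
  cc <- estimate_intensities(g, array(0.5, c(2, 3, 3)))
  expect_equal(unname(cc), c(5, 5))

  # exact forward-model image with u == 1: c1 telescopes to the constant,
  # the background estimator has an empty phase
  dims <- c(6, 2, 2)
  img <- voxel_grid(array(10 * 0.9^(seq_len(6) - 1), dims))
  u1 <- array(1, dims)
  expect_error(estimate_intensities(img, u1, 0.9), "background")
  u_almost <- u1
  u_almost[6, , ] <- 0
  cc2 <- estimate_intensities(img, u_almost, 0.9)
  expect_equal(cc2[["c1"]], 10, tolerance = 1e-12)
  expect_equal(cc2[["c2"]], 10, tolerance = 1e-12)

  # hand evaluation on a 2-voxel column
  col <- voxel_grid(array(c(8, 2), c(1, 1, 2)))
  u <- array(c(1, 0), c(1, 1, 2))
  cc3 <- estimate_intensities(col, u, 1)
  expect_equal(unname(cc3), c(8, 2))

  # empty foreground is the symmetric degenerate case
  expect_error(estimate_intensities(col, array(0, c(1, 1, 2))), "foreground")
})

test_that("intensity estimators are exactly scale-covariant and reduce to region means at gamma = 1", {
  set.seed(11)
  dims <- c(4, 5, 6)
  I <- array(runif(prod(dims), 1, 20), dims)
  u <- array(runif(prod(dims)), dims)
  base <- estimate_intensities(voxel_grid(I), u, 0.93)
  for (s in c(0.5, 3, 117)) {
    scaled <- estimate_intensities(voxel_grid(s * I), u, 0.93)
    expect_equal(unname(scaled), s * unname(base), tolerance = 1e-12)
  }
  # gamma = 1: plain weighted region means (the classic two-phase estimators)
  cc <- estimate_intensities(voxel_grid(I), u, 1)
  expect_equal(cc[["c1"]], sum(u * I) / sum(u), tolerance = 1e-12)
  expect_equal(cc[["c2"]], sum((1 - u) * I) / sum(1 - u), tolerance = 1e-12)
})

test_that("residual field signs and values follow the two-phase misfit", {
  # perfect foreground fit: e_r = -(I - c2 g)^2 <= 0
  dims <- c(4, 2, 2)
  gpow <- 0.9^(seq_len(4) - 1)
  img <- voxel_grid(array(3 * gpow, dims))
  er <- residual_field(img, c1 = 3, c2 = 7, bias = 0.9)
  expect_equal(er, -(img$values - 7 * array(gpow, dims))^2, tolerance = 1e-12)
  expect_true(all(er <= 0))

  # equidistant voxel
  eq <- residual_field(voxel_grid(array(5, c(1, 1, 1))), 4, 6)
  expect_equal(as.vector(eq), 0)

  # hand arithmetic: (3-2)^2 - (3-5)^2 = -3
  h <- residual_field(voxel_grid(array(3, c(1, 1, 1))), 2, 5)
  expect_equal(as.vector(h), -3)
})

test_that("shrinkage annihilates below threshold, shrinks radially above, and is non-expansive", {
  expect_equal(shrink(c(0.1, 0, 0), 0.5), c(0, 0, 0))
  expect_equal(shrink(c(2, 0, 0), 0.5), c(1.5, 0, 0))
  expect_equal(shrink(c(3, 4, 0), 1), c(2.4, 3.2, 0), tolerance = 1e-12)
  expect_equal(shrink(c(0, 0, 0), 0), c(0, 0, 0))
  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(3, sd = 2)
    t <- runif(1, 0, 3)
    s <- shrink(v, t)
    expect_lte(sqrt(sum(s^2)), sqrt(sum(v^2)) + 1e-14)
    # direction preserved when nonzero
    if (any(s != 0)) {
      expect_equal(s / sqrt(sum(s^2)), v / sqrt(sum(v^2)), tolerance = 1e-10)
    }
  }
})

test_that("gauss_seidel_sweep has the expected fixed points and clamping", {
  params <- model_params(lambda = 2, mu = 4, max_outer = 5)
  dims <- c(3, 4, 5)
  st <- dcac:::new_solver_state(array(0.4, dims))
  # constant u, zero residual, zero d/b: phi is the mean of equal values
  out <- gauss_seidel_sweep(st, array(0, dims), params)
  expect_equal(out, array(0.4, dims), tolerance = 1e-15)
  # strongly positive residual with u = 0 stays clamped at 0
  st0 <- dcac:::new_solver_state(array(0, dims))
  er <- array(10 * params$mu / params$lambda, dims)
  expect_equal(gauss_seidel_sweep(st0, er, params), array(0, dims))
})

test_that("gauss_seidel_sweep matches a loop-based scalar reference exactly", {
  # the 1x1x3 hand case: one sweep of neighbour means under replicated edges
  p1 <- model_params(lambda = 1, mu = 1, inner_sweeps = 1L)
  st <- dcac:::new_solver_state(array(c(0, 1, 0), c(1, 1, 3)))
  got <- gauss_seidel_sweep(st, array(0, c(1, 1, 3)), p1)
  # hand execution: u1 = (4*0 + 0 + 1)/6; u2 = (4*1 + u1 + 0)/6;
  # u3 = (5*0 + u2)/6
  u1 <- 1 / 6
  u2 <- (4 + u1) / 6
  u3 <- u2 / 6
  expect_equal(as.vector(got), c(u1, u2, u3), tolerance = 1e-15)

  # randomized cases, with d/b fields feeding zeta, against the reference
  set.seed(21)
  for (i in 1:5) {
    dims <- c(3, 4, 5)
    n <- prod(dims)
    st <- dcac:::new_solver_state(array(runif(n), dims))
    st$d <- list(z = array(rnorm(n), dims), y = array(rnorm(n), dims),
                 x = array(rnorm(n), dims))
    st$b <- list(z = array(rnorm(n), dims), y = array(rnorm(n), dims),
                 x = array(rnorm(n), dims))
    er <- array(rnorm(n), dims)
    p <- model_params(lambda = runif(1, 0.5, 20), mu = runif(1, 0.5, 20),
                      inner_sweeps = sample(1:3, 1))
    zeta <- zeta_reference(st$d$z, st$d$y, st$d$x, st$b$z, st$b$y, st$b$x)
    ref <- gs_reference(st$u, zeta, er, p$lambda / p$mu, p$inner_sweeps)
    got <- gauss_seidel_sweep(st, er, p)
    expect_equal(got, ref, tolerance = 1e-13)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("bregman update accumulates the constraint violation", {
  dims <- c(1, 1, 2)
  st <- dcac:::new_solver_state(array(c(0, 1), dims))
  # d = grad(u) exactly: b unchanged
  st$d <- dcac:::fgrad(st$u)
  st$b <- list(z = array(0.2, dims), y = array(-0.1, dims),
               x = array(0.3, dims))
  b_before <- st$b
  expect_equal(bregman_update(st)$b, b_before, tolerance = 1e-15)

  # from zero, b accumulates grad(u)
  st2 <- dcac:::new_solver_state(array(c(0, 1), dims))
  expect_equal(bregman_update(st2)$b, dcac:::fgrad(st2$u), tolerance = 1e-15)

  # scalar hand case on one forward-difference link
  st3 <- dcac:::new_solver_state(array(c(0, 1), dims))
  st3$d$x[1, 1, 1] <- 0.3
  st3$b$x[1, 1, 1] <- 0.1
  upd <- bregman_update(st3)
  expect_equal(upd$b$x[1, 1, 1], 0.1 + 1 - 0.3, tolerance = 1e-15)
})

test_that("segmentation energy matches closed forms and the loop oracle", {
  p <- model_params(lambda = 3, mu = 3, bias = depth_bias(0.9))
  dims <- c(4, 3, 3)
  gpow <- array(0.9^(seq_len(4) - 1), dims)
  img <- voxel_grid(7 * gpow)

  # u == 1 on a perfectly fit image: zero energy
  expect_equal(segmentation_energy(img, array(1, dims), 7, 2, p), 0,
               tolerance = 1e-12)
  # constant fractional u: no TV, only the weighted fidelity terms
  u_c <- array(0.3, dims)
  expect_equal(segmentation_energy(img, u_c, 7, 2, p),
               3 * sum((img$values - 2 * gpow)^2 * (1 - u_c)),
               tolerance = 1e-12)

  # unit step on a 1x1x2 grid: TV = 1
  p0 <- model_params(lambda = 1, mu = 1)
  z2 <- voxel_grid(array(0, c(1, 1, 2)))
  expect_equal(segmentation_energy(z2, array(c(0, 1), c(1, 1, 2)), 0, 0, p0),
               1, tolerance = 1e-15)

  # 2D checkerboard: isotropic TV = 2 + sqrt(2) by hand
  z4 <- voxel_grid(array(0, c(1, 2, 2)))
  u4 <- array(c(0, 1, 1, 0), c(1, 2, 2))
  expect_equal(segmentation_energy(z4, u4, 0, 0, p0), 2 + sqrt(2),
               tolerance = 1e-12)

  # random volumes against the loop-based oracle
  set.seed(8)
  for (i in 1:4) {
    I <- array(runif(36), c(3, 4, 3))
    u <- array(runif(36), c(3, 4, 3))
    lam <- runif(1, 0.5, 5)
    pp <- model_params(lambda = lam, mu = lam, bias = depth_bias(0.92))
    expect_equal(segmentation_energy(voxel_grid(I), u, 0.8, 0.2, pp),
                 energy_oracle(I, u, 0.8, 0.2, lam, 0.92), tolerance = 1e-12)
  }
})

test_that("threshold_partition uses a strict inequality", {
  u <- array(0.5, c(2, 2, 2))
  expect_false(any(threshold_partition(u, 0.5)$values))
  u2 <- array(c(0, 0.2, 0.5, 0.7, 0, 0, 1, 0.4), c(2, 2, 2))
  expect_identical(threshold_partition(u2, 0)$values, array(u2 > 0, dim(u2)))
  u3 <- array(c(0.2, 0.5, 0.7), c(1, 1, 3))
  expect_identical(as.vector(threshold_partition(u3, 0.5)$values),
                   c(FALSE, FALSE, TRUE))
})

test_that("the solver recovers a noise-free two-phase phantom exactly", {
  ph <- small_phantom(geometry = "box", gamma = 1, sigma = 0)
  fit <- split_bregman_segment(ph$image)
  expect_true(fit$converged)
  expect_identical(fit$mask$values, ph$truth$values)
  expect_equal(fit$c1, 10, tolerance = 5e-3)
  expect_equal(fit$c2, 2, tolerance = 5e-3)
  expect_true(all(fit$u >= 0 & fit$u <= 1))
})

test_that("a constant image yields an unmixed mask, not an error", {
  g <- voxel_grid(array(4, c(4, 6, 6)))
  fit <- split_bregman_segment(g)
  expect_true(all(fit$mask$values) || !any(fit$mask$values))
})

test_that("hitting the iteration cap flags non-convergence without erroring", {
  ph <- small_phantom(geometry = "ellipsoid", sigma = 0.8, seed = 9)
  fit <- split_bregman_segment(median_smooth(ph$image),
                               model_params(max_outer = 2L))
  expect_false(fit$converged)
  expect_identical(fit$iterations, 2L)
  expect_s3_class(fit$mask, "binary_mask")
})

test_that("solver inputs thinner than 2 voxels per axis are rejected", {
  expect_error(split_bregman_segment(voxel_grid(array(1, c(1, 8, 8)))),
               "at least 2 voxels")
})
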