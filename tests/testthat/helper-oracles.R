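# Independent oracles used to cross-check the package implementation.
# Everything here is deliberately written with explicit loops or a different
# algorithm than the package code paths it checks.

# Loop-based isotropic discrete TV (forward differences, zero at the far
# edge of each axis).
tv_oracle <- function(u) {
  d <- dim(u)
  s <- 0
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    gz <- if (z < d[1]) u[z + 1, y, x] - u[z, y, x] else 0
    gy <- if (y < d[2]) u[z, y + 1, x] - u[z, y, x] else 0
    gx <- if (x < d[3]) u[z, y, x + 1] - u[z, y, x] else 0
    s <- s + sqrt(gz^2 + gy^2 + gx^2)
  }
  s
}

# Discrete two-phase energy with a depth bias, evaluated by loops.
energy_oracle <- function(I, u, c1, c2, lam, gamma = 1) {
  d <- dim(I)
  g <- array(gamma^(seq_len(d[1]) - 1), d)
  tv_oracle(u) + lam * sum((I - c1 * g)^2 * u) +
    lam * sum((I - c2 * g)^2 * (1 - u))
}

# Exhaustive minimum of the binary partition energy over all 2^n labelings.
brute_force_min_energy <- function(I, c1, c2, lam, gamma = 1) {
  n <- length(I)
  stopifnot(n <= 16)
  emin <- Inf
  for (k in 0:(2^n - 1)) {
    u <- array(as.numeric(bitwAnd(bitwShiftR(k, 0:(n - 1)), 1L)), dim(I))
    emin <- min(emin, energy_oracle(I, u, c1, c2, lam, gamma))
  }
  emin
}

# Scalar reference for the Gauss-Seidel sweep: explicit loops in
# lexicographic (z, y, x) order, replicated-edge neighbour reads, in-place
# updates, clamped to [0, 1]. zeta is precomputed by the caller.
gs_reference <- function(u, zeta, er, lam_over_mu, sweeps) {
  d <- dim(u)
  v <- u
  for (s in seq_len(sweeps)) {
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      nb <- v[max(z - 1, 1), y, x] + v[min(z + 1, d[1]), y, x] +
        v[z, max(y - 1, 1), x] + v[z, min(y + 1, d[2]), x] +
        v[z, y, max(x - 1, 1)] + v[z, y, min(x + 1, d[3])]
      phi <- (nb + zeta[z, y, x] - lam_over_mu * er[z, y, x]) / 6
      v[z, y, x] <- max(0, min(1, phi))
    }
  }
  v
}

# Loop-based exact-adjoint divergence of (b - d), the zeta source term:
# backward differences in the interior, component zero-padded before the
# first plane, the (always zero) last gradient slot ignored.
zeta_reference <- function(dz, dy, dx, bz, by, bx) {
  d <- dim(dz)
  w <- list(bz - dz, by - dy, bx - dx)
  out <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      i <- c(z, y, x)[ax]
      at <- function(j) {
        idx <- c(z, y, x)
        idx[ax] <- j
        w[[ax]][idx[1], idx[2], idx[3]]
      }
      val <- if (i == 1) at(1)
      else if (i < n) at(i) - at(i - 1)
      else -at(n - 1)
      out[z, y, x] <- out[z, y, x] + val
    }
  }
  out
}

# Loop-based exact median filter with replicated edges.
median_oracle <- function(a, radius) {
  d <- dim(a)
  out <- a
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- pmin(pmax((z - radius[1]):(z + radius[1]), 1), d[1])
    yy <- pmin(pmax((y - radius[2]):(y + radius[2]), 1), d[2])
    xx <- pmin(pmax((x - radius[3]):(x + radius[3]), 1), d[3])
    out[z, y, x] <- median(a[zz, yy, xx, drop = FALSE])
  }
  out
}

# Independent convex two-phase Chan-Vese solver: Chambolle-Pock primal-dual
# iteration on min_{u in [0,1]} TV(u) + lam * <e_r, u>, with the phase
# constants refreshed as plain region means. A different splitting than the
# package's Split Bregman path: dual variable projected onto the unit ball,
# no Bregman vector, no Gauss-Seidel.
cv_chambolle_pock <- function(I, lam, iters = 400, c_update_every = 20) {
  dims <- dim(I)
  fg <- function(a, ax) {
    n <- dims[ax]
    idx <- c(seq_len(n)[-1], n)
    (switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
            a[, , idx, drop = FALSE])) - a
  }
  adj_div <- function(p, ax) {
    n <- dims[ax]
    take <- function(i) switch(ax, p[i, , , drop = FALSE],
                               p[, i, , drop = FALSE], p[, , i, drop = FALSE])
    parts <- list(take(1L))
    if (n > 2) parts <- c(parts, list(take(2:(n - 1)) - take(1:(n - 2))))
    parts <- c(parts, list(-take(n - 1L)))
    out <- array(0, dims)
    at <- 1L
    for (q in parts) {
      m <- dim(q)[ax]
      idx <- at:(at + m - 1L)
      if (ax == 1) out[idx, , ] <- q
      else if (ax == 2) out[, idx, ] <- q
      else out[, , idx] <- q
      at <- at + m
    }
    out
  }
  u <- (I - min(I)) / max(1e-12, max(I) - min(I))
  ub <- u
  pz <- py <- px <- array(0, dims)
  tau <- 0.25
  sg <- 1 / 3
  c1 <- sum(u * I) / max(sum(u), 1e-9)
  c2 <- sum((1 - u) * I) / max(sum(1 - u), 1e-9)
  for (it in seq_len(iters)) {
    if (it %% c_update_every == 1) {
      c1 <- sum(u * I) / max(sum(u), 1e-9)
      c2 <- sum((1 - u) * I) / max(sum(1 - u), 1e-9)
    }
    er <- (I - c1)^2 - (I - c2)^2
    pz <- pz + sg * fg(ub, 1)
    py <- py + sg * fg(ub, 2)
    px <- px + sg * fg(ub, 3)
    nrm <- pmax(1, sqrt(pz^2 + py^2 + px^2))
    pz <- pz / nrm
    py <- py / nrm
    px <- px / nrm
    un <- u + tau * (adj_div(pz, 1) + adj_div(py, 2) + adj_div(px, 3)) -
      tau * lam * er
    un <- pmin(pmax(un, 0), 1)
    ub <- 2 * un - u
    u <- un
  }
  list(u = u, c1 = c1, c2 = c2)
}
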