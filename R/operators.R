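# Discrete differential operators on (z, y, x) arrays.
#
# Gradient: forward differences with replicated-edge (Neumann) boundary, so
# the last difference along each axis is 0. Divergence: backward differences
# with the first difference 0, the matching adjoint-style pair. Axis 1 = z,
# 2 = y, 3 = x.

take_along <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

fdiff <- function(a, axis) {
  n <- dim(a)[axis]
  if (n == 1L) return(array(0, dim(a)))
  take_along(a, axis, c(seq_len(n)[-1L], n)) - a
}

bdiff <- function(a, axis) {
  n <- dim(a)[axis]
  if (n == 1L) return(array(0, dim(a)))
  a - take_along(a, axis, c(1L, seq_len(n - 1L)))
}

# Forward gradient as a list of per-axis components, each shaped like u.
fgrad <- function(u) {
  list(z = fdiff(u, 1L), y = fdiff(u, 2L), x = fdiff(u, 3L))
}

# Divergence as the exact negative adjoint of the forward-difference,
# replicated-edge gradient: backward differences in the interior, with the
# component treated as zero outside the first plane and the (always-zero)
# gradient slot at the last plane ignored. Using the exact adjoint is what
# makes the Bregman fixed point the true constrained optimum, boundary
# voxels included.
adiff <- function(a, axis) {
  n <- dim(a)[axis]
  if (n == 1L) return(array(0, dim(a)))
  first <- take_along(a, axis, 1L)
  if (n == 2L) {
    out_last <- -first
    return(abind_axis(first, out_last, axis = axis))
  }
  interior <- take_along(a, axis, 2:(n - 1L)) -
    take_along(a, axis, 1:(n - 2L))
  last <- -take_along(a, axis, n - 1L)
  abind_axis(first, interior, last, axis = axis)
}

# Concatenate arrays along an axis (all conforming on the other two).
abind_axis <- function(..., axis) {
  parts <- list(...)
  dims <- lapply(parts, dim)
  total <- sum(vapply(dims, `[`, integer(1), axis))
  out_dim <- dims[[1]]
  out_dim[axis] <- total
  out <- array(0, out_dim)
  at <- 1L
  for (p in parts) {
    n <- dim(p)[axis]
    idx <- at:(at + n - 1L)
    if (axis == 1L) out[idx, , ] <- p
    else if (axis == 2L) out[, idx, ] <- p
    else out[, , idx] <- p
    at <- at + n
  }
  out
}

bdiv <- function(v) {
  adiff(v$z, 1L) + adiff(v$y, 2L) + adiff(v$x, 3L)
}

vec_sub <- function(a, b) list(z = a$z - b$z, y = a$y - b$y, x = a$x - b$x)
vec_add <- function(a, b) list(z = a$z + b$z, y = a$y + b$y, x = a$x + b$x)
zero_field <- function(dims) {
  z <- array(0, dims)
  list(z = z, y = z, x = z)
}

# Isotropic vector soft-threshold applied voxelwise to a 3-component field.
shrink_field <- function(v, t) {
  mag <- sqrt(v$z^2 + v$y^2 + v$x^2)
  scl <- ifelse(mag > t, (mag - t) / mag, 0)
  list(z = v$z * scl, y = v$y * scl, x = v$x * scl)
}

# Isotropic discrete total variation: sum over voxels of |grad u|.
tv_norm <- function(u) {
  g <- fgrad(u)
  sum(sqrt(g$z^2 + g$y^2 + g$x^2))
}
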