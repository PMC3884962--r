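#' 3D intensity volume with physical voxel spacing
#'
#' A `voxel_grid` holds a 3D array of non-negative intensities indexed
#' `(z, y, x)` together with the physical voxel spacing `(dz, dy, dx)` in
#' micrometres. Slice `z = 1` is the shallowest plane (closest to the
#' objective); imaging depth increases with `z`, which is the convention the
#' depth-dependent bias field `gamma^z` relies on.
#'
#' @param values numeric 3D array, dimensions `(nz, ny, nx)`, all entries
#'   finite and `>= 0`. A matrix is promoted to a single-slice volume.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in micrometres, all
#'   strictly positive. Defaults to the acquisition geometry of the cleared
#'   quail-heart scans this model was developed for: 12.9 um between slices,
#'   1.75 um in-plane.
#' @return An object of class `voxel_grid`.
#' @seealso [binary_mask()], [read_volume()]
#' @export
voxel_grid <- function(values, spacing = c(12.9, 1.75, 1.75)) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, dim(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("voxel intensities must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("voxel intensities must be non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values (dz, dy, dx) in um",
         call. = FALSE)
  }
  structure(list(values = values, spacing = spacing), class = "voxel_grid")
}

#' Binary segmentation mask over a voxel grid
#'
#' A `binary_mask` is a strictly two-valued (logical) 3D array with the same
#' `(z, y, x)` shape as the volume it segments, plus the voxel spacing it
#' inherits from that volume. Masks are what thresholding the relaxed
#' partition function produces and what the Dice and volumetry routines
#' consume.
#'
#' @param values logical 3D array (numeric input is accepted if strictly
#'   two-valued, and coerced via `!= min`). A matrix is promoted to a
#'   single-slice mask.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(12.9, 1.75, 1.75)) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, dim(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  if (!is.logical(values)) {
    u <- unique(as.vector(values))
    if (length(u) > 2L || anyNA(u)) {
      stop("mask values must be strictly two-valued", call. = FALSE)
    }
    values <- array(values != min(u) | (length(u) == 1L && u[1] != 0),
                    dim = dim(values))
  }
  if (anyNA(values)) stop("mask values must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values (dz, dy, dx) in um",
         call. = FALSE)
  }
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

# Coerce volume-like input (voxel_grid or bare array) to a voxel_grid.
as_voxel_grid <- function(x, spacing = c(12.9, 1.75, 1.75)) {
  if (inherits(x, "voxel_grid")) return(x)
  voxel_grid(x, spacing)
}

as_binary_mask <- function(x, spacing = c(12.9, 1.75, 1.75)) {
  if (inherits(x, "binary_mask")) return(x)
  binary_mask(x, spacing)
}

# Shape check used by the solver: every axis needs at least 2 voxels for the
# difference stencils to carry information.
check_solver_grid <- function(grid) {
  d <- dim(grid$values)
  if (any(d < 2L)) {
    stop("solver input needs at least 2 voxels along every axis; got ",
         paste(d, collapse = " x "), call. = FALSE)
  }
  invisible(grid)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_grid: %d slices x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz, dy, dx): %g x %g x %g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("binary_mask: %d slices x %d x %d voxels, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
dim.binary_mask <- function(x) dim(x$values)
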