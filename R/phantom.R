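# Synthetic volumes with exactly the statistical structure the segmentation
# model assumes: a binary geometry taking two intensity constants, multiplied
# by the depth decay gamma^z, plus additive zero-mean Gaussian noise, clipped
# at zero (intensities are non-negative counts; the clip slightly biases the
# noise at very low SNR, which is documented behaviour).

# Run expr with a private RNG stream seeded by `seed`, restoring the global
# RNG state afterwards so phantom generation never perturbs user simulations.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic test volume
#'
#' @param shape volume dimensions `(nz, ny, nx)`, each >= 2.
#' @param geometry foreground shape: `"box"` (centred box), `"ellipsoid"`
#'   (centred, semi-axes 0.35 of each extent), `"two_chamber"` (two
#'   ellipsoids joined by a channel — a cartoon of separated heart chambers),
#'   or `"sponge"` (ellipsoid minus random spherical holes, a stand-in for
#'   trabecular myocardium; not anatomically calibrated).
#' @param c1,c2 foreground / background intensity constants, non-negative
#'   and distinct. Defaults 10 and 2 give a 5:1 fluorescence contrast.
#' @param gamma depth decay constant in `(0, 1]` applied as `gamma^z`.
#' @param sigma standard deviation of the additive Gaussian noise, `>= 0`.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @param n_holes,hole_radius sponge geometry controls: number of spherical
#'   holes and their radius range as a fraction of the smallest semi-axis.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 64L, 64L),
                         geometry = c("box", "ellipsoid", "two_chamber",
                                      "sponge"),
                         c1 = 10, c2 = 2, gamma = 1, sigma = 0, seed = 1L,
                         n_holes = 12L, hole_radius = c(0.05, 0.15)) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 2L)) {
    stop("'shape' must be three integers >= 2", call. = FALSE)
  }
  if (c1 < 0 || c2 < 0 || c1 == c2) {
    stop("'c1' and 'c2' must be non-negative and distinct", call. = FALSE)
  }
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  structure(list(shape = shape, geometry = geometry, c1 = c1, c2 = c2,
                 gamma = gamma, sigma = sigma, seed = as.integer(seed),
                 n_holes = as.integer(n_holes),
                 hole_radius = as.numeric(hole_radius)),
            class = "phantom_spec")
}

# Normalized coordinates in [-1, 1] per axis, as (nz, ny, nx) arrays.
unit_coords <- function(shape) {
  ax <- lapply(shape, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  list(z = array(rep(ax[[1]], times = shape[2] * shape[3]), shape),
       y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape),
       x = array(rep(ax[[3]], each = shape[1] * shape[2]), shape))
}

phantom_geometry <- function(spec) {
  co <- unit_coords(spec$shape)
  m <- switch(spec$geometry,
    box = abs(co$z) <= 0.5 & abs(co$y) <= 0.5 & abs(co$x) <= 0.5,
    ellipsoid = (co$z / 0.7)^2 + (co$y / 0.7)^2 + (co$x / 0.7)^2 <= 1,
    two_chamber = {
      left  <- (co$z / 0.6)^2 + (co$y / 0.55)^2 + ((co$x + 0.45) / 0.4)^2 <= 1
      right <- (co$z / 0.6)^2 + (co$y / 0.55)^2 + ((co$x - 0.45) / 0.4)^2 <= 1
      channel <- abs(co$x) <= 0.5 & (co$z / 0.2)^2 + (co$y / 0.2)^2 <= 1
      left | right | channel
    },
    sponge = {
      body <- (co$z / 0.75)^2 + (co$y / 0.75)^2 + (co$x / 0.75)^2 <= 1
      rmin <- min(spec$hole_radius) * 0.75
      rmax <- max(spec$hole_radius) * 0.75
      holes <- with_private_seed(spec$seed + 1L, {
        lapply(seq_len(spec$n_holes), function(i) {
          c(ctr = stats::runif(3, -0.6, 0.6), r = stats::runif(1, rmin, rmax))
        })
      })
      for (h in holes) {
        body <- body & ((co$z - h[1])^2 + (co$y - h[2])^2 +
                          (co$x - h[3])^2 > h[4]^2)
      }
      body
    })
  array(m, spec$shape)
}

#' Apply the forward image-formation model to a mask
#'
#' Builds `(c1 if foreground else c2) * gamma^z + N(0, sigma)`, clipped at
#' zero, over an arbitrary binary geometry. This is the image the
#' segmentation model assumes, so it is the natural ground-truth generator
#' for calibration and testing.
#'
#' @param mask a [binary_mask()] (or logical array): the true geometry.
#' @param c1,c2 foreground / background intensity constants.
#' @param gamma depth decay in `(0, 1]`.
#' @param sigma Gaussian noise standard deviation, `>= 0`.
#' @param seed integer seed (same seed, same volume, bit for bit).
#' @return A [voxel_grid()] with the mask's spacing.
#' @export
degrade_with_depth <- function(mask, c1, c2, gamma, sigma, seed = 1L) {
  mask <- as_binary_mask(mask)
  dims <- dim(mask$values)
  g <- bias_field(depth_bias(gamma), dims)
  ideal <- ifelse(mask$values, c1, c2) * g
  img <- if (sigma > 0) {
    noise <- with_private_seed(seed, stats::rnorm(length(ideal), 0, sigma))
    ideal + array(noise, dims)
  } else {
    ideal
  }
  voxel_grid(array(pmax(img, 0), dims), mask$spacing)
}

#' Generate a synthetic volume and its ground-truth mask
#'
#' Realizes the forward model of [phantom_spec()]: the chosen geometry takes
#' intensity `c1` (foreground) or `c2` (background), both attenuated by
#' `gamma^z`, with additive zero-mean Gaussian noise clipped at zero.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel spacing attached to the outputs.
#' @return A list with `image` (a [voxel_grid()]) and `truth`
#'   (a [binary_mask()]).
#' @export
generate_phantom <- function(spec, spacing = c(12.9, 1.75, 1.75)) {
  if (!inherits(spec, "phantom_spec")) {
    stop("'spec' must be a phantom_spec", call. = FALSE)
  }
  geom <- phantom_geometry(spec)
  n_fg <- sum(geom)
  if (n_fg == 0L || n_fg == length(geom)) {
    stop("phantom geometry produced an empty ",
         if (n_fg == 0L) "foreground" else "background",
         " phase; enlarge the volume or adjust the geometry", call. = FALSE)
  }
  truth <- binary_mask(geom, spacing)
  image <- degrade_with_depth(truth, spec$c1, spec$c2, spec$gamma,
                              spec$sigma, spec$seed)
  list(image = image, truth = truth)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %s, %d x %d x %d, c1 = %g, c2 = %g, gamma = %g, sigma = %g, seed = %d\n",
    x$geometry, x$shape[1], x$shape[2], x$shape[3], x$c1, x$c2, x$gamma,
    x$sigma, x$seed))
  invisible(x)
}
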