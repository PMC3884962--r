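#' Segmentation model parameters
#'
#' Bundles the weights and solver controls of the depth-corrected convex
#' active contour model. The energy is
#' `TV(u) + lambda * sum((I - c1 g)^2 u) + lambda * sum((I - c2 g)^2 (1 - u))`
#' with `g = gamma^z`, minimized over the relaxed partition `u` in `[0, 1]`
#' by Split Bregman with constraint weight `mu` on `d = grad(u)`.
#'
#' Defaults are calibrated for intensities normalized to a unit scale, which
#' the solver applies internally (see [split_bregman_segment()]): `lambda`
#' balances unit-order squared residuals against a TV term of order boundary
#' area, and `mu = lambda` makes the shrinkage threshold `1/mu` equal the
#' literal `1/lambda` form, so the two published readings coincide.
#'
#' @param lambda data-fidelity weight, `> 0`.
#' @param mu Split Bregman constraint weight, `> 0`.
#' @param bias a [depth_bias()] or bare `gamma` in `(0, 1]`.
#' @param alpha mask threshold in `[0, 1]`; the mask is `{u > alpha}`
#'   (strict). 0.5 follows the published choice.
#' @param max_outer maximum outer (Bregman) iterations.
#' @param inner_sweeps Gauss-Seidel sweeps per outer iteration.
#' @param tol relative L1-change stopping threshold on `u`.
#' @param shrink_threshold `"mu"` (default) applies soft-threshold `1/mu`,
#'   the value that exactly minimizes the decoupled `d`-subproblem with
#'   constraint weight `mu`; `"lambda"` is a compatibility mode using
#'   `1/lambda` (identical when `mu == lambda`).
#' @return An object of class `model_params`.
#' @export
model_params <- function(lambda = 10, mu = 10, bias = depth_bias(1),
                         alpha = 0.5, max_outer = 200L, inner_sweeps = 1L,
                         tol = 1e-3, shrink_threshold = c("mu", "lambda")) {
  shrink_threshold <- match.arg(shrink_threshold)
  stopifnot_scalar <- function(x, nm, lo, hi = Inf, strict_lo = TRUE) {
    if (length(x) != 1L || !is.finite(x) ||
        (if (strict_lo) x <= lo else x < lo) || x > hi) {
      stop("'", nm, "' out of range", call. = FALSE)
    }
  }
  stopifnot_scalar(lambda, "lambda", 0)
  stopifnot_scalar(mu, "mu", 0)
  stopifnot_scalar(alpha, "alpha", 0, 1, strict_lo = FALSE)
  stopifnot_scalar(tol, "tol", 0)
  max_outer <- as.integer(max_outer)
  inner_sweeps <- as.integer(inner_sweeps)
  if (is.na(max_outer) || max_outer < 1L) stop("'max_outer' must be >= 1", call. = FALSE)
  if (is.na(inner_sweeps) || inner_sweeps < 1L) stop("'inner_sweeps' must be >= 1", call. = FALSE)
  structure(list(lambda = lambda, mu = mu, bias = as_depth_bias(bias),
                 alpha = alpha, max_outer = max_outer,
                 inner_sweeps = inner_sweeps, tol = tol,
                 shrink_threshold = shrink_threshold),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:\n")
  cat(sprintf("  lambda = %g, mu = %g, gamma = %g, alpha = %g\n",
              x$lambda, x$mu, x$bias$gamma, x$alpha))
  cat(sprintf("  max_outer = %d, inner_sweeps = %d, tol = %g, shrink on 1/%s\n",
              x$max_outer, x$inner_sweeps, x$tol, x$shrink_threshold))
  invisible(x)
}
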