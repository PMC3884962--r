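#' Depth-dependent intensity bias field
#'
#' Fluorescence intensity in confocal stacks falls off with imaging depth
#' (scattering and absorption along the optical path). The model captures
#' this with a multiplicative bias field `gamma^z`, where `z` is the slice
#' index counted from the shallowest plane (`z = 0` at slice 1) and
#' `gamma` in `(0, 1]` is the per-slice decay constant. `gamma = 1` means no
#' fall-off and recovers the classic piecewise-constant (Chan-Vese) model.
#'
#' @param gamma per-slice decay constant in `(0, 1]`.
#' @return An object of class `depth_bias`.
#' @seealso [bias_at()], [fit_gamma()] for calibrating `gamma` from data.
#' @export
depth_bias <- function(gamma = 1) {
  gamma <- as.numeric(gamma)
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0 || gamma > 1) {
    stop("'gamma' must be a single value in (0, 1]", call. = FALSE)
  }
  structure(list(gamma = gamma), class = "depth_bias")
}

as_depth_bias <- function(x) {
  if (inherits(x, "depth_bias")) return(x)
  depth_bias(x)
}

#' Bias field value at a given depth
#'
#' @param bias a [depth_bias()] (or bare numeric `gamma`).
#' @param z slice depth(s), non-negative integers; `z = 0` is the shallowest
#'   slice.
#' @return `gamma^z`, in `(0, 1]` and non-increasing in `z`.
#' @export
bias_at <- function(bias, z) {
  bias <- as_depth_bias(bias)
  z <- as.numeric(z)
  if (any(z < 0) || any(z != floor(z))) {
    stop("'z' must be non-negative integer slice depths", call. = FALSE)
  }
  bias$gamma^z
}

# gamma^z replicated over a (nz, ny, nx) grid; depth 0 at slice 1.
bias_field <- function(bias, dims) {
  bias <- as_depth_bias(bias)
  prof <- bias$gamma^(seq_len(dims[1]) - 1)
  array(prof, dim = dims)  # z is the fastest index, so recycling fills slices
}

#' @export
print.depth_bias <- function(x, ...) {
  cat(sprintf("depth_bias: gamma = %g (bias at slice z: gamma^z)\n", x$gamma))
  invisible(x)
}
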