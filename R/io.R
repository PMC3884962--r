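#' Read a multi-page TIFF stack as a voxel grid
#'
#' Pages are stacked in file order along the depth axis, so page 1 becomes
#' slice `z = 1` (the shallowest plane). Integer sample types are returned as
#' their exact stored values — no rescaling to \[0, 1\] ever happens, so the
#' intensities the solver sees are the intensities the microscope wrote.
#' Float TIFFs (written by other tools) are read with their stored sample
#' values.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres. TIFF spacing
#'   metadata is unreliable across dialects, so the caller-supplied value is
#'   always the source of truth.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, spacing = c(12.9, 1.75, 1.75)) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      if (grepl("floating point", conditionMessage(e), fixed = TRUE)) {
        tiff::readTIFF(path, all = TRUE)
      } else {
        stop("could not read '", path, "' as a TIFF stack: ",
             conditionMessage(e), call. = FALSE)
      }
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) {
    stop("'", path, "' contains no image pages", call. = FALSE)
  }
  for (i in seq_along(pages)) {
    di <- dim(pages[[i]])
    if (length(di) == 3L && di[3] == 1L) {
      pages[[i]] <- pages[[i]][, , 1L]
      di <- dim(pages[[i]])
    }
    if (length(di) != 2L) {
      stop("page ", i, " of '", path, "' is not single-channel grayscale ",
           "(found ", di[length(di)], " channels); convert upstream",
           call. = FALSE)
    }
  }
  ref <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), ref)) {
      stop("page ", i, " of '", path, "' has shape ",
           paste(dim(pages[[i]]), collapse = " x "),
           ", expected ", paste(ref, collapse = " x "), call. = FALSE)
    }
  }
  nz <- length(pages)
  vol <- array(0, dim = c(nz, ref[1], ref[2]))
  for (z in seq_len(nz)) vol[z, , ] <- pages[[z]]
  voxel_grid(vol, spacing)
}

#' Read a TIFF stack as a binary mask
#'
#' Reads with [read_volume()] and thresholds strictly above zero, the
#' convention [write_mask()] uses (`{0, 255}` samples), so a written mask
#' reads back bit-exactly.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, spacing = c(12.9, 1.75, 1.75)) {
  grid <- read_volume(path, spacing)
  binary_mask(array(grid$values > 0, dim = dim(grid$values)), spacing)
}

#' Write a binary mask as an 8-bit TIFF stack
#'
#' Background voxels are stored as 0 and foreground as 255; page order is
#' depth order. Reading the file back and thresholding at `> 0` reproduces
#' the mask bit-exactly.
#'
#' @param mask a [binary_mask()] (or logical array).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  d <- dim(mask$values)
  pages <- lapply(seq_len(d[1]), function(z) {
    matrix(as.numeric(mask$values[z, , ]), d[2], d[3])
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                 error = function(e) {
                   stop("could not write mask to '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  invisible(path)
}

#' Write a voxel grid as an integer TIFF stack
#'
#' Samples are rounded to the nearest integer and stored at the requested
#' bit depth, which is the form real microscope exports take. Values must
#' fit the sample type (`0 .. 2^bits - 1`); nothing is rescaled.
#'
#' @param grid a [voxel_grid()] (or numeric array).
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, bits = 16L) {
  grid <- as_voxel_grid(grid)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16", call. = FALSE)
  top <- 2^bits - 1
  v <- round(grid$values)
  if (any(v > top)) {
    stop("intensities exceed the ", bits, "-bit sample range (max ",
         max(v), " > ", top, ")", call. = FALSE)
  }
  d <- dim(v)
  pages <- lapply(seq_len(d[1]), function(z) {
    matrix(v[z, , ] / top, d[2], d[3])
  })
  tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
           error = function(e) {
             stop("could not write volume to '", path, "': ",
                  conditionMessage(e), call. = FALSE)
           })
  invisible(path)
}
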