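#' Grid geometry helpers and statistical volume maps
#'
#' A `vol_map` holds one 3D statistical image (beta, t or p values) on the
#' dataset's common voxel grid, together with its affine and analysis mask.
#' Values are defined exactly on the mask; off-mask voxels are `NA`.
#'
#' @param values numeric vector of in-mask values (in mask linear-index
#'   order) or a full 3D array.
#' @param mask logical 3D array marking analysis voxels.
#' @param affine 4x4 voxel-to-world (RAS, mm) matrix.
#' @param kind one of `"beta"`, `"t"`, `"p"`.
#' @return object of class `vol_map`.
#' @export
vol_map <- function(values, mask, affine, kind = c("beta", "t", "p")) {
  kind <- match.arg(kind)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  arr <- array(NA_real_, dim(mask))
  if (is.array(values) && length(dim(values)) == 3L) {
    stopifnot(all(dim(values) == dim(mask)))
    arr[mask] <- values[mask]
  } else {
    stopifnot(length(values) == sum(mask))
    arr[mask] <- values
  }
  structure(list(values = arr, mask = mask, affine = affine, kind = kind),
            class = "vol_map")
}

#' @export
print.vol_map <- function(x, ...) {
  cat(sprintf("<vol_map [%s]> grid %s, %d in-mask voxels\n", x$kind,
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Default scanner affine for an isotropic grid
#'
#' RAS affine placing the grid centre at the world origin, `voxel_size` mm
#' isotropic, 0-based voxel indices.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size edge length in mm (default 3).
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid_shape, voxel_size = 3) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  aff
}

# world mm coordinates of 0-based voxel indices (n x 3 matrix or vector)
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

# mm -> nearest 0-based voxel index
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  round(t(solve(affine[1:3, 1:3]) %*% (t(xyz) - affine[1:3, 4])))
}

# linear index (1-based) <-> 0-based ijk for a given grid
index_to_ijk <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  i <- idx0 %% grid_shape[1]
  j <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  k <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(i, j, k)
}

ijk_to_index <- function(ijk, grid_shape) {
  ijk <- matrix(ijk, ncol = 3)
  1L + ijk[, 1] + grid_shape[1] * (ijk[, 2] + grid_shape[2] * ijk[, 3])
}

#' Gaussian spatial smoothing of a 4D BOLD array
#'
#' Separable isotropic Gaussian kernel, specified by its full width at half
#' maximum in mm. `fwhm = 0` returns the input unchanged (the unit-test
#' off-switch).
#'
#' @param bold 4D array (x, y, z, time).
#' @param fwhm kernel FWHM in mm.
#' @param voxel_size voxel edge length in mm.
#' @return smoothed array of the same dimensions.
#' @export
smooth_bold <- function(bold, fwhm = 8, voxel_size = 3) {
  stopifnot(length(dim(bold)) == 4L, fwhm >= 0)
  if (fwhm == 0) return(bold)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size   # in voxels
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  dm <- dim(bold)
  # convolve along one margin of a 3D array, replicate-padding the edges
  conv_axis <- function(arr, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                 m[rep(d[1], half), , drop = FALSE])
    out <- stats::filter(pad, kern, sides = 2)
    out <- out[(half + 1):(half + d[1]), , drop = FALSE]
    aperm(array(out, d), order(perm))
  }
  for (tt in seq_len(dm[4])) {
    v <- bold[, , , tt, drop = FALSE]
    dim(v) <- dm[1:3]
    for (ax in 1:3) v <- conv_axis(v, ax)
    bold[, , , tt] <- v
  }
  bold
}
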