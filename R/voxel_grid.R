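#' Define a voxel grid
#'
#' Regular 3-D grid in patient coordinates (mm), voxel-center convention:
#' the center of voxel (i, j, k) (1-based) sits at
#' `origin + (i-1, j-1, k-1) * spacing`.  Axis convention throughout the
#' package: x lateral, y longitudinal (cranio-caudal), z depth, with the skin
#' surface at z = 0 and tissue at z > 0.
#'
#' @param origin numeric(3), mm; center of the first voxel.
#' @param spacing numeric(3), mm; default 1 x 1 mm in-plane, 2.5 mm slice.
#' @param shape integer(3), number of voxels per axis.
#' @return A `voxel_grid` object.
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(1, 1, 2.5), c(10, 10, 4))
#' voxel_volume_cc(g)
#' @export
voxel_grid <- function(origin, spacing = c(1, 1, 2.5), shape) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (any(shape <= 0)) stop("grid shape must be positive")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = "/"), "mm, origin",
      paste(round(x$origin, 2), collapse = ", "), "mm\n")
  invisible(x)
}

#' Voxel volume in cc
#' @param grid a [voxel_grid()].
#' @return Volume of one voxel in cm^3.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' Coordinates of all voxel centers
#'
#' @param grid a [voxel_grid()].
#' @return An n x 3 matrix of voxel-center coordinates (mm), in column-major
#'   (x fastest) order matching a flattened array of dim `grid$shape`.
#' @export
grid_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  cbind(rep(xs, times = grid$shape[2] * grid$shape[3]),
        rep(rep(ys, each = grid$shape[1]), times = grid$shape[3]),
        rep(zs, each = grid$shape[1] * grid$shape[2]))
}

#' Number of voxels
#' @param grid a [voxel_grid()].
#' @export
n_voxels <- function(grid) prod(grid$shape)

as_mask_array <- function(mask, grid) array(mask, dim = grid$shape)

#' Mask volume in cc
#' @param mask logical vector/array over the grid.
#' @param grid a [voxel_grid()].
#' @export
mask_volume_cc <- function(mask, grid) sum(mask) * voxel_volume_cc(grid)
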