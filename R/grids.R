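#' Volume grid: shape, affine and voxel dimensions
#'
#' A `volume_grid` describes the sampling grid shared by every volume in a
#' case: the array shape in voxels and the 4x4 affine mapping 0-based voxel
#' indices to world millimetres (RAS orientation; world x > 0 is the right
#' hemisphere). All volumes participating in one analysis must live on one
#' grid; the package never resamples.
#'
#' @param shape integer vector of length 3, voxels per axis (all > 0).
#' @param affine 4x4 numeric voxel-to-mm transform; must be invertible.
#' @return An object of class `volume_grid` with fields `shape`, `affine`
#'   and `voxel_dims` (mm per axis, derived from the affine columns).
#' @examples
#' g <- volume_grid(c(64, 64, 64))
#' g$voxel_dims
#' @export
volume_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("`shape` must be 3 positive integers")
  affine <- unclass(as.matrix(affine))
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("`affine` is not invertible")
  voxel_dims <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_dims <= 0)) stop("voxel dimensions must be positive")
  structure(
    list(shape = shape, affine = affine, voxel_dims = voxel_dims),
    class = "volume_grid"
  )
}

#' Are two grids the same sampling grid?
#'
#' Compatibility means equal shapes and affines equal element-wise within an
#' absolute tolerance (default 1e-4 mm). Compatibility at tolerance zero is
#' an equivalence relation; at any tolerance it is symmetric.
#'
#' @param a,b `volume_grid` objects.
#' @param tol absolute tolerance on affine entries, in mm.
#' @return `TRUE` or `FALSE`.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_dims, 4), collapse = "x")))
  invisible(x)
}

# volume of one voxel in mm^3 (parallelepiped spanned by the affine columns)
voxel_volume_mm3 <- function(grid) {
  abs(det(grid$affine[1:3, 1:3]))
}

# world-x coordinate (mm, RAS) for 1-based array indices along dim 1..3;
# used for hemisphere attribution. `idx` is an n x 3 matrix of 1-based indices.
world_coords <- function(grid, idx) {
  v0 <- cbind(idx - 1, 1)            # 0-based homogeneous voxel coords
  t(grid$affine %*% t(v0))[, 1:3, drop = FALSE]
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!grids_compatible(a, b))
    stop(sprintf("%s are on incompatible grids; resampling is not supported",
                 what))
  invisible(TRUE)
}
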