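#' @useDynLib bundleseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames quantile sd var pf qf wilcox.test p.adjust lm coef
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Flat index helpers for (X, Y, Z) column-major arrays (0-based voxel coords)
#' @noRd
as_int_dims <- function(x) as.integer(dim(x))

# voxel-center grid coordinates (0-based) of a 3D array
grid_coords <- function(dims) {
  as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1), z = 0:(dims[3] - 1)))
}

# apply a 4x4 affine to n x 3 zero-based voxel coordinates -> world mm
voxel_to_world <- function(vox, affine) {
  p <- cbind(vox, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}

world_to_voxel <- function(world, affine) {
  p <- cbind(world, 1) %*% t(solve(affine))
  p[, 1:3, drop = FALSE]
}

# rotation part of an affine with voxel scaling removed
affine_rotation <- function(affine) {
  R <- affine[1:3, 1:3]
  sweep(R, 2, sqrt(colSums(R^2)), "/")
}

minmax_norm <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < .Machine$double.eps) return(array(0, dim(x)))
  (x - r[1]) / (r[2] - r[1])
}
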