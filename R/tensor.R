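#' Fit the diffusion tensor by log-linear least squares
#'
#' Ordinary least squares in log-signal space under the single-tensor model
#' \eqn{S_g = S_0 \exp(-b\, g^T D g)}. Signals are floored at
#' \code{1e-6 * S0} before the log so zero/negative samples cannot poison the
#' fit; voxels whose signal is entirely non-positive (or non-finite) are
#' flagged invalid rather than silently zeroed.
#'
#' @param dwi a [dwi_volume()].
#' @param mask optional 3D logical array restricting the fit.
#' @return A `tensor_field`: `coef` (X,Y,Z,6) with the six unique tensor
#'   coefficients (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz; mm^2/s) and `valid` (3D
#'   logical).
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  b <- dwi$bvals
  g <- dwi$bvecs
  dwis <- b > dwi$b0_threshold
  gd <- g[, dwis, drop = FALSE]
  # require >= 6 distinct non-collinear directions: rank of the quadratic-form
  # design must be 6
  Xq_d <- t(rbind(gd[1, ]^2, 2 * gd[1, ] * gd[2, ], 2 * gd[1, ] * gd[3, ],
                  gd[2, ]^2, 2 * gd[2, ] * gd[3, ], gd[3, ]^2))
  if (sum(dwis) < 6 || qr(Xq_d)$rank < 6)
    stopf("tensor fit needs >= 6 non-collinear b>0 directions (have rank %d)",
          if (sum(dwis) >= 1) qr(Xq_d)$rank else 0L)
  # all volumes (b0 included) enter the fit; b0 rows pin the intercept
  Xq <- t(rbind(g[1, ]^2, 2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
                g[2, ]^2, 2 * g[2, ] * g[3, ], g[3, ]^2))
  X <- cbind(1, -sweep(Xq, 1, b, "*"))
  # one shared projector for all voxels (same gradient scheme everywhere)
  P <- solve(crossprod(X), t(X))
  sig <- matrix(dwi$data, prod(d[1:3]), d[4])
  idx <- which(mask)
  s0 <- rowMeans(sig[idx, !dwis, drop = FALSE])
  valid_v <- is.finite(s0) & s0 > 0
  S <- sig[idx, , drop = FALSE]
  floor_v <- pmax(s0, .Machine$double.xmin) * 1e-6
  S <- pmax(S, floor_v)
  logS <- log(S)
  beta <- logS %*% t(P)                       # n x 7 (log S0, 6 coefficients)
  coef <- array(0, c(d[1:3], 6))
  cm <- matrix(coef, ncol = 6)
  cm[idx, ] <- beta[, 2:7]
  cm[idx[!valid_v], ] <- 0
  coef <- array(cm, c(d[1:3], 6))
  valid <- array(FALSE, d[1:3])
  valid[idx] <- valid_v
  structure(list(coef = coef, valid = valid, affine = dwi$affine),
            class = "tensor_field")
}

# eigenvalues (clamped >= 0, sorted descending) and V1 for all voxels
tensor_eigen <- function(tf) {
  d <- dim(tf$coef)
  e <- cpp_eig3_sym(matrix(tf$coef, ncol = 6))
  e$evals <- pmax(e$evals, 0)
  e
}

#' Diffusion tensor scalar maps
#'
#' Eigenvalues are clamped at zero before any scalar is derived. With sorted
#' eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}:
#' FA = \eqn{\sqrt{3/2}\,\|\lambda - \bar\lambda\| / \|\lambda\|}, MD =
#' \eqn{\bar\lambda}, AD = \eqn{\lambda_1}, RD = \eqn{(\lambda_2+\lambda_3)/2}.
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @param which one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @return 3D scalar array; invalid voxels are 0 (and remain flagged in `tf`).
#' @export
tensor_scalars <- function(tf, which = c("FA", "MD", "AD", "RD")) {
  which <- match.arg(which)
  d <- dim(tf$coef)[1:3]
  ev <- tensor_eigen(tf)$evals
  out <- switch(which,
    FA = {
      mn <- rowMeans(ev)
      num <- sqrt(rowSums((ev - mn)^2))
      den <- sqrt(rowSums(ev^2))
      fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
      pmin(pmax(fa, 0), 1)
    },
    MD = rowMeans(ev),
    AD = ev[, 1],
    RD = (ev[, 2] + ev[, 3]) / 2
  )
  out[!tf$valid] <- 0
  array(out, d)
}

#' Principal diffusion direction (V1)
#'
#' Per-voxel principal eigenvector, sign-canonicalized so the first nonzero
#' component is non-negative. Voxels with near-degenerate leading eigenvalues
#' (\eqn{\lambda_1 \approx \lambda_2}) are flagged unreliable and zeroed.
#'
#' @param tf a `tensor_field`.
#' @param degeneracy_tol relative \eqn{(\lambda_1-\lambda_2)/\lambda_1} below
#'   which a direction is considered unreliable.
#' @return list with `v1` (X,Y,Z,3 array) and `reliable` (3D logical).
#' @export
principal_direction <- function(tf, degeneracy_tol = 1e-3) {
  d <- dim(tf$coef)[1:3]
  e <- tensor_eigen(tf)
  v <- e$v1
  # sign canonicalization: first component with |.| > tol must be >= 0
  s <- sign(v[, 1])
  use2 <- abs(v[, 1]) < 1e-12
  s[use2] <- sign(v[use2, 2])
  use3 <- use2 & abs(v[, 2]) < 1e-12
  s[use3] <- sign(v[use3, 3])
  s[s == 0] <- 1
  v <- v * s
  l1 <- e$evals[, 1]
  reliable <- tf$valid & array(l1 > 0 & (l1 - e$evals[, 2]) / pmax(l1, 1e-300) > degeneracy_tol, d)
  v[!reliable, ] <- 0
  list(v1 = array(v, c(d, 3)), reliable = reliable)
}

#' Mean low-b (b ~ 0) image
#'
#' Voxelwise mean across all volumes with b at or below the b0 threshold.
#'
#' @param dwi a [dwi_volume()].
#' @return 3D scalar array.
#' @export
extract_lowb <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  b0 <- which(dwi$bvals <= dwi$b0_threshold)
  d <- dim(dwi$data)
  if (length(b0) == 1L) return(array(dwi$data[, , , b0], d[1:3]))
  array(rowMeans(matrix(dwi$data[, , , b0], prod(d[1:3]), length(b0))), d[1:3])
}

#' Resample and crop channels into the network frame
#'
#' Resamples each channel onto an axis-aligned isotropic grid of
#' `size^3` voxels at `spacing` mm centered on `center_mm` (world
#' coordinates). Scalar channels are interpolated trilinearly, label maps with
#' nearest neighbor; out-of-field voxels are zero filled. A warning is issued
#' when the crop window extends beyond the source field of view by more than
#' 50% of its voxels.
#'
#' @param channels named list of 3D arrays sharing one source frame.
#' @param affine 4x4 voxel-to-world matrix of the source frame.
#' @param center_mm length-3 world coordinate of the crop center (e.g. the
#'   pons mask center of mass, see [mask_center_mm()]).
#' @param size output grid edge length in voxels.
#' @param spacing output voxel size in mm.
#' @param nearest character vector naming channels to resample with nearest
#'   neighbor (label maps).
#' @return list with `channels` (named list of `size^3` arrays) and `affine`
#'   of the cropped frame.
#' @export
resample_crop <- function(channels, affine, center_mm, size = 64L, spacing = 1.0,
                          nearest = character()) {
  stopifnot(is.list(channels), length(channels) > 0)
  src_dims <- dim(channels[[1]])
  half <- spacing * (size - 1) / 2
  origin <- center_mm - half
  out_affine <- diag(c(spacing, spacing, spacing, 1))
  out_affine[1:3, 4] <- origin
  tgt <- grid_coords(c(size, size, size))
  world <- sweep(tgt * spacing, 2, origin, "+")
  src <- world_to_voxel(world, affine)
  oob <- src[, 1] < -0.5 | src[, 2] < -0.5 | src[, 3] < -0.5 |
    src[, 1] > src_dims[1] - 0.5 | src[, 2] > src_dims[2] - 0.5 | src[, 3] > src_dims[3] - 0.5
  if (mean(oob) > 0.5)
    warnf("crop window exceeds the source field of view (%.0f%% out of field); zero filling",
          100 * mean(oob))
  out <- lapply(names(channels) %||% seq_along(channels), function(nm) {
    ch <- channels[[nm]]
    mode <- if (nm %in% nearest) 1L else 0L
    v <- cpp_sample3d(as.double(ch), as_int_dims(ch), src, mode, 0.0)
    v[oob] <- 0
    array(v, c(size, size, size))
  })
  names(out) <- names(channels)
  list(channels = out, affine = out_affine)
}

#' Center of mass of a binary mask, in world mm
#' @param mask 3D array (nonzero = inside).
#' @param affine 4x4 voxel-to-world matrix.
#' @export
mask_center_mm <- function(mask, affine) {
  idx <- which(mask > 0, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stopf("mask is empty")
  colMeans(voxel_to_world(idx, affine))
}

#' Assemble the five-channel network input
#'
#' Channel order (low-b, FA, PFM1, PFM2, PFM3). Low-b and each PFM channel are
#' min-max normalized to [0, 1] inside the crop; FA is left as-is (already in
#' [0, 1]).
#'
#' @param lowb,fa 3D arrays in the cropped frame.
#' @param pfm 4D array (x, y, z, 3) in the cropped frame.
#' @param affine affine of the cropped frame.
#' @return a `channel_stack`: `data` (X,Y,Z,5), `affine`.
#' @export
channel_stack <- function(lowb, fa, pfm, affine = diag(4)) {
  d <- dim(lowb)
  stopifnot(identical(dim(fa), d), identical(dim(pfm)[1:3], d), dim(pfm)[4] == 3)
  data <- array(0, c(d, 5))
  data[, , , 1] <- minmax_norm(lowb)
  data[, , , 2] <- pmin(pmax(fa, 0), 1)
  for (k in 1:3) data[, , , 2 + k] <- minmax_norm(pfm[, , , k])
  if (any(!is.finite(data))) stopf("channel stack contains non-finite values")
  structure(list(data = data, affine = affine), class = "channel_stack")
}
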