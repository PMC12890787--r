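# Synthetic tubular bundle phantoms: eight bilateral tubes with controllable
# FA / low-b contrast and connectivity topology, four anchor ROIs, Rician
# noise, and an optional mass-effect lesion deformation.

# Normalized ([0,1]^3) control points per bundle, left side (x < 0.5).
# Vertical bundles run caudal (z ~ 0.08) to rostral (z ~ 0.90); SCP and Bic
# curve from the lateral cerebellar region up to the ventral diencephalon.
# MLc and CTG share two interchangeable mid-course "lanes" (A/B): which
# bundle occupies which lane is randomized per phantom, so their identities
# are carried by connectivity (endpoint ROI pair), not by position or
# scalar contrast.
bundle_geometry <- function(swap_lanes = FALSE) {
  zs <- c(0.08, 0.35, 0.62, 0.90)
  vert <- function(x, y) cbind(x = rep(x, 4), y = y, z = zs)
  laneA <- list(x = 0.38, yb = 0.55, ym = 0.58)
  laneB <- list(x = 0.28, yb = 0.50, ym = 0.53)
  ml_lane <- if (swap_lanes) laneB else laneA
  ctg_lane <- if (swap_lanes) laneA else laneB
  list(
    MLc = list(pair = c("thal", "med"), radius = 2.2,
               ctrl = vert(ml_lane$x, c(ml_lane$yb, ml_lane$ym, ml_lane$ym, 0.70))),
    SCP = list(pair = c("cb", "vdc"), radius = 3.0,
               ctrl = cbind(x = c(0.08, 0.14, 0.22, 0.36),
                            y = c(0.80, 0.72, 0.60, 0.30),
                            z = c(0.28, 0.48, 0.68, 0.90))),
    LFB = list(pair = c("vdc", "med"), radius = 2.6,
               ctrl = vert(0.20, c(0.36, 0.36, 0.34, 0.30))),
    MHB = list(pair = c("thal", "med"), radius = 1.6,
               ctrl = cbind(x = c(0.12, 0.12, 0.12, 0.18),
                            y = c(0.60, 0.60, 0.64, 0.72), z = zs)),
    Bic = list(pair = c("cb", "vdc"), radius = 2.4,
               ctrl = cbind(x = c(0.10, 0.18, 0.26, 0.34),
                            y = c(0.88, 0.78, 0.65, 0.42),
                            z = c(0.34, 0.52, 0.72, 0.88))),
    MLr = list(pair = c("thal", "med"), radius = 2.0,
               ctrl = vert(0.42, c(0.42, 0.42, 0.48, 0.60))),
    MLF = list(pair = c("vdc", "med"), radius = 1.4,
               ctrl = vert(0.46, c(0.55, 0.58, 0.50, 0.35))),
    CTG = list(pair = c("vdc", "med"), radius = 1.8,
               ctrl = vert(ctg_lane$x, c(ctg_lane$yb, ctg_lane$ym, ctg_lane$ym, 0.25)))
  )
}

# anchor ROI boxes in normalized coordinates (left CB mirrored for right)
roi_boxes <- function() {
  list(thal = list(x = c(0.08, 0.92), y = c(0.55, 0.85), z = c(0.84, 0.96)),
       med = list(x = c(0.15, 0.85), y = c(0.25, 0.75), z = c(0.02, 0.14)),
       cb_left = list(x = c(0.02, 0.20), y = c(0.60, 0.95), z = c(0.20, 0.45)),
       vdc = list(x = c(0.12, 0.88), y = c(0.12, 0.48), z = c(0.84, 0.96)))
}

# evenly distributed unit directions (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# axially symmetric eigenvalues (a, b, b) hitting an FA target at given MD:
# closed-form inversion of FA = (a - b) / sqrt(a^2 + 2 b^2)
fa_eigenvalues <- function(fa, md) {
  if (fa >= 1) stopf("FA target must be < 1 (got %g)", fa)
  if (fa <= 0) return(c(a = md, b = md))
  r <- (fa^2 + fa * sqrt(3 - 2 * fa^2)) / (1 - fa^2)   # a/b - 1
  b <- 3 * md / (r + 3)
  c(a = b * (1 + r), b = b)
}

#' Phantom specification
#'
#' @param frame_size cubic frame edge length in voxels.
#' @param spacing_mm isotropic voxel size.
#' @param bundles subset of bundle names to include (default: all eight).
#' @param fa_target tube fractional anisotropy.
#' @param fa_background background FA (near-isotropic).
#' @param md mean diffusivity, mm^2/s, tubes and background alike.
#' @param lowb_tube tube low-b intensity as a fraction of background S0.
#' @param s0 background non-diffusion-weighted signal level.
#' @param noise_sigma Rician noise level, fraction of `s0`.
#' @param n_directions diffusion directions on the b = 1000 shell (+ 2 b0).
#' @param jitter_sd control-point jitter (normalized units), mirrored
#'   left/right.
#' @param radius_scale global multiplier on tube radii (subject size
#'   variation).
#' @param ambiguous_swap randomize which of the two interchangeable
#'   mid-course lanes MLc and CTG occupy (connectivity-only ambiguity).
#' @param lesion optional list(center_norm, radius_mm, amplitude_mm) for
#'   [apply_lesion()].
#' @param rng_seed seed; all phantom randomness derives from it.
#' @export
phantom_spec <- function(frame_size = 64L, spacing_mm = 1.0,
                         bundles = names(bundle_geometry()),
                         fa_target = 0.7, fa_background = 0.05, md = 7e-4,
                         lowb_tube = 0.8, s0 = 100, noise_sigma = 0.05,
                         n_directions = 30L, jitter_sd = 0.015,
                         radius_scale = 1.0, ambiguous_swap = TRUE,
                         lesion = NULL, rng_seed = 1L) {
  stopifnot(frame_size >= 16, all(bundles %in% names(bundle_geometry())))
  structure(list(frame_size = as.integer(frame_size), spacing_mm = spacing_mm,
                 bundles = bundles, fa_target = fa_target,
                 fa_background = fa_background, md = md, lowb_tube = lowb_tube,
                 s0 = s0, noise_sigma = noise_sigma,
                 n_directions = as.integer(n_directions), jitter_sd = jitter_sd,
                 radius_scale = radius_scale, ambiguous_swap = isTRUE(ambiguous_swap),
                 lesion = lesion, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

rasterize_box <- function(box, S, mirror_x = FALSE) {
  out <- array(FALSE, c(S, S, S))
  rg <- function(r) max(1, ceiling(r[1] * (S - 1)) + 1):min(S, floor(r[2] * (S - 1)) + 1)
  xs <- rg(box$x); ys <- rg(box$y); zs <- rg(box$z)
  out[xs, ys, zs] <- TRUE
  if (mirror_x) {
    m <- array(FALSE, c(S, S, S))
    m[S:1, , ] <- out
    out <- out | m
  }
  out
}

# sample a cubic spline through 4 control points (rows), densely
sample_curve <- function(ctrl, n = 240) {
  t <- seq(1, nrow(ctrl), length.out = n)
  sapply(1:3, function(j) spline(seq_len(nrow(ctrl)), ctrl[, j], xout = t)$y)
}

#' Generate a ground-truthed bundle phantom
#'
#' Tubes are cubic splines through jittered control points, rasterized by
#' distance-to-curve; per-voxel tensors are axially symmetric, aligned with
#' the local tube tangent, with eigenvalues solved in closed form to hit the
#' FA target; the background is near-isotropic with randomly oriented mild
#' anisotropy. The DWI is synthesized on an `n_directions` b = 1000 s/mm^2
#' shell plus two b = 0 volumes, with Rician noise (magnitude of a
#' complex-Gaussian-perturbed signal). Left and right tubes are exact mirror
#' images; labels follow [label_scheme()] (left odd, right even).
#' Deterministic given `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom`: list with `dwi` ([dwi_volume()]), `rois`
#'   ([roi_set()]), `labels` ([label_map()]), `v1_true` (X,Y,Z,3 tangent
#'   field), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$rng_seed)
  S <- spec$frame_size
  sp <- spec$spacing_mm
  swap <- spec$ambiguous_swap && runif(1) < 0.5
  geoms <- bundle_geometry(swap)[spec$bundles]
  scheme <- label_scheme()
  dims <- c(S, S, S)
  labels <- array(0L, dims)
  best_d2 <- array(Inf, dims)      # contested voxels go to the nearest tube
  tangent <- array(0, c(dims, 3))
  # tube calibers shrink with the square root of the frame so that bundles
  # remain several voxels across at reduced frame sizes
  scale_r <- spec$radius_scale * sqrt(S / 64)
  for (nm in names(geoms)) {
    gb <- geoms[[nm]]
    ctrl <- gb$ctrl + matrix(rnorm(length(gb$ctrl), sd = spec$jitter_sd), nrow(gb$ctrl), 3)
    radius <- gb$radius * scale_r * runif(1, 0.95, 1.05)
    crv <- sample_curve(ctrl) * (S - 1)         # voxel coords, left side
    base_label <- scheme$label[scheme$bundle == nm & scheme$side == "left"]
    for (side in c("left", "right")) {
      cv <- crv
      if (side == "right") cv[, 1] <- (S - 1) - cv[, 1]
      lab <- if (side == "left") base_label else base_label + 1L
      cmask <- array(FALSE, dims)
      ii <- unique(round(cv)) + 1
      ok <- ii[, 1] >= 1 & ii[, 2] >= 1 & ii[, 3] >= 1 & ii[, 1] <= S & ii[, 2] <= S & ii[, 3] <= S
      cmask[ii[ok, , drop = FALSE]] <- TRUE
      dist2 <- cpp_edt_sq(as.integer(cmask), as.integer(dims), rep(sp, 3))
      tube <- dist2 <= radius^2 & dist2 < best_d2
      labels[tube] <- lab
      best_d2[tube] <- dist2[tube]
      # tangent from the nearest curve sample
      tv <- which(tube, arr.ind = TRUE) - 1
      if (nrow(tv) > 0) {
        tg <- diff(cv); tg <- rbind(tg, tg[nrow(tg), ])
        tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
        near <- apply(tv, 1, function(p) which.min(colSums((t(cv) - p)^2)))
        idx <- cbind(tv + 1, 1)
        for (j in 1:3) { idx[, 4] <- j; tangent[idx] <- tg[near, j] }
      }
    }
  }
  # ROIs
  boxes <- roi_boxes()
  rois <- roi_set(
    thal = rasterize_box(boxes$thal, S),
    med = rasterize_box(boxes$med, S),
    cb = rasterize_box(boxes$cb_left, S, mirror_x = TRUE),
    vdc = rasterize_box(boxes$vdc, S)
  )
  # per-voxel tensor coefficients
  n <- prod(dims)
  tube_idx <- labels > 0L
  ev_t <- fa_eigenvalues(spec$fa_target, spec$md)
  ev_b <- fa_eigenvalues(spec$fa_background, spec$md)
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  tmat <- matrix(tangent, n, 3)
  dir[tube_idx, ] <- tmat[tube_idx, ]
  a <- ifelse(tube_idx, ev_t["a"], ev_b["a"])
  b <- ifelse(tube_idx, ev_t["b"], ev_b["b"])
  amb <- as.vector(a - b)
  coef <- cbind(amb * dir[, 1]^2 + b, amb * dir[, 1] * dir[, 2], amb * dir[, 1] * dir[, 3],
                amb * dir[, 2]^2 + b, amb * dir[, 2] * dir[, 3], amb * dir[, 3]^2 + b)
  # DWI synthesis
  g <- fibonacci_directions(spec$n_directions)
  bvals <- c(0, 0, rep(1000, spec$n_directions))
  bvecs <- cbind(matrix(0, 3, 2), g)
  s0 <- ifelse(tube_idx, spec$s0 * spec$lowb_tube, spec$s0)
  nvol <- length(bvals)
  data <- array(0, c(dims, nvol))
  for (k in seq_len(nvol)) {
    if (bvals[k] == 0) sig <- s0
    else {
      gv <- bvecs[, k]
      q <- coef[, 1] * gv[1]^2 + 2 * coef[, 2] * gv[1] * gv[2] + 2 * coef[, 3] * gv[1] * gv[3] +
        coef[, 4] * gv[2]^2 + 2 * coef[, 5] * gv[2] * gv[3] + coef[, 6] * gv[3]^2
      sig <- s0 * exp(-bvals[k] * q)
    }
    if (spec$noise_sigma > 0) {
      sg <- spec$noise_sigma * spec$s0
      sig <- sqrt((sig + rnorm(n, sd = sg))^2 + rnorm(n, sd = sg)^2)
    }
    data[, , , k] <- sig
  }
  affine <- diag(c(sp, sp, sp, 1))
  phantom <- structure(list(
    dwi = dwi_volume(data, affine, bvals, bvecs),
    rois = rois,
    labels = label_map(labels, affine),
    v1_true = tangent,
    spec = spec
  ), class = "phantom")
  if (!is.null(spec$lesion)) phantom <- apply_lesion(phantom, spec$lesion)
  phantom
}

#' Connectivity-ambiguous two-tube phantom
#'
#' Two tubes with identical FA, low-b and (by construction) interchangeable
#' mid-course lanes, but different endpoint ROI pairs (thalamus-medulla vs
#' ventral-diencephalon-medulla): scalar channels alone cannot identify which
#' tube is which, while the fiber-map channels can.
#'
#' @param spec a [phantom_spec()]; its `bundles` is overridden with the
#'   MLc/CTG pair.
#' @export
make_ambiguous_pair <- function(spec = phantom_spec()) {
  spec$bundles <- c("MLc", "CTG")
  spec$ambiguous_swap <- TRUE
  generate_phantom(spec)
}

#' Apply a mass-effect lesion to a phantom
#'
#' A smooth radial displacement field with Gaussian falloff pushes tissue
#' away from the lesion center; the deformation is applied consistently (same
#' field) to every DWI volume (trilinear), the ROIs and the label map
#' (nearest neighbor) and the tangent field. Voxels in the lesion core
#' receive hemorrhage-like intensities (low signal on every volume, so low
#' low-b and near-zero FA) and background label.
#'
#' @param phantom a `phantom` from [generate_phantom()].
#' @param lesion list with `center_norm` (normalized coordinates, default
#'   near mid-frame), `radius_mm` (Gaussian falloff width), `amplitude_mm`
#'   (peak displacement), `core_frac` (core radius as a fraction of
#'   `radius_mm`, default 0.5).
#' @export
apply_lesion <- function(phantom, lesion = list()) {
  spec <- phantom$spec
  S <- spec$frame_size; sp <- spec$spacing_mm
  center <- (lesion$center_norm %||% c(0.5, 0.45, 0.7)) * (S - 1)
  radius <- lesion$radius_mm %||% (6 * S / 64)
  amp <- lesion$amplitude_mm %||% (4 * S / 64)
  core_frac <- lesion$core_frac %||% 0.5
  dims <- c(S, S, S)
  tgt <- grid_coords(dims)
  dvec <- sweep(tgt, 2, center)
  dist <- sqrt(rowSums((dvec * sp)^2))
  mag <- amp * exp(-dist^2 / (2 * radius^2))
  unit <- dvec / pmax(dist / sp, 1e-9)     # unit vector in voxel units
  src <- tgt - unit * (mag / sp)           # backward map: pull from toward center
  warp_lin <- function(v) array(cpp_sample3d(as.double(v), as.integer(dims), src, 0L, 0.0), dims)
  warp_nn <- function(v) array(cpp_sample3d(as.double(v), as.integer(dims), src, 1L, 0.0), dims)
  d4 <- dim(phantom$dwi$data)
  for (k in seq_len(d4[4])) phantom$dwi$data[, , , k] <- warp_lin(phantom$dwi$data[, , , k])
  lab <- warp_nn(phantom$labels$data)
  for (nm in names(phantom$rois)) phantom$rois[[nm]] <- warp_nn(phantom$rois[[nm]]) > 0.5
  for (j in 1:3) phantom$v1_true[, , , j] <- warp_lin(phantom$v1_true[, , , j])
  core <- array(dist <= core_frac * radius, dims)
  lab[core] <- 0
  for (k in seq_len(d4[4])) {
    vol <- phantom$dwi$data[, , , k]
    vol[core] <- 0.25 * spec$s0
    phantom$dwi$data[, , , k] <- vol
  }
  phantom$labels <- label_map(array(as.integer(round(lab)), dims), phantom$labels$affine)
  phantom$lesion_core <- core
  phantom$displacement_mm <- array(mag, dims)
  phantom
}

#' Displacement magnitude of the lesion field at a given distance
#'
#' Analytic value of the Gaussian-falloff displacement used by
#' [apply_lesion()], for oracle checks.
#'
#' @param dist_mm distance from the lesion center.
#' @param radius_mm falloff width.
#' @param amplitude_mm peak displacement.
#' @export
lesion_displacement <- function(dist_mm, radius_mm, amplitude_mm) {
  amplitude_mm * exp(-dist_mm^2 / (2 * radius_mm^2))
}
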