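#' Anchor ROI set for fiber-map seeding
#'
#' The four anchor regions that frame the rostral brainstem: thalamus,
#' medulla, cerebellar gray matter, ventral diencephalon. Masks must be
#' nonempty, pairwise disjoint, and live in the cropped frame.
#'
#' @param thal,med,cb,vdc binary 3D arrays in the cropped frame.
#' @export
roi_set <- function(thal, med, cb, vdc) {
  rois <- list(thal = thal, med = med, cb = cb, vdc = vdc)
  d <- dim(thal)
  for (nm in names(rois)) {
    if (!identical(dim(rois[[nm]]), d)) stopf("ROI '%s' has mismatched dimensions", nm)
    rois[[nm]] <- rois[[nm]] > 0
  }
  counts <- vapply(rois, sum, numeric(1))
  if (any(counts == 0)) warnf("empty ROI mask(s): %s", paste(names(counts)[counts == 0], collapse = ", "))
  overlap <- Reduce(`+`, rois)
  if (any(overlap > 1)) stopf("ROI masks overlap")
  structure(rois, class = "roi_set")
}

# fixed channel pairing of the probabilistic fiber map
pfm_pairs <- function() {
  list(c("thal", "med"), c("cb", "vdc"), c("vdc", "med"))
}

#' Probabilistic streamline tracking
#'
#' Propagates streamlines bidirectionally from each seed. At every step the
#' direction is drawn from a von Mises-Fisher distribution centered on the
#' local principal diffusion direction (sign-aligned with the previous step)
#' with concentration `kappa`; draws deviating more than `max_angle_deg` from
#' the previous direction are rejected (up to `max_tries` times, then the
#' streamline terminates). Streamlines also terminate on tracking-mask exit or
#' at the length cap. `kappa = Inf` is the deterministic limit (the direction
#' is the local V1 exactly). Fully reproducible under `set.seed()`.
#'
#' @param v1 (X,Y,Z,3) principal-direction field (unreliable voxels zero).
#' @param mask 3D logical tracking mask.
#' @param seeds n x 3 matrix of 0-based voxel coordinates.
#' @param step_mm step length in mm.
#' @param max_angle_deg maximum turning angle per step, degrees.
#' @param kappa von Mises-Fisher concentration.
#' @param max_len_mm maximum half-length (per direction) in mm.
#' @param spacing_mm voxel size of the (isotropic) frame.
#' @param max_tries rejection-sampling attempts per step.
#' @return a `streamline_set`: list with `points` (list of n_i x 3 matrices,
#'   voxel coordinates), `seed` (seed row index) and termination reasons for
#'   the forward/backward branch (`"mask_exit"`, `"angle"`, `"length"`).
#' @export
track_probabilistic <- function(v1, mask, seeds, step_mm = 0.5, max_angle_deg = 45,
                                kappa = 30, max_len_mm = 120, spacing_mm = 1.0,
                                max_tries = 8L) {
  stopifnot(step_mm > 0, max_angle_deg > 0, kappa > 0, max_len_mm > 0)
  if (is.null(dim(seeds)) || nrow(seeds) == 0) {
    warnf("empty seed set; returning no streamlines")
    return(structure(list(points = list(), seed = integer(), reason_fwd = character(),
                          reason_bwd = character()), class = "streamline_set"))
  }
  step_vox <- step_mm / spacing_mm
  max_steps <- floor(max_len_mm / step_mm)
  res <- cpp_track(as.double(v1), as_int_dims(mask), as.integer(mask),
                   as.matrix(seeds), step_vox, max_angle_deg, kappa,
                   as.integer(max_steps), as.integer(max_tries))
  codes <- c("mask_exit", "angle", "length")
  structure(list(points = res$points, seed = seq_len(nrow(seeds)),
                 reason_fwd = codes[res$reason_fwd], reason_bwd = codes[res$reason_bwd],
                 step_mm = step_mm),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines, mean length %.1f points\n",
              length(x$points),
              if (length(x$points)) mean(vapply(x$points, nrow, numeric(1))) else 0))
  invisible(x)
}

#' Retain streamlines connecting two ROIs
#'
#' Keeps exactly the streamlines having at least one point inside `roiA` and
#' at least one point inside `roiB`.
#'
#' @param s a `streamline_set`.
#' @param roiA,roiB binary 3D arrays.
#' @export
connectivity_filter <- function(s, roiA, roiB) {
  d <- dim(roiA)
  touches <- function(pts, roi) {
    if (nrow(pts) == 0) return(FALSE)
    v <- cpp_sample3d(as.double(roi), as.integer(d), pts, 1L, 0.0)
    any(v > 0)
  }
  keep <- vapply(s$points, function(p) touches(p, roiA) && touches(p, roiB), logical(1))
  structure(list(points = s$points[keep], seed = s$seed[keep],
                 reason_fwd = s$reason_fwd[keep], reason_bwd = s$reason_bwd[keep],
                 step_mm = s$step_mm),
            class = "streamline_set")
}

#' Streamline visitation counts
#'
#' Number of distinct streamlines intersecting each voxel; a streamline
#' increments a voxel at most once no matter how many of its points fall
#' inside it.
#'
#' @param s a `streamline_set`.
#' @param dims length-3 grid dimensions.
#' @return 3D integer count array.
#' @export
visitation_map <- function(s, dims) {
  cpp_visitation(s$points, as.integer(dims))
}

#' Histogram normalization of a count volume
#'
#' Counts are clipped at the `clip_pct`-th percentile of the nonzero values
#' and divided by that clip value, mapping the volume into [0, 1]. An all-zero
#' volume is returned unchanged.
#'
#' @param v non-negative count volume.
#' @param clip_pct clipping percentile (of nonzero counts).
#' @export
histogram_normalize <- function(v, clip_pct = 99) {
  nz <- v[v > 0]
  if (length(nz) == 0) return(array(0, dim(v)))
  clip <- as.numeric(quantile(nz, clip_pct / 100, type = 7))
  if (clip <= 0) return(array(0, dim(v)))
  array(pmin(v, clip) / clip, dim(v))
}

#' Build the three-channel probabilistic fiber map
#'
#' For each ROI pair (thalamus-medulla, cerebellar gray-ventral diencephalon,
#' ventral diencephalon-medulla): seed in both ROIs, track probabilistically,
#' retain streamlines touching both ROIs, accumulate distinct-streamline
#' visitation counts and histogram-normalize. The three channels are stacked
#' in that fixed order. A pair yielding zero retained streamlines produces an
#' all-zero channel with a warning (fiber-map dropout is itself diagnostic,
#' e.g. under mass-effect lesions).
#'
#' @param tf a `tensor_field` in the cropped frame.
#' @param rois a [roi_set()].
#' @param params list of tracking parameters (see [default_config()]); uses
#'   `track_*` and `pfm_clip_pct` keys.
#' @param spacing_mm voxel size of the cropped frame.
#' @return a `pfm_volume`: 4D array (X,Y,Z,3) in [0,1] plus attribute
#'   `n_retained` (retained streamline count per channel).
#' @export
build_pfm <- function(tf, rois, params = default_config(), spacing_mm = 1.0) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(tf$coef)[1:3]
  pd <- principal_direction(tf)
  fa <- tensor_scalars(tf, "FA")
  roi_union <- Reduce(`|`, rois)
  mask <- (fa > params$track_fa_threshold) | roi_union
  pfm <- array(0, c(d, 3))
  n_ret <- integer(3)
  pairs <- pfm_pairs()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    seeds <- rbind(which(rois[[pr[1]]], arr.ind = TRUE),
                   which(rois[[pr[2]]], arr.ind = TRUE)) - 1
    if (nrow(seeds) == 0) {
      warnf("PFM channel %d (%s-%s): empty seed ROIs; channel left zero", k, pr[1], pr[2])
      next
    }
    seeds <- seeds[rep(seq_len(nrow(seeds)), each = params$track_seeds_per_voxel), , drop = FALSE]
    s <- track_probabilistic(pd$v1, mask, seeds,
                             step_mm = params$track_step_mm,
                             max_angle_deg = params$track_max_angle_deg,
                             kappa = params$track_kappa,
                             max_len_mm = params$track_max_len_mm,
                             spacing_mm = spacing_mm)
    s <- connectivity_filter(s, rois[[pr[1]]], rois[[pr[2]]])
    n_ret[k] <- length(s$points)
    if (n_ret[k] == 0) {
      warnf("PFM channel %d (%s-%s): no streamlines connected the pair; channel left zero",
            k, pr[1], pr[2])
      next
    }
    pfm[, , , k] <- histogram_normalize(visitation_map(s, d), params$pfm_clip_pct)
  }
  structure(pfm, n_retained = n_ret, class = c("pfm_volume", "array"))
}
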