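#' Bundle label scheme
#'
#' The sixteen foreground labels encode eight bilateral brainstem bundles,
#' left = odd, right = even, in the fixed order MLc, SCP, LFB, MHB, Bic, MLr,
#' MLF, CTG. Label 0 is background.
#'
#' @return A data frame with columns `label`, `bundle`, `side`.
#' @export
label_scheme <- function() {
  bundles <- c("MLc", "SCP", "LFB", "MHB", "Bic", "MLr", "MLF", "CTG")
  data.frame(
    label = 1:16,
    bundle = rep(bundles, each = 2),
    side = rep(c("left", "right"), 8),
    stringsAsFactors = FALSE
  )
}

#' Read a diffusion-weighted volume with its gradient table
#'
#' Reads a 4D NIfTI image plus FSL-dialect `bval`/`bvec` text files. The
#' b-vectors (3-row FSL layout, image frame) are reoriented into the world
#' frame using the rotation part of the image affine.
#'
#' @param image_path path to a 4D NIfTI volume.
#' @param bval_path path to a whitespace-separated b-value file (s/mm^2).
#' @param bvec_path path to a 3-row whitespace-separated b-vector file.
#' @return A `dwi_volume`: list with `data` (4D array), `affine` (4x4,
#'   voxel-to-world RAS mm), `bvals`, `bvecs` (3 x G, world frame, unit norm
#'   for b > 0).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  img <- RNifti::readNifti(image_path)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) != 4L) stopf("expected a 4D image, got %dD", length(dim(data)))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  dwi_volume(data, affine, bvals, bvecs)
}

#' Construct and validate a `dwi_volume`
#'
#' @param data 4D intensity array (x, y, z, gradient).
#' @param affine 4x4 voxel-to-world matrix (RAS mm).
#' @param bvals per-gradient b-values (s/mm^2).
#' @param bvecs 3 x G gradient directions in the image frame; rotated to the
#'   world frame on construction.
#' @param b0_threshold b-values at or below this are treated as b = 0.
#' @export
dwi_volume <- function(data, affine, bvals, bvecs, b0_threshold = 50) {
  g <- dim(data)[4]
  if (length(bvals) != g || ncol(bvecs) != g)
    stopf("gradient table (%d bvals, %d bvecs) does not match image with %d volumes",
          length(bvals), ncol(bvecs), g)
  R <- affine_rotation(affine)
  bvecs <- R %*% bvecs
  dwis <- bvals > b0_threshold
  if (!any(!dwis)) stopf("no b<=%g volume present", b0_threshold)
  nrm <- sqrt(colSums(bvecs^2))
  bad <- dwis & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    bvecs[, dwis] <- sweep(bvecs[, dwis, drop = FALSE], 2, nrm[dwis], "/")
  }
  structure(list(data = data, affine = affine, bvals = bvals, bvecs = bvecs,
                 b0_threshold = b0_threshold),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %dx%dx%d, %d gradients (%d b0), b in [%g, %g]\n",
              d[1], d[2], d[3], d[4], sum(x$bvals <= x$b0_threshold),
              min(x$bvals), max(x$bvals)))
  invisible(x)
}

#' Construct a label map
#'
#' @param data 3D integer-valued array with values in 0..16.
#' @param affine 4x4 voxel-to-world matrix.
#' @param scheme label scheme data frame; defaults to [label_scheme()].
#' @export
label_map <- function(data, affine = diag(4), scheme = label_scheme()) {
  if (any(abs(data - round(data)) > 0)) stopf("label map grid must be integer-valued")
  vals <- unique(as.integer(data))
  bad <- setdiff(vals, c(0L, scheme$label))
  if (length(bad)) stopf("label values outside scheme: %s", paste(bad, collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine, scheme = scheme), class = "label_map")
}

#' Write / read a label map as integer NIfTI
#'
#' Round trips bit-exactly: data are stored with an integer on-disk type.
#' An all-background map is written with a warning.
#'
#' @param lm a `label_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  if (all(lm$data == 0L)) warnf("label map is empty (all background); writing anyway")
  img <- RNifti::asNifti(lm$data, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(lm$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.integer(img), dim(img))
  label_map(data, matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write a plain (scalar or multi-channel) volume as NIfTI
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path.
#' @export
write_volume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Default run configuration
#'
#' Flat key/value document collecting every tunable of the pipeline:
#' tractography parameters, CRF parameters, network/training settings and
#' seeds. Unknown keys are rejected when a config is loaded.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    b0_threshold = 50,
    frame_size = 64L, frame_spacing = 1.0,
    track_step_mm = 0.5, track_max_angle_deg = 45, track_kappa = 30,
    track_max_len_mm = 120, track_seeds_per_voxel = 5L, track_fa_threshold = 0.10,
    pfm_clip_pct = 99,
    crf_wu = 1.0, crf_lambda = 0.1, crf_sigma_b = 0.05, crf_sigma_k = 5,
    crf_nbhd = 3L, crf_iters = 5L,
    unet_levels = 5L, unet_base_features = 24L, unet_classes = 17L,
    train_lr = 1e-3, train_epochs = 30L, train_split = 0.8,
    train_loss = "dice", train_hybrid_alpha = 0.5,
    seed = 1L
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file with a flat key/value mapping. Every key must be one
#'   of the defaults from [default_config()]; unknown keys are an error.
#' @return full config list (defaults overridden by the file's values).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  modifyList(defaults, vals)
}

#' @rdname read_config
#' @param config named list of config values to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
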