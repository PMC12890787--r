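#' Add Rician noise to a diffusion volume
#'
#' Magnitude of the signal perturbed by complex Gaussian noise,
#' \eqn{|S + \sigma S_0 (\epsilon_1 + i \epsilon_2)|}.
#'
#' @param dwi a [dwi_volume()].
#' @param sigma noise level as a fraction of `s0_ref`.
#' @param s0_ref reference signal level (scanner units).
#' @param rng_seed seed.
#' @export
add_rician <- function(dwi, sigma, s0_ref = 100, rng_seed = 1L) {
  set.seed(rng_seed)
  sg <- sigma * s0_ref
  n <- length(dwi$data)
  dwi$data <- array(sqrt((dwi$data + rnorm(n, sd = sg))^2 + rnorm(n, sd = sg)^2),
                    dim(dwi$data))
  dwi
}

#' Derive the network input (and truth) from a phantom
#'
#' Runs the feature pipeline — tensor fit, low-b and FA maps, principal
#' directions, ROI-pair tractography and fiber-map construction — on a
#' phantom already living in the network frame.
#'
#' @param phantom a `phantom` from [generate_phantom()].
#' @param config pipeline configuration ([default_config()] keys).
#' @param track_seed seed for the probabilistic tracking.
#' @return list with `x` (X,Y,Z,5 channel array), `y` (3D integer labels),
#'   `v1` (X,Y,Z,3), `pfm`, `stack` (the full `channel_stack`).
#' @export
prepare_example <- function(phantom, config = default_config(), track_seed = 1L) {
  tf <- fit_tensor(phantom$dwi)
  lowb <- extract_lowb(phantom$dwi)
  fa <- tensor_scalars(tf, "FA")
  set.seed(track_seed)
  pfm <- build_pfm(tf, phantom$rois, config, spacing_mm = phantom$spec$spacing_mm)
  stack <- channel_stack(lowb, fa, unclass(pfm), phantom$dwi$affine)
  list(x = stack$data, y = phantom$labels$data,
       v1 = principal_direction(tf)$v1, pfm = pfm, stack = stack)
}

#' End-to-end segmentation
#'
#' Runs the full method on a diffusion volume: tensor fitting, resampling and
#' cropping into the isotropic network frame centered on the pons, fiber-map
#' tractography between the anchor ROI pairs, network inference, CRF
#' mean-field refinement and argmax labeling; the label map is mapped back
#' into the input scan's native grid by the inverse of the crop (nearest
#' neighbor).
#'
#' @param dwi a [dwi_volume()].
#' @param rois a [roi_set()] in the native grid.
#' @param model a trained `unet_model`.
#' @param config pipeline configuration.
#' @param pons_center crop center in world mm; default: the mid-point of the
#'   input field of view (phantoms are built pons-centered). Supply a mask
#'   center via [mask_center_mm()] for real data.
#' @param crf apply CRF refinement (`FALSE` = raw network argmax).
#' @param cparams a [crf_params()]; defaults derive from `config`.
#' @param ablate_pfm forwarded to [predict_softmax()].
#' @param track_seed seed for the tractography.
#' @return list with `labels` (native grid [label_map()]), `labels_frame`
#'   (cropped frame), `softmax`, `softmax_raw`, `pfm`, `stack`.
#' @export
segment <- function(dwi, rois, model, config = default_config(),
                    pons_center = NULL, crf = TRUE, cparams = NULL,
                    ablate_pfm = "none", track_seed = 1L) {
  d <- dim(dwi$data)[1:3]
  size <- config$frame_size; spc <- config$frame_spacing
  if (is.null(pons_center))
    pons_center <- colMeans(voxel_to_world(rbind((d - 1) / 2), dwi$affine))
  tf <- fit_tensor(dwi)
  lowb <- extract_lowb(dwi)
  native_is_frame <- identical(as.integer(d), rep(as.integer(size), 3)) &&
    isTRUE(all.equal(unname(dwi$affine[1:3, 1:3]), diag(3) * spc))
  if (native_is_frame) {
    tf_f <- tf; lowb_f <- lowb; rois_f <- rois
    frame_affine <- dwi$affine
  } else {
    chans <- c(list(lowb = lowb),
               setNames(lapply(1:6, function(j) tf$coef[, , , j]), paste0("c", 1:6)),
               lapply(rois, function(r) r + 0))
    rc <- resample_crop(chans, dwi$affine, pons_center, size, spc,
                        nearest = names(rois))
    lowb_f <- rc$channels$lowb
    coef_f <- array(0, c(size, size, size, 6))
    for (j in 1:6) coef_f[, , , j] <- rc$channels[[paste0("c", j)]]
    tf_f <- structure(list(coef = coef_f,
                           valid = array(TRUE, rep(size, 3)),
                           affine = rc$affine), class = "tensor_field")
    rois_f <- do.call(roi_set, lapply(rc$channels[names(rois)], function(r) r > 0.5))
    frame_affine <- rc$affine
  }
  fa_f <- tensor_scalars(tf_f, "FA")
  set.seed(track_seed)
  pfm <- build_pfm(tf_f, rois_f, config, spacing_mm = spc)
  stack <- channel_stack(lowb_f, fa_f, unclass(pfm), frame_affine)
  v1 <- if (ablate_pfm == "v1") principal_direction(tf_f)$v1 else NULL
  S <- predict_softmax(model, stack, ablate_pfm = ablate_pfm, v1 = v1)
  if (is.null(cparams))
    cparams <- crf_params(wu = config$crf_wu, lambda = config$crf_lambda,
                          sigma_b = config$crf_sigma_b, sigma_k = config$crf_sigma_k,
                          nbhd = config$crf_nbhd, iters = config$crf_iters)
  Sr <- if (crf) mean_field_refine(S, cparams) else S
  labels_frame <- crf_argmax(Sr, frame_affine)
  if (native_is_frame) {
    labels_native <- labels_frame
  } else {
    world <- voxel_to_world(grid_coords(d), dwi$affine)
    fv <- world_to_voxel(world, frame_affine)
    lv <- cpp_sample3d(as.double(labels_frame$data), as.integer(rep(size, 3)), fv, 1L, 0.0)
    labels_native <- label_map(array(as.integer(lv), d), dwi$affine)
  }
  list(labels = labels_native, labels_frame = labels_frame, softmax = Sr,
       softmax_raw = S, pfm = pfm, stack = stack)
}

#' Desk-scale study configuration
#'
#' The reduced problem size used throughout the package's own evaluation:
#' a 32-voxel frame, four bilateral bundles (MLc, SCP, LFB, CTG — one
#' representative per anchor-ROI pairing plus the connectivity-ambiguous
#' MLc/CTG lane pair), 5 seeds per ROI voxel, and a narrow network
#' ([6, 12, 24] features over three levels).
#'
#' @return a config list as from [default_config()].
#' @export
suite_config <- function() {
  cfg <- default_config()
  cfg$frame_size <- 32L
  cfg$track_seeds_per_voxel <- 5L
  cfg$crf_sigma_k <- 2.5      # smoothing width scales with the frame
  cfg$unet_levels <- 3L
  cfg$unet_base_features <- 6L
  cfg
}

#' @rdname suite_config
#' @export
suite_bundles <- function() c("MLc", "SCP", "LFB", "CTG")

#' Generate a phantom cohort with subject variation
#'
#' Each synthetic subject gets its own geometry jitter, tube caliber
#' (`radius_scale` drawn uniformly from `radius_range`) and noise
#' realization, all derived deterministically from `base_seed`.
#'
#' @param n number of subjects.
#' @param frame_size frame edge length.
#' @param bundles bundle subset.
#' @param base_seed root seed; subject i uses `base_seed * 1000 + i`.
#' @param noise_sigma Rician noise level.
#' @param radius_range subject tube-caliber range.
#' @export
phantom_suite <- function(n = 20, frame_size = 32L, bundles = suite_bundles(),
                          base_seed = 1L, noise_sigma = 0.05,
                          radius_range = c(0.85, 1.2)) {
  lapply(seq_len(n), function(i) {
    sd_i <- (base_seed * 1000L + i) %% .Machine$integer.max
    set.seed(sd_i)
    rs <- runif(1, radius_range[1], radius_range[2])
    generate_phantom(phantom_spec(frame_size = frame_size, bundles = bundles,
                                  noise_sigma = noise_sigma, radius_scale = rs,
                                  rng_seed = sd_i + 1L))
  })
}

#' Train a model on a phantom cohort
#'
#' Convenience wrapper: derives the network inputs for every phantom with
#' [prepare_example()], optionally zeroes the fiber-map channels (PFM
#' ablation trained in), and trains a network sized from `config`.
#'
#' @param phantoms list of phantoms.
#' @param config pipeline config (see [suite_config()]).
#' @param epochs,loss_kind,rng_seed forwarded to [train()].
#' @param ablate_pfm train with zeroed fiber-map channels.
#' @param verbose print progress.
#' @return list with `model` (trained), `examples` (prepared inputs),
#'   `history`.
#' @export
fit_suite_model <- function(phantoms, config = suite_config(), epochs = 30L,
                            loss_kind = "dice", rng_seed = 1L,
                            ablate_pfm = FALSE, verbose = FALSE) {
  examples <- lapply(seq_along(phantoms), function(i) {
    ex <- prepare_example(phantoms[[i]], config, track_seed = rng_seed * 100L + i)
    if (ablate_pfm) ex$x[, , , 3:5] <- 0
    ex
  })
  spec <- unet_spec(levels = config$unet_levels,
                    base_features = config$unet_base_features,
                    in_channels = 5L, classes = config$unet_classes,
                    input_size = config$frame_size)
  set.seed(rng_seed)
  model <- build_model(spec)
  model <- train(model, examples, loss_kind = loss_kind, epochs = epochs,
                 lr = config$train_lr, split = config$train_split,
                 rng_seed = rng_seed, verbose = verbose)
  list(model = model, examples = examples, history = model$history)
}

#' Test-retest reliability harness
#'
#' For each synthetic subject (random caliber/geometry perturbation), two
#' independently noised scans of the same anatomy are generated and
#' segmented; per-bundle volumes are collected and the two-way
#' mixed-effects ICC is computed per bundle across subjects.
#'
#' @param model a trained `unet_model`.
#' @param n_subjects number of synthetic subjects.
#' @param config pipeline config matching the model.
#' @param noise_sigma per-session Rician noise level.
#' @param bundles bundle subset (must match training).
#' @param base_seed root seed.
#' @param crf apply CRF refinement during segmentation.
#' @return list with `icc` (data frame: label, icc, ci), `volumes`
#'   (subjects x labels x 2 array).
#' @export
testretest_harness <- function(model, n_subjects = 20, config = suite_config(),
                               noise_sigma = 0.05, bundles = suite_bundles(),
                               base_seed = 7L, crf = TRUE) {
  labs <- sort(label_scheme()$label[label_scheme()$bundle %in% bundles])
  vols <- array(NA_real_, c(n_subjects, length(labs), 2),
                dimnames = list(NULL, paste0("L", labs), NULL))
  for (i in seq_len(n_subjects)) {
    sd_i <- (base_seed * 10000L + i * 10L) %% .Machine$integer.max
    set.seed(sd_i)
    rs <- runif(1, 0.85, 1.2)
    clean <- generate_phantom(phantom_spec(frame_size = config$frame_size,
                                           bundles = bundles, noise_sigma = 0,
                                           radius_scale = rs, rng_seed = sd_i + 1L))
    for (ses in 1:2) {
      ph <- clean
      ph$dwi <- add_rician(clean$dwi, noise_sigma, s0_ref = clean$spec$s0,
                           rng_seed = sd_i + 1L + ses)
      res <- segment(ph$dwi, ph$rois, model, config, crf = crf,
                     track_seed = sd_i + 100L + ses)
      for (j in seq_along(labs))
        vols[i, j, ses] <- sum(res$labels$data == labs[j]) *
          config$frame_spacing^3
    }
  }
  icc <- do.call(rbind, lapply(seq_along(labs), function(j) {
    r <- icc_two_way(vols[, j, ])
    data.frame(label = labs[j], icc = r$icc, ci_lo = r$ci[1], ci_hi = r$ci[2],
               degenerate = r$degenerate)
  }))
  list(icc = icc, volumes = vols)
}
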