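test_that("the FA-target eigenvalue inversion round-trips through the fit", {
  sp <- phantom_spec(frame_size = 32L, bundles = c("MLc", "LFB"),
                     fa_target = 0.8, noise_sigma = 0, rng_seed = 2)
  ph <- generate_phantom(sp)
  fa <- tensor_scalars(fit_tensor(ph$dwi), "FA")
  tube <- ph$labels$data > 0
  expect_equal(mean(fa[tube]), 0.8, tolerance = 0.01)
  expect_lt(sd(fa[tube]), 0.02)
  # closed-form inversion itself
  for (f in c(0.2, 0.5, 0.7, 0.95)) {
    ev <- bundleseg:::fa_eigenvalues(f, 7e-4)
    lam <- c(ev["a"], ev["b"], ev["b"])
    fa_check <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
    expect_equal(unname(fa_check), f, tolerance = 1e-10)
    expect_equal(unname(mean(lam)), 7e-4, tolerance = 1e-12)
  }
  expect_error(phantom_spec(fa_target = 1.2) |> generate_phantom(), "FA target")
})

test_that("left and right tube labels are exact mirror images", {
  ph <- generate_phantom(phantom_spec(frame_size = 32L, rng_seed = 6,
                                      noise_sigma = 0))
  lab <- ph$labels$data
  S <- dim(lab)[1]
  mirrored <- lab[S:1, , ]
  # swap left/right label codes in the mirrored volume
  swapped <- mirrored
  for (l in seq(1L, 15L, by = 2L)) {
    swapped[mirrored == l] <- l + 1L
    swapped[mirrored == l + 1L] <- l
  }
  storage.mode(swapped) <- "integer"
  expect_identical(lab, swapped)
})

test_that("phantom generation is bit-deterministic in its seed", {
  sp <- phantom_spec(frame_size = 24L, bundles = c("MLc", "CTG"), rng_seed = 9)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_identical(a$labels$data, b$labels$data)
  sp2 <- sp; sp2$rng_seed <- 10L
  expect_false(identical(generate_phantom(sp2)$dwi$data, a$dwi$data))
})

test_that("phantoms satisfy the downstream pipeline preconditions", {
  ph <- generate_phantom(phantom_spec(frame_size = 32L, rng_seed = 4))
  expect_s3_class(ph$dwi, "dwi_volume")     # constructor validated invariants
  counts <- vapply(ph$rois, sum, numeric(1))
  expect_true(all(counts > 0))
  overlap <- Reduce(`+`, ph$rois)
  expect_true(all(overlap <= 1))
  # per-bundle voxel counts span a wide (~5x) size range across the suite
  tab <- table(ph$labels$data[ph$labels$data > 0])
  expect_gte(max(tab) / min(tab), 3)
  # tube endpoints reach their declared ROI pair
  sch <- label_scheme()
  geoms <- bundleseg:::bundle_geometry()
  for (nm in c("MLc", "SCP", "LFB")) {
    ll <- sch$label[sch$bundle == nm]
    m <- ph$labels$data %in% ll
    dim(m) <- dim(ph$labels$data)
    pr <- geoms[[nm]]$pair
    expect_gt(sum(m & ph$rois[[pr[1]]]), 0)
    expect_gt(sum(m & ph$rois[[pr[2]]]), 0)
  }
})

test_that("the ambiguous pair is scalar-identical but connectivity-distinct", {
  sp <- phantom_spec(frame_size = 32L, rng_seed = 13)
  ph <- make_ambiguous_pair(sp)
  lab <- ph$labels$data
  sch <- label_scheme()
  m_ml <- lab %in% sch$label[sch$bundle == "MLc"]; dim(m_ml) <- dim(lab)
  m_ctg <- lab %in% sch$label[sch$bundle == "CTG"]; dim(m_ctg) <- dim(lab)
  expect_gt(sum(m_ml), 0); expect_gt(sum(m_ctg), 0)
  expect_equal(sum(m_ml & m_ctg), 0)        # labels differ by construction

  # scalar channels: same FA distribution in both tubes up to noise
  fa <- tensor_scalars(fit_tensor(ph$dwi), "FA")
  set.seed(1)
  a <- sample(fa[m_ml], 400, replace = TRUE)
  b <- sample(fa[m_ctg], 400, replace = TRUE)
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.05)

  # fiber map separates them: channel 1 (thal-med) lives on MLc, channel 3
  # (vdc-med) on CTG
  cfg <- suite_config()
  set.seed(2)
  pfm <- build_pfm(fit_tensor(ph$dwi), ph$rois, cfg)
  sep <- mean(pfm[, , , 1][m_ml] - pfm[, , , 3][m_ml]) +
    mean(pfm[, , , 3][m_ctg] - pfm[, , , 1][m_ctg])
  expect_gt(sep, 0)
})

test_that("the lane swap actually moves the ambiguous tubes across phantoms", {
  lanes <- vapply(1:8, function(s) {
    ph <- make_ambiguous_pair(phantom_spec(frame_size = 24L, rng_seed = s,
                                           noise_sigma = 0))
    idx <- which(ph$labels$data == 1L, arr.ind = TRUE)
    mean(idx[, 1])     # MLc left-tube mean x position
  }, numeric(1))
  expect_gt(diff(range(lanes)), 1.5)
})

test_that("a zero-amplitude lesion is the identity", {
  ph <- generate_phantom(phantom_spec(frame_size = 24L, bundles = c("MLc", "LFB"),
                                      noise_sigma = 0, rng_seed = 3))
  ph2 <- apply_lesion(ph, list(amplitude_mm = 0, radius_mm = 4, core_frac = 0))
  expect_equal(ph2$labels$data, ph$labels$data)
  expect_equal(ph2$dwi$data, ph$dwi$data, tolerance = 1e-12)
})

test_that("lesion displacement follows the analytic Gaussian falloff", {
  S <- 32L
  ph <- generate_phantom(phantom_spec(frame_size = S, bundles = "MLc",
                                      noise_sigma = 0, rng_seed = 3,
                                      ambiguous_swap = FALSE))
  les <- list(center_norm = c(0.25, 0.55, 0.5), radius_mm = 5,
              amplitude_mm = 3, core_frac = 0)
  ph2 <- apply_lesion(ph, les)
  # the left MLc tube's centroid shifts by about the analytic displacement at
  # its distance from the lesion center
  ctr <- les$center_norm * (S - 1)
  m1 <- which(ph$labels$data == 1L, arr.ind = TRUE) - 1
  m2 <- which(ph2$labels$data == 1L, arr.ind = TRUE) - 1
  # restrict to the lesion's axial band where displacement is strongest
  zband <- abs(m1[, 3] - ctr[3]) < 3
  zband2 <- abs(m2[, 3] - ctr[3]) < 3
  c1 <- colMeans(m1[zband, , drop = FALSE])
  c2 <- colMeans(m2[zband2, , drop = FALSE])
  d0 <- sqrt(sum((c1 - ctr)^2))
  expected <- lesion_displacement(d0, les$radius_mm, les$amplitude_mm)
  observed <- sqrt(sum((c2 - c1)^2))
  expect_equal(observed, expected, tolerance = 0.5)
  # displacement is away from the center
  expect_gt(sqrt(sum((c2 - ctr)^2)), d0)
})

test_that("a displaced tube stays trackable end-to-end", {
  ph <- generate_phantom(phantom_spec(frame_size = 32L, bundles = "MLc",
                                      noise_sigma = 0, rng_seed = 3,
                                      ambiguous_swap = FALSE,
                                      lesion = list(center_norm = c(0.3, 0.55, 0.5),
                                                    radius_mm = 5, amplitude_mm = 2.5,
                                                    core_frac = 0.3)))
  tf <- fit_tensor(ph$dwi)
  cfg <- suite_config()
  set.seed(4)
  pfm <- build_pfm(tf, ph$rois, cfg)
  expect_gt(attr(pfm, "n_retained")[1], 0)
})
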