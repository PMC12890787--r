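# Shared fixtures: small deterministic volumes, straight-tube phantoms, and
# a per-session cache for the (expensive) trained suite models so the
# training/ablation/reliability checks share one pair of fits.

suite_env <- new.env(parent = emptyenv())

# study conditions of the desk-scale evaluation suite
SUITE_N <- 20L
SUITE_EPOCHS <- 22L
SUITE_SEED <- 1L

get_suite_phantoms <- function() {
  if (is.null(suite_env$phantoms))
    suite_env$phantoms <- phantom_suite(n = SUITE_N, base_seed = SUITE_SEED)
  suite_env$phantoms
}

get_suite_fit <- function(ablate_pfm = FALSE) {
  key <- if (ablate_pfm) "fit_nopfm" else "fit_full"
  if (is.null(suite_env[[key]])) {
    suite_env[[key]] <- fit_suite_model(get_suite_phantoms(), suite_config(),
                                        epochs = SUITE_EPOCHS, rng_seed = SUITE_SEED,
                                        ablate_pfm = ablate_pfm)
  }
  suite_env[[key]]
}

# held-out examples (the validation split used inside train() is seeded
# identically, so recompute the same split here)
suite_val_idx <- function() {
  set.seed(SUITE_SEED)
  n <- SUITE_N
  ntr <- max(1, round(0.8 * n)); if (ntr >= n) ntr <- n - 1
  ord <- sample(n)
  ord[(ntr + 1):n]
}

# straight single-tube phantom along z for zero-dispersion tracking checks:
# V1 = (0,0,1) inside a cylinder, ROIs = slabs at both ends
straight_tube_fixture <- function(S = 32L, radius = 3) {
  dims <- c(S, S, S)
  ctr <- (S - 1) / 2
  g <- bundleseg:::grid_coords(dims)
  r2 <- (g[, 1] - ctr)^2 + (g[, 2] - ctr)^2
  tube <- array(r2 <= radius^2, dims)
  v1 <- array(0, c(dims, 3))
  v1[, , , 3][tube] <- 1
  thal <- array(FALSE, dims); thal[, , (S - 4):(S - 1)] <- TRUE
  med <- array(FALSE, dims); med[, , 2:5] <- TRUE
  cb <- array(FALSE, dims); cb[1:3, 1:3, 10:15] <- TRUE
  vdc <- array(FALSE, dims); vdc[(S - 2):S, (S - 2):S, 10:15] <- TRUE
  thal <- thal & tube; med <- med & tube
  list(tube = tube, v1 = v1,
       rois = roi_set(thal = thal, med = med, cb = cb, vdc = vdc),
       mask = tube, dims = dims)
}

# random probability field with rows summing to one
random_softmax <- function(dims, V, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(prod(dims) * V)), prod(dims), V)
  array(m / rowSums(m), c(dims, V))
}

# two-region probability instance: left half label 2, right half label 3,
# with a fraction of voxels' (true, wrong) probabilities swapped
two_region_instance <- function(S = 16L, p_true = 0.6, p_wrong = 0.3,
                                corrupt_frac = 0.05, seed = 1) {
  set.seed(seed)
  dims <- c(S, S, S)
  n <- prod(dims)
  truth <- array(ifelse(bundleseg:::grid_coords(dims)[, 1] < S / 2, 1L, 2L), dims)
  P <- matrix(0, n, 3)
  bg <- 1 - p_true - p_wrong
  P[truth == 1L, ] <- matrix(rep(c(bg, p_true, p_wrong), each = sum(truth == 1L)), ncol = 3)
  P[truth == 2L, ] <- matrix(rep(c(bg, p_wrong, p_true), each = sum(truth == 2L)), ncol = 3)
  bad <- sample(n, round(corrupt_frac * n))
  P[bad, 2:3] <- P[bad, 3:2]
  list(S = array(P, c(dims, 3)), truth = truth, corrupted = bad)
}

argmax_labels <- function(S) {
  d <- dim(S)
  array(max.col(matrix(S, prod(d[1:3]), d[4]), ties.method = "first") - 1L, d[1:3])
}
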