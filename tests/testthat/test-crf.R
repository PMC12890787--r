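# independent separable Gaussian smoothing oracle: explicit 1D passes with
# per-position renormalized truncated kernels, written in plain R loops
smooth_oracle <- function(vol, sigma) {
  d <- dim(vol)
  r <- max(1, ceiling(3 * sigma))
  kern <- exp(-0.5 * (-r:r)^2 / sigma^2)
  kern <- kern / sum(kern)
  out <- vol
  for (ax in 1:3) {
    nxt <- out
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      pos <- c(x, y, z)
      acc <- 0; wsum <- 0
      for (o in -r:r) {
        p <- pos; p[ax] <- p[ax] + o
        if (p[ax] >= 1 && p[ax] <= d[ax]) {
          acc <- acc + kern[o + r + 1] * out[p[1], p[2], p[3]]
          wsum <- wsum + kern[o + r + 1]
        }
      }
      nxt[x, y, z] <- acc / wsum
    }
    out <- nxt
  }
  out
}

# brute-force transcription of the printed composite energy
energy_oracle <- function(S, params) {
  d <- dim(S)
  V <- d[4]
  Sk <- array(0, d)
  for (v in 1:V) Sk[, , , v] <- smooth_oracle(S[, , , v], params$sigma_k)
  vox <- bundleseg:::grid_coords(d[1:3]) + 1
  n <- nrow(vox)
  pair_acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- abs(vox[i, ] - vox[j, ])
      if (max(dd) > params$nbhd) next
      for (v in 1:V)
        pair_acc <- pair_acc + (Sk[vox[j, 1], vox[j, 2], vox[j, 3], v] -
                                  Sk[vox[i, 1], vox[i, 2], vox[i, 3], v])^2
    }
  }
  un <- 0; ent <- 0
  for (i in seq_len(n)) for (v in 1:V) {
    s <- max(S[vox[i, 1], vox[i, 2], vox[i, 3], v], 1e-12)
    un <- un + log(s)
    if (v > 1) ent <- ent + S[vox[i, 1], vox[i, 2], vox[i, 3], v] * log(s)
  }
  -(pair_acc / (4 * pi * params$sigma_b * params$sigma_k) +
      params$wu * un + params$lambda * ent)
}

test_that("unary and entropy potentials follow their closed forms", {
  d <- c(3, 3, 3)
  S <- array(0, c(d, 3))
  S[, , , 1] <- exp(-1); S[, , , 2] <- 1 - 2 * exp(-1); S[, , , 3] <- exp(-1)
  u <- unary_potential(S)
  expect_equal(u[1, 1, 1, 1], 1)
  expect_equal(u[2, 2, 2, 2], -log(1 - 2 * exp(-1)))
  S1 <- array(0, c(d, 3)); S1[, , , 2] <- 1      # one-hot foreground
  expect_equal(unary_potential(S1)[1, 1, 1, 2], 0)
  expect_equal(entropy_potential(S1), array(0, d))
  # uniform over 16 foreground labels, zero background -> log 16
  S2 <- array(1 / 16, c(d, 17)); S2[, , , 1] <- 0
  expect_equal(entropy_potential(S2), array(log(16), d), tolerance = 1e-12)
  # elementwise loop oracle on a random field
  Sr <- random_softmax(d, 4, seed = 3)
  u2 <- unary_potential(Sr)
  h2 <- entropy_potential(Sr)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    expect_equal(u2[i, j, k, 2], -log(Sr[i, j, k, 2]), tolerance = 1e-12)
    expect_equal(h2[i, j, k],
                 -sum(Sr[i, j, k, 2:4] * log(Sr[i, j, k, 2:4])), tolerance = 1e-12)
  }
})

test_that("probability smoothing preserves constants and label sums", {
  d <- c(7, 7, 7)
  S <- array(0, c(d, 3))
  S[, , , 1] <- 0.2; S[, , , 2] <- 0.5; S[, , , 3] <- 0.3
  Sk <- smoothed_probabilities(S, 1.2)
  expect_equal(Sk, S, tolerance = 1e-12)       # constants exactly preserved
  Sr <- random_softmax(d, 3, seed = 8)
  Skr <- smoothed_probabilities(Sr, 1.0)
  sums <- rowSums(matrix(Skr, prod(d), 3))
  expect_true(all(abs(sums - 1) < 1e-5))
  # delta response matches the enumerated normalized separable stencil
  # (9^3 grid: the truncated +-3 sigma support fits without border effects)
  delta <- array(0, c(9, 9, 9, 1)); delta[5, 5, 5, 1] <- 1
  Sd <- smoothed_probabilities(delta, 1.0)
  k1 <- exp(-0.5 * (-3:3)^2); k1 <- k1 / sum(k1)
  expect_equal(Sd[5, 5, 5, 1], k1[4]^3, tolerance = 1e-12)
  expect_equal(Sd[6, 5, 5, 1] / Sd[5, 5, 5, 1], k1[5] / k1[4], tolerance = 1e-10)
  expect_equal(Sd[6, 6, 5, 1], k1[5]^2 * k1[4], tolerance = 1e-12)
})

test_that("vectorized composite energy equals the brute-force loop oracle", {
  params <- crf_params(wu = 1.3, lambda = 0.2, sigma_b = 0.4, sigma_k = 1.0,
                       nbhd = 3L, iters = 1L)
  for (seed in c(1, 2, 3)) {
    S <- random_softmax(c(6, 6, 6), 3, seed = seed)
    er <- crf_energy(S, params)
    expect_equal(er$total, er$unary + er$pairwise + er$entropy, tolerance = 1e-12)
    expect_equal(er$total, energy_oracle(S, params),
                 tolerance = 1e-8 * abs(er$total))
  }
})

test_that("energy terms scale linearly in their weights; constants kill the pairwise term", {
  S <- random_softmax(c(5, 5, 5), 3, seed = 4)
  p1 <- crf_params(wu = 1, lambda = 0.1, sigma_b = 0.3, sigma_k = 1, nbhd = 2L)
  p2 <- crf_params(wu = 2, lambda = 0.1, sigma_b = 0.3, sigma_k = 1, nbhd = 2L)
  e1 <- crf_energy(S, p1); e2 <- crf_energy(S, p2)
  expect_equal(e2$unary, 2 * e1$unary, tolerance = 1e-12)
  expect_equal(e2$pairwise, e1$pairwise, tolerance = 1e-12)
  expect_equal(e2$entropy, e1$entropy, tolerance = 1e-12)
  # spatially constant field: all smoothed differences vanish
  Sc <- array(0, c(5, 5, 5, 3))
  Sc[, , , 1] <- 0.5; Sc[, , , 2] <- 0.3; Sc[, , , 3] <- 0.2
  expect_equal(crf_energy(Sc, p1)$pairwise, 0, tolerance = 1e-12)
})

test_that("mean-field refinement has the unary-only fixed point", {
  S <- random_softmax(c(6, 6, 6), 4, seed = 5)
  p <- crf_params(wu = 1, lambda = 0, sigma_b = 1, sigma_k = 1, iters = 4L,
                  pairwise = FALSE)
  Q <- mean_field_refine(S, p)
  expect_equal(Q, S, tolerance = 1e-12)
})

test_that("mean-field refinement never breaks symmetry of a uniform field", {
  d <- c(6, 6, 6)
  S <- array(1 / 3, c(d, 3))
  # with the entropy term disabled the uniform field is a fixed point
  Q0 <- mean_field_refine(S, crf_params(lambda = 0, iters = 3L, sigma_k = 1.5))
  expect_equal(Q0, S, tolerance = 1e-9)
  # with it enabled, spatial uniformity and foreground-label exchange
  # symmetry are still never broken (the term deliberately demotes
  # uncertain foreground relative to background)
  Q <- mean_field_refine(S, crf_params(iters = 3L, sigma_k = 1.5))
  for (v in 1:3) expect_equal(max(Q[, , , v]) - min(Q[, , , v]), 0, tolerance = 1e-12)
  expect_equal(Q[, , , 2], Q[, , , 3], tolerance = 1e-12)
})

test_that("row sums stay one after every iteration and cost is fixed", {
  S <- random_softmax(c(8, 8, 8), 3, seed = 6)
  for (it in 1:3) {
    Q <- mean_field_refine(S, crf_params(iters = it, sigma_k = 1.5))
    rs <- rowSums(matrix(Q, 8^3, 3))
    expect_true(all(abs(rs - 1) < 1e-9))
  }
})

test_that("refinement denoises corrupted two-region instances", {
  p <- crf_params(sigma_k = 1.5, nbhd = 3L, iters = 5L)
  wins <- 0
  for (seed in 1:20) {
    inst <- two_region_instance(S = 16L, corrupt_frac = 0.05, seed = seed)
    before <- sum(argmax_labels(inst$S) != inst$truth)
    Q <- mean_field_refine(inst$S, p)
    after <- sum(argmax_labels(Q) != inst$truth)
    if (after < before) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("argmax labeling breaks ties toward background", {
  d <- c(3, 3, 3)
  Q <- array(0, c(d, 3))
  Q[, , , 1] <- 0.4; Q[, , , 2] <- 0.4; Q[, , , 3] <- 0.2
  lm <- crf_argmax(Q)
  expect_true(all(lm$data == 0L))
  # one-hot field reproduces its own labels; random field matches a loop oracle
  Sr <- random_softmax(d, 4, seed = 7)
  lm2 <- crf_argmax(Sr)
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_equal(lm2$data[i, j, k], which.max(Sr[i, j, k, ]) - 1L)
})
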