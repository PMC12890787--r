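# literal straight-line transcription of the gate formula, written
# independently of the package's layer kernels (plain R loops)
gate_oracle <- function(Fd1, Fe1, gating, w) {
  d <- dim(Fd1)
  n <- prod(d[1:3])
  relu_e <- pmax(Fe1, 0)
  a <- matrix(relu_e, n, dim(Fe1)[4]) %*% w$phia_w + w$phia_b
  for (j in seq_along(gating)) {
    gj <- gating[[j]]
    dg <- dim(gj)
    up <- array(0, c(d[1:3], dg[4]))
    # trilinear upsampling, voxel-center alignment with border clamping
    for (c in seq_len(dg[4])) for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      sc <- dg[1:3] / d[1:3]
      p <- (c(x, y, z) - 0.5) * sc - 0.5
      i0 <- floor(p); f <- p - i0
      cl <- function(i, ax) min(max(i, 0), dg[ax] - 1) + 1
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
          (if (dz) f[3] else 1 - f[3])
        acc <- acc + wgt * gj[cl(i0[1] + dx, 1), cl(i0[2] + dy, 2), cl(i0[3] + dz, 3), c]
      }
      up[x, y, z, c] <- acc
    }
    a <- a + matrix(tanh(up), n, dg[4]) %*% w$phi[[j]]$w + w$phi[[j]]$b
  }
  gate <- 1 / (1 + exp(-a))
  out <- array(0, d)
  for (c in seq_len(d[4])) out[, , , c] <- Fd1[, , , c] * array(gate, d[1:3])
  out
}

test_that("zero-weight attention gate halves the decoder tensor exactly", {
  set.seed(2)
  Fd1 <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  Fe1 <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  gating <- list(array(rnorm(4^3 * 8), c(4, 4, 4, 8)))
  w0 <- list(phia_w = matrix(0, 4, 1), phia_b = 0,
             phi = list(list(w = matrix(0, 8, 1), b = 0)))
  out <- attention_gate(Fd1, Fe1, gating, w0)
  expect_equal(out, 0.5 * Fd1, tolerance = 1e-15)
  # saturated gate passes the decoder tensor through unchanged
  wsat <- w0; wsat$phia_b <- 50
  expect_equal(attention_gate(Fd1, Fe1, gating, wsat), Fd1, tolerance = 1e-12)
  # gate range
  g <- attention_gate(Fd1, Fe1, gating, w0, return_gate = TRUE)$gate
  expect_true(all(g > 0 & g < 1))
})

test_that("attention gate matches an independent literal transcription", {
  set.seed(3)
  Fd1 <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  Fe1 <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  gating <- list(array(rnorm(3^3 * 5), c(3, 3, 3, 5)),
                 array(rnorm(2^3 * 7), c(2, 2, 2, 7)))
  w <- list(phia_w = matrix(rnorm(3), 3, 1), phia_b = 0.3,
            phi = list(list(w = matrix(rnorm(5), 5, 1), b = -0.2),
                       list(w = matrix(rnorm(7), 7, 1), b = 0.1)))
  expect_equal(attention_gate(Fd1, Fe1, gating, w),
               gate_oracle(Fd1, Fe1, gating, w), tolerance = 1e-6)
})

test_that("the full-scale architecture audit reproduces the printed contract", {
  set.seed(1)
  model <- build_model(unet_spec())
  audit <- unet_audit(model)
  expect_equal(audit$levels, 5L)
  expect_equal(audit$features, c(24L, 48L, 96L, 192L, 384L))
  expect_equal(audit$grid, c(64L, 32L, 16L, 8L, 4L))
  expect_equal(audit$kernel, 3L)
  expect_equal(audit$in_channels, 5L)
  expect_equal(audit$classes, 17L)
  # gate weights exist for decoder levels 2..4 only (coarsest excluded)
  expect_true(all(c("att_phia_w", "att_phi2_w", "att_phi3_w", "att_phi4_w") %in%
                    names(model$params)))
  expect_false("att_phi5_w" %in% names(model$params))
})

test_that("forward pass honors the shape contract and the ablation contract", {
  set.seed(4)
  spec <- unet_spec(levels = 3L, base_features = 4L, in_channels = 5L,
                    classes = 17L, input_size = 16L)
  model <- build_model(spec)
  x <- array(rnorm(16^3 * 5), c(16, 16, 16, 5))
  S <- predict_softmax(model, x)
  expect_equal(dim(S), c(16, 16, 16, 17))
  rs <- rowSums(matrix(S, 16^3, 17))
  expect_true(all(abs(rs - 1) < 1e-5))
  # ablated model: no gate parameters, same output shape
  set.seed(4)
  mab <- build_model(spec, ablate_attention = TRUE)
  expect_false(any(grepl("^att_", names(mab$params))))
  expect_equal(dim(predict_softmax(mab, x)), c(16, 16, 16, 17))
  # channel mismatch is a contract error
  expect_error(predict_softmax(model, array(0, c(16, 16, 16, 4))), "channels")
  # zero-PFM ablation equals manual channel zeroing
  x0 <- x; x0[, , , 3:5] <- 0
  expect_equal(predict_softmax(model, x, ablate_pfm = "zero"),
               predict_softmax(model, x0))
})

test_that("dice loss matches closed forms and a hand evaluation on a 2^3 grid", {
  d <- c(2, 2, 2)
  y <- array(c(1L, 1L, 0L, 0L, 2L, 0L, 0L, 0L), d)
  oh <- onehot(y, 17L)
  expect_lt(dice_loss(oh, oh), 1e-4)          # perfect prediction
  # uniform prediction over 17 labels vs the hand-evaluated formula
  S <- array(1 / 17, c(d, 17))
  eps <- 1e-5
  per_label <- vapply(2:17, function(v) {
    g <- oh[, , , v]
    (2 * sum(g / 17) + eps) / (sum(rep(1 / 17, 8)) + sum(g) + eps)
  }, numeric(1))
  expect_equal(dice_loss(S, oh), 1 - mean(per_label), tolerance = 1e-12)
  # fully disjoint prediction and truth (all foreground labels involved)
  y2 <- array(1L, d)
  Sd <- onehot(array(2L, d), 3L)
  expect_equal(dice_loss(Sd, onehot(y2, 3L)), 1, tolerance = 1e-3)
})

test_that("signed distance maps match a brute-force all-pairs oracle", {
  d <- c(5, 5, 5)
  lab <- array(0L, d); lab[3, 3, 3] <- 1L
  sdm <- signed_distance_map(lab, 1L)
  # single-voxel label: its own boundary; distances are to (3,3,3)
  g <- bundleseg:::grid_coords(d) + 1
  oracle <- array(sqrt(rowSums(sweep(g, 2, c(3, 3, 3))^2)), d)
  expect_equal(sdm, oracle, tolerance = 1e-9)

  set.seed(9)
  lab2 <- array(0L, d)
  lab2[2:4, 2:3, 2:4] <- 1L
  sdm2 <- signed_distance_map(lab2, 1L)
  # brute force: boundary voxels, then signed all-pairs distances
  mask <- lab2 == 1L
  is_boundary <- function(i, j, k) {
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d)) return(TRUE)
      if (!mask[p[1], p[2], p[3]]) return(TRUE)
    }
    FALSE
  }
  bvox <- NULL
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if (mask[i, j, k] && is_boundary(i, j, k)) bvox <- rbind(bvox, c(i, j, k))
  oracle2 <- array(0, d)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    dd <- sqrt(min(rowSums(sweep(bvox, 2, c(i, j, k))^2)))
    sgn <- if (mask[i, j, k]) { if (dd == 0) 0 else -1 } else 1
    oracle2[i, j, k] <- sgn * dd
  }
  expect_equal(sdm2, oracle2, tolerance = 1e-9)

  # absent label: constant positive field, finite loss
  sdm3 <- signed_distance_map(array(0L, d), 4L)
  expect_true(all(sdm3 > 0))
  expect_equal(max(sdm3), min(sdm3))
})

test_that("boundary loss is zero when logits equal the negated distance map", {
  d <- c(4, 4, 4)
  lab <- array(0L, d); lab[2:3, 2:3, 2:3] <- 1L
  V <- 3L
  sdm <- array(0, c(d, V - 1))
  sdm[, , , 1] <- signed_distance_map(lab, 1L)
  sdm[, , , 2] <- signed_distance_map(lab, 2L)
  logits <- array(0, c(d, V))
  logits[, , , 2:3] <- -sdm
  expect_equal(boundary_loss(logits, sdm), 0)
  logits2 <- logits; logits2[, , , 2] <- logits2[, , , 2] + 2
  expect_gt(boundary_loss(logits2, sdm), 0)
})

test_that("training is seed-deterministic and records a sane history", {
  set.seed(10)
  d <- c(8, 8, 8)
  mkex <- function(seed) {
    set.seed(seed)
    y <- array(0L, d); y[3:6, 3:6, 3:6] <- 1L
    x <- array(rnorm(prod(d) * 2, mean = as.vector(y)), c(d, 2))
    list(x = x, y = y)
  }
  ds <- lapply(1:3, mkex)
  spec <- unet_spec(levels = 2L, base_features = 4L, in_channels = 2L,
                    classes = 2L, input_size = 8L)
  run <- function() {
    set.seed(5)
    m <- build_model(spec)
    train(m, ds, epochs = 2L, rng_seed = 11, augment = FALSE)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(is.finite(m1$history$train_loss)))
  # running minimum of the training loss is nonincreasing (bookkeeping)
  expect_true(all(diff(cummin(m1$history$train_loss)) <= 0))
})

test_that("a small model can overfit one example (capacity sanity)", {
  set.seed(12)
  d <- c(8, 8, 8)
  y <- array(0L, d); y[3:6, 3:6, 3:6] <- 1L
  x <- array(0, c(d, 2))
  x[, , , 1] <- y + 0.1 * rnorm(prod(d))
  x[, , , 2] <- 0.5
  ds <- list(list(x = x, y = y), list(x = x, y = y))
  spec <- unet_spec(levels = 2L, base_features = 6L, in_channels = 2L,
                    classes = 2L, input_size = 8L)
  set.seed(5)
  m <- build_model(spec)
  m <- train(m, ds, epochs = 60L, rng_seed = 3, augment = FALSE, lr = 3e-3)
  S <- predict_softmax(m, x)
  pred <- argmax_labels(S)
  expect_gte(dice(pred == 1L, y == 1L), 0.9)
})

test_that("argmax output translates with a translated input away from borders", {
  set.seed(14)
  S <- 32L
  spec <- unet_spec(levels = 3L, base_features = 4L, in_channels = 2L,
                    classes = 3L, input_size = S)
  model <- build_model(spec)
  x <- array(0, c(S, S, S, 2))
  x[8:11, 8:11, 8:11, 1] <- 1
  x[9:10, 9:10, 9:10, 2] <- 2
  sh <- 8L
  xs <- array(0, c(S, S, S, 2))
  xs[8:11 + sh, 8:11 + sh, 8:11 + sh, 1] <- 1
  xs[9:10 + sh, 9:10 + sh, 9:10 + sh, 2] <- 2
  p1 <- argmax_labels(predict_softmax(model, x))
  p2 <- argmax_labels(predict_softmax(model, xs))
  # compare the overlapping interior after shifting (a deep margin: with
  # zero 'same' padding the borders bleed into the receptive field)
  idx <- 7:(S - sh - 6)
  a <- p1[idx, idx, idx]
  b <- p2[idx + sh, idx + sh, idx + sh]
  expect_gte(mean(a == b), 0.95)
})
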