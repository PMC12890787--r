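#' Network architecture specification
#'
#' Five resolution levels by default, level n holding `base_features * 2^(n-1)`
#' features (24 -> [24, 48, 96, 192, 384]), two 3x3x3 convolutions with ELU
#' activations per level, 2x max-pool halving between levels, 5 input
#' channels, 17 output classes, and a multi-decoder attention gate on the
#' finest skip connection.
#'
#' @param levels number of resolution levels.
#' @param base_features features at the finest level.
#' @param in_channels input channel count.
#' @param classes output class count (background + foreground labels).
#' @param input_size edge length of the (cubic) input grid.
#' @export
unet_spec <- function(levels = 5L, base_features = 24L, in_channels = 5L,
                      classes = 17L, input_size = 64L) {
  structure(list(levels = as.integer(levels),
                 base_features = as.integer(base_features),
                 features = as.integer(base_features * 2^(0:(levels - 1))),
                 kernel = 3L, convs_per_level = 2L,
                 in_channels = as.integer(in_channels),
                 classes = as.integer(classes),
                 input_size = as.integer(input_size)),
            class = "unet_spec")
}

he_init <- function(k3cin, cout) {
  matrix(rnorm(k3cin * cout, sd = sqrt(2 / k3cin)), k3cin, cout)
}

#' Build an attention-gated 3D U-Net model
#'
#' Encoder/decoder with skip connections at every level; the attention gate is
#' applied only on the finest skip connection (unless ablated), integrating
#' upsampled gating signals from all decoder levels except the coarsest.
#' Decoder upsampling is trilinear followed by a 3x3x3 convolution; the final
#' layer is a 1x1x1 convolution to the class logits.
#'
#' @param spec a [unet_spec()].
#' @param ablate_attention if `TRUE`, the forward pass contains no gate
#'   (output shapes unchanged).
#' @return a `unet_model`: list with `spec`, `params` (named weight arrays),
#'   `ablate_attention`.
#' @export
build_model <- function(spec = unet_spec(), ablate_attention = FALSE) {
  L <- spec$levels; nf <- spec$features; k <- spec$kernel
  p <- list()
  cin <- spec$in_channels
  for (n in seq_len(L)) {
    p[[sprintf("enc%d_c1_w", n)]] <- he_init(k^3 * cin, nf[n])
    p[[sprintf("enc%d_c1_b", n)]] <- numeric(nf[n])
    p[[sprintf("enc%d_c2_w", n)]] <- he_init(k^3 * nf[n], nf[n])
    p[[sprintf("enc%d_c2_b", n)]] <- numeric(nf[n])
    cin <- nf[n]
  }
  for (n in seq_len(L - 1)) {
    p[[sprintf("up%d_w", n)]] <- he_init(k^3 * nf[n + 1], nf[n])
    p[[sprintf("up%d_b", n)]] <- numeric(nf[n])
    p[[sprintf("dec%d_c1_w", n)]] <- he_init(k^3 * 2 * nf[n], nf[n])
    p[[sprintf("dec%d_c1_b", n)]] <- numeric(nf[n])
    p[[sprintf("dec%d_c2_w", n)]] <- he_init(k^3 * nf[n], nf[n])
    p[[sprintf("dec%d_c2_b", n)]] <- numeric(nf[n])
  }
  p[["out_w"]] <- he_init(nf[1], spec$classes)
  p[["out_b"]] <- numeric(spec$classes)
  if (!ablate_attention && L >= 3) {
    p[["att_phia_w"]] <- matrix(rnorm(nf[1], sd = sqrt(2 / nf[1])), nf[1], 1)
    p[["att_phia_b"]] <- 0
    for (n in 2:(L - 1)) {
      p[[sprintf("att_phi%d_w", n)]] <- matrix(rnorm(nf[n], sd = sqrt(2 / nf[n])), nf[n], 1)
      p[[sprintf("att_phi%d_b", n)]] <- 0
    }
  }
  structure(list(spec = spec, params = p, ablate_attention = isTRUE(ablate_attention)),
            class = "unet_model")
}

#' Architecture audit
#'
#' Walks the model parameters and reports, per level, the feature width,
#' spatial grid size, and kernel size, plus the input/output channel counts —
#' the machine-checkable face of the architecture contract.
#'
#' @param model a `unet_model`.
#' @return list with `levels`, `features`, `grid`, `kernel`, `in_channels`,
#'   `classes`, `n_params`.
#' @export
unet_audit <- function(model) {
  s <- model$spec
  widths <- vapply(seq_len(s$levels),
                   function(n) ncol(model$params[[sprintf("enc%d_c2_w", n)]]), integer(1))
  k <- as.integer(round((nrow(model$params$enc1_c2_w) / widths[1])^(1 / 3)))
  list(levels = s$levels, features = widths,
       grid = as.integer(s$input_size * 2^(1 - seq_len(s$levels))),
       kernel = k,
       in_channels = as.integer(nrow(model$params$enc1_c1_w) / k^3),
       classes = ncol(model$params$out_w),
       n_params = sum(vapply(model$params, length, numeric(1))))
}

# ---- primitive layers ----------------------------------------------------

conv_fwd <- function(x, w, b, k = 3L) cpp_conv3d_fwd(x, as_int_dims(x), w, b, k)

elu_fwd <- function(x) { y <- x; neg <- x < 0; y[neg] <- exp(x[neg]) - 1; y }
elu_bwd <- function(g, y) { d <- g; neg <- y < 0; d[neg] <- g[neg] * (y[neg] + 1); d }

conv1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  y <- matrix(x, prod(d[1:3]), d[4]) %*% w
  y <- sweep(y, 2, b, "+")
  array(y, c(d[1:3], ncol(w)))
}

cat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

softmax4 <- function(z) {
  d <- dim(z)
  m <- matrix(z, prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Multi-decoder attention gate
#'
#' Computes
#' \deqn{\Phi_{att} = F_{d1} \circ \sigma\big(\varphi_a \otimes
#'   \mathrm{relu}(F_{e1}) + \sum_n \varphi_n \otimes
#'   \tanh(U(F_{dn}))\big)}
#' where the \eqn{\varphi} are 1x1x1 convolutions producing a single gate
#' channel, U is trilinear upsampling to the resolution of \eqn{F_{e1}}, and
#' the sigmoid gate multiplies \eqn{F_{d1}} elementwise (broadcast over
#' channels). Note the gate modulates the incoming decoder tensor, not the
#' encoder features as in conventional attention U-Nets.
#'
#' @param Fd1 decoder tensor at full resolution (X,Y,Z,C).
#' @param Fe1 encoder tensor at full resolution.
#' @param gating list of decoder tensors at their native (coarser)
#'   resolutions; the coarsest decoder layer is excluded by the caller.
#' @param weights list with `phia_w` (C_e x 1), `phia_b` (scalar), and `phi`
#'   (list of `list(w, b)` matching `gating`).
#' @return the gated tensor (same shape as `Fd1`); with `return_gate = TRUE`,
#'   a list with `out` and the 3D `gate` field in (0, 1).
#' @param return_gate return the gate field alongside the output.
#' @export
attention_gate <- function(Fd1, Fe1, gating, weights, return_gate = FALSE) {
  d <- dim(Fd1)
  if (!identical(dim(Fe1)[1:3], d[1:3])) stopf("Fd1/Fe1 spatial dims differ")
  a <- conv1x1_fwd(pmax(Fe1, 0), weights$phia_w, weights$phia_b)
  for (j in seq_along(gating)) {
    up <- cpp_resize_trilinear_fwd(gating[[j]], as_int_dims(gating[[j]]),
                                   c(d[1:3], dim(gating[[j]])[4]))
    a <- a + conv1x1_fwd(tanh(up), weights$phi[[j]]$w, weights$phi[[j]]$b)
  }
  gate <- 1 / (1 + exp(-a[, , , 1]))
  out <- Fd1 * as.vector(gate)
  if (return_gate) list(out = out, gate = gate) else out
}

# ---- forward / backward --------------------------------------------------

gate_weights <- function(p, L) {
  list(phia_w = p$att_phia_w, phia_b = p$att_phia_b,
       phi = lapply(2:(L - 1), function(n)
         list(w = p[[sprintf("att_phi%d_w", n)]], b = p[[sprintf("att_phi%d_b", n)]])))
}

unet_forward <- function(model, x, store = FALSE) {
  s <- model$spec; L <- s$levels; p <- model$params; k <- s$kernel
  cache <- if (store) list(x = x) else NULL
  # in training mode the unfolded (im2col) patch matrices are kept so the
  # backward pass reuses them for both weight and input gradients
  conv <- if (store) {
    function(xx, wname, cname) {
      cols <- cpp_im2col(xx, as_int_dims(xx), k)
      cache[[cname]] <<- cols
      y <- cols %*% p[[paste0(wname, "_w")]]
      y <- sweep(y, 2, p[[paste0(wname, "_b")]], "+")
      array(y, c(dim(xx)[1:3], ncol(y)))
    }
  } else {
    function(xx, wname, cname)
      cpp_conv3d_fwd(xx, as_int_dims(xx), p[[paste0(wname, "_w")]],
                     p[[paste0(wname, "_b")]], k)
  }
  Fe <- vector("list", L); pool_am <- vector("list", L)
  t <- x
  for (n in seq_len(L)) {
    a1 <- elu_fwd(conv(t, sprintf("enc%d_c1", n), sprintf("enc%d_c1_cols", n)))
    a2 <- elu_fwd(conv(a1, sprintf("enc%d_c2", n), sprintf("enc%d_c2_cols", n)))
    Fe[[n]] <- a2
    if (store) cache[[sprintf("enc%d_a1", n)]] <- a1
    if (n < L) {
      mp <- cpp_maxpool3d_fwd(a2, as_int_dims(a2))
      t <- mp$y
      if (store) pool_am[[n]] <- mp$argmax
    }
  }
  Fd <- vector("list", L)
  Fd[[L]] <- Fe[[L]]
  pregate <- NULL; gate <- NULL
  for (n in (L - 1):1) {
    src <- Fd[[n + 1]]
    up <- cpp_resize_trilinear_fwd(src, as_int_dims(src), c(dim(src)[1:3] * 2L, dim(src)[4]))
    u <- elu_fwd(conv(up, sprintf("up%d", n), sprintf("up%d_cols", n)))
    if (store) cache[[sprintf("up%d_out", n)]] <- u
    if (n == 1 && !model$ablate_attention && L >= 3) {
      pregate <- u
      gt <- attention_gate(u, Fe[[1]], Fd[2:(L - 1)], gate_weights(p, L), return_gate = TRUE)
      u <- gt$out; gate <- gt$gate
    }
    ct <- cat4(u, Fe[[n]])
    b1 <- elu_fwd(conv(ct, sprintf("dec%d_c1", n), sprintf("dec%d_c1_cols", n)))
    b2 <- elu_fwd(conv(b1, sprintf("dec%d_c2", n), sprintf("dec%d_c2_cols", n)))
    Fd[[n]] <- b2
    if (store) cache[[sprintf("dec%d_b1", n)]] <- b1
  }
  logits <- conv1x1_fwd(Fd[[1]], p$out_w, p$out_b)
  if (store) {
    cache$Fe <- Fe; cache$Fd <- Fd; cache$pool_am <- pool_am
    cache$pregate <- pregate; cache$gate <- gate
  }
  list(logits = logits, cache = cache)
}

# conv backward from cached patch matrices; gx omitted when unused
conv_bwd_cached <- function(cache, cname, w, gout, in_dims, k, need_gx = TRUE) {
  d <- dim(gout)
  G <- matrix(gout, prod(d[1:3]), d[4])
  cols <- cache[[cname]]
  out <- list(gw = crossprod(cols, G), gb = colSums(G))
  if (need_gx)
    out$gx <- cpp_col2im(G %*% t(w), as.integer(in_dims), k)
  out
}

# backward pass; glogits is dLoss/dlogits. Returns named gradient list.
unet_backward <- function(model, glogits, cache) {
  s <- model$spec; L <- s$levels; p <- model$params; k <- s$kernel
  g <- list()
  Fe <- cache$Fe; Fd <- cache$Fd
  d1 <- dim(Fd[[1]])
  gm <- matrix(glogits, prod(d1[1:3]), dim(glogits)[4])
  fm <- matrix(Fd[[1]], prod(d1[1:3]), d1[4])
  g$out_w <- crossprod(fm, gm)
  g$out_b <- colSums(gm)
  gFd <- vector("list", L)
  gFd[[1]] <- array(gm %*% t(p$out_w), d1)
  gFe <- vector("list", L)
  gate_extra <- NULL      # gradients flowing into Fd[2..L-1] via the gate
  for (n in seq_len(L - 1)) {
    # through dec_n convs
    b1 <- cache[[sprintf("dec%d_b1", n)]]
    gb2 <- elu_bwd(gFd[[n]], Fd[[n]])
    bw2 <- conv_bwd_cached(cache, sprintf("dec%d_c2_cols", n),
                           p[[sprintf("dec%d_c2_w", n)]], gb2, as_int_dims(b1), k)
    g[[sprintf("dec%d_c2_w", n)]] <- bw2$gw; g[[sprintf("dec%d_c2_b", n)]] <- bw2$gb
    gb1 <- elu_bwd(bw2$gx, b1)
    u_out <- cache[[sprintf("up%d_out", n)]]
    ct_dims <- c(dim(b1)[1:3], dim(u_out)[4] + dim(Fe[[n]])[4])
    bw1 <- conv_bwd_cached(cache, sprintf("dec%d_c1_cols", n),
                           p[[sprintf("dec%d_c1_w", n)]], gb1, ct_dims, k)
    g[[sprintf("dec%d_c1_w", n)]] <- bw1$gw; g[[sprintf("dec%d_c1_b", n)]] <- bw1$gb
    dct <- bw1$gx
    cu <- dim(cache[[sprintf("up%d_out", n)]])[4]
    gu <- array(dct[, , , seq_len(cu)], c(dim(dct)[1:3], cu))
    ge <- array(dct[, , , cu + seq_len(dim(dct)[4] - cu)], c(dim(dct)[1:3], dim(dct)[4] - cu))
    gFe[[n]] <- if (is.null(gFe[[n]])) ge else gFe[[n]] + ge
    if (n == 1 && !model$ablate_attention && L >= 3) {
      # through the gate: u_gated = pregate * gate
      pregate <- cache$pregate; gate <- cache$gate
      gpre <- gu * as.vector(gate)
      dgate <- rowSums(matrix(gu * pregate, prod(dim(gate)), dim(gu)[4]))
      da <- array(dgate * as.vector(gate) * (1 - as.vector(gate)), c(dim(gate), 1))
      dam <- matrix(da, ncol = 1)
      # encoder branch: phia . relu(Fe1)
      re <- pmax(Fe[[1]], 0)
      rem <- matrix(re, prod(dim(gate)), dim(re)[4])
      g$att_phia_w <- crossprod(rem, dam)
      g$att_phia_b <- sum(dam)
      drelu <- array(dam %*% t(p$att_phia_w), dim(Fe[[1]]))
      drelu[Fe[[1]] <= 0] <- 0
      gFe[[1]] <- gFe[[1]] + drelu
      # decoder gating branches
      gate_extra <- vector("list", L)
      for (nn in 2:(L - 1)) {
        src <- Fd[[nn]]
        up <- cpp_resize_trilinear_fwd(src, as_int_dims(src), c(dim(gate), dim(src)[4]))
        tn <- tanh(up)
        tnm <- matrix(tn, prod(dim(gate)), dim(src)[4])
        wn <- p[[sprintf("att_phi%d_w", nn)]]
        g[[sprintf("att_phi%d_w", nn)]] <- crossprod(tnm, dam)
        g[[sprintf("att_phi%d_b", nn)]] <- sum(dam)
        dtn <- array(dam %*% t(wn), dim(up)) * (1 - tn^2)
        gate_extra[[nn]] <- cpp_resize_trilinear_bwd(dtn, as_int_dims(dtn), as_int_dims(src))
      }
      gu <- gpre
    }
    # through the up-convolution
    guc <- elu_bwd(gu, u_out)
    up_dims <- c(dim(u_out)[1:3], dim(Fd[[n + 1]])[4])
    uw <- conv_bwd_cached(cache, sprintf("up%d_cols", n),
                          p[[sprintf("up%d_w", n)]], guc, up_dims, k)
    g[[sprintf("up%d_w", n)]] <- uw$gw; g[[sprintf("up%d_b", n)]] <- uw$gb
    gsrc <- cpp_resize_trilinear_bwd(uw$gx, as_int_dims(uw$gx), as_int_dims(Fd[[n + 1]]))
    gFd[[n + 1]] <- if (is.null(gFd[[n + 1]])) gsrc else gFd[[n + 1]] + gsrc
    if (!is.null(gate_extra) && n + 1 <= L - 1 && !is.null(gate_extra[[n + 1]]))
      gFd[[n + 1]] <- gFd[[n + 1]] + gate_extra[[n + 1]]
  }
  gFe[[L]] <- gFd[[L]]     # Fd_L == Fe_L
  # encoder backward
  gnext <- NULL
  for (n in L:1) {
    ge <- gFe[[n]] %||% array(0, dim(Fe[[n]]))
    if (!is.null(gnext)) {
      gp <- cpp_maxpool3d_bwd(gnext, cache$pool_am[[n]], as_int_dims(Fe[[n]]))
      ge <- ge + gp
    }
    ga2 <- elu_bwd(ge, Fe[[n]])
    a1 <- cache[[sprintf("enc%d_a1", n)]]
    ew2 <- conv_bwd_cached(cache, sprintf("enc%d_c2_cols", n),
                           p[[sprintf("enc%d_c2_w", n)]], ga2, as_int_dims(a1), k)
    g[[sprintf("enc%d_c2_w", n)]] <- ew2$gw; g[[sprintf("enc%d_c2_b", n)]] <- ew2$gb
    ga1 <- elu_bwd(ew2$gx, a1)
    in_ch <- nrow(p[[sprintf("enc%d_c1_w", n)]]) / k^3
    in_dims <- c(dim(a1)[1:3], in_ch)
    # no consumer needs the gradient w.r.t. the network input itself
    ew1 <- conv_bwd_cached(cache, sprintf("enc%d_c1_cols", n),
                           p[[sprintf("enc%d_c1_w", n)]], ga1, in_dims, k,
                           need_gx = n > 1)
    g[[sprintf("enc%d_c1_w", n)]] <- ew1$gw; g[[sprintf("enc%d_c1_b", n)]] <- ew1$gb
    gnext <- if (n > 1) ew1$gx else NULL
  }
  g
}

# ---- losses --------------------------------------------------------------

#' One-hot encoding of a label map
#' @param labels 3D integer array with values 0..classes-1.
#' @param classes number of classes.
#' @export
onehot <- function(labels, classes) {
  d <- dim(labels)
  oh <- array(0, c(d, classes))
  m <- matrix(oh, prod(d), classes)
  m[cbind(seq_len(prod(d)), as.integer(labels) + 1L)] <- 1
  array(m, c(d, classes))
}

#' Soft Dice loss
#'
#' \eqn{1 - } mean over foreground labels of
#' \eqn{(2\sum S g + \epsilon) / (\sum S + \sum g + \epsilon)} with
#' \eqn{\epsilon = 10^{-5}}.
#'
#' @param S (X,Y,Z,V) probability field.
#' @param g one-hot ground truth of the same shape; 4th-dim slice 1 is
#'   background and excluded by default.
#' @param eps smoothing constant.
#' @return scalar loss; with `grad = TRUE`, list with `loss` and `gS`.
#' @param grad also return the gradient with respect to `S`.
#' @export
dice_loss <- function(S, g, eps = 1e-5, grad = FALSE) {
  d <- dim(S)
  V <- d[4]; n <- prod(d[1:3])
  Sm <- matrix(S, n, V); gm <- matrix(g, n, V)
  fg <- 2:V
  num <- 2 * colSums(Sm[, fg, drop = FALSE] * gm[, fg, drop = FALSE]) + eps
  den <- colSums(Sm[, fg, drop = FALSE]) + colSums(gm[, fg, drop = FALSE]) + eps
  loss <- 1 - mean(num / den)
  if (!grad) return(loss)
  gS <- matrix(0, n, V)
  nf <- length(fg)
  for (j in seq_along(fg)) {
    v <- fg[j]
    gS[, v] <- -(2 * gm[, v] * den[j] - num[j]) / den[j]^2 / nf
  }
  list(loss = loss, gS = array(gS, d))
}

#' Signed distance map of one label
#'
#' Euclidean distance (mm) to the label's boundary voxels (label voxels with
#' at least one 6-neighbor outside the label); negative inside the label,
#' zero on the boundary voxels, positive outside. An absent label yields a
#' constant `+max_dist` field (the frame diagonal).
#'
#' @param lm a [label_map()] (or plain 3D integer array).
#' @param v label value.
#' @param spacing voxel size (mm), length 1 or 3.
#' @export
signed_distance_map <- function(lm, v, spacing = 1.0) {
  data <- if (inherits(lm, "label_map")) lm$data else lm
  d <- dim(data)
  spacing <- rep(spacing, length.out = 3)
  mask <- data == v
  if (!any(mask)) {
    return(array(sqrt(sum((d * spacing)^2)), d))
  }
  # boundary voxels: inside with a face-neighbor outside (or at the frame edge)
  inside_all <- array(TRUE, d)
  shifted_and <- function(acc, ax, dlt) {
    idx_src <- lapply(seq_len(3), function(a) seq_len(d[a]))
    idx_dst <- idx_src
    nb <- array(FALSE, d)
    if (dlt > 0) { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (dlt in c(-1, 1)) inside_all <- shifted_and(inside_all, ax, dlt)
  boundary <- mask & !inside_all
  dist <- sqrt(cpp_edt_sq(as.integer(boundary), as.integer(d), as.double(spacing)))
  sgn <- array(1, d)
  sgn[mask] <- -1
  sgn[boundary] <- 0
  array(sgn * dist, d)
}

#' Boundary (signed-distance) training loss
#'
#' Mean absolute difference between the pre-softmax logits and the negated
#' signed distance maps of the foreground labels: logits are driven positive
#' inside a structure and negative outside, with magnitude growing with
#' distance from its boundary.
#'
#' @param logits (X,Y,Z,V) pre-softmax logits.
#' @param sdm (X,Y,Z,V-1) stack of per-foreground-label signed distance maps.
#' @param grad also return the gradient with respect to the logits.
#' @export
boundary_loss <- function(logits, sdm, grad = FALSE) {
  d <- dim(logits)
  V <- d[4]
  diff <- logits[, , , 2:V, drop = FALSE] - (-sdm)
  loss <- mean(abs(diff))
  if (!grad) return(loss)
  gl <- array(0, d)
  gl[, , , 2:V] <- sign(diff) / length(diff)
  list(loss = loss, glogits = gl)
}

# combined loss on logits; returns loss value and dLoss/dlogits.
# The "dice" kind optimizes foreground Dice + cross-entropy: the Dice term
# alone has degenerate optima under heavy class imbalance (an abandoned
# background class, or an all-background collapse); the cross-entropy term
# supplies dense, well-scaled gradients to every class including background.
loss_and_grad <- function(logits, oh, sdm, kind, alpha = 0.5) {
  S <- softmax4(logits)
  d <- dim(S)
  if (kind %in% c("dice", "hybrid")) {
    dl <- dice_loss(S, oh, grad = TRUE)
    # softmax backward
    n <- prod(d[1:3])
    gSm <- matrix(dl$gS, n, d[4]); Sm <- matrix(S, n, d[4])
    dot <- rowSums(gSm * Sm)
    gz_dice <- array(Sm * (gSm - dot), d)
    # auxiliary class-balanced cross-entropy: square-root inverse-frequency
    # voxel weights temper the background majority without letting rare
    # classes dominate, so the background class gets an explicit gradient
    # while foreground learning is not drowned out
    ohm <- matrix(oh, n, d[4])
    counts <- colSums(ohm)
    omega <- sqrt(n / (d[4] * (counts + 1)))
    wv <- as.vector(ohm %*% omega)          # per-voxel weight
    W <- sum(wv)
    ce <- -sum(wv * log(pmax(rowSums(ohm * matrix(S, n, d[4])), 1e-12))) / W
    gz_ce <- array((matrix(S, n, d[4]) - ohm) * wv / W, d)
    dl$loss <- dl$loss + ce
    gz_dice <- gz_dice + gz_ce
  }
  if (kind %in% c("boundary", "hybrid")) {
    bl <- boundary_loss(logits, sdm, grad = TRUE)
  }
  switch(kind,
    dice = list(loss = dl$loss, glogits = gz_dice),
    boundary = list(loss = bl$loss, glogits = bl$glogits),
    hybrid = list(loss = alpha * dl$loss + (1 - alpha) * bl$loss,
                  glogits = alpha * gz_dice + (1 - alpha) * bl$glogits))
}

# ---- training ------------------------------------------------------------

# random spatial + intensity augmentation of (x, y) pair.
# Affine: rotations up to +-10 deg per axis, isotropic scale +-10%;
# elastic: Gaussian-smoothed random displacement; intensity jitter +-10%
# per channel; Rician noise (magnitude of complex Gaussian perturbation).
augment_example <- function(x, y, params = list()) {
  d <- dim(x)[1:3]
  rot_deg <- params$rot_deg %||% 10
  scale_pct <- params$scale_pct %||% 0.10
  elastic_amp <- params$elastic_amp %||% 1.5
  jitter <- params$jitter %||% 0.10
  rician_sigma <- params$rician_sigma %||% 0.02
  ang <- runif(3, -rot_deg, rot_deg) * pi / 180
  sc <- 1 + runif(1, -scale_pct, scale_pct)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  A <- (Rx %*% Ry %*% Rz) / sc            # inverse map (target -> source)
  ctr <- (d - 1) / 2
  tgt <- grid_coords(d)
  src <- sweep(sweep(tgt, 2, ctr) %*% t(A), 2, ctr, "+")
  # smooth elastic displacement, identical for all channels and labels
  for (ax in 1:3) {
    f <- array(rnorm(prod(d)), d)
    f <- cpp_gauss_smooth3d(as.double(f), as.integer(d), max(2, d[1] / 8))
    f <- f / max(abs(f), 1e-12) * elastic_amp
    src[, ax] <- src[, ax] + as.vector(f)
  }
  xa <- array(0, dim(x))
  for (c in seq_len(dim(x)[4])) {
    v <- cpp_sample3d(as.double(x[, , , c]), as.integer(d), src, 0L, 0.0)
    v <- v * (1 + runif(1, -jitter, jitter))
    if (rician_sigma > 0) {
      v <- sqrt((v + rnorm(length(v), sd = rician_sigma))^2 +
                  rnorm(length(v), sd = rician_sigma)^2)
    }
    xa[, , , c] <- v
  }
  ya <- array(as.integer(cpp_sample3d(as.double(y), as.integer(d), src, 1L, 0.0)), d)
  list(x = xa, y = ya)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- gr * 0; state$v[[nm]] <- gr * 0 }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train the segmentation network
#'
#' Mini-batch (batch size 1) gradient training with Adam, a fixed
#' train/validation split, optional on-the-fly augmentation, and per-epoch
#' validation Dice. Deterministic given `rng_seed`. The `"dice"` loss kind
#' optimizes foreground Dice plus cross-entropy — the plain Dice term alone
#' has degenerate optima under the heavy class imbalance of whole-volume
#' segmentation; the cross-entropy term removes them. Validation Dice is
#' always reported as plain mean foreground Dice.
#'
#' @param model a `unet_model` from [build_model()].
#' @param dataset list of examples, each `list(x = (X,Y,Z,C) array,
#'   y = 3D integer label array)`.
#' @param loss_kind `"dice"`, `"boundary"` or `"hybrid"`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param split training fraction (the rest is validation).
#' @param augment logical; apply random augmentation to training examples.
#' @param augment_params list overriding augmentation magnitudes.
#' @param hybrid_alpha Dice weight of the hybrid loss.
#' @param rng_seed seed controlling the split, shuffling, init-independent
#'   augmentation and noise.
#' @param verbose print per-epoch progress.
#' @return the trained model, with `history` (per-epoch data frame: mean
#'   training loss, validation Dice) attached.
#' @export
train <- function(model, dataset, loss_kind = c("dice", "boundary", "hybrid"),
                  epochs = 30L, lr = 1e-3, split = 0.8, augment = TRUE,
                  augment_params = list(), hybrid_alpha = 0.5, rng_seed = 1L,
                  verbose = FALSE) {
  loss_kind <- match.arg(loss_kind)
  if (length(dataset) < 2) stopf("need at least 2 labeled examples")
  set.seed(rng_seed)
  n <- length(dataset)
  ntr <- max(1, round(split * n))
  if (ntr >= n) ntr <- n - 1
  ord <- sample(n)
  tr <- ord[seq_len(ntr)]; va <- ord[(ntr + 1):n]
  V <- model$spec$classes
  sdm_cache <- vector("list", n)
  need_sdm <- loss_kind %in% c("boundary", "hybrid")
  state <- list(t = 0, m = list(), v = list())
  hist <- data.frame(epoch = integer(), train_loss = numeric(), val_dice = numeric())
  for (ep in seq_len(epochs)) {
    ep_losses <- numeric(0)
    for (i in sample(tr)) {
      ex <- dataset[[i]]
      if (augment) ex <- augment_example(ex$x, ex$y, augment_params)
      oh <- onehot(ex$y, V)
      sdm <- NULL
      if (need_sdm) {
        d3 <- dim(ex$y)
        sdm <- array(0, c(d3, V - 1))
        for (v in seq_len(V - 1)) sdm[, , , v] <- signed_distance_map(ex$y, v)
      }
      fw <- unet_forward(model, ex$x, store = TRUE)
      lg <- loss_and_grad(fw$logits, oh, sdm, loss_kind, hybrid_alpha)
      grads <- unet_backward(model, lg$glogits, fw$cache)
      st <- adam_step(model$params, grads, state, lr)
      model$params <- st$params; state <- st$state
      ep_losses <- c(ep_losses, lg$loss)
    }
    vd <- mean(vapply(va, function(i) {
      pr <- predict_softmax(model, dataset[[i]]$x)
      mean_foreground_dice(crf_argmax(pr)$data, dataset[[i]]$y)
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses), val_dice = vd))
    if (verbose) message(sprintf("epoch %d: loss %.4f, val dice %.3f", ep, mean(ep_losses), vd))
  }
  model$history <- hist
  model
}

#' Mean Dice over the foreground labels present in the truth
#' @param pred,truth 3D integer label arrays.
#' @export
mean_foreground_dice <- function(pred, truth) {
  labs <- setdiff(sort(unique(as.integer(truth))), 0L)
  if (!length(labs)) return(NA_real_)
  mean(vapply(labs, function(v) dice(pred == v, truth == v), numeric(1)))
}

#' Network inference to a probability field
#'
#' @param model a trained `unet_model`.
#' @param x a `channel_stack` or (X,Y,Z,C) array.
#' @param ablate_pfm `"none"`, `"zero"` (channels 3-5 zeroed) or `"v1"`
#'   (channels 3-5 replaced by the principal-direction components, which must
#'   be supplied via `v1`).
#' @param v1 (X,Y,Z,3) array, required for `ablate_pfm = "v1"`.
#' @return (X,Y,Z,V) probability field with per-voxel sums of 1.
#' @export
predict_softmax <- function(model, x, ablate_pfm = c("none", "zero", "v1"), v1 = NULL) {
  ablate_pfm <- match.arg(ablate_pfm)
  if (inherits(x, "channel_stack")) x <- x$data
  if (dim(x)[4] != model$spec$in_channels)
    stopf("input has %d channels, model expects %d", dim(x)[4], model$spec$in_channels)
  if (ablate_pfm == "zero") x[, , , 3:5] <- 0
  if (ablate_pfm == "v1") {
    if (is.null(v1)) stopf("ablate_pfm = 'v1' requires the v1 field")
    x[, , , 3:5] <- v1
  }
  softmax4(unet_forward(model, x, store = FALSE)$logits)
}
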