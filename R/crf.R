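#' Semidense CRF parameters
#'
#' @param wu unary weight (dimensionless).
#' @param lambda label-entropy weight.
#' @param sigma_b shared RBF bandwidth of the spatial and intensity pairwise
#'   components (probability scale).
#' @param sigma_k Gaussian smoothing-kernel width, voxels.
#' @param nbhd Chebyshev half-span of the pairwise neighborhood, voxels.
#' @param iters fixed mean-field iteration count (no early stopping).
#' @param pairwise set `FALSE` for the \eqn{\sigma_b \to \infty} limit
#'   (pairwise term disabled).
#' @export
crf_params <- function(wu = 1.0, lambda = 0.1, sigma_b = 0.05, sigma_k = 5,
                       nbhd = 3L, iters = 5L, pairwise = TRUE) {
  stopifnot(sigma_b > 0, sigma_k > 0, nbhd >= 1, iters >= 1)
  structure(list(wu = wu, lambda = lambda, sigma_b = sigma_b, sigma_k = sigma_k,
                 nbhd = as.integer(nbhd), iters = as.integer(iters),
                 pairwise = isTRUE(pairwise)),
            class = "crf_params")
}

# floor probabilities before any log
PROB_FLOOR <- 1e-12

check_softmax <- function(S, tol = 1e-5) {
  d <- dim(S)
  stopifnot(length(d) == 4)
  rs <- rowSums(matrix(S, ncol = d[4]), dims = 1)
  if (max(abs(rs - 1)) > tol) stopf("probability field rows do not sum to 1")
  if (min(S) < 0) stopf("negative probabilities")
  invisible(TRUE)
}

#' Unary CRF potential
#'
#' \eqn{\psi_u(i, v) = -\log S(i, v)} with probabilities floored at 1e-12.
#'
#' @param S (X,Y,Z,V) probability field (label 1 of the 4th dim = background).
#' @return array of the same shape.
#' @export
unary_potential <- function(S) {
  array(-log(pmax(S, PROB_FLOOR)), dim(S))
}

#' Label-entropy CRF potential
#'
#' Per-voxel expected negative log probability over foreground labels:
#' \eqn{\psi_H(i) = -\sum_{v \ne bg} S(i,v) \log S(i,v)}. The background label
#' is excluded so that certainty is regularized for foreground structure
#' without background interference.
#'
#' @param S (X,Y,Z,V) probability field; 4th-dim slice 1 is background.
#' @return 3D per-voxel field.
#' @export
entropy_potential <- function(S) {
  d <- dim(S)
  fg <- array(S[, , , -1, drop = FALSE], c(prod(d[1:3]), d[4] - 1))
  h <- -rowSums(fg * log(pmax(fg, PROB_FLOOR)))
  array(h, d[1:3])
}

#' Gaussian-smoothed label probabilities
#'
#' Per-label 3D convolution with a normalized isotropic Gaussian of width
#' `sigma_k` voxels, truncated at 3 sigma (border-renormalized, so constants
#' are preserved exactly and interior per-voxel label sums are conserved).
#'
#' @param S (X,Y,Z,V) probability field.
#' @param sigma_k kernel width in voxels.
#' @export
smoothed_probabilities <- function(S, sigma_k) {
  stopifnot(sigma_k > 0)
  d <- dim(S)
  out <- array(0, d)
  for (v in seq_len(d[4]))
    out[, , , v] <- cpp_gauss_smooth3d(as.double(S[, , , v]), as.integer(d[1:3]), sigma_k)
  out
}

#' Composite CRF energy (diagnostic form)
#'
#' Evaluates the closed computational form of the CRF energy exactly as
#' printed, with the pairwise log-potential realized by Gaussian smoothing of
#' the probability field:
#' \deqn{E = -\sum_i \sum_v \Big[ \sum_{\{i,i'\} \in X_i}
#'   \frac{(S_{\sigma_K}(i';v) - S_{\sigma_K}(i;v))^2}{4\pi \sigma_b \sigma_K}
#'   + \log S(i,v)\,(1_{v \ne bg}\,\lambda\, S(i,v) + w_u) \Big]}
#' The pairwise sum runs over unordered voxel pairs within a Chebyshev
#' half-span of `nbhd` voxels. This is a diagnostic/audit quantity; the
#' mean-field solver ([mean_field_refine()]) is independent of it.
#'
#' @param S (X,Y,Z,V) probability field, 4th-dim slice 1 = background.
#' @param params a [crf_params()].
#' @return an `energy_report`: list with `total`, `unary`, `pairwise`,
#'   `entropy` (weighted terms; `total` is their sum).
#' @export
crf_energy <- function(S, params = crf_params()) {
  check_softmax(S)
  d <- dim(S)
  Sf <- pmax(S, PROB_FLOOR)
  # unary term: -sum wu * log S
  unary <- -params$wu * sum(log(Sf))
  # entropy term: -lambda * sum_{v != bg} S log S
  fg <- S[, , , -1, drop = FALSE]
  entropy <- -params$lambda * sum(fg * log(pmax(fg, PROB_FLOOR)))
  # pairwise term over unordered pairs within Chebyshev half-span
  Sk <- smoothed_probabilities(S, params$sigma_k)
  nb <- params$nbhd
  acc <- 0
  offs <- expand.grid(dx = -nb:nb, dy = -nb:nb, dz = -nb:nb)
  offs <- offs[offs$dx + (2 * nb + 1) * (offs$dy + (2 * nb + 1) * offs$dz) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    a <- Sk[xs, ys, zs, , drop = FALSE]
    b <- Sk[xs + dx, ys + dy, zs + dz, , drop = FALSE]
    acc <- acc + sum((b - a)^2)
  }
  pairwise <- -acc / (4 * pi * params$sigma_b * params$sigma_k)
  total <- unary + pairwise + entropy
  structure(list(total = total, unary = unary, pairwise = pairwise, entropy = entropy),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> total %.6g (unary %.6g, pairwise %.6g, entropy %.6g)\n",
              x$total, x$unary, x$pairwise, x$entropy))
  invisible(x)
}

#' Mean-field refinement of a probability field
#'
#' Runs exactly `iters` mean-field iterations (fixed run time, no early
#' stopping), starting from \eqn{Q^0 = S}. Per iteration, per voxel and label:
#' \deqn{\mathrm{logit}(i,v) = w_u \log S(i,v)
#'   + \frac{(K_{\sigma_K} \otimes Q^{t-1})(i,v)}{2 \sigma_b \sigma_K}
#'   + \lambda\, 1_{v \ne bg} \log Q^{t-1}(i,v)}
#' followed by a per-voxel softmax. The three terms are the coordinate-wise
#' stationarity contributions of the unary, convolution-approximated pairwise
#' support, and foreground-entropy energy terms. With `pairwise = FALSE`,
#' `wu = 1`, `lambda = 0` the update is the identity (unary-only fixed point).
#'
#' @param S (X,Y,Z,V) probability field, 4th-dim slice 1 = background.
#' @param params a [crf_params()].
#' @return refined probability field, rows summing to 1 after every iteration.
#' @export
mean_field_refine <- function(S, params = crf_params()) {
  check_softmax(S)
  d <- dim(S)
  n <- prod(d[1:3]); V <- d[4]
  logS <- matrix(log(pmax(S, PROB_FLOOR)), n, V)
  fg_cols <- 2:V
  Q <- S
  for (t in seq_len(params$iters)) {
    logit <- params$wu * logS
    if (params$pairwise) {
      Qs <- smoothed_probabilities(Q, params$sigma_k)
      logit <- logit + matrix(Qs, n, V) / (2 * params$sigma_b * params$sigma_k)
    }
    if (params$lambda != 0) {
      lq <- matrix(log(pmax(Q, PROB_FLOOR)), n, V)
      logit[, fg_cols] <- logit[, fg_cols] + params$lambda * lq[, fg_cols]
    }
    m <- logit - apply(logit, 1, max)
    e <- exp(m)
    Q <- array(e / rowSums(e), d)
  }
  Q
}

#' Per-voxel argmax labeling of a probability field
#'
#' Ties are broken toward background (conservative for small structures).
#'
#' @param Q (X,Y,Z,V) probability field, 4th-dim slice 1 = background.
#' @param affine affine of the frame.
#' @return a [label_map()] with values 0..V-1.
#' @export
crf_argmax <- function(Q, affine = diag(4)) {
  d <- dim(Q)
  m <- matrix(Q, prod(d[1:3]), d[4])
  # background (column 1) wins exact ties: scan columns in order, strict '>'
  best <- m[, 1]
  lab <- rep(0L, nrow(m))
  for (v in 2:d[4]) {
    gt <- m[, v] > best
    best[gt] <- m[gt, v]
    lab[gt] <- v - 1L
  }
  label_map(array(lab, d[1:3]), affine)
}
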