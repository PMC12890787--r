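#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks score 1 (absence
#' correctly predicted); empty vs nonempty scores 0.
#'
#' @param a,b binary (or logical) arrays on the same grid.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("dice: grids differ")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# boundary voxels of a binary mask: mask voxels with a 6-neighbor outside
# (frame edges count as outside)
mask_boundary <- function(mask) {
  d <- dim(mask)
  inside_all <- array(TRUE, d)
  for (ax in 1:3) for (dlt in c(-1L, 1L)) {
    nb <- array(FALSE, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (dlt > 0) { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    inside_all <- inside_all & nb
  }
  mask & !inside_all
}

#' Symmetric average Hausdorff distance
#'
#' Mean boundary-to-boundary distance in mm, symmetrized:
#' \eqn{\tfrac12[\mathrm{mean}_{x \in \partial A} d(x, \partial B) +
#' \mathrm{mean}_{y \in \partial B} d(y, \partial A)]} over boundary voxels.
#' Undefined (NA) if either mask is empty.
#'
#' @param a,b binary arrays on the same grid.
#' @param spacing voxel size in mm (length 1 or 3).
#' @export
average_hausdorff <- function(a, b, spacing = 1.0) {
  if (!identical(dim(a), dim(b))) stopf("average_hausdorff: grids differ")
  a <- a > 0; b <- b > 0
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  spacing <- rep(spacing, length.out = 3)
  ba <- mask_boundary(a); bb <- mask_boundary(b)
  d <- dim(a)
  dist_to_b <- sqrt(cpp_edt_sq(as.integer(bb), as.integer(d), as.double(spacing)))
  dist_to_a <- sqrt(cpp_edt_sq(as.integer(ba), as.integer(d), as.double(spacing)))
  (mean(dist_to_b[ba]) + mean(dist_to_a[bb])) / 2
}

#' Per-label segmentation report
#'
#' @param pred,truth [label_map()]s (or 3D integer arrays) on the same grid.
#' @param spacing voxel size in mm.
#' @return data frame with per-label Dice, average Hausdorff distance (mm),
#'   predicted and true volumes (mm^3).
#' @export
metric_report <- function(pred, truth, spacing = 1.0) {
  p <- if (inherits(pred, "label_map")) pred$data else pred
  t <- if (inherits(truth, "label_map")) truth$data else truth
  labs <- setdiff(sort(unique(c(as.integer(p), as.integer(t)))), 0L)
  vox_vol <- prod(rep(spacing, length.out = 3))
  do.call(rbind, lapply(labs, function(v) {
    data.frame(label = v,
               dice = dice(p == v, t == v),
               avg_hd = average_hausdorff(p == v, t == v, spacing),
               vol_pred = sum(p == v) * vox_vol,
               vol_truth = sum(t == v) * vox_vol)
  }))
}

#' Two-way mixed-effects intraclass correlation, ICC(A,1)
#'
#' Absolute-agreement, single-measurement ICC from the two-way ANOVA mean
#' squares, with the 95% CI from the standard F-distribution bounds
#' (McGraw & Wong). Zero between-subject variance is reported as ICC 0 with
#' a degenerate flag.
#'
#' @param measurements numeric matrix, subjects x sessions (>= 3 subjects,
#'   exactly 2 sessions for the test-retest design; k sessions supported).
#' @param conf confidence level.
#' @return list with `icc`, `ci` (length 2), `degenerate`.
#' @export
icc_two_way <- function(measurements, conf = 0.95) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stopf("ICC needs >= 3 subjects")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (msr <= mse || denom <= 0) {
    return(list(icc = 0, ci = c(0, 0), degenerate = TRUE))
  }
  icc <- (msr - mse) / denom
  # McGraw & Wong (1996) confidence bounds for ICC(A,1)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  Fstar <- (a * msc + b * mse) / msr
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  Fl <- qf(1 - alpha / 2, n - 1, v)
  Fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - Fl * mse) / (Fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (Fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * Fu * msr)
  list(icc = icc, ci = c(max(-1, lo), min(1, hi)), degenerate = FALSE)
}

# pooled-covariance linear discriminant score for a two-class problem,
# with a small ridge for singularity protection
lda_score <- function(xtr, ytr, xte, ridge = 1e-6) {
  xtr <- as.matrix(xtr); xte <- matrix(xte, ncol = ncol(xtr))
  mu0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
  mu1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  n0 <- sum(ytr == 0); n1 <- sum(ytr == 1)
  c0 <- sweep(xtr[ytr == 0, , drop = FALSE], 2, mu0)
  c1 <- sweep(xtr[ytr == 1, , drop = FALSE], 2, mu1)
  Sp <- (crossprod(c0) + crossprod(c1)) / (n0 + n1 - 2)
  k <- ncol(Sp)
  Sp_r <- Sp + diag(ridge * sum(diag(Sp)) / k, k)
  sing <- inherits(try(solve(Sp), silent = TRUE), "try-error")
  if (sing) warnf("singular pooled covariance; ridge-regularized")
  w <- solve(Sp_r, mu1 - mu0)
  drop(xte %*% w - sum(w * (mu0 + mu1) / 2))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#' @param scores numeric classifier scores.
#' @param groups binary group labels (0/1); AUC is P(score1 > score0) with
#'   ties counted half.
#' @export
roc_auc <- function(scores, groups) {
  s1 <- scores[groups == 1]; s0 <- scores[groups == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Leave-one-out LDA classification with ROC analysis
#'
#' For every subject, a pooled-covariance linear discriminant is fit on the
#' remaining subjects and scores the held-out one; the AUC of the held-out
#' scores is computed by the Mann-Whitney formulation. A singular pooled
#' covariance is ridge-regularized (`1e-6 * trace / k`) with a warning.
#'
#' @param features subjects x k numeric matrix.
#' @param groups binary group membership (coercible to 0/1), both groups
#'   nonempty.
#' @return list with `scores` (held-out discriminant scores), `auc`, and
#'   `roc` (data frame of FPR/TPR points).
#' @export
lda_loocv_auc <- function(features, groups) {
  x <- as.matrix(features)
  y <- as.integer(as.factor(groups)) - 1L
  if (length(unique(y)) != 2) stopf("need exactly two nonempty groups")
  n <- nrow(x)
  scores <- vapply(seq_len(n), function(i)
    lda_score(x[-i, , drop = FALSE], y[-i], x[i, ]), numeric(1))
  auc <- roc_auc(scores, y)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(th, function(t) mean(scores[y == 0] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[y == 1] >= t), numeric(1))
  )
  list(scores = scores, auc = auc, roc = roc)
}

#' Rank-based group comparison with FDR control
#'
#' Per-bundle two-tailed Wilcoxon rank-sum tests (or signed-rank tests when
#' `paired`), Benjamini-Hochberg corrected across bundles. All-tied values
#' yield p = 1.
#'
#' @param values numeric matrix, subjects x bundles (paired designs: both
#'   groups' subjects in matching row order).
#' @param groups two-level group vector (length = subjects).
#' @param paired use signed-rank tests on matched rows.
#' @return data frame with per-bundle `p` and BH-corrected `q`.
#' @export
group_compare <- function(values, groups, paired = FALSE) {
  v <- as.matrix(values)
  g <- as.factor(groups)
  if (nlevels(g) != 2) stopf("need exactly two groups")
  if (min(table(g)) < 3) stopf("need >= 3 subjects per group")
  lv <- levels(g)
  p <- apply(v, 2, function(col) {
    a <- col[g == lv[1]]; b <- col[g == lv[2]]
    if (length(unique(c(a, b))) == 1) return(1)
    if (paired) {
      d <- a - b
      if (all(d == 0)) return(1)
      suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    } else {
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }
  })
  data.frame(bundle = colnames(v) %||% seq_len(ncol(v)), p = p,
             q = p.adjust(p, method = "BH"), row.names = NULL)
}
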