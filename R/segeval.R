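# Segmentation-concordance toolkit: overlap/volume metrics, STAPLE
# consensus, shape features, Lin's concordance correlation.

#' Overlap and volume agreement metrics between two binary masks
#'
#' With voxel counts TP/FP/FN/TN (`a` is treated as reference, `b` as
#' prediction): Dice `2TP/(2TP+FP+FN)`, true positive rate `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, Matthews correlation coefficient, and volumetric
#' similarity `1 - |FP-FN|/(2TP+FP+FN)`. To keep the MCC informative on
#' large grids, true negatives are by default counted within the union
#' bounding box padded by 5 voxels rather than over the full volume.
#'
#' @param a,b Logical arrays of identical shape, not both empty.
#' @param mcc_full_volume Logical: count TN over the full array instead of
#'   the padded bounding box.
#' @param mcc_pad Bounding-box padding in voxels.
#' @return List with `dsc`, `tpr`, `precision`, `mcc`, `vs`.
#' @export
overlap_metrics <- function(a, b, mcc_full_volume = FALSE, mcc_pad = 5) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  if (!any(a) && !any(b)) stop("both masks are empty")
  tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
  dsc <- 2 * tp / (2 * tp + fp + fn)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  vs <- 1 - abs(fp - fn) / (2 * tp + fp + fn)
  if (mcc_full_volume) {
    tn <- sum(!a & !b)
  } else {
    idx <- which(a | b, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - mcc_pad, 1)
    hi <- pmin(apply(idx, 2, max) + mcc_pad, dim(a))
    sub <- function(m) m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    tn <- sum(!sub(a) & !sub(b))
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  list(dsc = dsc, tpr = tpr, precision = prec, mcc = mcc, vs = vs)
}

#' STAPLE consensus segmentation
#'
#' Simultaneous truth and performance level estimation: EM over the latent
#' true segmentation. The E-step computes the per-voxel posterior foreground
#' probability from the current per-rater sensitivities `p_j` and
#' specificities `q_j` and a spatially uniform prior (the mean foreground
#' fraction of the inputs); the M-step re-estimates each rater's `p_j`,
#' `q_j` from the posterior. Rates are clipped into `(delta, 1 - delta)` so
#' empty or full raters remain well defined. Deterministic.
#'
#' @param segmentations List of >= 2 logical arrays of identical shape.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the maximum parameter change.
#' @param delta Rate clipping margin.
#' @return List with `probability` (posterior foreground map), `consensus`
#'   (binary map at 0.5), `sensitivity` and `specificity` (per rater) and
#'   `n_iter`.
#' @export
staple <- function(segmentations, max_iter = 100, tol = 1e-6, delta = 1e-5) {
  if (length(segmentations) < 2) stop("need >= 2 segmentations")
  dims <- dim(segmentations[[1]])
  for (s in segmentations)
    if (!identical(dim(s), dims)) stop("segmentations must share a grid")
  D <- vapply(segmentations, function(s) as.numeric(s),
              numeric(prod(dims)))          # voxels x raters
  J <- ncol(D)
  prior <- mean(D)
  prior <- min(max(prior, delta), 1 - delta)
  p <- rep(1 - delta, J)  # initialization 0.99999 clipped into (0, 1)
  q <- rep(1 - delta, J)
  w <- NULL
  for (it in seq_len(max_iter)) {
    # E-step: posterior of foreground per voxel
    la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - prior) + (1 - D) %*% log(q) + D %*% log(1 - q)
    w <- 1 / (1 + exp(lb - la))
    # M-step
    sw <- sum(w); swc <- sum(1 - w)
    p_new <- as.vector(crossprod(D, w)) / sw
    q_new <- as.vector(crossprod(1 - D, 1 - w)) / swc
    p_new <- pmin(pmax(p_new, delta), 1 - delta)
    q_new <- pmin(pmax(q_new, delta), 1 - delta)
    change <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (change < tol) break
  }
  prob <- array(as.vector(w), dims)
  list(probability = prob, consensus = prob >= 0.5,
       sensitivity = p, specificity = q, n_iter = it)
}

#' Shape features of a binary mask
#'
#' Volume (`voxel count * voxel volume`, ml), surface area (cm^2, estimated
#' by the coarea/gradient-magnitude integral of a lightly smoothed 0/1
#' indicator, equivalent to averaging triangulated isosurface areas across
#' levels), and the three principal axis lengths `2 sqrt(5 lambda_k)` (mm)
#' from the eigenvalues of the covariance of foreground voxel-center
#' physical coordinates -- a solid ellipsoid with semi-axis `a` has
#' coordinate variance `a^2 / 5` along that axis, so this recovers the
#' exact axes in the continuum limit.
#'
#' @param mask Logical array (nonempty).
#' @param grid The [voxel_grid] the mask lives on.
#' @param smooth_vox Indicator smoothing (voxels) for the surface estimate.
#' @return List with `volume_ml`, `surface_area_cm2`, `major_axis_mm`,
#'   `minor_axis_mm`, `least_axis_mm`.
#' @export
shape_features <- function(mask, grid, smooth_vox = 1) {
  if (!any(mask)) stop("empty mask")
  d <- grid_sizes(grid)
  vol <- sum(mask) * voxel_volume_ml(grid)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1) {
    warning("single-voxel mask; axis lengths fall back to voxel edges")
    ax <- sort(d, decreasing = TRUE)
    return(list(volume_ml = vol,
                surface_area_cm2 = 2 * (d[1] * d[2] + d[1] * d[3] +
                                          d[2] * d[3]) / 100,
                major_axis_mm = ax[1], minor_axis_mm = ax[2],
                least_axis_mm = ax[3]))
  }
  coords <- sweep(sweep(idx - 1, 2, d, "*"), 2, grid$origin, "+")
  cv <- stats::cov(coords) * (nrow(idx) - 1) / nrow(idx)  # population
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  axes <- 2 * sqrt(5 * ev)
  # surface: |grad| integral of the smoothed indicator (coarea formula)
  f <- gaussian_smooth_3d(array(as.numeric(mask), dim(mask)),
                          rep(smooth_vox, 3))
  pad_diff <- function(a, axis) {
    dims <- dim(a); n <- dims[axis]
    g <- array(0, dims)
    sel <- function(i) switch(axis, a[i, , , drop = FALSE],
                              a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    asn <- function(i, v) switch(axis, g[i, , ] <<- v, g[, i, ] <<- v,
                                 g[, , i] <<- v)
    asn(2:(n - 1), (sel(3:n) - sel(1:(n - 2))) / (2 * d[axis]))
    asn(1, (sel(2) - sel(1)) / d[axis])
    asn(n, (sel(n) - sel(n - 1)) / d[axis])
    g
  }
  gm <- sqrt(pad_diff(f, 1)^2 + pad_diff(f, 2)^2 + pad_diff(f, 3)^2)
  area_mm2 <- sum(gm) * prod(d)
  list(volume_ml = vol, surface_area_cm2 = area_mm2 / 100,
       major_axis_mm = axes[1], minor_axis_mm = axes[2],
       least_axis_mm = axes[3])
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with population
#' moments; penalizes both scatter and location/scale shifts.
#'
#' @param x,y Paired numeric vectors (n >= 2).
#' @return Scalar CCC.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need >= 2 pairs")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) stop("CCC undefined: zero variances and equal means")
  2 * cxy / den
}
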