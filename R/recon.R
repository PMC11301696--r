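# Ordinary-Poisson OSEM reconstruction.
#
# Forward model per subset u:  m_u = attn_u .* (A_u P x) + rbar_u + sbar_u
# with the multiplicative update
#   x <- (x / s_u) .* (P' A_u' (attn_u .* (p_u / m_u)))
# where s_u = P' A_u' attn_u is the subset sensitivity image. Subsets are
# view-interleaved (view j belongs to subset j mod n_subsets), which keeps
# them balanced to within one view even when the mashed view count is not a
# multiple of the subset count.

#' Reconstruction configuration
#'
#' @param n_iterations Number of OSEM iterations (full passes).
#' @param n_subsets Number of view-interleaved subsets (<= number of views).
#' @param grid Output [voxel_grid].
#' @param psf_fwhm_mm Isotropic image-space PSF FWHM in mm (0 = off),
#'   applied inside both the forward and back projection.
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM in mm (0 = off),
#'   applied once after the final iteration.
#' @param tof Logical, reconstruct from TOF prompts.
#' @param eps_rel Division guard relative to the mean prompt value.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations, n_subsets, grid,
                         psf_fwhm_mm = 0, postfilter_fwhm_mm = 0,
                         tof = FALSE, eps_rel = 1e-10) {
  if (n_iterations < 1 || n_subsets < 1)
    stop("iterations and subsets must be >= 1")
  if (eps_rel <= 0) stop("eps_rel must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), grid = grid,
                 psf_fwhm_mm = psf_fwhm_mm,
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 tof = tof, eps_rel = eps_rel),
            class = "recon_config")
}

subset_rows <- function(g, n_subsets) {
  nproj <- g$n_projections
  lapply(seq_len(n_subsets), function(u) {
    views <- which((seq_len(g$n_views) - 1L) %% n_subsets == (u - 1L))
    as.vector(outer(seq_len(nproj), (views - 1L) * nproj, "+"))
  })
}

#' Ordinary-Poisson OSEM reconstruction
#'
#' Reconstructs an image from prompt counts with attenuation in the system
#' model and randoms and scatter as additive terms. The image is initialized
#' uniformly positive inside the sensitivity support; voxels with zero total
#' sensitivity are masked to 0 (with a warning). Non-negativity of the
#' iterates is preserved by construction. An optional image-space Gaussian
#' PSF is applied inside the system model and its adjoint, and an optional
#' Gaussian post-filter once at the end.
#'
#' The output lives in the decay-counts domain of the counts-preserving
#' projector; use [counts_to_activity()] to convert to Bq/ml.
#'
#' @param prompts Noisy (or noise-free) prompt [sinogram], >= 0.
#' @param randoms_or_delayed Additive randoms estimate: a non-TOF [sinogram]
#'   (delayed window) or one matching the prompts.
#' @param scatter Additive scatter estimate [sinogram] (may be zero).
#' @param attn Attenuation factor [sinogram] (non-TOF).
#' @param g A [scanner_geometry].
#' @param cfg A [recon_config].
#' @param track_loglik Logical: record the Poisson log-likelihood after each
#'   full iteration (adds one full forward projection per iteration).
#' @return A [volume_image] on `cfg$grid`. When `track_loglik = TRUE` the
#'   attribute `"loglik"` carries the per-iteration log-likelihood.
#' @export
op_osem <- function(prompts, randoms_or_delayed, scatter, attn, g, cfg,
                    track_loglik = FALSE) {
  if (any(prompts$values < 0)) stop("prompts must be >= 0")
  if (cfg$n_subsets > g$n_views)
    stop("more subsets than views")
  grid <- cfg$grid
  P <- get_projector(g, grid)
  ntof <- if (cfg$tof) g$n_tof_bins else 1L
  nlor <- g$n_projections * g$n_views
  npl <- g$n_planes
  as_lor <- function(s, tof_wanted) {
    v <- s$values
    if (tof_wanted) {
      if (!s$tof) v <- array(v, c(dim(v), ntof)) / ntof
      dim(v) <- c(nlor, npl, ntof)
    } else {
      if (s$tof) v <- apply(v, 1:3, sum)
      dim(v) <- c(nlor, npl)
    }
    v
  }
  pr <- as_lor(prompts, cfg$tof)
  add <- as_lor(randoms_or_delayed, cfg$tof) + as_lor(scatter, cfg$tof)
  at <- as_lor(attn, FALSE)
  eps <- cfg$eps_rel * max(mean(prompts$values), .Machine$double.xmin)
  rows <- subset_rows(g, cfg$n_subsets)
  mats <- if (cfg$tof) get_tof_matrices(g, grid) else list(P$A_cnt)
  A_sub <- lapply(rows, function(r) lapply(mats, function(M) M[r, , drop = FALSE]))
  psf_sig <- if (cfg$psf_fwhm_mm > 0)
    cfg$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / grid_sizes(grid) else NULL
  apply_psf <- function(x3) {
    if (is.null(psf_sig)) return(x3)
    gaussian_smooth_3d(x3, psf_sig)
  }
  dims <- grid_counts(grid)
  to3d <- function(m2) { x <- as.matrix(m2 %*% P$P_cnt); dim(x) <- dims; x }
  to2d <- function(x3) { dim(x3) <- c(dims[1] * dims[2], dims[3]); x3 %*% Matrix::t(P$P_cnt) }
  # subset sensitivity images s_u = adjoint of subset system applied to attn
  sens <- vector("list", cfg$n_subsets)
  for (u in seq_len(cfg$n_subsets)) {
    r <- rows[[u]]
    Y <- 0
    for (b in seq_len(ntof))
      Y <- Y + Matrix::crossprod(A_sub[[u]][[b]], at[r, , drop = FALSE])
    sens[[u]] <- apply_psf(to3d(Y))
  }
  total_sens <- Reduce(`+`, sens)
  mask <- total_sens > 0
  if (!all(mask)) warning("voxels with zero sensitivity masked out")
  x <- array(0, dims); x[mask] <- 1
  loglik <- numeric(0)
  full_model <- function(x3) {
    Y <- to2d(apply_psf(x3))
    m <- array(0, c(nlor, npl, ntof))
    for (b in seq_len(ntof))
      m[, , b] <- as.matrix(mats[[b]] %*% Y) * at
    dim(m) <- dim(pr)
    m + add
  }
  for (it in seq_len(cfg$n_iterations)) {
    for (u in seq_len(cfg$n_subsets)) {
      r <- rows[[u]]
      xs <- apply_psf(x)
      Y <- to2d(xs)
      back <- 0
      for (b in seq_len(ntof)) {
        fp <- as.matrix(A_sub[[u]][[b]] %*% Y) * at[r, , drop = FALSE]
        pu <- if (cfg$tof) pr[r, , b] else pr[r, , drop = FALSE]
        au <- if (cfg$tof) add[r, , b] else add[r, , drop = FALSE]
        ratio <- pu / (fp + au + eps)
        back <- back + Matrix::crossprod(A_sub[[u]][[b]],
                                         ratio * at[r, , drop = FALSE])
      }
      upd <- apply_psf(to3d(back))
      xnew <- array(0, dims)
      xnew[mask] <- x[mask] * upd[mask] / sens[[u]][mask]
      x <- xnew
    }
    if (track_loglik)
      loglik <- c(loglik, poisson_loglik_arrays(pr, full_model(x)))
  }
  if (cfg$postfilter_fwhm_mm > 0)
    x <- gaussian_smooth_3d(x, cfg$postfilter_fwhm_mm /
                                 (2 * sqrt(2 * log(2))) / grid_sizes(grid))
  out <- volume_image(x, grid, "reconstructed")
  if (track_loglik) attr(out, "loglik") <- loglik
  out
}

poisson_loglik_arrays <- function(p, m) {
  if (any(m == 0 & p > 0)) return(-Inf)
  pos <- p > 0
  sum(p[pos] * log(m[pos])) - sum(m)
}

#' Poisson log-likelihood of a sinogram model
#'
#' `sum(p * log(m) - m)` over bins, ignoring the constant `log(p!)` term.
#' Bins where the model is 0 but the data positive yield `-Inf` (reported,
#' not raised).
#'
#' @param prompts Observed counts [sinogram].
#' @param model Expected counts [sinogram] (same shape).
#' @return A scalar log-likelihood.
#' @export
poisson_loglik <- function(prompts, model) {
  if (!identical(dim(prompts$values), dim(model$values)))
    stop("prompts and model shapes differ")
  poisson_loglik_arrays(prompts$values, model$values)
}
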