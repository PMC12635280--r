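## DSC perfusion (nCBV with leakage correction) and DCE permeability
## (VFA T1 mapping + extended Tofts Ktrans), feeding the exclusion mask
## for tumor voxels dominated by blood.

#' Convert DSC signal to delta-R2*
#'
#' `dR2*(t) = -ln(S(t)/S0)/TE`, with S0 the mean over the pre-bolus
#' baseline frames. Non-finite values (S <= 0) are set to 0.
#'
#' @param series 4D signal array (time last).
#' @param te_ms Echo time of the DSC sequence.
#' @param baseline_frames Indices of pre-bolus frames (>= 3).
#' @return List: `delta_r2star` (4D, 1/s), `s0_map`, `n_nonfinite`.
#' @export
dsc_to_delta_r2star <- function(series, te_ms, baseline_frames) {
  if (length(baseline_frames) < 3) stop("need at least 3 baseline frames")
  nd <- dim(series)
  nv <- prod(nd[1:3])
  s0 <- array(rowMeans(matrix(series[, , , baseline_frames, drop = FALSE],
                              nv, length(baseline_frames))), nd[1:3])
  te_s <- te_ms * 1e-3
  y <- matrix(series, nv, nd[4])
  ratio <- y / c(s0)
  ratio[ratio <= 0] <- NA_real_ # flagged below, not a numerical warning
  dr2 <- -log(ratio) / te_s
  bad <- !is.finite(dr2)
  dr2[bad] <- 0
  dim(dr2) <- nd
  list(delta_r2star = dr2, s0_map = s0, n_nonfinite = sum(bad))
}

#' Semi-automatic arterial input function selection
#'
#' Averages the k vessel-mask voxels with the largest peak dR2*; ties
#' broken by earlier peak time, then by voxel index.
#'
#' @param delta_r2star 4D dR2* array.
#' @param vessel_mask Logical volume.
#' @param k Number of voxels to average. Default 5.
#' @return List: `aif` (curve, 1/s), `voxels` (linear indices used).
#' @export
select_aif <- function(delta_r2star, vessel_mask, k = 5) {
  idx <- which(vessel_mask != 0)
  if (length(idx) == 0) stop("vessel mask is empty")
  if (k > length(idx)) {
    warning("k exceeds vessel-mask size; using all ", length(idx), " voxels")
    k <- length(idx)
  }
  nd <- dim(delta_r2star)
  nv <- prod(nd[1:3])
  curves <- matrix(delta_r2star, nv, nd[4])[idx, , drop = FALSE]
  peak <- apply(curves, 1, max)
  peak_t <- apply(curves, 1, which.max)
  ord <- order(-peak, peak_t, idx)
  sel <- ord[seq_len(k)]
  list(aif = colMeans(curves[sel, , drop = FALSE]), voxels = idx[sel])
}

#' Linear-model leakage correction of DSC curves
#'
#' Per voxel, fits `dR2*(t) ~ K1 * Rbar(t) - K2 * int_0^t Rbar` by
#' ordinary least squares, where Rbar is the mean curve over a
#' non-enhancing reference mask; the corrected curve adds the leakage
#' term back: `corrected = dR2* + K2 * int Rbar`.
#'
#' @param delta_r2star 4D dR2* array.
#' @param reference_mask Logical mask of non-enhancing tissue.
#' @param times_s Frame times.
#' @return List: `corrected` (4D), `k1_map`, `k2_map`.
#' @export
leakage_correct <- function(delta_r2star, reference_mask, times_s) {
  if (!any(reference_mask != 0)) stop("reference mask is empty")
  nd <- dim(delta_r2star)
  nv <- prod(nd[1:3])
  y <- matrix(delta_r2star, nv, nd[4])
  rbar <- colMeans(y[which(reference_mask != 0), , drop = FALSE])
  rint <- cumtrapz_curve(rbar, times_s)
  x <- cbind(rbar, -rint)
  ## closed-form OLS for all voxels at once: B = (X'X)^-1 X' Y'
  beta <- solve(crossprod(x), t(y %*% x)) # 2 x nv
  k1 <- beta[1, ]; k2 <- beta[2, ]
  corrected <- y + outer(k2, rint)
  dim(corrected) <- nd
  k1m <- array(k1, nd[1:3]); k2m <- array(k2, nd[1:3])
  list(corrected = corrected, k1_map = k1m, k2_map = k2m)
}

#' Cerebral blood volume by AUC ratio
#'
#' Trapezoidal area under the (corrected) tissue curve divided by the
#' area under the AIF, clipped at zero.
#'
#' @param corrected 4D dR2* array (leakage-corrected).
#' @param aif AIF curve (same time base).
#' @param times_s Frame times.
#' @return CBV volume (dimensionless).
#' @export
compute_cbv <- function(corrected, aif, times_s) {
  auc_aif <- trapz_curve(aif, times_s)
  if (auc_aif <= 0) stop("AIF area under the curve must be > 0")
  nd <- dim(corrected)
  nv <- prod(nd[1:3])
  y <- matrix(corrected, nv, nd[4])
  wts <- trapz_weights(times_s)
  auc <- y %*% wts
  cbv <- pmax(auc / auc_aif, 0)
  dim(cbv) <- nd[1:3]
  cbv
}

trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

trapz_curve <- function(y, t) sum(y * trapz_weights(t))

#' Normalise CBV to contralateral normal-appearing white matter
#'
#' `ncbv = cbv / median(cbv over the reference mask)`, so the reference
#' median is exactly 1.
#'
#' @param cbv_map CBV volume.
#' @param nawm_mask Logical contralateral-NAWM mask.
#' @return nCBV volume.
#' @export
normalize_cbv <- function(cbv_map, nawm_mask) {
  if (!any(nawm_mask != 0)) stop("NAWM mask is empty")
  med <- stats::median(cbv_map[nawm_mask != 0])
  if (med <= 0) stop("median CBV over the NAWM mask must be > 0")
  cbv_map / med
}

#' Variable-flip-angle T1 fit
#'
#' Linearised SPGR fit `S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)` across
#' flip angles; `T1 = -TR / ln(slope)`, clipped to (0, 10 s], with
#' non-physical slopes flagged.
#'
#' @param vfa_volumes List of volumes, one per flip angle.
#' @param flip_angles_deg Flip angles (>= 2 distinct).
#' @param tr_ms Repetition time of the SPGR readout, ms.
#' @return List: `t10_ms`, `m0`, `flagged` (logical volume).
#' @export
vfa_t1_fit <- function(vfa_volumes, flip_angles_deg, tr_ms) {
  if (length(unique(flip_angles_deg)) < 2)
    stop("need at least 2 distinct flip angles")
  a <- flip_angles_deg * pi / 180
  nd <- dim(vfa_volumes[[1]])
  nv <- prod(nd)
  s <- vapply(vfa_volumes, function(v) as.vector(v), numeric(nv))
  ys <- sweep(s, 2, sin(a), `/`)
  xs <- sweep(s, 2, tan(a), `/`)
  xm <- rowMeans(xs); ym <- rowMeans(ys)
  xc <- xs - xm
  slope <- rowSums(xc * ys) / rowSums(xc^2)
  t1_max <- 10000
  flagged <- !is.finite(slope) | slope <= 0 | slope >= 1
  e1 <- pmin(pmax(slope, exp(-tr_ms / 1)), exp(-tr_ms / t1_max))
  t1 <- -tr_ms / log(e1)
  t1[flagged] <- t1_max
  intercept <- ym - slope * xm
  m0 <- intercept / (1 - pmin(pmax(slope, 0), 1 - 1e-12))
  dim(t1) <- nd; dim(m0) <- nd; dim(flagged) <- nd
  list(t10_ms = t1, m0 = m0, flagged = flagged)
}

#' Convert DCE dynamics to gadolinium concentration
#'
#' Per frame, inverts the SPGR signal equation for T1(t) — anchoring
#' the effective M0 on the baseline frames and the supplied T10 map so
#' scanner scaling cancels — then
#' `C(t) = (1/T1(t) - 1/T10)/r1`, clipped at 0.
#'
#' @param series 4D dynamic signal array.
#' @param t10_ms_map Pre-contrast T1 map, ms.
#' @param flip_deg Dynamic flip angle.
#' @param tr_ms SPGR repetition time, ms.
#' @param r1 Contrast-agent relaxivity, 1/s per mM. Default 3.6.
#' @param baseline_frames Pre-bolus frame indices.
#' @return 4D concentration array, mM.
#' @export
dce_to_concentration <- function(series, t10_ms_map, flip_deg, tr_ms,
                                 r1 = 3.6, baseline_frames = 1:5) {
  stopifnot(all(t10_ms_map > 0))
  nd <- dim(series)
  nv <- prod(nd[1:3])
  y <- matrix(series, nv, nd[4])
  sb <- rowMeans(y[, baseline_frames, drop = FALSE])
  a <- flip_deg * pi / 180
  e10 <- exp(-tr_ms / c(t10_ms_map))
  ## effective M0 sin(a) such that the baseline signal matches T10
  m0sa <- sb * (1 - e10 * cos(a)) / (1 - e10)
  u <- y / m0sa
  e1 <- (1 - u) / (1 - u * cos(a))
  e1 <- pmin(pmax(e1, 1e-8), 1 - 1e-8)
  t1 <- -tr_ms / log(e1) # ms
  conc <- (1 / t1 - 1 / c(t10_ms_map)) * 1000 / r1 # 1/s -> mM
  conc <- pmax(conc, 0)
  dim(conc) <- nd
  conc
}

## extended Tofts residual sum of squares for one voxel curve
ext_tofts_rss <- function(par, ct, cp, times_s) {
  model <- extended_tofts_curve(cp, times_s, ktrans_min = par[1],
                                kep_min = par[2], vp = par[3])
  sum((ct - model)^2)
}

#' Extended Tofts model fit for one concentration curve
#'
#' Bounded nonlinear least squares of
#' `Ct(t) = vp Cp(t) + Ktrans int Cp exp(-kep (t-u)) du` with
#' multi-start initialisation (Ktrans in \{0.01, 0.1, 1\}, kep in
#' \{0.1, 1\}, vp in \{0.01, 0.1\}); the best objective wins, ties by
#' lowest Ktrans. Bounds: Ktrans in \[0, 5\]/min, kep in \[0, 10\]/min,
#' vp in \[0, 1\].
#'
#' @param ct Tissue concentration curve, mM.
#' @param vif Plasma input curve, mM.
#' @param times_s Frame times (>= 20 frames).
#' @return List: `ktrans`, `kep`, `vp` (1/min, 1/min, fraction),
#'   `rss`, `converged`.
#' @export
fit_extended_tofts <- function(ct, vif, times_s) {
  if (length(times_s) < 20) stop("need at least 20 frames")
  if (all(vif == 0)) stop("VIF is identically zero")
  if (all(ct == 0))
    return(list(ktrans = 0, kep = 0, vp = 0, rss = 0, converged = TRUE))
  starts <- expand.grid(ktrans = c(0.01, 0.1, 1), kep = c(0.1, 1),
                        vp = c(0.01, 0.1))
  lower <- c(0, 0, 0); upper <- c(5, 10, 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), ext_tofts_rss,
                            ct = ct, cp = vif, times_s = times_s,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    return(list(ktrans = 0, kep = 0, vp = 0, rss = NA_real_,
                converged = FALSE))
  list(ktrans = best$par[1], kep = best$par[2], vp = best$par[3],
       rss = best$value, converged = best$convergence == 0)
}

#' Voxelwise extended Tofts fitting over a mask
#'
#' @param conc 4D concentration array.
#' @param vif Plasma input curve.
#' @param times_s Frame times.
#' @param mask Logical volume restricting the (expensive) fits.
#' @return List of volumes: `ktrans`, `kep`, `vp`, `valid` (logical:
#'   fit attempted and converged).
#' @export
fit_extended_tofts_map <- function(conc, vif, times_s, mask) {
  nd <- dim(conc)
  idx <- which(mask != 0)
  y <- matrix(conc, prod(nd[1:3]), nd[4])
  kt <- array(0, nd[1:3]); kep <- array(0, nd[1:3])
  vp <- array(0, nd[1:3]); valid <- array(FALSE, nd[1:3])
  for (i in idx) {
    f <- fit_extended_tofts(y[i, ], vif, times_s)
    kt[i] <- f$ktrans; kep[i] <- f$kep; vp[i] <- f$vp
    valid[i] <- isTRUE(f$converged)
  }
  list(ktrans = kt, kep = kep, vp = vp, valid = valid)
}

#' Blood-dominated voxel exclusion mask
#'
#' Two complementary criteria: (i) tumor voxels whose nCBV exceeds the
#' 95th percentile of nCBV over the mirrored (contralateral) tumor
#' region are hyperperfused; (ii) voxels whose fitted Ktrans exceeds
#' the 5th percentile of Ktrans over the contrast-enhancing tissue show
#' blood-brain-barrier leakage. Percentiles use linear interpolation.
#' Failed Ktrans fits never trigger exclusion.
#'
#' @param ncbv_map nCBV volume.
#' @param ktrans_map Ktrans volume (1/min); may be NULL to skip the
#'   permeability criterion.
#' @param ktrans_valid Logical volume of successful fits.
#' @param tumor_mask Logical whole-tumor mask.
#' @param contralateral_mask Logical mirrored-tumor mask.
#' @param et_mask Logical contrast-enhancing mask.
#' @return List: `mask` (voxels to exclude), `thr_ncbv`, `thr_ktrans`.
#' @export
blood_exclusion_mask <- function(ncbv_map, ktrans_map, ktrans_valid,
                                 tumor_mask, contralateral_mask, et_mask) {
  if (!any(contralateral_mask != 0)) stop("contralateral mask is empty")
  thr_ncbv <- stats::quantile(ncbv_map[contralateral_mask != 0], 0.95,
                              names = FALSE, type = 7)
  excl <- (tumor_mask != 0) & (ncbv_map > thr_ncbv)
  thr_ktrans <- NA_real_
  if (!is.null(ktrans_map)) {
    et_valid <- (et_mask != 0) & (ktrans_valid != 0)
    if (!any(et_valid)) {
      warning("no valid Ktrans fits in enhancing tissue; nCBV-only exclusion")
    } else {
      thr_ktrans <- stats::quantile(ktrans_map[et_valid], 0.05,
                                    names = FALSE, type = 7)
      excl <- excl | ((ktrans_valid != 0) & (ktrans_map > thr_ktrans))
    }
  }
  list(mask = excl, thr_ncbv = thr_ncbv, thr_ktrans = thr_ktrans)
}
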