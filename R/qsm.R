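## Quantitative susceptibility mapping: wrapped multi-echo phase in,
## total-susceptibility map out. The chain is Laplacian unwrapping ->
## (eroded brain + tumor) analysis mask -> multi-echo field fit ->
## V-SHARP background removal -> dipole inversion, with two independent
## inversion algorithms so downstream TIZ masks can be compared across
## algorithms.

## spectral Laplacian (continuous symbol), consistent between the
## forward operator and the Poisson solve in the unwrapper
spectral_laplacian_sym <- function(dim, voxel_size_mm) {
  kx <- fft_freq(dim[1], voxel_size_mm[1])
  ky <- fft_freq(dim[2], voxel_size_mm[2])
  kz <- fft_freq(dim[3], voxel_size_mm[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  dim(k2) <- dim
  -(2 * pi)^2 * k2
}

#' Laplacian phase unwrapping
#'
#' Solves `lap(phi_u) = cos(phi) lap(sin phi) - sin(phi) lap(cos phi)`
#' spectrally (periodic Poisson solve). The result is wrap-free up to a
#' harmonic component; with periodic boundaries the harmonic ambiguity
#' is a constant, fixed here by returning a zero-mean volume. A phase
#' that is already smooth is reproduced up to that constant.
#'
#' @param wrapped_phase Radians, values in `[-pi, pi)`.
#' @param voxel_size_mm Voxel spacing.
#' @return Unwrapped phase volume (radians, zero mean).
#' @export
laplacian_unwrap <- function(wrapped_phase, voxel_size_mm = c(1, 1, 1)) {
  if (all(wrapped_phase == 0)) return(wrapped_phase * 0)
  L <- spectral_laplacian_sym(dim(wrapped_phase), voxel_size_mm)
  lap <- function(x) ifft3_re(fft3(x) * L)
  rhs <- cos(wrapped_phase) * lap(sin(wrapped_phase)) -
    sin(wrapped_phase) * lap(cos(wrapped_phase))
  rhs_hat <- fft3(rhs)
  Linv <- 1 / L
  Linv[L == 0] <- 0
  ifft3_re(rhs_hat * Linv)
}

#' Analysis mask: eroded brain plus tumor
#'
#' The brain mask is eroded (default 3 mm) to drop boundary voxels with
#' unreliable phase, then the binarised tumor mask is added back so
#' cortex-adjacent tumor is never eroded away.
#'
#' @param brain_mask,tumor_mask Logical volumes on the same grid.
#' @param erosion_mm Erosion radius, mm (>= 0).
#' @param voxel_size_mm Voxel spacing.
#' @return Logical analysis mask.
#' @export
prepare_mask <- function(brain_mask, tumor_mask = NULL, erosion_mm = 3,
                         voxel_size_mm = c(1, 1, 1)) {
  if (erosion_mm < 0) stop("erosion_mm must be >= 0")
  out <- erode_ball(brain_mask, erosion_mm, voxel_size_mm)
  if (!is.null(tumor_mask)) {
    stopifnot(identical(dim(tumor_mask), dim(brain_mask)))
    out <- out | (tumor_mask != 0)
  }
  out
}

#' Multi-echo phase-to-field fit
#'
#' Per-voxel weighted least-squares slope of unwrapped phase against
#' echo time (intercept included, so a constant phase offset is
#' absorbed), weights proportional to squared echo magnitude; the slope
#' (rad/s) is converted to ppm of the main field.
#'
#' @param phases 4D array (echoes last), radians, unwrapped.
#' @param te_ms Echo times.
#' @param b0_tesla Field strength.
#' @param magnitudes Optional 4D magnitude array for the weights;
#'   uniform weights if omitted.
#' @return Field map in ppm.
#' @export
echo_phase_to_field <- function(phases, te_ms, b0_tesla, magnitudes = NULL) {
  nd <- dim(phases)
  ne <- nd[4]
  if (ne < 2) stop("need at least 2 echoes")
  nv <- prod(nd[1:3])
  y <- matrix(phases, nv, ne)
  te_s <- te_ms * 1e-3
  if (is.null(magnitudes)) {
    w <- matrix(1, nv, ne)
  } else {
    w <- matrix(magnitudes, nv, ne)^2
  }
  sw <- rowSums(w)
  xbar <- (w %*% te_s) / sw
  xc <- matrix(te_s, nv, ne, byrow = TRUE) - c(xbar)
  denom <- rowSums(w * xc^2)
  slope <- rowSums(w * xc * y) / denom
  slope[denom == 0 | !is.finite(slope)] <- 0 # zero-signal voxels
  f0_hz <- GAMMA_BAR_MHZ_PER_T * 1e6 * b0_tesla
  out <- slope / (2 * pi * f0_hz * 1e-6)
  dim(out) <- nd[1:3]
  out
}

#' V-SHARP background-field removal
#'
#' Variable-radius spherical-mean-value (SMV) high-pass: each mask voxel
#' is filtered with the largest sphere (default radii 12 mm down to the
#' voxel scale) that fits inside the mask at that voxel. Because any
#' harmonic field satisfies the spherical mean-value property, fields
#' generated by sources outside the mask are annihilated, while fields
#' of internal sources leave a residual. The SMV deconvolution is
#' Tikhonov-regularised and model-based: a source distribution g is
#' estimated by conjugate gradients so that its dipole field, passed
#' through each radius's SMV high-pass, matches the filtered data on
#' that radius's shell (`min sum_r |M_r (H_r (D g - data))|^2 +
#' lambda^2 |g|^2`), and the returned local field is the dipole field
#' of g. Parameterising through the dipole model restores the
#' harmonic-inside-the-mask component of the internal field that a
#' plain spectral division of the truncated filtered data cannot
#' recover.
#'
#' @param total_field_ppm Field map, ppm.
#' @param mask Logical analysis mask.
#' @param radii_mm Sphere radii, descending; radii below the largest
#'   voxel dimension are dropped.
#' @param lambda Tikhonov parameter for the SMV deconvolution.
#' @param voxel_size_mm Voxel spacing.
#' @param max_iter,tol Conjugate-gradient controls.
#' @return List: `local_field_ppm` (zero mean over the support),
#'   `vsharp_mask` (support after the smallest-radius erosion).
#' @export
vsharp <- function(total_field_ppm, mask, radii_mm = c(12, 8, 4, 2),
                   lambda = 0.05, voxel_size_mm = c(1, 1, 1),
                   max_iter = 80, tol = 1e-6) {
  stopifnot(identical(dim(total_field_ppm), dim(mask)))
  radii_mm <- sort(radii_mm[radii_mm >= max(voxel_size_mm)], decreasing = TRUE)
  if (length(radii_mm) == 0) stop("no usable SMV radius >= voxel size")
  dims <- dim(mask)
  mask <- mask != 0
  ## drop radii whose erosion empties the mask
  keep <- vapply(radii_mm, function(r)
    any(erode_ball(mask, r, voxel_size_mm)), TRUE)
  if (!all(keep)) {
    warning("mask smaller than largest SMV sphere; shrinking radius list to <= ",
            max(radii_mm[keep]), " mm")
    radii_mm <- radii_mm[keep]
  }
  f <- total_field_ppm
  f[!mask] <- 0
  d <- dipole_kernel(dims, voxel_size_mm)
  hs <- vector("list", length(radii_mm))
  ms <- vector("list", length(radii_mm))
  b <- array(0, dims)
  assigned <- array(FALSE, dims)
  support <- NULL
  for (i in seq_along(radii_mm)) {
    kh <- aa_sphere_kernel_ft(dims, voxel_size_mm, radii_mm[i])
    h <- 1 - Re(kh)
    er <- erode_ball(mask, radii_mm[i], voxel_size_mm)
    sel <- er & !assigned
    assigned <- assigned | er
    support <- er # smallest radius processed last
    filt <- array(0, dims)
    smv <- ifft3_re(fft3(f) * kh)
    filt[sel] <- f[sel] - smv[sel]
    hs[[i]] <- h * d
    ms[[i]] <- sel
    b <- b + ifft3_re(fft3(filt) * hs[[i]])
  }
  amul <- function(g) {
    ghat <- fft3(g)
    out <- lambda^2 * g
    for (i in seq_along(hs)) {
      y <- ifft3_re(ghat * hs[[i]])
      y[!ms[[i]]] <- 0
      out <- out + ifft3_re(fft3(y) * hs[[i]])
    }
    out
  }
  g <- array(0, dims)
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- rs
  if (b2 > 0) {
    for (it in seq_len(max_iter)) {
      ap <- amul(p)
      alpha <- rs / sum(p * ap)
      g <- g + alpha * p
      r <- r - alpha * ap
      rs_new <- sum(r * r)
      if (rs_new <= tol^2 * b2) break
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
  }
  local <- ifft3_re(fft3(g) * d)
  local[!support] <- 0
  local[support] <- local[support] - mean(local[support])
  list(local_field_ppm = local, vsharp_mask = support)
}

#' Thresholded k-space division (TKD) dipole inversion
#'
#' `chi = IFT( FT(field) / Dt(k) )` with the dipole kernel clamped away
#' from zero: `Dt = D` where `|D| >= threshold`, else
#' `sign(D) * threshold`. Output masked and mean-centred over the mask
#' (QSM is reference-free).
#'
#' @param local_field_ppm Background-free field, ppm.
#' @param mask Logical mask.
#' @param threshold Kernel clamp in `(0, 1/3]`. Default 0.2.
#' @param voxel_size_mm Voxel spacing.
#' @return List of class `chi_map`: `chi_ppm`, `algorithm_tag`, `mask`.
#' @export
dipole_invert_tkd <- function(local_field_ppm, mask, threshold = 0.2,
                              voxel_size_mm = c(1, 1, 1)) {
  if (threshold <= 0 || threshold > 1 / 3)
    stop("threshold must be in (0, 1/3]")
  d <- dipole_kernel(dim(mask), voxel_size_mm)
  dt <- ifelse(abs(d) >= threshold, d, ifelse(d < 0, -threshold, threshold))
  chi <- ifft3_re(fft3(local_field_ppm * (mask != 0)) / dt)
  chi[!mask] <- 0
  chi[mask != 0] <- chi[mask != 0] - mean(chi[mask != 0])
  structure(list(chi_ppm = chi, algorithm_tag = "tkd", mask = mask != 0),
            class = "chi_map")
}

#' Iterative Tikhonov-regularised dipole inversion
#'
#' Minimises `|W (D * chi - field)|^2 + lambda |grad chi|^2` (W = mask
#' indicator, periodic finite-difference gradient) by conjugate
#' gradients on the normal equations. Deterministic given its inputs.
#'
#' @param local_field_ppm Background-free field, ppm.
#' @param mask Logical mask.
#' @param lambda Gradient penalty weight (> 0). Default 1e-2.
#' @param max_iter CG iteration cap. Default 60.
#' @param tol Relative residual tolerance. Default 1e-8.
#' @param voxel_size_mm Voxel spacing.
#' @return List of class `chi_map`: `chi_ppm`, `algorithm_tag`, `mask`.
#' @export
dipole_invert_iter <- function(local_field_ppm, mask, lambda = 1e-2,
                               max_iter = 60, tol = 1e-8,
                               voxel_size_mm = c(1, 1, 1)) {
  if (lambda <= 0) stop("lambda must be > 0")
  dims <- dim(mask)
  w <- mask != 0
  d <- dipole_kernel(dims, voxel_size_mm)
  lap <- laplace_eigenvalues(dims) # voxel units; lambda is dimensionless
  dop <- function(x) ifft3_re(fft3(x) * d)
  amul <- function(x) dop(w * dop(x)) + lambda * ifft3_re(fft3(x) * lap)
  b <- dop(w * local_field_ppm)
  x <- array(0, dims)
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- rs
  if (b2 > 0) {
    for (it in seq_len(max_iter)) {
      ap <- amul(p)
      alpha <- rs / sum(p * ap)
      x <- x + alpha * p
      r <- r - alpha * ap
      rs_new <- sum(r * r)
      if (rs_new <= tol^2 * b2) break
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
  }
  x[!w] <- 0
  x[w] <- x[w] - mean(x[w])
  structure(list(chi_ppm = x, algorithm_tag = "iterative", mask = w),
            class = "chi_map")
}

#' Mono-exponential R2* fit from multi-echo magnitudes
#'
#' Log-linear least squares of `ln S` against echo time, weighted by
#' squared magnitude (log-domain noise scales as 1/S, so S^2 weights
#' are the heteroscedasticity-correct choice); `r2star` is the negated
#' slope clipped at zero, `s0` the exponentiated intercept.
#'
#' @param magnitudes 4D array (echoes last), positive.
#' @param te_ms Echo times.
#' @param weighted Magnitude-squared weights (default) or ordinary
#'   least squares.
#' @return List: `r2star` (1/s), `s0`.
#' @export
fit_r2star <- function(magnitudes, te_ms, weighted = TRUE) {
  nd <- dim(magnitudes)
  if (nd[4] < 2) stop("need at least 2 echoes")
  nv <- prod(nd[1:3])
  s <- matrix(magnitudes, nv, nd[4])
  y <- log(pmax(s, 1e-12))
  te_s <- te_ms * 1e-3
  w <- if (weighted) s^2 else matrix(1, nv, nd[4])
  sw <- rowSums(w)
  xbar <- rowSums(w * matrix(te_s, nv, nd[4], byrow = TRUE)) / sw
  ybar <- rowSums(w * y) / sw
  xc <- matrix(te_s, nv, nd[4], byrow = TRUE) - xbar
  denom <- rowSums(w * xc^2)
  slope <- rowSums(w * xc * y) / denom
  slope[denom == 0 | !is.finite(slope)] <- 0
  intercept <- ybar - slope * xbar
  r2 <- pmax(-slope, 0)
  dim(r2) <- nd[1:3]
  s0 <- exp(intercept)
  dim(s0) <- nd[1:3]
  list(r2star = r2, s0 = s0)
}

#' Full QSM reconstruction from a multi-echo acquisition
#'
#' Runs unwrapping per echo, mask preparation, the multi-echo field
#' fit, V-SHARP and both dipole inversions.
#'
#' @param gre A `multiecho_gre` object.
#' @param brain_mask,tumor_mask Logical volumes.
#' @param voxel_size_mm Voxel spacing.
#' @param erosion_mm Brain-mask erosion (default 3 mm).
#' @param vsharp_radii_mm,vsharp_lambda V-SHARP settings.
#' @param tkd_threshold,iter_lambda Inversion settings.
#' @return List: `total_field_ppm`, `local_field_ppm`, `analysis_mask`,
#'   `vsharp_mask`, `chi` (named list of `chi_map`s: tkd, iterative),
#'   `r2star`, `s0`.
#' @export
qsm_reconstruct <- function(gre, brain_mask, tumor_mask = NULL,
                            voxel_size_mm = c(1, 1, 1), erosion_mm = 3,
                            vsharp_radii_mm = seq(12, 2, by = -2),
                            vsharp_lambda = 0.05,
                            tkd_threshold = 0.2, iter_lambda = 1e-2) {
  nd <- dim(gre$signal)
  mags <- abs(gre$signal)
  phases <- array(0, nd)
  for (k in seq_len(nd[4]))
    phases[, , , k] <- laplacian_unwrap(Arg(gre$signal[, , , k]), voxel_size_mm)
  analysis_mask <- prepare_mask(brain_mask, tumor_mask, erosion_mm,
                                voxel_size_mm)
  total_field <- echo_phase_to_field(phases, gre$te_ms, gre$b0_tesla, mags)
  vs <- vsharp(total_field, analysis_mask, vsharp_radii_mm, vsharp_lambda,
               voxel_size_mm)
  r2fit <- fit_r2star(mags, gre$te_ms)
  list(
    total_field_ppm = total_field,
    local_field_ppm = vs$local_field_ppm,
    analysis_mask = analysis_mask,
    vsharp_mask = vs$vsharp_mask,
    chi = list(
      tkd = dipole_invert_tkd(vs$local_field_ppm, vs$vsharp_mask,
                              tkd_threshold, voxel_size_mm),
      iterative = dipole_invert_iter(vs$local_field_ppm, vs$vsharp_mask,
                                     iter_lambda, voxel_size_mm = voxel_size_mm)
    ),
    r2star = r2fit$r2star,
    s0 = r2fit$s0
  )
}
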