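## Symmetric digital tumor-brain phantom.
##
## An ellipsoidal "head" (GM shell over WM, paired ventricles, paired
## subcortical nuclei, paired vessels) is built exactly mirror-symmetric
## about the mid-sagittal index plane, then a one-sided tumor complex
## (edema shell ED, enhancing rim ET, necrotic core NCR) is stamped into
## one hemisphere together with a high-iron / low-myelin infiltration
## pocket (the planted TIZ) inside the edema. Every voxel carries known
## paramagnetic and diamagnetic source susceptibilities, so the whole
## reconstruction chain can be validated against ground truth.

#' Tissue label codes used by the phantom
#' @export
TISSUE_CODES <- c(
  background = 0L, wm = 1L, gm = 2L, csf = 3L, subcortical = 4L,
  vessel = 5L, ed = 6L, ncr = 7L, et = 8L, tiz = 9L
)

#' Phantom specification
#'
#' Bundles the geometry, acquisition parameters and per-tissue physical
#' properties of the synthetic phantom. Acquisition defaults follow a
#' 3 T protocol with eight gradient echoes at TE1/dTE = 5/5 ms. Tissue
#' susceptibility magnitudes are synthetic, plausibility-driven values
#' (no measured tissue table is reproduced); their ordering puts the
#' infiltration pocket far above normal tissue on the PDR scale:
#' strongly paramagnetic (iron-rich) and weakly diamagnetic
#' (myelin-poor).
#'
#' @param grid_shape Voxels per axis (length 3). Default 64^3.
#' @param voxel_size_mm Per-axis spacing, mm. Default 2 mm isotropic.
#' @param b0_tesla Field strength. Default 3.
#' @param te_ms Echo times, strictly increasing. Default `seq(5, 40, 5)`.
#' @param noise_sigma SD of the additive complex noise on the multi-echo
#'   signal, relative to white-matter m0. Default 0.02.
#' @param seed RNG seed used by all stochastic simulators.
#' @param tumor A list with `center_mm` and per-compartment `radii_mm`
#'   (ed, et, ncr, tiz) plus `tiz_offset_mm`; see defaults.
#' @param tissue_params Data frame of per-label physical parameters; see
#'   [default_tissue_params()].
#' @param dsc,dce Lists of dynamic-acquisition parameters (timing, bolus
#'   shape, noise); see source for defaults.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = c(2, 2, 2),
                         b0_tesla = 3,
                         te_ms = seq(5, 40, by = 5),
                         noise_sigma = 0.02,
                         seed = 20240101L,
                         tumor = NULL,
                         tissue_params = default_tissue_params(),
                         dsc = NULL, dce = NULL) {
  if (any(diff(te_ms) <= 0) || any(te_ms <= 0))
    stop("te_ms must be strictly increasing and positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(tissue_params$c_para < 0)) stop("c_para must be >= 0 for every label")
  if (any(tissue_params$c_dia > 0)) stop("c_dia must be <= 0 for every label")
  if (is.null(tumor)) {
    ## the infiltration pocket sits on the MEDIAL side of the enhancing
    ## rim: gliomas invade along deep white-matter tracts (toward the
    ## midline), not toward the cortex
    tumor <- list(
      center_mm = c(24, 0, 0),
      radii_mm = list(ed = c(18, 16, 16), et = c(10, 10, 10),
                      ncr = c(5, 5, 5), tiz = c(8, 10, 10)),
      tiz_offset_mm = c(-13, 0, 0)
    )
  }
  if (is.null(dsc)) {
    dsc <- list(n_frames = 120L, tr_s = 1.5, te_ms = 40,
                t0_s = 45, alpha = 3, beta_s = 4, peak_dr2s = 60,
                noise_sigma = 0.005)
  }
  if (is.null(dce)) {
    dce <- list(n_frames = 80L, frame_dt_s = 5, tr_ms = 5,
                flip_deg = 15, vfa_deg = c(5, 10, 15), r1 = 3.6,
                t0_s = 60, alpha = 3, beta_s = 8, peak_mM = 5,
                plateau_mM = 0.7, plateau_tau_s = 30,
                noise_sigma = 0.002)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    b0_tesla = b0_tesla, te_ms = te_ms, noise_sigma = noise_sigma,
    seed = as.integer(seed), tumor = tumor, tissue_params = tissue_params,
    dsc = dsc, dce = dce
  ), class = "phantom_spec")
}

#' Default per-tissue physical parameters (synthetic)
#'
#' `c_para`/`c_dia` are the paramagnetic (>= 0) and diamagnetic (<= 0)
#' source susceptibilities in ppm; `r2_base` the non-susceptibility
#' baseline R2 (1/s); `m0` the relative equilibrium signal; `t1_ms` the
#' longitudinal relaxation used for DCE; `cbv` the DSC blood-volume
#' fraction; `ktrans_min`/`ve`/`vp` the extended-Tofts parameters
#' (nonzero transfer only in enhancing tumor); `k2_dsc` the simulated
#' DSC leakage rate (enhancing tumor only).
#'
#' @return A data.frame with one row per label code.
#' @export
default_tissue_params <- function() {
  tp <- data.frame(
    label  = unname(TISSUE_CODES),
    tissue = names(TISSUE_CODES),
    ## vessel values are arterial: the phantom vessel exists to supply
    ## the AIF, and nearly fully oxygenated blood is close to
    ## susceptibility-matched with tissue (venous blood would be far
    ## more paramagnetic)
    #        bg    wm    gm    csf   subc  vess  ed    ncr   et    tiz
    c_para = c(0,  0.01, 0.03, 0.00, 0.09, 0.06, 0.02, 0.05, 0.06, 0.15),
    c_dia  = -c(0, 0.05, 0.02, 0.005, 0.02, 0.01, 0.02, 0.01, 0.03, 0.005),
    r2_base = c(0, 15,   14,   1,    16,   20,   12,   8,    14,   12),
    m0     = c(0,  0.90, 0.85, 1.00, 0.88, 0.95, 0.95, 0.80, 0.90, 0.95),
    t1_ms  = c(1e9, 850, 1400, 4000, 1100, 1700, 1500, 2500, 1200, 1500),
    cbv    = c(0,  0.025, 0.055, 0.005, 0.05, 1.0, 0.02, 0.005, 0.12, 0.025),
    k2_dsc = c(0, 0, 0, 0, 0, 0, 0, 0, 0.03, 0),
    ktrans_min = c(0, 0, 0, 0, 0, 0, 0, 0, 0.1, 0),
    ve     = c(0, 0, 0, 0, 0, 0, 0, 0, 0.2, 0),
    vp     = c(0, 0, 0, 0, 0, 1, 0, 0, 0.02, 0)
  )
  rownames(tp) <- tp$tissue
  tp
}

## voxel-centre coordinates (mm) relative to the grid centre, so the
## mid-sagittal index plane is exactly x = 0 and flips are exact.
grid_coords_mm <- function(spec) {
  n <- spec$grid_shape; v <- spec$voxel_size_mm
  lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * v[a])
}

## logical ellipsoid on the phantom grid; zero radius along any axis
## gives an empty region
ellipsoid_mask <- function(spec, center_mm, radii_mm) {
  if (any(radii_mm <= 0)) return(array(FALSE, spec$grid_shape))
  co <- grid_coords_mm(spec)
  qx <- ((co[[1]] - center_mm[1]) / radii_mm[1])^2
  qy <- ((co[[2]] - center_mm[2]) / radii_mm[2])^2
  qz <- ((co[[3]] - center_mm[3]) / radii_mm[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  dim(q) <- spec$grid_shape
  q <= 1
}

per_label_map <- function(labels, values_by_label) {
  lut <- numeric(max(labels) + 1L)
  lut[values_by_label$label + 1L] <- values_by_label$value
  out <- lut[labels + 1L]
  dim(out) <- dim(labels)
  out
}

## lookup a tissue_params column as a volume
param_map <- function(labels, tissue_params, column) {
  per_label_map(labels, data.frame(label = tissue_params$label,
                                   value = tissue_params[[column]]))
}

#' Build the phantom label map
#'
#' Stamps the symmetric head compartments, then the one-sided tumor
#' complex. Non-tumor labels are mirror-symmetric by construction; the
#' necrotic core sits inside the enhancing rim which sits inside the
#' edema shell, and the TIZ pocket is carved out of the edema (never
#' overlapping enhancing tumor or core).
#'
#' @param spec A [phantom_spec()].
#' @return Integer 3D array of label codes (see [TISSUE_CODES]).
#' @export
build_labels <- function(spec) {
  tm <- spec$tumor
  r <- tm$radii_mm
  zero_tumor <- all(unlist(r$ed) <= 0)
  if (!zero_tumor) {
    if (any(r$ncr > r$et) || any(r$et > r$ed))
      stop("tumor compartments must be nested: NCR inside ET inside ED")
    if (tm$center_mm[1] - r$ed[1] <= 0 && tm$center_mm[1] + r$ed[1] >= 0)
      stop("tumor edema crosses the mid-sagittal plane; keep it in one hemisphere")
    half_fov <- spec$grid_shape * spec$voxel_size_mm / 2
    if (any(abs(tm$center_mm) + r$ed >= half_fov))
      stop("tumor edema extends outside the field of view")
  }

  ## 6 mm cortical band: thick enough that a contralateral GM reference
  ## ring survives the 3 mm mask erosion plus the V-SHARP support erosion
  head_ax <- c(48, 54, 46)
  gm_thick <- 6
  lab <- array(TISSUE_CODES[["background"]], spec$grid_shape)
  head <- ellipsoid_mask(spec, c(0, 0, 0), head_ax)
  wm_core <- ellipsoid_mask(spec, c(0, 0, 0), head_ax - gm_thick)
  lab[head] <- TISSUE_CODES[["gm"]]
  lab[wm_core] <- TISSUE_CODES[["wm"]]
  for (s in c(-1, 1)) {
    lab[ellipsoid_mask(spec, c(s * 8, -6, 0), c(5, 14, 5))] <- TISSUE_CODES[["csf"]]
    lab[ellipsoid_mask(spec, c(s * 16, 10, 0), c(7, 8, 7))] <- TISSUE_CODES[["subcortical"]]
    lab[ellipsoid_mask(spec, c(s * 30, -30, 0), c(3, 3, 20))] <- TISSUE_CODES[["vessel"]]
  }

  if (!zero_tumor) {
    ed <- ellipsoid_mask(spec, tm$center_mm, r$ed)
    et <- ellipsoid_mask(spec, tm$center_mm, r$et)
    ncr <- ellipsoid_mask(spec, tm$center_mm, r$ncr)
    tiz <- ellipsoid_mask(spec, tm$center_mm + tm$tiz_offset_mm, r$tiz)
    lab[ed & head] <- TISSUE_CODES[["ed"]]
    lab[tiz & ed & !et & head] <- TISSUE_CODES[["tiz"]]
    lab[et & head] <- TISSUE_CODES[["et"]]
    lab[ncr & head] <- TISSUE_CODES[["ncr"]]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Assign ground-truth source maps to a label map
#'
#' Produces voxelwise paramagnetic/diamagnetic susceptibility, total
#' susceptibility, R2* (= baseline R2 plus the static-dephasing
#' contribution `kappa * (c_para + |c_dia|)`), m0 and T1 maps, plus the
#' planted-TIZ truth mask and hemisphere/brain masks.
#'
#' @param labels Integer label volume from [build_labels()].
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_truth`.
#' @export
assign_sources <- function(labels, spec) {
  tp <- spec$tissue_params
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% tp$label))
    stop("tissue_params missing labels: ",
         paste(setdiff(present, tp$label), collapse = ", "))
  kappa <- static_dephasing_kappa(spec$b0_tesla)
  chi_para <- param_map(labels, tp, "c_para")
  chi_dia <- param_map(labels, tp, "c_dia")
  r2_base <- param_map(labels, tp, "r2_base")
  co <- grid_coords_mm(spec)
  hemi <- array(rep(co[[1]] > 0, times = prod(spec$grid_shape[2:3])),
                spec$grid_shape)
  structure(list(
    labels = labels,
    chi_para = chi_para,
    chi_dia = chi_dia,
    chi_total = chi_para + chi_dia,
    r2star = r2_base + kappa * (chi_para + abs(chi_dia)),
    r2_base = r2_base,
    m0 = param_map(labels, tp, "m0"),
    t1_ms = param_map(labels, tp, "t1_ms"),
    kappa = kappa,
    tiz_truth = labels == TISSUE_CODES[["tiz"]],
    brain_mask = labels != TISSUE_CODES[["background"]],
    hemisphere_mask = hemi
  ), class = "phantom_truth")
}

#' Forward dipole field from a susceptibility distribution
#'
#' Periodic convolution with the unit dipole response:
#' `field = IFT( D(k) * FT(chi) )`, `D(k) = 1/3 - kz^2/|k|^2`, `D(0)=0`.
#' Input and output in ppm.
#'
#' @param chi_total Susceptibility volume, ppm.
#' @param spec A [phantom_spec()] (supplies voxel spacing).
#' @return Field perturbation volume, ppm (zero mean over the FOV).
#' @export
simulate_field <- function(chi_total, spec) {
  if (!all(is.finite(chi_total))) stop("chi_total must be finite")
  d <- dipole_kernel(dim(chi_total), spec$voxel_size_mm)
  ifft3_re(fft3(chi_total) * d)
}

#' Simulate the multi-echo gradient-echo acquisition
#'
#' `S(TE) = m0 exp(-R2* TE) exp(i 2 pi f0 field TE) + noise`, with
#' `f0 = gamma_bar * B0` and i.i.d. complex Gaussian noise of SD
#' `noise_sigma * m0_WM` per channel, seeded from the spec.
#'
#' @param truth A `phantom_truth` (needs `field_ppm` attached or passed).
#' @param spec A [phantom_spec()].
#' @param field_ppm Optional precomputed field; defaults to
#'   `simulate_field(truth$chi_total, spec)`.
#' @return List of class `multiecho_gre`: `signal` (complex 4D array,
#'   echoes last), `te_ms`, `b0_tesla`.
#' @export
simulate_gre <- function(truth, spec, field_ppm = NULL) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(field_ppm)) field_ppm <- simulate_field(truth$chi_total, spec)
  f0_hz <- GAMMA_BAR_MHZ_PER_T * 1e6 * spec$b0_tesla
  n <- spec$grid_shape
  ne <- length(spec$te_ms)
  sig <- array(complex(real = 0), c(n, ne))
  m0_wm <- spec$tissue_params["wm", "m0"]
  set.seed(spec$seed)
  for (k in seq_len(ne)) {
    te_s <- spec$te_ms[k] * 1e-3
    s <- truth$m0 * exp(-truth$r2star * te_s) *
      exp(1i * 2 * pi * f0_hz * field_ppm * 1e-6 * te_s)
    if (spec$noise_sigma > 0) {
      sd0 <- spec$noise_sigma * m0_wm
      s <- s + complex(real = rnorm(prod(n), 0, sd0),
                       imaginary = rnorm(prod(n), 0, sd0))
    }
    sig[, , , k] <- s
  }
  structure(list(signal = sig, te_ms = spec$te_ms, b0_tesla = spec$b0_tesla),
            class = "multiecho_gre")
}

## gamma-variate bolus, zero before t0, unit-free amplitude A
gamma_variate <- function(t, t0, alpha, beta, amplitude) {
  dt <- pmax(t - t0, 0)
  amplitude * dt^alpha * exp(-dt / beta)
}

## amplitude that puts the gamma-variate peak (at t0 + alpha*beta) at `peak`
gamma_amplitude_for_peak <- function(alpha, beta, peak) {
  peak / ((alpha * beta)^alpha * exp(-alpha))
}

#' Simulate the DSC bolus-passage series
#'
#' Arterial concentration follows a gamma-variate (bolus at
#' `dsc$t0_s = 45` s); tissue `dR2*(t)` is `cbv_label * Ca(t)` plus, in
#' enhancing tumor only, a leakage term `-K2 * integral of the
#' non-enhancing reference curve` matching the linear leakage-correction
#' model, so the correction is testable by construction. Signal:
#' `S(t) = S0 exp(-TE dR2*(t))` plus seeded Gaussian noise.
#'
#' @param labels Label volume.
#' @param spec A [phantom_spec()].
#' @return List of class `dsc_series`: `signal` (4D), `times_s`,
#'   `te_ms`, `s0_map`, `truth` (per-label cbv, k2, arterial curve).
#' @export
simulate_dsc <- function(labels, spec) {
  p <- spec$dsc
  t <- (seq_len(p$n_frames) - 1) * p$tr_s
  amp <- gamma_amplitude_for_peak(p$alpha, p$beta_s, p$peak_dr2s)
  ca <- gamma_variate(t, p$t0_s, p$alpha, p$beta_s, amp)
  tp <- spec$tissue_params
  cbv_map <- param_map(labels, tp, "cbv")
  k2_map <- param_map(labels, tp, "k2_dsc")
  ref_mask <- labels %in% TISSUE_CODES[c("wm", "gm", "subcortical", "ed", "tiz")]
  dim(ref_mask) <- dim(labels)
  ref_cbv <- mean(cbv_map[ref_mask])
  ref_curve <- ref_cbv * ca
  ref_cum <- cumtrapz_curve(ref_curve, t)

  s0 <- param_map(labels, tp, "m0")
  te_s <- p$te_ms * 1e-3
  n <- dim(labels)
  sig <- array(0, c(n, p$n_frames))
  set.seed(spec$seed + 1L)
  for (k in seq_len(p$n_frames)) {
    dr2 <- cbv_map * ca[k] - k2_map * ref_cum[k]
    s <- s0 * exp(-te_s * dr2)
    if (p$noise_sigma > 0) s <- s + rnorm(prod(n), 0, p$noise_sigma)
    sig[, , , k] <- s
  }
  structure(list(
    signal = sig, times_s = t, te_ms = p$te_ms, s0_map = s0,
    truth = list(cbv_by_label = stats::setNames(tp$cbv, tp$tissue),
                 k2_et = tp["et", "k2_dsc"], arterial_curve = ca,
                 reference_mask = ref_mask)
  ), class = "dsc_series")
}

## cumulative trapezoidal integral of y(t), same length as y
cumtrapz_curve <- function(y, t) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' Plasma (vascular) input function for the DCE simulation
#' @keywords internal
dce_vif <- function(t, p) {
  amp <- gamma_amplitude_for_peak(p$alpha, p$beta_s, p$peak_mM)
  gamma_variate(t, p$t0_s, p$alpha, p$beta_s, amp) +
    p$plateau_mM * (1 - exp(-pmax(t - p$t0_s, 0) / p$plateau_tau_s))
}

## SPGR steady-state signal
spgr_signal <- function(m0, t1_ms, flip_deg, tr_ms) {
  e1 <- exp(-tr_ms / t1_ms)
  a <- flip_deg * pi / 180
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Simulate the DCE acquisition (dynamics + VFA baselines)
#'
#' Tissue concentration follows the extended Tofts forward model driven
#' by a shared plasma input function (vessel voxels carry the input
#' function itself); `1/T1(t) = 1/T10 + r1 C(t)`; signals via the SPGR
#' equation at the dynamic flip angle; VFA baseline volumes at
#' 5/10/15 degrees from T10.
#'
#' @param labels Label volume.
#' @param spec A [phantom_spec()].
#' @return List of class `dce_series`: `signal` (4D), `times_s`,
#'   `vfa` (list of volumes), `vfa_deg`, `tr_ms`, `flip_deg`, `truth`.
#' @export
simulate_dce <- function(labels, spec) {
  p <- spec$dce
  tp <- spec$tissue_params
  if (any(tp$ktrans_min > 0 & tp$ve <= 0))
    stop("ve must be > 0 wherever ktrans > 0")
  t <- (seq_len(p$n_frames) - 1) * p$frame_dt_s
  cp <- dce_vif(t, p)

  ## per-label concentration curves (labels share kinetics)
  ct_by_label <- lapply(seq_len(nrow(tp)), function(i) {
    extended_tofts_curve(cp, t, ktrans_min = tp$ktrans_min[i],
                         kep_min = if (tp$ve[i] > 0) tp$ktrans_min[i] / tp$ve[i] else 0,
                         vp = tp$vp[i])
  })
  t10 <- param_map(labels, tp, "t1_ms")
  m0 <- param_map(labels, tp, "m0")
  n <- dim(labels)
  lut_idx <- integer(max(tp$label) + 1L)
  lut_idx[tp$label + 1L] <- seq_len(nrow(tp))
  lab_idx <- lut_idx[labels + 1L]

  sig <- array(0, c(n, p$n_frames))
  set.seed(spec$seed + 2L)
  for (k in seq_len(p$n_frames)) {
    ct_k <- vapply(seq_len(nrow(tp)), function(i) ct_by_label[[i]][k], 0)
    ct_vol <- ct_k[lab_idx]
    t1_k <- 1 / (1 / t10 + spec$dce$r1 * ct_vol * 1e-3) # r1 in 1/s/mM, T1 in ms
    s <- spgr_signal(m0, t1_k, p$flip_deg, p$tr_ms)
    if (p$noise_sigma > 0) s <- s + rnorm(prod(n), 0, p$noise_sigma)
    sig[, , , k] <- s
  }
  vfa <- lapply(p$vfa_deg, function(fa) {
    v <- spgr_signal(m0, t10, fa, p$tr_ms)
    if (p$noise_sigma > 0) v <- v + array(rnorm(prod(n), 0, p$noise_sigma), n)
    v
  })
  structure(list(
    signal = sig, times_s = t, vfa = vfa, vfa_deg = p$vfa_deg,
    tr_ms = p$tr_ms, flip_deg = p$flip_deg, r1 = p$r1,
    truth = list(vif_mM = cp,
                 ktrans_by_label = stats::setNames(tp$ktrans_min, tp$tissue),
                 ve_by_label = stats::setNames(tp$ve, tp$tissue),
                 vp_by_label = stats::setNames(tp$vp, tp$tissue),
                 t10_by_label = stats::setNames(tp$t1_ms, tp$tissue))
  ), class = "dce_series")
}

#' Extended Tofts concentration curve
#'
#' `Ct(t) = vp Cp(t) + Ktrans int_0^t Cp(u) exp(-kep (t-u)) du`,
#' evaluated by trapezoidal discrete convolution on the frame grid.
#' Rates are per minute; times in seconds.
#'
#' @param cp Plasma concentration curve (mM).
#' @param times_s Frame times (s).
#' @param ktrans_min,kep_min Transfer and efflux rates, 1/min.
#' @param vp Plasma volume fraction.
#' @return Tissue concentration curve (mM).
#' @export
extended_tofts_curve <- function(cp, times_s, ktrans_min, kep_min, vp) {
  n <- length(cp)
  if (ktrans_min <= 0) return(vp * cp)
  kep_s <- kep_min / 60
  conv <- numeric(n)
  for (k in 2:n) {
    dt <- times_s[k] - times_s[k - 1]
    e <- exp(-kep_s * dt)
    ## trapezoidal update of int cp(u) exp(-kep(t-u)) du
    conv[k] <- conv[k - 1] * e + dt * (cp[k] + cp[k - 1] * e) / 2
  }
  vp * cp + (ktrans_min / 60) * conv
}

#' Build the complete phantom
#'
#' Convenience wrapper running label construction, source assignment,
#' field simulation and (optionally) the GRE/DSC/DCE acquisitions.
#'
#' @param spec A [phantom_spec()].
#' @param with_dynamics Simulate DSC and DCE too? Default TRUE.
#' @return List: `spec`, `truth` (with `field_ppm`), `gre`, and if
#'   requested `dsc`, `dce`.
#' @export
build_phantom <- function(spec = phantom_spec(), with_dynamics = TRUE) {
  labels <- build_labels(spec)
  truth <- assign_sources(labels, spec)
  truth$field_ppm <- simulate_field(truth$chi_total, spec)
  out <- list(spec = spec, truth = truth,
              gre = simulate_gre(truth, spec, truth$field_ppm))
  if (with_dynamics) {
    out$dsc <- simulate_dsc(labels, spec)
    out$dce <- simulate_dce(labels, spec)
  }
  out
}
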