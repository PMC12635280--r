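# Phantom construction: geometry, symmetry, ground-truth sources, and
# the forward signal models.

test_that("label map nests tumor compartments and is symmetric outside them", {
  ph <- small_phantom()
  lab <- ph$truth$labels
  n_ncr <- sum(lab == TISSUE_CODES[["ncr"]])
  n_et <- sum(lab %in% TISSUE_CODES[c("ncr", "et")])
  n_ed <- sum(lab %in% TISSUE_CODES[c("ncr", "et", "ed", "tiz")])
  expect_true(n_ncr > 0 && n_ncr < n_et && n_et < n_ed)

  # flipping changes labels only at tumor compartments and their mirrors
  flipped <- mirror_lr(lab)
  diff_vox <- which(flipped != lab)
  tumor <- which(lab %in% TISSUE_CODES[c("ed", "ncr", "et", "tiz")])
  mirror_tumor <- which(mirror_lr(array(lab %in% TISSUE_CODES[c("ed", "ncr", "et", "tiz")],
                                        dim(lab))))
  expect_true(all(diff_vox %in% union(tumor, mirror_tumor)))

  # a TIZ pocket exists inside edema; a vessel label exists
  expect_gt(sum(lab == TISSUE_CODES[["tiz"]]), 0)
  expect_gt(sum(lab == TISSUE_CODES[["vessel"]]), 0)
})

test_that("zero tumor radii give a tumor-free, perfectly mirror-symmetric map", {
  spec <- small_spec()
  spec$tumor$radii_mm <- list(ed = c(0, 0, 0), et = c(0, 0, 0),
                              ncr = c(0, 0, 0), tiz = c(0, 0, 0))
  lab <- build_labels(spec)
  expect_equal(sum(lab %in% TISSUE_CODES[c("ed", "ncr", "et", "tiz")]), 0)
  expect_identical(mirror_lr(lab), lab)
})

test_that("invalid tumor geometry is rejected", {
  spec <- small_spec()
  spec$tumor$radii_mm$ncr <- c(30, 30, 30) # NCR larger than ET
  expect_error(build_labels(spec), "nested")
  spec2 <- small_spec()
  spec2$tumor$center_mm <- c(5, 0, 0) # edema crosses the midline
  expect_error(build_labels(spec2), "mid-sagittal")
})

test_that("phantom_spec validates acquisition and source-sign parameters", {
  expect_error(phantom_spec(te_ms = c(5, 5, 10)), "strictly increasing")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  tp <- default_tissue_params()
  tp$c_dia[2] <- 0.1
  expect_error(phantom_spec(tissue_params = tp), "c_dia")
})

test_that("assign_sources builds consistent ground-truth maps", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_true(all(tr$chi_para >= 0))
  expect_true(all(tr$chi_dia <= 0))
  expect_equal(tr$chi_total, tr$chi_para + tr$chi_dia)
  # r2star = baseline + kappa * (c_para + |c_dia|) by construction
  expect_equal(tr$r2star,
               tr$r2_base + tr$kappa * (tr$chi_para + abs(tr$chi_dia)))
  # zero-source voxels: r2star equals baseline exactly (background)
  bg <- tr$labels == TISSUE_CODES[["background"]]
  expect_true(all(tr$r2star[bg] == tr$r2_base[bg]))
  # TIZ pocket: more paramagnetic, less diamagnetic than surrounding edema
  tiz <- tr$labels == TISSUE_CODES[["tiz"]]
  ed <- tr$labels == TISSUE_CODES[["ed"]]
  expect_gt(min(tr$chi_para[tiz]), max(tr$chi_para[ed]))
  expect_lt(max(abs(tr$chi_dia[tiz])), min(abs(tr$chi_dia[ed])))
  expect_true(all(tr$tiz_truth == tiz))
  # missing label parameters -> configuration error
  spec_bad <- small_spec()
  spec_bad$tissue_params <- spec_bad$tissue_params[-10, ]
  expect_error(assign_sources(ph$truth$labels, spec_bad), "missing labels")
})

test_that("forward dipole field: uniform offset, zero mean, mirror symmetry", {
  spec <- small_spec()
  dims <- spec$grid_shape
  # uniform chi -> zero field (D(0) = 0 convention)
  u <- array(0.3, dims)
  expect_lt(max(abs(simulate_field(u, spec))), 1e-12)
  # any chi -> zero-mean field over the FOV
  ph <- small_phantom()
  expect_lt(abs(mean(ph$truth$field_ppm)), 1e-12)
  # mirror image of chi gives mirror image of field
  f1 <- simulate_field(ph$truth$chi_total, spec)
  f2 <- simulate_field(mirror_lr(ph$truth$chi_total), spec)
  expect_equal(f2, mirror_lr(f1), tolerance = 1e-10)
})

test_that("external field of a susceptibility sphere matches the analytic dipole", {
  # 96^3 grid, R = 16 mm sphere, compare against dChi/3 (R/r)^3 (3cos^2 - 1)
  dims <- c(96L, 96L, 96L)
  vx <- c(2, 2, 2)
  spec <- phantom_spec(grid_shape = dims, voxel_size_mm = vx)
  co <- lapply(1:3, function(a) (seq_len(dims[a]) - (dims[a] + 1) / 2) * vx[a])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  dim(r2) <- dims
  R <- 16
  dchi <- 0.1
  chi <- (r2 <= R^2) * dchi
  field <- simulate_field(chi, spec)
  r <- sqrt(r2)
  z2 <- outer(array(0, dims[1:2]), co[[3]]^2, `+`)
  dim(z2) <- dims
  cos2 <- z2 / r2
  analytic <- dchi / 3 * (R / r)^3 * (3 * cos2 - 1)
  # sample a shell away from the sphere edge and the FOV boundary,
  # where the analytic magnitude is well above the voxelization floor
  shell <- r > 1.6 * R & r < 2.4 * R & abs(analytic) > 0.2 * dchi / 3 * (R / (2.4 * R))^3 * 2
  expect_gt(sum(shell), 1000)
  rel <- abs(field[shell] - analytic[shell]) / abs(analytic[shell])
  expect_lt(median(rel), 0.05)
  expect_lt(mean(rel > 0.05), 0.25) # bulk within 5 percent
})

test_that("multi-echo GRE signal follows the closed-form model and is reproducible", {
  spec <- small_spec(noise_sigma = 0)
  ph <- small_phantom()
  gre <- simulate_gre(ph$truth, spec, ph$truth$field_ppm)
  # magnitude ratio between consecutive echoes = exp(-r2star dTE)
  m1 <- abs(gre$signal[, , , 1]); m2 <- abs(gre$signal[, , , 2])
  inside <- ph$truth$brain_mask
  dte_s <- (spec$te_ms[2] - spec$te_ms[1]) * 1e-3
  expect_equal(m2[inside] / m1[inside],
               exp(-ph$truth$r2star[inside] * dte_s), tolerance = 1e-10)
  # wrapped phase equals wrap(2 pi f0 field TE)
  f0 <- 42.577e6 * spec$b0_tesla
  for (k in c(1L, length(spec$te_ms))) {
    expected <- 2 * pi * f0 * ph$truth$field_ppm * 1e-6 * spec$te_ms[k] * 1e-3
    wrapped <- Arg(exp(1i * expected))
    expect_equal(Arg(gre$signal[, , , k])[inside], wrapped[inside],
                 tolerance = 1e-8)
  }
  # field = 0 gives identically zero phase
  gre0 <- simulate_gre(ph$truth, spec, array(0, dim(ph$truth$m0)))
  expect_true(all(abs(Arg(gre0$signal[, , , 3])[inside]) < 1e-12))
  # same seed -> identical bytes; noise is seed-controlled
  spec_n <- small_spec(noise_sigma = 0.02)
  g1 <- simulate_gre(ph$truth, spec_n, ph$truth$field_ppm)
  g2 <- simulate_gre(ph$truth, spec_n, ph$truth$field_ppm)
  expect_identical(g1$signal, g2$signal)
  expect_false(identical(g1$signal, gre$signal))
})

test_that("noise-free volumes of a tumor-free spec are mirror symmetric", {
  spec <- small_spec()
  spec$tumor$radii_mm <- list(ed = c(0, 0, 0), et = c(0, 0, 0),
                              ncr = c(0, 0, 0), tiz = c(0, 0, 0))
  ph <- build_phantom(spec, with_dynamics = FALSE)
  expect_equal(ph$truth$field_ppm, mirror_lr(ph$truth$field_ppm),
               tolerance = 1e-10)
  expect_identical(ph$truth$r2star, mirror_lr(ph$truth$r2star))
})

test_that("DSC series obeys the configured gamma-variate kinetics", {
  spec <- small_spec()
  spec$dsc$noise_sigma <- 0
  lab <- build_labels(spec)
  dsc <- simulate_dsc(lab, spec)
  # vessel voxel: peak of -ln(S/S0) at the gamma-variate peak time t0 + alpha beta
  v <- which(lab == TISSUE_CODES[["vessel"]])[1]
  idx <- arrayInd(v, dim(lab))
  curve <- dsc$signal[idx[1], idx[2], idx[3], ]
  s0 <- dsc$s0_map[idx[1], idx[2], idx[3]]
  dr2 <- -log(curve / s0)
  t_peak <- dsc$times_s[which.max(dr2)]
  expect_equal(t_peak, spec$dsc$t0_s + spec$dsc$alpha * spec$dsc$beta_s,
               tolerance = spec$dsc$tr_s + 1e-9)
  # zero-cbv label: flat signal
  bg <- which(lab == TISSUE_CODES[["background"]])[1]
  idx <- arrayInd(bg, dim(lab))
  expect_equal(stats::sd(dsc$signal[idx[1], idx[2], idx[3], ]), 0)
  # doubling cbv doubles the delta-R2* AUC (linearity, leakage-free label)
  spec2 <- spec
  spec2$tissue_params["gm", "cbv"] <- 2 * spec$tissue_params["gm", "cbv"]
  dsc2 <- simulate_dsc(lab, spec2)
  g <- which(lab == TISSUE_CODES[["gm"]])[1]
  idx <- arrayInd(g, dim(lab))
  a1 <- sum(-log(dsc$signal[idx[1], idx[2], idx[3], ] / dsc$s0_map[idx[1], idx[2], idx[3]]))
  a2 <- sum(-log(dsc2$signal[idx[1], idx[2], idx[3], ] / dsc2$s0_map[idx[1], idx[2], idx[3]]))
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("DCE series matches the SPGR/extended-Tofts forward model", {
  spec <- small_spec()
  spec$dce$noise_sigma <- 0
  lab <- build_labels(spec)
  dce <- simulate_dce(lab, spec)
  # zero-ktrans, zero-vp label: constant baseline signal
  w <- which(lab == TISSUE_CODES[["wm"]])[1]
  idx <- arrayInd(w, dim(lab))
  expect_equal(stats::sd(dce$signal[idx[1], idx[2], idx[3], ]), 0)
  # VFA volumes satisfy the SPGR ratio identity for the configured T10
  t10 <- spec$tissue_params["wm", "t1_ms"]
  e1 <- exp(-spec$dce$tr_ms / t10)
  s <- vapply(dce$vfa, function(v) v[idx[1], idx[2], idx[3]], 0)
  a <- spec$dce$vfa_deg * pi / 180
  slope <- diff(s / sin(a))[1] / diff(s / tan(a))[1]
  expect_equal(slope, e1, tolerance = 1e-9)
  # ET plateau: positive, and approaching (ve+vp) x VIF plateau from
  # below on a long horizon (the washout-equilibrium bound)
  t_long <- seq(0, 3000, by = 5)
  vif_long <- tizmapr:::dce_vif(t_long, spec$dce)
  ct <- extended_tofts_curve(vif_long, t_long,
                             ktrans_min = spec$tissue_params["et", "ktrans_min"],
                             kep_min = spec$tissue_params["et", "ktrans_min"] /
                               spec$tissue_params["et", "ve"],
                             vp = spec$tissue_params["et", "vp"])
  n <- length(ct)
  ve_vp <- spec$tissue_params["et", "ve"] + spec$tissue_params["et", "vp"]
  expect_gt(ct[n], 0)
  # small slack: the trapezoidal discrete convolution overshoots the
  # continuum steady state by O((kep dt)^2)
  expect_lt(ct[n], ve_vp * vif_long[n] * (1 + 1e-3))
  # ve <= 0 with ktrans > 0 is a parameter error
  spec_bad <- spec
  spec_bad$tissue_params["et", "ve"] <- 0
  expect_error(simulate_dce(lab, spec_bad), "ve must be")
})
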