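## Orchestration and I/O. Volumes travel as plain 3D/4D arrays in
## voxel-index space (x, y, z); NIfTI-1 files carry the geometry. All
## tunables live in one config list so every threshold and default has
## a single source of truth, and every computed per-subject threshold
## is logged into the report for provenance.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file.
#' @param expect_geometry Optional list(`dim`, `pixdim`) to enforce
#'   cross-input consistency (spacing tolerance 1e-3 mm).
#' @return Numeric array with attribute `pixdim` (mm).
#' @export
read_volume <- function(path, expect_geometry = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  if (!is.null(expect_geometry)) {
    if (!identical(dim(arr)[1:3], expect_geometry$dim[1:3]) ||
        any(abs(pd - expect_geometry$pixdim[seq_along(pd)]) > 1e-3))
      stop("geometry mismatch: ", path, " does not match ",
           expect_geometry$source %||% "reference geometry")
  }
  attr(arr, "pixdim") <- pd
  arr
}

#' Write a volume as NIfTI (float32; masks as uint8)
#'
#' @param obj Numeric or logical array.
#' @param path Output file (.nii or .nii.gz).
#' @param voxel_size_mm Voxel spacing, mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path, voxel_size_mm = c(1, 1, 1)) {
  is_mask <- is.logical(obj)
  arr <- if (is_mask) array(as.integer(obj), dim(obj)) else obj
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' Every tunable of the method with its default: mask erosion 3 mm,
#' V-SHARP radii 12 mm down to the voxel size with lambda 0.05, TKD
#' threshold 0.2, iterative-inversion lambda 1e-2, epsilon floor 1e-4
#' ppm, reference trim at the 95th percentile (per-tissue), exclusion
#' percentiles 95 (nCBV) / 5 (Ktrans), significance level 0.05.
#'
#' @param seed RNG seed for the phantom simulators.
#' @param ... Overrides of any default field.
#' @return Config list.
#' @export
default_config <- function(seed = 20240101L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    phantom = list(),        # phantom_spec() overrides
    use_dsc = TRUE, use_dce = TRUE,
    erosion_mm = 3,
    vsharp_radii_mm = seq(12, 2, by = -2),
    vsharp_lambda = 0.05,
    tkd_threshold = 0.2,
    iter_lambda = 1e-2,
    kappa = NULL,            # NULL = static-dephasing default at B0
    r2_baseline_mode = "label", # or "nawm"
    epsilon_ppm = 1e-4,
    trim_pct = 95,
    pooled_trim = FALSE,
    alpha = 0.05
  )
  ovr <- list(...)
  cfg[names(ovr)] <- ovr
  cfg
}

## deterministic 32-bit FNV-1a hash of a JSON-serialised object
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                          force = TRUE, null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Run the full phantom-to-report pipeline
#'
#' Simulates the phantom, reconstructs chi with both dipole-inversion
#' algorithms, decomposes into PCS/DCS, quantifies nCBV and Ktrans for
#' the blood-exclusion mask (or proceeds with an empty exclusion mask
#' when the dynamic stages are disabled), delineates the TIZ per
#' algorithm, computes the cross-algorithm Dice, and assembles the
#' statistics report. When `out_dir` is given, key maps and the report
#' (JSON, with a provenance sidecar) are written to disk.
#'
#' @param config See [default_config()].
#' @param out_dir Optional output directory.
#' @return List: `phantom`, `qsm`, `decomposition` (per algorithm),
#'   `hemo` (or NULL), `tiz` (per algorithm), `dice_cross_algorithm`,
#'   `report`, `thresholds`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  spec <- do.call(phantom_spec, c(list(seed = config$seed), config$phantom))
  vx <- spec$voxel_size_mm
  ph <- build_phantom(spec, with_dynamics = config$use_dsc || config$use_dce)
  labels <- ph$truth$labels
  tumor_mask <- labels %in% TISSUE_CODES[c("ed", "ncr", "et", "tiz")]
  dim(tumor_mask) <- dim(labels)
  et_mask <- labels == TISSUE_CODES[["et"]]

  qsm <- qsm_reconstruct(ph$gre, ph$truth$brain_mask, tumor_mask,
                         voxel_size_mm = vx,
                         erosion_mm = config$erosion_mm,
                         vsharp_radii_mm = config$vsharp_radii_mm,
                         vsharp_lambda = config$vsharp_lambda,
                         tkd_threshold = config$tkd_threshold,
                         iter_lambda = config$iter_lambda)

  kappa <- config$kappa %||% static_dephasing_kappa(spec$b0_tesla)
  if (config$r2_baseline_mode == "label") {
    baseline <- param_map(labels, spec$tissue_params, "r2_base")
  } else {
    contra_wm <- (labels == TISSUE_CODES[["wm"]]) & !ph$truth$hemisphere_mask
    baseline <- contra_wm # mask form: NAWM median
  }
  r2p <- estimate_r2prime(qsm$r2star, baseline)
  decomp <- lapply(qsm$chi, function(cm)
    decompose_map(cm, r2p$r2prime, kappa = kappa))

  hemo <- NULL
  exclusion <- NULL
  thresholds <- list()
  if (config$use_dsc || config$use_dce) {
    hemo <- list()
    ncbv <- NULL; kt <- NULL; kt_valid <- NULL
    if (config$use_dsc) {
      dsc <- ph$dsc
      base_fr <- which(dsc$times_s < spec$dsc$t0_s - 5)
      dr2 <- dsc_to_delta_r2star(dsc$signal, dsc$te_ms, base_fr)
      vessel <- labels == TISSUE_CODES[["vessel"]]
      aif <- select_aif(dr2$delta_r2star, vessel, k = 5)
      ref_mask <- labels %in% TISSUE_CODES[c("wm", "gm", "subcortical",
                                             "ed", "tiz")]
      dim(ref_mask) <- dim(labels)
      lc <- leakage_correct(dr2$delta_r2star, ref_mask, dsc$times_s)
      cbv <- compute_cbv(lc$corrected, aif$aif, dsc$times_s)
      nawm <- (labels == TISSUE_CODES[["wm"]]) & !ph$truth$hemisphere_mask
      ncbv <- normalize_cbv(cbv, nawm)
      hemo$cbv <- cbv; hemo$ncbv <- ncbv; hemo$k2_map <- lc$k2_map
      hemo$aif <- aif$aif
    }
    if (config$use_dce) {
      dce <- ph$dce
      vfa <- vfa_t1_fit(dce$vfa, dce$vfa_deg, dce$tr_ms)
      base_fr <- which(dce$times_s < spec$dce$t0_s - 5)
      conc <- dce_to_concentration(dce$signal, vfa$t10_ms, dce$flip_deg,
                                   dce$tr_ms, dce$r1, base_fr)
      vessel_idx <- which(labels == TISSUE_CODES[["vessel"]])
      cmat <- matrix(conc, prod(dim(labels)), dim(conc)[4])
      vif <- colMeans(cmat[vessel_idx, , drop = FALSE])
      fits <- fit_extended_tofts_map(conc, vif, dce$times_s, tumor_mask)
      kt <- fits$ktrans; kt_valid <- fits$valid
      hemo$t10 <- vfa$t10_ms; hemo$ktrans <- kt
      hemo$ktrans_valid <- kt_valid; hemo$vif <- vif
    }
    if (!is.null(ncbv)) {
      contra_tumor <- mirror_mask(tumor_mask)
      ex <- blood_exclusion_mask(ncbv, kt, kt_valid, tumor_mask,
                                 contra_tumor, et_mask)
      exclusion <- ex$mask
      thresholds$thr_ncbv <- ex$thr_ncbv
      thresholds$thr_ktrans <- ex$thr_ktrans
      hemo$exclusion <- ex
    }
  } else {
    warning("DSC/DCE disabled: TIZ computed with an empty exclusion mask")
  }

  tiz <- lapply(decomp, function(d)
    delineate_tiz(d, labels, exclusion, tumor_side = "right",
                  trim_pct = config$trim_pct, pooled = config$pooled_trim,
                  epsilon_ppm = config$epsilon_ppm))
  thresholds$theta_tiz <- vapply(tiz, function(t) t$threshold, 0)
  dice_cross <- dice(tiz$tkd$tiz$tiz_mask, tiz$iterative$tiz$tiz_mask)

  ## statistics on the primary (tkd-tagged) result
  prim <- tiz$tkd
  pdr <- prim$pdr_map$pdr
  tiz_mask <- prim$tiz$tiz_mask
  contra_gm <- (labels == TISSUE_CODES[["gm"]]) & !ph$truth$hemisphere_mask
  edema <- labels == TISSUE_CODES[["ed"]] | labels == TISSUE_CODES[["tiz"]]
  rest <- edema & !tiz_mask
  if (!is.null(exclusion)) rest <- rest & !exclusion
  eps <- config$epsilon_ppm
  report <- build_report(
    tiz_pdr_values = pmax(pdr[tiz_mask], eps),
    contralateral_pdr_values = pmax(pdr[contra_gm], eps),
    edema_rest_pdr_values = pmax(pdr[rest], eps),
    thresholds = thresholds,
    dice_cross_algorithm = dice_cross
  )

  result <- list(phantom = ph, qsm = qsm, decomposition = decomp,
                 hemo = hemo, exclusion = exclusion, tiz = tiz,
                 dice_cross_algorithm = dice_cross, report = report,
                 thresholds = thresholds)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir, vx)
  result
}

write_pipeline_outputs <- function(result, config, out_dir, vx) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wv <- function(obj, name) write_volume(obj, file.path(out_dir, name), vx)
  wv(result$phantom$truth$labels * 1, "labels.nii.gz")
  for (alg in names(result$decomposition)) {
    d <- result$decomposition[[alg]]
    wv(result$qsm$chi[[alg]]$chi_ppm, sprintf("chi_%s.nii.gz", alg))
    wv(d$pcs_ppm, sprintf("pcs_%s.nii.gz", alg))
    wv(d$dcs_ppm, sprintf("dcs_%s.nii.gz", alg))
    wv(result$tiz[[alg]]$pdr_map$pdr, sprintf("pdr_%s.nii.gz", alg))
    wv(result$tiz[[alg]]$tiz$tiz_mask, sprintf("tiz_%s.nii.gz", alg))
  }
  if (!is.null(result$hemo$ncbv)) wv(result$hemo$ncbv, "ncbv.nii.gz")
  if (!is.null(result$hemo$ktrans)) wv(result$hemo$ktrans, "ktrans.nii.gz")
  if (!is.null(result$exclusion)) wv(result$exclusion, "blood_exclusion.nii.gz")
  report <- unclass(result$report)
  report$tests <- lapply(report$tests, function(t) if (is.null(t)) NULL else unclass(t))
  report$features <- lapply(report$features, unclass)
  prov <- list(config = config, config_hash = config_hash(config),
               seed = config$seed, package_version = "0.1.0")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
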