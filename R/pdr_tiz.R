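## PDR (PCS over |DCS|) computation and TIZ delineation. The threshold
## is data-driven and subject-specific: PDR distributions of the
## contralateral gray and white matter are trimmed at their own 95th
## percentile (subcortical nuclei removed from GM first), and the
## maximum surviving GM PDR becomes the TIZ threshold — GM sits above
## WM on the PDR scale, so it is the conservative healthy reference.

#' Paramagnetic-to-diamagnetic ratio map
#'
#' `pdr = pcs / max(|dcs|, epsilon)`. The epsilon floor (default 1e-4
#' ppm) prevents division blow-up where the diamagnetic source
#' underflows; floored voxels are reported, not discarded — very large
#' finite PDR values are expected in pathology.
#'
#' @param pcs_map Paramagnetic source map, ppm (>= 0).
#' @param dcs_map Diamagnetic source map, ppm (<= 0).
#' @param mask Logical validity mask.
#' @param epsilon_ppm Floor for |DCS|, > 0. Default 1e-4.
#' @return List of class `pdr_map`: `pdr`, `valid_mask`, `floored`
#'   (logical volume), `epsilon_ppm`.
#' @export
compute_pdr <- function(pcs_map, dcs_map, mask = NULL, epsilon_ppm = 1e-4) {
  if (epsilon_ppm <= 0) stop("epsilon_ppm must be > 0")
  if (is.null(mask)) mask <- array(TRUE, dim(pcs_map))
  stopifnot(identical(dim(pcs_map), dim(dcs_map)))
  floored <- abs(dcs_map) < epsilon_ppm
  pdr <- pcs_map / pmax(abs(dcs_map), epsilon_ppm)
  pdr[!mask] <- 0
  structure(list(pdr = pdr, valid_mask = mask != 0,
                 floored = floored & (mask != 0),
                 epsilon_ppm = epsilon_ppm),
            class = "pdr_map")
}

#' Trim the healthy-reference PDR distributions
#'
#' Removes subcortical voxels from the (contralateral) GM mask, then
#' drops values above each tissue's own `trim_pct` percentile (linear
#' interpolation) to guard against outliers and segmentation errors.
#' A `pooled = TRUE` mode trims GM and WM against their pooled
#' percentile instead.
#'
#' @param pdr `pdr_map` or plain PDR volume.
#' @param gm_mask,wm_mask,subcortical_mask Logical volumes
#'   (contralateral hemisphere only).
#' @param trim_pct Percentile above which values are discarded.
#'   Default 95.
#' @param pooled Trim against the pooled GM+WM percentile? Default
#'   FALSE (per-tissue).
#' @return List: `gm_values`, `wm_values` (retained PDR values),
#'   `gm_cut`, `wm_cut` (the applied cutoffs).
#' @export
reference_trim <- function(pdr, gm_mask, wm_mask, subcortical_mask = NULL,
                           trim_pct = 95, pooled = FALSE) {
  p <- if (inherits(pdr, "pdr_map")) pdr$pdr else pdr
  gm <- gm_mask != 0
  if (!is.null(subcortical_mask)) gm <- gm & !(subcortical_mask != 0)
  if (!any(gm)) stop("GM mask empty after subcortical removal")
  gm_v <- p[gm]
  wm_v <- p[wm_mask != 0]
  if (pooled) {
    cut <- stats::quantile(c(gm_v, wm_v), trim_pct / 100, names = FALSE)
    gm_cut <- wm_cut <- cut
  } else {
    gm_cut <- stats::quantile(gm_v, trim_pct / 100, names = FALSE)
    wm_cut <- if (length(wm_v))
      stats::quantile(wm_v, trim_pct / 100, names = FALSE) else NA_real_
  }
  list(gm_values = gm_v[gm_v <= gm_cut],
       wm_values = wm_v[wm_v <= wm_cut],
       gm_cut = gm_cut, wm_cut = wm_cut)
}

#' TIZ threshold from the trimmed GM reference
#'
#' The maximum of the retained contralateral GM PDR values.
#'
#' @param trimmed_gm_values Nonempty numeric vector.
#' @return Scalar threshold.
#' @export
tiz_threshold <- function(trimmed_gm_values) {
  if (length(trimmed_gm_values) == 0) stop("empty trimmed GM reference")
  max(trimmed_gm_values)
}

#' Segment the tumor and immune cell infiltration zone
#'
#' Edema voxels (outside the blood-exclusion mask) whose PDR is
#' strictly above the threshold.
#'
#' @param pdr `pdr_map` or plain PDR volume.
#' @param edema_mask Logical edema mask.
#' @param exclusion_mask Logical blood-exclusion mask (may be NULL).
#' @param threshold Scalar >= 0.
#' @return List of class `tiz_result`: `tiz_mask`, `threshold`,
#'   `n_voxels`.
#' @export
segment_tiz <- function(pdr, edema_mask, exclusion_mask = NULL, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  p <- if (inherits(pdr, "pdr_map")) pdr$pdr else pdr
  keep <- edema_mask != 0
  if (!is.null(exclusion_mask)) keep <- keep & !(exclusion_mask != 0)
  tiz <- keep & (p > threshold)
  structure(list(tiz_mask = tiz, threshold = threshold,
                 n_voxels = sum(tiz)),
            class = "tiz_result")
}

#' Delineate the TIZ from decomposition outputs
#'
#' Convenience wrapper: PDR map, contralateral reference trimming, GM
#' threshold and segmentation in one call.
#'
#' @param decomposition A `decomposition` object.
#' @param labels Phantom/clinical label volume (codes as
#'   [TISSUE_CODES]).
#' @param exclusion_mask Logical blood-exclusion mask or NULL.
#' @param tumor_side Which hemisphere holds the tumor: "right" means
#'   positive-x side of the mid-sagittal plane.
#' @param trim_pct,pooled,epsilon_ppm Passed through.
#' @return List: `pdr_map`, `reference`, `threshold`, `tiz`
#'   (`tiz_result`).
#' @export
delineate_tiz <- function(decomposition, labels, exclusion_mask = NULL,
                          tumor_side = "right", trim_pct = 95,
                          pooled = FALSE, epsilon_ppm = 1e-4) {
  pdr <- compute_pdr(decomposition$pcs_ppm, decomposition$dcs_ppm,
                     decomposition$mask, epsilon_ppm)
  nd <- dim(labels)
  xs <- seq_len(nd[1]) - (nd[1] + 1) / 2
  tumor_x <- if (tumor_side == "right") xs > 0 else xs < 0
  contra <- array(rep(!tumor_x & xs != 0, times = prod(nd[2:3])), nd)
  gm <- (labels == TISSUE_CODES[["gm"]]) & contra
  wm <- (labels == TISSUE_CODES[["wm"]]) & contra
  sc <- (labels == TISSUE_CODES[["subcortical"]]) & contra
  ref <- reference_trim(pdr, gm, wm, sc, trim_pct, pooled)
  thr <- tiz_threshold(ref$gm_values)
  edema <- labels == TISSUE_CODES[["ed"]] | labels == TISSUE_CODES[["tiz"]]
  tiz <- segment_tiz(pdr, edema, exclusion_mask, thr)
  list(pdr_map = pdr, reference = ref, threshold = thr, tiz = tiz)
}

#' Mirror a mask across the mid-sagittal plane
#'
#' Alias of [mirror_lr()] restricted to logical input; realises the
#' "flip in the symmetric space" construction of contralateral masks.
#'
#' @param mask Logical volume on a grid symmetric about the plane.
#' @return Reflected logical volume.
#' @export
mirror_mask <- function(mask) {
  mirror_lr(mask != 0)
}
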