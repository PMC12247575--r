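#' Tissue probability maps for a phantom
#'
#' Binary tissue "probabilities" from the phantom labels: grey matter
#' (cortex, ERC, hippocampus, insula, cerebellum), white matter (white
#' matter core and pons), and the CSF compartment that stands in for the
#' extra-cerebral binding sources (meningeal shell and sinus), mirroring
#' the convention of representing ECB by the CSF segmentation.
#'
#' @param phantom a phantom [label_volume()].
#' @return List with arrays `gm`, `wm`, `csf` in `[0, 1]`.
#' @export
tissue_probability_maps <- function(phantom) {
  m <- phantom_masks(phantom)
  list(gm = (m$cortical_gm | m$erc | m$hippocampus | m$insula |
               m$cerebellum) * 1,
       wm = (m$white_matter | m$pons) * 1,
       csf = (m$meninges_shell | m$sinus) * 1)
}

#' Configuration for Mueller-Gartner partial-volume correction
#'
#' @param gm,wm,csf tissue probability volumes in `[0, 1]` on the image
#'   grid; per voxel they may sum to at most 1 (plus tolerance).
#' @param psf_fwhm point-spread FWHM in mm used by the correction
#'   (default 6.5).
#' @param wm_prob_threshold,csf_prob_threshold probability above which a
#'   voxel is used for the homogeneous white-matter / ECB-compartment
#'   estimate (default 0.95).
#' @param gm_mask_threshold minimum blurred grey-matter probability for the
#'   division; voxels below it are left unmodified and flagged.
#' @return An object of class `pvc_config`.
#' @export
pvc_config <- function(gm, wm, csf, psf_fwhm = 6.5,
                       wm_prob_threshold = 0.95,
                       csf_prob_threshold = 0.95,
                       gm_mask_threshold = 0.3) {
  stopifnot(psf_fwhm >= 0)
  for (p in list(gm, wm, csf))
    if (min(p) < 0 || max(p) > 1)
      stop("pvc_config: tissue probabilities must lie in [0, 1]")
  if (max(gm + wm + csf) > 1 + 1e-6)
    stop("pvc_config: tissue probabilities sum to more than 1")
  structure(list(gm = gm, wm = wm, csf = csf, psf_fwhm = psf_fwhm,
                 wm_prob_threshold = wm_prob_threshold,
                 csf_prob_threshold = csf_prob_threshold,
                 gm_mask_threshold = gm_mask_threshold),
            class = "pvc_config")
}

#' Mueller-Gartner partial-volume correction
#'
#' For grey-matter voxels, the white-matter and ECB (CSF-compartment)
#' contributions are estimated, blurred with the PSF, subtracted, and the
#' remainder divided by the blurred grey-matter probability:
#' `corrected = (observed - C_WM * blur(pWM) - C_ECB * blur(pCSF)) / blur(pGM)`.
#' `C_WM` is the mean of the observed image over voxels with
#' `pWM >= wm_prob_threshold` (the homogeneous white-matter assumption) and
#' `C_ECB` the analogous CSF-compartment estimate. Voxels whose blurred
#' grey-matter probability falls below `gm_mask_threshold` are left
#' unmodified and flagged in the attribute `"pvc_flagged"`.
#'
#' @param image a [pet_image()].
#' @param config a [pvc_config()]; its tissue maps must be on the image
#'   grid.
#' @return A corrected [pet_image()] with attribute `"pvc_flagged"` (the
#'   grey-matter voxels that were left unmodified).
#' @export
mg_pvc <- function(image, config) {
  stopifnot(inherits(image, "pet_image"), inherits(config, "pvc_config"))
  for (nm in c("gm", "wm", "csf")) {
    if (is.null(config[[nm]])) stop("mg_pvc: missing tissue map: ", nm)
    if (!identical(dim(config[[nm]]), image$grid$shape))
      stop("mg_pvc: tissue map '", nm, "' is not on the image grid")
  }
  vs <- image$grid$voxel_size
  fwhm <- rep(config$psf_fwhm, 3)
  b_gm <- psf_blur(config$gm, fwhm, vs)
  b_wm <- psf_blur(config$wm, fwhm, vs)
  b_csf <- psf_blur(config$csf, fwhm, vs)
  obs <- image$values
  wm_vox <- config$wm >= config$wm_prob_threshold
  csf_vox <- config$csf >= config$csf_prob_threshold
  if (!any(wm_vox)) stop("mg_pvc: no voxels above wm_prob_threshold")
  c_wm <- mean(obs[wm_vox])
  c_ecb <- if (any(csf_vox)) mean(obs[csf_vox]) else 0
  sel <- b_gm >= config$gm_mask_threshold
  out <- obs
  out[sel] <- (obs[sel] - c_wm * b_wm[sel] - c_ecb * b_csf[sel]) / b_gm[sel]
  prov <- image$provenance
  prov$pvc <- list(method = "muller_gartner", psf_fwhm = config$psf_fwhm,
                   c_wm = c_wm, c_ecb = c_ecb)
  res <- pet_image(out, image$grid, image$unit, prov)
  attr(res, "pvc_flagged") <- (config$gm > 0) & !sel
  res
}
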