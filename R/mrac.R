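#' Attenuation map (mu-map) container
#'
#' Holds 511-keV linear attenuation coefficients (cm^-1) together with the
#' provenance of the map and, for MR-derived maps, the intermediate pseudo-CT
#' and tissue-class volume.
#'
#' @param mu volume of linear attenuation coefficients, cm^-1, in [0, 0.25].
#' @param provenance one of `"CT"`, `"RESOLUTE"`, `"DEEPUTE"`, `"NOBONE"`,
#'   or a compound tag (see [stitch_fov()]).
#' @param pseudo_ct optional HU volume the map was derived from.
#' @param classes optional 3-class tissue volume (0 air, 1 soft, 2 bone).
#' @return an object of class `mu_map`.
#' @export
mu_map <- function(mu, provenance, pseudo_ct = NULL, classes = NULL) {
  stopifnot(is.array(mu), length(dim(mu)) == 3L)
  if (any(!is.finite(mu))) stop("mu-map contains non-finite values")
  if (min(mu) < 0 || max(mu) > 0.25)
    stop("mu values outside the physical range [0, 0.25] cm^-1")
  structure(list(mu = mu, provenance = provenance,
                 pseudo_ct = pseudo_ct, classes = classes),
            class = "mu_map")
}

#' @export
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map> %s  %s voxels, mu in [%.4f, %.4f] cm^-1\n",
              x$provenance, paste(dim(x$mu), collapse = "x"),
              min(x$mu), max(x$mu)))
  invisible(x)
}

#' Apparent transverse relaxation rate (R2*) from a dual-echo pair
#'
#' Two-point estimate `R2* = ln(S1/S2) / (TE2 - TE1)` per voxel, in s^-1.
#' Voxels where either echo is at or below the signal floor, or where noise
#' makes the estimate negative, are set to 0; values above `clamp_max` are
#' clamped. Bone is the tissue of interest: its fast signal decay between the
#' ultrashort first echo and the conventional second echo yields large R2*.
#'
#' @param ute1,ute2 echo volumes on a shared grid.
#' @param te1_ms,te2_ms echo times in ms (defaults are the UTE protocol values
#'   0.07 and 2.46 ms).
#' @param clamp_max ceiling in s^-1.
#' @param eps signal floor; default `1e-6 * max(ute1)`.
#' @return volume of R2* values in s^-1.
#' @export
compute_r2star <- function(ute1, ute2, te1_ms = 0.07, te2_ms = 2.46,
                           clamp_max = 3000, eps = NULL) {
  check_same_grid(ute1, ute2, "echo volumes")
  if (!(te2_ms > te1_ms && te1_ms > 0))
    stop("echo times must satisfy 0 < te1 < te2")
  if (is.null(eps)) eps <- 1e-6 * max(ute1)
  dte_s <- (te2_ms - te1_ms) / 1000
  r2 <- array(0, dim(ute1))
  ok <- ute1 > eps & ute2 > eps
  r2[ok] <- log(ute1[ok] / ute2[ok]) / dte_s
  r2[r2 < 0] <- 0
  r2[r2 > clamp_max] <- clamp_max
  as_volume(r2, voxel_spacing(ute1))
}

#' Convert Hounsfield units to 511-keV linear attenuation
#'
#' Standard bilinear conversion: below water (HU <= 0) attenuation scales
#' linearly from air (-1000 HU, mu = 0) to water; above water a shallower
#' bone slope applies:
#' `mu = mu_water * (HU + 1000)/1000` for HU <= 0, and
#' `mu = mu_water + k_bone * HU` for HU > 0. The vendor curve used clinically
#' is proprietary; the constants here are conventional 511-keV values and are
#' configurable. The map is continuous at 0 HU and monotone in HU.
#'
#' @param ct HU volume (values in [-1024, 4000]).
#' @param mu_water water attenuation at 511 keV, cm^-1.
#' @param k_bone bone slope, cm^-1 per HU.
#' @param provenance provenance tag for the resulting map.
#' @return a [mu_map()].
#' @export
hu_to_mu <- function(ct, mu_water = 0.096, k_bone = 5.1e-5,
                     provenance = "CT") {
  if (any(!is.finite(ct))) stop("CT volume contains non-finite values")
  mu <- ifelse(ct <= 0, mu_water * (ct + 1000) / 1000, mu_water + k_bone * ct)
  mu[mu < 0] <- 0
  mu_map(as_volume(array(mu, dim(ct)), voxel_spacing(ct)), provenance,
         pseudo_ct = ct)
}

#' Three-class tissue segmentation of a CT-like volume
#'
#' Thresholds an HU-scaled volume into air / soft tissue / bone, the classes
#' used to score pseudo-CTs against the reference CT.
#'
#' @param ct_like HU volume.
#' @param air_max HU below which a voxel is air.
#' @param bone_min HU above which a voxel is bone.
#' @return integer volume: 0 air, 1 soft, 2 bone.
#' @export
classify_tissue <- function(ct_like, air_max = -500, bone_min = 300) {
  if (any(!is.finite(ct_like))) stop("input contains non-finite values")
  cls <- array(1L, dim(ct_like))
  cls[ct_like < air_max] <- 0L
  cls[ct_like > bone_min] <- 2L
  as_volume(cls, voxel_spacing(ct_like))
}

#' Stitch two attenuation maps across a field-of-view boundary
#'
#' Clinically the reference CT often covers less than the PET/MRI axial
#' field of view; the MR-based map fills in outside. Output takes the primary
#' map inside `fov_mask` and the fallback outside.
#'
#' @param primary,fallback [mu_map()] objects on a shared grid.
#' @param fov_mask logical volume, TRUE where the primary map is valid.
#' @return a [mu_map()] with compound provenance.
#' @export
stitch_fov <- function(primary, fallback, fov_mask) {
  stopifnot(inherits(primary, "mu_map"), inherits(fallback, "mu_map"))
  check_same_grid(primary$mu, fallback$mu, "mu-maps")
  check_same_grid(primary$mu, fov_mask, "mu-map and FOV mask")
  mu <- ifelse(fov_mask, primary$mu, fallback$mu)
  mu_map(as_volume(array(mu, dim(fov_mask)), voxel_spacing(primary$mu)),
         sprintf("%s+%s", primary$provenance, fallback$provenance))
}
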