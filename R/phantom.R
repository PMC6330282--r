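#' @useDynLib petmrac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm median quantile sd approx
NULL

# seven pediatric age brackets; skull thickness and peak density grow with age
.age_classes <- c("0-2m", "2m-1y", "1-2y", "2-4y", "4-8y", "8-11y", "11-14y")
.age_defaults <- data.frame(
  age_class = .age_classes,
  skull_thickness_mm = c(1.5, 2.5, 3.5, 4.0, 5.0, 6.0, 7.0),
  skull_peak_hu = c(400, 600, 800, 1000, 1200, 1350, 1500),
  bone_r2star = c(600, 750, 900, 1050, 1200, 1350, 1500),
  stringsAsFactors = FALSE
)

#' Age classes supported by the phantom generator
#' @return character vector of the seven pediatric age brackets.
#' @export
age_classes <- function() .age_classes

#' Per-tissue signal/density parameters
#'
#' Mean proton-density-weighted signal `S0` (arbitrary units), apparent
#' relaxation rate `r2star` (s^-1), CT density `hu` (HU), and the
#' between-voxel spreads (`r2star_sd`, `hu_sd`) that give each subject a
#' spatially varying tissue texture. Bone entries are placeholders; they are
#' overridden from the age class of the phantom spec. Set `jitter = FALSE`
#' for perfectly homogeneous tissues (useful for closed-form checks).
#'
#' @param jitter logical; include between-voxel spread?
#' @return data.frame keyed by tissue name.
#' @export
tissue_params <- function(jitter = TRUE) {
  tp <- data.frame(
    tissue = c("air", "soft", "bone", "internal_air", "brain", "tumor"),
    label = c(0L, 1L, 2L, 3L, 4L, 5L),
    S0 = c(0.5, 100, 60, 0.5, 100, 100),
    r2star = c(0, 30, 1200, 0, 25, 28),
    hu = c(-1000, 30, 1200, -1000, 40, 38),
    r2star_sd = c(0, 4, 150, 0, 3, 3),
    hu_sd = c(0, 8, 30, 0, 6, 6),
    stringsAsFactors = FALSE
  )
  if (!jitter) tp$r2star_sd <- tp$hu_sd <- rep(0, nrow(tp))
  rownames(tp) <- tp$tissue
  tp
}

#' Specification of one synthetic pediatric head phantom
#'
#' Defines the anatomy (concentric ellipsoidal head: scalp shell, skull layer
#' of configurable mm thickness, brain interior), the spherical tumor, the
#' optional internal air structures, and the signal/noise model. Skull
#' thickness, peak skull density and bone R2* default from the age class but
#' can be overridden. The default grid is a desk-scale 96^3 at 2 mm; the
#' full-resolution protocol grid (192^3 at 1.6 mm) is reachable by argument.
#'
#' @param age_class one of [age_classes()].
#' @param grid_shape voxels per axis (all >= 32).
#' @param voxel_mm isotropic voxel size, mm.
#' @param skull_thickness_mm skull layer thickness; default by age class.
#' @param skull_peak_hu peak skull density in HU; default by age class.
#' @param bone_r2star mean bone R2* in s^-1; default by age class.
#' @param scalp_mm soft-tissue shell thickness outside the skull.
#' @param tumor_center_mm tumor center as mm offsets (axial, AP, LR) from the
#'   head center, or NULL for an automatic right-hemisphere placement.
#' @param tumor_radius_mm tumor radius in mm, or NULL for an automatic radius
#'   scaled to the brain size.
#' @param tumor_to_background_ratio peak tumor-to-background uptake ratio;
#'   must exceed the 1.6 delineation threshold for the tumor to be detectable.
#' @param air_nasal,air_mastoid,air_postop internal air cavity toggles.
#' @param hot_spot add an extratumoral scalp hot spot (covered by the
#'   exclusion mask) to the activity map?
#' @param noise_sigma additive Gaussian echo noise, as a fraction of the
#'   soft-tissue S0.
#' @param activity_sd amplitude of the smooth background-uptake heterogeneity.
#' @param tissue per-tissue parameter table, see [tissue_params()].
#' @param seed integer seed; the same spec and seed reproduce the phantom
#'   bit for bit.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(age_class = "4-8y",
                         grid_shape = c(96, 96, 96),
                         voxel_mm = 2,
                         skull_thickness_mm = NULL,
                         skull_peak_hu = NULL,
                         bone_r2star = NULL,
                         scalp_mm = 5,
                         tumor_center_mm = NULL,
                         tumor_radius_mm = NULL,
                         tumor_to_background_ratio = 2.5,
                         air_nasal = TRUE,
                         air_mastoid = TRUE,
                         air_postop = FALSE,
                         hot_spot = FALSE,
                         noise_sigma = 0.05,
                         activity_sd = 0.05,
                         tissue = tissue_params(),
                         seed = 1L) {
  age_class <- match.arg(age_class, .age_classes)
  row <- .age_defaults[.age_defaults$age_class == age_class, ]
  spec <- list(
    age_class = age_class,
    grid_shape = as.integer(rep_len(grid_shape, 3L)),
    voxel_mm = as.numeric(voxel_mm),
    skull_thickness_mm = skull_thickness_mm %||% row$skull_thickness_mm,
    skull_peak_hu = skull_peak_hu %||% row$skull_peak_hu,
    bone_r2star = bone_r2star %||% row$bone_r2star,
    scalp_mm = scalp_mm,
    tumor_center_mm = tumor_center_mm,
    tumor_radius_mm = tumor_radius_mm,
    tumor_to_background_ratio = tumor_to_background_ratio,
    air_nasal = isTRUE(air_nasal),
    air_mastoid = isTRUE(air_mastoid),
    air_postop = isTRUE(air_postop),
    hot_spot = isTRUE(hot_spot),
    noise_sigma = as.numeric(noise_sigma),
    activity_sd = as.numeric(activity_sd),
    te1_ms = 0.07,
    te2_ms = 2.46,
    tissue = tissue,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 32)) stop("grid_shape must be >= 32 per axis")
  if (spec$voxel_mm <= 0) stop("voxel_mm must be positive")
  if (spec$skull_thickness_mm < spec$voxel_mm)
    stop("skull_thickness_mm must be at least one voxel")
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative")
  geo <- phantom_geometry(spec)
  if (any(geo$brain_semi_mm <= 2))
    stop("head too small: no brain compartment left inside the skull")
  if (geo$tumor_radius_mm <= 0) stop("tumor radius must be positive")
  # analytic containment: tumor sphere inside the brain ellipsoid
  ctr <- geo$tumor_center_mm
  rho <- sqrt(sum((ctr / (geo$brain_semi_mm - geo$tumor_radius_mm))^2))
  if (any(geo$brain_semi_mm - geo$tumor_radius_mm <= 0) || rho > 1)
    stop("tumor does not fit inside the brain compartment; ",
         "reduce tumor_radius_mm or move tumor_center_mm")
  invisible(spec)
}

# derived geometry in mm: ellipsoid semi-axes per compartment, tumor placement
phantom_geometry <- function(spec) {
  half_fov <- spec$grid_shape * spec$voxel_mm / 2
  head_semi <- c(0.80, 0.88, 0.84) * half_fov
  skull_outer <- head_semi - spec$scalp_mm
  skull_inner <- skull_outer - spec$skull_thickness_mm
  brain_semi <- skull_inner
  radius <- spec$tumor_radius_mm %||%
    min(12, max(3 * spec$voxel_mm, round(0.35 * brain_semi[3], 1)))
  center <- spec$tumor_center_mm %||% c(0, 0.15 * brain_semi[2],
                                        0.45 * brain_semi[3])
  list(head_semi_mm = head_semi, skull_outer_mm = skull_outer,
       skull_inner_mm = skull_inner, brain_semi_mm = brain_semi,
       tumor_center_mm = center, tumor_radius_mm = radius)
}

#' @export
print.phantom_spec <- function(x, ...) {
  geo <- phantom_geometry(x)
  cat(sprintf(
    "<phantom_spec> age %s, %s voxels at %.2f mm, skull %.1f mm / %d HU peak\n",
    x$age_class, paste(x$grid_shape, collapse = "x"), x$voxel_mm,
    x$skull_thickness_mm, round(x$skull_peak_hu)))
  cat(sprintf("  tumor r=%.1f mm at (%s) mm, T/B ratio %.2f, noise %.3f, seed %d\n",
              geo$tumor_radius_mm,
              paste(sprintf("%.1f", geo$tumor_center_mm), collapse = ", "),
              x$tumor_to_background_ratio, x$noise_sigma, x$seed))
  invisible(x)
}

# mm coordinate arrays (axial, AP, LR) relative to the grid center
grid_coords_mm <- function(spec) {
  lapply(1:3, function(i) {
    n <- spec$grid_shape[i]
    (seq_len(n) - (n + 1) / 2) * spec$voxel_mm
  })
}

# squared normalized ellipsoid radius for semi-axes a (length 3, mm)
ellipsoid_rho2 <- function(coords, a, center = c(0, 0, 0)) {
  n <- vapply(coords, length, 1L)
  z2 <- ((coords[[1]] - center[1]) / a[1])^2
  y2 <- ((coords[[2]] - center[2]) / a[2])^2
  x2 <- ((coords[[3]] - center[3]) / a[3])^2
  array(rep(z2, times = n[2] * n[3]), n) +
    array(rep(rep(y2, each = n[1]), times = n[3]), n) +
    array(rep(x2, each = n[1] * n[2]), n)
}

# squared Euclidean distance (mm^2) from a point
dist2_mm <- function(coords, center) {
  ellipsoid_rho2(coords, c(1, 1, 1), center)
}

#' Build the tissue label map of a phantom
#'
#' Concentric ellipsoids: background air (0), scalp soft tissue (1), skull
#' bone layer (2), brain (4); optional internal air structures (3: stylized
#' nasal cavity, mastoid cells, post-surgical pocket) and a spherical tumor
#' (5) fully inside the brain. Purely geometric and deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return integer label volume.
#' @export
build_anatomy <- function(spec) {
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  coords <- grid_coords_mm(spec)
  lab <- array(0L, spec$grid_shape)
  lab[ellipsoid_rho2(coords, geo$head_semi_mm) <= 1] <- 1L
  lab[ellipsoid_rho2(coords, geo$skull_outer_mm) <= 1] <- 2L
  lab[ellipsoid_rho2(coords, geo$skull_inner_mm) <= 1] <- 4L
  a <- geo$brain_semi_mm
  carve <- function(mask) {
    # internal air only displaces brain tissue, keeping the skull intact
    lab[mask & lab == 4L] <<- 3L
  }
  if (spec$air_nasal)
    carve(ellipsoid_rho2(coords, c(7, 9, 6),
                         c(-0.40 * a[1], 0.55 * a[2], 0)) <= 1)
  if (spec$air_mastoid) {
    carve(dist2_mm(coords, c(-0.45 * a[1], -0.30 * a[2], 0.62 * a[3])) <= 5^2)
    carve(dist2_mm(coords, c(-0.45 * a[1], -0.30 * a[2], -0.62 * a[3])) <= 5^2)
  }
  if (spec$air_postop)
    carve(dist2_mm(coords, c(0.30 * a[1], -0.20 * a[2], -0.40 * a[3])) <= 6^2)
  tum <- dist2_mm(coords, geo$tumor_center_mm) <= geo$tumor_radius_mm^2
  if (any(lab[tum] != 4L))
    stop("tumor overlaps non-brain tissue; adjust placement or cavity toggles")
  lab[tum] <- 5L
  as_volume(lab, spec$voxel_mm)
}

# monotone R2* -> HU relation used to give bone a density texture tied to its
# relaxation rate (the physical basis of UTE bone mapping); logistic in R2*
# with midpoint at the age-class mean rate and upper level twice the peak HU
bone_hu_from_r2star <- function(r2, spec, L = 200, k = 0.004) {
  U <- 2 * spec$skull_peak_hu - L
  L + (U - L) / (1 + exp(-k * (r2 - spec$bone_r2star)))
}

#' Synthesize CT and dual-echo UTE signals for a label map
#'
#' Each tissue draws per-voxel (R2*, HU) around its configured mean; bone HU
#' is tied to bone R2* through a monotone logistic relation so that denser
#' bone decays faster, which is the contrast the segmentation-based AC method
#' calibrates against. Echo signals follow mono-exponential decay
#' `S(TE) = S0 exp(-TE * R2*)` with additive Gaussian noise of sd
#' `noise_sigma * S0_soft`. Tissue texture is drawn from the subject seed;
#' echo noise from `noise_seed`, so repeated examinations of one subject
#' share anatomy and tissue texture but not noise.
#'
#' @param labels label volume from [build_anatomy()].
#' @param spec the [phantom_spec()].
#' @param noise_seed seed for the additive echo noise (defaults to a stream
#'   derived from the spec seed).
#' @return list with volumes `ct_hu`, `ute1`, `ute2`, `r2star_true`.
#' @export
synthesize_signals <- function(labels, spec,
                               noise_seed = substream_seed(spec$seed, "echo-noise")) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative")
  tp <- spec$tissue
  dims <- dim(labels)
  r2 <- array(0, dims); hu <- array(-1000, dims); s0 <- array(0.5, dims)
  with_seed(substream_seed(spec$seed, "tissue"), {
    for (i in seq_len(nrow(tp))) {
      m <- labels == tp$label[i]
      n <- sum(m)
      if (n == 0) next
      s0[m] <- tp$S0[i]
      if (tp$tissue[i] == "bone") {
        rs <- spec$bone_r2star +
          if (tp$r2star_sd[i] > 0) rnorm(n, 0, tp$r2star_sd[i]) else 0
        rs <- pmin(pmax(rs, 300), 3000)
        r2[m] <- rs
        hu[m] <- bone_hu_from_r2star(rs, spec) +
          if (tp$hu_sd[i] > 0) rnorm(n, 0, tp$hu_sd[i]) else 0
      } else {
        r2[m] <- pmax(tp$r2star[i] +
          if (tp$r2star_sd[i] > 0) rnorm(n, 0, tp$r2star_sd[i]) else 0, 0)
        hu[m] <- tp$hu[i] +
          if (tp$hu_sd[i] > 0) rnorm(n, 0, tp$hu_sd[i]) else 0
      }
    }
  })
  hu <- pmin(pmax(hu, -1000), 3000)
  s1 <- s0 * exp(-spec$te1_ms / 1000 * r2)
  s2 <- s0 * exp(-spec$te2_ms / 1000 * r2)
  if (spec$noise_sigma > 0) {
    sd_n <- spec$noise_sigma * tp["soft", "S0"]
    with_seed(noise_seed, {
      s1 <- s1 + rnorm(length(s1), 0, sd_n)
      s2 <- s2 + rnorm(length(s2), 0, sd_n)
    })
  }
  sp <- voxel_spacing(labels)
  list(ct_hu = as_volume(array(hu, dims), sp),
       ute1 = as_volume(array(s1, dims), sp),
       ute2 = as_volume(array(s2, dims), sp),
       r2star_true = as_volume(array(r2, dims), sp))
}

# smooth random field in [-inf,inf]: coarse Gaussian grid, trilinear upsample
smooth_field <- function(dims, n_knots = 5, sd = 1) {
  coarse <- array(rnorm(n_knots^3, 0, sd), rep(n_knots, 3))
  up1 <- function(a, n_out) {
    # linear interpolation along the first axis, then rotate axes
    d <- dim(a)
    xin <- seq(0, 1, length.out = d[1])
    xout <- seq(0, 1, length.out = n_out)
    flat <- matrix(a, d[1], prod(d[-1]))
    out <- apply(flat, 2, function(col) approx(xin, col, xout)$y)
    aperm(array(out, c(n_out, d[2], d[3])), c(2, 3, 1))
  }
  f <- coarse
  for (i in 1:3) f <- up1(f, dims[i])
  f
}

#' Synthesize the FET-like activity map, background ROI and exclusion mask
#'
#' Brain background uptake is 1 (arbitrary SUV-like units) with mild smooth
#' heterogeneity; the tumor peaks at `ratio` times background with a
#' parabolic internal gradient; scalp and bone take low uptake. The
#' background ROI is a box in the hemisphere mirrored from the tumor,
#' restricted to brain tissue. An optional extratumoral scalp hot spot is
#' exactly covered by the exclusion mask.
#'
#' @inheritParams synthesize_signals
#' @param noise_seed seed for the heterogeneity field.
#' @return list with `activity`, `background_roi`, `exclusion_mask`, and
#'   `flags` (e.g. `"sub-threshold tumor"`).
#' @export
synthesize_activity <- function(labels, spec,
                                noise_seed = substream_seed(spec$seed, "activity")) {
  ratio <- spec$tumor_to_background_ratio
  flags <- character(0)
  if (ratio <= 1.6) {
    warning("tumor_to_background_ratio <= 1.6: tumor is below the ",
            "delineation threshold by design")
    flags <- c(flags, "sub-threshold tumor")
  }
  geo <- phantom_geometry(spec)
  coords <- grid_coords_mm(spec)
  dims <- dim(labels)
  act <- array(0, dims)
  act[labels == 1L] <- 0.25
  act[labels == 2L] <- 0.05
  act[labels == 4L] <- 1
  d2 <- dist2_mm(coords, geo$tumor_center_mm)
  tum <- labels == 5L
  prof <- 1 - 0.3 * d2[tum] / geo$tumor_radius_mm^2
  # normalized so the hottest voxel sits exactly at ratio * background
  act[tum] <- ratio * prof / max(prof)
  if (spec$activity_sd > 0) {
    f <- with_seed(noise_seed, smooth_field(dims, 5, spec$activity_sd))
    inside <- labels %in% c(4L, 5L)
    act[inside] <- act[inside] * (1 + f[inside])
  }
  excl <- array(FALSE, dims)
  if (spec$hot_spot) {
    hs_center <- c(0.2 * geo$head_semi_mm[1], 0, 0) +
      c(0, (geo$skull_outer_mm[2] + geo$head_semi_mm[2]) / 2, 0)
    hs <- dist2_mm(coords, hs_center) <= 4^2 & labels == 1L
    act[hs] <- 2.2
    excl[hs] <- TRUE
  }
  act[act < 0] <- 0
  # mirrored background ROI: reflect the tumor center across the midsagittal
  # plane (left-right axis), keep brain voxels only
  roi_center <- geo$tumor_center_mm * c(1, 1, -1)
  half <- 8
  roi <- abs(outer(rep(1, dims[1] * dims[2]),
                   coords[[3]] - roi_center[3])) <= half
  roi <- array(roi, dims)
  z_ok <- abs(coords[[1]] - roi_center[1]) <= half
  y_ok <- abs(coords[[2]] - roi_center[2]) <= half
  roi <- roi & array(rep(z_ok, times = dims[2] * dims[3]), dims) &
    array(rep(rep(y_ok, each = dims[1]), times = dims[3]), dims)
  roi <- roi & labels == 4L
  if (!any(roi)) stop("background ROI is empty; tumor placement leaves no ",
                      "mirrored brain tissue")
  if (any(roi & tum)) stop("background ROI overlaps the tumor")
  sp <- voxel_spacing(labels)
  list(activity = as_volume(act, sp),
       background_roi = as_volume(roi, sp),
       exclusion_mask = as_volume(excl, sp),
       flags = flags)
}

#' Build one complete phantom case
#'
#' Runs [build_anatomy()], [synthesize_signals()] and
#' [synthesize_activity()] and assembles the result. Repeated examinations
#' (`exam_index > 1`) reuse the subject's anatomy and tissue texture but draw
#' fresh echo noise and uptake heterogeneity, emulating a follow-up scan.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier.
#' @param exam_index examination number for this subject (1 = baseline).
#' @return an object of class `phantom_case`.
#' @export
build_phantom <- function(spec, subject_id = "S01", exam_index = 1L) {
  labels <- build_anatomy(spec)
  exam_seed <- substream_seed(spec$seed, "exam", exam_index)
  sig <- synthesize_signals(labels, spec, noise_seed = exam_seed)
  act <- synthesize_activity(labels, spec,
                             noise_seed = substream_seed(exam_seed, "activity"))
  case <- list(labels = labels, ct_hu = sig$ct_hu,
               ute1 = sig$ute1, ute2 = sig$ute2,
               r2star_true = sig$r2star_true,
               activity = act$activity,
               background_roi = act$background_roi,
               exclusion_mask = act$exclusion_mask,
               flags = act$flags,
               te1_ms = spec$te1_ms, te2_ms = spec$te2_ms,
               subject_id = subject_id, exam_index = as.integer(exam_index),
               seed = spec$seed, spec = spec)
  class(case) <- "phantom_case"
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s exam %d: %s voxels, age %s, seed %d\n",
              x$subject_id, x$exam_index,
              paste(dim(x$labels), collapse = "x"),
              x$spec$age_class, x$seed))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
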