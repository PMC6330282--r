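#' Fit the bone R2*-to-HU sigmoid
#'
#' The continuous-bone AC method maps the apparent relaxation rate of
#' candidate bone voxels to CT density through a four-parameter logistic
#' curve `HU(r) = L + (U - L) / (1 + exp(-k (r - r0)))`, fitted by nonlinear
#' least squares on (R2*, HU) pairs pooled over the calibration patients.
#' A sigmoid (rather than a polynomial) keeps the mapping bounded for the
#' thin, low-density skulls of young children.
#'
#' @param r2 vector of bone-voxel R2* values, s^-1.
#' @param hu matching CT values, HU.
#' @param min_samples refuse to fit below this many samples.
#' @return object of class `bone_sigmoid` with elements `L`, `U`, `r0`, `k`,
#'   `rmse`, `n`, `converged`.
#' @export
fit_bone_sigmoid <- function(r2, hu, min_samples = 100) {
  ok <- is.finite(r2) & is.finite(hu)
  r2 <- r2[ok]; hu <- hu[ok]
  if (length(r2) < min_samples)
    stop(sprintf("only %d bone samples; need at least %d to calibrate",
                 length(r2), min_samples))
  start <- list(L = 0,
                U = unname(quantile(hu, 0.95)),
                r0 = median(r2),
                k = 1 / max(stats::IQR(r2), 1e-6))
  fit <- minpack.lm::nlsLM(
    hu ~ L + (U - L) / (1 + exp(-k * (r2 - r0))),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- as.list(stats::coef(fit))
  if (p$U < p$L) {  # reparameterize to the increasing branch
    tmp <- p$L; p$L <- p$U; p$U <- tmp; p$k <- -p$k
  }
  res <- structure(list(L = p$L, U = p$U, r0 = p$r0, k = p$k,
                        rmse = sqrt(mean(stats::residuals(fit)^2)),
                        n = length(r2),
                        converged = fit$convInfo$isConv %||% TRUE),
                   class = "bone_sigmoid")
  if (!isTRUE(res$converged))
    warning(sprintf("sigmoid fit did not converge (rmse %.1f HU, n=%d)",
                    res$rmse, res$n))
  if (!(res$U > res$L) || res$k <= 0)
    warning("degenerate sigmoid fit: U <= L or non-positive steepness")
  res
}

#' @export
print.bone_sigmoid <- function(x, ...) {
  cat(sprintf(
    "<bone_sigmoid> HU(r) = %.1f + (%.1f - %.1f)/(1+exp(-%.4g (r - %.1f)))\n",
    x$L, x$U, x$L, x$k, x$r0))
  cat(sprintf("  fitted on %d bone voxels, rmse %.1f HU\n", x$n, x$rmse))
  invisible(x)
}

#' Evaluate the bone sigmoid
#' @param object a `bone_sigmoid`.
#' @param r2 R2* values, s^-1 (vector or volume).
#' @param ... unused.
#' @return predicted HU, bounded in `[L, U]`.
#' @export
predict.bone_sigmoid <- function(object, r2, ...) {
  object$L + (object$U - object$L) / (1 + exp(-object$k * (r2 - object$r0)))
}

#' Cross-validated calibration of the bone sigmoid
#'
#' Splits subjects into folds and fits one sigmoid per fold on the training
#' cases only (the fold's own cases are excluded), so that no patient is
#' scored with a mapping calibrated on itself. Bone samples are taken where
#' the co-registered CT exceeds `bone_hu_threshold`; R2* is estimated from
#' the case's own echo pair.
#'
#' @param cases list of `phantom_case` objects with CT available.
#' @param folds number of folds (default 2).
#' @param seed fold-shuffle seed.
#' @param bone_hu_threshold HU above which a voxel counts as bone.
#' @param max_samples per-fold cap on pooled samples (subsampled
#'   deterministically for speed).
#' @return object of class `resolute_calibration`: per-fold `bone_sigmoid`
#'   fits plus the subject-to-fold map.
#' @export
calibrate_bone_sigmoid <- function(cases, folds = 2, seed = 1L,
                                   bone_hu_threshold = 300,
                                   max_samples = 20000) {
  if (length(cases) < 2) stop("need at least 2 cases to cross-validate")
  subjects <- vapply(cases, function(cs) cs$subject_id, "")
  split <- kfold_split(subjects, folds, seed = seed)
  samples <- lapply(cases, function(cs) {
    sm <- smoothed_echoes(cs)
    r2 <- compute_r2star(sm$ute1, sm$ute2, cs$te1_ms, cs$te2_ms)
    # censored estimates (floored at 0 or clamped at the ceiling) carry no
    # information about the R2*-HU relation and would bias the fit
    m <- cs$ct_hu > bone_hu_threshold & r2 > 0 & r2 < max(r2)
    list(r2 = as.numeric(r2[m]), hu = as.numeric(cs$ct_hu[m]))
  })
  fits <- lapply(seq_len(attr(split, "k")), function(f) {
    train <- which(fold_of(split, subjects) != f)
    if (!length(train)) stop("fold ", f, " has no training cases")
    r2 <- unlist(lapply(samples[train], `[[`, "r2"))
    hu <- unlist(lapply(samples[train], `[[`, "hu"))
    if (length(r2) > max_samples) {
      idx <- with_seed(substream_seed(seed, "subsample", f),
                       sample.int(length(r2), max_samples))
      r2 <- r2[idx]; hu <- hu[idx]
    }
    fit_bone_sigmoid(r2, hu)
  })
  structure(list(fits = fits, split = split,
                 bone_hu_threshold = bone_hu_threshold),
            class = "resolute_calibration")
}

#' @export
print.resolute_calibration <- function(x, ...) {
  cat(sprintf("<resolute_calibration> %d folds over %d subjects\n",
              length(x$fits), length(x$split)))
  for (i in seq_along(x$fits))
    cat(sprintf("  fold %d: U=%.0f HU, r0=%.0f s^-1, k=%.4g, rmse=%.1f\n", i,
                x$fits[[i]]$U, x$fits[[i]]$r0, x$fits[[i]]$k, x$fits[[i]]$rmse))
  invisible(x)
}

#' Sigmoid parameters applicable to a given case
#'
#' Returns the fold fit that was calibrated without this case's subject.
#'
#' @param calib a `resolute_calibration`.
#' @param case a `phantom_case`.
#' @return a `bone_sigmoid`.
#' @export
params_for_case <- function(calib, case) {
  calib$fits[[fold_of(calib$split, case$subject_id)]]
}

# separable 3-tap (0.25, 0.5, 0.25) smoothing with replicated edges; one pass
# per axis. The segmentation AC path smooths the echoes before taking signal
# ratios: the two-point R2* estimate is useless at raw-voxel SNR in bone.
smooth3 <- function(x) {
  d <- dim(x)
  for (ax in 1:3) {
    idx <- lapply(d, seq_len)
    lo <- idx; hi <- idx
    n <- d[ax]
    lo[[ax]] <- c(1, seq_len(n - 1))
    hi[[ax]] <- c(seq_len(n - 1) + 1, n)
    x <- 0.5 * x + 0.25 * do.call(`[`, c(list(x), lo, list(drop = FALSE))) +
      0.25 * do.call(`[`, c(list(x), hi, list(drop = FALSE)))
  }
  x
}

# echoes smoothed for segmentation use, spacing preserved
smoothed_echoes <- function(case) {
  sp <- voxel_spacing(case$ute1)
  list(ute1 = as_volume(smooth3(case$ute1), sp),
       ute2 = as_volume(smooth3(case$ute2), sp))
}

# binary 6-neighbourhood erosion, borders treated as background
erode_mask <- function(mask, iterations = 1) {
  d <- dim(mask)
  shift <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
    else { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (i in seq_len(iterations)) {
    mask <- mask & shift(mask, 1, 1) & shift(mask, 1, -1) &
      shift(mask, 2, 1) & shift(mask, 2, -1) &
      shift(mask, 3, 1) & shift(mask, 3, -1)
  }
  mask
}

# UTE-driven air/head segmentation shared by the segmentation AC methods:
# air where both echoes sit at the noise floor (default 5% of the median
# soft-tissue signal, itself estimated from the first echo)
ute_air_mask <- function(s1, s2, floor_frac = 0.05) {
  hi <- quantile(s1, 0.99)
  # degenerate volume with no tissue signal above the air level: the upper
  # tail is not separated from the bulk, so everything is air
  if (hi <= 5 * max(quantile(s1, 0.5), 1e-12))
    return(array(TRUE, dim(s1)))
  soft_ref <- median(s1[s1 > 0.2 * hi])
  floor <- floor_frac * soft_ref
  s1 <= floor & s2 <= floor
}

#' Segmentation-based continuous-bone attenuation map
#'
#' Classifies UTE voxels into air (both echoes at the signal floor),
#' candidate bone (R2* above a threshold, restricted to an outer-head shell
#' where the skull lives), and soft tissue; assigns a pseudo-CT of -1000 HU
#' to air, a fixed soft-tissue HU, and the calibrated sigmoid of R2* to
#' bone; converts to attenuation with [hu_to_mu()]. The geometric shell
#' replaces the template-space regional masks used clinically, which phantom
#' data does not need.
#'
#' @param case a `phantom_case`.
#' @param params a [fit_bone_sigmoid()] result from a fold not containing
#'   this case (see [params_for_case()]).
#' @param soft_hu HU assigned to soft tissue.
#' @param shell_depth_mm depth of the outer-head shell in which bone is
#'   allowed.
#' @param bone_r2_threshold R2* above which a shell voxel is candidate bone.
#'   The default 200 s^-1 sits between the soft-tissue R2* range (tens of
#'   s^-1, modestly inflated by the echo smoothing near interfaces) and the
#'   calibrated bone range.
#' @param floor_frac air signal floor as a fraction of median soft signal.
#' @return a [mu_map()] with provenance `"RESOLUTE"`, carrying the pseudo-CT
#'   and the 3-class segmentation.
#' @export
build_resolute_map <- function(case, params, soft_hu = 30,
                               shell_depth_mm = 15,
                               bone_r2_threshold = 200,
                               floor_frac = 0.05) {
  stopifnot(inherits(params, "bone_sigmoid"))
  if (!(params$U > params$L) || params$k <= 0 || !is.finite(params$r0))
    stop("invalid sigmoid parameters")
  thr <- bone_r2_threshold
  sm <- smoothed_echoes(case)
  r2 <- compute_r2star(sm$ute1, sm$ute2, case$te1_ms, case$te2_ms)
  air <- ute_air_mask(sm$ute1, sm$ute2, floor_frac)
  head <- !air
  it <- max(1L, round(shell_depth_mm / voxel_spacing(case$ute1)[1]))
  shell <- head & !erode_mask(head, it)
  bone <- shell & r2 > thr
  pseudo <- array(soft_hu, dim(r2))
  pseudo[air] <- -1000
  pseudo[bone] <- predict(params, r2[bone])
  cls <- array(1L, dim(r2)); cls[air] <- 0L; cls[bone] <- 2L
  sp <- voxel_spacing(case$ute1)
  m <- hu_to_mu(as_volume(pseudo, sp), provenance = "RESOLUTE")
  m$classes <- as_volume(cls, sp)
  m
}

#' Bone-less two-class attenuation map (DIXON-like baseline)
#'
#' Air/soft segmentation only: every non-air voxel, bone included, gets the
#' soft-tissue attenuation. This emulates the vendor fat/water map whose
#' missing bone is the known failure mode the continuous-bone methods fix.
#'
#' @inheritParams build_resolute_map
#' @return a [mu_map()] with provenance `"NOBONE"`.
#' @export
build_nobone_map <- function(case, soft_hu = 30, floor_frac = 0.05) {
  sm <- smoothed_echoes(case)
  air <- ute_air_mask(sm$ute1, sm$ute2, floor_frac)
  pseudo <- array(soft_hu, dim(case$ute1))
  pseudo[air] <- -1000
  cls <- array(1L, dim(case$ute1)); cls[air] <- 0L
  sp <- voxel_spacing(case$ute1)
  m <- hu_to_mu(as_volume(pseudo, sp), provenance = "NOBONE")
  m$classes <- as_volume(cls, sp)
  m
}
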