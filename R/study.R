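#' Configuration of an end-to-end phantom study
#'
#' Describes the phantom battery (subjects, repeated examinations, ages,
#' grid), the AC methods to compare, the cross-validation folds, the PET
#' simulation, and the output directory. The desk scale (default) runs a
#' 32^3 battery sized for a CPU; `scale = "full"` switches to the
#' protocol-resolution geometry and published training settings.
#'
#' @param n_subjects number of subjects.
#' @param n_repeat how many of the subjects get a second examination.
#' @param age_classes age brackets cycled over subjects. The desk default
#'   uses the four oldest brackets: at desk voxel size the thin infant skull
#'   is below one voxel and cannot be represented.
#' @param grid_shape,voxel_mm phantom grid.
#' @param noise_sigma echo noise level passed to the phantoms.
#' @param methods AC methods to evaluate (subset of ct, resolute, deepute,
#'   nobone; ct is always computed as reference).
#' @param resolute_folds folds for the sigmoid calibration (clinical: 2).
#' @param deepute_folds folds for network training (published protocol: 4;
#'   desk default 2).
#' @param net a [network_spec()] for DeepUTE.
#' @param train a [train_config()] for DeepUTE.
#' @param angles_deg PET projection angles.
#' @param counts expected counts per volume for Poisson sinogram noise
#'   (NULL = noiseless).
#' @param reduced_fov if TRUE, the reference CT covers only the central 75%
#'   of slices and every map is completed outside that field of view with
#'   the bone-less map, as done clinically when CT coverage is short.
#' @param out_dir where [run_study()] writes its report (NULL = nowhere).
#' @param seed global seed; all stage seeds derive from it.
#' @param scale `"desk"` or `"full"`.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 8, n_repeat = 2,
                         age_classes = c("2-4y", "4-8y", "8-11y", "11-14y"),
                         grid_shape = c(32, 32, 32), voxel_mm = 2.5,
                         noise_sigma = 0.05,
                         methods = c("resolute", "deepute", "nobone"),
                         resolute_folds = 2, deepute_folds = 2,
                         net = network_spec(depth = 2, base_channels = 4),
                         train = deepute_desk_config(),
                         angles_deg = 0:179, counts = NULL,
                         reduced_fov = FALSE,
                         out_dir = NULL, seed = 1L,
                         scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    grid_shape <- c(192, 192, 192); voxel_mm <- 1.6
    age_classes <- .age_classes
    net <- network_spec(depth = 4, base_channels = 16)
    train <- train_config()
    deepute_folds <- 4
  }
  methods <- match.arg(methods, c("ct", "resolute", "deepute", "nobone"),
                       several.ok = TRUE)
  methods <- setdiff(unique(methods), "ct")
  stopifnot(n_subjects >= 2, n_repeat >= 0, n_repeat <= n_subjects)
  structure(list(n_subjects = n_subjects, n_repeat = n_repeat,
                 age_classes = age_classes, grid_shape = grid_shape,
                 voxel_mm = voxel_mm, noise_sigma = noise_sigma,
                 methods = methods, resolute_folds = resolute_folds,
                 deepute_folds = deepute_folds, net = net, train = train,
                 angles_deg = angles_deg, counts = counts,
                 reduced_fov = reduced_fov,
                 out_dir = out_dir, seed = as.integer(seed), scale = scale),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %s scale: %d subjects (+%d repeats), %s at %.2g mm, methods %s, seed %d\n",
    x$scale, x$n_subjects, x$n_repeat, paste(x$grid_shape, collapse = "x"),
    x$voxel_mm, paste(x$methods, collapse = "/"), x$seed))
  invisible(x)
}

# build the phantom battery described by a study config
build_battery <- function(cfg) {
  cases <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", i)
    spec <- phantom_spec(
      age_class = cfg$age_classes[(i - 1) %% length(cfg$age_classes) + 1],
      grid_shape = cfg$grid_shape, voxel_mm = cfg$voxel_mm,
      noise_sigma = cfg$noise_sigma,
      seed = substream_seed(cfg$seed, "phantom", i))
    n_exams <- 1L + (i <= cfg$n_repeat)
    for (e in seq_len(n_exams))
      cases[[length(cases) + 1]] <- build_phantom(spec, sid, e)
  }
  cases
}

# central-slices CT field-of-view mask for the reduced-FOV variant
ct_fov_mask <- function(dims, frac = 0.75) {
  nz <- dims[1]
  keep <- round(nz * (1 - frac) / 2)
  mask <- array(FALSE, dims)
  mask[(keep + 1):(nz - keep), , ] <- TRUE
  mask
}

# attenuation maps for one case under every requested method
build_maps <- function(case, cfg, calib, cv) {
  maps <- list(ct = hu_to_mu(case$ct_hu))
  maps$ct$classes <- classify_tissue(case$ct_hu)
  nobone <- build_nobone_map(case)
  if ("nobone" %in% cfg$methods || cfg$reduced_fov) maps$nobone <- nobone
  if ("resolute" %in% cfg$methods)
    maps$resolute <- build_resolute_map(case, params_for_case(calib, case))
  if ("deepute" %in% cfg$methods)
    maps$deepute <- deepute_map(case, model_for_case(cv, case))
  if (cfg$reduced_fov) {
    fov <- ct_fov_mask(dim(case$ct_hu))
    for (nm in setdiff(names(maps), "nobone")) {
      st <- stitch_fov(maps[[nm]], nobone, fov)
      # tissue classes are scored on the native (unstitched) map
      st$classes <- maps[[nm]]$classes
      maps[[nm]] <- st
    }
  }
  maps[unique(c("ct", cfg$methods))]
}

#' Run the end-to-end attenuation-correction study
#'
#' Generates the phantom battery, calibrates the bone sigmoid and trains the
#' pseudo-CT network with subject-level cross-validation, builds every
#' attenuation map, simulates and reconstructs PET per method, computes the
#' clinical metrics, filters the evaluable cohort (reference BTV > 1 mL),
#' and summarizes agreement per method and metric. Deterministic given the
#' config seed.
#'
#' @param cfg a [study_config()].
#' @param verbose print stage progress.
#' @return object of class `ac_study` with elements `metrics` (per exam and
#'   method), `agreement` (per method and metric), `bland_altman` (per-exam
#'   flags), `segmentation` (per-exam tissue-class and tumor Jaccard), and
#'   `config`. If `cfg$out_dir` is set, CSV tables and a JSON config sidecar
#'   are written there.
#' @export
run_study <- function(cfg = study_config(), verbose = interactive()) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  say("building %d-subject battery ...", cfg$n_subjects)
  cases <- stage("phantom", build_battery(cfg))

  calib <- NULL
  if ("resolute" %in% cfg$methods) {
    say("calibrating bone sigmoid (%d-fold) ...", cfg$resolute_folds)
    calib <- stage("resolute", calibrate_bone_sigmoid(
      cases, folds = cfg$resolute_folds,
      seed = substream_seed(cfg$seed, "resolute-folds")))
  }
  cv <- NULL
  if ("deepute" %in% cfg$methods) {
    say("training pseudo-CT network (%d-fold) ...", cfg$deepute_folds)
    cfg_t <- cfg$train
    cfg_t$seed <- substream_seed(cfg$seed, "deepute-train")
    cv <- stage("deepute", deepute_crossval(
      cases, k = cfg$deepute_folds, net = cfg$net, cfg = cfg_t,
      seed = substream_seed(cfg$seed, "deepute-folds")))
  }

  metrics <- list(); seg <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    say("case %d/%d: maps + PET + metrics ...", ci, length(cases))
    maps <- stage("mumaps", build_maps(case, cfg, calib, cv))
    sino <- stage("petsim", project_emission(
      case$activity, maps$ct, cfg$angles_deg, counts = cfg$counts,
      seed = substream_seed(cfg$seed, "counts", ci)))
    truth_cls <- classify_tissue(case$ct_hu)
    ct_mask <- NULL
    for (nm in names(maps)) {
      rec <- stage("petsim", reconstruct_with_ac(sino, maps[[nm]]))
      B <- background_mean(rec, case$background_roi)
      delin <- delineate_btv(rec, B, case$exclusion_mask)
      metrics[[length(metrics) + 1]] <- tumor_metrics(
        rec, delin, B, ac_method = toupper(nm),
        subject_id = case$subject_id, exam_index = case$exam_index)
      if (nm == "ct") ct_mask <- delin$tumor_mask
      cls <- maps[[nm]]$classes
      seg[[length(seg) + 1]] <- data.frame(
        subject_id = case$subject_id, exam_index = case$exam_index,
        ac_method = toupper(nm),
        jaccard_air = if (!is.null(cls)) jaccard(cls == 0, truth_cls == 0) else NA_real_,
        jaccard_soft = if (!is.null(cls)) jaccard(cls == 1, truth_cls == 1) else NA_real_,
        jaccard_bone = if (!is.null(cls)) jaccard(cls == 2, truth_cls == 2) else NA_real_,
        jaccard_tumor = if (!is.null(ct_mask)) jaccard(delin$tumor_mask, ct_mask) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  seg <- do.call(rbind, seg)

  say("cohort filter + agreement ...")
  metrics <- stage("clinical", cohort_filter(metrics, ref_method = "CT"))
  ba <- stage("agreement", bland_altman_table(metrics, ref_method = "CT"))
  agr <- list()
  ref <- metrics[metrics$ac_method == "CT", ]
  key <- function(d) paste(d$subject_id, d$exam_index)
  for (mth in toupper(cfg$methods)) {
    te <- metrics[metrics$ac_method == mth & !metrics$flagged, ]
    r <- ref[match(key(te), key(ref)), ]
    for (mname in c("tmean_b", "tmax_b", "btv_ml")) {
      s <- stage("agreement", log_agreement(te[[mname]], r[[mname]],
                                            te$subject_id))
      agr[[length(agr) + 1]] <- cbind(
        data.frame(ac_method = mth, metric = mname, stringsAsFactors = FALSE),
        as.data.frame(s))
    }
  }
  agr <- do.call(rbind, agr)

  res <- structure(list(metrics = metrics, agreement = agr,
                        bland_altman = ba, segmentation = seg, config = cfg),
                   class = "ac_study")
  if (!is.null(cfg$out_dir)) write_study(res, cfg$out_dir)
  res
}

# CSV report bundle; fixed numeric formatting keeps reruns byte-identical
write_study <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  wr(res$metrics, "metrics.csv")
  wr(res$agreement, "agreement.csv")
  wr(res$bland_altman, "bland_altman.csv")
  wr(res$segmentation, "segmentation.csv")
  cfg <- res$config
  cfg$net <- unclass(cfg$net); cfg$train <- unclass(cfg$train)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.ac_study <- function(x, ...) {
  cat(sprintf("<ac_study> %d evaluable examinations, methods: %s\n",
              nrow(x$metrics[x$metrics$ac_method == "CT", ]),
              paste(setdiff(unique(x$metrics$ac_method), "CT"),
                    collapse = ", ")))
  cat("\nAgreement with CT-AC (relative % difference):\n")
  a <- x$agreement
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-8s %-8s mean %+6.1f%%  CI [%+.1f%%, %+.1f%%]  LoA [%+.1f%%, %+.1f%%]  p=%.2g\n",
                a$ac_method[i], a$metric[i], a$mean_pct[i],
                a$ci_lo_pct[i], a$ci_hi_pct[i],
                a$loa_lo_pct[i], a$loa_hi_pct[i], a$p_value[i]))
  flags <- stats::aggregate(outside ~ ac_method, x$bland_altman, sum)
  cat("\nExaminations outside acceptance limits:\n")
  for (i in seq_len(nrow(flags)))
    cat(sprintf("  %-8s %d\n", flags$ac_method[i], flags$outside[i]))
  invisible(x)
}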