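#' Mean background uptake
#'
#' Arithmetic mean of the activity over the background ROI (healthy-appearing
#' tissue in the hemisphere contralateral to the tumor).
#'
#' @param activity activity volume.
#' @param roi logical volume, non-empty.
#' @return scalar background mean B.
#' @export
background_mean <- function(activity, roi) {
  check_same_grid(activity, roi, "activity and ROI")
  if (!any(roi)) stop("background ROI is empty")
  mean(activity[roi])
}

#' Biological tumor volume by threshold auto-contour
#'
#' Tumor tissue is every voxel with uptake strictly above `threshold * B`
#' (the clinical auto-contour uses 1.6 x background), minus the exclusion
#' mask that removes extratumoral structures with physiologically high
#' uptake (vessels, pineal body, skin).
#'
#' @param activity activity volume.
#' @param B background mean (> 0), from [background_mean()].
#' @param exclusion_mask logical volume of voxels removed from evaluation
#'   (NULL for none).
#' @param threshold threshold multiplier on B.
#' @return object of class `delineation`: `tumor_mask`, `btv_ml`,
#'   `threshold_used` (absolute activity cut), `background_mean`.
#' @export
delineate_btv <- function(activity, B, exclusion_mask = NULL,
                          threshold = 1.6) {
  if (!is.finite(B) || B <= 0) stop("background mean must be positive")
  cut <- threshold * B
  mask <- activity > cut            # strictly above
  if (!is.null(exclusion_mask)) {
    check_same_grid(activity, exclusion_mask, "activity and exclusion mask")
    mask <- mask & !exclusion_mask
  }
  structure(list(tumor_mask = as_volume(mask, voxel_spacing(activity)),
                 btv_ml = sum(mask) * voxel_volume_ml(activity),
                 threshold_used = cut,
                 background_mean = B),
            class = "delineation")
}

#' @export
print.delineation <- function(x, ...) {
  cat(sprintf("<delineation> BTV %.3f mL (%d voxels > %.3f)\n",
              x$btv_ml, sum(x$tumor_mask), x$threshold_used))
  invisible(x)
}

#' Clinical uptake metrics for one examination and AC method
#'
#' T_MEAN and T_MAX over the tumor mask and their ratios to the background
#' mean — the semi-quantitative measures used diagnostically. An empty
#' tumor mask yields a flagged record with NA metrics (the tumor was missed
#' by this AC method); flagged records are excluded from ratio summaries.
#'
#' @param activity activity volume.
#' @param delin a [delineate_btv()] result.
#' @param B background mean.
#' @param ac_method provenance tag of the AC method.
#' @param subject_id,exam_index identifiers.
#' @return one-row data.frame with class `metrics_record` columns: B, t_mean,
#'   t_max, tmean_b, tmax_b, btv_ml, flagged.
#' @export
tumor_metrics <- function(activity, delin, B, ac_method = "CT",
                          subject_id = "S01", exam_index = 1L) {
  stopifnot(inherits(delin, "delineation"))
  m <- delin$tumor_mask
  if (!any(m)) {
    return(data.frame(subject_id = subject_id, exam_index = exam_index,
                      ac_method = ac_method, B = B,
                      t_mean = NA_real_, t_max = NA_real_,
                      tmean_b = NA_real_, tmax_b = NA_real_,
                      btv_ml = 0, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  vals <- activity[m]
  data.frame(subject_id = subject_id, exam_index = exam_index,
             ac_method = ac_method, B = B,
             t_mean = mean(vals), t_max = max(vals),
             tmean_b = mean(vals) / B, tmax_b = max(vals) / B,
             btv_ml = delin$btv_ml, flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Jaccard similarity of two masks
#'
#' `|A intersect B| / |A union B|`; 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical volumes on a shared grid.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b, "masks")
  u <- sum(mask_a | mask_b)
  if (u == 0) return(1)
  sum(mask_a & mask_b) / u
}

#' Clinical acceptance rules
#'
#' A metric difference is acceptable when it is small in absolute terms OR
#' small relative to the reference — large absolute changes are tolerable in
#' large or very active tumors. Defaults are the clinical limits:
#' T_MEAN/B +-0.05 or 5%, T_MAX/B +-0.1 or 5%, BTV +-2 mL or 10%.
#'
#' @return data.frame with columns metric, abs_limit, rel_limit_pct.
#' @export
acceptance_rules <- function() {
  data.frame(metric = c("tmean_b", "tmax_b", "btv_ml"),
             abs_limit = c(0.05, 0.1, 2),
             rel_limit_pct = c(5, 5, 10),
             stringsAsFactors = FALSE)
}

#' Check one examination's metrics against the reference
#'
#' A metric passes when `|delta| <= abs_limit` or
#' `|delta|/reference <= rel_limit`. If the reference value is 0 the relative
#' criterion is undefined and only the absolute limit applies.
#'
#' @param test,ref one-row metric records ([tumor_metrics()]) for the same
#'   subject and examination.
#' @param rules an [acceptance_rules()]-style data.frame.
#' @return data.frame per metric: delta, rel_pct, pass.
#' @export
acceptance_check <- function(test, ref, rules = acceptance_rules()) {
  if (!identical(test$subject_id, ref$subject_id) ||
      !identical(as.integer(test$exam_index), as.integer(ref$exam_index)))
    stop("test and reference records are from different examinations")
  out <- lapply(seq_len(nrow(rules)), function(i) {
    mname <- rules$metric[i]
    d <- test[[mname]] - ref[[mname]]
    rel <- if (is.finite(ref[[mname]]) && ref[[mname]] != 0)
      abs(d) / abs(ref[[mname]]) * 100 else NA_real_
    pass <- isTRUE(abs(d) <= rules$abs_limit[i]) ||
      isTRUE(rel <= rules$rel_limit_pct[i])
    data.frame(metric = mname, delta = d, rel_pct = rel, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Restrict a metrics table to the evaluable cohort
#'
#' Keeps examinations whose reference CT-AC biological tumor volume exceeds
#' `min_btv_ml` (inclusion criterion: active tumor area above 1 mL).
#' Idempotent.
#'
#' @param records data.frame of stacked [tumor_metrics()] rows for all
#'   methods.
#' @param ref_method the reference AC tag.
#' @param min_btv_ml inclusion threshold in mL.
#' @return the filtered records.
#' @export
cohort_filter <- function(records, ref_method = "CT", min_btv_ml = 1) {
  ref <- records[records$ac_method == ref_method, ]
  keep <- ref[ref$btv_ml > min_btv_ml, c("subject_id", "exam_index")]
  key <- function(d) paste(d$subject_id, d$exam_index)
  records[key(records) %in% key(keep), , drop = FALSE]
}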