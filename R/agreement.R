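#' Log-scale agreement summary between an AC method and the reference
#'
#' The clinical metrics are ratio-scaled and close to log-normal, so
#' agreement is summarized on the log scale: per-exam differences
#' `d_i = ln(test_i) - ln(ref_i)`, mean with t-based 95% CI, 95% limits of
#' agreement `mean +- 1.96 SD`, and a two-sided one-sample t-test of the mean
#' against zero. Every result is exponentiated and reported as a percentage
#' difference `(e^x - 1) * 100`.
#'
#' When subjects contribute repeated examinations, the SD behind the limits
#' of agreement combines between- and within-subject variance from a one-way
#' variance-components decomposition (subject random intercept), and the CI
#' and p-value are computed on subject means so that repeated examinations
#' do not masquerade as independent subjects. With one exam per subject both
#' reduce exactly to the ordinary sample SD and t-test.
#'
#' @param test,ref positive metric values, paired per examination.
#' @param subject_id subject identifier per examination.
#' @param conf_level confidence level for the CI.
#' @param method `"components"` (variance-components SD, default) or
#'   `"subject_means"` (average repeated exams first).
#' @return one-row data.frame of class `agreement_summary`: mean_pct,
#'   ci_lo_pct, ci_hi_pct, loa_lo_pct, loa_hi_pct, p_value, n_exams,
#'   n_subjects.
#' @export
log_agreement <- function(test, ref, subject_id = seq_along(test),
                          conf_level = 0.95,
                          method = c("components", "subject_means")) {
  method <- match.arg(method)
  ok <- is.finite(test) & is.finite(ref)
  test <- test[ok]; ref <- ref[ok]; subject_id <- as.character(subject_id[ok])
  if (length(test) < 3) stop("need at least 3 paired examinations")
  if (any(test <= 0) || any(ref <= 0))
    stop("log-scale agreement requires positive values")
  d <- log(test) - log(ref)
  n <- length(d)
  subj <- factor(subject_id)
  m <- nlevels(subj)
  if (m < 2) stop("confidence intervals need at least 2 subjects")
  smeans <- tapply(d, subj, mean)
  mu <- mean(d)

  if (method == "subject_means" || max(table(subj)) == 1) {
    sd_tot <- if (method == "subject_means") sd(smeans) else sd(d)
  } else {
    # one-way variance components (unbalanced): sigma_b^2 from mean squares
    ni <- as.numeric(table(subj))
    fit <- stats::aov(d ~ subj)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    n0 <- (n - sum(ni^2) / n) / (m - 1)
    sb2 <- max((msb - msw) / n0, 0)
    sd_tot <- sqrt(sb2 + msw)
  }

  se <- sd(smeans) / sqrt(m)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = m - 1)
  if (se < 1e-12) {
    ci <- c(mu, mu)
    p <- 1   # degenerate: no variability, no evidence against zero by convention
  } else {
    ci <- mu + c(-1, 1) * tcrit * se
    tt <- stats::t.test(smeans, mu = 0)
    p <- tt$p.value
  }
  if (!is.finite(sd_tot)) sd_tot <- 0
  loa <- mu + c(-1, 1) * 1.96 * sd_tot
  pct <- function(x) (exp(x) - 1) * 100
  structure(data.frame(mean_pct = pct(mu),
                       ci_lo_pct = pct(ci[1]), ci_hi_pct = pct(ci[2]),
                       loa_lo_pct = pct(loa[1]), loa_hi_pct = pct(loa[2]),
                       p_value = p, n_exams = n, n_subjects = m,
                       stringsAsFactors = FALSE),
            class = c("agreement_summary", "data.frame"))
}

#' Per-examination Bland-Altman table with acceptance flags
#'
#' Differences of each method against the reference on the native metric
#' scale, flagged against the clinical acceptance limits (a point is flagged
#' when it exceeds both the absolute and the relative limit).
#'
#' @param records stacked [tumor_metrics()] rows for all methods.
#' @param ref_method reference AC tag.
#' @param rules acceptance limits, see [acceptance_rules()].
#' @return data.frame with one row per (exam, method, metric): reference
#'   value, difference, and `outside` flag.
#' @export
bland_altman_table <- function(records, ref_method = "CT",
                               rules = acceptance_rules()) {
  ref <- records[records$ac_method == ref_method, ]
  test <- records[records$ac_method != ref_method, ]
  key <- function(d) paste(d$subject_id, d$exam_index)
  rows <- list()
  for (i in seq_len(nrow(test))) {
    r <- ref[key(ref) == key(test[i, ]), ]
    if (nrow(r) != 1) next
    for (j in seq_len(nrow(rules))) {
      mname <- rules$metric[j]
      if (!is.finite(test[[mname]][i]) || !is.finite(r[[mname]])) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = test$subject_id[i], exam_index = test$exam_index[i],
          ac_method = test$ac_method[i], metric = mname,
          ref = r[[mname]], diff = NA_real_, outside = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      d <- test[[mname]][i] - r[[mname]]
      rel <- if (r[[mname]] != 0) abs(d) / abs(r[[mname]]) * 100 else NA_real_
      outside <- abs(d) > rules$abs_limit[j] &&
        !(isTRUE(rel <= rules$rel_limit_pct[j]))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = test$subject_id[i], exam_index = test$exam_index[i],
        ac_method = test$ac_method[i], metric = mname,
        ref = r[[mname]], diff = d, outside = outside,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bland-Altman plot of one metric for all methods
#'
#' Per-exam difference to the reference against the reference value, with
#' the acceptance band (absolute limit, widened where the relative limit
#' dominates) and the mean-difference line per method.
#'
#' @param ba a [bland_altman_table()] result.
#' @param metric which metric to plot.
#' @param rules acceptance limits.
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, the plotted subset.
#' @export
plot_bland_altman <- function(ba, metric = "tmax_b",
                              rules = acceptance_rules(), file = NULL) {
  sub <- ba[ba$metric == metric & is.finite(ba$diff), ]
  if (!nrow(sub)) stop("no finite differences to plot for ", metric)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  rule <- rules[rules$metric == metric, ]
  methods <- unique(sub$ac_method)
  cols <- stats::setNames(seq_along(methods) + 1, methods)
  xr <- range(sub$ref)
  xs <- seq(max(xr[1] * 0.9, 1e-6), xr[2] * 1.05, length.out = 100)
  band <- pmax(rule$abs_limit, xs * rule$rel_limit_pct / 100)
  graphics::plot(sub$ref, sub$diff, col = cols[sub$ac_method], pch = 19,
                 xlab = sprintf("reference %s", metric),
                 ylab = "difference to reference",
                 ylim = range(c(sub$diff, band, -band)),
                 main = sprintf("Bland-Altman: %s", metric))
  graphics::lines(xs, band, lty = 1)
  graphics::lines(xs, -band, lty = 1)
  for (mth in methods)
    graphics::abline(h = mean(sub$diff[sub$ac_method == mth]),
                     col = cols[mth], lty = 2)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topleft", legend = methods, col = cols, pch = 19,
                   bty = "n")
  invisible(sub)
}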