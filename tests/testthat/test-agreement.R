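test_that("identical measurements give zero difference and zero-width limits", {
  ref <- c(1.8, 2.1, 1.5, 2.4)
  s <- log_agreement(ref, ref, subject_id = letters[1:4])
  expect_equal(s$mean_pct, 0)
  expect_equal(s$loa_lo_pct, 0)
  expect_equal(s$loa_hi_pct, 0)
  expect_equal(s$p_value, 1)
})

test_that("a constant 1.05 ratio is reported as exactly +5 percent", {
  ref <- c(1.8, 2.1, 1.5, 2.4, 3.0)
  s <- log_agreement(1.05 * ref, ref, subject_id = letters[1:5])
  expect_equal(s$mean_pct, 5, tolerance = 1e-12)
  expect_equal(s$loa_lo_pct, 5, tolerance = 1e-12)
  expect_equal(s$loa_hi_pct, 5, tolerance = 1e-12)
})

test_that("with one exam per subject the SD reduces to the sample SD", {
  set.seed(8)
  ref <- runif(12, 1, 3)
  test <- ref * exp(rnorm(12, 0.02, 0.05))
  s <- log_agreement(test, ref, subject_id = sprintf("S%02d", 1:12))
  d <- log(test) - log(ref)
  expect_equal(s$loa_hi_pct, (exp(mean(d) + 1.96 * sd(d)) - 1) * 100)
  expect_equal(s$loa_lo_pct, (exp(mean(d) - 1.96 * sd(d)) - 1) * 100)
  expect_equal(s$p_value, t.test(d)$p.value)
})

test_that("repeated examinations widen the variance via components", {
  set.seed(9)
  subj <- rep(sprintf("S%02d", 1:8), each = 3)
  bias <- rep(rnorm(8, 0, 0.10), each = 3)       # strong between-subject part
  d <- 0.02 + bias + rnorm(24, 0, 0.02)
  ref <- runif(24, 1, 3)
  s <- log_agreement(ref * exp(d), ref, subject_id = subj)
  expect_equal(s$n_subjects, 8)
  expect_equal(s$n_exams, 24)
  # the components SD must reflect the between-subject spread, not just the
  # within-subject residual
  sd_tot <- log(1 + s$loa_hi_pct / 100) - log(1 + s$mean_pct / 100)
  expect_gt(sd_tot / 1.96, 0.05)
  # alternative estimator on subject means is available and close
  s2 <- log_agreement(ref * exp(d), ref, subject_id = subj,
                      method = "subject_means")
  expect_lt(abs(s2$mean_pct - s$mean_pct), 1.5)
})

test_that("summaries built from ratios and from logs coincide", {
  set.seed(10)
  ref <- runif(10, 1, 3)
  ratio <- exp(rnorm(10, 0.03, 0.04))
  s1 <- log_agreement(ref * ratio, ref, subject_id = 1:10)
  s2 <- log_agreement(ratio, rep(1, 10), subject_id = 1:10)
  expect_equal(s1$mean_pct, s2$mean_pct)
  expect_equal(s1$loa_hi_pct, s2$loa_hi_pct)
})

test_that("the confidence interval shrinks roughly as one over sqrt(n)", {
  set.seed(11)
  width <- vapply(c(10, 40, 160), function(n) {
    ref <- runif(n, 1, 3)
    s <- log_agreement(ref * exp(rnorm(n, 0.02, 0.05)), ref, subject_id = 1:n)
    s$ci_hi_pct - s$ci_lo_pct
  }, 0)
  expect_true(all(diff(width) < 0))
  expect_gt(width[1] / width[3], 2.5)   # expected factor 4 with slack
})

test_that("invalid inputs are refused", {
  expect_error(log_agreement(c(1, 2), c(1, 2), 1:2), "at least 3")
  expect_error(log_agreement(c(1, 2, -1), c(1, 2, 3), 1:3), "positive")
  expect_error(log_agreement(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)),
               "at least 2 subjects")
})

test_that("the Bland-Altman table flags exactly the injected outlier", {
  mk <- function(id, method, tmax_b) data.frame(
    subject_id = id, exam_index = 1L, ac_method = method, B = 1,
    t_mean = 1.8, t_max = tmax_b, tmean_b = 1.8, tmax_b = tmax_b,
    btv_ml = 10, flagged = FALSE, stringsAsFactors = FALSE)
  tab <- rbind(mk("A", "CT", 2.0), mk("A", "X", 2.0),
               mk("B", "CT", 2.0), mk("B", "X", 2.2))   # delta 0.2: outside
  ba <- bland_altman_table(tab)
  expect_equal(sum(ba$outside[ba$metric == "tmax_b"]), 1)
  expect_equal(ba$subject_id[ba$metric == "tmax_b" & ba$outside], "B")
  # an all-pass cohort has no flags
  tab2 <- rbind(mk("A", "CT", 2.0), mk("A", "X", 2.01))
  expect_equal(sum(bland_altman_table(tab2)$outside), 0)
  # band values echo the acceptance rules
  expect_equal(acceptance_rules()$abs_limit, c(0.05, 0.1, 2))
  expect_equal(acceptance_rules()$rel_limit_pct, c(5, 5, 10))
})

test_that("the Bland-Altman plot writes a figure file", {
  mk <- function(id, method, tmax_b) data.frame(
    subject_id = id, exam_index = 1L, ac_method = method, B = 1,
    t_mean = 1.8, t_max = tmax_b, tmean_b = 1.8, tmax_b = tmax_b,
    btv_ml = 10, flagged = FALSE, stringsAsFactors = FALSE)
  tab <- rbind(mk("A", "CT", 2.0), mk("A", "X", 2.05),
               mk("B", "CT", 1.9), mk("B", "X", 1.95))
  ba <- bland_altman_table(tab)
  f <- tempfile(fileext = ".png")
  plot_bland_altman(ba, "tmax_b", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
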