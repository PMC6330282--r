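test_that("background mean is the plain ROI average", {
  act <- as_volume(array(1, c(2, 2, 2)), 2)
  roi <- array(TRUE, c(2, 2, 2))
  expect_equal(background_mean(act, roi), 1)
  act2 <- as_volume(array(c(0.8, 1.2, 5, 5, 5, 5, 5, 5), c(2, 2, 2)), 2)
  roi2 <- array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  expect_equal(background_mean(act2, roi2), 1)
  expect_error(background_mean(act, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("BTV auto-contour enumerates the toy grid with a strict boundary", {
  # 4x4x1 grid at 2 mm isotropic: two voxels above 1.6 B, one exactly at it
  act <- array(1, c(1, 4, 4))
  act[1, 1, 1] <- 2.0; act[1, 2, 2] <- 1.7; act[1, 3, 3] <- 1.6
  act <- as_volume(act, 2)
  d <- delineate_btv(act, B = 1.0)
  expect_equal(sum(d$tumor_mask), 2)
  expect_equal(d$btv_ml, 2 * 0.008)        # 0.016 mL
  expect_false(d$tumor_mask[1, 3, 3])      # strictly "above" the threshold
  # uniform activity at exactly B: empty delineation
  flat <- as_volume(array(1, c(1, 4, 4)), 2)
  expect_equal(delineate_btv(flat, 1)$btv_ml, 0)
  expect_error(delineate_btv(flat, 0), "positive")
})

test_that("exclusion masking removes hot structures from the contour", {
  act <- array(1, c(1, 4, 4)); act[1, 1, 1] <- 3
  act <- as_volume(act, 2)
  excl <- array(FALSE, c(1, 4, 4)); excl[1, 1, 1] <- TRUE
  expect_equal(delineate_btv(act, 1, excl)$btv_ml, 0)
})

test_that("tumor metrics and ratios follow the definitions", {
  act <- array(1, c(1, 4, 4)); act[1, 1, 1] <- 2.0; act[1, 2, 2] <- 1.7
  act <- as_volume(act, 2)
  d <- delineate_btv(act, 1)
  rec <- tumor_metrics(act, d, B = 1)
  expect_equal(rec$t_mean, 1.85)
  expect_equal(rec$t_max, 2.0)
  expect_equal(rec$tmean_b, 1.85)
  expect_equal(rec$tmax_b, 2.0)
  rec2 <- tumor_metrics(act, d, B = 2)
  expect_equal(rec2$tmax_b, rec$tmax_b / 2)   # ratios scale inversely with B
  # all-equal mask values collapse mean and max
  flat <- as_volume(array(2, c(1, 4, 4)), 2)
  df <- delineate_btv(flat, 1)
  rf <- tumor_metrics(flat, df, 1)
  expect_equal(rf$t_mean, rf$t_max)
})

test_that("an empty tumor mask yields a flagged record", {
  flat <- as_volume(array(1, c(1, 4, 4)), 2)
  d <- delineate_btv(flat, 1)
  rec <- tumor_metrics(flat, d, 1)
  expect_true(rec$flagged)
  expect_true(is.na(rec$tmax_b))
  expect_equal(rec$btv_ml, 0)
})

test_that("Jaccard overlap handles identity, disjoint and partial cases", {
  a <- array(FALSE, c(1, 4, 4)); b <- a
  a[1, 1, 1:4] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b[1, 3, 1:4] <- TRUE
  expect_equal(jaccard(a, b), 0)
  b[] <- FALSE; b[1, 1, 3:4] <- TRUE; b[1, 2, 1:2] <- TRUE   # |B|=4, overlap 2
  expect_equal(jaccard(a, b), 2 / 6)
  expect_equal(jaccard(a, b), jaccard(b, a))
  empty <- array(FALSE, c(1, 4, 4))
  expect_equal(jaccard(empty, empty), 1)
})

test_that("Jaccard agrees with a set-arithmetic oracle on random masks", {
  set.seed(31)
  for (i in 1:20) {
    a <- array(runif(64) < 0.4, c(4, 4, 4))
    b <- array(runif(64) < 0.4, c(4, 4, 4))
    ia <- which(a); ib <- which(b)
    oracle <- if (!length(union(ia, ib))) 1 else
      length(intersect(ia, ib)) / length(union(ia, ib))
    expect_equal(jaccard(a, b), oracle)
  }
})

test_that("acceptance limits combine absolute and relative cut-offs", {
  mk <- function(tmean_b, tmax_b, btv) data.frame(
    subject_id = "S01", exam_index = 1L, ac_method = "X", B = 1,
    t_mean = tmean_b, t_max = tmax_b, tmean_b = tmean_b, tmax_b = tmax_b,
    btv_ml = btv, flagged = FALSE, stringsAsFactors = FALSE)
  ref <- mk(1.8, 2.0, 40)
  # overestimation of 0.13 on T_MAX/B at a reference of 2.0 fails both limits
  chk <- acceptance_check(mk(1.8, 2.13, 40), ref)
  expect_false(chk$pass[chk$metric == "tmax_b"])
  # identical metrics pass everywhere
  expect_true(all(acceptance_check(ref, ref)$pass))
  # BTV 40 -> 43 mL: over the 2 mL limit but inside 10% relative
  chk2 <- acceptance_check(mk(1.8, 2.0, 43), ref)
  expect_true(chk2$pass[chk2$metric == "btv_ml"])
  # truth table around the dual cut-off for T_MEAN/B (abs 0.05 / rel 5%)
  cases <- list(list(1.88, TRUE),      # 0.08 over, but within 5% relative
                list(1.84, TRUE),      # within absolute 0.05
                list(2.5, FALSE))      # fails both
  for (cs in cases) {
    chk3 <- acceptance_check(mk(cs[[1]], 2.0, 40), ref)
    expect_equal(chk3$pass[chk3$metric == "tmean_b"], cs[[2]],
                 label = sprintf("tmean_b=%g", cs[[1]]))
  }
  expect_error(acceptance_check(mk(1, 1, 1),
                                transform(ref, exam_index = 2L)),
               "different examinations")
})

test_that("cohort filter keeps reference BTV > 1 mL and is idempotent", {
  rec <- function(id, method, btv) data.frame(
    subject_id = id, exam_index = 1L, ac_method = method, B = 1,
    t_mean = 2, t_max = 2, tmean_b = 2, tmax_b = 2, btv_ml = btv,
    flagged = FALSE, stringsAsFactors = FALSE)
  tab <- rbind(rec("A", "CT", 0.5), rec("A", "NOBONE", 3),
               rec("B", "CT", 2), rec("B", "NOBONE", 0.2))
  kept <- cohort_filter(tab)
  expect_setequal(unique(kept$subject_id), "B")
  expect_identical(cohort_filter(kept), kept)
})

test_that("BTV is monotone non-increasing in the threshold multiplier", {
  case <- fixture_phantom("btv_mono", noise = 0, seed = 23)
  B <- background_mean(case$activity, case$background_roi)
  btv <- vapply(c(1.2, 1.6, 2.0, 2.4), function(th)
    delineate_btv(case$activity, B, case$exclusion_mask, threshold = th)$btv_ml,
    0)
  expect_true(all(diff(btv) <= 0))
})
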