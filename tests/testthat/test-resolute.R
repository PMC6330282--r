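true_sig <- function(r, L, U, r0, k) L + (U - L) / (1 + exp(-k * (r - r0)))

test_that("sigmoid fit recovers known parameters from noisy pairs", {
  set.seed(42)
  L <- 0; U <- 1500; r0 <- 800; k <- 0.01
  r <- runif(1e4, 100, 1600)
  hu <- true_sig(r, L, U, r0, k) + rnorm(1e4, 0, 30)
  fit <- fit_bone_sigmoid(r, hu)
  expect_lt(abs(fit$L - L), 0.05 * U)   # L is 0: relative to the range
  expect_lt(abs(fit$U - U) / U, 0.05)
  expect_lt(abs(fit$r0 - r0) / r0, 0.05)
  expect_lt(abs(fit$k - k) / k, 0.05)
})

test_that("noiseless exact-sigmoid pairs are fitted to machine accuracy", {
  set.seed(7)
  r <- runif(500, 100, 1600)
  hu <- true_sig(r, 50, 1400, 700, 0.008)
  fit <- fit_bone_sigmoid(r, hu)
  expect_lt(fit$rmse, 1e-6 * 1400)
})

test_that("sigmoid predictions are bounded, monotone, and symmetric at r0", {
  fit <- structure(list(L = 100, U = 1300, r0 = 600, k = 0.009),
                   class = "bone_sigmoid")
  r <- seq(-500, 4000, by = 10)
  p <- predict(fit, r)
  expect_true(all(p >= 100 & p <= 1300))
  expect_true(all(diff(p) > 0))
  expect_equal(predict(fit, 600), (100 + 1300) / 2)
})

test_that("too few bone samples are refused", {
  expect_error(fit_bone_sigmoid(1:50, 1:50), "at least")
})

test_that("cross-validated calibration never fits a case on itself", {
  cases <- fixture_battery(4, noise = 0)
  cal <- calibrate_bone_sigmoid(cases, folds = 2, seed = 3)
  folds <- unclass(cal$split)
  # each fold fit pooled only the *other* fold's bone samples
  counts <- vapply(cases, function(cs) {
    sm <- petmrac:::smoothed_echoes(cs)
    r2 <- compute_r2star(sm$ute1, sm$ute2, cs$te1_ms, cs$te2_ms)
    sum(cs$ct_hu > 300 & r2 > 0 & r2 < max(r2))
  }, 0)
  for (f in 1:2) {
    train_n <- sum(counts[folds[vapply(cases, `[[`, "", "subject_id")] != f])
    expect_equal(cal$fits[[f]]$n, min(train_n, 20000))
  }
  p <- params_for_case(cal, cases[[1]])
  expect_s3_class(p, "bone_sigmoid")
  expect_identical(p, cal$fits[[folds[["S01"]]]])
})

test_that("noiseless phantoms are segmented almost perfectly", {
  cases <- fixture_battery(4, noise = 0)
  cal <- calibrate_bone_sigmoid(cases, folds = 2, seed = 3)
  case <- cases[[2]]
  m <- build_resolute_map(case, params_for_case(cal, case))
  truth <- classify_tissue(case$ct_hu)
  expect_gt(jac_of(m$classes == 2, truth == 2), 0.9)
  # continuous-bone map beats the bone-less baseline on attenuation error
  mu_true <- hu_to_mu(case$ct_hu)
  nb <- build_nobone_map(case)
  expect_lt(mean(abs(m$mu - mu_true$mu)), mean(abs(nb$mu - mu_true$mu)))
})

test_that("an all-air volume yields a zero attenuation map", {
  sp <- 2.5
  quiet <- structure(list(
    ute1 = as_volume(array(0.5, c(32, 32, 32)), sp),
    ute2 = as_volume(array(0.5, c(32, 32, 32)), sp),
    te1_ms = 0.07, te2_ms = 2.46, subject_id = "A0", exam_index = 1L),
    class = "phantom_case")
  params <- structure(list(L = 100, U = 1300, r0 = 600, k = 0.009),
                      class = "bone_sigmoid")
  m <- build_resolute_map(quiet, params)
  expect_true(all(m$mu == 0))
  expect_true(all(build_nobone_map(quiet)$mu == 0))
})

test_that("the bone-less baseline assigns soft attenuation inside the head", {
  case <- fixture_phantom("nobone_case", noise = 0, seed = 17)
  nb <- build_nobone_map(case)
  bone <- case$labels == 2L
  soft_mu <- 0.096 + 5.1e-5 * 30   # 30 HU sits on the bone slope
  expect_equal(unique(round(nb$mu[bone], 8)), round(soft_mu, 8))
  # two-class property: at most two distinct values overall
  expect_lte(length(unique(round(as.numeric(nb$mu), 8))), 2)
})

test_that("invalid sigmoid parameters are rejected when building the map", {
  case <- fixture_phantom("nobone_case", noise = 0, seed = 17)
  bad <- structure(list(L = 1300, U = 100, r0 = 600, k = 0.01),
                   class = "bone_sigmoid")
  expect_error(build_resolute_map(case, bad), "invalid sigmoid")
})
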