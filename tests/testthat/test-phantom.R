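test_that("anatomy contains exactly the requested compartments", {
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                       air_nasal = FALSE, air_mastoid = FALSE,
                       air_postop = FALSE, seed = 2)
  lab <- build_anatomy(spec)
  expect_setequal(sort(unique(as.integer(lab))), c(0L, 1L, 2L, 4L, 5L))
  spec2 <- phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                        air_nasal = TRUE, seed = 2)
  expect_true(3L %in% unique(as.integer(build_anatomy(spec2))))
})

test_that("anatomy and full case are deterministic given spec and seed", {
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, seed = 9)
  expect_identical(build_anatomy(spec), build_anatomy(spec))
  c1 <- build_phantom(spec, "S01")
  c2 <- build_phantom(spec, "S01")
  for (f in c("labels", "ct_hu", "ute1", "ute2", "activity"))
    expect_identical(c1[[f]], c2[[f]])
})

test_that("skull shell thickness matches the spec under a ray-cast oracle", {
  spec <- phantom_spec(grid_shape = 48, voxel_mm = 2, skull_thickness_mm = 4,
                       seed = 1, air_nasal = FALSE, air_mastoid = FALSE)
  lab <- build_anatomy(spec)
  # rays along each principal axis through the center voxel
  ctr <- (dim(lab) + 1L) %/% 2L
  runs <- c()
  rays <- list(lab[, ctr[2], ctr[3]], lab[ctr[1], , ctr[3]], lab[ctr[1], ctr[2], ])
  for (ray in rays) {
    r <- rle(ray)
    runs <- c(runs, r$lengths[r$values == 2L])
  }
  expect_true(length(runs) >= 6)      # both sides of three axes
  expect_equal(min(runs), 2)          # 4 mm / 2 mm voxels
})

test_that("noiseless echoes follow mono-exponential decay exactly", {
  tp <- tissue_params(jitter = FALSE)
  tp["bone", c("S0", "r2star")] <- c(100, 1000)
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, noise_sigma = 0,
                       bone_r2star = 1000, tissue = tp, seed = 3)
  lab <- build_anatomy(spec)
  sig <- synthesize_signals(lab, spec)
  bone <- lab == 2L
  expect_equal(unique(round(sig$ute1[bone], 6)), 100 * exp(-7e-5 * 1000))
  expect_equal(round(median(sig$ute1[bone]), 2), 93.24)
  expect_equal(round(median(sig$ute2[bone]), 2), 8.54)
  expect_true(all(sig$ct_hu[lab == 0L] == -1000))
})

test_that("echo signal ordering: bone decays, water-like tissue does not", {
  tp <- tissue_params(jitter = FALSE)
  tp["soft", "r2star"] <- 0
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, noise_sigma = 0,
                       tissue = tp, seed = 4)
  lab <- build_anatomy(spec)
  sig <- synthesize_signals(lab, spec)
  expect_true(all(sig$ute1[lab == 2L] > sig$ute2[lab == 2L]))
  expect_equal(sig$ute1[lab == 1L], sig$ute2[lab == 1L], tolerance = 1e-12)
})

test_that("tissue statistics are seed-stable in distribution", {
  specs <- lapply(c(21, 22), function(s)
    phantom_spec(grid_shape = 32, voxel_mm = 2.5, seed = s))
  stats <- lapply(specs, function(sp) {
    lab <- build_anatomy(sp)
    sig <- synthesize_signals(lab, sp)
    m <- lab == 2L
    c(mean(sig$ct_hu[m]), mean(sig$ute1[m]), n = sum(m),
      sd_hu = sd(sig$ct_hu[m]), sd_s1 = sd(sig$ute1[m]))
  })
  # same label-wise means within 3 standard errors over thousands of voxels
  n <- min(stats[[1]]["n"], stats[[2]]["n"])
  expect_gt(n, 1000)
  expect_lt(abs(stats[[1]][1] - stats[[2]][1]),
            3 * sqrt(stats[[1]]["sd_hu"]^2 + stats[[2]]["sd_hu"]^2) / sqrt(n))
  expect_lt(abs(stats[[1]][2] - stats[[2]][2]),
            3 * sqrt(stats[[1]]["sd_s1"]^2 + stats[[2]]["sd_s1"]^2) / sqrt(n))
})

test_that("activity map encodes the tumor-to-background ratio by construction", {
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, noise_sigma = 0,
                       activity_sd = 0, tumor_to_background_ratio = 2.5,
                       seed = 5)
  case <- build_phantom(spec, "S01")
  B <- mean(case$activity[case$background_roi])
  expect_equal(max(case$activity[case$labels == 5L]) / B, 2.5, tolerance = 1e-9)
  expect_false(any(case$background_roi & case$labels == 5L))
})

test_that("sub-threshold tumors are flagged", {
  spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                       tumor_to_background_ratio = 1.5, seed = 6)
  lab <- build_anatomy(spec)
  expect_warning(act <- synthesize_activity(lab, spec), "below the delineation")
  expect_true("sub-threshold tumor" %in% act$flags)
})

test_that("an extratumoral hot spot is exactly covered by the exclusion mask", {
  base <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, noise_sigma = 0,
                       activity_sd = 0, hot_spot = FALSE, seed = 7)
  hot <- phantom_spec(grid_shape = 32, voxel_mm = 2.5, noise_sigma = 0,
                      activity_sd = 0, hot_spot = TRUE, seed = 7)
  c0 <- build_phantom(base, "S01"); c1 <- build_phantom(hot, "S01")
  B <- mean(c1$activity[c1$background_roi])
  del_excl <- delineate_btv(c1$activity, B, c1$exclusion_mask)
  del_raw <- delineate_btv(c1$activity, B, NULL)
  hot_supra <- sum(c1$exclusion_mask & c1$activity > 1.6 * B)
  expect_gt(hot_supra, 0)
  expect_equal(sum(del_raw$tumor_mask) - sum(del_excl$tumor_mask), hot_supra)
  # with the exclusion applied, the hot spot does not change the BTV
  B0 <- mean(c0$activity[c0$background_roi])
  del0 <- delineate_btv(c0$activity, B0, c0$exclusion_mask)
  expect_equal(del_excl$btv_ml, del0$btv_ml)
})

test_that("thicker skulls never have fewer bone voxels", {
  counts <- vapply(c(4, 5.5, 7), function(th) {
    spec <- phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                         skull_thickness_mm = th, seed = 8)
    sum(build_anatomy(spec) == 2L)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(grid_shape = 16), "grid_shape")
  expect_error(phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                            skull_thickness_mm = 1), "voxel")
  expect_error(phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                            noise_sigma = -0.1), "noise_sigma")
  expect_error(phantom_spec(grid_shape = 32, voxel_mm = 2.5,
                            tumor_center_mm = c(0, 0, 40)), "tumor")
})
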