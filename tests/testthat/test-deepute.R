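tiny_net <- function(base = 2, seed = 1, in_ch = 3)
  build_network(network_spec(depth = 2, base_channels = base,
                             in_channels = in_ch, convs_per_block = 1),
                seed = seed)

test_that("the network maps 16-slice windows to one HU channel", {
  m <- tiny_net()
  x <- list(array(rnorm(16 * 192 * 192 * 3), c(16, 192, 192, 3)))
  fw <- petmrac:::unet_forward(m, x, train = FALSE)
  expect_equal(dim(fw$preds[[1]]), c(16, 192, 192, 1))
})

test_that("parameter count strictly increases with base width", {
  expect_gt(n_parameters(tiny_net(base = 4)), n_parameters(tiny_net(base = 2)))
})

test_that("network spec enforces its invariants", {
  expect_error(network_spec(window_depth = 8), "fixed at 16")
  expect_error(network_spec(dropout_range = c(0.05, 0.3)), "dropout")
  expect_error(network_spec(dropout_range = c(0.3, 0.1)), "dropout")
})

test_that("backpropagation matches finite differences", {
  set.seed(1)
  m <- tiny_net(in_ch = 2)
  for (nm in names(m$units)) m$units[[nm]]$p_drop <- 0
  x <- list(array(rnorm(16 * 8 * 8 * 2), c(16, 8, 8, 2)))
  loss_of <- function(model) {
    f <- petmrac:::unet_forward(model, x, train = TRUE)
    sum(f$preds[[1]]^2) / 2
  }
  fw <- petmrac:::unet_forward(m, x, train = TRUE)
  g <- petmrac:::unet_backward(m, fw$caches, fw$units, fw$preds)
  eps <- 1e-5
  for (nm in names(m$units)) {
    for (fld in c("w", "gamma", "beta")) {
      if (is.null(m$units[[nm]][[fld]])) next
      gname <- c(w = "gw", gamma = "ggamma", beta = "gbeta")[[fld]]
      i <- min(3, length(m$units[[nm]][[fld]]))
      m2 <- m; m2$units[[nm]][[fld]][i] <- m2$units[[nm]][[fld]][i] + eps
      m3 <- m; m3$units[[nm]][[fld]][i] <- m3$units[[nm]][[fld]][i] - eps
      fd <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      if (abs(fd) > 1e-4)
        expect_lt(abs(fd - g[[nm]][[gname]][i]) / abs(fd), 1e-5,
                  label = sprintf("gradient of %s$%s", nm, fld))
    }
  }
})

test_that("window extraction counts and indexing follow the sliding rule", {
  case20 <- toy_case(20)
  w <- extract_windows(case20)
  expect_equal(length(w$x), 5)                 # S - 16 + 1
  expect_equal(w$starts, 1:5)
  expect_equal(dim(w$x[[1]]), c(16, 20, 20, 3))
  # window at start s, slice j comes from source slice s + j - 1
  r2 <- compute_r2star(petmrac:::smoothed_echoes(case20)$ute1,
                       petmrac:::smoothed_echoes(case20)$ute2)
  nc <- w$norm[[3]]
  for (s in c(2, 4)) for (j in c(1, 16))
    expect_equal(w$x[[s]][j, , , 3],
                 (r2[s + j - 1, , ] - nc$center) / nc$scale)
  expect_equal(w$y[[3]][5, , , 1], case20$ct_hu[7, , ])
  w16 <- extract_windows(toy_case(16))
  expect_equal(length(w16$x), 1)               # boundary: exactly one window
  expect_error(extract_windows(toy_case(15)), "fewer than 16")
})

test_that("a zero learning rate leaves the loss unchanged", {
  case <- toy_case(18, n = 8)
  m <- tiny_net()
  m <- deepute_train(m, list(case),
                     train_config(learning_rate = 0, epochs = 3,
                                  window_stride = 2, seed = 5,
                                  max_restarts = 0))
  expect_equal(diff(range(m$loss_history)), 0, tolerance = 1e-8)
})

test_that("training is deterministic given the seed", {
  case <- toy_case(18, n = 8)
  run <- function() {
    m <- tiny_net(seed = 2)
    deepute_train(m, list(case),
                  train_config(learning_rate = 1e-3, epochs = 2,
                               window_stride = 2, seed = 5,
                               max_restarts = 0))$loss_history
  }
  expect_identical(run(), run())
})

test_that("overlap averaging reproduces a constant-output model everywhere", {
  case <- toy_case(20, n = 8)
  m <- tiny_net()
  for (nm in names(m$units)) {
    m$units[[nm]]$w[] <- 0
    m$units[[nm]]$b[] <- 0
    if (!is.null(m$units[[nm]]$gamma)) m$units[[nm]]$gamma[] <- 0
  }
  m$units[["out"]]$b[] <- 2
  m$target <- list(center = 100, scale = 50)
  pc <- predict_volume(m, case)
  expect_true(all(abs(pc - (2 * 50 + 100)) < 1e-9))
})

test_that("overlap averaging equals the brute-force per-voxel mean", {
  case <- toy_case(18, n = 8)
  m <- tiny_net(seed = 6)
  m$target <- list(center = 0, scale = 1)
  pc <- predict_volume(m, case)
  # oracle: explicit window list, accumulate and divide
  w <- extract_windows(case, stride = 1L)
  acc <- array(0, dim(case$ute1)); cnt <- numeric(18)
  for (i in seq_along(w$x)) {
    fw <- petmrac:::unet_forward(m, w$x[i], train = FALSE)
    s <- w$starts[i]
    acc[s:(s + 15), , ] <- acc[s:(s + 15), , ] + fw$preds[[1]][, , , 1]
    cnt[s:(s + 15)] <- cnt[s:(s + 15)] + 1
  }
  expect_equal(cnt, vapply(1:18, function(j) min(j, 18 - 16 + 1, 19 - j), 0))
  expect_equal(as.numeric(pc), as.numeric(sweep(acc, 1, cnt, `/`)))
})

test_that("slice coverage counts match the closed form", {
  S <- 20
  cnt <- numeric(S)
  for (s in 1:(S - 16 + 1)) cnt[s:(s + 15)] <- cnt[s:(s + 15)] + 1
  closed <- vapply(1:S, function(j)
    min(j, S - 16 + 1, 16, S - j + 1), 0)
  expect_equal(cnt, closed)
  expect_equal(cnt[1], 1)    # first slice seen by a single window
  expect_equal(cnt[10], 5)   # central slice by five
})

test_that("constant-model inference is slice-reversal equivariant", {
  case <- toy_case(20, n = 8)
  rev_case <- case
  for (f in c("ute1", "ute2", "ct_hu"))
    rev_case[[f]] <- as_volume(case[[f]][20:1, , ], 2)
  m <- tiny_net()
  for (nm in names(m$units)) { m$units[[nm]]$w[] <- 0; m$units[[nm]]$b[] <- 0
    if (!is.null(m$units[[nm]]$gamma)) m$units[[nm]]$gamma[] <- 0 }
  m$units[["out"]]$b[] <- 1
  m$target <- list(center = 0, scale = 1)
  expect_equal(as.numeric(predict_volume(m, rev_case)),
               as.numeric(predict_volume(m, case)[20:1, , ]))
})

test_that("cross-validated training assigns held-out models per subject", {
  cases <- fixture_battery(4, noise = 0.05, seed0 = 70)
  cv <- deepute_crossval(cases, k = 2,
                         net = network_spec(depth = 2, base_channels = 2,
                                            convs_per_block = 1),
                         cfg = train_config(learning_rate = 1e-3, epochs = 1,
                                            window_stride = 8, seed = 9,
                                            max_restarts = 0),
                         seed = 9)
  expect_length(cv$models, 2)
  m1 <- model_for_case(cv, cases[[1]])
  expect_s3_class(m1, "deepute_model")
  expect_identical(m1, cv$models[[petmrac:::fold_of(cv$split, "S01")]])
})
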