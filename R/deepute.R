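#' Architecture of the pseudo-CT encoder-decoder network
#'
#' A U-net-style 3D fully convolutional network over 16-slice windows with
#' (echo1, echo2, R2*) input channels and one HU output channel. Max pooling
#' is replaced by stride-2 convolutions; every convolution except the final
#' 1x1x1 output is followed by batch normalization, ReLU and dropout, with
#' the dropout fraction increasing linearly along the encoder and mirrored
#' (decreasing) along the decoder. Weights are He-normal initialized.
#' Channel width doubles per resolution level from `base_channels`.
#'
#' @param depth number of resolution levels (depth - 1 downsamplings).
#' @param base_channels channels at the first level; the published network is
#'   far wider, desk-scale runs use 4-16.
#' @param in_channels input channels (echo1, echo2, R2*).
#' @param window_depth slices per window; fixed at 16.
#' @param dropout_range dropout fractions at the first and last encoder level.
#' @param convs_per_block convolutions per resolution block (2 is the
#'   canonical U-net block; 1 is a cheaper variant).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(depth = 4, base_channels = 16, in_channels = 3,
                         window_depth = 16, dropout_range = c(0.1, 0.3),
                         convs_per_block = 2) {
  if (window_depth != 16) stop("window depth is fixed at 16 slices")
  if (depth < 2) stop("need at least 2 resolution levels")
  if (!convs_per_block %in% 1:2) stop("convs_per_block must be 1 or 2")
  dropout <- seq(dropout_range[1], dropout_range[2], length.out = depth)
  if (any(dropout < 0.1 - 1e-9) || any(dropout > 0.3 + 1e-9) ||
      any(diff(dropout) < 0))
    stop("dropout schedule must be nondecreasing within [0.1, 0.3]")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 window_depth = 16L,
                 convs_per_block = as.integer(convs_per_block),
                 dropout = dropout),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  ch <- x$base_channels * 2^(seq_len(x$depth) - 1)
  cat(sprintf("<network_spec> %d levels, channels %s, dropout %s\n",
              x$depth, paste(ch, collapse = "/"),
              paste(sprintf("%.2f", x$dropout), collapse = "/")))
  invisible(x)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_unit <- function(k, cin, cout, stride, pad, kind, p_drop, use_bn = TRUE) {
  # upsampling units store weights in the layout of the adjoint stride-2
  # convolution (fine-grid channels in slot 4), so their output channel count
  # is cin, not cout
  head_ch <- if (kind == "up") cin else cout
  fan_in <- if (kind == "up") cout else k^3 * cin
  w <- he_init(c(k, k, k, cin, cout), fan_in)
  list(kind = kind, k = k, stride = stride, pad = pad,
       w = w, b = numeric(head_ch),
       use_bn = use_bn,
       gamma = if (use_bn) rep(1, head_ch) else NULL,
       beta = if (use_bn) numeric(head_ch) else NULL,
       rmean = if (use_bn) numeric(head_ch) else NULL,
       rvar = if (use_bn) rep(1, head_ch) else NULL,
       p_drop = p_drop)
}

#' Instantiate the network with He-initialized weights
#'
#' @param spec a [network_spec()].
#' @param seed initialization seed.
#' @return object of class `deepute_model` (untrained).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  d <- spec$depth
  ch <- spec$base_channels * 2^(seq_len(d) - 1)
  units <- with_seed(seed, {
    u <- list()
    for (l in seq_len(d)) {
      cin <- if (l == 1) spec$in_channels else ch[l - 1]
      u[[paste0("enc", l)]] <- new_unit(3, cin, ch[l], 1, 1, "conv",
                                        spec$dropout[l])
      if (spec$convs_per_block == 2)
        u[[paste0("enc", l, "b")]] <- new_unit(3, ch[l], ch[l], 1, 1, "conv",
                                               spec$dropout[l])
      if (l < d)
        u[[paste0("down", l)]] <- new_unit(2, ch[l], ch[l], 2, 0, "conv",
                                           spec$dropout[l + 1])
    }
    for (l in rev(seq_len(d - 1))) {
      # upsampling weights are stored in the layout of the adjoint stride-2
      # convolution: (2,2,2, coarse-grid-out, fine-grid-in) swapped roles
      u[[paste0("up", l)]] <- new_unit(2, ch[l], ch[l + 1], 2, 0, "up",
                                       spec$dropout[l])
      u[[paste0("dec", l)]] <- new_unit(3, 2 * ch[l], ch[l], 1, 1, "conv",
                                        spec$dropout[l])
      if (spec$convs_per_block == 2)
        u[[paste0("dec", l, "b")]] <- new_unit(3, ch[l], ch[l], 1, 1, "conv",
                                               spec$dropout[l])
    }
    u[["out"]] <- new_unit(1, ch[1], 1, 1, 0, "conv", 0, use_bn = FALSE)
    u
  })
  structure(list(spec = spec, units = units, seed = as.integer(seed),
                 trained = FALSE, norm = NULL, target = NULL,
                 loss_history = numeric(0)),
            class = "deepute_model")
}

#' @export
print.deepute_model <- function(x, ...) {
  np <- sum(vapply(x$units, function(u)
    length(u$w) + length(u$b) + length(u$gamma) + length(u$beta), 0))
  cat(sprintf("<deepute_model> %d levels, base %d, %s parameters, %s\n",
              x$spec$depth, x$spec$base_channels, format(np, big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs, final loss %.1f HU^2)",
                                     length(x$loss_history),
                                     utils::tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `deepute_model`.
#' @return integer count of weights, biases and batch-norm parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$units, function(u)
    length(u$w) + length(u$b) + length(u$gamma) + length(u$beta), 0))
}

# ---- layer forward/backward -------------------------------------------------

wmat <- function(u) {
  wd <- dim(u$w)
  matrix(u$w, prod(wd[1:4]), wd[5])
}

# forward through one convolution unit (direct kernels; output volumes are
# small enough to stay cache-hot)
conv_fwd_one <- function(u, x) {
  wd <- dim(u$w)
  if (u$kind == "up") {
    # adjoint of a stride-2 k=2 convolution: learned 2x upsampling
    xd <- dim(x)
    big <- as.integer(c(xd[1:3] * 2L, wd[4]))
    y <- conv3d_bwd_x(x, dim(x), u$w, wd, big, 2L, 0L)
    y <- y + rep(u$b, each = prod(big[1:3]))
    dim(y) <- big
    list(y = y, P = NULL)
  } else {
    y <- conv3d_fwd(x, dim(x), u$w, wd, u$b, as.integer(u$stride),
                    as.integer(u$pad))
    list(y = y, P = NULL)
  }
}

conv_bwd_one <- function(u, x, gy, P = NULL) {
  wd <- dim(u$w)
  if (u$kind == "up") {
    G <- im2col3d(gy, dim(gy), u$k, 2L, 0L)
    xd <- dim(x)
    xm <- matrix(x, prod(xd[1:3]), xd[4])
    gx <- G %*% wmat(u)
    dim(gx) <- xd
    gw <- crossprod(G, xm)
    dim(gw) <- wd
    gb <- colSums(matrix(gy, prod(dim(gy)[1:3]), dim(gy)[4]))
    list(gx = gx, gw = gw, gb = gb)
  } else {
    if (is.null(P))
      P <- im2col3d(x, dim(x), u$k, as.integer(u$stride), as.integer(u$pad))
    gym <- matrix(gy, prod(dim(gy)[1:3]), dim(gy)[4])
    gw <- crossprod(P, gym)
    dim(gw) <- wd
    gx <- col2im3d(tcrossprod(gym, wmat(u)), dim(x), u$k,
                   as.integer(u$stride), as.integer(u$pad))
    list(gx = gx, gw = gw, gb = colSums(gym))
  }
}

as_mat <- function(x) { d <- dim(x); dim(x) <- c(prod(d[1:3]), d[4]); x }

# batch-norm + ReLU + dropout over a batch (list of 4D arrays); returns
# outputs plus the cache needed for the backward pass
unit_head_fwd <- function(u, ys, train, bn_momentum = 0.9) {
  cache <- list()
  if (u$use_bn) {
    mats <- lapply(ys, as_mat)
    m <- sum(vapply(mats, nrow, 0L))
    if (train) {
      mu <- Reduce(`+`, lapply(mats, colSums)) / m
      v <- Reduce(`+`, lapply(mats, function(a) colSums(a^2))) / m - mu^2
      v <- pmax(v, 0)
      u$rmean <- bn_momentum * u$rmean + (1 - bn_momentum) * mu
      u$rvar <- bn_momentum * u$rvar + (1 - bn_momentum) * v
    } else {
      mu <- u$rmean; v <- u$rvar
    }
    invstd <- 1 / sqrt(v + 1e-5)
    xhat <- lapply(mats, function(a)
      sweep(sweep(a, 2, mu, `-`), 2, invstd, `*`))
    ys <- mapply(function(xh, y) {
      out <- sweep(sweep(xh, 2, u$gamma, `*`), 2, u$beta, `+`)
      dim(out) <- dim(y); out
    }, xhat, ys, SIMPLIFY = FALSE)
    cache$xhat <- xhat; cache$invstd <- invstd; cache$m <- m
  }
  relu_mask <- lapply(ys, function(y) y > 0)
  ys <- mapply(function(y, mk) y * mk, ys, relu_mask, SIMPLIFY = FALSE)
  if (train && u$p_drop > 0) {
    drop_mask <- lapply(ys, function(y)
      (array(stats::runif(length(y)), dim(y)) >= u$p_drop) / (1 - u$p_drop))
    ys <- mapply(`*`, ys, drop_mask, SIMPLIFY = FALSE)
    cache$drop_mask <- drop_mask
  }
  cache$relu_mask <- relu_mask
  list(unit = u, ys = ys, cache = cache)
}

unit_head_bwd <- function(u, gys, cache) {
  if (!is.null(cache$drop_mask))
    gys <- mapply(`*`, gys, cache$drop_mask, SIMPLIFY = FALSE)
  gys <- mapply(function(g, mk) g * mk, gys, cache$relu_mask, SIMPLIFY = FALSE)
  ggamma <- gbeta <- NULL
  if (u$use_bn) {
    gmats <- lapply(gys, as_mat)
    m <- cache$m
    gbeta <- Reduce(`+`, lapply(gmats, colSums))
    ggamma <- Reduce(`+`, mapply(function(g, xh) colSums(g * xh),
                                 gmats, cache$xhat, SIMPLIFY = FALSE))
    # standard batch-norm backward, pooled over the batch
    sum_dxhat <- Reduce(`+`, lapply(gmats, function(g)
      colSums(sweep(g, 2, u$gamma, `*`))))
    sum_dxhat_xhat <- Reduce(`+`, mapply(function(g, xh)
      colSums(sweep(g, 2, u$gamma, `*`) * xh), gmats, cache$xhat,
      SIMPLIFY = FALSE))
    gys <- mapply(function(g, xh) {
      dxhat <- sweep(as_mat(g), 2, u$gamma, `*`)
      out <- sweep(dxhat -
                     matrix(sum_dxhat / m, nrow(dxhat), ncol(dxhat), byrow = TRUE) -
                     sweep(xh, 2, sum_dxhat_xhat / m, `*`),
                   2, cache$invstd, `*`)
      dim(out) <- dim(g); out
    }, gys, cache$xhat, SIMPLIFY = FALSE)
  }
  list(gys = gys, ggamma = ggamma, gbeta = gbeta)
}

# full forward over a batch; returns per-sample predictions and caches
unet_forward <- function(model, xs, train = FALSE) {
  d <- model$spec$depth
  units <- model$units
  caches <- list()
  acts <- list(xs)
  skips <- list()
  cur <- xs
  run_unit <- function(nm, xin) {
    u <- units[[nm]]
    fo <- lapply(xin, function(x) conv_fwd_one(u, x))
    hd <- unit_head_fwd(u, lapply(fo, `[[`, "y"), train)
    units[[nm]] <<- hd$unit
    caches[[nm]] <<- list(xs = xin, Ps = lapply(fo, `[[`, "P"),
                          head = hd$cache)
    hd$ys
  }
  two <- model$spec$convs_per_block %||% 1L
  for (l in seq_len(d)) {
    cur <- run_unit(paste0("enc", l), cur)
    if (two == 2) cur <- run_unit(paste0("enc", l, "b"), cur)
    skips[[l]] <- cur
    if (l < d) cur <- run_unit(paste0("down", l), cur)
  }
  for (l in rev(seq_len(d - 1))) {
    up <- run_unit(paste0("up", l), cur)
    cat_in <- mapply(function(a, s) {
      out <- array(0, c(dim(a)[1:3], dim(a)[4] + dim(s)[4]))
      out[, , , seq_len(dim(a)[4])] <- a
      out[, , , dim(a)[4] + seq_len(dim(s)[4])] <- s
      out
    }, up, skips[[l]], SIMPLIFY = FALSE)
    cur <- run_unit(paste0("dec", l), cat_in)
    if (two == 2) cur <- run_unit(paste0("dec", l, "b"), cur)
  }
  uo <- units[["out"]]
  fo <- lapply(cur, function(x) conv_fwd_one(uo, x))
  caches[["out"]] <- list(xs = cur, Ps = lapply(fo, `[[`, "P"))
  list(preds = lapply(fo, `[[`, "y"), caches = caches, units = units)
}

# full backward pass; returns gradients per unit
unet_backward <- function(model, caches, units, gpreds) {
  d <- model$spec$depth
  grads <- list()
  uo <- units[["out"]]
  bw <- mapply(function(x, gy, P) conv_bwd_one(uo, x, gy, P),
               caches[["out"]]$xs, gpreds, caches[["out"]]$Ps,
               SIMPLIFY = FALSE)
  grads[["out"]] <- list(gw = Reduce(`+`, lapply(bw, `[[`, "gw")),
                         gb = Reduce(`+`, lapply(bw, `[[`, "gb")))
  cur_g <- lapply(bw, `[[`, "gx")
  skip_g <- vector("list", d)
  two <- model$spec$convs_per_block %||% 1L
  bwd_unit <- function(nm, g) {
    u <- units[[nm]]
    hb <- unit_head_bwd(u, g, caches[[nm]]$head)
    bw <- mapply(function(x, gy, P) conv_bwd_one(u, x, gy, P),
                 caches[[nm]]$xs, hb$gys, caches[[nm]]$Ps, SIMPLIFY = FALSE)
    grads[[nm]] <<- list(gw = Reduce(`+`, lapply(bw, `[[`, "gw")),
                         gb = Reduce(`+`, lapply(bw, `[[`, "gb")),
                         ggamma = hb$ggamma, gbeta = hb$gbeta)
    lapply(bw, `[[`, "gx")
  }
  for (l in seq_len(d - 1)) {
    if (two == 2) cur_g <- bwd_unit(paste0("dec", l, "b"), cur_g)
    nm2 <- paste0("dec", l)
    u2 <- units[[nm2]]
    hb <- unit_head_bwd(u2, cur_g, caches[[nm2]]$head)
    bw <- mapply(function(x, gy, P) conv_bwd_one(u2, x, gy, P),
                 caches[[nm2]]$xs, hb$gys, caches[[nm2]]$Ps, SIMPLIFY = FALSE)
    grads[[nm2]] <- list(gw = Reduce(`+`, lapply(bw, `[[`, "gw")),
                         gb = Reduce(`+`, lapply(bw, `[[`, "gb")),
                         ggamma = hb$ggamma, gbeta = hb$gbeta)
    gcat <- lapply(bw, `[[`, "gx")
    gup <- lapply(gcat, function(a) a[, , , seq_len(dim(a)[4] / 2), drop = FALSE])
    skip_g[[l]] <- lapply(gcat, function(a)
      a[, , , dim(a)[4] / 2 + seq_len(dim(a)[4] / 2), drop = FALSE])
    nm <- paste0("up", l)
    u <- units[[nm]]
    hb <- unit_head_bwd(u, gup, caches[[nm]]$head)
    bw <- mapply(function(x, gy, P) conv_bwd_one(u, x, gy, P),
                 caches[[nm]]$xs, hb$gys, caches[[nm]]$Ps, SIMPLIFY = FALSE)
    grads[[nm]] <- list(gw = Reduce(`+`, lapply(bw, `[[`, "gw")),
                        gb = Reduce(`+`, lapply(bw, `[[`, "gb")),
                        ggamma = hb$ggamma, gbeta = hb$gbeta)
    cur_g <- lapply(bw, `[[`, "gx")
  }
  for (l in rev(seq_len(d))) {
    if (l < d) {
      nm2 <- paste0("down", l)
      u2 <- units[[nm2]]
      hb <- unit_head_bwd(u2, cur_g, caches[[nm2]]$head)
      bw <- mapply(function(x, gy, P) conv_bwd_one(u2, x, gy, P),
                   caches[[nm2]]$xs, hb$gys, caches[[nm2]]$Ps,
                   SIMPLIFY = FALSE)
      grads[[nm2]] <- list(gw = Reduce(`+`, lapply(bw, `[[`, "gw")),
                           gb = Reduce(`+`, lapply(bw, `[[`, "gb")),
                           ggamma = hb$ggamma, gbeta = hb$gbeta)
      cur_g <- lapply(bw, `[[`, "gx")
      cur_g <- mapply(`+`, cur_g, skip_g[[l]], SIMPLIFY = FALSE)
    }
    if (two == 2) cur_g <- bwd_unit(paste0("enc", l, "b"), cur_g)
    cur_g <- bwd_unit(paste0("enc", l), cur_g)
  }
  grads
}

# ---- windows ----------------------------------------------------------------

#' Extract 16-slice training windows from a case
#'
#' Builds the (echo1, echo2, R2*) channel stack, records per-case robust
#' normalization constants (median center, upper-quantile scale per channel),
#' and cuts dense sliding windows of 16 axial slices with the matching CT
#' target slices.
#'
#' @param case a `phantom_case` (needs >= 16 slices).
#' @param stride slice stride between window starts (1 = dense, the inference
#'   contract; larger strides subsample windows for training).
#' @return list with `x` (list of (16,H,W,3) arrays), `y` (list of
#'   (16,H,W,1) HU arrays), `starts` (1-based first slice of each window),
#'   and `norm` (per-channel centers/scales).
#' @export
extract_windows <- function(case, stride = 1L) {
  nslices <- dim(case$ute1)[1]
  if (nslices < 16) stop("volume has fewer than 16 slices")
  # the derived R2* channel uses the same smoothed-echo estimate as the
  # segmentation path; the raw two-point ratio is censoring noise in bone
  # and carries no usable signal for a small network
  sm <- smoothed_echoes(case)
  r2 <- compute_r2star(sm$ute1, sm$ute2, case$te1_ms, case$te2_ms)
  chans <- list(case$ute1, case$ute2, r2)
  norm <- lapply(chans, function(v) {
    ctr <- median(v)
    list(center = ctr, scale = max(quantile(v, 0.99) - ctr, 1e-6))
  })
  chans <- mapply(function(v, nc) (v - nc$center) / nc$scale, chans, norm,
                  SIMPLIFY = FALSE)
  starts <- seq(1L, nslices - 16L + 1L, by = as.integer(stride))
  d <- dim(case$ute1)
  x <- lapply(starts, function(s) {
    w <- array(0, c(16, d[2], d[3], 3))
    for (ch in 1:3) w[, , , ch] <- chans[[ch]][s:(s + 15), , ]
    w
  })
  y <- lapply(starts, function(s) {
    array(case$ct_hu[s:(s + 15), , ], c(16, d[2], d[3], 1))
  })
  list(x = x, y = y, starts = starts, norm = norm)
}

#' Training configuration
#'
#' Published settings: Adam with learning rate 1e-4, mean-squared-error loss
#' in HU, batch size 2, 100 epochs, dense windows. Targets are standardized
#' internally for optimization and predictions are mapped back to HU, so the
#' recorded loss history is in HU^2 either way. Desk-scale runs use fewer
#' epochs, a larger learning rate matched to the much smaller step count, and
#' strided training windows; see [deepute_desk_config()].
#'
#' @param learning_rate Adam step size (>= 0; 0 freezes the network, which is
#'   occasionally useful as a control).
#' @param epochs passes over the training windows.
#' @param batch_size windows per gradient step.
#' @param window_stride slice stride between training windows.
#' @param seed seed for initialization, shuffling and dropout.
#' @param max_restarts He initialization is a lottery at small widths: a few
#'   percent to half of inits stall on a no-bone plateau within a short
#'   epoch budget. After `probe_epochs` epochs, a run whose normalized loss
#'   (fraction of target variance left unexplained) still exceeds
#'   `probe_threshold` is abandoned and reinitialized with a derived seed,
#'   up to `max_restarts` times; if all candidates stall, the best one is
#'   trained to completion. Set 0 to disable.
#' @param probe_epochs,probe_threshold see `max_restarts`.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100, batch_size = 2,
                         window_stride = 1, seed = 1L,
                         max_restarts = 2, probe_epochs = 2,
                         probe_threshold = 0.6) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 window_stride = as.integer(window_stride),
                 seed = as.integer(seed),
                 max_restarts = as.integer(max_restarts),
                 probe_epochs = as.integer(probe_epochs),
                 probe_threshold = probe_threshold),
            class = "train_config")
}

#' Desk-scale training configuration
#' @param epochs,seed see [train_config()].
#' @return a [train_config()] with desk-scale defaults.
#' @export
deepute_desk_config <- function(epochs = 24, seed = 1L) {
  train_config(learning_rate = 6e-3, epochs = epochs, batch_size = 2,
               window_stride = 4, seed = seed)
}

adam_step <- function(model, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$opt)) model$opt <- list()
  for (nm in names(grads)) {
    u <- model$units[[nm]]
    g <- grads[[nm]]
    fields <- c("w" = "gw", "b" = "gb",
                if (u$use_bn) c("gamma" = "ggamma", "beta" = "gbeta"))
    for (f in names(fields)) {
      gv <- g[[fields[[f]]]]
      if (is.null(gv)) next
      key <- paste0(nm, ".", f)
      st <- model$opt[[key]] %||% list(m = 0 * gv, v = 0 * gv)
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$units[[nm]][[f]] <- u[[f]] - lr * mhat / (sqrt(vhat) + eps)
      model$opt[[key]] <- st
    }
  }
  model
}

#' Train the pseudo-CT network
#'
#' Minimizes the mean-squared error between predicted and reference CT over
#' shuffled 16-slice windows with Adam. Deterministic given the config seed.
#'
#' @param model a [build_network()] result (or a trained model to continue).
#' @param cases list of training `phantom_case` objects.
#' @param cfg a [train_config()].
#' @return the trained model with `loss_history` (per-epoch mean loss, HU^2).
#' @export
deepute_train <- function(model, cases, cfg = train_config()) {
  stopifnot(inherits(model, "deepute_model"), inherits(cfg, "train_config"))
  if (!length(cases)) stop("need at least one training case")
  wins <- lapply(cases, extract_windows, stride = cfg$window_stride)
  xs <- do.call(c, lapply(wins, `[[`, "x"))
  ys <- do.call(c, lapply(wins, `[[`, "y"))
  if (is.null(model$target)) {
    ally <- unlist(ys, use.names = FALSE)
    model$target <- list(center = mean(ally), scale = max(sd(ally), 1e-6))
  }
  tc <- model$target
  ys <- lapply(ys, function(y) (y - tc$center) / tc$scale)
  nwin <- length(xs)

  run_epochs <- function(model, epochs, seed) {
    t_step <- length(model$loss_history) * ceiling(nwin / cfg$batch_size)
    with_seed(seed, {
      train_mode <- cfg$learning_rate > 0   # lr 0: pure-evaluation control
      for (ep in seq_len(epochs)) {
        ord <- sample.int(nwin)
        ep_loss <- 0; nb <- 0L
        for (b0 in seq(1, nwin, by = cfg$batch_size)) {
          idx <- ord[b0:min(b0 + cfg$batch_size - 1, nwin)]
          fw <- unet_forward(model, xs[idx], train = train_mode)
          model$units <- fw$units
          resid <- mapply(function(p, y) p - y, fw$preds, ys[idx],
                          SIMPLIFY = FALSE)
          nel <- sum(vapply(resid, length, 0))
          loss <- sum(vapply(resid, function(r) sum(r^2), 0)) / nel
          if (!is.finite(loss))
            stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
          ep_loss <- ep_loss + loss; nb <- nb + 1L
          if (cfg$learning_rate > 0) {
            gpreds <- lapply(resid, function(r) 2 * r / nel)
            grads <- unet_backward(model, fw$caches, fw$units, gpreds)
            t_step <- t_step + 1L
            model <- adam_step(model, grads, cfg$learning_rate, t_step)
          }
        }
        model$loss_history <- c(model$loss_history, ep_loss / nb * tc$scale^2)
      }
    })
    model
  }

  probe_ep <- min(cfg$probe_epochs %||% 0L, cfg$epochs)
  thr <- cfg$probe_threshold %||% Inf
  restarts <- cfg$max_restarts %||% 0L
  if (restarts > 0 && probe_ep > 0 && cfg$learning_rate > 0) {
    best <- NULL
    for (attempt in 0:restarts) {
      cand <- if (attempt == 0) model else
        build_network(model$spec,
                      seed = substream_seed(cfg$seed, "restart", attempt))
      cand$target <- tc
      cand <- run_epochs(cand, probe_ep,
                         substream_seed(cfg$seed, "train", attempt))
      norm_loss <- utils::tail(cand$loss_history, 1) / tc$scale^2
      cand$attempt <- attempt
      if (is.null(best) ||
          norm_loss < utils::tail(best$loss_history, 1) / tc$scale^2)
        best <- cand
      if (norm_loss <= thr) { best <- cand; break }
    }
    model <- best
    model <- run_epochs(model, cfg$epochs - probe_ep,
                        substream_seed(cfg$seed, "train-main", model$attempt))
  } else {
    model <- run_epochs(model, cfg$epochs, substream_seed(cfg$seed, "train"))
  }
  model$trained <- TRUE
  model
}

#' Predict a whole pseudo-CT volume by overlap averaging
#'
#' Runs the network on every dense 16-slice window (stride 1) and averages
#' the predictions of all windows covering each voxel, as done at test time
#' clinically. Averaging happens on the HU scale.
#'
#' @param model a trained `deepute_model`.
#' @param case a `phantom_case`.
#' @return pseudo-CT volume in HU.
#' @export
predict_volume <- function(model, case) {
  wins <- extract_windows(case, stride = 1L)
  d <- dim(case$ute1)
  acc <- array(0, d)
  cnt <- numeric(d[1])
  tc <- model$target %||% list(center = 0, scale = 1)
  for (i in seq_along(wins$x)) {
    fw <- unet_forward(model, wins$x[i], train = FALSE)
    pred <- fw$preds[[1]] * tc$scale + tc$center
    s <- wins$starts[i]
    acc[s:(s + 15), , ] <- acc[s:(s + 15), , ] + pred[, , , 1]
    cnt[s:(s + 15)] <- cnt[s:(s + 15)] + 1
  }
  acc <- sweep(acc, 1, cnt, `/`)
  as_volume(acc, voxel_spacing(case$ute1))
}

#' @export
predict.deepute_model <- function(object, case, ...) {
  predict_volume(object, case)
}

#' Attenuation map from the CNN pseudo-CT
#'
#' @param case a `phantom_case`.
#' @param model a trained `deepute_model` from a fold not containing this
#'   case's subject.
#' @return a [mu_map()] with provenance `"DEEPUTE"`.
#' @export
deepute_map <- function(case, model) {
  pseudo <- predict_volume(model, case)
  pseudo <- pmin(pmax(pseudo, -1000), 3000)
  m <- hu_to_mu(as_volume(array(pseudo, dim(case$ute1)),
                          voxel_spacing(case$ute1)),
                provenance = "DEEPUTE")
  m$classes <- classify_tissue(m$pseudo_ct)
  m
}

#' Subject-level cross-validated training
#'
#' Trains one network per fold on the training subjects only; each case is
#' then predicted by the model whose fold held it out.
#'
#' @param cases list of `phantom_case` objects.
#' @param k folds (published protocol: 4).
#' @param net a [network_spec()].
#' @param cfg a [train_config()].
#' @param seed fold-shuffle seed.
#' @return object of class `deepute_crossval`: models per fold + fold split.
#' @export
deepute_crossval <- function(cases, k = 4, net = network_spec(), cfg = train_config(),
                             seed = 1L) {
  subjects <- vapply(cases, function(cs) cs$subject_id, "")
  split <- kfold_split(subjects, k, seed = seed)
  models <- lapply(seq_len(attr(split, "k")), function(f) {
    train <- which(fold_of(split, subjects) != f)
    cfg_f <- cfg
    cfg_f$seed <- substream_seed(cfg$seed, "fold", f)
    model <- build_network(net, seed = cfg_f$seed)
    deepute_train(model, cases[train], cfg_f)
  })
  structure(list(models = models, split = split), class = "deepute_crossval")
}

#' Model applicable to a given case
#' @param cv a `deepute_crossval`.
#' @param case a `phantom_case`.
#' @return the `deepute_model` trained without this case's subject.
#' @export
model_for_case <- function(cv, case) {
  cv$models[[fold_of(cv$split, case$subject_id)]]
}
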