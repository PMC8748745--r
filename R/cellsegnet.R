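#' @title Compact 3D segmentation network
#'
#' @description A shallow U-Net-style 3D convolutional network for 3-class
#' voxel classification (background / membrane / foreground). The encoder has
#' `n_levels` scales joined by stride-2 convolutions with a residual
#' projection of the 2x-average-pooled input; the decoder uses learned 2x
#' upsampling whose output is trimmed on the trailing edges to match the
#' corresponding encoder map before skip concatenation, so the network maps
#' a cuboid of any extent to logits of the same extent. Training samples
#' variable-size cuboids, which improves robustness at cuboid interfaces.
#'
#' @name cellsegnet
NULL

#' Network configuration
#'
#' @param n_levels Number of resolution levels (default 3).
#' @param base_channels Channels at full resolution (default 16); deeper
#'   levels double the width.
#' @param residual_downsampling Keep the residual projection across the
#'   stride-2 downsampling (default `TRUE`; the supported architecture).
#' @param parameter_budget Soft ceiling on trainable scalars; exceeding it
#'   warns but does not fail.
#' @return A `network_config` list.
#' @export
network_config <- function(n_levels = 3L, base_channels = 16L,
                           residual_downsampling = TRUE,
                           parameter_budget = 1.5e6) {
  stopifnot(n_levels >= 2L, base_channels >= 2L, isTRUE(residual_downsampling))
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = 2L,
                 residual_downsampling = TRUE,
                 parameter_budget = parameter_budget),
            class = "network_config")
}

.he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

.param_shapes <- function(cfg) {
  L <- cfg$n_levels; b <- cfg$base_channels
  sh <- list(stem1_W = c(3, 3, 3, 1, b), stem1_b = b,
             stem2_W = c(3, 3, 3, b, b), stem2_b = b)
  for (l in 2:L) {
    cp <- b * 2^(l - 2); cl <- b * 2^(l - 1)
    sh[[paste0("down", l, "_W")]] <- c(3, 3, 3, cp, cl)
    sh[[paste0("down", l, "_b")]] <- cl
    sh[[paste0("proj", l, "_W")]] <- c(1, 1, 1, cp, cl)
    sh[[paste0("proj", l, "_b")]] <- cl
    sh[[paste0("conv", l, "_W")]] <- c(3, 3, 3, cl, cl)
    sh[[paste0("conv", l, "_b")]] <- cl
  }
  for (l in (L - 1):1) {
    cl <- b * 2^(l - 1); cd <- b * 2^l
    sh[[paste0("up", l, "_W")]] <- c(2, 2, 2, cd, cl)
    sh[[paste0("up", l, "_b")]] <- cl
    sh[[paste0("dec", l, "_W")]] <- c(3, 3, 3, 2 * cl, cl)
    sh[[paste0("dec", l, "_b")]] <- cl
  }
  sh$head_W <- c(1, 1, 1, b, 3)
  sh$head_b <- 3
  sh
}

#' Build (initialize) a segmentation network
#'
#' He-normal weight initialization, zero biases; deterministic for a fixed
#' seed. Warns (without failing) if the parameter count exceeds the
#' configured budget.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for the initialization.
#' @return A `cellseg_net` object (list with `config` and `params`).
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  sh <- .param_shapes(cfg)
  params <- .with_seed(seed, {
    lapply(names(sh), function(nm) {
      d <- sh[[nm]]
      if (grepl("_b$", nm)) return(numeric(d))
      fan_in <- prod(d[1:4])
      .he_init(d, fan_in)
    })
  })
  names(params) <- names(sh)
  net <- structure(list(config = cfg, params = params), class = "cellseg_net")
  np <- count_parameters(net)
  if (np > cfg$parameter_budget)
    warning("network has ", np, " parameters, exceeding the budget of ",
            cfg$parameter_budget)
  net
}

#' Count trainable parameters of a network
#' @param net A `cellseg_net`.
#' @return Integer scalar.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

#' @export
print.cellseg_net <- function(x, ...) {
  cat("cellseg_net:", x$config$n_levels, "levels,",
      x$config$base_channels, "base channels,",
      count_parameters(x), "parameters\n")
  invisible(x)
}

.softmax4 <- function(logits) {
  m <- pmax(logits[, , , 1], logits[, , , 2], logits[, , , 3])
  e <- exp(logits - as.vector(m))
  s <- e[, , , 1] + e[, , , 2] + e[, , , 3]
  e / as.vector(s)
}

# forward pass on one cuboid; returns probs (and the backward cache handle)
.net_forward <- function(net, x, want_cache = FALSE) {
  r <- cpp_net_forward(as.numeric(x), dim(x), net$params,
                       net$config$n_levels, net$config$base_channels,
                       want_cache)
  logits <- r$logits
  list(probs = .softmax4(logits), logits = logits, cache = r$cache)
}

#' Run the network on a single cuboid
#'
#' @param net A `cellseg_net` (trained or freshly built).
#' @param x Numeric 3D array `(Z, Y, X)`.
#' @return 4D array `(Z, Y, X, 3)` of class probabilities summing to 1 per
#'   voxel (softmax output), class order background / membrane / foreground.
#' @export
forward_network <- function(net, x) {
  .net_forward(net, x, want_cache = FALSE)$probs
}

#' Per-voxel class decision
#'
#' Argmax over the class axis with ties broken by class priority
#' foreground > membrane > background; the returned masks partition the
#' volume.
#'
#' @param probs 4D array `(Z, Y, X, 3)` of class probabilities.
#' @return List of `background`, `membrane`, `foreground` 0/1 masks.
#' @export
semantic_argmax <- function(probs) {
  d <- dim(probs)[1:3]
  m <- matrix(probs, ncol = 3L)
  cls <- max.col(m, ties.method = "last")  # class order makes last = priority
  masks <- lapply(1:3, function(c) array(as.integer(cls == c), d))
  names(masks) <- .canonical_classes
  masks
}

#' Training configuration
#'
#' @param cuboid_min,cuboid_max Minimum / maximum training cuboid extents
#'   per axis (defaults 56^3 and 64^3); each draw picks a uniform extent in
#'   the range.
#' @param batch_size Cuboids per optimization step (default 7).
#' @param learning_rate Adam step size (constant over the run).
#' @param steps Number of optimization steps.
#' @param seed RNG seed for sampling and initialization.
#' @param alpha Loss regularization constant.
#' @param w_min Interior floor of the reverse-distance weights.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @return A `train_config` list.
#' @export
train_config <- function(cuboid_min = c(56L, 56L, 56L),
                         cuboid_max = c(64L, 64L, 64L),
                         batch_size = 7L, learning_rate = 1e-3,
                         steps = 200L, seed = 1L, alpha = 0.1, w_min = 0.5,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  cuboid_min <- rep(as.integer(cuboid_min), length.out = 3L)
  cuboid_max <- rep(as.integer(cuboid_max), length.out = 3L)
  stopifnot(all(cuboid_min <= cuboid_max), batch_size >= 1L, steps >= 0L,
            learning_rate > 0, alpha > 0, w_min > 0, w_min <= 1)
  structure(list(cuboid_min = cuboid_min, cuboid_max = cuboid_max,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, steps = as.integer(steps),
                 seed = as.integer(seed), alpha = alpha, w_min = w_min,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

# reflective padding of a 3D array up to the given minimum extent
.pad_reflect <- function(a, min_extent) {
  d <- dim(a)
  need <- pmax(min_extent - d, 0L)
  if (all(need == 0L)) return(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; len <- max(n, min_extent[ax])
    if (n == 1L) return(rep(1L, len))
    j <- (seq_len(len) - 1L) %% (2L * n - 2L)
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Sampler of variable-size training cuboids
#'
#' Returns a closure that, on each call, draws a uniform random extent in
#' `[cuboid_min, cuboid_max]` per axis and a uniform random origin, and
#' returns the corresponding crops of the image, masks and weights. The
#' sequence is deterministic for a fixed seed and independent of the
#' caller's RNG state. Volumes smaller than `cuboid_min` are padded
#' reflectively first.
#'
#' @param image Intensity volume `(Z, Y, X)`.
#' @param masks List of the three class masks.
#' @param weights List of the three class weight volumes.
#' @param cfg A [train_config()].
#' @param seed Sampler seed (defaults to `cfg$seed`).
#' @return Function returning `list(x =, g =, w =)` on each call.
#' @export
sample_training_cuboids <- function(image, masks, weights, cfg = train_config(),
                                    seed = cfg$seed) {
  pad_to <- pmax(dim(image), cfg$cuboid_min)
  image <- .pad_reflect(image, pad_to)
  masks <- lapply(masks, .pad_reflect, min_extent = pad_to)
  weights <- lapply(weights, .pad_reflect, min_extent = pad_to)
  d <- dim(image)
  state <- .with_seed(seed, get(".Random.seed", envir = globalenv()))
  function() {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    ext <- vapply(1:3, function(a)
      if (cfg$cuboid_min[a] >= d[a]) d[a] else
        sample(cfg$cuboid_min[a]:min(cfg$cuboid_max[a], d[a]), 1L), integer(1))
    org <- vapply(1:3, function(a)
      sample.int(d[a] - ext[a] + 1L, 1L), integer(1))
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    zi <- org[1]:(org[1] + ext[1] - 1L)
    yi <- org[2]:(org[2] + ext[2] - 1L)
    xi <- org[3]:(org[3] + ext[3] - 1L)
    g <- array(0, c(ext, 3L)); w <- array(1, c(ext, 3L))
    for (c in 1:3) {
      g[, , , c] <- masks[[.canonical_classes[c]]][zi, yi, xi]
      w[, , , c] <- weights[[.canonical_classes[c]]][zi, yi, xi]
    }
    list(x = image[zi, yi, xi, drop = FALSE], g = g, w = w,
         origin = org, extent = ext)
  }
}

#' Train the semantic segmentation network
#'
#' Minimizes [total_loss()] by Adam over variable-size cuboids sampled from
#' the training volumes. Masks and reverse-distance weights are derived from
#' the label volumes. Supports warm starting from an existing network
#' (fine-tuning / transfer mode); `steps = 0` then returns the warm-start
#' parameters unchanged.
#'
#' @param dataset List of training pairs, each `list(intensity =, labels =)`.
#' @param cfg A [train_config()].
#' @param net_cfg A [network_config()] (ignored when `init` is given).
#' @param init Optional `cellseg_net` to warm-start from.
#' @param membrane_thickness Membrane thickness used to derive masks from
#'   the label volumes.
#' @param verbose Print a progress line every 50 steps.
#' @return List with `net` (trained `cellseg_net`) and `log`, a
#'   `training_log` data frame of per-step loss terms plus the config
#'   snapshot as attributes.
#' @export
train_semantic_model <- function(dataset, cfg = train_config(),
                                 net_cfg = network_config(), init = NULL,
                                 membrane_thickness = 2, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  net <- if (is.null(init)) build_network(net_cfg, seed = cfg$seed) else init
  samplers <- lapply(seq_along(dataset), function(i) {
    pair <- dataset[[i]]
    masks <- semantic_masks_from_labels(pair$labels, membrane_thickness)
    weights <- lapply(masks, reverse_distance_weights, w_min = cfg$w_min)
    sample_training_cuboids(pair$intensity, masks, weights, cfg,
                            seed = cfg$seed + i)
  })
  n_par <- length(net$params)
  m <- lapply(net$params, function(p) array(0, dim(as.array(p))))
  v <- m
  log_rows <- vector("list", cfg$steps)
  pick <- .with_seed(cfg$seed + 104729L,
                     sample.int(length(dataset), max(cfg$steps, 1L) *
                                  cfg$batch_size, replace = TRUE))
  k <- 0L
  for (step in seq_len(cfg$steps)) {
    grads <- NULL
    tot <- fg <- oth <- 0
    for (b in seq_len(cfg$batch_size)) {
      k <- k + 1L
      cub <- samplers[[pick[k]]]()
      fwd <- .net_forward(net, cub$x, want_cache = TRUE)
      lb <- total_loss(fwd$probs, cub$g, cub$w, alpha = cfg$alpha)
      if (!is.finite(lb$total))
        stop("training diverged: non-finite loss at step ", step, call. = FALSE)
      dP <- total_loss_gradient(fwd$probs, cub$g, cub$w, alpha = cfg$alpha)
      # softmax backward: dlogits_c = p_c * (dp_c - sum_c dp_c p_c)
      p <- fwd$probs
      inner <- p[, , , 1] * dP[, , , 1] + p[, , , 2] * dP[, , , 2] +
        p[, , , 3] * dP[, , , 3]
      dlogits <- p * (dP - as.vector(inner)) / cfg$batch_size
      g <- cpp_net_backward(fwd$cache, dlogits, net$params)
      grads <- if (is.null(grads)) g else
        setNames(lapply(names(g), function(nm) grads[[nm]] + g[[nm]]),
                 names(g))
      tot <- tot + lb$total / cfg$batch_size
      fg <- fg + lb$foreground_term / cfg$batch_size
      oth <- oth + lb$others_term / cfg$batch_size
    }
    t_ <- step
    for (nm in names(net$params)) {
      gr <- grads[[nm]]
      m[[nm]] <- cfg$beta1 * m[[nm]] + (1 - cfg$beta1) * gr
      v[[nm]] <- cfg$beta2 * v[[nm]] + (1 - cfg$beta2) * gr^2
      mh <- m[[nm]] / (1 - cfg$beta1^t_)
      vh <- v[[nm]] / (1 - cfg$beta2^t_)
      net$params[[nm]] <- net$params[[nm]] -
        cfg$learning_rate * mh / (sqrt(vh) + cfg$epsilon)
    }
    log_rows[[step]] <- data.frame(step = step, total = tot,
                                   foreground = fg, others = oth)
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d  loss %.4f (fg %.4f + others %.4f)",
                      step, tot, fg, oth))
  }
  log <- if (cfg$steps > 0) do.call(rbind, log_rows) else
    data.frame(step = integer(0), total = numeric(0),
               foreground = numeric(0), others = numeric(0))
  attr(log, "train_config") <- cfg
  attr(log, "network_config") <- net$config
  class(log) <- c("training_log", class(log))
  list(net = net, log = log)
}

#' Predict class probabilities for a full volume
#'
#' Runs the network tile by tile following a tiling layout and stitches the
#' per-tile probabilities from tile core regions (overlap margins
#' discarded). Optionally the volume is mirror-padded by `border` voxels on
#' every face first (overlap-tile style), moving convolution border effects
#' into padding that is cropped away; the default is no border padding,
#' which keeps the input distribution identical to training crops. Volumes
#' smaller than the network's comfortable minimum (8 voxels per axis) are
#' padded reflectively as needed.
#'
#' @param image Intensity volume `(Z, Y, X)`.
#' @param net A trained `cellseg_net`.
#' @param layout Optional [plan_tiles()] layout for the padded extent;
#'   defaults to tiles of `tile_extent` with `overlap`.
#' @param tile_extent,overlap Defaults used when `layout` is `NULL`.
#' @param border Mirror-padding width in voxels (default 0: none).
#' @return 4D array `(Z, Y, X, 3)` of class probabilities.
#' @export
predict_semantic_volume <- function(image, net, layout = NULL,
                                    tile_extent = c(64L, 64L, 64L),
                                    overlap = c(8L, 8L, 8L),
                                    border = 0L) {
  d0 <- dim(image)
  padded <- .mirror_pad(image, rep(as.integer(border), 3L))
  padded <- .pad_reflect(padded, pmax(dim(padded), 8L))
  d <- dim(padded)
  if (is.null(layout)) layout <- plan_tiles(d, tile_extent, overlap)
  stopifnot(all(layout$extent == d))
  tiles <- lapply(layout$tiles, function(tl) {
    lo <- tl$tile[, "lo"]; hi <- tl$tile[, "hi"]
    forward_network(net, padded[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                drop = FALSE])
  })
  probs <- stitch_probability_tiles(layout, tiles)
  probs[border + seq_len(d0[1]), border + seq_len(d0[2]),
        border + seq_len(d0[3]), , drop = FALSE]
}

# symmetric mirror padding (no repeated edge voxel) on all six faces
.mirror_pad <- function(a, pad) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; p <- min(pad[ax], n - 1L)
    c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Save / load a network checkpoint
#'
#' The checkpoint holds the parameters together with the architecture
#' configuration snapshot.
#'
#' @param net A `cellseg_net`.
#' @param path Checkpoint file path (RDS).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "cellseg_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "cellseg_net"))
  net
}
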