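test_that("the default network respects the parameter budget", {
  net <- build_network(network_config(), seed = 1)
  expect_lte(count_parameters(net), 1.5e6)
  expect_gt(count_parameters(net), 1e5)
  # initialization is deterministic per seed
  net2 <- build_network(network_config(), seed = 1)
  expect_identical(net$params, net2$params)
})

test_that("output extent equals input extent for cubic and non-cubic cuboids", {
  net <- build_network(network_config(), seed = 2)
  for (ext in list(c(16, 16, 16), c(20, 16, 12), c(15, 13, 11),
                   c(9, 17, 23))) {
    probs <- forward_network(net, array(rnorm(prod(ext)), ext))
    expect_identical(dim(probs), c(as.integer(ext), 3L))
    s <- probs[, , , 1] + probs[, , , 2] + probs[, , , 3]
    expect_lt(max(abs(s - 1)), 1e-5)
  }
})

test_that("argmax masks partition the volume and honor the tie priority", {
  d <- c(4, 4, 4)
  p <- random_probs(d, 31)
  m <- semantic_argmax(p)
  expect_true(all(m$background + m$membrane + m$foreground == 1L))
  # one-hot input reproduces itself
  g <- random_masks4(d, 32)
  m2 <- semantic_argmax(g)
  expect_identical(m2$background, array(as.integer(g[, , , 1]), d))
  # exact foreground/membrane tie goes to foreground
  tie <- array(1 / 3, c(1, 1, 1, 3))
  tie[1, 1, 1, ] <- c(0.2, 0.4, 0.4)
  mt <- semantic_argmax(tie)
  expect_identical(mt$foreground[1, 1, 1], 1L)
  tie[1, 1, 1, ] <- c(0.4, 0.4, 0.2)  # background/membrane tie -> membrane
  expect_identical(semantic_argmax(tie)$membrane[1, 1, 1], 1L)
})

test_that("cuboid sampling is deterministic, in range, and a true crop", {
  ex <- gt_phantom(c(40, 40, 40), 8, 17)
  weights <- lapply(ex$masks, reverse_distance_weights)
  cfg <- train_config(cuboid_min = c(20, 20, 20), cuboid_max = c(28, 28, 28),
                      seed = 5)
  s1 <- sample_training_cuboids(ex$ph$intensity, ex$masks, weights, cfg)
  s2 <- sample_training_cuboids(ex$ph$intensity, ex$masks, weights, cfg)
  for (i in 1:20) {
    a <- s1(); b <- s2()
    expect_identical(a, b)
    expect_true(all(dim(a$x) >= 20 & dim(a$x) <= 28))
    lo <- a$origin; hi <- a$origin + a$extent - 1L
    expect_identical(a$x,
                     ex$ph$intensity[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    expect_identical(a$g[, , , 2],
                     ex$masks$membrane[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] * 1)
  }
  # sampling must not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(s1()); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("warm start with zero steps returns the initial parameters", {
  ex <- gt_phantom(c(24, 24, 24), 2, 41)
  init <- build_network(network_config(n_levels = 2, base_channels = 4),
                        seed = 9)
  fit <- train_semantic_model(list(list(intensity = ex$ph$intensity,
                                        labels = ex$ph$labels)),
                              train_config(steps = 0, cuboid_min = 16,
                                           cuboid_max = 16, batch_size = 1),
                              init = init)
  expect_identical(fit$net$params, init$params)
  expect_identical(nrow(fit$log), 0L)
})

test_that("a brief training run reduces the loss on a small phantom", {
  ex <- gt_phantom(c(32, 32, 32), 4, 55, noise_sd = 0.05)
  cfg <- train_config(cuboid_min = c(20, 20, 20), cuboid_max = c(24, 24, 24),
                      batch_size = 1, steps = 40, seed = 3,
                      learning_rate = 2e-3)
  fit <- train_semantic_model(list(list(intensity = ex$ph$intensity,
                                        labels = ex$ph$labels)),
                              cfg, network_config(n_levels = 2,
                                                  base_channels = 8))
  expect_identical(nrow(fit$log), 40L)
  expect_lt(mean(tail(fit$log$total, 10)), mean(head(fit$log$total, 10)))
  # training is reproducible for a fixed seed on one device
  fit2 <- train_semantic_model(list(list(intensity = ex$ph$intensity,
                                         labels = ex$ph$labels)),
                               cfg, network_config(n_levels = 2,
                                                   base_channels = 8))
  expect_identical(fit$net$params, fit2$net$params)
})

test_that("tiled prediction equals the direct forward pass on one tile", {
  net <- build_network(network_config(n_levels = 2, base_channels = 4),
                       seed = 4)
  x <- array(rnorm(18^3), c(18, 18, 18))
  lay <- plan_tiles(c(18, 18, 18), c(18, 18, 18))
  expect_equal(predict_semantic_volume(x, net, lay), forward_network(net, x))
})

test_that("different tilings agree except at rare boundary voxels", {
  net <- build_network(network_config(n_levels = 2, base_channels = 4),
                       seed = 6)
  ex <- gt_phantom(c(36, 36, 36), 6, 61)
  p1 <- predict_semantic_volume(ex$ph$intensity, net,
                                tile_extent = c(36, 36, 36))
  p2 <- predict_semantic_volume(ex$ph$intensity, net,
                                tile_extent = c(24, 24, 24),
                                overlap = c(8, 8, 8))
  a1 <- semantic_argmax(p1); a2 <- semantic_argmax(p2)
  agree <- mean(a1$foreground == a2$foreground & a1$membrane == a2$membrane)
  expect_gte(agree, 0.99)
})

test_that("checkpoints round-trip through save and load", {
  net <- build_network(network_config(n_levels = 2, base_channels = 4),
                       seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  expect_identical(load_network(f)$params, net$params)
})
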