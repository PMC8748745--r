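test_that("reverse-distance weights follow the boundary-to-interior ramp", {
  # uniform-depth slab: single distance value, weights all one
  slab <- array(0L, c(7, 7, 7)); slab[4, , ] <- 1L
  expect_true(all(reverse_distance_weights(slab) == 1))
  # solid 9^3 cube: boundary voxels 1, center w_min
  cube <- array(0L, c(11, 11, 11)); cube[2:10, 2:10, 2:10] <- 1L
  w <- reverse_distance_weights(cube, w_min = 0.5)
  expect_equal(w[2, 5, 5], 1)        # face-adjacent to outside
  expect_equal(w[6, 6, 6], 0.5)      # deepest interior
  expect_true(all(w[cube == 0L] == 1))
  expect_true(all(w > 0 & w <= 1))
  # empty mask: all ones
  expect_true(all(reverse_distance_weights(array(0L, c(4, 4, 4))) == 1))
})

test_that("confidence replacement has the stated fixed points and shape", {
  expect_equal(confidence_transform(0), 0)
  expect_equal(confidence_transform(0.1, alpha = 0.1), 0.5)
  expect_equal(confidence_transform(1, alpha = 0.1), 0.909091, tolerance = 1e-6)
  p <- seq(0, 1, by = 0.01)
  r <- confidence_transform(p)
  expect_true(all(diff(r) > 0))  # strictly increasing
  expect_true(all(r < 1))
})

test_that("Dice and foreground terms match a scalar-arithmetic oracle", {
  # p = g binary, unit weights: zero loss
  g <- array(c(1, 0, 1, 0, 0, 1, 1, 0), c(2, 2, 2))
  expect_identical(dice_term(g, g), 0)
  # p = 0 against positives: maximal loss 1
  expect_equal(dice_term(array(0, c(2, 2, 2)), g), 1)
  expect_equal(foreground_term(array(0, c(2, 2, 2)), g), 1)
  # both empty: degenerate denominator handled as 0
  z <- array(0, c(2, 2, 2))
  expect_identical(dice_term(z, z), 0)
  expect_identical(foreground_term(z, z), 0)
  # random case vs independent scalar recomputation
  set.seed(4)
  p <- array(runif(8), c(2, 2, 2))
  w <- array(runif(8, 0.5, 1), c(2, 2, 2))
  oracle <- 1 - 2 * sum(p * g * w) / (sum(p^2) + sum(g^2))
  expect_equal(dice_term(p, g, w), oracle, tolerance = 1e-12)
  r <- p / (p + 0.1)
  oracle_fg <- 1 - 2 * sum(r * g * w) / (sum(r^2) + sum(g^2))
  expect_equal(foreground_term(p, g, w, 0.1), oracle_fg, tolerance = 1e-12)
})

test_that("the foreground term reduces to plain Dice as alpha vanishes", {
  set.seed(11)
  for (i in 1:5) {
    # the replacement tends to the identity on binary predictions
    p <- array(rbinom(27, 1, 0.5) * 1.0, c(3, 3, 3))
    g <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    w <- array(runif(27, 0.5, 1), c(3, 3, 3))
    expect_equal(foreground_term(p, g, w, alpha = 1e-12),
                 dice_term(p, g, w), tolerance = 1e-6)
    expect_identical(dice_term(g * 1.0, g), 0)
  }
})

test_that("a perfect prediction keeps the residual foreground penalty", {
  d <- c(3, 3, 3)
  g4 <- random_masks4(d, 8)
  lb <- total_loss(g4, g4, NULL, alpha = 0.1)
  expect_equal(lb$others_term, 0)
  expect_lt(abs(lb$foreground_term - 0.004525), 1e-6)
  expect_equal(lb$total, lb$foreground_term + lb$others_term)
  # the residual value is independent of the number of positive voxels
  g1 <- array(0, c(1, 1, 1, 3)); g1[1, 1, 1, 3] <- 1
  expect_lt(abs(total_loss(g1, g1)$foreground_term - 0.004525), 1e-6)
})

test_that("total loss stays in [0, 2] and the books balance", {
  for (seed in 1:6) {
    d <- c(4, 4, 4)
    p <- random_probs(d, seed)
    g <- random_masks4(d, seed + 100)
    w <- array(runif(prod(d) * 3, 0.5, 1), c(d, 3))
    lb <- total_loss(p, g, w)
    expect_gte(lb$total, 0); expect_lte(lb$total, 2)
    expect_gte(lb$foreground_term, 0); expect_lte(lb$foreground_term, 1)
    expect_gte(lb$others_term, 0); expect_lte(lb$others_term, 1)
    expect_equal(lb$total, lb$foreground_term + lb$others_term)
  }
  # uniform p = 1/3
  d <- c(4, 4, 4)
  u <- array(1 / 3, c(d, 3))
  lb <- total_loss(u, random_masks4(d, 3))
  expect_gte(lb$total, 0); expect_lte(lb$total, 2)
})

test_that("analytic gradient matches central finite differences", {
  h <- 1e-5
  worst <- 0
  for (seed in 1:10) {
    d <- c(6, 6, 6)
    p <- random_probs(d, seed)
    g <- random_masks4(d, seed + 50)
    w <- array(runif(prod(d) * 3, 0.5, 1), c(d, 3))
    gr <- total_loss_gradient(p, g, w)
    set.seed(seed)
    for (k in 1:6) {
      idx <- matrix(c(sample(6, 3, TRUE), sample(3, 1)), 1)
      pp <- p; pp[idx] <- pp[idx] + h
      pm <- p; pm[idx] <- pm[idx] - h
      fd <- (total_loss(pp, g, w)$total - total_loss(pm, g, w)$total) / (2 * h)
      rel <- abs(fd - gr[idx]) / max(abs(fd), 1e-8)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the regularizer penalizes low confidence most heavily", {
  # single positive voxel: |dL/dp| at p = 0.1 exceeds |dL/dp| at p = 0.5
  g <- array(1, c(1, 1, 1))
  g10 <- loss_gradient_foreground(array(0.1, c(1, 1, 1)), g, alpha = 0.1)
  g50 <- loss_gradient_foreground(array(0.5, c(1, 1, 1)), g, alpha = 0.1)
  expect_gt(abs(g10), abs(g50))
  # near 1 the regularized gradient is flatter than plain Dice
  p9 <- array(0.95, c(1, 1, 1))
  plain <- cellseg3d:::.dice_grad(p9, g, array(1, c(1, 1, 1)))
  expect_lt(abs(loss_gradient_foreground(p9, g)), abs(plain))
  # qualitative profile: steep below 0.2, monotonically flattening
  ps <- c(0.05, 0.1, 0.2, 0.5, 0.9)
  mags <- vapply(ps, function(p)
    abs(loss_gradient_foreground(array(p, c(1, 1, 1)), g)), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("false-positive voxels are pushed down by the Dice gradient", {
  # voxel with g = 0 amid correct positives: gradient >= 0 on that voxel
  g <- array(c(1, 1, 1, 0), c(4, 1, 1))
  p <- array(c(0.9, 0.9, 0.9, 0.6), c(4, 1, 1))
  gr <- cellseg3d:::.dice_grad(p, g, array(1, c(4, 1, 1)))
  expect_gte(gr[4, 1, 1], 0)
})

test_that("increasing confidence at a true positive never raises the loss", {
  set.seed(13)
  d <- c(4, 4, 4)
  g <- random_masks4(d, 77)
  p <- random_probs(d, 78)
  pos <- which(g[, , , 3] == 1)[1:5]
  base <- total_loss(p, g)$foreground_term
  for (i in pos) {
    for (delta in c(0.05, 0.2)) {
      p2 <- p
      fg2 <- p2[, , , 3]; fg2[i] <- min(fg2[i] + delta, 1)
      p2[, , , 3] <- fg2
      expect_lte(total_loss(p2, g)$foreground_term, base + 1e-12)
    }
  }
})
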