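test_that("Jaccard and Dice follow their set definitions", {
  a <- 1:10
  expect_identical(jaccard(a, a), 1)
  expect_identical(dsc(a, a), 1)
  expect_identical(jaccard(1:5, 6:10), 0)
  expect_identical(dsc(1:5, 6:10), 0)
  expect_equal(jaccard(1:5, 1:10), 0.5)
  expect_equal(dsc(1:5, 1:10), 2 * 5 / 15)
  expect_identical(jaccard(integer(0), integer(0)), 1)
  expect_identical(dsc(integer(0), integer(0)), 1)
  # JI <= DSC for random sets (algebraic identity)
  set.seed(5)
  for (i in 1:20) {
    s <- sample(1:50, sample(1:30, 1))
    g <- sample(1:50, sample(1:30, 1))
    expect_lte(jaccard(s, g), dsc(s, g) + 1e-12)
  }
})

test_that("instance matching picks the maximal-overlap prediction", {
  lab <- array(0L, c(6, 6, 1))
  lab[1:3, , 1] <- 1L; lab[4:6, , 1] <- 2L
  # identity match
  m <- match_instances(lab, lab)
  expect_identical(m$pred_id, m$gt_id)
  expect_identical(m$intersection, c(18L, 18L))
  expect_true(all(m$ji == 1) && all(m$dsc == 1))
  # label permutation leaves scores unchanged
  perm <- lab; perm[lab == 1L] <- 9L; perm[lab == 2L] <- 4L
  m2 <- match_instances(perm, lab)
  expect_identical(m2$ji, m$ji)
  # a 60/40 split matches the 60% instance
  pred <- array(0L, c(10, 1, 1)); gt <- array(0L, c(10, 1, 1))
  gt[1:10, 1, 1] <- 1L
  pred[1:6, 1, 1] <- 5L; pred[7:10, 1, 1] <- 3L
  m3 <- match_instances(pred, gt)
  expect_identical(m3$pred_id, 5L)
  # zero overlap: JI = DSC = 0, no match
  m4 <- match_instances(array(0L, c(4, 1, 1)),
                        array(rep(1L, 4), c(4, 1, 1)))
  expect_true(is.na(m4$pred_id)) ; expect_identical(m4$ji, 0)
  expect_error(match_instances(lab, array(0L, c(2, 2, 2))), "shape")
})

test_that("adapted Rand error matches exhaustive pair counting", {
  lab <- array(0L, c(8, 1, 1))
  lab[1:4, 1, 1] <- 1L; lab[5:8, 1, 1] <- 2L
  expect_equal(adapted_rand_error(lab, lab)$are, 0)
  # two equal cells merged into one prediction: brute-force same-pair count
  merged <- array(0L, c(8, 1, 1)); merged[1:8, 1, 1] <- 1L
  r <- adapted_rand_error(merged, lab)
  # exhaustive enumeration over all ordered voxel pairs (n = 8)
  p <- as.integer(merged); g <- as.integer(lab)
  pairs <- expand.grid(i = 1:8, j = 1:8)
  same_p <- p[pairs$i] == p[pairs$j]
  same_g <- g[pairs$i] == g[pairs$j]
  prec_bf <- sum(same_p & same_g) / sum(same_p)
  rec_bf <- sum(same_p & same_g) / sum(same_g)
  expect_equal(r$precision, prec_bf)
  expect_equal(r$recall, rec_bf)
  expect_equal(r$are, 1 - 2 * prec_bf * rec_bf / (prec_bf + rec_bf))
  # invariant under label permutation
  perm <- lab; perm[lab == 1L] <- 7L; perm[lab == 2L] <- 3L
  expect_equal(adapted_rand_error(perm, lab)$are, 0)
  expect_error(adapted_rand_error(array(0L, c(2, 2, 2)),
                                  array(0L, c(2, 2, 2))), "background")
})

test_that("variation of information separates split and merge errors", {
  lab <- array(0L, c(8, 1, 1))
  lab[1:4, 1, 1] <- 1L; lab[5:8, 1, 1] <- 2L
  expect_equal(variation_of_information(lab, lab),
               list(voi_split = 0, voi_merge = 0))
  merged <- array(1L, c(8, 1, 1))
  expect_equal(variation_of_information(merged, lab),
               list(voi_split = 0, voi_merge = 1))
  # one cell split into two equal halves: (1, 0)
  split <- lab
  gt1 <- array(1L, c(8, 1, 1))
  expect_equal(variation_of_information(split, gt1),
               list(voi_split = 1, voi_merge = 0))
  # swapping the roles exchanges the components
  v1 <- variation_of_information(merged, lab)
  v2 <- variation_of_information(lab, merged)
  expect_equal(v1$voi_split, v2$voi_merge)
  expect_equal(v1$voi_merge, v2$voi_split)
})

test_that("the evaluation report aggregates a hand-built toy volume correctly", {
  gt <- array(0L, c(12, 1, 1))
  gt[1:4, 1, 1] <- 1L; gt[5:8, 1, 1] <- 2L; gt[9:12, 1, 1] <- 3L
  expect_warning(rep0 <- evaluate_segmentation(gt, gt), NA)
  expect_equal(rep0$avg_ji, 1); expect_equal(rep0$avg_dsc, 1)
  expect_equal(rep0$frac_ji_gt_70, 1); expect_equal(rep0$frac_dsc_gt_50, 1)
  expect_equal(rep0$are, 0)
  expect_equal(rep0$voi_split, 0); expect_equal(rep0$voi_merge, 0)

  # prediction: cell 1 exact; cells 2+3 merged into one instance
  pred <- array(0L, c(12, 1, 1))
  pred[1:4, 1, 1] <- 4L; pred[5:12, 1, 1] <- 6L
  rep1 <- evaluate_segmentation(pred, gt)
  # independent scalar recomputation: JI(cell1) = 1, JI(2) = JI(3) = 4/8
  expect_equal(rep1$avg_ji, mean(c(1, 0.5, 0.5)))
  expect_equal(rep1$avg_dsc, mean(c(1, 2 * 4 / 12, 2 * 4 / 12)))
  expect_equal(rep1$frac_ji_gt_70, 1 / 3)   # strict >
  expect_equal(rep1$frac_ji_gt_50, 1 / 3)   # 0.5 is not > 0.5
  expect_equal(rep1$frac_dsc_gt_50, 1)      # 0.667 > 0.5
  expect_gte(rep1$frac_ji_gt_50, rep1$frac_ji_gt_70)
  expect_gte(rep1$frac_dsc_gt_50, rep1$frac_dsc_gt_70)
  expect_gt(rep1$are, 0)
  expect_equal(rep1$voi_merge, 2 / 3)  # H(gt|pred): 8 of 12 voxels in a 50/50 mix
  expect_equal(rep1$voi_split, 0)
})

test_that("all metrics are invariant to label permutations of either input", {
  set.seed(77)
  gt <- array(sample(0:4, 5^3, TRUE), c(5, 5, 5))
  pred <- array(sample(0:3, 5^3, TRUE), c(5, 5, 5))
  shuf <- function(l, from, to) { out <- l
    for (i in seq_along(from)) out[l == from[i]] <- to[i]
    out }
  pred_p <- shuf(pred, 1:3, c(9L, 7L, 8L))
  gt_p <- shuf(gt, 1:4, c(12L, 11L, 14L, 13L))
  r0 <- evaluate_segmentation(pred, gt)
  r1 <- evaluate_segmentation(pred_p, gt_p)
  for (f in c("avg_ji", "avg_dsc", "are", "voi_split", "voi_merge",
              "frac_ji_gt_70", "frac_dsc_gt_50"))
    expect_equal(r1[[f]], r0[[f]], info = f)
})
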