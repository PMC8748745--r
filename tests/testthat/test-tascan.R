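test_that("touching geometry counts faces exactly", {
  # a single 1x1x1 supervoxel has surface 6
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  g <- build_touching_graph(one)
  expect_identical(g$nodes$surface, 6)
  expect_identical(nrow(g$edges), 0L)
  # two 3^3 cubes sharing a full face: S_u = 54, S_uv = 9
  two <- array(0L, c(8, 5, 5))
  two[1:3, 1:3, 1:3] <- 1L; two[4:6, 1:3, 1:3] <- 2L
  g2 <- build_touching_graph(two)
  expect_identical(g2$nodes$surface, c(54, 54))
  expect_identical(g2$edges$area, 9)
  # volume boundary faces count toward the surface
  corner <- array(0L, c(2, 2, 2)); corner[1, 1, 1] <- 1L
  expect_identical(build_touching_graph(corner)$nodes$surface, 6)
  # edge-diagonal contact is not a touching face
  diag2 <- array(0L, c(3, 3, 3)); diag2[1, 1, 1] <- 1L; diag2[2, 2, 1] <- 2L
  expect_identical(nrow(build_touching_graph(diag2)$edges), 0L)
})

test_that("touching graph invariants hold on random labelings", {
  for (seed in 1:4) {
    set.seed(seed)
    lab <- array(sample(0:5, 6^3, TRUE), c(6, 6, 6))
    g <- build_touching_graph(lab)
    su <- setNames(g$nodes$surface, g$nodes$id)
    expect_true(all(g$edges$area <=
                    pmin(su[as.character(g$edges$u)],
                         su[as.character(g$edges$v)])))
    per_u <- tapply(c(g$edges$area, g$edges$area),
                    c(g$edges$u, g$edges$v), sum)
    expect_true(all(per_u <= su[names(per_u)]))
  }
})

test_that("engulfed supervoxels are absorbed to a fixpoint", {
  mk <- function(nodes, edges) structure(list(nodes = nodes, edges = edges),
                                         class = "touching_graph")
  # u fully enclosed by v
  g <- mk(data.frame(id = c(1, 2), volume = c(8, 100),
                     surface = c(24, 150)),
          data.frame(u = 1, v = 2, area = 24))
  a <- absorb_engulfed_supervoxels(g)
  expect_identical(nrow(a$nodes), 1L)
  expect_identical(unname(attr(a, "mapping")["1"]), 2)
  # two equal cubes sharing one face: 9 < 27, not merged
  g2 <- mk(data.frame(id = c(1, 2), volume = c(27, 27), surface = c(54, 54)),
           data.frame(u = 1, v = 2, area = 9))
  expect_identical(nrow(absorb_engulfed_supervoxels(g2)$nodes), 2L)
  # chain: absorbing A into B makes B absorbable by C
  g3 <- mk(data.frame(id = c(1, 2, 3), volume = c(5, 10, 200),
                      surface = c(20, 30, 300)),
           data.frame(u = c(1, 2), v = c(2, 3), area = c(12, 14)))
  # A(1): 12 > 10 -> into B; B then has surface 30+20-24 = 26, edge to C 14 > 13
  a3 <- absorb_engulfed_supervoxels(g3)
  expect_identical(nrow(a3$nodes), 1L)
  expect_true(all(attr(a3, "mapping") == 3))
})

test_that("touching-area clustering equals brute-force closure, order-free", {
  # the worked rule: A-B 40, B-C 10, threshold 30 -> {A,B}, {C}
  g <- structure(list(nodes = data.frame(id = 1:3, volume = 1, surface = 1),
                      edges = data.frame(u = c(1, 2), v = c(2, 3),
                                         area = c(40, 10))),
                 class = "touching_graph")
  part <- cluster_by_touching_area(g, 30)
  expect_identical(part$cluster, c(1L, 1L, 2L))
  # no qualifying edges: every supervoxel its own cell
  none <- cluster_by_touching_area(g, 100)
  expect_identical(none$cluster, 1:3)

  for (seed in 1:40) {
    gr <- random_graph(seed)
    ma <- sample(1:60, 1)
    ref <- closure_partition(gr, ma)
    part <- cluster_by_touching_area(gr, ma)
    expect_identical(partition_signature(part),
                     outer(ref, ref, "=="))
    # random orderings of nodes and edges give the identical partition
    for (k in 1:5) {
      gp <- gr
      gp$nodes <- gp$nodes[sample(nrow(gp$nodes)), , drop = FALSE]
      if (nrow(gp$edges))
        gp$edges <- gp$edges[sample(nrow(gp$edges)), , drop = FALSE]
      swap <- runif(nrow(gp$edges)) < 0.5
      tmp <- gp$edges$u[swap]
      gp$edges$u[swap] <- gp$edges$v[swap]; gp$edges$v[swap] <- tmp
      p2 <- cluster_by_touching_area(gp, ma)
      expect_identical(partition_signature(p2), partition_signature(part))
    }
  }
})

test_that("watershed labels every foreground voxel into connected supervoxels", {
  expect_true(all(watershed_supervoxels(array(0L, c(5, 5, 5))) == 0L))
  sphere <- ball_mask(c(15, 15, 15), c(8, 8, 8), 5)
  sv <- watershed_supervoxels(sphere)
  expect_identical(sort(unique(as.integer(sv[sphere == 1L]))), 1L)
  expect_true(all(sv[sphere == 0L] == 0L))
  # two balls joined by a thin bridge split into (at least) two supervoxels
  bb <- bridged_balls_mask()
  svb <- watershed_supervoxels(bb)
  expect_true(all(svb[bb == 1L] > 0L))
  expect_gte(length(setdiff(unique(as.integer(svb)), 0L)), 2L)
  # the split crosses the bridge: ball centers end up in different labels
  expect_false(svb[7, 7, 7] == svb[18, 7, 7])
  # each supervoxel is 6-connected
  for (id in setdiff(unique(as.integer(svb)), 0L)) {
    m <- array(0L, dim(svb)); m[svb == id] <- 1L
    expect_identical(max(dbscan_baseline(m)), 1L)
  }
})

test_that("leftover voxels go to the nearest cell, smallest id on ties", {
  inst <- array(0L, c(7, 1, 1))
  inst[1, 1, 1] <- 5L
  q <- array(0L, c(7, 1, 1)); q[2, 1, 1] <- 1L
  out <- assign_unlabeled_voxels(inst, unassigned_foreground = q)
  expect_identical(out[2, 1, 1], 5L)
  # exact tie between cells 2 and 7 resolves to 2
  inst2 <- array(0L, c(5, 1, 1)); inst2[1, 1, 1] <- 7L; inst2[5, 1, 1] <- 2L
  q2 <- array(0L, c(5, 1, 1)); q2[3, 1, 1] <- 1L
  expect_identical(assign_unlabeled_voxels(inst2,
                                           unassigned_foreground = q2)[3, 1, 1],
                   2L)
  # no instances at all: warning, voxels left 0
  expect_warning(out0 <- assign_unlabeled_voxels(array(0L, c(3, 3, 3)),
                                                 membrane = array(1L, c(3, 3, 3))),
                 "no instances")
  expect_true(all(out0 == 0L))
  # random fixture vs exhaustive nearest search
  set.seed(8)
  inst3 <- array(0L, c(6, 6, 6))
  sites <- matrix(cbind(sample(6, 10, TRUE), sample(6, 10, TRUE),
                        sample(6, 10, TRUE)), ncol = 3)
  for (i in seq_len(nrow(sites)))
    inst3[sites[i, 1], sites[i, 2], sites[i, 3]] <- sample(1:4, 1)
  q3 <- array(1L, c(6, 6, 6)); q3[inst3 > 0] <- 0L
  out3 <- assign_unlabeled_voxels(inst3, unassigned_foreground = q3)
  lab_sites <- which(inst3 > 0, arr.ind = TRUE)
  for (i in which(q3 == 1L)) {
    co <- arrayInd(i, dim(inst3))
    d2 <- colSums((t(lab_sites) - as.vector(co))^2)
    best <- min(d2)
    expect_identical(out3[i],
                     min(inst3[lab_sites[d2 == best, , drop = FALSE]]))
  }
})

test_that("segmenting a single-cell mask returns exactly one instance", {
  ex <- gt_phantom(c(24, 24, 24), 1, 19)
  seg <- segment_instances(ex$masks, min_area = 30)
  expect_identical(seg$n_instances, 1L)
  # all tissue voxels labeled, background untouched
  expect_true(all(seg$labels[ex$ph$labels > 0L] == 1L))
  expect_true(all(seg$labels[ex$ph$labels == 0L] == 0L))
})

test_that("instance volume is conserved through leftover assignment", {
  ex <- gt_phantom(c(40, 40, 40), 8, 23)
  seg <- segment_instances(ex$masks, min_area = 30)
  expect_identical(sum(seg$labels > 0L),
                   sum(ex$masks$foreground == 1L | ex$masks$membrane == 1L))
  # instance ids are consecutive from 1 with decreasing volume
  vols <- as.integer(table(seg$labels[seg$labels > 0]))
  expect_identical(sort(unique(as.integer(seg$labels))),
                   0:seg$n_instances)
  expect_true(all(diff(vols) <= 0))
})

test_that("TASCAN matches the density-clustering baseline on hole-free masks", {
  for (seed in c(19, 23)) {
    ex <- gt_phantom(c(40, 40, 40), 8, seed)
    seg <- segment_instances(ex$masks, min_area = 30)
    expect_identical(seg$n_instances,
                     max(dbscan_baseline(ex$masks$foreground)))
  }
})

test_that("huge min_area degenerates to one cell per absorbed supervoxel", {
  ex <- gt_phantom(c(32, 32, 32), 4, 29)
  sv <- watershed_supervoxels(ex$masks$foreground)
  ab <- absorb_engulfed_supervoxels(build_touching_graph(sv))
  seg <- segment_instances(ex$masks, min_area = .Machine$integer.max)
  expect_identical(seg$n_instances, nrow(ab$nodes))
})
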