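# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# solid Euclidean ball in a (Z,Y,X) volume
ball_mask <- function(extent, center, radius) {
  m <- array(0L, extent)
  for (x in seq_len(extent[3])) for (y in seq_len(extent[2]))
    for (z in seq_len(extent[1]))
      if ((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2 <= radius^2)
        m[z, y, x] <- 1L
  m
}

# two balls joined by a 1-voxel-wide bridge along z
bridged_balls_mask <- function() {
  m <- ball_mask(c(24L, 13L, 13L), c(7, 7, 7), 4) |
    ball_mask(c(24L, 13L, 13L), c(18, 7, 7), 4)
  m <- m * 1L
  m[12:13, 7, 7] <- 1L
  m
}

# random class-probability volume (softmax of Gaussian logits)
random_probs <- function(extent, seed) {
  set.seed(seed)
  l <- array(rnorm(prod(extent) * 3), c(extent, 3))
  e <- exp(l)
  s <- e[, , , 1] + e[, , , 2] + e[, , , 3]
  e / as.vector(s)
}

# random one-hot masks over the 3 classes
random_masks4 <- function(extent, seed) {
  set.seed(seed)
  cls <- array(sample(1:3, prod(extent), TRUE), extent)
  g <- array(0, c(extent, 3))
  for (c in 1:3) g[, , , c] <- (cls == c) * 1
  g
}

# random supervoxel graph with <= n_max nodes, as a touching_graph
random_graph <- function(seed, n_max = 12L) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  ids <- sort(sample(1:99, n))
  all_pairs <- t(combn(ids, 2))
  m <- nrow(all_pairs)
  pick <- runif(m) < 0.4
  edges <- data.frame(u = all_pairs[pick, 1], v = all_pairs[pick, 2],
                      area = sample(1:60, sum(pick), TRUE))
  structure(list(nodes = data.frame(id = ids, volume = sample(10:100, n, TRUE),
                                    surface = sample(60:200, n, TRUE)),
                 edges = edges),
            class = "touching_graph")
}

# brute-force transitive closure over edges with area >= min_area
closure_partition <- function(graph, min_area) {
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- diag(TRUE, n)
  e <- graph$edges[graph$edges$area >= min_area, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    i <- match(e$u[k], ids); j <- match(e$v[k], ids)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  # canonical labels: index of first member of each component
  apply(adj, 1, function(r) which(r)[1])
}

# canonical co-membership signature of a partition data.frame (id, cluster)
partition_signature <- function(part) {
  part <- part[order(part$id), ]
  cl <- part$cluster
  outer(cl, cl, "==")
}

# small phantom + ground-truth masks, memoised per (extent, n, seed)
gt_phantom <- local({
  cache <- list()
  function(extent, n_cells, seed, noise_sd = 0) {
    key <- paste(c(extent, n_cells, seed, noise_sd), collapse = "_")
    if (is.null(cache[[key]])) {
      ph <- generate_phantom(phantom_spec(extent = extent, n_cells = n_cells,
                                          noise_sd = noise_sd, seed = seed))
      cache[[key]] <<- list(ph = ph,
                            masks = semantic_masks_from_labels(ph$labels, 2))
    }
    cache[[key]]
  }
})
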