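#' @title Touching-area supervoxel clustering (TASCAN)
#'
#' @description Instance segmentation from semantic masks. The foreground is
#' pre-clustered into supervoxels by a seeded watershed on the negated
#' Euclidean distance transform. Supervoxels form a graph whose nodes carry
#' surface areas `S_u` (exposed voxel faces) and whose edges carry touching
#' areas `S_uv` (shared voxel faces, 6-connectivity). Small supervoxels more
#' than half engulfed by a neighbor are absorbed; the remaining supervoxels
#' are merged into cells as connected components over edges with
#' `S_uv >= min_area` — the pipeline's single hyperparameter. Membrane and
#' stray foreground voxels are finally assigned to their nearest cell.
#' Because the merge criterion is symmetric in the two supervoxels, the
#' result does not depend on processing order.
#'
#' @name tascan
NULL

.as_int_array <- function(a) {
  storage.mode(a) <- "integer"
  a
}

#' Watershed pre-clustering of the foreground into supervoxels
#'
#' Seeds are 6-connected plateaus of local maxima of the Euclidean distance
#' transform (window maxima with Chebyshev separation `h_sep`); the flood
#' fills the foreground in order of decreasing distance, so each supervoxel
#' is a 6-connected cluster around one interior maximum.
#'
#' @param foreground Binary 3D mask.
#' @param h_sep Minimum seed separation in voxels (default 3).
#' @param tolerance Minimum basin prominence in distance units (default 1):
#'   a basin whose peak rises less than this above its highest saddle to a
#'   neighbor is merged into that neighbor, the usual watershed tolerance
#'   that suppresses shallow spurious basins in thin corners.
#' @return Integer 3D label array over foreground voxels (0 elsewhere).
#' @export
watershed_supervoxels <- function(foreground, h_sep = 3L, tolerance = 1) {
  d <- dim(foreground)
  fg <- .as_int_array((foreground > 0) * 1L)
  if (!any(fg == 1L)) return(array(0L, d))
  edt <- as.numeric(cpp_edt3(fg, dim(fg)))
  maxima <- cpp_window_maxima(edt, fg, dim(fg), as.integer(h_sep))
  # fuse maxima plateaus closer than h_sep (Chebyshev) into one seed each
  dil <- cpp_box_dilate(maxima, dim(fg), as.integer(max(h_sep %/% 2L, 1L)))
  comp <- cpp_label_components6(dil, dim(fg))
  seeds <- array(0L, dim(fg))
  mx <- maxima == 1L
  seeds[mx] <- comp[mx]
  sv <- cpp_seeded_watershed(edt, seeds, fg, dim(fg))
  if (tolerance > 0) sv <- .merge_shallow_basins(sv, edt, tolerance)
  sv
}

# merge watershed basins whose prominence (peak minus highest saddle to a
# neighbor) is below tol; processed lowest peak first, recomputing after
# each merge
.merge_shallow_basins <- function(sv, edt, tol) {
  bs <- cpp_basin_saddles(sv, as.numeric(edt), dim(sv))
  peak <- setNames(bs$peak, bs$id)
  edges <- data.frame(u = bs$edge_u, v = bs$edge_v, saddle = bs$saddle)
  mapping <- setNames(bs$id, bs$id)
  repeat {
    if (nrow(edges) == 0L) break
    su <- pmin(peak[as.character(edges$u)], peak[as.character(edges$v)])
    prom <- su - edges$saddle
    cand <- which(prom < tol)
    if (!length(cand)) break
    i <- cand[order(prom[cand], -edges$saddle[cand])][1]
    u <- edges$u[i]; v <- edges$v[i]
    # absorb the lower-peak basin into the other
    if (peak[as.character(u)] <= peak[as.character(v)]) { from <- u; into <- v }
    else { from <- v; into <- u }
    peak[as.character(into)] <- max(peak[as.character(into)],
                                    peak[as.character(from)])
    peak <- peak[names(peak) != as.character(from)]
    eu <- ifelse(edges$u == from, into, edges$u)
    ev <- ifelse(edges$v == from, into, edges$v)
    lo <- pmin(eu, ev); hi <- pmax(eu, ev)
    keep <- lo != hi
    if (any(keep)) {
      agg <- stats::aggregate(saddle ~ u + v,
                              data.frame(u = lo[keep], v = hi[keep],
                                         saddle = edges$saddle[keep]), max)
      edges <- agg[order(agg$u, agg$v), , drop = FALSE]
    } else edges <- edges[0, , drop = FALSE]
    mapping[mapping == from] <- into
  }
  lut <- integer(max(as.integer(names(mapping))))
  lut[as.integer(names(mapping))] <- mapping
  out <- sv
  nz <- sv > 0L
  out[nz] <- lut[sv[nz]]
  # compact ids to 1..K preserving order
  ids <- sort(unique(out[out > 0L]))
  lut2 <- integer(max(ids)); lut2[ids] <- seq_along(ids)
  out[nz] <- lut2[out[nz]]
  out
}

#' Build the touching graph of a supervoxel labeling
#'
#' @param sv Integer 3D supervoxel label array (0 = outside).
#' @return A `touching_graph`: `nodes` data frame (`id`, `volume`,
#'   `surface`) and `edges` data frame (`u`, `v`, `area`), with `surface`
#'   counting all exposed voxel faces (volume boundary included) and `area`
#'   the shared faces of the pair. Edges with zero touching area are absent.
#' @export
build_touching_graph <- function(sv) {
  g <- cpp_touching_graph(.as_int_array(sv), dim(sv))
  structure(list(
    nodes = data.frame(id = g$id, volume = g$volume, surface = g$surface),
    edges = data.frame(u = g$edge_u, v = g$edge_v, area = g$edge_area)),
    class = "touching_graph")
}

#' @export
print.touching_graph <- function(x, ...) {
  cat("touching_graph:", nrow(x$nodes), "supervoxels,",
      nrow(x$edges), "touching pairs\n")
  invisible(x)
}

#' Absorb engulfed supervoxels
#'
#' Iterates to a fixpoint: whenever a supervoxel `u` shares more than
#' `ratio` of its surface with a single neighbor `v` (`S_uv > ratio * S_u`),
#' `u` is merged into `v`. Merges are applied largest touching area first,
#' and surfaces/touching areas are recomputed after each merge, so chains of
#' absorptions resolve fully.
#'
#' @param graph A [build_touching_graph()] result.
#' @param ratio Surface fraction threshold (default 0.5, i.e. at least half
#'   of the surface).
#' @return A `touching_graph` of the merged nodes, with attribute `mapping`:
#'   named integer vector from original node id to merged node id.
#' @export
absorb_engulfed_supervoxels <- function(graph, ratio = 0.5) {
  nodes <- graph$nodes; edges <- graph$edges
  mapping <- setNames(nodes$id, nodes$id)
  repeat {
    if (nrow(edges) == 0L) break
    su <- setNames(nodes$surface, nodes$id)
    # candidate absorptions in either direction
    cand_u <- edges$area > ratio * su[as.character(edges$u)]
    cand_v <- edges$area > ratio * su[as.character(edges$v)]
    cand <- which(cand_u | cand_v)
    if (!length(cand)) break
    i <- cand[order(-edges$area[cand], edges$u[cand], edges$v[cand])][1]
    # absorb the engulfed endpoint into the other
    if (cand_u[i]) { from <- edges$u[i]; into <- edges$v[i] }
    else { from <- edges$v[i]; into <- edges$u[i] }
    # update node table
    iu <- match(from, nodes$id); iv <- match(into, nodes$id)
    suv <- edges$area[i]
    nodes$volume[iv] <- nodes$volume[iv] + nodes$volume[iu]
    nodes$surface[iv] <- nodes$surface[iv] + nodes$surface[iu] - 2 * suv
    nodes <- nodes[-iu, , drop = FALSE]
    # rewire edges of `from` to `into`, summing parallel touching areas
    eu <- ifelse(edges$u == from, into, edges$u)
    ev <- ifelse(edges$v == from, into, edges$v)
    lo <- pmin(eu, ev); hi <- pmax(eu, ev)
    keep <- lo != hi
    if (any(keep)) {
      agg <- stats::aggregate(area ~ u + v,
                              data.frame(u = lo[keep], v = hi[keep],
                                         area = edges$area[keep]), sum)
      edges <- agg[order(agg$u, agg$v), , drop = FALSE]
      rownames(edges) <- NULL
    } else edges <- edges[0, , drop = FALSE]
    mapping[mapping == from] <- into
  }
  structure(list(nodes = nodes, edges = edges),
            class = "touching_graph", mapping = mapping)
}

#' Cluster supervoxels by touching area
#'
#' Connected components of the subgraph containing exactly the edges with
#' touching area `>= min_area`; pairs below the threshold are taken as
#' separate cells. The criterion is symmetric in the pair, so the partition
#' is independent of node processing order.
#'
#' @param graph A `touching_graph`.
#' @param min_area Minimum touching area in faces (default 30).
#' @return Data frame (`id`, `cluster`) with clusters numbered consecutively
#'   by their smallest member id.
#' @export
cluster_by_touching_area <- function(graph, min_area = 30) {
  stopifnot(min_area >= 1)
  ids <- graph$nodes$id
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  e <- graph$edges[graph$edges$area >= min_area, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    ru <- find(match(e$u[k], ids)); rv <- find(match(e$v[k], ids))
    if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
  }
  root <- vapply(seq_along(ids), find, integer(1))
  # number clusters by smallest member id
  smallest <- tapply(ids, root, min)
  ord <- rank(smallest)
  cl <- as.integer(ord[as.character(root)])
  data.frame(id = ids, cluster = cl)
}

#' Assign leftover voxels to their nearest cells
#'
#' Every voxel flagged in `membrane` or `unassigned_foreground` receives the
#' label of the nearest instance voxel by exact Euclidean distance, ties
#' going to the smallest instance id. True background stays 0.
#'
#' @param instances Integer 3D instance label array.
#' @param membrane Binary membrane mask (may be `NULL`).
#' @param unassigned_foreground Binary mask of foreground voxels without an
#'   instance (may be `NULL`).
#' @return Updated instance label array.
#' @export
assign_unlabeled_voxels <- function(instances, membrane = NULL,
                                    unassigned_foreground = NULL) {
  d <- dim(instances)
  query <- array(0L, d)
  if (!is.null(membrane)) query[membrane > 0] <- 1L
  if (!is.null(unassigned_foreground)) query[unassigned_foreground > 0] <- 1L
  query[instances > 0] <- 0L
  if (!any(query == 1L)) return(instances)
  if (!any(instances > 0)) {
    warning("no instances to assign to; leaving queried voxels at 0")
    return(instances)
  }
  cpp_nearest_label_assign(.as_int_array(instances), query, dim(instances))
}

#' Two-stage instance segmentation from semantic masks
#'
#' Composition of the full second stage: watershed supervoxels, touching
#' graph, absorption of engulfed supervoxels, touching-area clustering with
#' `min_area`, relabeling to instances (numbered 1..K by decreasing volume)
#' and nearest-cell assignment of membrane and stray foreground voxels.
#'
#' @param masks List of `background`, `membrane`, `foreground` masks
#'   partitioning the volume.
#' @param min_area Minimum touching area (default 30), the single
#'   hyperparameter of the pipeline.
#' @param h_sep Watershed seed separation (default 3).
#' @param assign_leftovers Assign membrane / stray foreground voxels to
#'   nearest cells (default `TRUE`).
#' @return An `instance_segmentation`: list with `labels` (integer 3D
#'   array), `provenance` (named vector supervoxel id -> instance id) and
#'   `n_instances`.
#' @export
segment_instances <- function(masks, min_area = 30, h_sep = 3L,
                              assign_leftovers = TRUE) {
  d <- dim(masks$foreground)
  sv <- watershed_supervoxels(masks$foreground, h_sep = h_sep)
  if (!any(sv > 0L)) {
    return(structure(list(labels = array(0L, d),
                          provenance = setNames(integer(0), character(0)),
                          n_instances = 0L),
                     class = "instance_segmentation"))
  }
  graph <- build_touching_graph(sv)
  absorbed <- absorb_engulfed_supervoxels(graph)
  amap <- attr(absorbed, "mapping")
  part <- cluster_by_touching_area(absorbed, min_area = min_area)
  cl_of_node <- setNames(part$cluster, part$id)
  sv_to_cluster <- cl_of_node[as.character(amap)]
  names(sv_to_cluster) <- names(amap)
  # relabel supervoxels to clusters
  lut <- integer(max(graph$nodes$id))
  lut[as.integer(names(sv_to_cluster))] <- sv_to_cluster
  inst <- array(0L, d)
  nz <- sv > 0L
  inst[nz] <- lut[sv[nz]]
  # renumber 1..K by descending volume (ties: smaller provisional id first)
  vols <- tabulate(inst[nz])
  ord <- order(-vols, seq_along(vols))
  renum <- integer(length(vols)); renum[ord] <- seq_along(ord)
  inst[nz] <- renum[inst[nz]]
  provenance <- setNames(renum[sv_to_cluster], names(sv_to_cluster))
  if (assign_leftovers) {
    stray <- array(0L, d)
    stray[masks$foreground > 0 & inst == 0L] <- 1L
    inst <- assign_unlabeled_voxels(inst, masks$membrane, stray)
  }
  structure(list(labels = inst, provenance = provenance,
                 n_instances = length(unique(provenance))),
            class = "instance_segmentation")
}

#' @export
print.instance_segmentation <- function(x, ...) {
  cat("instance_segmentation:", x$n_instances, "cells,",
      sum(x$labels > 0), "labeled voxels\n")
  invisible(x)
}

#' Density-based voxel clustering baseline
#'
#' DBSCAN on the voxel grid with `eps = 1` (6-neighborhood reachability) and
#' `min_pts = 1`, which reduces exactly to 6-connected component labeling of
#' the foreground. Used as the ablation baseline that touching-area
#' clustering is compared against.
#'
#' @param foreground Binary 3D mask.
#' @return Integer 3D label array of density clusters.
#' @export
dbscan_baseline <- function(foreground) {
  fg <- .as_int_array((foreground > 0) * 1L)
  cpp_label_components6(fg, dim(fg))
}
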