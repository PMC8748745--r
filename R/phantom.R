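#' @title Synthetic membrane phantoms
#'
#' @description Generates 3D membrane images with voxel-perfect instance
#' ground truth: a Voronoi tessellation of well-separated seed points models
#' densely packed convex cells, thin bright membranes separate neighbors and
#' line the tissue border, and optional membrane "holes" reproduce the
#' foreground adhesions (clumped cells) that the two-stage pipeline is built
#' to resolve.
#'
#' @name phantom
NULL

# run expr under a fixed Mersenne-Twister seed without disturbing the caller's
# RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Specify a synthetic membrane phantom
#'
#' @param extent Volume extent `(Z, Y, X)` in voxels.
#' @param n_cells Number of cells (Voronoi regions).
#' @param membrane_thickness Membrane thickness in voxels (>= 1).
#' @param noise_sd Additive Gaussian noise SD, relative to the
#'   membrane-interior contrast of 1.0.
#' @param hole_rate Fraction of cell-cell interfaces given a membrane hole.
#' @param hole_radius Hole radius in voxels (voxels strictly closer than this
#'   to a hole center lose their membrane signal).
#' @param background_margin Empty border width in voxels.
#' @param seed Integer seed; fixed seeds give bit-identical phantoms
#'   (Mersenne-Twister).
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(extent = c(64L, 64L, 64L), n_cells = 30L,
                         membrane_thickness = 2, noise_sd = 0.05,
                         hole_rate = 0, hole_radius = 2,
                         background_margin = 2L, seed = 1L) {
  extent <- as.integer(extent)
  stopifnot(length(extent) == 3L, all(extent >= 1L), n_cells >= 1L,
            membrane_thickness >= 1, noise_sd >= 0,
            hole_rate >= 0, hole_rate <= 1, hole_radius >= 0,
            background_margin >= 0L)
  inner <- extent - 2L * as.integer(background_margin)
  if (any(inner < 1L) || prod(inner) < 64 * n_cells)
    stop("infeasible packing: ", n_cells, " cells do not fit in extent ",
         paste(extent, collapse = "x"), " with margin ", background_margin,
         " (need >= ~4^3 voxels per cell)", call. = FALSE)
  structure(list(extent = extent, n_cells = as.integer(n_cells),
                 membrane_thickness = membrane_thickness, noise_sd = noise_sd,
                 hole_rate = hole_rate, hole_radius = hole_radius,
                 background_margin = as.integer(background_margin),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# best-candidate (greedy farthest-point) sampling of n integer points in the
# box [lo, hi] per axis; deterministic under the active RNG
.sample_seed_points <- function(n, lo, hi, n_candidates = 24L) {
  pts <- matrix(0, nrow = n, ncol = 3)
  draw <- function() vapply(1:3, function(a)
    sample(seq.int(lo[a], hi[a]), 1L), numeric(1))
  pts[1, ] <- draw()
  if (n > 1) for (i in 2:n) {
    best <- NULL; bestd <- -1
    for (k in seq_len(n_candidates)) {
      cand <- draw()
      d <- min(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - cand)^2))
      if (d > bestd) { bestd <- d; best <- cand }
    }
    pts[i, ] <- best
  }
  if (anyDuplicated(pts)) stop("infeasible packing: duplicate seed points",
                               call. = FALSE)
  pts
}

#' Generate a synthetic membrane phantom
#'
#' Places `n_cells` well-separated seed points in the interior (greedy
#' farthest-point sampling), labels interior voxels by their nearest seed
#' (Voronoi), and renders an intensity image that is ~1.0 on the membrane
#' shell between differing labels and at the tissue border, ~0.0 in cell
#' interiors and background, plus additive Gaussian noise. A fraction
#' `hole_rate` of cell-cell interfaces receives an intensity hole of radius
#' `hole_radius`, the image-level cause of clumped-cell adhesions; the label
#' volume keeps the true instances.
#'
#' @param spec A [phantom_spec()].
#' @return List with `intensity` (3D array), `labels` (3D integer array,
#'   0 = background), `hole_centers` (matrix of (z,y,x) rows, possibly empty)
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    ext <- spec$extent; m <- spec$background_margin
    lo <- rep(m + 1L, 3L); hi <- ext - m
    pts <- .sample_seed_points(spec$n_cells, lo, hi)

    labels <- array(0L, ext)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    gz <- rep(zi, times = length(yi) * length(xi))
    gy <- rep(rep(yi, each = length(zi)), times = length(xi))
    gx <- rep(xi, each = length(zi) * length(yi))
    bestd <- rep(Inf, length(gz)); bestl <- integer(length(gz))
    for (i in seq_len(spec$n_cells)) {
      d <- (gz - pts[i, 1])^2 + (gy - pts[i, 2])^2 + (gx - pts[i, 3])^2
      upd <- d < bestd
      bestd[upd] <- d[upd]; bestl[upd] <- i
    }
    labels[zi, yi, xi] <- bestl

    masks <- semantic_masks_from_labels(labels, spec$membrane_thickness)
    intensity <- array(0, ext)
    intensity[masks$membrane == 1L] <- 1

    hole_centers <- matrix(integer(0), ncol = 3)
    if (spec$hole_rate > 0 && spec$hole_radius > 0) {
      faces <- .interface_faces(labels)
      if (nrow(faces) > 0) {
        keys <- paste(faces[, "u"], faces[, "v"])
        pairs <- unique(keys)
        chosen <- pairs[runif(length(pairs)) < spec$hole_rate]
        for (pr in chosen) {
          cand <- which(keys == pr)
          f <- faces[cand[sample.int(length(cand), 1L)], ]
          hole_centers <- rbind(hole_centers, f[c("z", "y", "x")])
        }
        intensity <- .apply_intensity_holes(intensity, hole_centers,
                                            spec$hole_radius)
      }
    }
    if (spec$noise_sd > 0)
      intensity <- intensity + rnorm(length(intensity), sd = spec$noise_sd)
    list(intensity = intensity, labels = labels,
         hole_centers = hole_centers, spec = spec)
  })
}

# inter-cell faces: rows (u, v, z, y, x) with u < v; coordinates of the
# u-side voxel of each shared face
.interface_faces <- function(labels) {
  d <- dim(labels)
  out <- list()
  shifts <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (s in shifts) {
    a <- labels[1:(d[1] - s[1]), 1:(d[2] - s[2]), 1:(d[3] - s[3]), drop = FALSE]
    b <- labels[(1 + s[1]):d[1], (1 + s[2]):d[2], (1 + s[3]):d[3], drop = FALSE]
    sel <- which(a > 0L & b > 0L & a != b)
    if (!length(sel)) next
    da <- dim(a)
    z <- (sel - 1L) %% da[1] + 1L
    y <- ((sel - 1L) %/% da[1]) %% da[2] + 1L
    x <- (sel - 1L) %/% (da[1] * da[2]) + 1L
    u <- pmin(a[sel], b[sel]); v <- pmax(a[sel], b[sel])
    out[[length(out) + 1L]] <- cbind(u = u, v = v, z = z, y = y, x = x)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 5,
                                  dimnames = list(NULL, c("u", "v", "z", "y", "x"))))
  do.call(rbind, out)
}

# one representative face per cell-cell interface whose local neighborhood
# (Chebyshev radius rad) contains no third cell: hole protocols built on such
# faces perforate a clean two-cell membrane rather than a junction
.clean_interface_faces <- function(labels, faces = .interface_faces(labels),
                                   rad = 3L) {
  d <- dim(labels)
  keys <- paste(faces[, "u"], faces[, "v"])
  out <- NULL
  for (kk in unique(keys)) {
    rows <- faces[keys == kk, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      f <- rows[i, ]
      zr <- max(1, f["z"] - rad):min(d[1], f["z"] + rad)
      yr <- max(1, f["y"] - rad):min(d[2], f["y"] + rad)
      xr <- max(1, f["x"] - rad):min(d[3], f["x"] + rad)
      loc <- unique(as.integer(labels[zr, yr, xr]))
      if (all(loc %in% c(0L, f[["u"]], f[["v"]]))) { out <- rbind(out, f); break }
    }
  }
  out
}

.apply_intensity_holes <- function(intensity, centers, radius) {
  d <- dim(intensity)
  r <- ceiling(radius)
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    zr <- max(1, c0[1] - r):min(d[1], c0[1] + r)
    yr <- max(1, c0[2] - r):min(d[2], c0[2] + r)
    xr <- max(1, c0[3] - r):min(d[3], c0[3] + r)
    for (x in xr) for (y in yr) {
      dz2 <- (zr - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2
      hit <- zr[dz2 < radius^2]
      if (length(hit)) intensity[hit, y, x] <- 0
    }
  }
  intensity
}

#' Derive semantic class masks from an instance label volume
#'
#' The membrane mask holds labeled voxels within `membrane_thickness / 2`
#' (measured to the inter-voxel interface) of a boundary to a different label
#' or to the background; the foreground mask holds the remaining labeled
#' voxels; the background mask is everything else. The three masks are
#' disjoint and cover the volume.
#'
#' @param labels Integer 3D array, 0 = background.
#' @param membrane_thickness Membrane thickness in voxels.
#' @return List of three integer 0/1 arrays: `background`, `membrane`,
#'   `foreground`.
#' @export
semantic_masks_from_labels <- function(labels, membrane_thickness = 2) {
  d <- dim(labels)
  membrane <- array(0L, d)
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  cutoff <- membrane_thickness / 2 + 0.5  # voxel-center to interface offset
  for (l in ids) {
    # pad with in-mask voxels so the volume edge itself is not an interface
    mp <- array(1L, d + 2L)
    mp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- (labels == l) * 1L
    dm <- array(cpp_edt3(mp, dim(mp)), d + 2L)
    dm <- dm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
    membrane[labels == l & dm <= cutoff] <- 1L
  }
  foreground <- array(0L, d)
  foreground[labels > 0L & membrane == 0L] <- 1L
  background <- array(0L, d)
  background[labels == 0L] <- 1L
  list(background = background, membrane = membrane, foreground = foreground)
}

#' Punch holes in semantic masks
#'
#' Relabels membrane voxels strictly closer than `hole_radius` to each center
#' as foreground, creating adhesions between neighboring cells' foreground
#' components while preserving the mask partition. This stresses the
#' instance-segmentation stage independently of the network.
#'
#' @param masks List of `background`, `membrane`, `foreground` masks
#'   partitioning the volume.
#' @param hole_centers Matrix with one (z, y, x) row per hole (1-based).
#' @param hole_radius Hole radius in voxels (strict `<` comparison, so radius
#'   0 is a no-op).
#' @param seed Unused; retained so hole protocols can be specified alongside
#'   the phantom seed.
#' @return The modified mask list.
#' @export
punch_membrane_holes <- function(masks, hole_centers, hole_radius, seed = NULL) {
  d <- dim(masks$membrane)
  if (is.null(dim(hole_centers))) hole_centers <- matrix(hole_centers, ncol = 3)
  if (nrow(hole_centers) == 0 || hole_radius <= 0) return(masks)
  if (any(hole_centers < 1) ||
      any(t(hole_centers) > d))
    stop("hole center outside volume", call. = FALSE)
  r <- ceiling(hole_radius)
  for (i in seq_len(nrow(hole_centers))) {
    c0 <- hole_centers[i, ]
    zr <- max(1, c0[1] - r):min(d[1], c0[1] + r)
    yr <- max(1, c0[2] - r):min(d[2], c0[2] + r)
    xr <- max(1, c0[3] - r):min(d[3], c0[3] + r)
    for (x in xr) for (y in yr) {
      d2 <- (zr - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2
      hit <- zr[d2 < hole_radius^2]
      if (!length(hit)) next
      sel <- hit[masks$membrane[cbind(hit, y, x)] == 1L]
      if (length(sel)) {
        masks$membrane[cbind(sel, y, x)] <- 0L
        masks$foreground[cbind(sel, y, x)] <- 1L
      }
    }
  }
  masks
}
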