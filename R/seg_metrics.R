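#' @title Segmentation evaluation metrics
#'
#' @description Per-cell Jaccard index and Dice similarity coefficient with
#' overall (average) and cell-count (fraction above 0.7 / 0.5) summaries,
#' plus the partition-level adapted Rand error (1 minus the pair-counting
#' F-score) and the variation of information split into over-segmentation
#' (split) and under-segmentation (merge) conditional entropies in bits.
#'
#' @name seg_metrics
NULL

.voxel_set <- function(s) {
  if (is.logical(s)) return(which(s))
  if (is.array(s)) return(which(s > 0))
  as.integer(s)
}

#' Jaccard index of two voxel sets
#'
#' `|seg intersect gt| / |seg union gt|`; 1 when both sets are empty.
#'
#' @param seg,gt Voxel sets: logical/binary arrays or integer index vectors.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(seg, gt) {
  a <- .voxel_set(seg); b <- .voxel_set(gt)
  if (!length(a) && !length(b)) return(1)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Dice similarity coefficient of two voxel sets
#'
#' `2 |seg intersect gt| / (|seg| + |gt|)`; 1 when both sets are empty.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(seg, gt) {
  a <- .voxel_set(seg); b <- .voxel_set(gt)
  if (!length(a) && !length(b)) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Match predicted instances to ground-truth cells
#'
#' Each ground-truth cell (label > 0) is matched to the predicted instance
#' with maximal voxel intersection (ties to the smaller predicted id);
#' cells with no overlapping prediction get JI = DSC = 0.
#'
#' @param pred,gt Integer 3D label arrays of the same shape, 0 = background.
#' @return Data frame with one row per ground-truth cell: `gt_id`,
#'   `pred_id` (`NA` if unmatched), `intersection`, `ji`, `dsc`.
#' @export
match_instances <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  gt_ids <- sort(setdiff(unique(as.integer(gt)), 0L))
  sel <- gt > 0L & pred > 0L
  ov <- if (any(sel))
    as.data.frame(table(gt = gt[sel], pred = pred[sel]),
                  stringsAsFactors = FALSE)
  else data.frame(gt = integer(0), pred = integer(0), Freq = integer(0))
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ov$gt <- as.integer(ov$gt); ov$pred <- as.integer(ov$pred)
  gt_size <- table(factor(gt[gt > 0L], levels = gt_ids))
  pred_size <- table(pred[pred > 0L])
  rows <- lapply(gt_ids, function(id) {
    o <- ov[ov$gt == id, , drop = FALSE]
    ng <- as.integer(gt_size[as.character(id)])
    if (nrow(o) == 0L)
      return(data.frame(gt_id = id, pred_id = NA_integer_,
                        intersection = 0L, ji = 0, dsc = 0))
    o <- o[order(-o$Freq, o$pred), , drop = FALSE]
    best <- o[1, ]
    np <- as.integer(pred_size[as.character(best$pred)])
    inter <- best$Freq
    data.frame(gt_id = id, pred_id = best$pred, intersection = inter,
               ji = inter / (ng + np - inter), dsc = 2 * inter / (ng + np))
  })
  do.call(rbind, rows)
}

#' Adapted Rand error
#'
#' Pair-counting precision and recall from the prediction x ground-truth
#' contingency table over voxels with a nonzero ground-truth label
#' (background excluded); the error is 1 minus their F-score. 0 for
#' identical partitions, strictly positive otherwise.
#'
#' @inheritParams match_instances
#' @return List with `are`, `precision`, `recall`.
#' @export
adapted_rand_error <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  sel <- gt > 0L
  if (!any(sel)) stop("all-background ground truth", call. = FALSE)
  p <- as.integer(pred[sel]); g <- as.integer(gt[sel])
  tab <- table(p, g)
  sum_ij <- sum(tab^2)
  sum_i <- sum(rowSums(tab)^2)   # over predicted segments
  sum_j <- sum(colSums(tab)^2)   # over ground-truth cells
  precision <- sum_ij / sum_i
  recall <- sum_ij / sum_j
  fscore <- 2 * precision * recall / (precision + recall)
  list(are = 1 - fscore, precision = precision, recall = recall)
}

.cond_entropy_bits <- function(a, b) {
  # H(a | b), base 2
  tab <- table(a, b)
  n <- sum(tab)
  pj <- colSums(tab) / n
  h <- 0
  for (j in seq_along(pj)) {
    col <- tab[, j]
    col <- col[col > 0]
    pc <- col / sum(col)
    h <- h - pj[j] * sum(pc * log2(pc))
  }
  as.numeric(h)
}

#' Variation of information (split / merge components)
#'
#' `voi_split = H(pred | gt)` measures over-segmentation (splits),
#' `voi_merge = H(gt | pred)` measures under-segmentation (merges); both in
#' bits, computed over voxels that are foreground in either partition. Their
#' sum is the total variation of information
#' `2 H(pred, gt) - H(pred) - H(gt)`.
#'
#' @inheritParams match_instances
#' @return List with `voi_split` and `voi_merge` (bits).
#' @export
variation_of_information <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  sel <- gt > 0L | pred > 0L
  if (!any(sel)) stop("empty foreground in both partitions", call. = FALSE)
  p <- as.integer(pred[sel]); g <- as.integer(gt[sel])
  list(voi_split = .cond_entropy_bits(p, g),
       voi_merge = .cond_entropy_bits(g, p))
}

#' Evaluate an instance segmentation against ground truth
#'
#' Aggregates [match_instances()] into average JI/DSC over ground-truth
#' cells, the cell-count accuracies (fractions of cells with JI or DSC
#' strictly above 0.7 and 0.5), and attaches [adapted_rand_error()] and
#' [variation_of_information()].
#'
#' @inheritParams match_instances
#' @return An `evaluation_report` list: `avg_ji`, `avg_dsc`,
#'   `frac_ji_gt_70`, `frac_dsc_gt_70`, `frac_ji_gt_50`, `frac_dsc_gt_50`,
#'   `are`, `voi_split`, `voi_merge`, `n_gt_cells`, `n_pred_cells`, and the
#'   per-cell `matches` table.
#' @export
evaluate_segmentation <- function(pred, gt) {
  m <- match_instances(pred, gt)
  are <- adapted_rand_error(pred, gt)
  voi <- variation_of_information(pred, gt)
  structure(list(
    avg_ji = mean(m$ji), avg_dsc = mean(m$dsc),
    frac_ji_gt_70 = mean(m$ji > 0.7), frac_dsc_gt_70 = mean(m$dsc > 0.7),
    frac_ji_gt_50 = mean(m$ji > 0.5), frac_dsc_gt_50 = mean(m$dsc > 0.5),
    are = are$are, voi_split = voi$voi_split, voi_merge = voi$voi_merge,
    n_gt_cells = nrow(m),
    n_pred_cells = length(setdiff(unique(as.integer(pred)), 0L)),
    matches = m), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "evaluation_report: %d gt cells vs %d predicted\n",
    "  Avg JI %.4f  Avg DSC %.4f\n",
    "  JI>0.7 %.3f  DSC>0.7 %.3f  JI>0.5 %.3f  DSC>0.5 %.3f\n",
    "  ARE %.4f  VOI split %.4f  merge %.4f (bits)\n"),
    x$n_gt_cells, x$n_pred_cells, x$avg_ji, x$avg_dsc,
    x$frac_ji_gt_70, x$frac_dsc_gt_70, x$frac_ji_gt_50, x$frac_dsc_gt_50,
    x$are, x$voi_split, x$voi_merge))
  invisible(x)
}
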