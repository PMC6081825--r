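#' Object-level evaluation of nuclear segmentation
#'
#' Instances in the predicted mask are matched one-to-one to ground-truth
#' instances when their intersection over union exceeds 0.5 (strictly:
#' IoU = 0.5 does not match). With a threshold above 0.5 a predicted object
#' can exceed the threshold with at most one ground-truth object, so greedy
#' matching in descending IoU is equivalent to the optimal one-to-one
#' assignment. Matched pairs are true positives; unmatched predictions false
#' positives; unmatched ground truths false negatives. Precision, recall and
#' F1 follow, plus the pixel-level standard error sigma/sqrt(n) of the
#' output-minus-ground-truth difference.
#'
#' @name evaluation
NULL

#' Intersection over union of two pixel sets
#'
#' @param a,b logical matrices (same grid) or integer index vectors.
#' @return |A intersect B| / |A union B|. Both-empty input is an error.
#' @export
iou <- function(a, b) {
  if (is.matrix(a)) { stopifnot(identical(dim(a), dim(b))); a <- which(a); b <- which(b) }
  un <- length(union(a, b))
  if (un == 0L) stop("IoU of two empty sets is undefined")
  length(intersect(a, b)) / un
}

#' Match predicted to ground-truth objects by IoU
#'
#' @param gt,pred integer label matrices on the same grid (0 = background).
#' @param iou_threshold match threshold; pairs need IoU strictly greater.
#' @return an `nf_match`: list with counts `tp`, `fp`, `fn` and `pairs`, a
#'   data frame (gt_label, pred_label, iou) of matches.
#' @export
match_objects <- function(gt, pred, iou_threshold = 0.5) {
  stopifnot(identical(dim(gt), dim(pred)))
  ng <- max(gt, 0L); np <- max(pred, 0L)
  pairs <- data.frame(gt_label = integer(0), pred_label = integer(0),
                      iou = numeric(0))
  if (ng > 0L && np > 0L) {
    sel <- gt > 0L & pred > 0L
    if (any(sel)) {
      inter <- table(factor(gt[sel], levels = 1:ng),
                     factor(pred[sel], levels = 1:np))
      a_gt <- tabulate(gt[gt > 0L], nbins = ng)
      a_pr <- tabulate(pred[pred > 0L], nbins = np)
      ioum <- inter / (outer(a_gt, a_pr, "+") - inter)
      cand <- which(ioum > iou_threshold, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        vals <- ioum[cand]
        ord <- order(-vals, cand[, 1], cand[, 2])
        used_g <- logical(ng); used_p <- logical(np)
        for (k in ord) {
          g <- cand[k, 1]; p <- cand[k, 2]
          if (used_g[g] || used_p[p]) next
          used_g[g] <- TRUE; used_p[p] <- TRUE
          pairs <- rbind(pairs, data.frame(gt_label = g, pred_label = p,
                                           iou = ioum[g, p]))
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs,
                 n_gt = ng, n_pred = np),
            class = "nf_match")
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2 Precision Recall / (Precision + Recall). Degenerate conventions:
#' precision 0 when TP+FP = 0, recall 0 when TP+FN = 0, F1 = 0 when
#' precision + recall = 0.
#'
#' @param match an `nf_match` from [match_objects()], or a list with `tp`,
#'   `fp`, `fn` counts.
#' @return named numeric vector (precision, recall, f1).
#' @export
compute_metrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Pixel-level standard error of a segmentation output
#'
#' sigma / sqrt(n), where sigma is the population standard deviation of the
#' per-pixel difference between output and ground truth and n is the total
#' pixel count. Computed over the concatenated pixels of all supplied grids.
#'
#' @param output numeric probability map(s) or binary map(s): matrix or list
#'   of matrices.
#' @param gt matching binary ground-truth map(s).
#' @return a single non-negative numeric.
#' @export
standard_error <- function(output, gt) {
  if (!is.list(output)) { output <- list(output); gt <- list(gt) }
  diffs <- unlist(Map(function(o, g) {
    stopifnot(identical(dim(o), dim(g)))
    as.numeric(o) - as.numeric(g)
  }, output, gt), use.names = FALSE)
  n <- length(diffs)
  if (n == 0L) stop("empty grid")
  sigma <- sqrt(mean((diffs - mean(diffs))^2))   # population SD
  sigma / sqrt(n)
}

#' Touching-nuclei separation assay
#'
#' For every ground-truth pair of touching nuclei, the pair counts as
#' correctly separated iff both members are matched (per [match_objects()])
#' to two distinct predicted labels.
#'
#' @param scene an `nf_scene` (carries `touching_pairs`) or a bare list with
#'   `mask` and `touching_pairs`.
#' @param pred predicted integer label mask.
#' @param iou_threshold match threshold passed to [match_objects()].
#' @return list with `separated`, `total_touching` and `rate` (NA when the
#'   scene has no touching pairs).
#' @export
touching_separation <- function(scene, pred, iou_threshold = 0.5) {
  tp_pairs <- scene$touching_pairs
  total <- nrow(tp_pairs)
  if (total == 0L)
    return(list(separated = 0L, total_touching = 0L, rate = NA_real_))
  m <- match_objects(scene$mask, pred, iou_threshold)
  map <- integer(m$n_gt)
  if (nrow(m$pairs) > 0L) map[m$pairs$gt_label] <- m$pairs$pred_label
  sep <- 0L
  for (r in seq_len(total)) {
    pa <- map[tp_pairs[r, 1]]; pb <- map[tp_pairs[r, 2]]
    if (pa > 0L && pb > 0L && pa != pb) sep <- sep + 1L
  }
  list(separated = sep, total_touching = total, rate = sep / total)
}

#' Standard error over repeated train/test permutations
#'
#' The pixel-level standard error can be computed over several random
#' train/test permutations of a scene set: each repetition splits the
#' scenes, calls `train_fn(train_scenes)` for a fitted object and
#' `predict_fn(fit, scene)` for a binary/probability output map, and pools
#' all test pixels of all repetitions into one [standard_error()].
#'
#' @param scenes list of `nf_scene`.
#' @param train_fn function(list of scenes) -> fitted object.
#' @param predict_fn function(fit, scene) -> numeric output matrix.
#' @param n_splits number of train/test permutations.
#' @param ratio training fraction per split.
#' @param seed base seed; split i uses `seed + i`.
#' @return list with `standard_error` (pooled) and `per_split` (vector).
#' @export
multi_split_standard_error <- function(scenes, train_fn, predict_fn,
                                       n_splits = 3L, ratio = 0.5,
                                       seed = 1L) {
  outs <- list(); gts <- list(); per <- numeric(n_splits)
  for (i in seq_len(n_splits)) {
    sp <- split_dataset(scenes, ratio, seed = seed + i)
    fit <- train_fn(sp$train)
    o <- lapply(sp$test, function(sc) predict_fn(fit, sc))
    g <- lapply(sp$test, function(sc) (sc$mask > 0L) * 1)
    per[i] <- standard_error(o, g)
    outs <- c(outs, o); gts <- c(gts, g)
  }
  list(standard_error = standard_error(outs, gts), per_split = per)
}

#' Per-object match table
#'
#' One row per object: matched pairs as TP with their IoU, unmatched ground
#' truths as FN, unmatched predictions as FP.
#'
#' @param match an `nf_match` from [match_objects()].
#' @return data frame (gt_label, pred_label, iou, status).
#' @export
match_table <- function(match) {
  tp <- if (nrow(match$pairs) > 0L)
    data.frame(gt_label = match$pairs$gt_label,
               pred_label = match$pairs$pred_label,
               iou = match$pairs$iou, status = "TP")
  else data.frame(gt_label = integer(0), pred_label = integer(0),
                  iou = numeric(0), status = character(0))
  fn_g <- setdiff(seq_len(match$n_gt), match$pairs$gt_label)
  fp_p <- setdiff(seq_len(match$n_pred), match$pairs$pred_label)
  rbind(tp,
        if (length(fn_g)) data.frame(gt_label = fn_g, pred_label = NA_integer_,
                                     iou = NA_real_, status = "FN"),
        if (length(fp_p)) data.frame(gt_label = NA_integer_, pred_label = fp_p,
                                     iou = NA_real_, status = "FP"))
}

#' Write a metrics report as CSV plus a text summary
#'
#' @param match an `nf_match`.
#' @param se pixel-level standard error (or NA).
#' @param path_csv,path_txt output paths (either may be NULL to skip).
#' @return invisibly, the named metric vector.
#' @export
write_metrics_report <- function(match, se = NA_real_, path_csv = NULL,
                                 path_txt = NULL) {
  m <- compute_metrics(match)
  if (!is.null(path_csv)) {
    df <- data.frame(tp = match$tp, fp = match$fp, fn = match$fn,
                     precision = m["precision"], recall = m["recall"],
                     f1 = m["f1"], standard_error = se)
    write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_txt)) {
    writeLines(c(
      sprintf("objects: gt=%d pred=%d", match$n_gt, match$n_pred),
      sprintf("TP=%d FP=%d FN=%d", match$tp, match$fp, match$fn),
      sprintf("Precision=%.4f Recall=%.4f F1=%.4f", m["precision"],
              m["recall"], m["f1"]),
      sprintf("StandardError=%.6g", se)), path_txt)
  }
  invisible(m)
}
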