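# COCO-style detection evaluation for a single foreground class:
# greedy score-ordered matching per image, a global precision-recall curve,
# 101-point interpolated average precision, and AP/AP50/AP75/AR aggregated
# over the ten IoU thresholds 0.50, 0.55, ..., 0.95.
#
# Boxes are corner-coordinate data.frames: columns x1, y1, x2, y2 (pixels,
# x2 > x1, y2 > y1), plus image_id and, for detections, score.

.validate_boxes <- function(df, need_score = FALSE, what = "boxes") {
  req <- c("image_id", "x1", "y1", "x2", "y2")
  if (need_score) req <- c(req, "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(what, " must have columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (!all(is.finite(df$x1) & is.finite(df$y1) &
             is.finite(df$x2) & is.finite(df$y2))) {
      stop(what, ": box coordinates must be finite")
    }
    if (any(df$x2 <= df$x1 | df$y2 <= df$y1)) {
      stop(what, ": degenerate (zero-area) box")
    }
  }
  invisible(df)
}

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 vectors `(x1, y1, x2, y2)` with `x2 > x1`,
#'   `y2 > y1`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("degenerate (zero-area) box")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# n x 4 vs m x 4 -> n x m IoU matrix (vectorized)
box_iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  x1 <- outer(a[, 1], b[, 1], pmax); y1 <- outer(a[, 2], b[, 2], pmax)
  x2 <- outer(a[, 3], b[, 3], pmin); y2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, "+") - inter)
}

# Greedy matching at one IoU threshold. Detections are processed in
# descending score order (ties broken by input order); each matches the
# unmatched ground-truth box of highest IoU provided IoU >= threshold, and
# each ground truth is usable once. Returns the TP flags in global score
# order plus the total ground-truth count.
match_detections <- function(dets, gts, iou_thresh, max_dets = Inf) {
  .validate_boxes(dets, need_score = TRUE, what = "detections")
  .validate_boxes(gts, what = "ground truth")
  if (nrow(dets) && is.finite(max_dets)) {
    keep <- unlist(lapply(split(seq_len(nrow(dets)), dets$image_id),
                          function(ix) {
      ord <- ix[order(-dets$score[ix])]
      utils::head(ord, max_dets)
    }), use.names = FALSE)
    dets <- dets[sort(keep), , drop = FALSE]
  }
  ord <- order(-dets$score)          # stable: ties keep input order
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_by_img <- split(seq_len(nrow(gts)), gts$image_id)
  gt_used <- logical(nrow(gts))
  gmat <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(dets))) {
    gix <- gt_by_img[[as.character(dets$image_id[i])]]
    if (is.null(gix)) next
    d <- c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i])
    best <- -1; best_g <- 0L
    for (g in gix) {
      if (gt_used[g]) next
      v <- iou(d, gmat[g, ])
      if (v > best) { best <- v; best_g <- g }
    }
    if (best_g > 0L && best >= iou_thresh) {
      tp[i] <- TRUE
      gt_used[best_g] <- TRUE
    }
  }
  list(tp = tp, scores = dets$score, n_gt = nrow(gts))
}

#' Precision-recall points from greedy matching at one IoU threshold
#'
#' @param dets data.frame of detections (`image_id, x1, y1, x2, y2, score`).
#' @param gts data.frame of ground-truth boxes (`image_id, x1, y1, x2, y2`).
#' @param iou_thresh IoU threshold for a match.
#' @return data.frame with columns `recall` and `precision`, one row per
#'   detection in descending score order (cumulative counts). Zero rows if
#'   there are no detections.
#' @export
match_and_pr <- function(dets, gts, iou_thresh) {
  m <- match_detections(dets, gts, iou_thresh)
  k <- length(m$tp)
  if (k == 0L) return(data.frame(recall = numeric(0), precision = numeric(0)))
  ctp <- cumsum(m$tp)
  data.frame(recall = if (m$n_gt > 0) ctp / m$n_gt else rep(0, k),
             precision = ctp / seq_len(k))
}

#' 101-point interpolated average precision
#'
#' Precision is replaced by its running maximum over decreasing recall (the
#' precision envelope) and sampled on the recall grid `0, 0.01, ..., 1`;
#' the average of the 101 samples is the AP. Recalls never reached score a
#' precision of zero.
#'
#' @param pr data.frame from [match_and_pr()].
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(pr) {
  if (nrow(pr) == 0L) return(0)
  ord <- order(pr$recall)
  rec <- pr$recall[ord]
  prec <- pr$precision[ord]
  env <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, rec, left.open = TRUE) + 1L  # first point with recall >= r
  p <- ifelse(idx <= length(rec), env[idx], 0)
  mean(p)
}

#' Evaluate detections against ground truth
#'
#' Computes the COCO-style summary for a single foreground class: AP averaged
#' over the IoU thresholds `0.50:0.05:0.95`, AP50 and AP75 at the fixed
#' thresholds, and AR (recall at a per-image detection cap, averaged over the
#' same thresholds).
#'
#' @inheritParams match_and_pr
#' @param iou_thresholds vector of matching thresholds (default
#'   `seq(0.5, 0.95, 0.05)`).
#' @param max_dets per-image cap on detections entering the AR computation
#'   (default 100, the COCO convention).
#' @param image_ids optional explicit set of image ids; defaults to the union
#'   of ids present in `dets` and `gts`. Must be non-empty.
#' @return Object of class `eval_result`: list with `ap`, `ap50`, `ap75`,
#'   `ar`, `per_threshold` (named vector of per-threshold APs), and
#'   `per_threshold_recall`.
#' @export
evaluate_detections <- function(dets, gts,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                max_dets = 100L, image_ids = NULL) {
  .validate_boxes(dets, need_score = TRUE, what = "detections")
  .validate_boxes(gts, what = "ground truth")
  if (is.null(image_ids)) image_ids <- union(dets$image_id, gts$image_id)
  if (length(image_ids) == 0L) stop("no images to evaluate")
  aps <- numeric(length(iou_thresholds))
  recs <- numeric(length(iou_thresholds))
  for (i in seq_along(iou_thresholds)) {
    t <- iou_thresholds[i]
    aps[i] <- average_precision(match_and_pr(dets, gts, t))
    m <- match_detections(dets, gts, t, max_dets = max_dets)
    recs[i] <- if (m$n_gt > 0) sum(m$tp) / m$n_gt else 0
  }
  names(aps) <- names(recs) <- sprintf("%.2f", iou_thresholds)
  structure(list(ap = mean(aps),
                 ap50 = if ("0.50" %in% names(aps)) aps[["0.50"]] else NA_real_,
                 ap75 = if ("0.75" %in% names(aps)) aps[["0.75"]] else NA_real_,
                 ar = mean(recs),
                 per_threshold = aps,
                 per_threshold_recall = recs),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AP %.4f | AP50 %.4f | AP75 %.4f | AR %.4f\n",
              x$ap, x$ap50, x$ap75, x$ar))
  invisible(x)
}

#' Read COCO-dialect annotations into corner-coordinate boxes
#'
#' Expects the usual structure: `images` (id, file_name, width, height),
#' `annotations` (id, image_id, bbox `[x, y, w, h]`), `categories`. Bounding
#' boxes are converted to corner coordinates `x1 = x, y1 = y, x2 = x + w,
#' y2 = y + h`.
#'
#' @param path path to the JSON file.
#' @return list with `images` (data.frame) and `boxes` (data.frame with
#'   `image_id, x1, y1, x2, y2`).
#' @export
read_coco_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- do.call(rbind, lapply(j$images, function(im) {
    data.frame(id = im$id, file_name = im$file_name,
               width = im$width, height = im$height)
  }))
  boxes <- if (length(j$annotations)) {
    do.call(rbind, lapply(j$annotations, function(a) {
      bb <- as.numeric(unlist(a$bbox))
      data.frame(image_id = a$image_id, x1 = bb[1], y1 = bb[2],
                 x2 = bb[1] + bb[3], y2 = bb[2] + bb[4])
    }))
  } else {
    data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0))
  }
  list(images = images, boxes = boxes)
}

#' Write an evaluation result as JSON
#'
#' @param result an `eval_result` from [evaluate_detections()].
#' @param path output path.
#' @export
write_eval_result <- function(result, path) {
  stopifnot(inherits(result, "eval_result"))
  jsonlite::write_json(
    list(AP = result$ap, AP50 = result$ap50, AP75 = result$ap75,
         AR = result$ar, per_threshold = as.list(result$per_threshold)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
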