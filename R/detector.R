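# A deliberately tiny anchor-based single-stage detector: 4-stage conv
# backbone (strides 4, 8, 16, 32) -> FPN -> optional ABFP refinement ->
# shared classification/regression head over per-level anchors. Every layer
# has an analytic backward pass, so the whole model trains with plain SGD on
# one CPU and gradients can be checked against finite differences.

.DET_STRIDES <- c(4L, 8L, 16L, 32L)

#' Build the micro detector
#'
#' @param image_size input side length in pixels; must be divisible by the
#'   coarsest stride (32).
#' @param out_channels uniform neck width (default 16).
#' @param attention `TRUE` for the FPN + ABFP neck, `FALSE` for the
#'   convolution-refinement ablation arm.
#' @param reduction_ratio channel-attention reduction ratio (default 4).
#' @param widths backbone stage widths at strides 4/8/16/32.
#' @param stem_width width of the stride-2 stem convolution.
#' @param ratios anchor aspect ratios (height/width) per position.
#' @param anchor_scale anchor base size as a multiple of the level stride.
#' @param pos_iou,neg_iou anchor assignment thresholds: IoU >= `pos_iou` is
#'   positive, IoU < `neg_iou` negative, in between ignored.
#' @param prior_prob initial foreground probability used to set the
#'   classification bias.
#' @param seed RNG seed for Kaiming-uniform initialization.
#' @return Object of class `micro_detector`: list with `params` (flat named
#'   list of arrays), `cfg`, `neck_cfg`, and precomputed `anchors`.
#' @export
build_detector <- function(image_size = 128L, out_channels = 16L,
                           attention = TRUE, reduction_ratio = 4L,
                           widths = c(16L, 32L, 64L, 128L), stem_width = 8L,
                           ratios = c(0.5, 1, 2), anchor_scale = 4,
                           pos_iou = 0.5, neg_iou = 0.4,
                           prior_prob = 0.01, seed = 1L) {
  if (image_size %% max(.DET_STRIDES) != 0L) {
    stop("image size ", image_size, " is not divisible by the pyramid stride ",
         max(.DET_STRIDES))
  }
  stopifnot(length(widths) == 4L, length(ratios) >= 1L)
  set.seed(seed)
  A <- length(ratios)
  C <- as.integer(out_channels)
  p <- list()
  p[["bb.stem.w"]] <- .kaiming_uniform(c(1L, 3L, 3L, stem_width), 9L)
  p[["bb.stem.b"]] <- numeric(stem_width)
  p[["bb.stem.g"]] <- rep(1, stem_width)
  p[["bb.stem.s"]] <- numeric(stem_width)
  prev <- stem_width
  for (s in 1:4) {
    p[[paste0("bb.conv", s, ".w")]] <-
      .kaiming_uniform(c(prev, 3L, 3L, widths[s]), prev * 9L)
    p[[paste0("bb.conv", s, ".b")]] <- numeric(widths[s])
    p[[paste0("bb.conv", s, ".g")]] <- rep(1, widths[s])
    p[[paste0("bb.conv", s, ".s")]] <- numeric(widths[s])
    prev <- widths[s]
  }
  neck_cfg <- neck_config(in_channels = widths, out_channels = C,
                          attention = attention,
                          reduction_ratio = reduction_ratio)
  p <- c(p, fpn_params(neck_cfg), abfp_params(neck_cfg))
  p[["head.shared.w"]] <- .kaiming_uniform(c(C, 3L, 3L, C), C * 9L)
  p[["head.shared.b"]] <- numeric(C)
  p[["head.shared.g"]] <- rep(1, C)
  p[["head.shared.s"]] <- numeric(C)
  p[["head.cls.w"]] <- .kaiming_uniform(c(C, 3L, 3L, A), C * 9L)
  p[["head.cls.b"]] <- rep(-log((1 - prior_prob) / prior_prob), A)
  p[["head.reg.w"]] <- .kaiming_uniform(c(C, 3L, 3L, 4L * A), C * 9L)
  p[["head.reg.b"]] <- numeric(4L * A)
  cfg <- list(image_size = as.integer(image_size), out_channels = C,
              attention = isTRUE(attention), widths = widths,
              stem_width = stem_width, ratios = ratios,
              anchor_scale = anchor_scale, n_anchors = A,
              pos_iou = pos_iou, neg_iou = neg_iou, seed = as.integer(seed))
  structure(list(params = p, cfg = cfg, neck_cfg = neck_cfg,
                 anchors = build_anchors(image_size, ratios, anchor_scale)),
            class = "micro_detector")
}

#' @export
print.micro_detector <- function(x, ...) {
  cat("<micro_detector> image ", x$cfg$image_size, "px, neck width ",
      x$cfg$out_channels, ", attention ",
      if (x$cfg$attention) "on" else "off", ", ",
      detector_param_count(x), " parameters\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count of a detector
#' @param detector a [build_detector()] result.
#' @return integer count.
#' @export
detector_param_count <- function(detector) {
  sum(vapply(detector$params, length, integer(1)))
}

# Anchor table: one row per (level, column j, row i, ratio a), ordered to
# match the column-major flattening of the (A, H_l, W_l) head outputs
# (ratio fastest, then row, then column, levels concatenated fine->coarse).
build_anchors <- function(image_size, ratios, anchor_scale) {
  A <- length(ratios)
  out <- vector("list", length(.DET_STRIDES))
  level_sizes <- integer(length(.DET_STRIDES))
  for (l in seq_along(.DET_STRIDES)) {
    s <- .DET_STRIDES[l]
    H <- image_size %/% s; W <- image_size %/% s
    base <- anchor_scale * s
    a <- rep(seq_len(A), times = H * W)
    i <- rep(rep(seq_len(H), each = A), times = W)
    j <- rep(seq_len(W), each = A * H)
    cx <- (j - 0.5) * s; cy <- (i - 0.5) * s
    w <- base / sqrt(ratios[a]); h <- base * sqrt(ratios[a])
    out[[l]] <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    level_sizes[l] <- A * H * W
  }
  list(boxes = do.call(rbind, out), level_sizes = level_sizes,
       strides = .DET_STRIDES, n_per_cell = A)
}

# RetinaNet-style max-IoU assignment with per-GT force matching.
assign_anchors <- function(anchor_boxes, gt_boxes, pos_iou = 0.5,
                           neg_iou = 0.4) {
  n <- nrow(anchor_boxes)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0L) {
    return(list(labels = integer(n), gt_index = integer(n)))
  }
  M <- box_iou_matrix(anchor_boxes, gt_boxes)
  best <- do.call(pmax, c(lapply(seq_len(ncol(M)), function(g) M[, g]),
                          list(0)))
  gt_index <- max.col(M, ties.method = "first")
  labels <- integer(n)
  labels[best >= pos_iou] <- 1L
  labels[best >= neg_iou & best < pos_iou] <- -1L
  for (g in seq_len(ncol(M))) {       # every GT gets its best anchor
    jbest <- which.max(M[, g])
    if (M[jbest, g] > 0) { labels[jbest] <- 1L; gt_index[jbest] <- g }
  }
  list(labels = labels, gt_index = gt_index)
}

# (dx, dy, dw, dh) offsets of GT boxes relative to their anchors
encode_boxes <- function(anchors, gt) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  acx <- (anchors[, 1] + anchors[, 3]) / 2
  acy <- (anchors[, 2] + anchors[, 4]) / 2
  gw <- gt[, 3] - gt[, 1]; gh <- gt[, 4] - gt[, 2]
  gcx <- (gt[, 1] + gt[, 3]) / 2; gcy <- (gt[, 2] + gt[, 4]) / 2
  rbind((gcx - acx) / aw, (gcy - acy) / ah, log(gw / aw), log(gh / ah))
}

decode_boxes <- function(anchors, deltas) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  acx <- (anchors[, 1] + anchors[, 3]) / 2
  acy <- (anchors[, 2] + anchors[, 4]) / 2
  cx <- acx + deltas[1, ] * aw
  cy <- acy + deltas[2, ] * ah
  w <- aw * exp(pmin(pmax(deltas[3, ], -4), 4))
  h <- ah * exp(pmin(pmax(deltas[4, ], -4), 4))
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

detector_fwd <- function(detector, image) {
  cfg <- detector$cfg
  p <- detector$params
  if (is.matrix(image)) image <- array(image, c(1L, nrow(image), ncol(image)))
  if (dim(image)[2L] != cfg$image_size || dim(image)[3L] != cfg$image_size) {
    stop("image must be ", cfg$image_size, "x", cfg$image_size)
  }
  image <- (image - 0.5) * 2      # center [0,1] intensities
  conv_relu <- function(x, key, stride, norm = FALSE) {
    cv <- conv2d_fwd(x, p[[paste0(key, ".w")]], p[[paste0(key, ".b")]],
                     stride = stride, pad = 1L)
    if (norm) {
      nn <- instnorm_fwd(cv$out, p[[paste0(key, ".g")]],
                         p[[paste0(key, ".s")]])
      rl <- relu_fwd(nn$out)
      list(out = rl$out, cv = cv$cache, nn = nn$cache, rl = rl$cache)
    } else {
      rl <- relu_fwd(cv$out)
      list(out = rl$out, cv = cv$cache, nn = NULL, rl = rl$cache)
    }
  }
  stem <- conv_relu(image, "bb.stem", 2L, norm = TRUE)
  stages <- vector("list", 4L)
  x <- stem$out
  for (s in 1:4) {
    stages[[s]] <- conv_relu(x, paste0("bb.conv", s), 2L, norm = TRUE)
    x <- stages[[s]]$out
  }
  levels <- lapply(stages, `[[`, "out")
  fpn <- fpn_fwd(levels, detector$neck_cfg, p)
  neck <- abfp_fwd(fpn$out, detector$neck_cfg, p)
  n_lvl <- length(neck$out)
  head <- vector("list", n_lvl)
  cls <- vector("list", n_lvl); reg <- vector("list", n_lvl)
  for (l in seq_len(n_lvl)) {
    sh <- conv_relu(neck$out[[l]], "head.shared", 1L, norm = TRUE)
    cc <- conv2d_fwd(sh$out, p[["head.cls.w"]], p[["head.cls.b"]], pad = 1L)
    rc <- conv2d_fwd(sh$out, p[["head.reg.w"]], p[["head.reg.b"]], pad = 1L)
    head[[l]] <- list(sh = sh, cc = cc$cache, rc = rc$cache)
    cls[[l]] <- cc$out; reg[[l]] <- rc$out
  }
  list(cls = cls, reg = reg,
       cache = list(stem = stem, stages = stages, fpn = fpn, neck = neck,
                    head = head))
}

detector_bwd <- function(detector, cache, dcls, dreg) {
  p <- detector$params
  grads <- list()
  gadd <- function(key, val) grads[[key]] <<- (grads[[key]] %||% 0) + val
  bwd_conv_relu <- function(block, key, dout) {
    dpre <- relu_bwd(block$rl, dout)
    if (!is.null(block$nn)) {
      nb <- instnorm_bwd(block$nn, dpre)
      gadd(paste0(key, ".g"), nb$dgamma)
      gadd(paste0(key, ".s"), nb$dbeta)
      dpre <- nb$dx
    }
    cb <- conv2d_bwd(block$cv, dpre)
    gadd(paste0(key, ".w"), cb$dw)
    gadd(paste0(key, ".b"), cb$db)
    cb$dx
  }
  n_lvl <- length(dcls)
  dneck <- vector("list", n_lvl)
  for (l in seq_len(n_lvl)) {
    h <- cache$head[[l]]
    cb <- conv2d_bwd(h$cc, dcls[[l]])
    gadd("head.cls.w", cb$dw); gadd("head.cls.b", cb$db)
    rb <- conv2d_bwd(h$rc, dreg[[l]])
    gadd("head.reg.w", rb$dw); gadd("head.reg.b", rb$db)
    dneck[[l]] <- bwd_conv_relu(h$sh, "head.shared", cb$dx + rb$dx)
  }
  nb <- abfp_bwd(cache$neck$cache, dneck, grads)
  grads <- nb$grads
  fb <- fpn_bwd(cache$fpn$cache, nb$dlevels, grads)
  grads <- fb$grads
  dx <- NULL
  for (s in 4:1) {
    din <- if (s == 4L) fb$dlevels[[s]] else fb$dlevels[[s]] + dx
    dx <- bwd_conv_relu(cache$stages[[s]], paste0("bb.conv", s), din)
  }
  bwd_conv_relu(cache$stem, "bb.stem", dx)
  grads
}

# flatten per-level head outputs into the anchor ordering
flatten_cls <- function(cls) unlist(lapply(cls, as.vector), use.names = FALSE)
flatten_reg <- function(reg) {
  do.call(cbind, lapply(reg, function(r) matrix(as.vector(r), nrow = 4L)))
}

# inverse of the flattening, for gradients
unflatten_cls <- function(dz, cls) {
  out <- vector("list", length(cls)); ofs <- 0L
  for (l in seq_along(cls)) {
    n <- length(cls[[l]])
    out[[l]] <- array(dz[ofs + seq_len(n)], dim(cls[[l]]))
    ofs <- ofs + n
  }
  out
}

unflatten_reg <- function(dmat, reg) {
  out <- vector("list", length(reg)); ofs <- 0L
  for (l in seq_along(reg)) {
    n <- length(reg[[l]]) %/% 4L
    out[[l]] <- array(dmat[, ofs + seq_len(n)], dim(reg[[l]]))
    ofs <- ofs + n
  }
  out
}

#' Greedy non-maximum suppression
#'
#' @param boxes `n x 4` matrix of corner boxes.
#' @param scores length-`n` confidence scores.
#' @param iou_thresh suppression threshold (default 0.5).
#' @return integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.5) {
  ord <- order(-scores)
  if (length(ord) <= 2048L) {     # precompute all pairwise overlaps at once
    M <- box_iou_matrix(boxes, boxes)
    keep <- integer(0)
    while (length(ord)) {
      i <- ord[1L]
      keep <- c(keep, i)
      ord <- ord[-1L]
      if (!length(ord)) break
      ord <- ord[M[i, ord] <= iou_thresh]
    }
    return(keep)
  }
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (!length(ord)) break
    ious <- box_iou_matrix(matrix(boxes[i, ], 1L),
                           boxes[ord, , drop = FALSE])[1L, ]
    ord <- ord[ious <= iou_thresh]
  }
  keep
}

#' Decode detector outputs into scored boxes
#'
#' Applies the sigmoid to the classification logits, keeps anchors above the
#' score threshold (capped at `pre_nms` per image), decodes the box deltas
#' against their anchors, clips to the image, and runs class-agnostic NMS.
#'
#' @param detector a [build_detector()] result.
#' @param images list of `H x W` matrices in `[0, 1]`.
#' @param image_ids ids to attach to the detections.
#' @param score_thresh minimum score (default 0.05).
#' @param nms_iou NMS IoU threshold (default 0.5).
#' @param max_per_image cap on detections per image (default 100).
#' @param pre_nms cap on candidates entering NMS (default 1000).
#' @return data.frame `image_id, x1, y1, x2, y2, score`.
#' @export
predict_detector <- function(detector, images, image_ids = seq_along(images),
                             score_thresh = 0.05, nms_iou = 0.5,
                             max_per_image = 100L, pre_nms = 1000L) {
  res <- vector("list", length(images))
  size <- detector$cfg$image_size
  for (k in seq_along(images)) {
    fw <- detector_fwd(detector, images[[k]])
    z <- flatten_cls(fw$cls)
    scores <- sigmoid(z)
    cand <- which(scores > score_thresh)
    if (!length(cand)) next
    if (length(cand) > pre_nms) {
      cand <- cand[order(-scores[cand])[seq_len(pre_nms)]]
    }
    deltas <- flatten_reg(fw$reg)[, cand, drop = FALSE]
    boxes <- decode_boxes(detector$anchors$boxes[cand, , drop = FALSE], deltas)
    boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), size)
    boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), size)
    ok <- boxes[, 3] - boxes[, 1] > 1e-3 & boxes[, 4] - boxes[, 2] > 1e-3
    boxes <- boxes[ok, , drop = FALSE]
    sc <- scores[cand][ok]
    if (!nrow(boxes)) next
    keep <- nms(boxes, sc, nms_iou)
    keep <- utils::head(keep, max_per_image)
    res[[k]] <- data.frame(image_id = image_ids[k],
                           x1 = boxes[keep, 1], y1 = boxes[keep, 2],
                           x2 = boxes[keep, 3], y2 = boxes[keep, 4],
                           score = sc[keep])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), score = numeric(0))
  }
  rownames(out) <- NULL
  out
}
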