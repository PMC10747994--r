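# Deterministic synthetic inputs: (a) seeded random feature pyramids for unit
# tests, and (b) CT-like grayscale slices with low-contrast elliptical
# "lesions" on a smoothly textured background, with tight ground-truth boxes,
# written as 8-bit PNG plus COCO-dialect JSON.

#' Generate a seeded random feature pyramid
#'
#' Standard-normal activations, spatial shapes ceil-halving from `base_hw`.
#' Bit-identical for identical seeds.
#'
#' @param n_levels number of levels `N >= 1`.
#' @param channels shared channel count `C`.
#' @param base_hw integer `c(H, W)` (or scalar) of the finest level.
#' @param seed RNG seed.
#' @return A [feature_pyramid()].
#' @export
make_pyramid <- function(n_levels, channels, base_hw, seed = 1L) {
  if (length(base_hw) == 1L) base_hw <- c(base_hw, base_hw)
  set.seed(seed)
  h <- base_hw[1L]; w <- base_hw[2L]
  levels <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    levels[[l]] <- array(stats::rnorm(channels * h * w), c(channels, h, w))
    h <- ceiling(h / 2); w <- ceiling(w / 2)
  }
  feature_pyramid(levels)
}

#' Specification of a synthetic lesion scene
#'
#' Describes the study conditions the generator emulates: 2-d grayscale
#' slices whose lesions are low-contrast ellipses of varying size, shape and
#' orientation with blurred edges, sitting on smooth anatomical-looking
#' background texture, degraded by additive Gaussian noise.
#'
#' @param image_size side length in pixels (default 128; 512 supported).
#' @param n_lesions lesions per image (exact count, `>= 0`).
#' @param contrast lesion-minus-background intensity gap in `[0, 1]`;
#'   default 0.15, deliberately low.
#' @param noise_sigma standard deviation of the additive pixel noise.
#' @param texture list with `scale` (correlation length in pixels),
#'   `amplitude` (intensity s.d. of the smooth field) and `mean` (background
#'   gray level).
#' @param edge_sigma Gaussian blur (pixels) applied to the lesion mask to
#'   blur the lesion boundary.
#' @param axis_range semi-axis range as a fraction of `image_size`.
#' @param seed RNG seed; the whole dataset is a pure function of the spec.
#' @return Object of class `lesion_scene_spec`.
#' @export
lesion_scene_spec <- function(image_size = 128L, n_lesions = 2L,
                              contrast = 0.15, noise_sigma = 0.03,
                              texture = list(scale = 16, amplitude = 0.04,
                                             mean = 0.45),
                              edge_sigma = 1.5,
                              axis_range = c(0.045, 0.125), seed = 1L) {
  stopifnot(image_size >= 16L, n_lesions >= 0L, contrast >= 0, contrast <= 1,
            noise_sigma >= 0, axis_range[1] > 0, axis_range[2] >= axis_range[1])
  if (2 * axis_range[2] * image_size >= image_size - 4) {
    stop("lesion larger than image")
  }
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 contrast = contrast, noise_sigma = noise_sigma,
                 texture = texture, edge_sigma = edge_sigma,
                 axis_range = axis_range, seed = as.integer(seed)),
            class = "lesion_scene_spec")
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a matrix (zero padding at the border)
.blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  x <- array(m, c(1L, nrow(m), ncol(m)))
  x <- conv2d_fwd(x, array(k, c(1L, length(k), 1L, 1L)), pad = 0L,
                  stride = 1L)$out
  # pad rows manually to keep shape: conv above shrank rows by 2r
  full <- matrix(0, nrow(m), ncol(m))
  full[(r + 1L):(nrow(m) - r), ] <- x[1L, , ]
  x <- array(full, c(1L, nrow(m), ncol(m)))
  x <- conv2d_fwd(x, array(k, c(1L, 1L, length(k), 1L)), pad = 0L,
                  stride = 1L)$out
  out <- matrix(0, nrow(m), ncol(m))
  out[, (r + 1L):(ncol(m) - r)] <- x[1L, , ]
  out
}

# smooth random background field ~ mean + amplitude * (coarse noise,
# bilinearly upsampled)
.background <- function(size, texture) {
  n <- max(2L, ceiling(size / texture$scale))
  coarse <- array(stats::rnorm(n * n), c(1L, n, n))
  f <- resize_bilinear_fwd(coarse, size, size)$out[1L, , ]
  texture$mean + texture$amplitude * f
}

# Rasterize a rotated ellipse on pixel centers (x = col - 0.5, y = row - 0.5).
lesion_mask <- function(size, cx, cy, a, b, theta) {
  xs <- seq_len(size) - 0.5
  ys <- seq_len(size) - 0.5
  X <- matrix(xs, size, size, byrow = TRUE) - cx
  Y <- matrix(ys, size, size) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# tight axis-aligned extents of a rotated ellipse
.ellipse_extents <- function(a, b, theta) {
  c(ex = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    ey = sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

#' Generate a synthetic lesion-detection dataset
#'
#' Each image is a smooth textured background plus `spec$n_lesions`
#' non-overlapping low-contrast ellipses (random center, semi-axes,
#' orientation) whose edges are blurred, then additive Gaussian noise,
#' clamped to `[0, 1]`. Bounding boxes are the tight analytic extents of each
#' ellipse. The dataset is bit-identical when regenerated from the same spec.
#'
#' @param spec a [lesion_scene_spec()].
#' @param n_images number of images.
#' @return list with `images` (list of `size x size` matrices in `[0, 1]`),
#'   `annotations` (data.frame `id, image_id, x1, y1, x2, y2, cx, cy, a, b,
#'   theta`), `image_ids`, and `spec`.
#' @export
make_lesion_dataset <- function(spec, n_images) {
  stopifnot(inherits(spec, "lesion_scene_spec"), n_images >= 1L)
  set.seed(spec$seed)
  size <- spec$image_size
  ax_lo <- spec$axis_range[1] * size
  ax_hi <- spec$axis_range[2] * size
  images <- vector("list", n_images)
  ann <- vector("list", n_images)
  aid <- 0L
  for (img in seq_len(n_images)) {
    canvas <- .background(size, spec$texture)
    boxes <- matrix(numeric(0), ncol = 4L)
    rows <- list()
    placed <- 0L
    tries <- 0L
    while (placed < spec$n_lesions && tries < 200L) {
      tries <- tries + 1L
      a <- stats::runif(1, ax_lo, ax_hi)
      b <- stats::runif(1, ax_lo, ax_hi)
      theta <- stats::runif(1, 0, pi)
      ext <- .ellipse_extents(a, b, theta)
      margin <- 2
      if (2 * max(ext) + 2 * margin >= size) stop("lesion larger than image")
      cx <- stats::runif(1, ext["ex"] + margin, size - ext["ex"] - margin)
      cy <- stats::runif(1, ext["ey"] + margin, size - ext["ey"] - margin)
      box <- c(cx - ext["ex"], cy - ext["ey"], cx + ext["ex"], cy + ext["ey"])
      if (nrow(boxes) &&
          any(box_iou_matrix(matrix(box, 1L), boxes) > 0)) next
      placed <- placed + 1L
      aid <- aid + 1L
      boxes <- rbind(boxes, box)
      mask <- lesion_mask(size, cx, cy, a, b, theta)
      soft <- .blur(mask * 1.0, spec$edge_sigma)
      canvas <- canvas + spec$contrast * soft
      rows[[placed]] <- data.frame(id = aid, image_id = img,
                                   x1 = box[1], y1 = box[2],
                                   x2 = box[3], y2 = box[4],
                                   cx = cx, cy = cy, a = a, b = b,
                                   theta = theta)
    }
    if (placed < spec$n_lesions) {
      stop("could not place ", spec$n_lesions, " non-overlapping lesions")
    }
    if (spec$noise_sigma > 0) {
      canvas <- canvas + matrix(stats::rnorm(size * size, 0, spec$noise_sigma),
                                size, size)
    }
    images[[img]] <- pmin(pmax(canvas, 0), 1)
    ann[[img]] <- if (placed) do.call(rbind, rows) else NULL
  }
  annotations <- do.call(rbind, ann)
  if (is.null(annotations)) {
    annotations <- data.frame(id = integer(0), image_id = integer(0),
                              x1 = numeric(0), y1 = numeric(0),
                              x2 = numeric(0), y2 = numeric(0),
                              cx = numeric(0), cy = numeric(0),
                              a = numeric(0), b = numeric(0),
                              theta = numeric(0))
  }
  rownames(annotations) <- NULL
  list(images = images, annotations = annotations,
       image_ids = seq_len(n_images), spec = spec)
}

#' Split a dataset into train/test image index sets
#'
#' Images (not individual lesions) are assigned to splits by shuffled index,
#' mirroring a patient-level split at toy scale.
#'
#' @param dataset result of [make_lesion_dataset()].
#' @param train_frac fraction of images in the training split.
#' @param seed shuffle seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1L) {
  n <- length(dataset$images)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- min(n - 1L, max(1L, floor(train_frac * n)))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

#' Write a lesion dataset as PNG images plus COCO-dialect JSON
#'
#' @param dataset result of [make_lesion_dataset()].
#' @param dir output directory (created if missing); images are written as
#'   8-bit grayscale `img_<id>.png` and annotations as `annotations.json`
#'   with `bbox = [x, y, w, h]` records.
#' @return the directory path, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  size <- dataset$spec$image_size
  files <- sprintf("img_%04d.png", dataset$image_ids)
  for (i in seq_along(dataset$images)) {
    png::writePNG(dataset$images[[i]], file.path(dir, files[i]))
  }
  ann <- dataset$annotations
  j <- list(
    images = lapply(seq_along(files), function(i) {
      list(id = dataset$image_ids[i], file_name = files[i],
           width = size, height = size)
    }),
    annotations = lapply(seq_len(nrow(ann)), function(k) {
      list(id = ann$id[k], image_id = ann$image_id[k],
           category_id = 1L,
           bbox = c(ann$x1[k], ann$y1[k],
                    ann$x2[k] - ann$x1[k], ann$y2[k] - ann$y1[k]),
           area = (ann$x2[k] - ann$x1[k]) * (ann$y2[k] - ann$y1[k]),
           iscrowd = 0L,
           ellipse = list(cx = ann$cx[k], cy = ann$cy[k], a = ann$a[k],
                          b = ann$b[k], theta = ann$theta[k]))
    }),
    categories = list(list(id = 1L, name = "lesion"))
  )
  jsonlite::write_json(j, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a lesion dataset written by [write_lesion_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `images` (list of matrices), `annotations`
#'   (corner-coordinate data.frame) and `image_ids`.
#' @export
read_lesion_dataset <- function(dir) {
  cc <- read_coco_annotations(file.path(dir, "annotations.json"))
  images <- lapply(seq_len(nrow(cc$images)), function(i) {
    m <- png::readPNG(file.path(dir, cc$images$file_name[i]))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  list(images = images, annotations = cc$boxes, image_ids = cc$images$id)
}
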