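#' Construct a multi-level feature pyramid
#'
#' A feature pyramid is an ordered list of feature maps, each a numeric array
#' of dimension `channels x height x width`, whose spatial resolution halves
#' (ceiling division, so odd sizes are allowed) from one level to the next —
#' the `{C2..C5}` / `{P2..P5}` structure produced by a detection backbone or
#' neck. Levels produced by a neck share one channel count `C`, which is what
#' makes the unweighted cross-level average of the balanced feature pyramid
#' well defined; raw backbone pyramids may carry differing per-level channel
#' counts, in which case `channel_count` is `NA` and integration is rejected.
#'
#' @param levels list of numeric 3-d arrays, finest resolution first, each
#'   with dim `c(C, H_l, W_l)`.
#' @param level_names optional character vector of level identifiers; defaults
#'   to `"P2", "P3", ...`.
#' @return An object of class `feature_pyramid`: a list with elements
#'   `levels`, `level_names`, and `channel_count`.
#' @examples
#' p <- feature_pyramid(list(array(0, c(8, 16, 16)), array(0, c(8, 8, 8))))
#' p$channel_count
#' @export
feature_pyramid <- function(levels, level_names = NULL) {
  if (!is.list(levels) || length(levels) < 1L) {
    stop("'levels' must be a non-empty list of C x H x W arrays")
  }
  dims <- lapply(levels, function(x) {
    if (!is.numeric(x) || length(dim(x)) != 3L) {
      stop("each pyramid level must be a numeric 3-d array (C x H x W)")
    }
    if (any(dim(x) == 0L)) stop("zero-sized feature map is not allowed")
    dim(x)
  })
  chans <- vapply(dims, `[`, numeric(1), 1L)
  C <- if (length(unique(chans)) == 1L) as.integer(chans[1L]) else NA_integer_
  for (l in seq_along(dims)) {
    if (l > 1L) {
      ok <- dims[[l]][2L] == ceiling(dims[[l - 1L]][2L] / 2) &&
            dims[[l]][3L] == ceiling(dims[[l - 1L]][3L] / 2)
      if (!ok) {
        stop("level ", l, " must have ceil-halved spatial shape of level ",
             l - 1L, " (got ", dims[[l]][2L], "x", dims[[l]][3L], ")")
      }
    }
  }
  if (is.null(level_names)) level_names <- paste0("P", seq_along(levels) + 1L)
  stopifnot(length(level_names) == length(levels))
  structure(list(levels = levels, level_names = level_names,
                 channel_count = C),
            class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("<feature_pyramid> ", length(x$levels), " levels, C = ",
      x$channel_count, "\n", sep = "")
  for (l in seq_along(x$levels)) {
    d <- dim(x$levels[[l]])
    cat("  ", x$level_names[l], ": ", d[1L], " x ", d[2L], " x ", d[3L],
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.feature_pyramid <- function(x) length(x$levels)

pyramid_shapes <- function(pyramid) lapply(pyramid$levels, dim)

#' Construct a balanced semantic map
#'
#' The balanced semantic map is a single feature map at the resolution of one
#' "intermediate" pyramid level. It holds the unweighted mean of all rescaled
#' levels before refinement and the attention-refined map afterwards.
#'
#' @param map numeric array, dim `c(C, H, W)`.
#' @param source_level_index 1-based index of the pyramid level whose spatial
#'   shape the map shares.
#' @return Object of class `balanced_semantic_map`.
#' @export
balanced_semantic_map <- function(map, source_level_index) {
  stopifnot(is.numeric(map), length(dim(map)) == 3L,
            source_level_index >= 1L)
  structure(list(map = map, source_level_index = as.integer(source_level_index)),
            class = "balanced_semantic_map")
}

#' @export
print.balanced_semantic_map <- function(x, ...) {
  d <- dim(x$map)
  cat("<balanced_semantic_map> ", d[1L], " x ", d[2L], " x ", d[3L],
      " (level index ", x$source_level_index, ")\n", sep = "")
  invisible(x)
}

# Internal rescale with cache: integer-factor downscale -> non-overlapping max
# pooling with kernel = stride = factor (one pool covers multiple octaves);
# everything else -> nearest-neighbour interpolation to the exact target.
rescale_fwd <- function(map, to_h, to_w, upsample_mode = "nearest") {
  d <- dim(map)
  if (to_h == d[2L] && to_w == d[3L]) {
    return(list(out = map, cache = list(kind = "id")))
  }
  down <- to_h <= d[2L] && to_w <= d[3L]
  if (down && d[2L] %% to_h == 0L && d[3L] %% to_w == 0L) {
    r <- maxpool_fwd(map, d[2L] %/% to_h, d[3L] %/% to_w)
    return(list(out = r$out, cache = list(kind = "pool", c = r$cache)))
  }
  if (!down && upsample_mode == "bilinear") {
    r <- resize_bilinear_fwd(map, to_h, to_w)
    return(list(out = r$out, cache = list(kind = "bilinear", c = r$cache)))
  }
  r <- resize_nearest_fwd(map, to_h, to_w)
  list(out = r$out, cache = list(kind = "nearest", c = r$cache))
}

rescale_bwd <- function(cache, dout) {
  switch(cache$kind,
         id = dout,
         pool = maxpool_bwd(cache$c, dout),
         bilinear = resize_bilinear_bwd(cache$c, dout),
         nearest = resize_nearest_bwd(cache$c, dout))
}

#' Rescale a feature map to another pyramid level's spatial shape
#'
#' Downscaling uses non-overlapping max pooling whenever the scale factor is
#' an integer on both axes (a single pooling window whose stride equals the
#' total factor, so a two-octave jump pools 4x4 blocks); upscaling uses
#' nearest-neighbour interpolation by default, replicating pixels exactly for
#' integer factors. Non-integer factors (which arise between ceil-halved odd
#' shapes, e.g. 5x5 -> 3x3) fall back to nearest-neighbour interpolation to
#' the exact target shape in either direction.
#'
#' @param map numeric array `c(C, H, W)`.
#' @param to_shape integer vector `c(H, W)` target spatial shape.
#' @param mode `"down"` requires the target to be no larger than the source on
#'   both axes, `"up"` the converse; equal shapes are allowed in either mode.
#' @param upsample_mode `"nearest"` (default) or `"bilinear"`.
#' @return A numeric array `c(C, to_shape)`.
#' @examples
#' m <- array(c(1, 3, 2, 4), c(1, 2, 2))
#' rescale_to_level(m, c(1, 1), "down")[1, , ]  # max over the window -> 4
#' @export
rescale_to_level <- function(map, to_shape, mode = c("down", "up"),
                             upsample_mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(is.numeric(map), length(dim(map)) == 3L)
  d <- dim(map)
  if (any(d == 0L) || any(to_shape < 1L)) {
    stop("zero-sized source or target map")
  }
  to_h <- as.integer(to_shape[1L]); to_w <- as.integer(to_shape[2L])
  if (mode == "down" && (to_h > d[2L] || to_w > d[3L])) {
    stop("mode 'down' requires target shape <= source shape on both axes")
  }
  if (mode == "up" && (to_h < d[2L] || to_w < d[3L])) {
    stop("mode 'up' requires target shape >= source shape on both axes")
  }
  rescale_fwd(map, to_h, to_w, upsample_mode)$out
}

# Forward with caches, used by both the public API and the training path.
integrate_fwd <- function(levels, idx, upsample_mode = "nearest") {
  C <- dim(levels[[1L]])[1L]
  for (l in seq_along(levels)) {
    if (dim(levels[[l]])[1L] != C) {
      stop("mismatched channel counts across pyramid levels")
    }
  }
  to <- dim(levels[[idx]])[2:3]
  caches <- vector("list", length(levels))
  acc <- 0
  for (l in seq_along(levels)) {
    r <- rescale_fwd(levels[[l]], to[1L], to[2L], upsample_mode)
    caches[[l]] <- r$cache
    acc <- acc + r$out
  }
  list(out = acc / length(levels), caches = caches, n = length(levels))
}

integrate_bwd <- function(fw, dout) {
  g <- dout / fw$n
  lapply(fw$caches, rescale_bwd, dout = g)
}

strengthen_fwd <- function(levels, refined, upsample_mode = "nearest") {
  caches <- vector("list", length(levels))
  outs <- vector("list", length(levels))
  for (l in seq_along(levels)) {
    to <- dim(levels[[l]])[2:3]
    r <- rescale_fwd(refined, to[1L], to[2L], upsample_mode)
    caches[[l]] <- r$cache
    outs[[l]] <- levels[[l]] + r$out
  }
  list(out = outs, caches = caches)
}

strengthen_bwd <- function(fw, douts) {
  drefined <- 0
  for (l in seq_along(douts)) {
    drefined <- drefined + rescale_bwd(fw$caches[[l]], douts[[l]])
  }
  list(dlevels = douts, drefined = drefined)
}

default_intermediate_index <- function(n_levels) n_levels %/% 2L + 1L

#' Integrate a pyramid into its balanced semantic map
#'
#' Every level is rescaled to the spatial shape of the intermediate level and
#' the rescaled maps are averaged element-wise with equal weights:
#' `C_bar = (1/N) * sum_l resize(C_l)`. The operation has no learned
#' parameters. With a single-level pyramid the level is returned unchanged.
#'
#' @param pyramid a [feature_pyramid()].
#' @param intermediate_index 1-based index of the target level; defaults to
#'   `N %/% 2 + 1`, the coarser of the two middle levels of a 4-level pyramid.
#' @param upsample_mode interpolation used when a coarser level is brought up
#'   to the intermediate resolution.
#' @return A [balanced_semantic_map()].
#' @export
integrate_pyramid <- function(pyramid, intermediate_index = NULL,
                              upsample_mode = c("nearest", "bilinear")) {
  stopifnot(inherits(pyramid, "feature_pyramid"))
  upsample_mode <- match.arg(upsample_mode)
  n <- length(pyramid$levels)
  if (is.null(intermediate_index)) intermediate_index <- default_intermediate_index(n)
  if (intermediate_index < 1L || intermediate_index > n) {
    stop("intermediate_index must be in [1, ", n, "]")
  }
  fw <- integrate_fwd(pyramid$levels, intermediate_index, upsample_mode)
  balanced_semantic_map(fw$out, intermediate_index)
}

#' Strengthen a pyramid with a (refined) balanced semantic map
#'
#' The inverse of [integrate_pyramid()]: the refined balanced map is rescaled
#' back to every level's own spatial shape (max pooling towards coarser
#' levels, nearest-neighbour interpolation towards finer ones) and added
#' element-wise to the original level, so every level receives the same
#' aggregated information. Output shapes equal input shapes exactly.
#'
#' @param pyramid a [feature_pyramid()].
#' @param refined a [balanced_semantic_map()] whose map has the spatial shape
#'   of the level it was integrated at.
#' @param upsample_mode interpolation for levels finer than the refined map.
#' @return A [feature_pyramid()] with identical shape signature.
#' @export
strengthen_pyramid <- function(pyramid, refined,
                               upsample_mode = c("nearest", "bilinear")) {
  stopifnot(inherits(pyramid, "feature_pyramid"),
            inherits(refined, "balanced_semantic_map"))
  upsample_mode <- match.arg(upsample_mode)
  idx <- refined$source_level_index
  if (idx > length(pyramid$levels) ||
      !all(dim(refined$map) == dim(pyramid$levels[[idx]]))) {
    stop("refined map shape does not match pyramid level ", idx)
  }
  fw <- strengthen_fwd(pyramid$levels, refined$map, upsample_mode)
  feature_pyramid(fw$out, pyramid$level_names)
}
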