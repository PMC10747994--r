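# Baseline top-down FPN and the composed FPN + ABFP neck:
# rescale -> integrate -> refine (parallel attention) -> strengthen,
# applied to the uniform-channel FPN outputs. The neck consumes and produces
# pyramids with identical shape signatures, so the refinement is stackable on
# any producer of a uniform-channel pyramid.

#' Neck configuration
#'
#' @param in_channels integer vector of per-level backbone channel counts
#'   (finest level first); its length fixes the number of levels `N`.
#' @param out_channels uniform channel width of the neck outputs (default 256).
#' @param intermediate_index 1-based pyramid level at which the balanced
#'   semantic map lives; default `N %/% 2 + 1` (the coarser middle level).
#' @param attention `TRUE` for the parallel-attention refinement, `FALSE` for
#'   the ablation arm where refinement is a single 3x3 convolution.
#' @param reduction_ratio channel-attention reduction ratio.
#' @param upsample_mode `"nearest"` (default) or `"bilinear"` for all
#'   upscaling inside the neck.
#' @param attention_bias include bias terms in the attention MLP and 7x7 conv.
#' @return Object of class `neck_config`.
#' @export
neck_config <- function(in_channels, out_channels = 256L,
                        intermediate_index = NULL, attention = TRUE,
                        reduction_ratio = 16L,
                        upsample_mode = c("nearest", "bilinear"),
                        attention_bias = TRUE) {
  upsample_mode <- match.arg(upsample_mode)
  in_channels <- as.integer(in_channels)
  n <- length(in_channels)
  stopifnot(n >= 2L, all(in_channels > 0L), out_channels > 0L)
  if (is.null(intermediate_index)) intermediate_index <- default_intermediate_index(n)
  stopifnot(intermediate_index >= 1L, intermediate_index <= n)
  structure(list(in_channels = in_channels,
                 out_channels = as.integer(out_channels),
                 intermediate_index = as.integer(intermediate_index),
                 attention = isTRUE(attention),
                 reduction_ratio = as.integer(reduction_ratio),
                 upsample_mode = upsample_mode,
                 attention_bias = isTRUE(attention_bias)),
            class = "neck_config")
}

#' Read / write a neck configuration as YAML
#'
#' @param cfg a [neck_config()].
#' @param path file path.
#' @return `read_neck_config()` returns a `neck_config`.
#' @export
write_neck_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "neck_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_neck_config
#' @export
read_neck_config <- function(path) {
  v <- yaml::read_yaml(path)
  neck_config(in_channels = v$in_channels, out_channels = v$out_channels,
              intermediate_index = v$intermediate_index,
              attention = v$attention, reduction_ratio = v$reduction_ratio,
              upsample_mode = v$upsample_mode,
              attention_bias = v$attention_bias)
}

#' Initialize FPN parameters
#'
#' Standard top-down FPN: per-level 1x1 lateral convolutions onto the shared
#' width, nearest-neighbour top-down addition, and per-level 3x3 output
#' convolutions. Keys: `fpn.lateral<l>.{w,b}`, `fpn.out<l>.{w,b}`.
#'
#' @param cfg a [neck_config()].
#' @param seed optional RNG seed (Kaiming-uniform weights, zero biases).
#' @return Flat named list of parameter arrays.
#' @export
fpn_params <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "neck_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  oc <- cfg$out_channels
  for (l in seq_along(cfg$in_channels)) {
    ic <- cfg$in_channels[l]
    p[[paste0("fpn.lateral", l, ".w")]] <-
      .kaiming_uniform(c(ic, 1L, 1L, oc), ic)
    p[[paste0("fpn.lateral", l, ".b")]] <- numeric(oc)
    p[[paste0("fpn.out", l, ".w")]] <-
      .kaiming_uniform(c(oc, 3L, 3L, oc), oc * 9L)
    p[[paste0("fpn.out", l, ".b")]] <- numeric(oc)
  }
  p
}

#' Initialize ABFP refinement parameters
#'
#' With `cfg$attention` on: channel-attention MLP (`att.ch.w0/b0/w1/b1`) and
#' spatial 7x7 kernel (`att.sp.w/b`). With attention off: one 3x3 refinement
#' convolution (`att.refine.w/b`).
#'
#' @inheritParams fpn_params
#' @return Flat named list of parameter arrays.
#' @export
abfp_params <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "neck_config"))
  if (!is.null(seed)) set.seed(seed)
  C <- cfg$out_channels
  p <- list()
  if (cfg$attention) {
    cap <- channel_attention_params(C, cfg$reduction_ratio,
                                    bias = cfg$attention_bias)
    sap <- spatial_attention_params(bias = cfg$attention_bias)
    p[["att.ch.w0"]] <- cap$w0; p[["att.ch.w1"]] <- cap$w1
    if (cfg$attention_bias) { p[["att.ch.b0"]] <- cap$b0; p[["att.ch.b1"]] <- cap$b1 }
    p[["att.sp.w"]] <- sap$kernel
    if (cfg$attention_bias) p[["att.sp.b"]] <- sap$bias
  } else {
    p[["att.refine.w"]] <- .kaiming_uniform(c(C, 3L, 3L, C), C * 9L)
    p[["att.refine.b"]] <- numeric(C)
  }
  p
}

.cap_from_flat <- function(p, cfg) {
  structure(list(w0 = p[["att.ch.w0"]], b0 = p[["att.ch.b0"]],
                 w1 = p[["att.ch.w1"]], b1 = p[["att.ch.b1"]],
                 channels = cfg$out_channels,
                 reduction = min(cfg$reduction_ratio, cfg$out_channels)),
            class = "channel_attention_params")
}

.sap_from_flat <- function(p) {
  structure(list(kernel = p[["att.sp.w"]], bias = p[["att.sp.b"]]),
            class = "spatial_attention_params")
}

#' Closed-form count of the ABFP refinement parameters
#'
#' With attention on: shared MLP `2 * C * (C/r)` weights (plus `C/r + C`
#' biases), and the 7x7 2-plane spatial kernel `7*7*2` (plus 1 bias). With
#' attention off: the 3x3 refinement convolution `9*C^2` (plus `C` biases).
#'
#' @param cfg a [neck_config()].
#' @return Integer parameter count.
#' @export
abfp_param_count <- function(cfg) {
  C <- cfg$out_channels
  if (cfg$attention) {
    r <- min(cfg$reduction_ratio, C)
    hidden <- C %/% r
    n <- 2L * C * hidden + 7L * 7L * 2L
    if (cfg$attention_bias) n <- n + hidden + C + 1L
  } else {
    n <- 9L * C * C + C
  }
  as.integer(n)
}

fpn_fwd <- function(levels, cfg, params) {
  n <- length(levels)
  if (n != length(cfg$in_channels)) {
    stop("pyramid has ", n, " levels but config expects ",
         length(cfg$in_channels))
  }
  lat <- vector("list", n); lat_cache <- vector("list", n)
  for (l in seq_len(n)) {
    if (dim(levels[[l]])[1L] != cfg$in_channels[l]) {
      stop("level ", l, " has ", dim(levels[[l]])[1L],
           " channels, config expects ", cfg$in_channels[l])
    }
    cv <- conv2d_fwd(levels[[l]], params[[paste0("fpn.lateral", l, ".w")]],
                     params[[paste0("fpn.lateral", l, ".b")]])
    lat[[l]] <- cv$out; lat_cache[[l]] <- cv$cache
  }
  td <- vector("list", n); up_cache <- vector("list", n)
  td[[n]] <- lat[[n]]
  for (l in seq(n - 1L, 1L)) {
    to <- dim(lat[[l]])[2:3]
    r <- rescale_fwd(td[[l + 1L]], to[1L], to[2L], cfg$upsample_mode)
    up_cache[[l]] <- r$cache
    td[[l]] <- lat[[l]] + r$out
  }
  outs <- vector("list", n); out_cache <- vector("list", n)
  for (l in seq_len(n)) {
    cv <- conv2d_fwd(td[[l]], params[[paste0("fpn.out", l, ".w")]],
                     params[[paste0("fpn.out", l, ".b")]], pad = 1L)
    outs[[l]] <- cv$out; out_cache[[l]] <- cv$cache
  }
  list(out = outs,
       cache = list(lat_cache = lat_cache, up_cache = up_cache,
                    out_cache = out_cache, n = n))
}

fpn_bwd <- function(cache, douts, grads = list()) {
  n <- cache$n
  dtd <- vector("list", n)
  for (l in seq_len(n)) {
    cb <- conv2d_bwd(cache$out_cache[[l]], douts[[l]])
    grads[[paste0("fpn.out", l, ".w")]] <-
      (grads[[paste0("fpn.out", l, ".w")]] %||% 0) + cb$dw
    grads[[paste0("fpn.out", l, ".b")]] <-
      (grads[[paste0("fpn.out", l, ".b")]] %||% 0) + cb$db
    dtd[[l]] <- cb$dx
  }
  dlat <- vector("list", n)
  for (l in seq_len(n - 1L)) {
    dlat[[l]] <- dtd[[l]]
  }
  dlat[[n]] <- dtd[[n]]
  for (l in seq_len(n - 1L)) {
    # top-down addition: gradient flows up the chain into coarser laterals
    dlat[[l + 1L]] <- dlat[[l + 1L]] + rescale_bwd(cache$up_cache[[l]], dlat[[l]])
  }
  dlevels <- vector("list", n)
  for (l in seq_len(n)) {
    cb <- conv2d_bwd(cache$lat_cache[[l]], dlat[[l]])
    grads[[paste0("fpn.lateral", l, ".w")]] <-
      (grads[[paste0("fpn.lateral", l, ".w")]] %||% 0) + cb$dw
    grads[[paste0("fpn.lateral", l, ".b")]] <-
      (grads[[paste0("fpn.lateral", l, ".b")]] %||% 0) + cb$db
    dlevels[[l]] <- cb$dx
  }
  list(dlevels = dlevels, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline FPN forward pass
#'
#' 1x1 lateral convolutions project each backbone level onto the shared
#' width, coarser levels are upsampled and added top-down, and a 3x3
#' convolution smooths each merged level. Spatial shapes are preserved per
#' level.
#'
#' @param backbone_features a [feature_pyramid()] whose per-level channel
#'   counts match `cfg$in_channels`.
#' @param cfg a [neck_config()].
#' @param params flat parameter list from [fpn_params()].
#' @return A [feature_pyramid()] with `cfg$out_channels` channels per level.
#' @export
fpn_forward <- function(backbone_features, cfg, params) {
  stopifnot(inherits(backbone_features, "feature_pyramid"),
            inherits(cfg, "neck_config"))
  fw <- fpn_fwd(backbone_features$levels, cfg, params)
  feature_pyramid(fw$out, backbone_features$level_names)
}

abfp_fwd <- function(levels, cfg, params, gates = NULL) {
  idx <- cfg$intermediate_index
  int_fw <- integrate_fwd(levels, idx, cfg$upsample_mode)
  if (cfg$attention || !is.null(gates)) {
    cap <- if (is.null(gates)) .cap_from_flat(params, cfg) else NULL
    sap <- if (is.null(gates)) .sap_from_flat(params) else NULL
    ref_fw <- abfp_refine_fwd(int_fw$out, cap, sap, gates)
    refined <- ref_fw$out
  } else {
    ref_fw <- conv2d_fwd(int_fw$out, params[["att.refine.w"]],
                         params[["att.refine.b"]], pad = 1L)
    refined <- ref_fw$out
  }
  st_fw <- strengthen_fwd(levels, refined, cfg$upsample_mode)
  list(out = st_fw$out,
       cache = list(int_fw = int_fw, ref_fw = ref_fw, st_fw = st_fw,
                    mode = if (cfg$attention || !is.null(gates)) "att" else "conv"))
}

abfp_bwd <- function(cache, douts, grads = list()) {
  sb <- strengthen_bwd(cache$st_fw, douts)
  if (cache$mode == "att") {
    rb <- abfp_refine_bwd(cache$ref_fw$cache, sb$drefined)
    dint <- rb$dx
    if (!is.null(rb$grads$channel)) {
      g <- rb$grads
      grads[["att.ch.w0"]] <- (grads[["att.ch.w0"]] %||% 0) + g$channel$w0
      grads[["att.ch.w1"]] <- (grads[["att.ch.w1"]] %||% 0) + g$channel$w1
      if (!is.null(g$channel$b0))
        grads[["att.ch.b0"]] <- (grads[["att.ch.b0"]] %||% 0) + g$channel$b0
      if (!is.null(g$channel$b1))
        grads[["att.ch.b1"]] <- (grads[["att.ch.b1"]] %||% 0) + g$channel$b1
      grads[["att.sp.w"]] <- (grads[["att.sp.w"]] %||% 0) + g$spatial$kernel
      if (!is.null(g$spatial$bias))
        grads[["att.sp.b"]] <- (grads[["att.sp.b"]] %||% 0) + g$spatial$bias
    }
  } else {
    cb <- conv2d_bwd(cache$ref_fw$cache, sb$drefined)
    grads[["att.refine.w"]] <- (grads[["att.refine.w"]] %||% 0) + cb$dw
    grads[["att.refine.b"]] <- (grads[["att.refine.b"]] %||% 0) + cb$db
    dint <- cb$dx
  }
  dlevels_int <- integrate_bwd(cache$int_fw, dint)
  dlevels <- mapply(function(a, b) a + b, sb$dlevels, dlevels_int,
                    SIMPLIFY = FALSE)
  list(dlevels = dlevels, grads = grads)
}

#' ABFP refinement applied to a uniform-channel pyramid
#'
#' Integrates the pyramid into its balanced semantic map, refines the map
#' (parallel channel + spatial attention, or a single 3x3 convolution when
#' `cfg$attention` is off — the convolution-refinement ablation arm), and
#' strengthens every level by adding the rescaled refined map back. Input and
#' output shape signatures are identical, so the operation stacks on any
#' neck.
#'
#' @param fpn_outputs a [feature_pyramid()] with `cfg$out_channels` channels
#'   at every level (e.g. the output of [fpn_forward()]).
#' @param cfg a [neck_config()].
#' @param params flat parameter list from [abfp_params()].
#' @param gates optional fixed-gate override forwarded to [abfp_refine()].
#' @return A [feature_pyramid()] with the same shape signature.
#' @export
abfp_forward <- function(fpn_outputs, cfg, params, gates = NULL) {
  stopifnot(inherits(fpn_outputs, "feature_pyramid"),
            inherits(cfg, "neck_config"))
  if (is.na(fpn_outputs$channel_count) ||
      fpn_outputs$channel_count != cfg$out_channels) {
    stop("pyramid has ", fpn_outputs$channel_count,
         " channels, config expects ", cfg$out_channels)
  }
  fw <- abfp_fwd(fpn_outputs$levels, cfg, params, gates)
  feature_pyramid(fw$out, fpn_outputs$level_names)
}
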