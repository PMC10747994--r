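# Channel attention, spatial attention, and the parallel additive refinement
# applied to the balanced semantic map:
#   M_c(F) = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))),  MLP(x) = W1 relu(W0 x)
#   M_s(F) = sigmoid(conv7x7([channel-avg(F); channel-max(F)]))
#   F_ab   = M_c(F) (*) F  (+)  M_s(F) (*) F
# The two gates act in parallel on the same input and their gated copies are
# summed, unlike the sequential composition of standard CBAM.

.kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

#' Parameters of the channel attention gate
#'
#' A single MLP (`W1 relu(W0 x)`) shared between the global-average-pool and
#' global-max-pool branches, squeezing `C` channels to `C / r` hidden units.
#' The reduction ratio is clamped so the hidden width is at least 1 and must
#' then divide `C` exactly.
#'
#' @param channels number of input channels `C`.
#' @param reduction reduction ratio `r` (default 16).
#' @param bias include bias vectors in both layers (default `TRUE`).
#' @param init `"kaiming"` (uniform, fan-in scaled weights, zero biases) or
#'   `"zero"`.
#' @param seed optional RNG seed for reproducible initialization.
#' @return Object of class `channel_attention_params` with elements
#'   `w0` (`C/r x C`), `b0`, `w1` (`C x C/r`), `b1`, `channels`, `reduction`.
#' @export
channel_attention_params <- function(channels, reduction = 16L, bias = TRUE,
                                     init = c("kaiming", "zero"), seed = NULL) {
  init <- match.arg(init)
  reduction <- min(as.integer(reduction), as.integer(channels))
  if (reduction < 1L || channels %% reduction != 0L) {
    stop("reduction ratio ", reduction, " does not divide C = ", channels)
  }
  hidden <- channels %/% reduction
  if (!is.null(seed)) set.seed(seed)
  if (init == "zero") {
    w0 <- matrix(0, hidden, channels); w1 <- matrix(0, channels, hidden)
  } else {
    w0 <- matrix(.kaiming_uniform(c(hidden, channels), channels), hidden)
    w1 <- matrix(.kaiming_uniform(c(channels, hidden), hidden), channels)
  }
  structure(list(w0 = w0, b0 = if (bias) numeric(hidden) else NULL,
                 w1 = w1, b1 = if (bias) numeric(channels) else NULL,
                 channels = as.integer(channels), reduction = reduction),
            class = "channel_attention_params")
}

#' Parameters of the spatial attention gate
#'
#' One 7x7 convolution over the two stacked per-pixel channel statistics
#' (average plane first, then max plane), producing a single-plane
#' pre-activation.
#'
#' @param bias include the scalar bias (default `TRUE`).
#' @param init `"kaiming"` or `"zero"`.
#' @param seed optional RNG seed.
#' @return Object of class `spatial_attention_params` with elements
#'   `kernel` (array `2 x 7 x 7 x 1`) and `bias` (scalar or `NULL`).
#' @export
spatial_attention_params <- function(bias = TRUE, init = c("kaiming", "zero"),
                                     seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  kernel <- if (init == "zero") array(0, c(2L, 7L, 7L, 1L))
            else .kaiming_uniform(c(2L, 7L, 7L, 1L), 2L * 49L)
  structure(list(kernel = kernel, bias = if (bias) 0 else NULL),
            class = "spatial_attention_params")
}

.attention_map <- function(values, kind) {
  structure(values, kind = kind, class = c("attention_map", class(values)))
}

.as_map_array <- function(f) {
  if (inherits(f, "balanced_semantic_map")) f$map else f
}

channel_attention_fwd <- function(x, p) {
  C <- dim(x)[1L]
  if (C != p$channels) stop("channel attention expects C = ", p$channels)
  av <- global_avg_pool_fwd(x)
  mx <- global_max_pool_fwd(x)
  mlp <- function(v) {
    h_pre <- as.vector(p$w0 %*% v) + if (is.null(p$b0)) 0 else p$b0
    h <- pmax(h_pre, 0)
    z <- as.vector(p$w1 %*% h) + if (is.null(p$b1)) 0 else p$b1
    list(z = z, h = h, h_pre = h_pre, v = v)
  }
  ma <- mlp(av$out); mm <- mlp(mx$out)
  m <- sigmoid(ma$z + mm$z)
  list(out = m, cache = list(av = av, mx = mx, ma = ma, mm = mm, m = m, p = p))
}

channel_attention_bwd <- function(cache, dm) {
  p <- cache$p
  dz <- dm * cache$m * (1 - cache$m)
  grads <- list(w0 = 0 * p$w0, w1 = 0 * p$w1,
                b0 = if (is.null(p$b0)) NULL else 0 * p$b0,
                b1 = if (is.null(p$b1)) NULL else 0 * p$b1)
  back_branch <- function(br) {
    grads$w1 <<- grads$w1 + dz %o% br$h
    if (!is.null(grads$b1)) grads$b1 <<- grads$b1 + dz
    dh <- as.vector(crossprod(p$w1, dz)) * (br$h_pre > 0)
    grads$w0 <<- grads$w0 + dh %o% br$v
    if (!is.null(grads$b0)) grads$b0 <<- grads$b0 + dh
    as.vector(crossprod(p$w0, dh))
  }
  dv_avg <- back_branch(cache$ma)
  dv_max <- back_branch(cache$mm)
  dx <- global_avg_pool_bwd(cache$av$cache, dv_avg) +
        global_max_pool_bwd(cache$mx$cache, dv_max)
  list(dx = dx, grads = grads)
}

spatial_attention_fwd <- function(x, p) {
  d <- dim(x)
  C <- d[1L]
  xm <- matrix(x, nrow = C)
  avg_plane <- colMeans(xm)
  am <- max.col(t(xm), ties.method = "first")
  pick <- cbind(am, seq_len(ncol(xm)))
  max_plane <- t(xm)[cbind(seq_len(ncol(xm)), am)]
  planes <- array(rbind(avg_plane, max_plane), c(2L, d[2L], d[3L]))
  cv <- conv2d_fwd(planes, p$kernel, p$bias, stride = 1L, pad = 3L)
  m <- sigmoid(cv$out[1L, , ])
  list(out = m, cache = list(cv = cv, m = m, C = C, am = am, in_dim = d))
}

spatial_attention_bwd <- function(cache, dm) {
  dz <- dm * cache$m * (1 - cache$m)
  dz_arr <- array(dz, c(1L, dim(dm)[1L], dim(dm)[2L]))
  cb <- conv2d_bwd(cache$cv$cache, dz_arr)
  dplanes <- cb$dx
  C <- cache$C
  davg <- as.vector(dplanes[1L, , ])
  dmax <- as.vector(dplanes[2L, , ])
  npix <- length(davg)
  dxm <- matrix(rep(davg / C, each = C), nrow = C)
  dxm[cbind(cache$am, seq_len(npix))] <-
    dxm[cbind(cache$am, seq_len(npix))] + dmax
  list(dx = array(dxm, cache$in_dim),
       grads = list(kernel = cb$dw,
                    bias = if (is.null(cb$db)) NULL else cb$db))
}

#' Channel attention gate
#'
#' Global average- and max-pooled channel descriptors are passed through one
#' shared two-layer MLP (ReLU between the layers), the two outputs are added,
#' and a sigmoid maps the result to a per-channel gate in (0, 1).
#'
#' @param f feature map, numeric array `c(C, H, W)` or a
#'   [balanced_semantic_map()].
#' @param params a [channel_attention_params()].
#' @return An `attention_map` of kind `"channel"`: a length-`C` numeric vector
#'   with every entry strictly in (0, 1).
#' @export
channel_attention <- function(f, params) {
  stopifnot(inherits(params, "channel_attention_params"))
  x <- .as_map_array(f)
  .attention_map(channel_attention_fwd(x, params)$out, "channel")
}

#' Spatial attention gate
#'
#' The per-pixel channel average and channel maximum are stacked (average
#' first) into a 2-plane map, convolved with a 7x7 kernel (stride 1, zero
#' padding 3, so H x W is preserved), and sigmoid-activated into a per-pixel
#' gate in (0, 1).
#'
#' @inheritParams channel_attention
#' @param params a [spatial_attention_params()].
#' @return An `attention_map` of kind `"spatial"`: an `H x W` matrix with
#'   entries strictly in (0, 1).
#' @export
spatial_attention <- function(f, params) {
  stopifnot(inherits(params, "spatial_attention_params"))
  x <- .as_map_array(f)
  .attention_map(spatial_attention_fwd(x, params)$out, "spatial")
}

abfp_refine_fwd <- function(x, cap, sap, gates = NULL) {
  d <- dim(x)
  if (is.null(gates)) {
    ca <- channel_attention_fwd(x, cap)
    sa <- spatial_attention_fwd(x, sap)
    mc <- ca$out; ms <- sa$out
  } else {
    ca <- sa <- NULL
    mc <- as.vector(gates$channel)
    ms <- gates$spatial
    if (length(mc) == 1L) mc <- rep(mc, d[1L])
    if (length(ms) == 1L) ms <- matrix(ms, d[2L], d[3L])
  }
  ms_full <- array(rep(ms, each = d[1L]), d)
  out <- x * mc + x * ms_full
  list(out = out,
       cache = list(x = x, mc = mc, ms_full = ms_full, ca = ca, sa = sa,
                    d = d))
}

abfp_refine_bwd <- function(cache, dout) {
  d <- cache$d
  dx <- dout * cache$mc + dout * cache$ms_full
  dmc <- rowSums(matrix(dout * cache$x, nrow = d[1L]))
  dms <- matrix(colSums(matrix(dout * cache$x, nrow = d[1L])), d[2L], d[3L])
  grads <- list(channel = NULL, spatial = NULL)
  if (!is.null(cache$ca)) {
    cb <- channel_attention_bwd(cache$ca$cache, dmc)
    sb <- spatial_attention_bwd(cache$sa$cache, dms)
    dx <- dx + cb$dx + sb$dx
    grads$channel <- cb$grads
    grads$spatial <- sb$grads
  }
  list(dx = dx, grads = grads)
}

#' Refine a balanced semantic map with parallel channel and spatial attention
#'
#' Computes `F_ab = M_c(F_b) * F_b + M_s(F_b) * F_b`, broadcasting the
#' channel gate over pixels and the spatial gate over channels. The two
#' branches are parallel and summed, so with both gates at 0.5 the map passes
#' through unchanged; no normalization is applied after the sum.
#'
#' @param f_b the balanced semantic map (a [balanced_semantic_map()] or a
#'   plain `c(C, H, W)` array).
#' @param cap a [channel_attention_params()].
#' @param sap a [spatial_attention_params()].
#' @param gates optional list `list(channel =, spatial =)` of fixed gate
#'   values that bypass the attention computations (used for identity checks
#'   and ablations); scalars are broadcast.
#' @return Same type as `f_b`, refined.
#' @export
abfp_refine <- function(f_b, cap = NULL, sap = NULL, gates = NULL) {
  x <- .as_map_array(f_b)
  if (is.null(gates)) {
    stopifnot(inherits(cap, "channel_attention_params"),
              inherits(sap, "spatial_attention_params"))
  }
  out <- abfp_refine_fwd(x, cap, sap, gates)$out
  if (inherits(f_b, "balanced_semantic_map")) {
    balanced_semantic_map(out, f_b$source_level_index)
  } else {
    out
  }
}

#' Save / load a flat parameter archive
#'
#' Parameters throughout the package are kept as flat named lists mapping a
#' dotted key to a numeric array, e.g. `att.ch.w0`, `att.ch.b0`, `att.ch.w1`,
#' `att.ch.b1` (channel-attention MLP), `att.sp.w`, `att.sp.b` (7x7 spatial
#' kernel and bias), `fpn.lateral<l>.{w,b}`, `fpn.out<l>.{w,b}` (FPN convs),
#' `bb.*` (micro backbone) and `head.*` (detector heads). `save_checkpoint()`
#' serializes such a list; `load_checkpoint()` restores it.
#'
#' @param params flat named list of numeric arrays.
#' @param path file path.
#' @return `load_checkpoint()` returns the named list, invisibly for save.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
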