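# Low-level array operations on C x H x W feature maps.
#
# All feature maps are numeric 3-d arrays with dim = c(channels, height, width).
# Every forward op returns list(out = , cache = ) and has a matching backward
# that maps the upstream gradient to gradients w.r.t. inputs and parameters,
# so the whole detector is differentiable analytically. Convolutions are
# evaluated as im2col gathers followed by a single BLAS matrix product.

.op_cache <- new.env(parent = emptyenv())

# Precomputed scatter-add: contributions are sorted by target index once, so
# each backward pass reduces to one permutation, one cumsum and one diff.
.scatter_plan <- function(grp) {
  ord <- order(grp, method = "radix")
  gs <- grp[ord]
  ends <- c(which(gs[-1L] != gs[-length(gs)]), length(gs))
  list(ord = ord, ends = ends, targets = as.integer(gs[ends]))
}

.scatter_add <- function(plan, v, out_len) {
  cs <- cumsum(v[plan$ord])
  out <- numeric(out_len)
  out[plan$targets] <- diff(c(0, cs[plan$ends]))
  out
}

# Gather-index table for im2col: (C*kh*kw) x (Hout*Wout) linear indices into
# the zero-padded input array. Column entries are ordered channel-fastest,
# then kernel row, then kernel column, matching a weight array of
# dim c(Cin, kh, kw, Cout) flattened to (Cin*kh*kw) x Cout.
.im2col_plan <- function(C, H, W, kh, kw, stride, pad) {
  key <- paste(C, H, W, kh, kw, stride, pad, sep = "_")
  plan <- .op_cache[[key]]
  if (!is.null(plan)) return(plan)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Hout <- (Hp - kh) %/% stride + 1L
  Wout <- (Wp - kw) %/% stride + 1L
  stopifnot(Hout >= 1L, Wout >= 1L)
  ent_c  <- rep(seq_len(C), times = kh * kw)
  ent_di <- rep(rep(seq_len(kh), each = C), times = kw)
  ent_dj <- rep(seq_len(kw), each = C * kh)
  a <- ent_c + C * (ent_di - 1) + C * Hp * (ent_dj - 1)
  base_r <- rep((seq_len(Hout) - 1L) * stride, times = Wout)
  base_q <- rep((seq_len(Wout) - 1L) * stride, each = Hout)
  b <- C * base_r + C * Hp * base_q
  idx <- outer(a, b, "+")
  plan <- list(idx = idx, Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout,
               K = C * kh * kw, scatter = .scatter_plan(as.vector(idx)))
  .op_cache[[key]] <- plan
  plan
}

.pad_map <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad))
  xp[, pad + seq_len(d[2L]), pad + seq_len(d[3L])] <- x
  xp
}

# w: array dim c(Cin, kh, kw, Cout); b: length Cout (or NULL for no bias)
conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  dx <- dim(x); dw <- dim(w)
  if (dx[1L] != dw[1L]) {
    stop("conv2d: input has ", dx[1L], " channels but kernel expects ", dw[1L])
  }
  plan <- .im2col_plan(dx[1L], dx[2L], dx[3L], dw[2L], dw[3L], stride, pad)
  xp <- .pad_map(x, pad)
  X <- matrix(xp[as.vector(plan$idx)], nrow = plan$K)
  Wmat <- matrix(w, nrow = plan$K)
  out <- crossprod(Wmat, X)
  if (!is.null(b)) out <- out + b
  dim(out) <- c(dw[4L], plan$Hout, plan$Wout)
  list(out = out,
       cache = list(X = X, plan = plan, w = w, b = b, stride = stride,
                    pad = pad, in_dim = dx))
}

conv2d_bwd <- function(cache, dout) {
  dw_dim <- dim(cache$w)
  Cout <- dw_dim[4L]
  dmat <- matrix(dout, nrow = Cout)
  dW <- cache$X %*% t(dmat)
  dim(dW) <- dw_dim
  db <- if (is.null(cache$b)) NULL else rowSums(dmat)
  Wmat <- matrix(cache$w, nrow = cache$plan$K)
  dX <- Wmat %*% dmat
  plan <- cache$plan
  d <- cache$in_dim
  dxp <- .scatter_add(plan$scatter, dX, d[1L] * plan$Hp * plan$Wp)
  dim(dxp) <- c(d[1L], plan$Hp, plan$Wp)
  p <- cache$pad
  dx <- if (p > 0L) dxp[, p + seq_len(d[2L]), p + seq_len(d[3L]), drop = FALSE]
        else dxp
  dim(dx) <- d
  list(dx = dx, dw = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

sigmoid <- function(z) stats::plogis(z)

# Non-overlapping max pooling with kernel = stride = (kh, kw).
maxpool_fwd <- function(x, kh, kw = kh) {
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  if (H %% kh != 0L || W %% kw != 0L) {
    stop("maxpool: spatial size ", H, "x", W,
         " is not divisible by pooling window ", kh, "x", kw)
  }
  Hout <- H %/% kh; Wout <- W %/% kw
  off <- as.vector(outer(C * (seq_len(kh) - 1L), C * H * (seq_len(kw) - 1L), "+"))
  base <- as.vector(outer(outer(seq_len(C), C * kh * (seq_len(Hout) - 1L), "+"),
                          C * H * kw * (seq_len(Wout) - 1L), "+"))
  idx <- outer(off, base, "+")
  vals <- matrix(x[as.vector(idx)], nrow = length(off))
  M <- ncol(vals)
  am <- max.col(t(vals), ties.method = "first")
  pick <- cbind(am, seq_len(M))
  out <- vals[pick]
  dim(out) <- c(C, Hout, Wout)
  list(out = out, cache = list(sel = idx[pick], in_dim = d))
}

maxpool_bwd <- function(cache, dout) {
  dx <- numeric(prod(cache$in_dim))
  dx[cache$sel] <- dout        # windows are disjoint: each source picked once
  dim(dx) <- cache$in_dim
  dx
}

.nearest_axis <- function(n_in, n_out) {
  src <- floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1
  pmin(pmax(as.integer(src), 1L), n_in)
}

# Nearest-neighbour resize to an arbitrary target shape. For integer upscale
# factors this is exact pixel replication.
resize_nearest_fwd <- function(x, to_h, to_w) {
  d <- dim(x)
  key <- paste("rn", d[1L], d[2L], d[3L], to_h, to_w, sep = "_")
  plan <- .op_cache[[key]]
  if (is.null(plan)) {
    ri <- .nearest_axis(d[2L], to_h)
    cj <- .nearest_axis(d[3L], to_w)
    C <- d[1L]
    g <- outer(outer(seq_len(C), C * (ri - 1L), "+"),
               C * d[2L] * (cj - 1L), "+")
    plan <- list(ri = ri, cj = cj, scatter = .scatter_plan(as.vector(g)))
    .op_cache[[key]] <- plan
  }
  out <- x[, plan$ri, plan$cj, drop = FALSE]
  list(out = out, cache = list(plan = plan, in_dim = d))
}

resize_nearest_bwd <- function(cache, dout) {
  d <- cache$in_dim
  dx <- .scatter_add(cache$plan$scatter, dout, prod(d))
  dim(dx) <- d
  dx
}

# Bilinear resize (half-pixel centers, clamped borders). Separable: each
# output pixel mixes at most 2 source rows and 2 source columns.
.bilinear_axis <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  lo <- floor(pos)
  frac <- pos - lo
  i0 <- pmin(pmax(as.integer(lo) + 1L, 1L), n_in)
  i1 <- pmin(i0 + 1L, n_in)
  # when clamped, collapse the weight onto the surviving tap
  frac[lo < 0] <- 0
  frac[lo + 1L >= n_in] <- 0
  list(i0 = i0, i1 = i1, w1 = frac, w0 = 1 - frac)
}

resize_bilinear_fwd <- function(x, to_h, to_w) {
  d <- dim(x)
  ay <- .bilinear_axis(d[2L], to_h)
  ax <- .bilinear_axis(d[3L], to_w)
  C <- d[1L]
  term <- function(ri, wr, cj, wc) {
    t0 <- x[, ri, cj, drop = FALSE]
    t0 * rep(wr, each = C) * rep(wc, each = C * to_h)
  }
  out <- term(ay$i0, ay$w0, ax$i0, ax$w0) + term(ay$i1, ay$w1, ax$i0, ax$w0) +
         term(ay$i0, ay$w0, ax$i1, ax$w1) + term(ay$i1, ay$w1, ax$i1, ax$w1)
  list(out = out, cache = list(ay = ay, ax = ax, in_dim = d, to_h = to_h,
                               to_w = to_w))
}

resize_bilinear_bwd <- function(cache, dout) {
  d <- cache$in_dim
  C <- d[1L]
  ay <- cache$ay; ax <- cache$ax
  dx <- numeric(prod(d))
  scatter <- function(ri, wr, cj, wc) {
    w <- dout * rep(wr, each = C) * rep(wc, each = C * cache$to_h)
    g <- outer(outer(seq_len(C), C * (ri - 1L), "+"), C * d[2L] * (cj - 1L), "+")
    acc <- rowsum(as.vector(w), group = as.vector(g))
    dx[as.integer(rownames(acc))] <<- dx[as.integer(rownames(acc))] + acc
  }
  scatter(ay$i0, ay$w0, ax$i0, ax$w0)
  scatter(ay$i1, ay$w1, ax$i0, ax$w0)
  scatter(ay$i0, ay$w0, ax$i1, ax$w1)
  scatter(ay$i1, ay$w1, ax$i1, ax$w1)
  dim(dx) <- d
  dx
}

# Instance normalization: each channel of each map is standardized over its
# own H x W extent, then scaled/shifted by learned per-channel gamma/beta.
# Stabilizes very short from-scratch training schedules.
instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]; M <- d[2L] * d[3L]
  xm <- matrix(x, nrow = C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowSums(xc * xc) / M
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- array(xhat * gamma + beta, d)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

instnorm_bwd <- function(cache, dout) {
  d <- cache$d
  C <- d[1L]; M <- d[2L] * d[3L]
  dy <- matrix(dout, nrow = C)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- (dxhat - rowMeans(dxhat) -
         cache$xhat * rowSums(dxhat * cache$xhat) / M) * cache$inv
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

global_avg_pool_fwd <- function(x) {
  d <- dim(x)
  list(out = rowMeans(matrix(x, nrow = d[1L])), cache = d)
}

global_avg_pool_bwd <- function(cache, dv) {
  d <- cache
  array(rep(dv / (d[2L] * d[3L]), times = d[2L] * d[3L]), d)
}

global_max_pool_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1L])
  am <- max.col(xm, ties.method = "first")
  pick <- cbind(seq_len(d[1L]), am)
  list(out = xm[pick], cache = list(d = d, pick = pick))
}

global_max_pool_bwd <- function(cache, dv) {
  dxm <- matrix(0, nrow = cache$d[1L], ncol = cache$d[2L] * cache$d[3L])
  dxm[cache$pick] <- dv
  array(dxm, cache$d)
}
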