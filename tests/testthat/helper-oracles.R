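# Independent brute-force oracles used throughout the suite. These
# deliberately re-derive every quantity with scalar loops and explicit
# arithmetic, sharing no code with the implementation they check.

oracle_nearest_resize <- function(map, to_h, to_w) {
  d <- dim(map)
  out <- array(0, c(d[1], to_h, to_w))
  for (c in seq_len(d[1])) {
    for (i in seq_len(to_h)) {
      si <- min(max(floor((i - 0.5) * d[2] / to_h) + 1, 1), d[2])
      for (j in seq_len(to_w)) {
        sj <- min(max(floor((j - 0.5) * d[3] / to_w) + 1, 1), d[3])
        out[c, i, j] <- map[c, si, sj]
      }
    }
  }
  out
}

oracle_maxpool <- function(map, kh, kw) {
  d <- dim(map)
  to_h <- d[2] %/% kh
  to_w <- d[3] %/% kw
  out <- array(-Inf, c(d[1], to_h, to_w))
  for (c in seq_len(d[1])) {
    for (i in seq_len(to_h)) {
      for (j in seq_len(to_w)) {
        win <- map[c, (i - 1) * kh + seq_len(kh), (j - 1) * kw + seq_len(kw)]
        out[c, i, j] <- max(win)
      }
    }
  }
  out
}

# resize by the package's stated rule: integer-factor downscale = max pool,
# otherwise nearest-neighbour interpolation
oracle_rescale <- function(map, to_h, to_w) {
  d <- dim(map)
  if (to_h == d[2] && to_w == d[3]) return(map)
  if (to_h <= d[2] && to_w <= d[3] && d[2] %% to_h == 0 && d[3] %% to_w == 0) {
    return(oracle_maxpool(map, d[2] %/% to_h, d[3] %/% to_w))
  }
  oracle_nearest_resize(map, to_h, to_w)
}

oracle_integrate <- function(levels, idx) {
  to <- dim(levels[[idx]])[2:3]
  acc <- array(0, c(dim(levels[[1]])[1], to[1], to[2]))
  for (l in seq_along(levels)) {
    acc <- acc + oracle_rescale(levels[[l]], to[1], to[2])
  }
  acc / length(levels)
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# element-wise scalar recomputation of the parallel-attention refinement
oracle_abfp_refine <- function(x, cap, sap) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[c, , ])
    mx[c] <- max(x[c, , ])
  }
  mlp <- function(v) {
    h <- numeric(nrow(cap$w0))
    for (k in seq_len(nrow(cap$w0))) {
      s <- if (is.null(cap$b0)) 0 else cap$b0[k]
      for (c in seq_len(C)) s <- s + cap$w0[k, c] * v[c]
      h[k] <- max(s, 0)
    }
    z <- numeric(C)
    for (c in seq_len(C)) {
      s <- if (is.null(cap$b1)) 0 else cap$b1[c]
      for (k in seq_along(h)) s <- s + cap$w1[c, k] * h[k]
      z[c] <- s
    }
    z
  }
  mc <- oracle_sigmoid(mlp(avg) + mlp(mx))
  avg_p <- matrix(0, H, W); max_p <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    avg_p[i, j] <- mean(x[, i, j])
    max_p[i, j] <- max(x[, i, j])
  }
  ms <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- if (is.null(sap$bias)) 0 else sap$bias
    for (di in -3:3) for (dj in -3:3) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        s <- s + sap$kernel[1, di + 4, dj + 4, 1] * avg_p[ii, jj] +
                 sap$kernel[2, di + 4, dj + 4, 1] * max_p[ii, jj]
      }
    }
    ms[i, j] <- oracle_sigmoid(s)
  }
  out <- array(0, d)
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    out[c, i, j] <- mc[c] * x[c, i, j] + ms[i, j] * x[c, i, j]
  }
  out
}

# 101-point AP by direct per-grid-point scan over the raw PR points
oracle_ap_grid <- function(pr) {
  if (nrow(pr) == 0) return(0)
  grid <- seq(0, 1, by = 0.01)
  vals <- numeric(length(grid))
  for (g in seq_along(grid)) {
    sel <- pr$recall >= grid[g]
    vals[g] <- if (any(sel)) max(pr$precision[sel]) else 0
  }
  mean(vals)
}

# random toy detection/ground-truth scenario on a few images
random_eval_case <- function(seed) {
  set.seed(seed)
  n_img <- sample(1:3, 1)
  gts <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    x1 <- runif(k, 0, 60); y1 <- runif(k, 0, 60)
    data.frame(image_id = im, x1 = x1, y1 = y1,
               x2 = x1 + runif(k, 5, 30), y2 = y1 + runif(k, 5, 30))
  }))
  if (is.null(gts)) {
    gts <- data.frame(image_id = 1, x1 = 1, y1 = 1, x2 = 10, y2 = 10)
  }
  dets <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    k <- sample(1:5, 1)
    g <- gts[gts$image_id == im, , drop = FALSE]
    rows <- lapply(seq_len(k), function(d) {
      if (nrow(g) && runif(1) < 0.6) {    # jittered copy of a GT box
        r <- g[sample(nrow(g), 1), ]
        j <- runif(4, -4, 4)
        data.frame(image_id = im, x1 = r$x1 + j[1], y1 = r$y1 + j[2],
                   x2 = r$x2 + j[3], y2 = r$y2 + j[4],
                   score = runif(1))
      } else {
        x1 <- runif(1, 0, 70); y1 <- runif(1, 0, 70)
        data.frame(image_id = im, x1 = x1, y1 = y1,
                   x2 = x1 + runif(1, 5, 25), y2 = y1 + runif(1, 5, 25),
                   score = runif(1))
      }
    })
    do.call(rbind, rows)
  }))
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, ]
  if (!nrow(dets)) {
    dets <- data.frame(image_id = 1, x1 = 1, y1 = 1, x2 = 9, y2 = 9,
                       score = 0.5)
  }
  list(dets = dets, gts = gts)
}

finite_diff <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
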