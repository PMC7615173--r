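# Low-level differentiable tensor operations.
#
# Feature maps are numeric arrays with channel-last layout: (s1, ..., sd, C)
# for d = 2 or 3 spatial dimensions. Every op comes as a forward returning
# the output (plus whatever cache the backward needs) and a backward mapping
# the output gradient to input/parameter gradients. Convolutions use
# same-padding with zeros; the spatial shape is preserved by construction.

conv_pad <- function(K, dilation) (dilation * (K - 1L)) %/% 2L

nd_pad <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  dx <- dim(x)
  d <- length(dx) - 1L
  sp <- dx[seq_len(d)]
  C <- dx[d + 1L]
  out <- array(0, c(sp + 2L * pad, C))
  if (d == 2L) {
    out[pad[1L] + seq_len(sp[1L]), pad[2L] + seq_len(sp[2L]), ] <- x
  } else {
    out[pad[1L] + seq_len(sp[1L]), pad[2L] + seq_len(sp[2L]),
        pad[3L] + seq_len(sp[3L]), ] <- x
  }
  out
}

nd_unpad <- function(xp, pad, sp) {
  if (all(pad == 0L)) return(xp)
  if (length(sp) == 2L) {
    xp[pad[1L] + seq_len(sp[1L]), pad[2L] + seq_len(sp[2L]), , drop = FALSE]
  } else {
    xp[pad[1L] + seq_len(sp[1L]), pad[2L] + seq_len(sp[2L]),
       pad[3L] + seq_len(sp[3L]), , drop = FALSE]
  }
}

# Extract the shifted window matching the output grid for one kernel tap,
# flattened to a (n_pixels x C) matrix.
nd_tap <- function(xp, st, sp, C) {
  if (length(sp) == 2L) {
    m <- xp[st[1L]:(st[1L] + sp[1L] - 1L),
            st[2L]:(st[2L] + sp[2L] - 1L), , drop = FALSE]
  } else {
    m <- xp[st[1L]:(st[1L] + sp[1L] - 1L),
            st[2L]:(st[2L] + sp[2L] - 1L),
            st[3L]:(st[3L] + sp[3L] - 1L), , drop = FALSE]
  }
  dim(m) <- c(prod(sp), C)
  m
}

nd_tap_add <- function(xp, st, sp, C, add) {
  dim(add) <- c(sp, C)
  if (length(sp) == 2L) {
    i <- st[1L]:(st[1L] + sp[1L] - 1L)
    j <- st[2L]:(st[2L] + sp[2L] - 1L)
    xp[i, j, ] <- xp[i, j, , drop = FALSE] + add
  } else {
    i <- st[1L]:(st[1L] + sp[1L] - 1L)
    j <- st[2L]:(st[2L] + sp[2L] - 1L)
    k <- st[3L]:(st[3L] + sp[3L] - 1L)
    xp[i, j, k, ] <- xp[i, j, k, , drop = FALSE] + add
  }
  xp
}

# Cache of im2col gather indices, keyed by (spatial shape, kernel,
# dilation, channels). Entries above ~16M elements are not cached and the
# convolution falls back to the tap-wise path.
.conv_idx_cache <- new.env(parent = emptyenv())
.conv_idx_limit <- 2^24

conv_idx <- function(sp, K, dilation, cin) {
  key <- paste(c(sp, K, dilation, cin), collapse = "_")
  cached <- get0(key, envir = .conv_idx_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  d <- length(sp)
  pad <- conv_pad(K, dilation)
  spp <- sp + 2L * pad
  n <- prod(sp)
  pos <- arrayInd(seq_len(n), sp)
  taps <- (arrayInd(seq_len(prod(K)), K) - 1L) * dilation
  mult <- cumprod(c(1, spp))[seq_len(d)]
  base <- matrix(0L, n, prod(K))
  for (t in seq_len(prod(K))) {
    coords <- sweep(pos, 2L, taps[t, ], `+`)
    base[, t] <- as.integer(1 + rowSums(sweep(coords - 1, 2L, mult, `*`)))
  }
  npad <- prod(spp)
  idx <- as.integer(outer(as.vector(base), (seq_len(cin) - 1L) * npad, `+`))
  res <- list(idx = idx, pad = pad, n = n, prodK = prod(K))
  if (length(idx) <= .conv_idx_limit)
    assign(key, res, envir = .conv_idx_cache)
  res
}

# Spatially flip a kernel and swap its channel axes, turning a convolution
# into its own input-gradient operator (exact for stride-1 same padding).
flip_kernel <- function(W) {
  dw <- dim(W)
  d <- length(dw) - 2L
  args <- lapply(dw[seq_len(d)], function(k) k:1)
  Wf <- do.call(`[`, c(list(W), args, list(TRUE, TRUE), list(drop = FALSE)))
  aperm(Wf, c(seq_len(d), d + 2L, d + 1L))
}

# Same-padded n-dimensional convolution.
# x: (s1..sd, Cin); W: (K1..Kd, Cin, Cout); b: length-Cout or NULL.
nd_conv_fwd <- function(x, W, b = NULL, dilation = 1L) {
  dx <- dim(x)
  d <- length(dx) - 1L
  sp <- dx[seq_len(d)]
  cin <- dx[d + 1L]
  dw <- dim(W)
  K <- dw[seq_len(d)]
  if (dw[d + 1L] != cin)
    stop_shape("conv: input has ", cin, " channels but kernel expects ",
               dw[d + 1L])
  cout <- dw[d + 2L]
  if (prod(sp) * prod(K) * cin > .conv_idx_limit)
    return(nd_conv_fwd_taps(x, W, b, dilation))
  ci <- conv_idx(sp, K, dilation, cin)
  xp <- nd_pad(x, ci$pad)
  X <- matrix(xp[ci$idx], ci$n, ci$prodK * cin)
  out <- X %*% matrix(W, ci$prodK * cin, cout)
  if (!is.null(b)) out <- out + matrix(b, ci$n, cout, byrow = TRUE)
  array(out, c(sp, cout))
}

nd_conv_bwd <- function(x, W, dilation, gout) {
  dx <- dim(x)
  d <- length(dx) - 1L
  sp <- dx[seq_len(d)]
  cin <- dx[d + 1L]
  dw <- dim(W)
  K <- dw[seq_len(d)]
  cout <- dw[d + 2L]
  if (prod(sp) * prod(K) * cin > .conv_idx_limit)
    return(nd_conv_bwd_taps(x, W, dilation, gout))
  ci <- conv_idx(sp, K, dilation, cin)
  xp <- nd_pad(x, ci$pad)
  X <- matrix(xp[ci$idx], ci$n, ci$prodK * cin)
  G <- matrix(gout, ci$n, cout)
  gW <- array(crossprod(X, G), dw)
  gb <- colSums(G)
  gx <- nd_conv_fwd(gout, flip_kernel(W), NULL, dilation)
  list(gx = gx, gW = gW, gb = gb)
}

nd_conv_fwd_taps <- function(x, W, b = NULL, dilation = 1L) {
  dx <- dim(x)
  d <- length(dx) - 1L
  sp <- dx[seq_len(d)]
  cin <- dx[d + 1L]
  dw <- dim(W)
  K <- dw[seq_len(d)]
  cout <- dw[d + 2L]
  pad <- conv_pad(K, dilation)
  xp <- nd_pad(x, pad)
  n <- prod(sp)
  out <- matrix(if (is.null(b)) 0 else rep(b, each = n), n, cout)
  Wm <- matrix(W, prod(K), cin * cout)
  taps <- arrayInd(seq_len(prod(K)), K)
  for (t in seq_len(nrow(taps))) {
    st <- 1L + (taps[t, ] - 1L) * dilation
    out <- out + nd_tap(xp, st, sp, cin) %*% matrix(Wm[t, ], cin, cout)
  }
  array(out, c(sp, cout))
}

nd_conv_bwd_taps <- function(x, W, dilation, gout) {
  dx <- dim(x)
  d <- length(dx) - 1L
  sp <- dx[seq_len(d)]
  cin <- dx[d + 1L]
  dw <- dim(W)
  K <- dw[seq_len(d)]
  cout <- dw[d + 2L]
  pad <- conv_pad(K, dilation)
  xp <- nd_pad(x, pad)
  n <- prod(sp)
  G <- matrix(gout, n, cout)
  gb <- colSums(G)
  Wm <- matrix(W, prod(K), cin * cout)
  gWm <- matrix(0, prod(K), cin * cout)
  gxp <- array(0, dim(xp))
  taps <- arrayInd(seq_len(prod(K)), K)
  for (t in seq_len(nrow(taps))) {
    st <- 1L + (taps[t, ] - 1L) * dilation
    xs <- nd_tap(xp, st, sp, cin)
    gWm[t, ] <- crossprod(xs, G)
    gxp <- nd_tap_add(gxp, st, sp, cin, G %*% t(matrix(Wm[t, ], cin, cout)))
  }
  list(gx = nd_unpad(gxp, pad, sp),
       gW = array(gWm, dw),
       gb = gb)
}

relu_fwd <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

relu_bwd <- function(x, gout) {
  g <- gout * (x > 0)
  dim(g) <- dim(x)
  g
}

sigmoid <- function(x) {
  y <- plogis(x)
  dim(y) <- dim(x)
  y
}

sigmoid_bwd <- function(y, gout) {
  g <- gout * y * (1 - y)
  dim(g) <- dim(y)
  g
}

# Instance normalisation: standardise each channel over its spatial extent,
# then apply a learned per-channel affine (gamma, beta).
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  dx <- dim(x)
  d <- length(dx) - 1L
  n <- prod(dx[seq_len(d)])
  C <- dx[d + 1L]
  xm <- matrix(x, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  istd <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = array(y, dx), xhat = xhat, istd = istd, dims = dx)
}

inorm_bwd <- function(cache, gamma, gout) {
  dx <- cache$dims
  d <- length(dx) - 1L
  n <- prod(dx[seq_len(d)])
  C <- dx[d + 1L]
  g <- matrix(gout, n, C)
  xhat <- cache$xhat
  ggamma <- colSums(g * xhat)
  gbeta <- colSums(g)
  gxh <- sweep(g, 2L, gamma, `*`)
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * xhat)
  gx <- sweep(gxh, 2L, m1) - sweep(xhat, 2L, m2, `*`)
  gx <- sweep(gx, 2L, cache$istd, `*`)
  list(gx = array(gx, dx), ggamma = ggamma, gbeta = gbeta)
}

# Slice an array along one axis, keeping all dimensions.
aslice <- function(x, axis, idx) {
  nd <- length(dim(x))
  args <- rep(list(quote(expr = )), nd)
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

aslice_set <- function(x, axis, idx, value) {
  nd <- length(dim(x))
  args <- rep(list(quote(expr = )), nd)
  args[[axis]] <- idx
  do.call(`[<-`, c(list(x), args, list(value)))
}

# 2x max pooling over every spatial axis (spatial dims must be even).
maxpool2_fwd <- function(x) {
  d <- length(dim(x)) - 1L
  masks <- vector("list", d)
  for (j in seq_len(d)) {
    s <- dim(x)[j]
    if (s %% 2L != 0L)
      stop_shape("maxpool: spatial dim ", j, " (", s, ") is not even")
    a <- aslice(x, j, seq.int(1L, s, 2L))
    b <- aslice(x, j, seq.int(2L, s, 2L))
    masks[[j]] <- a >= b
    y <- pmax(a, b)
    dim(y) <- dim(a)
    x <- y
  }
  list(out = x, masks = masks)
}

maxpool2_bwd <- function(cache, gout) {
  g <- gout
  d <- length(dim(g)) - 1L
  for (j in rev(seq_len(d))) {
    mask <- cache$masks[[j]]
    s <- dim(g)[j] * 2L
    dims <- dim(g)
    dims[j] <- s
    big <- array(0, dims)
    big <- aslice_set(big, j, seq.int(1L, s, 2L), g * mask)
    big <- aslice_set(big, j, seq.int(2L, s, 2L), g * !mask)
    g <- big
  }
  g
}

# Nearest-neighbour 2x upsampling over every spatial axis.
upsample2_fwd <- function(x) {
  d <- length(dim(x)) - 1L
  for (j in seq_len(d)) {
    x <- aslice(x, j, rep(seq_len(dim(x)[j]), each = 2L))
  }
  x
}

upsample2_bwd <- function(gout) {
  g <- gout
  d <- length(dim(g)) - 1L
  for (j in seq_len(d)) {
    s <- dim(g)[j]
    g <- aslice(g, j, seq.int(1L, s, 2L)) + aslice(g, j, seq.int(2L, s, 2L))
  }
  g
}

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  d <- length(da) - 1L
  if (!all(da[seq_len(d)] == db[seq_len(d)]))
    stop_shape("cat_channels: spatial shapes differ")
  out <- array(0, c(da[seq_len(d)], da[d + 1L] + db[d + 1L]))
  out <- aslice_set(out, d + 1L, seq_len(da[d + 1L]), a)
  aslice_set(out, d + 1L, da[d + 1L] + seq_len(db[d + 1L]), b)
}

split_channels_bwd <- function(g, c1) {
  d <- length(dim(g)) - 1L
  C <- dim(g)[d + 1L]
  list(ga = aslice(g, d + 1L, seq_len(c1)),
       gb = aslice(g, d + 1L, (c1 + 1L):C))
}

# Kaiming-style weight initialisation for a conv kernel of shape
# (K..., Cin, Cout): sd = sqrt(2 / (prod(K) * Cin)).
he_init <- function(shape) {
  d <- length(shape) - 2L
  fan_in <- prod(shape[seq_len(d)]) * shape[d + 1L]
  array(rnorm(prod(shape), sd = sqrt(2 / fan_in)), shape)
}
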