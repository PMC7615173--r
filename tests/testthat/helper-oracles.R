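# Shared helpers: numeric differentiation, brute-force receptive-field
# oracle, tiny fixtures.

# Central finite-difference gradient of scalar-valued f at array x.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force receptive-field footprint of the central output unit of a
# linear conv stack: perturb one input pixel at a time and record whether
# the central output changes.
brute_force_footprint <- function(stack, input_shape) {
  cin <- erf_probe_channels_export(stack)
  base <- array(0, c(input_shape, cin))
  centre <- (input_shape + 1L) %/% 2L
  out0 <- stack_forward_export(stack, base)
  c0 <- do.call(`[`, c(list(out0), as.list(centre), list(1L)))
  support <- array(FALSE, input_shape)
  for (i in seq_len(prod(input_shape))) {
    pos <- arrayInd(i, input_shape)
    x <- base
    x <- do.call(`[<-`, c(list(x), as.list(pos), list(1L), list(1)))
    out <- stack_forward_export(stack, x)
    ci <- do.call(`[`, c(list(out), as.list(centre), list(1L)))
    support[i] <- abs(ci - c0) > 0
  }
  support
}

# minimal wrappers over the exported probe interface
erf_probe_channels_export <- function(stack) stack$channels
stack_forward_export <- function(stack, x) {
  for (l in stack$layers) x <- mismatch:::nd_conv_fwd(x, l$W, dilation = l$dilation)
  x
}

# Brute-force ECE: per-pixel loop following the binning definition
# directly, independent of the vectorised implementation.
brute_force_ece <- function(p, y, M = 5L) {
  p <- as.numeric(p); y <- as.numeric(y)
  width <- 0.5 / M
  sums_conf <- numeric(M); sums_corr <- numeric(M); counts <- integer(M)
  for (i in seq_along(p)) {
    conf <- max(p[i], 1 - p[i])
    pred <- if (p[i] > 0.5) 1 else 0
    b <- 1L
    for (m in seq_len(M)) {
      lo <- 0.5 + (m - 1) * width
      hi <- 0.5 + m * width
      inside <- if (m == 1L) conf >= lo - 1e-15 && conf <= hi + 1e-15
                else conf > lo + 1e-15 && conf <= hi + 1e-15
      # edge ties belong to the lower bin: assign the first matching bin
      if (inside) { b <- m; break }
    }
    counts[b] <- counts[b] + 1L
    sums_conf[b] <- sums_conf[b] + conf
    sums_corr[b] <- sums_corr[b] + as.integer(pred == y[i])
  }
  n <- length(p)
  ece <- 0
  for (m in seq_len(M)) {
    if (counts[m] > 0L)
      ece <- ece + (counts[m] / n) *
        abs(sums_corr[m] / counts[m] - sums_conf[m] / counts[m])
  }
  ece
}

dice_loss_grad_export <- function(p, y, smooth = 1e-6) {
  mismatch:::dice_loss_grad(p, y, smooth)
}

# a parameter list of the same structure with every entry zeroed
unflatten_zero <- function(params) {
  mismatch:::unflatten_params(numeric(length(unlist(params))), params)
}

tiny_net_spec <- function(variant = "MM", width = 2L, seed = 1L, ...) {
  network_spec(dims = 2L, base_width = width, depth = 3L,
               decoder_variant = variant, seed = seed, ...)
}
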