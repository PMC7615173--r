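# Analytic effective-receptive-field (ERF) conditions for the two
# attention-shifting block designs, plus an empirical gradient-probe ERF.
#
# The ERF of a stack of n layers with kernel size K grows like K*sqrt(n),
# so adding layers enlarges the ERF sublinearly while widening the kernel
# enlarges it linearly. The two closed forms below compare a side branch
# against a two-convolution main branch acting on a depth-n feature map:
# a single dilated convolution with effective kernel K' (positive
# attention), and a two-stage residual ensemble (negative attention).

#' ERF ratio of the dilated side branch over the plain main branch
#'
#' For an incoming feature map at depth `n`, the main branch adds two
#' convolutions of kernel `K` while the side branch adds one convolution
#' with effective kernel `K_side`. The ratio of their effective receptive
#' fields is `(K_side/K) * sqrt(1 / (1 + 1/(n+1)))`; values above 1 mean
#' the side branch sees further than the main branch, which is the design
#' condition of the positive attention shifting block.
#'
#' @param K main-branch kernel size (odd positive integer).
#' @param K_side side-branch effective kernel size (odd positive integer).
#' @param n depth index of the incoming feature map (positive integer).
#' @return positive scalar; strictly increasing in `n` for fixed kernels.
#' @examples
#' erf_ratio_pasb(K = 3, K_side = 9, n = 1) # 3 * sqrt(2/3)
#' @export
erf_ratio_pasb <- function(K, K_side, n) {
  K <- assert_odd(K, "K")
  K_side <- assert_odd(K_side, "K_side")
  n <- assert_count(n, "n")
  (K_side / K) * sqrt(1 / (1 + 1 / (n + 1)))
}

#' Minimal admissible side-branch kernel size
#'
#' The positive-attention design requires the side branch ERF to exceed the
#' main branch ERF at every depth. The worst case is the shallow limit
#' (n -> 0), where the depth correction tends to sqrt(0.5), so the side
#' kernel must exceed `K / sqrt(0.5) = sqrt(2) * K`. With `doubling = TRUE`
#' the factor is doubled (a safety-margin design choice) and the result is
#' rounded up to the nearest odd integer, since convolution kernels are odd.
#'
#' @param K main-branch kernel size (odd positive integer).
#' @param doubling double the minimal factor before rounding (default TRUE).
#' @return smallest admissible odd kernel size. Without doubling this is the
#'   smallest odd integer strictly greater than `sqrt(2) * K`; with doubling
#'   the smallest odd integer at least `2 * sqrt(2) * K`.
#' @examples
#' minimal_side_kernel(3)                   # 9
#' minimal_side_kernel(3, doubling = FALSE) # 5
#' @export
minimal_side_kernel <- function(K, doubling = TRUE) {
  K <- assert_odd(K, "K")
  assert_flag(doubling, "doubling")
  bound <- K / sqrt(0.5)
  if (doubling) bound <- 2 * bound
  k <- ceiling(bound)
  # round up to odd; the un-doubled condition is strict (> bound)
  if (k %% 2L == 0L) k <- k + 1L
  if (!doubling && k <= bound) k <- k + 2L
  as.integer(k)
}

#' Binomial path weight of a residual ensemble
#'
#' A network of `N` residual-wrapped layers is an ensemble of `2^N` paths;
#' the paths traversing exactly `k` of the layers carry total weight
#' `choose(N, k) p^k (1-p)^(N-k)`, where `p` is the probability of passing
#' through a layer rather than skipping it.
#'
#' @param N number of residual-wrapped layers (non-negative integer).
#' @param k number of layers traversed, `0 <= k <= N`.
#' @param p layer-traversal probability.
#' @return the path weight; weights over `k = 0..N` sum to 1.
#' @examples
#' binomial_path_weight(2, 1, 0.5) # 0.5
#' @export
binomial_path_weight <- function(N, k, p) {
  N <- assert_count(N, "N", min = 0L)
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != round(k) ||
      k < 0L || k > N)
    stop_invalid("k must be an integer in [0, ", N, "], got ", k)
  p <- assert_prob(p, "p")
  choose(N, as.integer(k)) * p^k * (1 - p)^(N - k)
}

#' ERF ratio of the residual side branch over the plain main branch
#'
#' The negative-attention side branch wraps its two convolution stages in
#' identity skip connections, turning it into a binomial ensemble of short
#' paths. Weighting each path's depth correction by its binomial weight
#' gives, for a depth-`n` input and traversal probability `p`,
#' `p^2 sqrt(1/(1+2/n)) + 2p(1-p) sqrt(1/(1+1/(n+1))) + (1-p)^2`.
#' The ratio is strictly below 1 for every finite `n` (the side branch sees
#' less far than the main branch) and tends to 1 as `n` grows.
#'
#' @param n depth index of the incoming feature map (positive integer).
#' @param p layer-traversal probability (default 0.5).
#' @return scalar in (0, 1).
#' @examples
#' erf_ratio_nasb(1) # ~0.8026
#' @export
erf_ratio_nasb <- function(n, p = 0.5) {
  n <- assert_count(n, "n")
  p <- assert_prob(p, "p")
  w2 <- binomial_path_weight(2L, 2L, p)
  w1 <- binomial_path_weight(2L, 1L, p)
  w0 <- binomial_path_weight(2L, 0L, p)
  w2 * sqrt(1 / (1 + 2 / n)) + w1 * sqrt(1 / (1 + 1 / (n + 1))) + w0
}

#' Empirical gradient-probe measurement of the effective receptive field
#'
#' Probes a small convolutional network by back-propagating a unit gradient
#' from the central output unit (every channel of the central pixel) of a
#' constant all-ones input. The absolute input gradient, summed over
#' channels, maps how strongly each input pixel influences the centre; the
#' support area counts pixels whose gradient exceeds a stated fraction of
#' the peak.
#'
#' @param network a probe-able network: an attention/plain block created by
#'   [new_block()] or a linear stack from [conv_stack()].
#' @param input_shape odd spatial dimensions, e.g. `c(21, 21)`, so that a
#'   unique centre exists.
#' @param probe_threshold fraction of the peak gradient a pixel must exceed
#'   to count as support (default 0.01).
#' @param input optional probe input; defaults to an all-ones array.
#' @return an object of class `erf_profile`: `gradient_map` (spatial array),
#'   `support_area` (pixel count), `center`, `threshold`.
#' @export
measure_empirical_erf <- function(network, input_shape,
                                  probe_threshold = 0.01, input = NULL) {
  if (any(input_shape %% 2L == 0L))
    stop_invalid("input_shape must be odd in every spatial dimension")
  if (probe_threshold <= 0 || probe_threshold >= 1)
    stop_invalid("probe_threshold must be in (0,1)")
  cin <- erf_probe_channels(network)
  if (is.null(input)) input <- array(1, c(input_shape, cin))
  fw <- erf_probe_forward(network, input)
  out <- fw$out
  d <- length(dim(out)) - 1L
  center <- (dim(out)[seq_len(d)] + 1L) %/% 2L
  gout <- array(0, dim(out))
  cout <- dim(out)[d + 1L]
  gout <- do.call(`[<-`, c(list(gout), as.list(center),
                           list(seq_len(cout)), list(1)))
  gin <- erf_probe_backward(network, fw, gout)
  gmap <- apply(abs(gin), seq_len(d), sum)
  peak <- max(gmap)
  if (peak == 0)
    stop(errorCondition(
      "gradient probe returned an all-zero map for a connected network",
      class = c("mm_numerical_failure", "error")))
  structure(list(gradient_map = gmap,
                 support_area = sum(gmap > probe_threshold * peak),
                 center = center,
                 threshold = probe_threshold),
            class = "erf_profile")
}

#' @export
print.erf_profile <- function(x, ...) {
  cat("ERF gradient probe: support_area =", x$support_area,
      "pixels above", x$threshold, "of peak; centre at (",
      paste(x$center, collapse = ", "), ")\n")
  invisible(x)
}

#' Export an ERF profile as CSV
#'
#' Writes one `(row, col, gradient)` line per pixel (plus `slice` for 3D
#' probes), preceded by a `#` comment line summarising the support area,
#' threshold and centre.
#'
#' @param profile an `erf_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_erf_profile <- function(profile, path) {
  gm <- profile$gradient_map
  idx <- arrayInd(seq_along(gm), dim(gm))
  df <- as.data.frame(idx)
  names(df) <- c("row", "col", "slice")[seq_len(ncol(idx))]
  df$gradient <- as.numeric(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# support_area=%d threshold=%g center=%s",
                     profile$support_area, profile$threshold,
                     paste(profile$center, collapse = "x")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# --- probe interface -------------------------------------------------------

erf_probe_channels <- function(network) UseMethod("erf_probe_channels")
erf_probe_forward <- function(network, input) UseMethod("erf_probe_forward")
erf_probe_backward <- function(network, fw, gout) UseMethod("erf_probe_backward")

#' Linear convolution stack for receptive-field probing
#'
#' Builds a bias-free stack of convolutions with no nonlinearity, useful as
#' a transparent reference network whose receptive-field footprint is known
#' in closed form.
#'
#' @param kernels integer vector of odd kernel sizes, one per layer.
#' @param dilations dilation rate per layer (recycled).
#' @param channels channel width used throughout (default 1).
#' @param weights `"uniform"` (all entries 1 / fan-in) or `"random"`.
#' @param dims number of spatial dimensions (default 2).
#' @param seed RNG seed for random weights.
#' @return an object of class `conv_stack`.
#' @export
conv_stack <- function(kernels, dilations = 1L, channels = 1L,
                       weights = c("uniform", "random"), dims = 2L,
                       seed = 1L) {
  weights <- match.arg(weights)
  dilations <- rep_len(as.integer(dilations), length(kernels))
  layers <- with_seed(seed, lapply(seq_along(kernels), function(i) {
    K <- assert_odd(kernels[i], "kernel")
    shape <- c(rep(K, dims), channels, channels)
    W <- if (weights == "uniform") {
      array(1 / (K^dims * channels), shape)
    } else he_init(shape)
    list(W = W, dilation = dilations[i])
  }))
  structure(list(layers = layers, channels = channels, dims = dims),
            class = "conv_stack")
}

#' @export
erf_probe_channels.conv_stack <- function(network) network$channels

#' @export
erf_probe_forward.conv_stack <- function(network, input) {
  xs <- list(input)
  for (l in network$layers) {
    xs[[length(xs) + 1L]] <- nd_conv_fwd(xs[[length(xs)]], l$W,
                                         dilation = l$dilation)
  }
  list(out = xs[[length(xs)]], xs = xs)
}

#' @export
erf_probe_backward.conv_stack <- function(network, fw, gout) {
  g <- gout
  for (i in rev(seq_along(network$layers))) {
    l <- network$layers[[i]]
    g <- nd_conv_bwd(fw$xs[[i]], l$W, l$dilation, g)$gx
  }
  g
}
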