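# Decoder building blocks.
#
# All three blocks share a main branch of two (conv -> ReLU -> instance
# norm) stages with odd kernels and same padding. The gated blocks add a
# side branch whose sigmoid output multiplies the main output elementwise:
#   * PASB (positive attention): one dilated convolution, so the gate has a
#     larger effective receptive field than the main branch and dilates
#     high-confidence foreground features;
#   * NASB (negative attention): two conv stages each wrapped in an identity
#     residual connection, an ensemble dominated by short paths whose gate
#     has a smaller effective receptive field, eroding foreground features.

#' Specification of a decoder block
#'
#' @param in_channels,out_channels channel widths (positive integers).
#' @param main_kernel odd kernel size of the main-branch convolutions
#'   (default 3).
#' @param side_dilation dilation rate of the PASB side convolution
#'   (default 5).
#' @param block_kind `"plain"`, `"pasb"` or `"nasb"`.
#' @param norm_kind `"instance"` (default; well-defined at batch size 1) or
#'   `"none"`.
#' @param gate_mode how the attention gate combines with the main branch:
#'   `"multiply"` (default), i.e. `main * sigmoid(side)`, or `"one_plus"`,
#'   i.e. `main * (1 + sigmoid(side))`.
#' @param seed integer seed for weight initialisation.
#' @return a `block_spec` list.
#' @export
block_spec <- function(in_channels, out_channels, main_kernel = 3L,
                       side_dilation = 5L,
                       block_kind = c("plain", "pasb", "nasb"),
                       norm_kind = c("instance", "none"),
                       gate_mode = c("multiply", "one_plus"),
                       seed = 1L) {
  spec <- list(
    in_channels = assert_count(in_channels, "in_channels"),
    out_channels = assert_count(out_channels, "out_channels"),
    main_kernel = assert_odd(main_kernel, "main_kernel"),
    side_dilation = assert_count(side_dilation, "side_dilation"),
    block_kind = match.arg(block_kind),
    norm_kind = match.arg(norm_kind),
    gate_mode = match.arg(gate_mode),
    seed = as.integer(seed))
  class(spec) <- "block_spec"
  spec
}

norm_on <- function(spec) spec$norm_kind != "none"

# One main-branch stage: conv -> ReLU -> (instance norm).
stage_params <- function(K, cin, cout, dims, norm) {
  p <- list(W = he_init(c(rep(K, dims), cin, cout)), b = numeric(cout))
  if (norm) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

stage_fwd <- function(x, p, dilation = 1L, norm = TRUE) {
  z <- nd_conv_fwd(x, p$W, p$b, dilation)
  r <- relu_fwd(z)
  if (norm) {
    ino <- inorm_fwd(r, p$gamma, p$beta)
    list(out = ino$out, x = x, z = z, r = r, ino = ino)
  } else {
    list(out = r, x = x, z = z, r = r, ino = NULL)
  }
}

stage_bwd <- function(cache, p, dilation, norm, gout) {
  if (norm) {
    ib <- inorm_bwd(cache$ino, p$gamma, gout)
    gr <- ib$gx
  } else {
    gr <- gout
  }
  gz <- relu_bwd(cache$z, gr)
  cb <- nd_conv_bwd(cache$x, p$W, dilation, gz)
  g <- list(W = cb$gW, b = cb$gb)
  if (norm) {
    g$gamma <- ib$ggamma
    g$beta <- ib$gbeta
  }
  list(gx = cb$gx, gp = g)
}

#' Initialise the parameters of a block
#'
#' Draws all weights from the block's seed (Kaiming-scaled normals for
#' convolutions, unit scale / zero shift for normalisation), so the same
#' spec always yields the same parameters.
#'
#' @param spec a [block_spec()].
#' @param dims number of spatial dimensions (2 or 3).
#' @return nested list of parameter arrays.
#' @export
block_params <- function(spec, dims = 2L) {
  K <- spec$main_kernel
  cin <- spec$in_channels
  cout <- spec$out_channels
  nrm <- norm_on(spec)
  with_seed(spec$seed, {
    p <- list(main1 = stage_params(K, cin, cout, dims, nrm),
              main2 = stage_params(K, cout, cout, dims, nrm))
    if (spec$block_kind == "pasb") {
      p$side <- list(W = he_init(c(rep(K, dims), cin, cout)),
                     b = numeric(cout))
    } else if (spec$block_kind == "nasb") {
      p$side1 <- stage_params(K, cin, cout, dims, nrm)
      p$side2 <- stage_params(K, cout, cout, dims, nrm)
      if (cin != cout)
        p$proj <- list(W = he_init(c(rep(1L, dims), cin, cout)),
                       b = numeric(cout))
    }
    p
  })
}

main_branch_fwd <- function(x, params, spec) {
  nrm <- norm_on(spec)
  s1 <- stage_fwd(x, params$main1, norm = nrm)
  s2 <- stage_fwd(s1$out, params$main2, norm = nrm)
  list(out = s2$out, s1 = s1, s2 = s2)
}

main_branch_bwd <- function(cache, params, spec, gout) {
  nrm <- norm_on(spec)
  b2 <- stage_bwd(cache$s2, params$main2, 1L, nrm, gout)
  b1 <- stage_bwd(cache$s1, params$main1, 1L, nrm, b2$gx)
  list(gx = b1$gx, gp = list(main1 = b1$gp, main2 = b2$gp))
}

#' Forward pass of a decoder block
#'
#' Runs the block described by `spec` on a channel-last feature map.
#' `plain_block_forward()`, `pasb_forward()` and `nasb_forward()` are
#' convenience wrappers fixing the block kind.
#'
#' @param x feature map, array of shape (spatial..., in_channels); a plain
#'   matrix is treated as a single-channel 2D map.
#' @param spec a [block_spec()].
#' @param params block parameters; defaults to [block_params()] drawn from
#'   `spec$seed`.
#' @param with_tape if TRUE, return `list(out, tape)` where `tape` feeds
#'   [block_backward()]; otherwise just the output feature map.
#' @return output feature map of shape (spatial..., out_channels), spatial
#'   shape identical to the input.
#' @export
block_forward <- function(x, spec, params = NULL, with_tape = FALSE) {
  x <- as_image_array(x)
  dims <- length(dim(x)) - 1L
  if (dim(x)[dims + 1L] != spec$in_channels)
    stop_shape("block expects ", spec$in_channels, " channels, got ",
               dim(x)[dims + 1L])
  if (is.null(params)) params <- block_params(spec, dims)
  main <- main_branch_fwd(x, params, spec)
  tape <- list(x = x, main = main)
  if (spec$block_kind == "plain") {
    out <- main$out
  } else {
    if (spec$block_kind == "pasb") {
      pre <- nd_conv_fwd(x, params$side$W, params$side$b,
                         spec$side_dilation)
      tape$side <- list(pre = pre)
    } else {
      nrm <- norm_on(spec)
      t1 <- stage_fwd(x, params$side1, norm = nrm)
      skip1 <- if (is.null(params$proj)) x else
        nd_conv_fwd(x, params$proj$W, params$proj$b, 1L)
      y1 <- t1$out + skip1
      t2 <- stage_fwd(y1, params$side2, norm = nrm)
      pre <- y1 + t2$out
      tape$side <- list(t1 = t1, t2 = t2, y1 = y1, pre = pre)
    }
    gate <- sigmoid(tape$side$pre)
    tape$gate <- gate
    out <- if (spec$gate_mode == "multiply") main$out * gate
           else main$out * (1 + gate)
    dim(out) <- dim(main$out)
  }
  tape$out <- out
  if (with_tape) list(out = out, tape = tape) else out
}

#' @rdname block_forward
#' @export
plain_block_forward <- function(x, spec, params = NULL) {
  if (spec$block_kind != "plain") stop_invalid("spec$block_kind must be 'plain'")
  block_forward(x, spec, params)
}

#' @rdname block_forward
#' @export
pasb_forward <- function(x, spec, params = NULL) {
  if (spec$block_kind != "pasb") stop_invalid("spec$block_kind must be 'pasb'")
  block_forward(x, spec, params)
}

#' @rdname block_forward
#' @export
nasb_forward <- function(x, spec, params = NULL) {
  if (spec$block_kind != "nasb") stop_invalid("spec$block_kind must be 'nasb'")
  block_forward(x, spec, params)
}

#' Backward pass of a decoder block
#'
#' @param tape tape from `block_forward(..., with_tape = TRUE)`.
#' @param spec the block's [block_spec()].
#' @param params the parameters used in the forward pass.
#' @param gout gradient of the loss with respect to the block output.
#' @return `list(gx, gp)`: input gradient and parameter gradients (same
#'   structure as `params`).
#' @export
block_backward <- function(tape, spec, params, gout) {
  main <- tape$main
  if (spec$block_kind == "plain") {
    mb <- main_branch_bwd(main, params, spec, gout)
    return(list(gx = mb$gx, gp = mb$gp))
  }
  gate <- tape$gate
  if (spec$gate_mode == "multiply") {
    gmain <- gout * gate
    ggate <- gout * main$out
  } else {
    gmain <- gout * (1 + gate)
    ggate <- gout * main$out
  }
  dim(gmain) <- dim(gout)
  gpre <- sigmoid_bwd(gate, ggate)
  mb <- main_branch_bwd(main, params, spec, gmain)
  gp <- mb$gp
  if (spec$block_kind == "pasb") {
    sb <- nd_conv_bwd(tape$x, params$side$W, spec$side_dilation, gpre)
    gp$side <- list(W = sb$gW, b = sb$gb)
    gx <- mb$gx + sb$gx
  } else {
    nrm <- norm_on(spec)
    side <- tape$side
    # pre = y1 + stage2(y1); y1 = stage1(x) + skip(x)
    b2 <- stage_bwd(side$t2, params$side2, 1L, nrm, gpre)
    gy1 <- gpre + b2$gx
    b1 <- stage_bwd(side$t1, params$side1, 1L, nrm, gy1)
    gp$side1 <- b1$gp
    gp$side2 <- b2$gp
    gx_side <- b1$gx
    if (is.null(params$proj)) {
      gx_side <- gx_side + gy1
    } else {
      pb <- nd_conv_bwd(tape$x, params$proj$W, 1L, gy1)
      gp$proj <- list(W = pb$gW, b = pb$gb)
      gx_side <- gx_side + pb$gx
    }
    gx <- mb$gx + gx_side
  }
  dim(gx) <- dim(tape$x)
  list(gx = gx, gp = gp)
}

#' Instantiate a block as a probe-able network object
#'
#' Pairs a [block_spec()] with its seeded parameters so the block can be
#' probed by [measure_empirical_erf()] or called repeatedly without
#' re-initialising.
#'
#' @param spec a [block_spec()].
#' @param dims number of spatial dimensions.
#' @return an object of class `mm_block`.
#' @export
new_block <- function(spec, dims = 2L) {
  structure(list(spec = spec, params = block_params(spec, dims)),
            class = "mm_block")
}

#' Stack several blocks of one kind into a probe-able network
#'
#' Chains `n_blocks` equal-width blocks of a single kind. Receptive-field
#' effects accumulate with depth, so a short stack is the natural unit for
#' comparing the effective receptive fields of the three block designs with
#' [measure_empirical_erf()] (decoders likewise apply the blocks in series).
#'
#' @param block_kind `"plain"`, `"pasb"` or `"nasb"`.
#' @param width channel width used throughout.
#' @param n_blocks number of chained blocks (default 3).
#' @param norm_kind normalisation inside the blocks; default `"none"` for
#'   probing, since normalisation statistics couple all pixels and confound
#'   the locality measurement.
#' @param seed master seed; block `i` is initialised from `seed * 100 + i`.
#' @param dims number of spatial dimensions.
#' @param ... further arguments passed to [block_spec()].
#' @return an object of class `mm_block_stack`.
#' @export
block_stack <- function(block_kind, width = 8L, n_blocks = 3L,
                        norm_kind = "none", seed = 1L, dims = 2L, ...) {
  specs <- lapply(seq_len(n_blocks), function(i)
    block_spec(width, width, block_kind = block_kind, norm_kind = norm_kind,
               seed = seed * 100L + i, ...))
  structure(list(specs = specs,
                 params = lapply(specs, block_params, dims = dims),
                 width = as.integer(width)),
            class = "mm_block_stack")
}

#' @export
erf_probe_channels.mm_block_stack <- function(network) network$width

#' @export
erf_probe_forward.mm_block_stack <- function(network, input) {
  tapes <- vector("list", length(network$specs))
  x <- input
  for (i in seq_along(network$specs)) {
    fw <- block_forward(x, network$specs[[i]], network$params[[i]],
                        with_tape = TRUE)
    tapes[[i]] <- fw$tape
    x <- fw$out
  }
  list(out = x, tapes = tapes)
}

#' @export
erf_probe_backward.mm_block_stack <- function(network, fw, gout) {
  g <- gout
  for (i in rev(seq_along(network$specs))) {
    g <- block_backward(fw$tapes[[i]], network$specs[[i]],
                        network$params[[i]], g)$gx
  }
  g
}

#' @export
erf_probe_channels.mm_block <- function(network) network$spec$in_channels

#' @export
erf_probe_forward.mm_block <- function(network, input) {
  block_forward(input, network$spec, network$params, with_tape = TRUE)
}

#' @export
erf_probe_backward.mm_block <- function(network, fw, gout) {
  block_backward(fw$tape, network$spec, network$params, gout)$gx
}
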