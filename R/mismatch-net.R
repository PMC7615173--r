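# The MisMatch network: a U-net style encoder shared by two decoders built
# from attention-shifting blocks. Decoder 1 (positive attention) dilates
# high-confidence foreground, decoder 2 (negative attention) erodes it; the
# final prediction is the elementwise average of the two sigmoid outputs.
# The same code builds the 3D variant by replacing 2D convolutions with 3D
# ones throughout (dims = 3).

decoder_kinds <- function(variant) {
  switch(variant,
         "MM"   = c("pasb", "nasb"),
         "MM-a" = c("plain", "plain"),
         "MM-b" = c("plain", "nasb"),
         "MM-c" = c("plain", "pasb"),
         "unet" = "plain",
         stop_invalid("unknown decoder_variant: ", variant))
}

#' Specification of a MisMatch network
#'
#' @param dims 2 or 3 spatial dimensions.
#' @param in_channels number of input modalities (default 1).
#' @param base_width channels of the first encoder stage; the reference
#'   settings are 24 for the 2D network and 8 for the 3D network.
#' @param depth number of resolution levels including the bottleneck
#'   (>= 2); spatial dims of inputs must be divisible by `2^(depth - 1)`.
#' @param decoder_variant `"MM"` (positive + negative attention decoders,
#'   the full framework), `"MM-a"` (two plain decoders), `"MM-b"` (plain +
#'   negative), `"MM-c"` (plain + positive), or `"unet"` (a single plain
#'   decoder: the supervised baseline).
#' @param main_kernel,side_dilation,norm_kind,gate_mode block settings, see
#'   [block_spec()].
#' @param share_decoder_init copy decoder-1 parameters into decoder 2 when
#'   the two decoders have identical topology (only meaningful for
#'   `"MM-a"`); default FALSE, matching independent random initialisation.
#' @param seed integer seed for all weight initialisation.
#' @return a `network_spec` list.
#' @export
network_spec <- function(dims = 2L, in_channels = 1L, base_width = 24L,
                         depth = 3L,
                         decoder_variant = c("MM", "MM-a", "MM-b", "MM-c",
                                             "unet"),
                         main_kernel = 3L, side_dilation = 5L,
                         norm_kind = "instance", gate_mode = "multiply",
                         share_decoder_init = FALSE, seed = 1L) {
  if (!(dims %in% c(2L, 3L))) stop_invalid("dims must be 2 or 3")
  spec <- list(dims = as.integer(dims),
               in_channels = assert_count(in_channels, "in_channels"),
               base_width = assert_count(base_width, "base_width"),
               depth = assert_count(depth, "depth", min = 2L),
               decoder_variant = match.arg(decoder_variant),
               main_kernel = assert_odd(main_kernel, "main_kernel"),
               side_dilation = assert_count(side_dilation, "side_dilation"),
               norm_kind = norm_kind,
               gate_mode = gate_mode,
               share_decoder_init = assert_flag(share_decoder_init,
                                                "share_decoder_init"),
               seed = as.integer(seed))
  class(spec) <- "network_spec"
  spec
}

level_widths <- function(spec) spec$base_width * 2L^(seq_len(spec$depth) - 1L)

net_block_spec <- function(spec, cin, cout, kind, seed) {
  block_spec(cin, cout, main_kernel = spec$main_kernel,
             side_dilation = spec$side_dilation, block_kind = kind,
             norm_kind = spec$norm_kind, gate_mode = spec$gate_mode,
             seed = seed)
}

#' Build a MisMatch network
#'
#' Instantiates the encoder and decoder blocks of a [network_spec()] with
#' seeded weights. Encoder stages are plain blocks separated by 2x max
#' pooling; each decoder stage upsamples (nearest neighbour), concatenates
#' the encoder skip feature, and applies its block; each decoder ends in a
#' 1x1 convolution with a sigmoid head.
#'
#' @param spec a [network_spec()].
#' @return an object of class `mismatch_net` with elements `spec`,
#'   `blocks` (the per-stage block specs) and `params`.
#' @export
build_network <- function(spec) {
  w <- level_widths(spec)
  L <- spec$depth
  kinds <- decoder_kinds(spec$decoder_variant)
  # per-stage block specs; seeds are derived deterministically from the
  # network seed so that each stage gets an independent stream
  sid <- spec$seed * 10000L
  enc_in <- c(spec$in_channels, w[-L])
  enc_specs <- lapply(seq_len(L), function(l)
    net_block_spec(spec, enc_in[l], w[l], "plain", sid + l))
  dec_specs <- lapply(seq_along(kinds), function(h) {
    lapply(rev(seq_len(L - 1L)), function(l)
      net_block_spec(spec, w[l + 1L] + w[l], w[l], kinds[h],
                     sid + 100L * h + l))
  })
  params <- list(
    enc = lapply(enc_specs, block_params, dims = spec$dims),
    dec = lapply(seq_along(kinds), function(h) {
      lev <- lapply(dec_specs[[h]], block_params, dims = spec$dims)
      head <- with_seed(sid + 100L * h, list(
        W = he_init(c(rep(1L, spec$dims), w[1L], 1L)),
        b = numeric(1L)))
      list(levels = lev, head = head)
    }))
  if (spec$share_decoder_init && length(kinds) == 2L &&
      kinds[1L] == kinds[2L]) {
    params$dec[[2L]] <- params$dec[[1L]]
  }
  structure(list(spec = spec,
                 blocks = list(enc = enc_specs, dec = dec_specs),
                 params = params),
            class = "mismatch_net")
}

#' Number of trainable parameters
#' @param network a `mismatch_net`.
#' @return integer count.
#' @export
n_params <- function(network) {
  length(unlist(network$params, use.names = FALSE))
}

check_divisible <- function(sp, depth) {
  m <- 2L^(depth - 1L)
  if (any(sp %% m != 0L))
    stop_shape("input spatial dims (", paste(sp, collapse = "x"),
               ") must each be divisible by ", m)
}

decoder_fwd <- function(params_dec, specs_dec, bottom, skips) {
  u <- bottom
  tapes <- vector("list", length(specs_dec))
  cats <- vector("list", length(specs_dec))
  for (i in seq_along(specs_dec)) {
    skip <- skips[[length(skips) - i + 1L]]
    up <- upsample2_fwd(u)
    xin <- cat_channels(up, skip)
    cats[[i]] <- dim(up)[length(dim(up))]
    fw <- block_forward(xin, specs_dec[[i]], params_dec$levels[[i]],
                        with_tape = TRUE)
    tapes[[i]] <- fw$tape
    u <- fw$out
  }
  z <- nd_conv_fwd(u, params_dec$head$W, params_dec$head$b, 1L)
  p <- sigmoid(z)
  list(p = p, u = u, tapes = tapes, cats = cats)
}

decoder_bwd <- function(params_dec, specs_dec, dtape, gp) {
  gz <- sigmoid_bwd(dtape$p, gp)
  hb <- nd_conv_bwd(dtape$u, params_dec$head$W, 1L, gz)
  g <- hb$gx
  gp_levels <- vector("list", length(specs_dec))
  gskips <- vector("list", length(specs_dec))
  for (i in rev(seq_along(specs_dec))) {
    bb <- block_backward(dtape$tapes[[i]], specs_dec[[i]],
                         params_dec$levels[[i]], g)
    gp_levels[[i]] <- bb$gp
    sp2 <- split_channels_bwd(bb$gx, dtape$cats[[i]])
    gskips[[i]] <- sp2$gb
    g <- upsample2_bwd(sp2$ga)
  }
  list(gp = list(levels = gp_levels, head = list(W = hb$gW, b = hb$gb)),
       gbottom = g, gskips = gskips)
}

#' Forward pass of a MisMatch network
#'
#' @param network a [build_network()] result.
#' @param x input image, array (spatial..., channels); a matrix is treated
#'   as a single-channel 2D image. Spatial dims must be divisible by
#'   `2^(depth - 1)`.
#' @param with_tape keep the intermediate activations needed by
#'   [net_backward()].
#' @return a `paired_prediction`: `p1` and `p2` are the per-decoder
#'   foreground probability maps (p2 is NULL for the `"unet"` variant) and
#'   `fused` their elementwise average (equal to `p1` for `"unet"`).
#' @export
net_forward <- function(network, x, with_tape = FALSE) {
  spec <- network$spec
  x <- as_image_array(x)
  if (length(dim(x)) - 1L != spec$dims)
    stop_shape("network is ", spec$dims, "D but input has ",
               length(dim(x)) - 1L, " spatial dims")
  check_divisible(spatial_dims(x), spec$depth)
  L <- spec$depth
  skips <- vector("list", L - 1L)
  etapes <- vector("list", L)
  pools <- vector("list", L - 1L)
  h <- x
  for (l in seq_len(L)) {
    fw <- block_forward(h, network$blocks$enc[[l]], network$params$enc[[l]],
                        with_tape = TRUE)
    etapes[[l]] <- fw$tape
    if (l < L) {
      skips[[l]] <- fw$out
      mp <- maxpool2_fwd(fw$out)
      pools[[l]] <- mp
      h <- mp$out
    } else {
      h <- fw$out
    }
  }
  dts <- lapply(seq_along(network$blocks$dec), function(hd)
    decoder_fwd(network$params$dec[[hd]], network$blocks$dec[[hd]], h, skips))
  p1 <- dts[[1L]]$p
  p2 <- if (length(dts) > 1L) dts[[2L]]$p else NULL
  fused <- if (is.null(p2)) p1 else (p1 + p2) / 2
  dim(fused) <- dim(p1)
  out <- structure(list(p1 = p1, p2 = p2, fused = fused),
                   class = "paired_prediction")
  if (with_tape)
    out$tape <- list(etapes = etapes, pools = pools, dts = dts,
                     nskips = L - 1L)
  out
}

#' Backward pass of a MisMatch network
#'
#' @param network the network used in the forward pass.
#' @param pred a `paired_prediction` from `net_forward(..., with_tape=TRUE)`.
#' @param gp1,gp2 gradients of the loss with respect to `p1` / `p2` (`gp2`
#'   ignored for single-decoder variants; NULL means zero).
#' @return parameter gradients with the same structure as `network$params`.
#' @export
net_backward <- function(network, pred, gp1, gp2 = NULL) {
  spec <- network$spec
  tape <- pred$tape
  if (is.null(tape)) stop_invalid("forward pass was run without a tape")
  L <- spec$depth
  nheads <- length(network$blocks$dec)
  gps <- list(gp1, gp2)
  gdec <- vector("list", nheads)
  gbottom <- NULL
  gskips <- NULL
  for (hd in seq_len(nheads)) {
    g <- gps[[hd]]
    if (is.null(g)) g <- array(0, dim(pred$p1))
    db <- decoder_bwd(network$params$dec[[hd]], network$blocks$dec[[hd]],
                      tape$dts[[hd]], g)
    gdec[[hd]] <- db$gp
    gbottom <- if (is.null(gbottom)) db$gbottom else gbottom + db$gbottom
    if (is.null(gskips)) gskips <- db$gskips
    else gskips <- Map(`+`, gskips, db$gskips)
  }
  # decoder level i consumed skip (L - i); reorder to encoder order
  gskip_enc <- rev(gskips)
  genc <- vector("list", L)
  g <- gbottom
  for (l in rev(seq_len(L))) {
    if (l < L) {
      g <- maxpool2_bwd(tape$pools[[l]], g)
      g <- g + gskip_enc[[l]]
    }
    bb <- block_backward(tape$etapes[[l]], network$blocks$enc[[l]],
                         network$params$enc[[l]], g)
    genc[[l]] <- bb$gp
    g <- bb$gx
  }
  list(enc = genc, dec = gdec)
}

#' Threshold a probability map into a binary mask
#'
#' @param p probability map (array in `[0,1]`).
#' @param threshold decision threshold (default 0.5).
#' @return integer array of 0/1 with the spatial dimensions of `p`.
#' @export
predict_mask <- function(p, threshold = 0.5) {
  d <- length(dim(p)) - 1L
  m <- array(as.integer(p > threshold), dim(p))
  if (dim(p)[d + 1L] == 1L) {
    dim(m) <- dim(p)[seq_len(d)]
  }
  m
}

#' @export
print.mismatch_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("MisMatch network (%dD, variant %s): base width %d, depth %d, %d parameters\n",
              s$dims, s$decoder_variant, s$base_width, s$depth, n_params(x)))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS files holding a version tag, the [network_spec()]
#' and the parameter arrays; `load_checkpoint()` rebuilds the network and
#' restores the weights, so a checkpoint is reproducible given (spec, seed).
#'
#' @param network a `mismatch_net`.
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored `mismatch_net`.
#' @export
save_checkpoint <- function(network, path) {
  saveRDS(list(format = "mismatch-checkpoint", version = 1L,
               spec = unclass(network$spec), params = network$params),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mismatch-checkpoint"))
    stop_format("not a mismatch checkpoint: ", path)
  spec <- do.call(network_spec, obj$spec[setdiff(names(obj$spec), NULL)])
  net <- build_network(spec)
  net$params <- obj$params
  net
}
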