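# Synthetic phantoms with known ground truth: thin tubular structures
# (rasterised correlated random walks with jittered radius, emulating
# vessels) and ellipsoidal blobs (emulating compact tumours), in 2D or 3D.
# Images are contrast * mask + Gaussian noise, normalised case-wise to zero
# mean and unit variance. A benchmark draws the labelled subset from a
# single jittered "case" so the labelled data are correlated, as when all
# labelled slices come from one scan.

#' Specification of a phantom image
#'
#' @param dims 2 or 3.
#' @param shape spatial extent, e.g. `c(64, 64)`.
#' @param n_objects number of foreground objects (0 gives pure background).
#' @param object_kind `"tube"` or `"blob"`.
#' @param radius_range tube radius / blob semi-axis range in pixels.
#' @param intensity_contrast foreground-background mean intensity gap in
#'   raw (pre-normalisation) units.
#' @param noise_sigma additive Gaussian noise scale in the same units.
#' @param seed integer seed; the same spec always generates the same
#'   phantom.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(dims = 2L, shape = c(64L, 64L), n_objects = 3L,
                         object_kind = c("tube", "blob"),
                         radius_range = c(1.5, 3), intensity_contrast = 1,
                         noise_sigma = 0.3, seed = 1L) {
  object_kind <- match.arg(object_kind)
  if (!(dims %in% c(2L, 3L))) stop_invalid("dims must be 2 or 3")
  if (length(shape) != dims) stop_invalid("shape must have length dims")
  if (any(radius_range <= 0)) stop_invalid("radius_range must be positive")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  structure(list(dims = as.integer(dims), shape = as.integer(shape),
                 n_objects = assert_count(n_objects, "n_objects", min = 0L),
                 object_kind = object_kind,
                 radius_range = as.numeric(radius_range),
                 intensity_contrast = as.numeric(intensity_contrast),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Draw object geometry (not yet rasterised). Tubes: start point, unit step
# headings as cumulative angles with Gaussian increments, base radius with
# per-step jitter. Blobs: centre, semi-axes, rotation.
sample_geometry <- function(spec) {
  margin <- ceiling(max(spec$radius_range)) + 1L
  lo <- rep(margin + 1L, spec$dims)
  hi <- spec$shape - margin
  if (spec$n_objects > 0L && any(hi < lo))
    stop_invalid("objects of radius up to ", max(spec$radius_range),
                 " cannot fit a ", paste(spec$shape, collapse = "x"),
                 " phantom")
  lapply(seq_len(spec$n_objects), function(i) {
    start <- vapply(seq_len(spec$dims), function(j)
      stats::runif(1, lo[j], hi[j]), numeric(1))
    if (spec$object_kind == "tube") {
      n_steps <- round(0.75 * min(spec$shape))
      ang0 <- stats::runif(spec$dims - 1L, 0, 2 * pi)
      dang <- matrix(stats::rnorm(n_steps * (spec$dims - 1L), 0, 0.15),
                     n_steps, spec$dims - 1L)
      list(kind = "tube", start = start, ang0 = ang0, dang = dang,
           radius = stats::runif(1, spec$radius_range[1],
                                 spec$radius_range[2]),
           rjit = stats::rnorm(n_steps, 0, 0.08))
    } else {
      axes <- stats::runif(spec$dims, spec$radius_range[1],
                           spec$radius_range[2])
      rot <- if (spec$dims == 2L) stats::runif(1, 0, pi) else
        qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      list(kind = "blob", center = start, axes = axes, rot = rot)
    }
  })
}

jitter_geometry <- function(geometry, shift_sd = 2, angle_sd = 0.1) {
  lapply(geometry, function(g) {
    shift <- stats::rnorm(length(g$start %||% g$center), 0, shift_sd)
    if (g$kind == "tube") {
      g$start <- g$start + shift
      g$ang0 <- g$ang0 + stats::rnorm(length(g$ang0), 0, angle_sd)
    } else {
      g$center <- g$center + shift
    }
    g
  })
}

tube_path <- function(g, dims) {
  ang <- apply(g$dang, 2L, cumsum)
  if (is.null(dim(ang))) ang <- matrix(ang, ncol = dims - 1L)
  ang <- sweep(ang, 2L, g$ang0, `+`)
  steps <- if (dims == 2L) {
    cbind(cos(ang[, 1L]), sin(ang[, 1L]))
  } else {
    cbind(cos(ang[, 1L]) * sin(ang[, 2L]),
          sin(ang[, 1L]) * sin(ang[, 2L]),
          cos(ang[, 2L]))
  }
  pts <- rbind(g$start, sweep(apply(steps, 2L, cumsum), 1L, 0) +
                 matrix(g$start, nrow(steps), dims, byrow = TRUE))
  radii <- c(g$radius, pmax(0.5, g$radius * (1 + g$rjit)))
  list(pts = pts, radii = radii)
}

stamp_ball <- function(mask, center, r, shape) {
  d <- length(shape)
  lo <- pmax(1L, floor(center - r))
  hi <- pmin(shape, ceiling(center + r))
  if (any(hi < lo)) return(mask)
  rng <- lapply(seq_len(d), function(j) lo[j]:hi[j])
  grid <- as.matrix(expand.grid(rng))
  d2 <- rowSums(sweep(grid, 2L, center)^2)
  inside <- grid[d2 <= r^2, , drop = FALSE]
  if (nrow(inside) > 0L) {
    mult <- cumprod(c(1L, shape[-d]))
    flat <- 1L + as.integer(rowSums(sweep(inside - 1L, 2L, mult, `*`)))
    mask[flat] <- 1L
  }
  mask
}

rasterise_geometry <- function(geometry, spec) {
  mask <- array(0L, spec$shape)
  for (g in geometry) {
    if (g$kind == "tube") {
      path <- tube_path(g, spec$dims)
      for (i in seq_len(nrow(path$pts)))
        mask <- stamp_ball(mask, path$pts[i, ], path$radii[i], spec$shape)
    } else {
      R <- if (spec$dims == 2L) {
        matrix(c(cos(g$rot), sin(g$rot), -sin(g$rot), cos(g$rot)), 2, 2)
      } else g$rot
      r <- max(g$axes)
      lo <- pmax(1L, floor(g$center - r))
      hi <- pmin(spec$shape, ceiling(g$center + r))
      rng <- lapply(seq_len(spec$dims), function(j) lo[j]:hi[j])
      grid <- as.matrix(expand.grid(rng))
      local <- sweep(grid, 2L, g$center) %*% R
      q <- rowSums(sweep(local, 2L, g$axes, `/`)^2)
      inside <- grid[q <= 1, , drop = FALSE]
      if (nrow(inside) > 0L) {
        mult <- cumprod(c(1L, spec$shape[-spec$dims]))
        flat <- 1L + as.integer(rowSums(sweep(inside - 1L, 2L, mult, `*`)))
        mask[flat] <- 1L
      }
    }
  }
  mask
}

render_phantom <- function(geometry, spec) {
  mask <- rasterise_geometry(geometry, spec)
  img <- spec$intensity_contrast * mask
  if (spec$noise_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  mu <- mean(img)
  s <- stats::sd(as.numeric(img))
  img <- if (is.na(s) || s < 1e-12) img * 0 else (img - mu) / s
  list(image = array(img, c(spec$shape, 1L)), mask = array(mask, spec$shape))
}

#' Generate one phantom image with its ground-truth mask
#'
#' @param spec a [phantom_spec()].
#' @return `list(image, mask)`: image is a (spatial..., 1) array normalised
#'   case-wise to zero mean / unit variance; mask a binary spatial array.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$seed, render_phantom(sample_geometry(spec), spec))
}

#' Keep only slices with enough foreground
#'
#' Retains pairs whose mask has strictly more than `foreground_min`
#' foreground pixels.
#'
#' @param pairs list of `list(image, mask)`.
#' @param foreground_min threshold (default 100); a slice with exactly this
#'   many foreground pixels is rejected.
#' @return the kept pairs.
#' @export
filter_slices <- function(pairs, foreground_min = 100L) {
  keep <- vapply(pairs, function(p) sum(p$mask) > foreground_min, logical(1))
  pairs[keep]
}

#' Crop fixed-size patches from the four corners of a 2D slice
#'
#' Windows are half-open with 0-based anchors: a patch with anchor
#' `c(a, b)` covers rows `a .. a+crop-1` and columns `b .. b+crop-1` in
#' 0-based indexing.
#'
#' @param image 2D image (matrix or (H, W, C) array).
#' @param mask optional mask cropped identically.
#' @param crop patch side length; must not exceed either spatial dim.
#' @return list of 4 `list(image, mask, anchor)` entries ordered top-left,
#'   top-right, bottom-left, bottom-right.
#' @export
corner_crops <- function(image, mask = NULL, crop) {
  image <- as_image_array(image, "image")
  sp <- spatial_dims(image)
  if (length(sp) != 2L) stop_invalid("corner_crops expects a 2D slice")
  crop <- assert_count(crop, "crop")
  if (any(crop > sp))
    stop_invalid("crop ", crop, " exceeds image dims ",
                 paste(sp, collapse = "x"))
  anchors <- list(c(0L, 0L), c(0L, sp[2L] - crop),
                  c(sp[1L] - crop, 0L), c(sp[1L] - crop, sp[2L] - crop))
  lapply(anchors, function(a) {
    ri <- (a[1L] + 1L):(a[1L] + crop)
    ci <- (a[2L] + 1L):(a[2L] + crop)
    list(image = image[ri, ci, , drop = FALSE],
         mask = if (!is.null(mask)) mask[ri, ci],
         anchor = a)
  })
}

#' Seeded random sub-volume crop
#'
#' Draws a uniformly random corner (0-based offset) and crops a
#' `size`-shaped window; the mask is cropped identically.
#'
#' @param volume spatial array, optionally with a trailing channel axis.
#' @param mask optional mask of the spatial shape.
#' @param size crop extent per spatial axis (default `c(96, 96, 96)`).
#' @param seed integer seed; the same seed gives the same crop.
#' @return `list(image, mask, offset)` with `offset` 0-based.
#' @export
random_subvolume <- function(volume, mask = NULL, size = c(96L, 96L, 96L),
                             seed = 1L) {
  dv <- dim(volume)
  d <- length(size)
  has_channel <- length(dv) == d + 1L
  sp <- if (has_channel) dv[seq_len(d)] else dv
  if (length(sp) != d) stop_invalid("volume and size dimensionality differ")
  if (any(size > sp))
    stop_invalid("crop size ", paste(size, collapse = "x"),
                 " exceeds volume dims ", paste(sp, collapse = "x"))
  off <- with_seed(seed, vapply(seq_len(d), function(j)
    sample.int(sp[j] - size[j] + 1L, 1L) - 1L, integer(1)))
  rng <- lapply(seq_len(d), function(j) (off[j] + 1L):(off[j] + size[j]))
  img <- if (has_channel) {
    do.call(`[`, c(list(volume), rng, list(quote(expr = )), list(drop = FALSE)))
  } else {
    do.call(`[`, c(list(volume), rng, list(drop = FALSE)))
  }
  list(image = img,
       mask = if (!is.null(mask)) do.call(`[`, c(list(mask), rng,
                                                 list(drop = FALSE))),
       offset = off)
}

#' Split sizes for a phantom benchmark
#'
#' @param n_labelled,n_unlabelled,n_val,n_test split sizes.
#' @param foreground_min minimum foreground pixels per kept image
#'   (strictly greater than; default 100).
#' @return a `split_spec` list.
#' @export
split_spec <- function(n_labelled = 5L, n_unlabelled = 100L, n_val = 10L,
                       n_test = 20L, foreground_min = 100L) {
  structure(list(n_labelled = assert_count(n_labelled, "n_labelled",
                                           min = 0L),
                 n_unlabelled = assert_count(n_unlabelled, "n_unlabelled",
                                             min = 0L),
                 n_val = assert_count(n_val, "n_val", min = 0L),
                 n_test = assert_count(n_test, "n_test", min = 0L),
                 foreground_min = assert_count(foreground_min,
                                               "foreground_min", min = 0L)),
            class = "split_spec")
}

draw_filtered <- function(n, spec, seed_base, foreground_min, what,
                          geometry = NULL) {
  out <- vector("list", n)
  attempts <- 0L
  max_attempts <- max(20L * n, 50L)
  i <- 1L
  while (i <= n) {
    if (attempts >= max_attempts)
      stop_invalid("could not generate ", n, " ", what, " images passing ",
                   "the >", foreground_min, " foreground filter in ",
                   max_attempts, " attempts; requested counts exceed the ",
                   "generated pool")
    attempts <- attempts + 1L
    item <- with_seed(seed_base + 7919L * attempts, {
      geo <- if (is.null(geometry)) sample_geometry(spec)
             else jitter_geometry(geometry)
      render_phantom(geo, spec)
    })
    if (sum(item$mask) > foreground_min) {
      item$seed <- seed_base + 7919L * attempts
      out[[i]] <- item
      i <- i + 1L
    }
  }
  out
}

#' Build a reproducible semi-supervised phantom benchmark
#'
#' Generates disjoint labelled / unlabelled / validation / test splits of
#' phantoms passing the foreground filter. The labelled subset is drawn
#' from a single "case": one base geometry jittered per image (small
#' translations and heading perturbations, fresh noise), emulating the
#' regime where all labels come from one scan. All other splits are
#' independent phantoms.
#'
#' @param split a [split_spec()].
#' @param phantom a [phantom_spec()]; its seed is the master seed of the
#'   benchmark.
#' @return a [data_stream()] with a `manifest` attribute (data.frame of
#'   split, index, foreground count, seed).
#' @export
make_benchmark <- function(split = split_spec(), phantom = phantom_spec()) {
  ms <- phantom$seed
  case_geo <- with_seed(ms * 13L + 1L, sample_geometry(phantom))
  lab <- draw_filtered(split$n_labelled, phantom, ms * 1000L + 1L,
                       split$foreground_min, "labelled", geometry = case_geo)
  unl <- draw_filtered(split$n_unlabelled, phantom, ms * 1000L + 200000L,
                       split$foreground_min, "unlabelled")
  val <- draw_filtered(split$n_val, phantom, ms * 1000L + 400000L,
                       split$foreground_min, "validation")
  tst <- draw_filtered(split$n_test, phantom, ms * 1000L + 600000L,
                       split$foreground_min, "test")
  strip <- function(items) lapply(items, function(x)
    list(image = x$image, mask = x$mask))
  manifest <- do.call(rbind, Map(function(items, nm) {
    if (length(items) == 0L) return(NULL)
    data.frame(split = nm, index = seq_along(items),
               foreground = vapply(items, function(x) sum(x$mask),
                                   numeric(1)),
               seed = vapply(items, function(x) x$seed, numeric(1)))
  }, list(lab, unl, val, tst),
     list("labelled", "unlabelled", "val", "test")))
  ds <- data_stream(labelled = strip(lab),
                    unlabelled = lapply(unl, function(x) x$image),
                    val = strip(val), test = strip(tst))
  attr(ds, "manifest") <- manifest
  attr(ds, "phantom_spec") <- phantom
  attr(ds, "split_spec") <- split
  ds
}
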