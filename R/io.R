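# Readers/writers for standard formats (NIfTI volumes, PNG slices) and the
# YAML run configuration.

#' Case-wise intensity normalisation
#'
#' Standardises an image to zero mean and unit variance over all voxels of
#' the case; constant images map to all zeros.
#'
#' @param x numeric array.
#' @return normalised array of the same shape.
#' @export
case_normalise <- function(x) {
  mu <- mean(x)
  s <- stats::sd(as.numeric(x))
  out <- if (is.na(s) || s < 1e-12) x * 0 else (x - mu) / s
  dim(out) <- dim(x)
  out
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read an image volume or slice
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and 2D PNG slices. Voxel
#' spacing is preserved for NIfTI (PNG gets unit spacing) so that surface
#' distances can be reported in physical units.
#'
#' @param path file path.
#' @param normalise apply [case_normalise()] on read (default FALSE).
#' @return `list(image, spacing, path)`; `image` is a numeric array.
#' @export
read_volume <- function(path, normalise = FALSE) {
  if (!file.exists(path)) stop_format("cannot read volume: no file at ", path)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)
    data <- array(as.numeric(img), dim(img))
  } else if (grepl("\\.png$", path)) {
    data <- png::readPNG(path)
    spacing <- rep(1, 2L)
  } else {
    stop_format("unsupported volume format: ", path)
  }
  if (normalise) data <- case_normalise(data)
  list(image = data, spacing = spacing, path = path)
}

#' Write an image volume or slice
#'
#' NIfTI output keeps the given voxel spacing; PNG output requires values
#' in `[0, 1]` (use `rescale = TRUE` to min-max scale, with the original
#' range returned for exact inversion).
#'
#' @param image numeric array (2D for PNG).
#' @param path output path ending in `.nii`, `.nii.gz` or `.png`.
#' @param spacing voxel spacing per axis (NIfTI only).
#' @param rescale min-max rescale to `[0,1]` before writing a PNG.
#' @return invisibly, `list(path, lo, hi)` where `lo`/`hi` record the
#'   rescaling applied (NA if none).
#' @export
write_volume <- function(image, path, spacing = NULL, rescale = FALSE) {
  lo <- NA_real_
  hi <- NA_real_
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(array(as.numeric(image), dim(image)))
    if (!is.null(spacing)) RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.png$", path)) {
    m <- image
    if (length(dim(m)) == 3L && dim(m)[3L] == 1L) dim(m) <- dim(m)[1:2]
    if (rescale) {
      lo <- min(m)
      hi <- max(m)
      m <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    }
    if (any(m < 0 | m > 1))
      stop_format("PNG values must lie in [0,1]; use rescale = TRUE")
    png::writePNG(m, path)
  } else {
    stop_format("unsupported volume format: ", path)
  }
  invisible(list(path = path, lo = lo, hi = hi))
}

#' Write a phantom benchmark to disk
#'
#' Saves every image/mask pair of a benchmark [data_stream()] as PNG (2D)
#' or NIfTI (3D) files under per-split directories, plus a `manifest.csv`
#' with path, split, foreground count, generator seed and the PNG rescale
#' range.
#'
#' @param stream a [make_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_benchmark <- function(stream, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phantom <- attr(stream, "phantom_spec")
  ext <- if (!is.null(phantom) && phantom$dims == 3L) ".nii.gz" else ".png"
  rows <- list()
  emit <- function(split, i, image, mask) {
    sdir <- file.path(dir, split)
    dir.create(sdir, showWarnings = FALSE)
    ipath <- file.path(sdir, sprintf("img_%03d%s", i, ext))
    inf <- write_volume(image, ipath, rescale = (ext == ".png"))
    mpath <- NA_character_
    if (!is.null(mask)) {
      mpath <- file.path(sdir, sprintf("msk_%03d%s", i, ext))
      write_volume(array(as.numeric(mask), dim(mask)), mpath)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      split = split, index = i, image = ipath, mask = mpath,
      foreground = if (is.null(mask)) NA_real_ else sum(mask),
      lo = inf$lo, hi = inf$hi)
  }
  for (i in seq_along(stream$labelled))
    emit("labelled", i, stream$labelled[[i]]$image, stream$labelled[[i]]$mask)
  for (i in seq_along(stream$unlabelled))
    emit("unlabelled", i, stream$unlabelled[[i]], NULL)
  for (i in seq_along(stream$val))
    emit("val", i, stream$val[[i]]$image, stream$val[[i]]$mask)
  for (i in seq_along(stream$test))
    emit("test", i, stream$test[[i]]$image, stream$test[[i]]$mask)
  manifest <- do.call(rbind, rows)
  gm <- attr(stream, "manifest")
  if (!is.null(gm))
    manifest$seed <- gm$seed[match(paste(manifest$split, manifest$index),
                                   paste(gm$split, gm$index))]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

build_from <- function(fun, args, what) {
  if (is.null(args)) args <- list()
  unknown <- setdiff(names(args), names(formals(fun)))
  if (length(unknown) > 0L)
    stop_invalid("unknown ", what, " config keys: ",
                 paste(unknown, collapse = ", "))
  do.call(fun, args)
}

#' Read and validate a YAML run configuration
#'
#' Recognised top-level keys: `network`, `train`, `loss`, `phantom`,
#' `split`, `output_dir`, `log_level`; unknown keys (at either level) are
#' rejected. Each section is passed through its spec constructor so every
#' value is validated.
#'
#' @param path YAML file path.
#' @return list with `network` ([network_spec()]), `train`
#'   ([train_config()]), `loss` ([loss_config()]), `phantom`
#'   ([phantom_spec()]), `split` ([split_spec()]), `output_dir`,
#'   `log_level`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("no config file at ", path)
  raw <- yaml::read_yaml(path)
  known <- c("network", "train", "loss", "phantom", "split", "output_dir",
             "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$phantom$shape))
    raw$phantom$shape <- as.integer(unlist(raw$phantom$shape))
  list(network = build_from(network_spec, raw$network, "network"),
       train = build_from(train_config, raw$train, "train"),
       loss = build_from(loss_config, raw$loss, "loss"),
       phantom = build_from(phantom_spec, raw$phantom, "phantom"),
       split = build_from(split_spec, raw$split, "split"),
       output_dir = raw$output_dir %||% ".",
       log_level = raw$log_level %||% "info")
}
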