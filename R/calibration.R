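# Pixel-wise calibration analysis and segmentation accuracy metrics.
#
# For binary segmentation each pixel's predicted class is the more probable
# of {foreground p, background 1-p}, so its confidence max(p, 1-p) lies in
# [0.5, 1]. Pixels are binned into M equal-width confidence intervals over
# [0.5, 1]; the expected calibration error (ECE) is the bin-count-weighted
# mean absolute gap between per-bin accuracy and per-bin confidence.

#' Bin pixels by confidence and compute the expected calibration error
#'
#' Bins are left-open/right-closed except the first, which includes 0.5;
#' confidences exactly on an interior edge fall in the lower bin. Predicted
#' class ties at p = 0.5 go to background. Empty bins contribute zero
#' weight to the ECE.
#'
#' @param p foreground probability map (values in `[0, 1]`).
#' @param y binary ground-truth mask of matching spatial shape.
#' @param M number of confidence bins over `[0.5, 1]` (default 5).
#' @return an object of class `calibration_report`: `bin_edges` (length
#'   M+1), per-bin `counts`, `accuracy`, `confidence` (NaN for empty bins),
#'   scalar `ece` and `n_pixels`.
#' @export
bin_pixels <- function(p, y, M = 5L) {
  M <- assert_count(M, "M")
  if (length(p) == 0L) stop_invalid("empty probability map")
  p <- as.numeric(p)
  y <- as.numeric(y)
  if (length(p) != length(y))
    stop_shape("prediction and mask sizes differ (", length(p), " vs ",
               length(y), ")")
  if (any(p < 0 | p > 1)) stop_invalid("probabilities must lie in [0,1]")
  if (any(y != 0 & y != 1)) stop_invalid("mask must be binary")
  pred <- as.integer(p > 0.5)
  conf <- pmax(p, 1 - p)
  correct <- as.integer(pred == y)
  width <- 0.5 / M
  # ceiling((conf - 0.5)/width) puts interior-edge ties in the lower bin;
  # conf == 0.5 lands in bin 1
  bin <- pmin(M, pmax(1L, ceiling((conf - 0.5) / width - 1e-12)))
  counts <- tabulate(bin, nbins = M)
  acc <- vapply(seq_len(M), function(m)
    if (counts[m] == 0L) NaN else mean(correct[bin == m]), numeric(1))
  cf <- vapply(seq_len(M), function(m)
    if (counts[m] == 0L) NaN else mean(conf[bin == m]), numeric(1))
  n <- length(p)
  occupied <- counts > 0L
  ece <- sum((counts[occupied] / n) * abs(acc[occupied] - cf[occupied]))
  structure(list(bin_edges = seq(0.5, 1, length.out = M + 1L),
                 counts = counts, accuracy = acc, confidence = cf,
                 ece = ece, n_pixels = n),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report: %d pixels, %d bins, ECE = %.4f\n",
              x$n_pixels, length(x$counts), x$ece))
  print(reliability_diagram_data(x), row.names = FALSE)
  invisible(x)
}

#' Per-bin table for a reliability diagram
#'
#' @param report a [bin_pixels()] result.
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`,
#'   `midpoint`, `count`, `accuracy`, `confidence`, `empty`.
#' @export
reliability_diagram_data <- function(report) {
  M <- length(report$counts)
  e <- report$bin_edges
  data.frame(bin = seq_len(M),
             lower = e[-(M + 1L)],
             upper = e[-1L],
             midpoint = (e[-(M + 1L)] + e[-1L]) / 2,
             count = report$counts,
             accuracy = report$accuracy,
             confidence = report$confidence,
             empty = report$counts == 0L)
}

# Face-connected boundary of a binary mask; pixels at the array border
# count as boundary (outside the image is background).
mask_boundary <- function(mask) {
  d <- length(dim(mask))
  interior_bg <- array(FALSE, dim(mask))
  has_bg_neigh <- array(FALSE, dim(mask))
  for (ax in seq_len(d)) {
    s <- dim(mask)[ax]
    fwd <- aslice(mask, ax, c(seq_len(s - 1L) + 1L, s))  # neighbour below (border padded w/ self)
    bwd <- aslice(mask, ax, c(1L, seq_len(s - 1L)))
    has_bg_neigh <- has_bg_neigh | (fwd == 0) | (bwd == 0)
    edge <- array(FALSE, dim(mask))
    edge <- aslice_set(edge, ax, c(1L, s), TRUE)
    has_bg_neigh <- has_bg_neigh | edge
  }
  which(mask == 1 & has_bg_neigh, arr.ind = TRUE)
}

surface_distances <- function(a_idx, b_idx, spacing) {
  A <- sweep(a_idx, 2L, spacing, `*`)
  B <- sweep(b_idx, 2L, spacing, `*`)
  # min over B of distances from each row of A
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Segmentation accuracy and surface-distance metrics
#'
#' IoU and Dice from set overlap, plus symmetric Hausdorff distance and
#' average surface distance on face-connected surface voxels, scaled by the
#' voxel spacing. Two empty masks are defined as perfect agreement (IoU =
#' Dice = 1, distances 0); one empty mask yields infinite distances with a
#' warning.
#'
#' @param pred_mask,y binary masks of identical shape.
#' @param spacing physical voxel size per axis (default 1).
#' @param distances compute surface distances (default TRUE; set FALSE to
#'   skip the expensive part when only overlap is needed).
#' @return list with `iou`, `dice`, `hausdorff`, `asd`.
#' @export
segmentation_metrics <- function(pred_mask, y, spacing = NULL,
                                 distances = TRUE) {
  if (is.null(dim(pred_mask))) pred_mask <- as.array(pred_mask)
  if (is.null(dim(y))) y <- as.array(y)
  check_same_shape(pred_mask, y, "segmentation_metrics")
  a <- pred_mask != 0
  b <- y != 0
  inter <- sum(a & b)
  union <- sum(a | b)
  na <- sum(a)
  nb <- sum(b)
  if (union == 0L) {
    return(list(iou = 1, dice = 1, hausdorff = 0, asd = 0))
  }
  iou <- inter / union
  dice <- 2 * inter / (na + nb)
  if (!distances)
    return(list(iou = iou, dice = dice, hausdorff = NA_real_,
                asd = NA_real_))
  spacing <- spacing %||% rep(1, length(dim(y)))
  if (na == 0L || nb == 0L) {
    warning("one mask is empty: surface distances are infinite")
    return(list(iou = iou, dice = dice, hausdorff = Inf, asd = Inf))
  }
  sa <- mask_boundary(array(as.integer(a), dim(y)))
  sb <- mask_boundary(array(as.integer(b), dim(y)))
  dab <- surface_distances(sa, sb, spacing)
  dba <- surface_distances(sb, sa, spacing)
  list(iou = iou, dice = dice,
       hausdorff = max(max(dab), max(dba)),
       asd = mean(c(dab, dba)))
}

#' Paired IoU / ECE table and quadratic robustness trend
#'
#' `iou_ece_table()` evaluates a model on test pairs and returns one
#' (IoU, ECE) row per image. `iou_ece_trend()` fits the second-order
#' regression IoU = b0 + b1 ECE + b2 ECE^2; a flatter fitted slope means
#' segmentation accuracy degrades less as calibration worsens.
#'
#' @param network a trained `mismatch_net`.
#' @param pairs labelled test pairs.
#' @param bins calibration bins.
#' @return `iou_ece_table()`: data.frame `iou`, `ece`; `iou_ece_trend()`:
#'   list with `coefficients` (b0, b1, b2), `slope` (b1) and the `lm` fit.
#' @export
iou_ece_table <- function(network, pairs, bins = 5L) {
  ev <- evaluate_network(network, pairs, bins = bins)
  ev[, c("iou", "ece")]
}

#' @rdname iou_ece_table
#' @param table a data.frame with columns `iou` and `ece`.
#' @export
iou_ece_trend <- function(table) {
  fit <- stats::lm(iou ~ ece + I(ece^2), data = table)
  co <- stats::coef(fit)
  # with fewer points than coefficients or degenerate ECE spread the
  # quadratic term can be NA; treat it as zero curvature
  co[is.na(co)] <- 0
  list(coefficients = co, slope = unname(co[2L]), fit = fit)
}
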