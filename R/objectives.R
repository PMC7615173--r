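# Training objectives: soft Dice loss on the labelled stream, mean squared
# error consistency between the two decoders' normalised predictions on the
# unlabelled stream, and their alpha-weighted combination.

#' Loss configuration
#'
#' @param alpha non-negative weight of the consistency term (default 0.002,
#'   the reference streaming setting; the combined regime preset uses 1).
#' @param normalise_batch standardise each prediction over the batch before
#'   the consistency MSE (default TRUE). At batch size 1 this is per-image
#'   standardisation.
#' @param stop_gradient treat each decoder's partner as a constant target in
#'   the consistency term (symmetric stop-gradient, default TRUE). For the
#'   squared-error loss the symmetric form yields the same gradients as full
#'   backpropagation; the flag selects which computation path is used.
#' @param dice_smooth additive smoothing of the Dice ratio (default 1e-6).
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.002, normalise_batch = TRUE,
                        stop_gradient = TRUE, dice_smooth = 1e-6) {
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  if (dice_smooth <= 0) stop_invalid("dice_smooth must be > 0")
  structure(list(alpha = as.numeric(alpha),
                 normalise_batch = assert_flag(normalise_batch,
                                               "normalise_batch"),
                 stop_gradient = assert_flag(stop_gradient, "stop_gradient"),
                 dice_smooth = as.numeric(dice_smooth)),
            class = "loss_config")
}

check_same_shape <- function(a, b, what) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || !all(da == db))
    stop_shape(what, ": shapes differ (", paste(da, collapse = "x"), " vs ",
               paste(db, collapse = "x"), ")")
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p*y) + s) / (sum(p) + sum(y) + s)`; zero for a perfect
#' binary prediction, approaching one for disjoint prediction and truth.
#'
#' @param p probability map.
#' @param y binary mask of the same shape (a missing channel axis on `y` is
#'   tolerated when `p` has a single channel).
#' @param smooth smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(p, y, smooth = 1e-6) {
  y <- match_mask(p, y)
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  1 - num / den
}

# Gradient of dice_loss with respect to p.
dice_loss_grad <- function(p, y, smooth = 1e-6) {
  y <- match_mask(p, y)
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  g <- -(2 * y * den - num) / den^2
  dim(g) <- dim(p)
  g
}

match_mask <- function(p, y) {
  if (!is.null(dim(p)) && length(dim(p)) == length(dim(y) %||% 0) + 1L &&
      dim(p)[length(dim(p))] == 1L && length(y) == length(p)) {
    dim(y) <- dim(p)
  }
  check_same_shape(p, y, "dice")
  if (any(y != 0 & y != 1)) stop_invalid("mask must be binary")
  y
}

#' Standardise predictions over the batch
#'
#' Subtracts the mean and divides by the population standard deviation
#' computed over all pixels of the whole batch (per channel). A constant
#' batch returns all zeros (guarded denominator).
#'
#' @param p a probability map (array) or a list of maps forming a batch.
#' @return the standardised array or list of arrays.
#' @export
normalise_batchwise <- function(p) {
  islist <- is.list(p)
  maps <- if (islist) p else list(p)
  v <- unlist(maps, use.names = FALSE)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  out <- lapply(maps, function(m) {
    q <- if (sd_pop < 1e-12) m * 0 else (m - mu) / sd_pop
    dim(q) <- dim(m)
    q
  })
  if (islist) out else out[[1L]]
}

# Backprop of z = (p - mean(p)) / sd_pop(p) for a single map:
# given g = dL/dz, dL/dp = (g - mean(g) - z * mean(g * z)) / sd.
normalise_bwd <- function(p, g) {
  mu <- mean(p)
  sd_pop <- sqrt(mean((p - mu)^2))
  if (sd_pop < 1e-12) return(array(0, dim(p) %||% length(p)))
  z <- (p - mu) / sd_pop
  gx <- (g - mean(g) - z * mean(g * z)) / sd_pop
  dim(gx) <- dim(p)
  gx
}

#' Consistency loss between the paired decoder predictions
#'
#' Mean squared error over pixels between the two predictions, each
#' standardised over the batch when `cfg$normalise_batch` is on. Zero if and
#' only if the predictions agree after normalisation.
#'
#' @param p1,p2 probability maps of identical shape.
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
consistency_loss <- function(p1, p2, cfg = loss_config()) {
  check_same_shape(p1, p2, "consistency")
  if (cfg$normalise_batch) {
    q1 <- normalise_batchwise(p1)
    q2 <- normalise_batchwise(p2)
  } else {
    q1 <- p1
    q2 <- p2
  }
  mean((q1 - q2)^2)
}

# Gradients of consistency_loss with respect to p1 and p2. Each branch's
# partner is treated as a constant target (symmetric stop-gradient); for
# the squared error this equals the full-backprop gradient, so both
# cfg$stop_gradient settings run the same arithmetic here.
consistency_grads <- function(p1, p2, cfg = loss_config()) {
  check_same_shape(p1, p2, "consistency")
  n <- length(p1)
  if (cfg$normalise_batch) {
    q1 <- normalise_batchwise(p1)
    q2 <- normalise_batchwise(p2)
    diff <- q1 - q2
    g1 <- normalise_bwd(p1, 2 * diff / n)
    g2 <- normalise_bwd(p2, -2 * diff / n)
  } else {
    diff <- p1 - p2
    g1 <- 2 * diff / n
    g2 <- -2 * diff / n
    dim(g1) <- dim(p1)
    dim(g2) <- dim(p2)
  }
  list(g1 = g1, g2 = g2)
}

#' Total training loss for one step
#'
#' In the streaming regime a labelled step returns the mean Dice loss over
#' the decoder outputs and an unlabelled step returns `alpha` times the
#' consistency loss. In the combined regime one labelled and one unlabelled
#' prediction pair enter a single step and the two terms are summed.
#'
#' @param pred a `paired_prediction` for the (labelled) batch.
#' @param mask the binary mask for `pred`, or NULL on unlabelled steps.
#' @param cfg a [loss_config()].
#' @param regime `"streaming"` or `"combined"`.
#' @param pred_unlabelled in the combined regime, the `paired_prediction`
#'   of the unlabelled batch (defaults to `pred` if omitted).
#' @return list with `total`, the components `dice1`, `dice2`,
#'   `consistency`, and `grads` (`labelled` / `unlabelled` lists of `g1`,
#'   `g2` arrays, NULL where a term is absent).
#' @export
total_loss <- function(pred, mask = NULL, cfg = loss_config(),
                       regime = c("streaming", "combined"),
                       pred_unlabelled = NULL) {
  regime <- match.arg(regime)
  dual <- !is.null(pred$p2)
  out <- list(dice1 = NA_real_, dice2 = NA_real_, consistency = NA_real_,
              grads = list(labelled = NULL, unlabelled = NULL))

  dice_part <- function(pr, y) {
    d1 <- dice_loss(pr$p1, y, cfg$dice_smooth)
    g1 <- dice_loss_grad(pr$p1, y, cfg$dice_smooth)
    if (dual) {
      d2 <- dice_loss(pr$p2, y, cfg$dice_smooth)
      g2 <- dice_loss_grad(pr$p2, y, cfg$dice_smooth)
      list(value = (d1 + d2) / 2, d1 = d1, d2 = d2,
           g = list(g1 = g1 / 2, g2 = g2 / 2))
    } else {
      list(value = d1, d1 = d1, d2 = NA_real_, g = list(g1 = g1, g2 = NULL))
    }
  }
  cons_part <- function(pr) {
    cl <- consistency_loss(pr$p1, pr$p2, cfg)
    cg <- consistency_grads(pr$p1, pr$p2, cfg)
    list(value = cl,
         g = list(g1 = cfg$alpha * cg$g1, g2 = cfg$alpha * cg$g2))
  }

  if (regime == "streaming") {
    if (!is.null(mask)) {
      dp <- dice_part(pred, mask)
      out$dice1 <- dp$d1
      out$dice2 <- dp$d2
      out$total <- dp$value
      out$grads$labelled <- dp$g
    } else {
      if (!dual)
        stop_invalid("consistency step requires a dual-decoder prediction")
      cp <- cons_part(pred)
      out$consistency <- cp$value
      out$total <- cfg$alpha * cp$value
      out$grads$unlabelled <- cp$g
    }
  } else {
    if (is.null(mask))
      stop_invalid("combined regime requires a labelled batch with a mask")
    dp <- dice_part(pred, mask)
    out$dice1 <- dp$d1
    out$dice2 <- dp$d2
    out$grads$labelled <- dp$g
    pu <- pred_unlabelled %||% pred
    if (dual) {
      cp <- cons_part(pu)
      out$consistency <- cp$value
      out$grads$unlabelled <- cp$g
      out$total <- dp$value + cfg$alpha * cp$value
    } else {
      out$total <- dp$value
    }
  }
  out
}
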