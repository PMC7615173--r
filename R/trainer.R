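# Semi-supervised training loop.
#
# Streaming regime: labelled items are interleaved sparsely into the
# unlabelled stream (each labelled item visited exactly once per epoch) so
# the network does not repeatedly see the scarce labels; labelled steps
# take the Dice loss, unlabelled steps the weighted consistency loss.
# Combined regime: every step draws one labelled and one unlabelled item
# and minimises Dice + alpha * consistency jointly.

#' Training configuration
#'
#' @param regime `"streaming"` or `"combined"`.
#' @param lr learning rate; defaults to 2e-5 for streaming and 1e-2 for
#'   combined (the reference settings of the two regimes).
#' @param epochs number of passes (default 50).
#' @param avg_last_k checkpoints (one per epoch) averaged into the final
#'   model (default 10); must not exceed `epochs`.
#' @param seed integer seed controlling all shuffling.
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @param ensemble_prediction if TRUE the final model is kept as the list of
#'   last checkpoints and prediction averages their outputs instead of their
#'   weights (off by default: weight averaging).
#' @return a `train_config` list.
#' @export
train_config <- function(regime = c("streaming", "combined"), lr = NULL,
                         epochs = 50L, avg_last_k = 10L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         ensemble_prediction = FALSE) {
  regime <- match.arg(regime)
  lr <- lr %||% if (regime == "streaming") 2e-5 else 1e-2
  if (lr <= 0) stop_invalid("lr must be > 0")
  epochs <- assert_count(epochs, "epochs")
  avg_last_k <- assert_count(avg_last_k, "avg_last_k")
  if (avg_last_k > epochs)
    stop_invalid("avg_last_k (", avg_last_k, ") must be <= epochs (",
                 epochs, ")")
  structure(list(regime = regime, lr = lr, epochs = epochs,
                 avg_last_k = avg_last_k, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 ensemble_prediction = assert_flag(ensemble_prediction,
                                                   "ensemble_prediction")),
            class = "train_config")
}

#' Bundle labelled / unlabelled / validation / test data
#'
#' @param labelled list of `list(image, mask)` pairs (non-empty).
#' @param unlabelled list of images.
#' @param val,test held-out labelled pairs.
#' @return a `data_stream` list.
#' @export
data_stream <- function(labelled, unlabelled = list(), val = list(),
                        test = list()) {
  if (length(labelled) == 0L)
    stop_invalid("labelled set must be non-empty")
  structure(list(labelled = labelled, unlabelled = unlabelled, val = val,
                 test = test),
            class = "data_stream")
}

# Deterministic interleave: labelled item i is visited after unlabelled
# step floor((i - 0.5) * n_unl / n_lab), so labels arrive at rate
# n_lab / n_unl and each appears exactly once per pass.
streaming_schedule <- function(n_lab, n_unl, lab_ord, unl_ord) {
  if (n_unl == 0L)
    return(data.frame(type = "labelled", idx = lab_ord))
  after <- floor((seq_len(n_lab) - 0.5) * n_unl / n_lab)
  type <- character(0)
  idx <- integer(0)
  li <- 1L
  for (u in 0L:n_unl) {
    while (li <= n_lab && after[li] == u) {
      type <- c(type, "labelled")
      idx <- c(idx, lab_ord[li])
      li <- li + 1L
    }
    if (u < n_unl) {
      type <- c(type, "unlabelled")
      idx <- c(idx, unl_ord[u + 1L])
    }
  }
  data.frame(type = type, idx = idx)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  list(theta = theta - cfg$lr * mhat / (sqrt(vhat) + cfg$eps),
       state = state)
}

#' Train a MisMatch network
#'
#' Runs the semi-supervised loop with Adam at batch size 1, records every
#' loss component, snapshots the parameters after each epoch, and returns
#' the network with the last `avg_last_k` checkpoints averaged (weight
#' averaging; see `ensemble_prediction` in [train_config()]).
#'
#' Steps whose loss carries no gradient (for example unlabelled steps with
#' `alpha = 0`) skip the optimiser update, so a run with `alpha = 0`
#' reproduces the purely supervised trajectory exactly.
#'
#' @param network a [build_network()] result.
#' @param data a [data_stream()].
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param supervised_only iterate the same schedule but visit only the
#'   labelled steps (baseline trajectory; default FALSE).
#' @param verbose print a line per epoch.
#' @return list with `network` (checkpoint-averaged), `network_last` (final
#'   epoch weights), `history` (one row per executed step), `checkpoints`
#'   (flat parameter vectors of the last `avg_last_k` epochs) and `val_iou`.
#' @export
train <- function(network, data, cfg = train_config(),
                  loss_cfg = loss_config(), supervised_only = FALSE,
                  verbose = FALSE) {
  if (!inherits(data, "data_stream")) data <- do.call(data_stream, data)
  if (length(data$labelled) == 0L) stop_invalid("labelled set is empty")
  dual <- length(network$blocks$dec) > 1L
  theta <- flatten_params(network$params)
  opt <- adam_init(length(theta))
  n_lab <- length(data$labelled)
  n_unl <- length(data$unlabelled)
  hist <- list()
  ckpts <- list()
  step <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ords <- with_seed(cfg$seed + 1009L * epoch, {
      list(lab = sample.int(n_lab),
           unl = if (n_unl > 0L) sample.int(n_unl) else integer(0))
    })
    sched <- if (cfg$regime == "streaming") {
      streaming_schedule(n_lab, n_unl, ords$lab, ords$unl)
    } else {
      k <- max(n_lab, n_unl)
      data.frame(type = "combined",
                 idx = rep_len(ords$lab, k),
                 uidx = if (n_unl > 0L) rep_len(ords$unl, k) else NA_integer_)
    }
    if (supervised_only) sched <- sched[sched$type != "unlabelled", , drop = FALSE]

    for (r in seq_len(nrow(sched))) {
      network$params <- unflatten_params(theta, network$params)
      ty <- sched$type[r]
      if (ty == "labelled") {
        item <- data$labelled[[sched$idx[r]]]
        pred <- net_forward(network, item$image, with_tape = TRUE)
        ls <- total_loss(pred, item$mask, loss_cfg, regime = "streaming")
        gp <- net_backward(network, pred, ls$grads$labelled$g1,
                           ls$grads$labelled$g2)
        grad <- flatten_params(gp)
      } else if (ty == "unlabelled") {
        # a single-decoder network has no consistency pair: unlabelled
        # steps carry no loss and are skipped
        if (supervised_only || !dual) next
        img <- data$unlabelled[[sched$idx[r]]]
        pred <- net_forward(network, img, with_tape = TRUE)
        ls <- total_loss(pred, NULL, loss_cfg, regime = "streaming")
        gu <- ls$grads$unlabelled
        grad <- flatten_params(net_backward(network, pred, gu$g1, gu$g2))
      } else {
        item <- data$labelled[[sched$idx[r]]]
        pred <- net_forward(network, item$image, with_tape = TRUE)
        pu <- NULL
        if (dual && !supervised_only && n_unl > 0L) {
          img <- data$unlabelled[[sched$uidx[r]]]
          pu <- net_forward(network, img, with_tape = TRUE)
        }
        ls <- total_loss(pred, item$mask, loss_cfg, regime = "combined",
                         pred_unlabelled = pu)
        grad <- flatten_params(net_backward(network, pred,
                                            ls$grads$labelled$g1,
                                            ls$grads$labelled$g2))
        if (!is.null(pu) && !is.null(ls$grads$unlabelled)) {
          grad <- grad + flatten_params(
            net_backward(network, pu, ls$grads$unlabelled$g1,
                         ls$grads$unlabelled$g2))
        }
      }
      if (!is.finite(ls$total))
        stop("training aborted: non-finite loss at epoch ", epoch,
             " step ", step + 1L, " (", ty, " step)")
      step <- step + 1L
      hist[[step]] <- data.frame(step = step, epoch = epoch, type = ty,
                                 dice1 = ls$dice1, dice2 = ls$dice2,
                                 consistency = ls$consistency,
                                 total = ls$total)
      if (any(grad != 0)) {
        up <- adam_step(opt, theta, grad, cfg)
        theta <- up$theta
        opt <- up$state
      }
    }
    ckpts[[length(ckpts) + 1L]] <- theta
    if (length(ckpts) > cfg$avg_last_k) ckpts[[1L]] <- NULL
    if (verbose)
      message(sprintf("epoch %d/%d: mean total loss %.4f", epoch, cfg$epochs,
                      mean(vapply(hist[(step - nrow(sched) + 1L):step],
                                  function(h) h$total, numeric(1)))))
  }

  network$params <- unflatten_params(theta, network$params)
  network_last <- network
  avg <- network
  avg$params <- unflatten_params(Reduce(`+`, ckpts) / length(ckpts),
                                 network$params)
  result <- list(network = avg, network_last = network_last,
                 history = do.call(rbind, hist), checkpoints = ckpts,
                 val_iou = NA_real_)
  if (cfg$ensemble_prediction) {
    result$ensemble <- lapply(ckpts, unflatten_params,
                              skeleton = network$params)
  }
  if (length(data$val) > 0L) {
    ev <- evaluate_network(avg, data$val)
    result$val_iou <- mean(ev$iou)
  }
  result
}

#' Average a list of checkpoints
#'
#' Arithmetic mean of each parameter array across checkpoints; all
#' checkpoints must share one architecture.
#'
#' @param checkpoints list of parameter lists (as in `network$params`) or of
#'   flat parameter vectors.
#' @return the averaged parameters, in the structure of the first element.
#' @export
average_checkpoints <- function(checkpoints) {
  if (length(checkpoints) == 0L) stop_invalid("no checkpoints given")
  flats <- lapply(checkpoints, function(ck)
    if (is.list(ck)) flatten_params(ck) else as.numeric(ck))
  n <- unique(vapply(flats, length, integer(1)))
  if (length(n) != 1L)
    stop_invalid("checkpoints have mismatched parameter counts: ",
                 paste(vapply(flats, length, integer(1)), collapse = ", "))
  avg <- Reduce(`+`, flats) / length(flats)
  if (is.list(checkpoints[[1L]]))
    unflatten_params(avg, checkpoints[[1L]])
  else avg
}

#' Evaluate a network on labelled pairs
#'
#' Computes per-item IoU and Dice of the thresholded fused prediction plus
#' the expected calibration error of the probability map.
#'
#' @param network a trained `mismatch_net`.
#' @param pairs list of `list(image, mask)`.
#' @param threshold decision threshold (default 0.5).
#' @param bins calibration bins (default 5).
#' @return data.frame with columns `item`, `iou`, `dice`, `ece`.
#' @export
evaluate_network <- function(network, pairs, threshold = 0.5, bins = 5L) {
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- net_forward(network, pairs[[i]]$image)
    m <- predict_mask(pr$fused, threshold)
    y <- pairs[[i]]$mask
    sm <- segmentation_metrics(m, y, distances = FALSE)
    rep_ <- bin_pixels(pr$fused, y, M = bins)
    data.frame(item = i, iou = sm$iou, dice = sm$dice, ece = rep_$ece)
  })
  do.call(rbind, rows)
}
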