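# Dice loss, batch-wise normalisation, consistency MSE, and the combined
# objective.

test_that("dice loss matches hand computations and stays in [0,1]", {
  y <- array(0, c(4, 4)); y[1, 1:4] <- 1
  p_perfect <- array(y, c(4, 4, 1))
  expect_equal(dice_loss(p_perfect, y, smooth = 1e-12), 0, tolerance = 1e-9)
  # all-ones prediction vs empty truth tends to 1 as smooth -> 0
  expect_equal(dice_loss(array(1, c(4, 4, 1)), array(0, c(4, 4)),
                         smooth = 1e-12), 1, tolerance = 1e-9)
  # 4 true foreground pixels, prediction hits exactly 2: 1 - 4/6
  p <- array(0, c(4, 4, 1)); p[1, 1:2, 1] <- 1
  expect_equal(dice_loss(p, y, smooth = 1e-12), 1 - 4 / 6, tolerance = 1e-9)
  # random maps stay inside [0,1]
  set.seed(1)
  for (i in 1:20) {
    pr <- array(runif(16), c(4, 4, 1))
    yr <- array(rbinom(16, 1, 0.4), c(4, 4))
    d <- dice_loss(pr, yr)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(dice_loss(p, array(0, c(3, 3))), class = "mm_shape_error")
  expect_error(dice_loss(p, y * 2), class = "mm_invalid_argument")
})

test_that("dice gradient matches finite differences", {
  set.seed(2)
  p <- array(runif(36, 0.05, 0.95), c(6, 6, 1))
  y <- array(rbinom(36, 1, 0.5), c(6, 6))
  g <- dice_loss_grad_export(p, y)
  ng <- numeric_gradient(function(pp) dice_loss(array(pp, dim(p)), y), p)
  expect_equal(g, ng, tolerance = 1e-6)
})

test_that("batch-wise normalisation standardises with the population sd", {
  out <- normalise_batchwise(list(array(0.2, c(1, 1, 1)),
                                  array(0.8, c(1, 1, 1))))
  expect_equal(as.numeric(out[[1]]), -1)
  expect_equal(as.numeric(out[[2]]), 1)
  # constant batch: guarded to zeros
  expect_true(all(normalise_batchwise(array(0.5, c(4, 4, 1))) == 0))
  # any non-constant batch: mean 0, population variance 1
  set.seed(3)
  b <- list(array(runif(16), c(4, 4, 1)), array(runif(16), c(4, 4, 1)))
  q <- unlist(normalise_batchwise(b))
  expect_equal(mean(q), 0, tolerance = 1e-12)
  expect_equal(mean(q^2), 1, tolerance = 1e-12)
})

test_that("consistency loss follows the normalised MSE definition", {
  p <- array(runif(16), c(4, 4, 1))
  expect_equal(consistency_loss(p, p), 0, tolerance = 1e-12)
  cfg_raw <- loss_config(normalise_batch = FALSE)
  one <- array(1, c(4, 4, 1)); zero <- array(0, c(4, 4, 1))
  expect_equal(consistency_loss(one, zero, cfg_raw), 1)
  expect_equal(consistency_loss(array(0.8, c(4, 4, 1)),
                                array(0.6, c(4, 4, 1)), cfg_raw), 0.04,
               tolerance = 1e-12)
  # symmetry and non-negativity
  set.seed(4)
  a <- array(runif(16), c(4, 4, 1)); b <- array(runif(16), c(4, 4, 1))
  expect_equal(consistency_loss(a, b), consistency_loss(b, a))
  expect_gte(consistency_loss(a, b), 0)
  # zero iff equal after normalisation: affinely related maps collapse
  expect_equal(consistency_loss(a, 0.5 + 0.2 * a), 0, tolerance = 1e-12)
})

test_that("consistency gradients equal the stop-gradient manual expression", {
  set.seed(5)
  p1 <- array(runif(16, 0.1, 0.9), c(4, 4, 1))
  p2 <- array(runif(16, 0.1, 0.9), c(4, 4, 1))
  for (normalise in c(TRUE, FALSE)) {
    cfg <- loss_config(normalise_batch = normalise)
    g <- mismatch:::consistency_grads(p1, p2, cfg)
    # gradient w.r.t. branch 1 of mean((q1 - const)^2), const = q2 frozen
    q2 <- if (normalise) normalise_batchwise(p2) else p2
    f1 <- function(pp) {
      q1 <- if (normalise) normalise_batchwise(array(pp, dim(p1)))
            else array(pp, dim(p1))
      mean((q1 - q2)^2)
    }
    expect_equal(g$g1, numeric_gradient(f1, p1), tolerance = 1e-6)
    # and symmetrically for branch 2
    q1 <- if (normalise) normalise_batchwise(p1) else p1
    f2 <- function(pp) {
      q2b <- if (normalise) normalise_batchwise(array(pp, dim(p2)))
             else array(pp, dim(p2))
      mean((q1 - q2b)^2)
    }
    expect_equal(g$g2, numeric_gradient(f2, p2), tolerance = 1e-6)
  }
})

test_that("total loss combines components per regime", {
  set.seed(6)
  y <- array(rbinom(64, 1, 0.3), c(8, 8))
  mk <- function(p1, p2) structure(list(p1 = p1, p2 = p2,
                                        fused = (p1 + p2) / 2),
                                   class = "paired_prediction")
  p1 <- array(runif(64), c(8, 8, 1)); p2 <- array(runif(64), c(8, 8, 1))
  pred <- mk(p1, p2)
  cfg <- loss_config(alpha = 0.002)
  # streaming labelled: mean of the two per-decoder Dice losses
  ls <- total_loss(pred, y, cfg, regime = "streaming")
  expect_equal(ls$total, (dice_loss(p1, y) + dice_loss(p2, y)) / 2)
  # streaming unlabelled: alpha-weighted consistency
  lu <- total_loss(pred, NULL, cfg, regime = "streaming")
  expect_equal(lu$total, 0.002 * consistency_loss(p1, p2, cfg))
  # alpha = 0 makes the unlabelled step cost exactly zero
  l0 <- total_loss(pred, NULL, loss_config(alpha = 0), regime = "streaming")
  expect_identical(l0$total, 0)
  expect_true(all(unlist(l0$grads$unlabelled) == 0))
  # labelled step with both decoders perfect is zero
  yb <- array(y, c(8, 8, 1))
  lp <- total_loss(mk(yb, yb), y, loss_config(dice_smooth = 1e-12),
                   regime = "streaming")
  expect_equal(lp$total, 0, tolerance = 1e-9)
  # combined: Dice mean plus alpha times consistency of the unlabelled pair
  pu <- mk(array(runif(64), c(8, 8, 1)), array(runif(64), c(8, 8, 1)))
  lc <- total_loss(pred, y, cfg, regime = "combined", pred_unlabelled = pu)
  expect_equal(lc$total,
               (dice_loss(p1, y) + dice_loss(p2, y)) / 2 +
                 0.002 * consistency_loss(pu$p1, pu$p2, cfg))
  # the stated arithmetic: dice components 0.4 / 0.2, consistency 0.04
  expect_equal((0.4 + 0.2) / 2 + 0.002 * 0.04, 0.30008)
  # labelled regimes require masks
  expect_error(total_loss(pred, NULL, cfg, regime = "combined"),
               class = "mm_invalid_argument")
})
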