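# Block forward/backward contracts: shape preservation, gating arithmetic,
# determinism, and agreement between backpropagated and finite-difference
# gradients.

test_that("all block kinds preserve spatial shape for odd kernels and dilations", {
  x <- array(rnorm(12 * 10 * 2), c(12, 10, 2))
  for (kind in c("plain", "pasb", "nasb")) {
    for (K in c(1L, 3L, 5L)) {
      for (dil in c(1L, 2L, 5L)) {
        sp <- block_spec(2, 3, main_kernel = K, side_dilation = dil,
                         block_kind = kind, seed = 3)
        out <- block_forward(x, sp)
        expect_identical(dim(out), c(12L, 10L, 3L))
      }
    }
  }
  # 3D as well
  x3 <- array(rnorm(6^3 * 2), c(6, 6, 6, 2))
  sp <- block_spec(2, 4, block_kind = "nasb", seed = 1)
  expect_identical(dim(block_forward(x3, sp)), c(6L, 6L, 6L, 4L))
})

test_that("zero-weight blocks follow the gating arithmetic", {
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  for (kind in c("plain", "pasb", "nasb")) {
    sp <- block_spec(1, 1, block_kind = kind, norm_kind = "none", seed = 1)
    pars <- block_params(sp, 2)
    zero <- unflatten_zero(pars)
    out <- block_forward(x, sp, zero)
    # main branch is zero everywhere, so any gate yields zero output
    expect_true(all(out == 0))
  }
})

test_that("side-branch gate follows sigmoid arithmetic", {
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  sp <- block_spec(1, 1, block_kind = "pasb", norm_kind = "none", seed = 5)
  pars <- block_params(sp, 2)
  # zero side branch: gate = sigmoid(0) = 0.5 exactly
  p0 <- pars
  p0$side$W[] <- 0
  p0$side$b[] <- 0
  main <- block_forward(x, block_spec(1, 1, block_kind = "plain",
                                      norm_kind = "none", seed = 5),
                        list(main1 = pars$main1, main2 = pars$main2))
  out0 <- block_forward(x, sp, p0)
  expect_equal(out0, main * 0.5, tolerance = 1e-12)
  # large positive side bias saturates the gate: output ~= main
  pb <- p0
  pb$side$b[] <- 20
  expect_equal(block_forward(x, sp, pb), main, tolerance = 1e-7)
})

test_that("nasb side branch with zero conv weights reduces to sigmoid of the skips", {
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  sp <- block_spec(1, 1, block_kind = "nasb", norm_kind = "none", seed = 2)
  pars <- block_params(sp, 2)
  pz <- pars
  pz$side1$W[] <- 0; pz$side1$b[] <- 0
  pz$side2$W[] <- 0; pz$side2$b[] <- 0
  main <- block_forward(x, block_spec(1, 1, block_kind = "plain",
                                      norm_kind = "none", seed = 2),
                        list(main1 = pars$main1, main2 = pars$main2))
  out <- block_forward(x, sp, pz)
  # pure skips pass x through both residual stages: gate = sigmoid(x)
  expect_equal(out, main * plogis(x), tolerance = 1e-12)
  # and an all-zero input gives gate 0.5
  x0 <- array(0, c(8, 8, 1))
  main0 <- block_forward(x0, block_spec(1, 1, block_kind = "plain",
                                        norm_kind = "none", seed = 2),
                         list(main1 = pars$main1, main2 = pars$main2))
  expect_equal(block_forward(x0, sp, pz), main0 * 0.5, tolerance = 1e-12)
})

test_that("blocks are deterministic under a fixed seed", {
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  for (kind in c("plain", "pasb", "nasb")) {
    sp <- block_spec(2, 3, block_kind = kind, seed = 42)
    expect_identical(block_forward(x, sp), block_forward(x, sp))
  }
})

test_that("gate values lie in (0,1) so gated outputs never exceed the main branch", {
  x <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  for (kind in c("pasb", "nasb")) {
    sp <- block_spec(2, 2, block_kind = kind, norm_kind = "none", seed = 9)
    pars <- block_params(sp, 2)
    fw <- block_forward(x, sp, pars, with_tape = TRUE)
    expect_true(all(fw$tape$gate > 0 & fw$tape$gate < 1))
    main <- fw$tape$main$out
    expect_true(all(abs(fw$out) <= abs(main) + 1e-12))
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(7)
  x <- array(rnorm(7 * 7), c(7, 7, 1))
  gout <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  for (kind in c("plain", "pasb", "nasb")) {
    sp <- block_spec(1, 2, block_kind = kind, seed = 11)
    pars <- block_params(sp, 2)
    fw <- block_forward(x, sp, pars, with_tape = TRUE)
    bw <- block_backward(fw$tape, sp, pars, gout)
    fx <- function(xx) sum(block_forward(array(xx, dim(x)), sp, pars) * gout)
    ng <- numeric_gradient(fx, x)
    expect_equal(bw$gx, ng, tolerance = 1e-4)
    # one convolution weight tensor per branch
    fw1 <- function(WW) {
      p2 <- pars
      p2$main1$W <- array(WW, dim(pars$main1$W))
      sum(block_forward(x, sp, p2) * gout)
    }
    expect_equal(bw$gp$main1$W, numeric_gradient(fw1, pars$main1$W),
                 tolerance = 1e-4)
  }
})

test_that("channel mismatches raise shape errors", {
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  sp <- block_spec(2, 2, block_kind = "plain", seed = 1)
  expect_error(block_forward(x, sp), class = "mm_shape_error")
})

test_that("block stacks probe with the expected footprint growth", {
  st <- block_stack("plain", width = 4L, n_blocks = 2L, seed = 2)
  prof <- measure_empirical_erf(st, c(13L, 13L), probe_threshold = 1e-9)
  nz <- which(prof$gradient_map > 0, arr.ind = TRUE)
  # two blocks of two 3x3 convs each: footprint extent 4*(3-1)+1 = 9
  expect_lte(diff(range(nz[, 1])) + 1L, 9L)
})
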