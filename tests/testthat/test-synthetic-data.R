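# Phantom generation, selection rules, cropping, and benchmark assembly.

test_that("phantom generation is reproducible and respects its spec", {
  spec <- phantom_spec(seed = 21)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(dim(a$image), c(64L, 64L, 1L))
  expect_identical(sort(unique(as.integer(a$mask))), c(0L, 1L))
  # case-wise normalisation: zero mean, unit variance
  expect_equal(mean(a$image), 0, tolerance = 1e-9)
  expect_equal(sd(as.numeric(a$image)), 1, tolerance = 1e-9)
})

test_that("noise-free phantoms have two intensity levels and empty specs none", {
  spec <- phantom_spec(noise_sigma = 0, intensity_contrast = 1, seed = 3)
  ph <- generate_phantom(spec)
  expect_lte(length(unique(as.numeric(ph$image))), 2L)
  empty <- generate_phantom(phantom_spec(n_objects = 0, seed = 3))
  expect_equal(sum(empty$mask), 0)
  # blobs rasterise too, in 2D and 3D
  blob <- generate_phantom(phantom_spec(object_kind = "blob",
                                        radius_range = c(4, 8), seed = 4))
  expect_gt(sum(blob$mask), 0)
  b3 <- generate_phantom(phantom_spec(dims = 3, shape = c(24L, 24L, 24L),
                                      n_objects = 2, object_kind = "blob",
                                      radius_range = c(3, 5), seed = 5))
  expect_identical(dim(b3$mask), c(24L, 24L, 24L))
  expect_gt(sum(b3$mask), 0)
})

test_that("objects that cannot fit raise an invalid-argument error", {
  expect_error(generate_phantom(phantom_spec(shape = c(8L, 8L),
                                             radius_range = c(6, 8))),
               class = "mm_invalid_argument")
})

test_that("the foreground filter is strictly greater-than", {
  mk <- function(n) {
    m <- array(0L, c(32, 32)); m[seq_len(n)] <- 1L
    list(image = array(0, c(32, 32, 1)), mask = m)
  }
  kept <- filter_slices(list(mk(100), mk(101), mk(0)), foreground_min = 100)
  expect_length(kept, 1L)
  expect_equal(sum(kept[[1]]$mask), 101)
})

test_that("corner crops anchor at the four corners with half-open windows", {
  img <- matrix(seq_len(282 * 426), 282, 426)
  msk <- array(rbinom(282 * 426, 1, 0.1), c(282, 426))
  crops <- corner_crops(img, msk, crop = 176)
  expect_length(crops, 4L)
  anchors <- do.call(rbind, lapply(crops, `[[`, "anchor"))
  expect_equal(anchors, rbind(c(0, 0), c(0, 250), c(106, 0), c(106, 250)))
  for (cr in crops) {
    expect_identical(dim(cr$image)[1:2], c(176L, 176L))
    expect_identical(dim(cr$mask), c(176L, 176L))
  }
  # content check: top-left crop is the identity window
  expect_equal(crops[[1]]$image[, , 1], img[1:176, 1:176])
  expect_equal(crops[[4]]$image[, , 1], img[107:282, 251:426])
  # an image exactly crop-sized yields four identical patches
  small <- matrix(rnorm(176 * 176), 176, 176)
  cs <- corner_crops(small, crop = 176)
  expect_equal(cs[[1]]$image, cs[[4]]$image)
  expect_error(corner_crops(small, crop = 200),
               class = "mm_invalid_argument")
})

test_that("random sub-volumes are seeded, in-range and identity at full size", {
  vol <- array(rnorm(20 * 20 * 155), c(20, 20, 155))
  msk <- array(rbinom(20 * 20 * 155, 1, 0.1), c(20, 20, 155))
  a <- random_subvolume(vol, msk, size = c(16L, 16L, 96L), seed = 4)
  b <- random_subvolume(vol, msk, size = c(16L, 16L, 96L), seed = 4)
  expect_identical(a$offset, b$offset)
  expect_identical(a$image, b$image)
  # valid depth offsets span 155 - 96 + 1 = 60 positions (0-based 0..59)
  offs <- vapply(1:100, function(s)
    random_subvolume(vol, size = c(16L, 16L, 96L), seed = s)$offset[3],
    integer(1))
  expect_true(all(offs >= 0L & offs <= 59L))
  expect_gt(length(unique(offs)), 30L)
  # identity crop at full size
  full <- random_subvolume(vol, size = c(20L, 20L, 155L), seed = 9)
  expect_identical(full$offset, c(0L, 0L, 0L))
  expect_equal(full$image, vol)
  expect_error(random_subvolume(vol, size = c(32L, 16L, 96L)),
               class = "mm_invalid_argument")
})

test_that("benchmarks have the requested disjoint splits and reproduce from the seed", {
  split <- split_spec(n_labelled = 4, n_unlabelled = 6, n_val = 2,
                      n_test = 3, foreground_min = 50)
  phantom <- phantom_spec(shape = c(48L, 48L), seed = 31)
  b1 <- make_benchmark(split, phantom)
  b2 <- make_benchmark(split, phantom)
  expect_length(b1$labelled, 4L)
  expect_length(b1$unlabelled, 6L)
  expect_length(b1$val, 2L)
  expect_length(b1$test, 3L)
  expect_identical(b1$labelled[[1]]$image, b2$labelled[[1]]$image)
  expect_identical(b1$unlabelled[[3]], b2$unlabelled[[3]])
  # every kept image passes its own filter
  man <- attr(b1, "manifest")
  expect_true(all(man$foreground > 50))
  # splits use disjoint generator seeds
  expect_false(any(duplicated(man$seed)))
  # labelled images come from one jittered case: pairwise mask overlap of
  # labelled items exceeds overlap between labelled and independent test
  ov <- function(m1, m2) sum(m1 & m2) / sum(m1 | m2)
  lab_ov <- mean(c(ov(b1$labelled[[1]]$mask, b1$labelled[[2]]$mask),
                   ov(b1$labelled[[2]]$mask, b1$labelled[[3]]$mask)))
  cross_ov <- mean(c(ov(b1$labelled[[1]]$mask, b1$test[[1]]$mask),
                     ov(b1$labelled[[2]]$mask, b1$test[[2]]$mask)))
  expect_gt(lab_ov, cross_ov)
})

test_that("impossible split requests fail with a pool-exhaustion error", {
  split <- split_spec(n_labelled = 2, n_unlabelled = 0, n_val = 0,
                      n_test = 0, foreground_min = 5000)
  expect_error(make_benchmark(split, phantom_spec(shape = c(32L, 32L),
                                                  seed = 1)),
               "exceed the generated pool", class = "mm_invalid_argument")
})

test_that("benchmark difficulty rises with the noise level", {
  # the supervised baseline, trained identically, loses test IoU as
  # noise_sigma grows over a 3-point grid (averaged over 2 seeds)
  iou_at <- function(noise) {
    mean(vapply(1:2, function(s) {
      bench <- make_benchmark(
        split_spec(4, 0, n_val = 0, n_test = 4, foreground_min = 20),
        phantom_spec(shape = c(32L, 32L), n_objects = 2,
                     radius_range = c(1.5, 2.5), noise_sigma = noise,
                     seed = 40 + s))
      net <- build_network(network_spec(dims = 2, base_width = 2, depth = 2,
                                        decoder_variant = "unet",
                                        seed = 50 + s))
      fit <- train(net, bench,
                   train_config(lr = 1e-2, epochs = 6, avg_last_k = 2,
                                seed = 60 + s))
      mean(evaluate_network(fit$network, bench$test)$iou)
    }, numeric(1)))
  }
  ious <- vapply(c(0.1, 0.8, 2.5), iou_at, numeric(1))
  expect_true(all(diff(ious) < 0))
})
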