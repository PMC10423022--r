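test_that("crop and stitch are exact inverses on non-overlapping grids", {
  set.seed(5)
  img <- prob_map(matrix(runif(64 * 64), 64, 64))
  grid <- patch_grid(c(64L, 64L), 2L, 2L)
  expect_identical(grid$n, 4L)
  patches <- crop_patches(img, grid)
  expect_true(all(vapply(patches, function(p) all(dim(p) == c(32L, 32L)),
                         logical(1))))
  expect_equal(unclass(stitch(patches, grid)), unclass(img))
  # 1 x 1 grid is the identity
  g1 <- patch_grid(c(64L, 64L), 1L, 1L)
  expect_equal(unclass(stitch(crop_patches(img, g1), g1)), unclass(img))
  # constant image -> constant patches
  cimg <- prob_map(matrix(0.3, 64, 64))
  expect_true(all(vapply(crop_patches(cimg, grid),
                         function(p) all(unclass(p) == 0.3), logical(1))))
  expect_error(crop_patches(img, patch_grid(c(32L, 32L), 2L, 2L)), "match")
  expect_error(stitch(patches[1:2], grid), "expected 4")
})

test_that("overlapping patches are averaged where they meet", {
  grid <- patch_grid(c(8L, 8L), nrows = 2L, ncols = 1L, patch = c(6L, 8L))
  expect_identical(grid$n, 2L)
  p0 <- prob_map(matrix(0, 6, 8))
  p1 <- prob_map(matrix(1, 6, 8))
  out <- stitch(list(p0, p1), grid)
  expect_true(all(unclass(out)[3:6, ] == 0.5))   # overlap rows
  expect_true(all(unclass(out)[1:2, ] == 0))
  expect_true(all(unclass(out)[7:8, ] == 1))
})

test_that("point sets stitch by anchor translation", {
  grid <- patch_grid(c(8L, 16L), 1L, 2L)
  ps <- list(point_set(cbind(2, 3), c(8, 8)), point_set(cbind(5, 1), c(8, 8)))
  out <- stitch_pointsets(ps, grid)
  expect_setequal(paste(out[, 1], out[, 2]), c("2 3", "5 9"))
})

test_that("fusion is the symmetric pixel-wise mean", {
  a <- prob_map(matrix(0.2, 8, 8))
  b <- prob_map(matrix(0.8, 8, 8))
  expect_true(all(unclass(fuse(a, b)) == 0.5))
  expect_equal(unclass(fuse(a, b)), unclass(fuse(b, a)))
  expect_equal(unclass(fuse(a, a)), unclass(a))
  expect_error(fuse(a, prob_map(matrix(0.5, 4, 4))), "shape")
})

test_that("network gradients match finite differences end to end", {
  set.seed(3)
  img <- prob_map(matrix(runif(64), 8, 8))
  lab <- rand_mask(8L, 8L, 0.3)
  w <- class_weighting(lab)
  params <- phdseg:::with_seed(1, branch_model(4L, 6L))
  f <- phdseg:::net_forward(params, img)
  g <- phdseg:::net_backward(params, f, phdseg:::pixel_loss_grad(f$prob, lab, w))
  lossfun <- function(p) {
    pixel_loss(phdseg:::net_forward(p, img)$prob, lab, w)
  }
  eps <- 1e-6
  for (nm in c("w1", "w2", "w3", "w4", "b2", "b4")) {
    i <- sample(length(params[[nm]]), 1L)
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    expect_equal(g[[nm]][i], (lossfun(p2) - lossfun(params)) / eps,
                 tolerance = 1e-3, info = nm)
  }
})

test_that("short training runs are seeded-deterministic and shrink the loss", {
  ph <- generate_phantom(21, c(32L, 32L), 2L, 3L)
  pairs <- list(list(image = render_intensity(ph$gt, seed = 22),
                     label = ph$gt))
  cfg <- psnet_config(epochs = 3L, steps_per_epoch = 4L, seed = 7L,
                      ch1 = 4L, ch2 = 8L)
  f1 <- train_psnet(pairs, cfg)
  f2 <- train_psnet(pairs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_lt(f1$history$total[3], f1$history$total[1])
  # warm-up epochs carry zero structural weights
  expect_true(all(f1$history$lambda1 == 0))
  pred <- predict_psnet(f1, pairs[[1]]$image)
  expect_s3_class(pred$prob, "prob_map")
  expect_s3_class(pred$mask, "binary_mask")
  # prediction is deterministic
  pred2 <- predict_psnet(f1, pairs[[1]]$image)
  expect_identical(unclass(pred$prob), unclass(pred2$prob))
  # fusing two identical maps binarizes like either branch
  expect_identical(unclass(binarize(fuse(pred$prob_global, pred$prob_global))),
                   unclass(binarize(pred$prob_global)))
})

test_that("single-branch ablations train and predict", {
  ph <- generate_phantom(23, c(32L, 32L), 2L, 3L)
  pairs <- list(list(image = render_intensity(ph$gt, seed = 24),
                     label = ph$gt))
  for (arch in c("global", "local")) {
    fit <- train_psnet(pairs, psnet_config(epochs = 2L, steps_per_epoch = 2L,
                                           seed = 3L, ch1 = 4L, ch2 = 8L,
                                           arch = arch))
    expect_identical(nrow(fit$history), 2L)
    pred <- predict_psnet(fit, pairs[[1]]$image)
    expect_identical(dim(pred$prob), c(32L, 32L))
    if (arch == "global") expect_null(pred$prob_local)
    if (arch == "local") expect_null(pred$prob_global)
  }
})
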