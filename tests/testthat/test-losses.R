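test_that("pixel loss vanishes on perfect one-hot predictions", {
  g <- binary_mask(matrix(c(0L, 1L), 4, 4))
  s <- prob_map(matrix(as.numeric(unclass(g)), 4, 4))
  expect_equal(pixel_loss(s, g), 0, tolerance = 1e-12)
  w <- class_weighting(g)
  expect_equal(pixel_loss(s, g, w), 0, tolerance = 1e-12)
})

test_that("uniform predictions give the closed-form cross-entropy", {
  g <- binary_mask(matrix(c(0L, 1L), 4, 4))
  s <- prob_map(matrix(0.5, 4, 4))
  # Dice term = 0.5 at s = 0.5; CE term = log 2 with unit weights
  expect_equal(pixel_loss(s, g), 0.5 + log(2), tolerance = 1e-12)
})

test_that("pixel loss matches independent term-by-term summation", {
  # 4 x 4 fixture: s = 0.8 on the correct class, class frequencies 1/4, 3/4
  g <- matrix(0L, 4, 4); g[1, ] <- 1L
  sfg <- ifelse(g == 1L, 0.8, 0.2)
  w <- class_weighting(binary_mask(g))
  expect_equal(unname(w$w), c(1 / 0.75, 1 / 0.25))
  # independent summation with explicit loops
  ce_ref <- 0; inter <- 0
  for (r in 1:4) for (c in 1:4) {
    for (cls in 1:2) {
      gic <- if (cls == 2L) g[r, c] else 1L - g[r, c]
      sic <- if (cls == 2L) sfg[r, c] else 1 - sfg[r, c]
      wc <- unname(w$w[cls])
      ce_ref <- ce_ref - wc * gic * log(sic) / 16
      inter <- inter + gic * sic
    }
  }
  dice_ref <- 1 - 2 * inter / 32
  expect_equal(pixel_loss(prob_map(sfg), binary_mask(g), w),
               dice_ref + ce_ref, tolerance = 1e-12)
})

test_that("pixel loss gradient matches finite differences", {
  set.seed(2)
  g <- rand_mask(6L, 6L, 0.3)
  sfg <- matrix(runif(36, 0.1, 0.9), 6, 6)
  w <- class_weighting(g)
  an <- phdseg:::pixel_loss_grad(prob_map(sfg), g, w)
  eps <- 1e-7
  for (idx in sample(36, 5)) {
    s2 <- sfg; s2[idx] <- s2[idx] + eps
    num <- (pixel_loss(prob_map(s2), g, w) - pixel_loss(prob_map(sfg), g, w)) / eps
    expect_equal(an[idx], num, tolerance = 1e-4)
  }
})

test_that("the skeleton-distance loss composes global and patch terms", {
  # single-point skeletons at known distances; tau = 0
  sp <- tolerance_spec(0)
  gt_g <- binary_mask(`[<-`(matrix(0L, 8, 8), cbind(2, 2), 1L))
  pr_g <- prob_with_points(c(8L, 8L), cbind(2, 3))        # PHD = 2
  gt_l <- list(binary_mask(`[<-`(matrix(0L, 8, 8), cbind(4, 2), 1L)),
               binary_mask(`[<-`(matrix(0L, 8, 8), cbind(4, 2), 1L)))
  pr_l <- list(prob_with_points(c(8L, 8L), cbind(4, 4)),  # PHD = 4
               prob_with_points(c(8L, 8L), cbind(4, 5)))  # PHD = 6
  expect_equal(phd_loss(pr_g, pr_l, gt_g, gt_l, sp), 2 + (4 + 6) / 2)
  # exact predictions give zero
  exact <- prob_with_points(c(8L, 8L), cbind(2, 2))
  expect_equal(phd_loss(exact, list(), gt_g, list(), sp), 0)
  # empty prediction skeleton falls back to the frame diagonal
  blank <- prob_map(matrix(0, 8, 8))
  expect_equal(phd_loss(blank, list(), gt_g, list(), sp), sqrt(128))
  # patches with an empty side are excluded from the local mean
  pr_l2 <- list(prob_with_points(c(8L, 8L), cbind(4, 4)), blank)
  expect_equal(phd_loss(pr_g, pr_l2, gt_g, gt_l, sp), 2 + 4)
})

test_that("the similarity loss compares stitched local structure to global", {
  sp <- tolerance_spec(0)
  grid <- patch_grid(c(8L, 16L), 1L, 2L)
  glob <- prob_with_points(c(8L, 16L), rbind(c(3, 3), c(3, 12)))
  locals <- crop_patches(glob, grid)
  expect_equal(similarity_loss(glob, locals, grid, sp), 0)
  # global shifted by 5 columns relative to the stitched locals
  glob2 <- prob_with_points(c(8L, 16L), cbind(3, 8))
  locals2 <- list(prob_with_points(c(8L, 8L), cbind(3, 3)),
                  prob_map(matrix(0, 8, 8)))
  expect_equal(similarity_loss(glob2, locals2, grid, sp), 10)
})

test_that("the coarse-to-fine schedule warms up and ramps linearly", {
  sch <- loss_schedule(k = 5L, ramp = c(0.1, 0.05), caps = c(1, 1))
  expect_equal(schedule_weights(0, sch), c(lambda1 = 0, lambda2 = 0))
  expect_equal(schedule_weights(4, sch), c(lambda1 = 0, lambda2 = 0))
  expect_equal(schedule_weights(7, sch), c(lambda1 = 0.3, lambda2 = 0.15))
  # caps bind; weights are non-decreasing
  vals <- t(vapply(0:40, schedule_weights, numeric(2), sched = sch))
  expect_true(all(diff(vals[, 1]) >= 0))
  expect_true(all(diff(vals[, 2]) >= 0))
  expect_equal(max(vals[, 1]), 1)
})

test_that("the total loss is the weighted sum of its components", {
  expect_equal(total_loss(c(1, 2, 3), c(0, 0)), 1)
  expect_equal(total_loss(c(1, 2, 3), c(1, 1)), 6)
  expect_equal(total_loss(c(0.5, 4, 6), c(0.25, 0.5)), 4.5)
  # linearity in each component
  set.seed(9)
  for (i in 1:5) {
    comp <- runif(3); wt <- runif(2); a <- runif(1)
    expect_equal(total_loss(comp * a, wt * 0 + wt),
                 comp[1] * a + wt[1] * comp[2] * a + wt[2] * comp[3] * a)
  }
})
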