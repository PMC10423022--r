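test_that("confusion metrics follow the confusion-matrix definitions", {
  # 4 x 4 fixture built to have TP = 2, FP = 1, FN = 1
  gt <- matrix(0L, 4, 4); gt[1, 1:3] <- 1L            # |gt| = 3
  pr <- matrix(0L, 4, 4); pr[1, 1:2] <- 1L; pr[3, 3] <- 1L
  rep <- confusion_metrics(binary_mask(pr), binary_mask(gt))
  expect_equal(unname(rep["f1"]), 2 / 3)
  expect_equal(unname(rep["iou"]), 1 / 2)
  expect_equal(unname(rep["rvd"]), 0)                  # |pred| == |gt|
  expect_equal(unname(rep["tpvf"]), 2 / 3)
  expect_equal(unname(rep["tnvf"]), 12 / 13)
  # disjoint masks
  d1 <- matrix(0L, 4, 4); d1[1, 1] <- 1L
  d2 <- matrix(0L, 4, 4); d2[4, 4] <- 1L
  rd <- confusion_metrics(binary_mask(d2), binary_mask(d1))
  expect_equal(unname(rd["f1"]), 0)
  expect_equal(unname(rd["iou"]), 0)
  expect_error(confusion_metrics(binary_mask(d1), binary_mask(matrix(0L, 4, 4))),
               "no foreground")
  expect_error(confusion_metrics(binary_mask(d1), binary_mask(matrix(0L, 2, 2))),
               "shape")
})

test_that("distance metrics match an exhaustive reference on random masks", {
  p1 <- matrix(0L, 6, 6); p1[1, 1] <- 1L
  p2 <- matrix(0L, 6, 6); p2[4, 5] <- 1L
  rep <- distance_metrics(binary_mask(p2), binary_mask(p1))
  expect_equal(unname(rep["hd"]), 5)
  expect_equal(unname(rep["assd"]), 5)
  # brute-force oracle over all pairs
  set.seed(13)
  for (i in 1:10) {
    a <- rand_mask(15L, 15L, 0.2)
    b <- rand_mask(15L, 15L, 0.2)
    A <- which(unclass(a) == 1L, arr.ind = TRUE)
    B <- which(unclass(b) == 1L, arr.ind = TRUE)
    dmat <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
    hd_ref <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
    assd_ref <- mean(c(apply(dmat, 1, min), apply(dmat, 2, min)))
    rep <- distance_metrics(a, b)
    expect_equal(unname(rep["hd"]), hd_ref, tolerance = 1e-12)
    expect_equal(unname(rep["assd"]), assd_ref, tolerance = 1e-12)
    # symmetry
    expect_equal(unclass(distance_metrics(b, a)), unclass(rep),
                 ignore_attr = TRUE)
  }
})

test_that("Betti numbers and Betti error capture components and holes", {
  ring <- ring_mask(12L)
  expect_equal(betti_numbers(ring), c(b0 = 1L, b1 = 1L))
  broken <- unclass(ring)
  broken[2, 5] <- 0L                                  # open the loop
  expect_equal(betti_numbers(binary_mask(broken)), c(b0 = 1L, b1 = 0L))
  expect_equal(betti_error(binary_mask(broken), ring), 1)
  # two disjoint rings vs one ring: |db0| + |db1| = 2
  two <- matrix(0L, 26, 12)
  two[2:9, c(2, 9)] <- 1L; two[c(2, 9), 2:9] <- 1L
  two[14:21, c(2, 9)] <- 1L; two[c(14, 21), 2:9] <- 1L
  one <- matrix(0L, 26, 12)
  one[2:9, c(2, 9)] <- 1L; one[c(2, 9), 2:9] <- 1L
  expect_equal(betti_error(binary_mask(one), binary_mask(two)), 2)
  expect_equal(betti_error(ring, ring), 0)
  expect_equal(betti_numbers(binary_mask(matrix(0L, 4, 4))), c(b0 = 0L, b1 = 0L))
})

test_that("clDice rewards centerline containment", {
  ring <- dilate_mask(ring_mask(20L, 5L, 5L, 10L), 1)   # thickness-3 ring
  fat <- dilate_mask(ring, 2)
  expect_equal(cldice(ring, ring), 1)
  expect_equal(cldice(fat, ring), 1)                    # skeletons mutually inside
  d1 <- matrix(0L, 8, 8); d1[2, 2:4] <- 1L
  d2 <- matrix(0L, 8, 8); d2[7, 5:7] <- 1L
  expect_equal(cldice(binary_mask(d1), binary_mask(d2)), 0)
  expect_error(cldice(binary_mask(matrix(0L, 8, 8)), binary_mask(d1)),
               "non-empty")
})

test_that("region metrics score cell partitions on the contingency table", {
  ph <- generate_phantom(5, c(48L, 48L), 4L, 3L)
  perfect <- region_metrics(ph$gt, ph$gt)
  expect_equal(unname(perfect["vrand"]), 1)
  expect_equal(unname(perfect["vinfo"]), 1)
  expect_equal(unname(perfect["ari"]), 1)
  expect_equal(unname(perfect["voi"]), 0)
  # gt splits the frame into 2 cells, pred merges them:
  # VOI = entropy of the gt two-cell partition
  gt <- matrix(0L, 9, 8); gt[4, ] <- 1L               # cells of 24 and 40 px
  pr <- matrix(0L, 9, 8)
  rm <- region_metrics(binary_mask(pr), binary_mask(gt))
  p <- c(24, 40) / 64
  expect_equal(unname(rm["voi"]), -sum(p * log(p)))
  expect_equal(unname(rm["ari"]), 0)                   # single pred segment
  # independent ARI cross-check on a random pair
  skip_if_not_installed("mclust")
  a <- generate_phantom(8, c(48L, 48L), 4L, 3L)
  b <- perturb(a, "delete_edges", fraction = 0.4, seed = 2)
  la <- phdseg:::region_labels(a$gt)
  lb <- phdseg:::region_labels(b)
  keep <- la > 0L
  expect_equal(unname(region_metrics(b, a$gt)["ari"]),
               mclust::adjustedRandIndex(lb[keep], la[keep]),
               tolerance = 1e-12)
})

test_that("every metric attains its perfect value on pred == gt", {
  ph <- generate_phantom(2, c(48L, 48L), 4L, 3L)
  rep <- all_metrics(ph$gt, ph$gt)
  dirs <- attr(rep, "direction")
  for (m in names(rep)) {
    if (dirs[[m]] == "lower") {
      expect_equal(unname(rep[m]), 0, info = m)
    } else {
      expect_equal(unname(rep[m]), 1, info = m)
    }
  }
})

test_that("skeletonized variants reduce thickness sensitivity", {
  ph <- generate_phantom(9, c(48L, 48L), 3L, 1L)
  skel <- ph$gt
  fat <- dilate_mask(skel, 2)
  f1_plain <- evaluate_masks(fat, skel, "f1")
  f1_sk <- with_skeletonization("f1", fat, skel)
  expect_gt(f1_sk, f1_plain)
  # already-thin masks: -SK variant changes nothing
  expect_equal(with_skeletonization("f1", skel, skel),
               evaluate_masks(skel, skel, "f1"))
  expect_equal(with_skeletonization("iou", fat, fat), 1)
})
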