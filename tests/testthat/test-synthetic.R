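test_that("phantom generation is deterministic and topologically correct", {
  a <- generate_phantom(17, c(64L, 64L), 4L, 3L)
  b <- generate_phantom(17, c(64L, 64L), 4L, 3L)
  expect_identical(unclass(a$gt), unclass(b$gt))
  expect_identical(unclass(a$skeleton), unclass(b$skeleton))
  # n_cells = 2 on 64 x 64 -> exactly 2 background cells
  two <- generate_phantom(3, c(64L, 64L), 2L, 3L)
  expect_identical(count_components(invert_mask(two$gt), 4L), 2L)
  # cell count holds across seeds
  for (s in 1:10) {
    ph <- generate_phantom(s, c(64L, 64L), 4L, 3L)
    expect_identical(count_components(invert_mask(ph$gt), 4L), 4L)
  }
  expect_error(generate_phantom(1, c(8L, 8L), 8L), "too small")
  expect_error(generate_phantom(1, c(64L, 64L), 1L), "n_cells")
})

test_that("thick phantoms skeletonize back to the thin reference", {
  for (s in c(2, 5)) {
    thick <- generate_phantom(s, c(64L, 64L), 3L, 3L)
    thin <- generate_phantom(s, c(64L, 64L), 3L, 1L)
    P <- phdseg:::ps_points(mask_to_pointset(thick$gt, skeletonize = TRUE))
    S <- phdseg:::ps_points(thin$skeleton)
    expect_lte(max(phdseg:::nn_dists(P, S)), 1.5)
  }
})

test_that("perturbations implement their error models", {
  ph <- generate_phantom(8, c(64L, 64L), 4L, 3L)
  # null shift is the identity
  expect_identical(unclass(perturb(ph, "shift", dr = 0L, dc = 0L)),
                   unclass(ph$gt))
  # full deletion empties the mask
  expect_identical(sum(perturb(ph, "delete_edges", fraction = 1)), 0L)
  # dilation keeps the skeleton's component count
  d2 <- perturb(ph, "dilate", r = 2)
  expect_identical(count_components(zhang_suen_thin(d2), 8L),
                   count_components(zhang_suen_thin(ph$gt), 8L))
  # spurs only add foreground
  sp <- perturb(ph, "add_spurs", k = 4L, seed = 5)
  expect_true(all(unclass(sp) >= unclass(ph$gt)))
  expect_gt(sum(sp), sum(ph$gt))
  # deterministic per seed
  expect_identical(unclass(perturb(ph, "delete_edges", fraction = 0.3, seed = 9)),
                   unclass(perturb(ph, "delete_edges", fraction = 0.3, seed = 9)))
  expect_error(perturb(ph, "shift", dr = 100L, dc = 0L), "out of frame")
})

test_that("dilation is topology-neutral; branch deletion often is not", {
  # deleting a branch that ends at the frame border prunes an open curve and
  # is invisible to Betti numbers — a genuine blind spot of pure topology
  # metrics — so deletion is only required to register on most mosaics
  hits <- 0L
  for (s in 1:20) {
    ph <- generate_phantom(s, c(64L, 64L), 4L, 3L)
    expect_equal(betti_error(perturb(ph, "dilate", r = 2), ph$gt), 0)
    del <- perturb(ph, "delete_edges", fraction = 0.4, seed = s)
    b <- betti_error(del, ph$gt)
    expect_gte(b, 0)
    if (b > 0) hits <- hits + 1L
  }
  expect_gte(hits, 10L)
})

test_that("trial simulation matches the subject model", {
  # perfect reliability: unanimous votes for the tolerated prediction
  tr1 <- make_trials(5, seed = 2, frame = c(48L, 48L), n_cells = 3L,
                     reliability = 1)
  expect_true(all(vapply(tr1, `[[`, numeric(1), "votes_a") == 20))
  expect_true(all(vapply(tr1, `[[`, numeric(1), "votes_b") == 0))
  # the empirical vote share estimates the configured reliability
  tr <- make_trials(50, seed = 4, frame = c(48L, 48L), n_cells = 3L,
                    reliability = 0.9)
  va <- sum(vapply(tr, `[[`, numeric(1), "votes_a"))
  vb <- sum(vapply(tr, `[[`, numeric(1), "votes_b"))
  expect_lt(abs(va / (va + vb) - 0.9), 0.03)
  # determinism
  tr2 <- make_trials(5, seed = 2, frame = c(48L, 48L), n_cells = 3L,
                     reliability = 1)
  expect_identical(unclass(tr1[[3]]$pred_b), unclass(tr2[[3]]$pred_b))
})

test_that("trials serialize to rasters plus manifest and read back", {
  dir <- tempfile("trials")
  tr <- make_trials(3, seed = 6, frame = c(48L, 48L), n_cells = 3L)
  manifest <- write_trials(tr, dir)
  expect_true(file.exists(manifest))
  back <- read_trials(manifest)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(unclass(back[[i]]$gt), unclass(tr[[i]]$gt))
    expect_identical(unclass(back[[i]]$pred_a), unclass(tr[[i]]$pred_a))
    expect_identical(back[[i]]$votes_a, tr[[i]]$votes_a)
  }
  # scores agree between the in-memory and round-tripped trials
  expect_equal(consistency_score(back, "f1"), consistency_score(tr, "f1"))
  unlink(dir, recursive = TRUE)
})
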