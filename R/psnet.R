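# The two-branch (global-local) segmentation pipeline: patch cropping and
# stitching, probability fusion, and the coarse-to-fine training loop that
# combines the pixel, skeleton-distance and similarity losses.

#' Patch grid over a frame
#'
#' A regular grid of same-size patches covering the frame. The default is
#' non-overlapping tiling (stitch is then the exact inverse of crop);
#' overlapping grids are supported and stitching averages overlapped pixels.
#'
#' @param frame integer (H, W).
#' @param nrows,ncols grid dimensions; default 2 x 2 (N = 4 patches).
#' @param patch integer (h, w) patch size; default `frame / c(nrows, ncols)`
#'   (must divide the frame exactly when left at the default).
#' @return A `patch_grid`: list with `frame`, `patch`, `anchors` (N x 2
#'   matrix of top-left (row, col) corners) and `n`.
#' @export
patch_grid <- function(frame, nrows = 2L, ncols = 2L, patch = NULL) {
  frame <- as.integer(frame)
  if (is.null(patch)) {
    if (frame[1L] %% nrows != 0L || frame[2L] %% ncols != 0L) {
      stop("frame is not divisible by the grid; give an explicit patch size")
    }
    patch <- c(frame[1L] %/% nrows, frame[2L] %/% ncols)
    anchors <- as.matrix(expand.grid(
      row = seq(1L, frame[1L], by = patch[1L]),
      col = seq(1L, frame[2L], by = patch[2L])))
  } else {
    patch <- as.integer(patch)
    rs <- unique(c(seq(1L, frame[1L] - patch[1L] + 1L,
                       by = max(1L, ceiling((frame[1L] - patch[1L]) / max(1L, nrows - 1L)))),
                   frame[1L] - patch[1L] + 1L))
    cs <- unique(c(seq(1L, frame[2L] - patch[2L] + 1L,
                       by = max(1L, ceiling((frame[2L] - patch[2L]) / max(1L, ncols - 1L)))),
                   frame[2L] - patch[2L] + 1L))
    anchors <- as.matrix(expand.grid(row = rs, col = cs))
  }
  structure(list(frame = frame, patch = as.integer(patch),
                 anchors = anchors, n = nrow(anchors)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid: %d patches of %d x %d over %d x %d>\n",
              x$n, x$patch[1], x$patch[2], x$frame[1], x$frame[2]))
  invisible(x)
}

#' Crop an image into grid patches
#'
#' @param image matrix-like ([prob_map()] or [binary_mask()]).
#' @param grid a [patch_grid()] whose frame matches the image shape.
#' @return List of N patches, same class as the input, in grid order.
#' @export
crop_patches <- function(image, grid) {
  if (!identical(as.integer(dim(image)), grid$frame)) {
    stop("grid frame does not match image shape")
  }
  wrap <- if (is_binary_mask(image)) binary_mask else
          if (is_prob_map(image)) prob_map else identity
  m <- as_matrix_plain(image)
  lapply(seq_len(grid$n), function(i) {
    r <- grid$anchors[i, 1L]; c0 <- grid$anchors[i, 2L]
    wrap(m[r:(r + grid$patch[1L] - 1L), c0:(c0 + grid$patch[2L] - 1L)])
  })
}

#' Stitch patches back into a frame
#'
#' Exact inverse of [crop_patches()] on non-overlapping grids; overlapping
#' pixels are averaged.
#'
#' @param patches list of N matrices conforming to the grid.
#' @param grid a [patch_grid()].
#' @return A [prob_map()] (or plain matrix if inputs are not maps).
#' @export
stitch <- function(patches, grid) {
  if (length(patches) != grid$n) stop("expected ", grid$n, " patches")
  acc <- matrix(0, grid$frame[1L], grid$frame[2L])
  cnt <- matrix(0, grid$frame[1L], grid$frame[2L])
  for (i in seq_len(grid$n)) {
    r <- grid$anchors[i, 1L]; c0 <- grid$anchors[i, 2L]
    ri <- r:(r + grid$patch[1L] - 1L); ci <- c0:(c0 + grid$patch[2L] - 1L)
    acc[ri, ci] <- acc[ri, ci] + as_matrix_plain(patches[[i]])
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) stop("grid does not cover the frame")
  prob_map(pmin(pmax(acc / cnt, 0), 1))
}

#' Stitch per-patch point sets into frame coordinates
#'
#' Translates each local point set by its patch anchor and unions the
#' results — the point-set counterpart of [stitch()].
#'
#' @param pointsets list of N [point_set()]s in patch coordinates.
#' @param grid a [patch_grid()].
#' @return A [point_set()] in frame coordinates.
#' @export
stitch_pointsets <- function(pointsets, grid) {
  if (length(pointsets) != grid$n) stop("expected ", grid$n, " point sets")
  pts <- lapply(seq_len(grid$n), function(i) {
    p <- as_points_matrix(pointsets[[i]], "pointsets")
    if (nrow(p) == 0L) return(p)
    cbind(p[, 1L] + grid$anchors[i, 1L] - 1L,
          p[, 2L] + grid$anchors[i, 2L] - 1L)
  })
  point_set(do.call(rbind, pts), shape = grid$frame)
}

#' Fuse global and local probability maps
#'
#' Pixel-wise mean of the two maps (average pooling over the two branches).
#'
#' @param global_prob,stitched_local_prob same-shape [prob_map()]s.
#' @return A [prob_map()].
#' @export
fuse <- function(global_prob, stitched_local_prob) {
  if (!identical(dim(global_prob), dim(stitched_local_prob))) {
    stop("probability maps must share the same shape")
  }
  prob_map((as_matrix_plain(global_prob) +
            as_matrix_plain(stitched_local_prob)) / 2)
}

#' Training configuration
#'
#' @param epochs training epochs; default 20.
#' @param steps_per_epoch optimizer steps per epoch per pair; default 8.
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling initialization (the whole run is
#'   deterministic given it).
#' @param grid_nrows,grid_ncols local-branch patch grid; default 2 x 2.
#' @param tau_loss tolerance for the training losses; default 2 (the
#'   tolerance at which structural guidance helps segmentation most —
#'   deliberately smaller than the evaluation default of 3).
#' @param threshold binarization threshold for skeleton extraction.
#' @param schedule a [loss_schedule()]; set `caps = c(0, 0)` for a
#'   pixel-only ablation.
#' @param arch `"both"` (global + local, default), `"global"`, or
#'   `"local"` — the architecture ablation switch.
#' @param ch1,ch2 network widths (see [branch_model()]).
#' @param pixel_branch_agg `"mean"` (default) or `"sum"` over the two
#'   branches' pixel losses.
#' @return A `psnet_config` list.
#' @export
psnet_config <- function(epochs = 20L, steps_per_epoch = 8L, lr = 0.01,
                         seed = 1L, grid_nrows = 2L, grid_ncols = 2L,
                         tau_loss = 2, threshold = 0.5,
                         schedule = loss_schedule(),
                         arch = c("both", "global", "local"),
                         ch1 = 8L, ch2 = 16L,
                         pixel_branch_agg = c("mean", "sum")) {
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch), lr = lr,
                 seed = as.integer(seed), grid_nrows = as.integer(grid_nrows),
                 grid_ncols = as.integer(grid_ncols), tau_loss = tau_loss,
                 threshold = threshold, schedule = schedule,
                 arch = match.arg(arch), ch1 = as.integer(ch1),
                 ch2 = as.integer(ch2),
                 pixel_branch_agg = match.arg(pixel_branch_agg)),
            class = "psnet_config")
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# one optimizer step on one (image, label) pair; returns grads and losses
psnet_step <- function(params, img, label, grid, w, lambdas, cfg) {
  spec <- tolerance_spec(tau = cfg$tau_loss)
  use_g <- cfg$arch %in% c("both", "global")
  use_l <- cfg$arch %in% c("both", "local")
  n_branch <- use_g + use_l
  agg <- if (cfg$pixel_branch_agg == "mean") 1 / n_branch else 1

  grads <- NULL
  lpix <- 0; lphd <- 0; lsim <- 0
  fwd_g <- NULL; fwd_l <- NULL
  label_patches <- if (use_l) crop_patches(label, grid) else NULL

  if (use_g) {
    fwd_g <- net_forward(params, img)
    lpix_g <- pixel_loss(fwd_g$prob, label, w)
    dpix_g <- pixel_loss_grad(fwd_g$prob, label, w) * agg
    lpix <- lpix + lpix_g * agg
  }
  if (use_l) {
    img_patches <- crop_patches(img, grid)
    fwd_l <- lapply(img_patches, function(p) net_forward(params, p))
    lpix_l <- vapply(seq_len(grid$n), function(i) {
      pixel_loss(fwd_l[[i]]$prob, label_patches[[i]], w)
    }, numeric(1))
    dpix_l <- lapply(seq_len(grid$n), function(i) {
      pixel_loss_grad(fwd_l[[i]]$prob, label_patches[[i]], w) * agg / grid$n
    })
    lpix <- lpix + mean(lpix_l) * agg
  }

  dglobal <- if (use_g) dpix_g else NULL
  dlocal <- if (use_l) dpix_l else NULL

  need_skel <- (lambdas[1L] > 0 || lambdas[2L] > 0)
  if (need_skel) {
    Xg <- if (use_g) soft_skeleton(fwd_g$prob, cfg$threshold)$points else NULL
    Xl <- if (use_l) {
      lapply(fwd_l, function(f) soft_skeleton(f$prob, cfg$threshold)$points)
    } else NULL

    if (lambdas[1L] > 0) {
      Yg <- mask_to_pointset(label, skeletonize = TRUE)
      if (use_g) {
        lphd <- lphd + phd_or_fallback(Xg, Yg, spec, dim(label))
        dglobal <- dglobal +
          lambdas[1L] * phd_loss_grad(Xg, Yg, spec, dim(label))
      }
      if (use_l) {
        Yl <- lapply(label_patches, mask_to_pointset, skeletonize = TRUE)
        valid <- which(vapply(seq_len(grid$n), function(i) {
          nrow(Xl[[i]]) > 0L && nrow(Yl[[i]]) > 0L
        }, logical(1)))
        if (length(valid) > 0L) {
          vals <- vapply(valid, function(i) {
            phd_distance(Xl[[i]], Yl[[i]], spec)
          }, numeric(1))
          lphd <- lphd + mean(vals)
          for (i in valid) {
            dlocal[[i]] <- dlocal[[i]] + (lambdas[1L] / length(valid)) *
              phd_loss_grad(Xl[[i]], Yl[[i]], spec, grid$patch)
          }
        }
      }
    }
    if (lambdas[2L] > 0 && use_g && use_l) {
      Xhat <- stitch_pointsets(Xl, grid)
      lsim <- phd_or_fallback(Xg, Xhat, spec, dim(label))
      if (nrow(Xg) > 0L && nrow(Xhat) > 0L) {
        dglobal <- dglobal +
          lambdas[2L] * phd_loss_grad(Xg, Xhat, spec, dim(label))
        dsim_frame <- phd_loss_grad(Xhat, Xg, spec, dim(label))
        for (i in seq_len(grid$n)) {
          r <- grid$anchors[i, 1L]; c0 <- grid$anchors[i, 2L]
          dlocal[[i]] <- dlocal[[i]] + lambdas[2L] *
            dsim_frame[r:(r + grid$patch[1L] - 1L),
                       c0:(c0 + grid$patch[2L] - 1L)]
        }
      }
    }
  }

  if (use_g) grads <- sum_grads(grads, net_backward(params, fwd_g, dglobal))
  if (use_l) {
    for (i in seq_len(grid$n)) {
      grads <- sum_grads(grads, net_backward(params, fwd_l[[i]], dlocal[[i]]))
    }
  }
  list(grads = grads,
       losses = c(pixel = lpix, phd = lphd, sim = lsim,
                  total = total_loss(c(lpix, lphd, lsim), lambdas)))
}

#' Train the two-branch segmentation model
#'
#' Coarse-to-fine training on (image, label) pairs: both branches share one
#' parameter set; every epoch the structural-loss weights come from the
#' schedule (pixel-only warm-up, then a linear ramp), each pair gets
#' `steps_per_epoch` full-batch Adam steps, and per-epoch mean loss
#' components are recorded. The run is deterministic given `config$seed`.
#'
#' @param pairs list of `list(image = prob_map, label = binary_mask)`.
#' @param config a [psnet_config()].
#' @return A `psnet_fit`: list with `params` ([branch_model()]), `grid`,
#'   `config`, `weights` (the class weighting used) and `history`
#'   (data.frame epoch / lambda1 / lambda2 / pixel / phd / sim / total).
#' @export
train_psnet <- function(pairs, config = psnet_config()) {
  stopifnot(length(pairs) >= 1L)
  frame <- dim(pairs[[1L]]$image)
  grid <- patch_grid(frame, config$grid_nrows, config$grid_ncols)
  w <- class_weighting(lapply(pairs, `[[`, "label"))
  params <- with_seed(config$seed, branch_model(config$ch1, config$ch2))
  opt <- adam_init(params)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    lambdas <- schedule_weights(epoch, config$schedule)
    comp <- c(pixel = 0, phd = 0, sim = 0, total = 0)
    nsteps <- 0L
    for (step in seq_len(config$steps_per_epoch)) {
      for (pair in pairs) {
        st <- psnet_step(params, pair$image, pair$label, grid, w, lambdas,
                         config)
        if (!all(is.finite(st$losses))) {
          stop("non-finite loss at epoch ", epoch)
        }
        upd <- adam_step(params, st$grads, opt, lr = config$lr)
        params <- upd$params
        opt <- upd$state
        comp <- comp + st$losses
        nsteps <- nsteps + 1L
      }
    }
    hist[[epoch + 1L]] <- data.frame(
      epoch = epoch, lambda1 = lambdas[[1L]], lambda2 = lambdas[[2L]],
      t(comp / nsteps))
  }
  structure(list(params = params, grid = grid, config = config, weights = w,
                 history = do.call(rbind, hist)),
            class = "psnet_fit")
}

#' @export
print.psnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<psnet_fit: %d epochs, final total loss %.4f>\n",
              nrow(h), h$total[nrow(h)]))
  invisible(x)
}

#' Predict with a trained two-branch model
#'
#' Runs the global branch on the full image and the local branch on grid
#' patches, stitches the local probabilities, fuses the two maps by
#' pixel-wise averaging, and binarizes at 0.5. With a single-branch
#' architecture the corresponding branch's map is used alone.
#'
#' @param fit a [train_psnet()] result.
#' @param image a [prob_map()] intensity image.
#' @param grid optional [patch_grid()]; defaults to the training grid.
#' @return List with `prob` (fused [prob_map()]), `mask`
#'   ([binary_mask()]), and the per-branch maps `prob_global`,
#'   `prob_local`.
#' @export
predict_psnet <- function(fit, image, grid = NULL) {
  stopifnot(inherits(fit, "psnet_fit"))
  if (is.null(grid)) grid <- fit$grid
  arch <- fit$config$arch
  pg <- pl <- NULL
  if (arch %in% c("both", "global")) {
    pg <- net_forward(fit$params, image)$prob
  }
  if (arch %in% c("both", "local")) {
    patches <- crop_patches(image, grid)
    probs <- lapply(patches, function(p) net_forward(fit$params, p)$prob)
    pl <- stitch(probs, grid)
  }
  fused <- if (!is.null(pg) && !is.null(pl)) fuse(pg, pl)
           else if (!is.null(pg)) pg else pl
  list(prob = fused, mask = binarize(fused, 0.5),
       prob_global = pg, prob_local = pl)
}
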