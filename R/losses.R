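# Training losses: weighted cross-entropy + soft Dice pixel loss, the
# skeleton-distance (PHD) loss on global and local branches, the global-local
# similarity loss, and the coarse-to-fine weight schedule.

#' Per-class weights from training masks
#'
#' The class weight is the reciprocal of the class frequency over the
#' supplied masks (two classes: background, membrane), so the rare membrane
#' class is up-weighted in the cross-entropy term.
#'
#' @param masks a [binary_mask()] or list of them (the training labels).
#' @return A `class_weighting`: list with `w` = c(background, membrane).
#' @export
class_weighting <- function(masks) {
  if (is_binary_mask(masks)) masks <- list(masks)
  fg <- sum(vapply(masks, function(m) sum(m), numeric(1)))
  tot <- sum(vapply(masks, function(m) length(m), numeric(1)))
  freq <- c(bg = (tot - fg) / tot, fg = fg / tot)
  if (any(freq == 0)) stop("both classes must occur in the training masks")
  structure(list(w = 1 / freq), class = "class_weighting")
}

# stack a membrane prob map into the (background, membrane) pair
as_class_probs <- function(s) {
  if (is_prob_map(s)) {
    sm <- as_matrix_plain(s)
    return(list(bg = 1 - sm, fg = sm))
  }
  stopifnot(is.list(s), length(s) == 2L)
  list(bg = as_matrix_plain(s[[1L]]), fg = as_matrix_plain(s[[2L]]))
}

#' Pixel-wise loss: soft Dice plus weighted cross-entropy
#'
#' The Dice term is the generalized soft Dice over both classes,
#' `1 - 2 * sum(g * s) / (sum(g) + sum(s))` with sums over pixels and
#' classes; the cross-entropy term is
#' `-(1/M) * sum w_c g_ic log s_ic` with the per-class weights of
#' [class_weighting()]. Zero for a perfect one-hot prediction; the log is
#' clamped at machine epsilon.
#'
#' @param s predicted class probabilities: a membrane [prob_map()] (the
#'   background channel is its complement) or a list of two maps
#'   (background, membrane) summing to 1 per pixel.
#' @param g ground-truth [binary_mask()] (1 = membrane).
#' @param w a [class_weighting()]; default equal weights.
#' @return Non-negative scalar.
#' @export
pixel_loss <- function(s, g, w = NULL) {
  stopifnot(is_binary_mask(g))
  sc <- as_class_probs(s)
  if (!identical(dim(sc$fg), dim(g))) stop("prediction/label shape mismatch")
  gm <- as_matrix_plain(g)
  gc <- list(bg = 1 - gm, fg = gm)
  wts <- if (is.null(w)) c(bg = 1, fg = 1) else w$w
  m <- length(gm)
  inter <- sum(gc$bg * sc$bg) + sum(gc$fg * sc$fg)
  denom <- 2 * m  # sum(g) + sum(s); both sum to M over the two classes
  dice <- 1 - 2 * inter / denom
  eps <- .Machine$double.eps
  ce <- -(sum(wts[["bg"]] * gc$bg * log(pmax(sc$bg, eps))) +
          sum(wts[["fg"]] * gc$fg * log(pmax(sc$fg, eps)))) / m
  dice + ce
}

# gradient of pixel_loss w.r.t. the membrane probability map (chain rule
# through s_bg = 1 - s_fg folded in); used by the training loop
pixel_loss_grad <- function(s, g, w = NULL) {
  sc <- as_class_probs(s)
  gm <- as_matrix_plain(g)
  wts <- if (is.null(w)) c(bg = 1, fg = 1) else w$w
  m <- length(gm)
  eps <- .Machine$double.eps
  # dice: d/ds_fg [1 - (sum(g*s))/M] with s_bg = 1 - s_fg
  ddice <- -(gm - (1 - gm)) / m
  dce <- (-wts[["fg"]] * gm / pmax(sc$fg, eps) +
          wts[["bg"]] * (1 - gm) / pmax(sc$bg, eps)) / m
  ddice + dce
}

default_fallback <- function(shape) sqrt(sum(as.numeric(shape)^2))

# PHD between two skeleton point sets with the documented empty-set policy:
# both empty -> 0; one empty -> the frame diagonal as a large finite penalty
phd_or_fallback <- function(X, Y, spec, shape) {
  nx <- nrow(X); ny <- nrow(Y)
  if (nx == 0L && ny == 0L) return(0)
  if (nx == 0L || ny == 0L) return(default_fallback(shape))
  phd_distance(X, Y, spec)
}

#' Skeleton-distance (PHD) training loss
#'
#' Sum of the global term — PHD between the skeleton of the binarized
#' global prediction and the skeleton of the global ground truth — and a
#' local term averaging the same quantity over patches (patches where
#' either skeleton is empty are excluded from the mean). If the global
#' prediction skeleton is empty while the ground truth is not, the frame
#' diagonal is returned as a large finite penalty so training never crashes
#' at initialization.
#'
#' @param pred_global membrane [prob_map()] for the full frame.
#' @param pred_locals list of membrane [prob_map()]s, one per patch (may be
#'   empty for a global-only model).
#' @param gt_global full-frame ground-truth [binary_mask()].
#' @param gt_locals list of per-patch ground-truth [binary_mask()]s aligned
#'   with `pred_locals`.
#' @param spec a [tolerance_spec()]; the training default is `tau = 2`.
#' @param threshold binarization threshold for the predictions.
#' @return Non-negative scalar.
#' @export
phd_loss <- function(pred_global, pred_locals, gt_global, gt_locals,
                     spec = tolerance_spec(tau = 2), threshold = 0.5) {
  Xg <- soft_skeleton(pred_global, threshold)$points
  Yg <- mask_to_pointset(gt_global, skeletonize = TRUE)
  total <- phd_or_fallback(Xg, Yg, spec, dim(gt_global))
  if (length(pred_locals) > 0L) {
    vals <- numeric(0)
    for (i in seq_along(pred_locals)) {
      Xl <- soft_skeleton(pred_locals[[i]], threshold)$points
      Yl <- mask_to_pointset(gt_locals[[i]], skeletonize = TRUE)
      if (nrow(Xl) > 0L && nrow(Yl) > 0L) {
        vals <- c(vals, phd_distance(Xl, Yl, spec))
      }
    }
    if (length(vals) > 0L) total <- total + mean(vals)
  }
  total
}

#' Global-local similarity loss
#'
#' Stitches the per-patch prediction skeleton point sets into global
#' coordinates (translating each by its patch anchor) and returns the PHD
#' between the global prediction skeleton and the stitched local skeleton,
#' encouraging the two branches to agree on membrane structure.
#'
#' @inheritParams phd_loss
#' @param grid a [patch_grid()] mapping patches into the frame.
#' @return Non-negative scalar.
#' @export
similarity_loss <- function(pred_global, pred_locals, grid,
                            spec = tolerance_spec(tau = 2), threshold = 0.5) {
  Xg <- soft_skeleton(pred_global, threshold)$points
  Xl <- stitch_pointsets(lapply(pred_locals, function(p) {
    soft_skeleton(p, threshold)$points
  }), grid)
  phd_or_fallback(Xg, Xl, spec, dim(pred_global))
}

# straight-through subgradient of a PHD term w.r.t. the membrane probability
# map: surviving prediction-skeleton pixels with positive tolerance distance
# are pushed down, unmatched ground-truth skeleton pixels are pushed up
phd_loss_grad <- function(X, Y, spec, shape) {
  grad <- matrix(0, shape[1L], shape[2L])
  nx <- nrow(X); ny <- nrow(Y)
  if (nx == 0L || ny == 0L) return(grad)
  Xm <- as_points_matrix(X, "X"); Ym <- as_points_matrix(Y, "Y")
  psi_x <- psi_apply(nn_dists(Xm, Ym), spec)
  psi_y <- psi_apply(nn_dists(Ym, Xm), spec)
  grad[Xm] <- grad[Xm] + psi_x / nx
  grad[Ym] <- grad[Ym] - psi_y / ny
  grad
}

#' Coarse-to-fine loss schedule
#'
#' Pixel-only warm-up for the first `k` epochs (both structural weights 0),
#' then a linear ramp `min(cap, ramp * (epoch - k + 1))` per weight. The
#' default warm-up of 5 epochs is the setting at which adding the
#' structural losses helps most.
#'
#' @param k warm-up epochs (weights are 0 for `epoch < k`).
#' @param ramp length-2 per-epoch increments for (lambda1, lambda2).
#' @param caps length-2 maximal (lambda1, lambda2).
#' @return A `loss_schedule`.
#' @export
loss_schedule <- function(k = 5L, ramp = c(0.1, 0.1), caps = c(1, 1)) {
  stopifnot(k >= 0, length(ramp) == 2L, length(caps) == 2L,
            all(ramp >= 0), all(caps >= 0))
  structure(list(k = as.integer(k), ramp = ramp, caps = caps),
            class = "loss_schedule")
}

#' Structural-loss weights at a given epoch
#'
#' @param epoch integer >= 0 (0-based).
#' @param sched a [loss_schedule()].
#' @return Numeric `c(lambda1, lambda2)`, non-decreasing in epoch.
#' @export
schedule_weights <- function(epoch, sched = loss_schedule()) {
  stopifnot(epoch >= 0)
  if (epoch < sched$k) return(c(lambda1 = 0, lambda2 = 0))
  lam <- pmin(sched$caps, sched$ramp * (epoch - sched$k + 1))
  c(lambda1 = lam[1L], lambda2 = lam[2L])
}

#' Combine the three loss components
#'
#' `L = Lpixel + lambda1 * Lphd + lambda2 * Lsim`.
#'
#' @param components numeric (Lpixel, Lphd, Lsim).
#' @param weights numeric (lambda1, lambda2).
#' @return Scalar total loss.
#' @export
total_loss <- function(components, weights) {
  stopifnot(length(components) == 3L, all(is.finite(components)),
            length(weights) == 2L)
  components[1L] + weights[1L] * components[2L] + weights[2L] * components[3L]
}
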