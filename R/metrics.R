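#' Pixel-confusion metrics
#'
#' F1 (Dice), precision, recall, IoU (Jaccard), true-positive and
#' true-negative volume fractions, and the signed relative volume
#' difference, all computed from the pixel confusion matrix with foreground
#' = membrane.
#'
#' @param pred,gt same-shape [binary_mask()]s.
#' @param abs_rvd report |RVD| instead of the signed value? Default `FALSE`.
#' @return A `metric_report` (see [metric_report()]) with entries
#'   `f1`, `precision`, `recall`, `iou`, `tpvf`, `tnvf`, `rvd`.
#' @export
confusion_metrics <- function(pred, gt, abs_rvd = FALSE) {
  check_same_shape(pred, gt)
  p <- as_matrix_plain(pred); g <- as_matrix_plain(gt)
  tp <- sum(p == 1L & g == 1L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  tn <- sum(p == 0L & g == 0L)
  if (tp + fn == 0L) stop("ground truth has no foreground: recall/RVD undefined")
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rvd <- (tp + fp - (tp + fn)) / (tp + fn)
  if (abs_rvd) rvd <- abs(rvd)
  metric_report(
    c(f1 = f1, precision = prec, recall = tp / (tp + fn),
      iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
      tpvf = tp / (tp + fn),
      tnvf = if (tn + fp == 0) 1 else tn / (tn + fp),
      rvd = rvd))
}

#' Boundary-distance metrics
#'
#' Hausdorff distance (maximum of the two directed maximal nearest-neighbour
#' distances) and the average symmetric surface distance (all
#' nearest-neighbour distances pooled over both directions) between the
#' foreground pixel sets.
#'
#' @param pred,gt non-empty [binary_mask()]s.
#' @return A `metric_report` with entries `hd`, `assd`.
#' @export
distance_metrics <- function(pred, gt) {
  P <- ps_points(mask_to_pointset(pred, skeletonize = FALSE))
  G <- ps_points(mask_to_pointset(gt, skeletonize = FALSE))
  if (nrow(P) == 0L || nrow(G) == 0L) {
    stop("distance metrics need non-empty foreground on both sides")
  }
  dpg <- nn_dists(P, G)
  dgp <- nn_dists(G, P)
  metric_report(c(hd = max(max(dpg), max(dgp)),
                  assd = mean(c(dpg, dgp))))
}

#' Betti numbers of a mask
#'
#' b0 = number of 8-connected foreground components; b1 = number of holes,
#' i.e. 4-connected background components not touching the frame border
#' (the standard 8/4 foreground/background digital-topology pairing).
#'
#' @param mask a [binary_mask()].
#' @return Named integer vector `c(b0 = ..., b1 = ...)`.
#' @export
betti_numbers <- function(mask) {
  stopifnot(is_binary_mask(mask))
  if (sum(mask) == 0L) return(c(b0 = 0L, b1 = 0L))
  b0 <- count_components(mask, connectivity = 8L)
  bg_lab <- label_components(invert_mask(mask), connectivity = 4L)
  border <- unique(c(bg_lab[1L, ], bg_lab[nrow(bg_lab), ],
                     bg_lab[, 1L], bg_lab[, ncol(bg_lab)]))
  holes <- setdiff(setdiff(unique(as.vector(bg_lab)), 0L), border)
  c(b0 = b0, b1 = length(holes))
}

#' Betti error between prediction and ground truth
#'
#' Skeletonizes both masks, computes Betti numbers (components b0, holes
#' b1), and returns |delta b0| + |delta b1| — a pure topology criterion: a
#' single broken membrane loop costs 1 no matter how small the gap.
#'
#' @param pred,gt same-shape [binary_mask()]s.
#' @return Non-negative integer.
#' @export
betti_error <- function(pred, gt) {
  check_same_shape(pred, gt)
  bp <- betti_numbers(zhang_suen_thin(pred))
  bg <- betti_numbers(zhang_suen_thin(gt))
  sum(abs(bp - bg))
}

#' Centerline Dice (clDice)
#'
#' Harmonic mean of topology precision (fraction of the prediction's
#' skeleton lying inside the ground-truth mask) and topology sensitivity
#' (fraction of the ground truth's skeleton lying inside the prediction):
#' insensitive to membrane thickness, sensitive to missing or spurious
#' centerline structure.
#'
#' @param pred,gt same-shape [binary_mask()]s with non-empty skeletons.
#' @return Scalar in \[0, 1\].
#' @export
cldice <- function(pred, gt) {
  check_same_shape(pred, gt)
  sp <- as_matrix_plain(zhang_suen_thin(pred))
  sg <- as_matrix_plain(zhang_suen_thin(gt))
  if (sum(sp) == 0L || sum(sg) == 0L) stop("clDice needs non-empty skeletons")
  tprec <- sum(sp == 1L & as_matrix_plain(gt) == 1L) / sum(sp)
  tsens <- sum(sg == 1L & as_matrix_plain(pred) == 1L) / sum(sg)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

# region labelings: cells = 4-connected components of the background
region_labels <- function(mask) label_components(invert_mask(mask), 4L)

# contingency counts between two labelings restricted to gt-interior pixels;
# prediction membrane pixels in the restricted set form one label-0 segment
region_contingency <- function(pred, gt) {
  lp <- region_labels(pred)
  lg <- region_labels(gt)
  keep <- lg > 0L
  table(pred = lp[keep], gt = lg[keep])
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Region-partition metrics
#'
#' Derives cell partitions from both masks (4-connected components of the
#' background, so 8-connected membranes separate cells), restricts to
#' ground-truth cell-interior pixels, and scores the two partitions on the
#' joint contingency table: the foreground-restricted Rand F-score
#' (`vrand`), the information-theoretic F-score (`vinfo`), the adjusted
#' Rand index (`ari`), and the variation of information (`voi`,
#' lower-better, in nats).
#'
#' @param pred,gt same-shape [binary_mask()]s.
#' @return A `metric_report` with entries `vrand`, `vinfo`, `ari`, `voi`.
#' @export
region_metrics <- function(pred, gt) {
  check_same_shape(pred, gt)
  tab <- region_contingency(pred, gt)
  n <- sum(tab)
  pij <- tab / n
  si <- rowSums(pij)   # prediction segment marginals
  tj <- colSums(pij)   # ground-truth segment marginals
  sum_p2 <- sum(pij^2); sum_s2 <- sum(si^2); sum_t2 <- sum(tj^2)
  vrand <- if (sum_s2 + sum_t2 == 0) 1 else 2 * sum_p2 / (sum_s2 + sum_t2)
  hs <- entropy_nats(si); ht <- entropy_nats(tj)
  hj <- entropy_nats(as.vector(pij))
  mi <- hs + ht - hj
  vinfo <- if (hs + ht == 0) 1 else 2 * mi / (hs + ht)
  voi <- hs + ht - 2 * mi
  # adjusted Rand index on pair counts
  comb2 <- function(x) x * (x - 1) / 2
  a <- sum(comb2(as.vector(tab)))
  b1 <- sum(comb2(rowSums(tab))); b2 <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expctd <- b1 * b2 / tot
  mx <- (b1 + b2) / 2
  ari <- if (mx == expctd) 1 else (a - expctd) / (mx - expctd)
  metric_report(c(vrand = vrand, vinfo = vinfo, ari = ari, voi = voi))
}

#' Named metric values with direction tags
#'
#' @param values named numeric vector.
#' @return A `metric_report`: the vector plus a `direction` attribute
#'   (`"higher"` or `"lower"`) per entry.
#' @export
metric_report <- function(values) {
  stopifnot(is.numeric(values), !is.null(names(values)), all(is.finite(values)))
  dirs <- vapply(names(values), metric_direction, character(1))
  structure(values, direction = dirs, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  df <- data.frame(metric = names(x), value = as.numeric(x),
                   direction = attr(x, "direction"), row.names = NULL)
  print(df)
  invisible(x)
}

metric_ids <- c("f1", "precision", "recall", "iou", "tpvf", "tnvf", "rvd",
                "hd", "assd", "betti", "cldice",
                "vrand", "vinfo", "ari", "voi", "phd")

#' Direction tag of a metric
#'
#' @param metric one of `"f1"`, `"precision"`, `"recall"`, `"iou"`, `"tpvf"`,
#'   `"tnvf"`, `"rvd"`, `"hd"`, `"assd"`, `"betti"`, `"cldice"`, `"vrand"`,
#'   `"vinfo"`, `"ari"`, `"voi"`, `"phd"`.
#' @return `"higher"` (higher is better) or `"lower"`.
#' @export
metric_direction <- function(metric) {
  metric <- match.arg(metric, metric_ids)
  if (metric %in% c("hd", "assd", "betti", "voi", "phd", "rvd")) "lower"
  else "higher"
}

#' Evaluate a single metric on a prediction / ground-truth pair
#'
#' One entry point over the whole suite. `rvd` compares by |RVD| (closer to
#' zero is better) when used for preference ranking.
#'
#' @param pred,gt same-shape [binary_mask()]s.
#' @param metric metric id; see [metric_direction()] for the list.
#' @param tau tolerance for `metric = "phd"`, default 3 (the threshold with
#'   the best observed human consistency).
#' @param skeletonize thin both masks first (the "-SK" metric variants)?
#'   For `"phd"` this is the standard skeleton extraction step and defaults
#'   on unless disabled.
#' @return Scalar metric value.
#' @export
evaluate_masks <- function(pred, gt, metric, tau = 3, skeletonize = FALSE) {
  metric <- match.arg(metric, metric_ids)
  if (metric == "phd") {
    X <- mask_to_pointset(pred, skeletonize = skeletonize)
    Y <- mask_to_pointset(gt, skeletonize = skeletonize)
    return(phd_distance(X, Y, tolerance_spec(tau = tau)))
  }
  if (skeletonize) {
    pred <- zhang_suen_thin(pred)
    gt <- zhang_suen_thin(gt)
  }
  switch(metric,
    f1 = ,
    precision = ,
    recall = ,
    iou = ,
    tpvf = ,
    tnvf = ,
    rvd = unname(confusion_metrics(pred, gt)[metric]),
    hd = ,
    assd = unname(distance_metrics(pred, gt)[metric]),
    betti = betti_error(pred, gt),
    cldice = cldice(pred, gt),
    vrand = ,
    vinfo = ,
    ari = ,
    voi = unname(region_metrics(pred, gt)[metric])
  )
}

#' Skeletonized ("-SK") variant of a metric
#'
#' Thins both masks with [zhang_suen_thin()] and applies the named metric —
#' the cheap structural fix the perceptual Hausdorff distance is compared
#' against.
#'
#' @inheritParams evaluate_masks
#' @return Scalar metric value.
#' @export
with_skeletonization <- function(metric, pred, gt, tau = 3) {
  evaluate_masks(pred, gt, metric, tau = tau, skeletonize = TRUE)
}

#' Full metric report for a pair of masks
#'
#' @inheritParams evaluate_masks
#' @return A `metric_report` over the full suite.
#' @export
all_metrics <- function(pred, gt, tau = 3, skeletonize = FALSE) {
  vals <- vapply(metric_ids, function(m) {
    evaluate_masks(pred, gt, m, tau = tau, skeletonize = skeletonize)
  }, numeric(1))
  metric_report(vals)
}

check_same_shape <- function(pred, gt) {
  stopifnot(is_binary_mask(pred), is_binary_mask(gt))
  if (!identical(dim(pred), dim(gt))) {
    stop("prediction and ground truth must share the same shape")
  }
  invisible(TRUE)
}
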