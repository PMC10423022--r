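#' Point sets of skeleton pixel coordinates
#'
#' A `point_set` is an n x 2 integer matrix of (row, col) pixel coordinates
#' (1-based, origin top-left) plus the shape of the frame it came from. It is
#' the structural summary a membrane mask reduces to after skeletonization,
#' and the object the perceptual Hausdorff distance operates on.
#'
#' @param points n x 2 integer matrix (or data.frame) of (row, col) pairs.
#' @param shape integer (H, W) of the source frame.
#' @return A `point_set`.
#' @export
point_set <- function(points, shape) {
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(integer(0), 0L, 2L)
  if (ncol(pts) != 2L) stop("points must be an n x 2 (row, col) matrix")
  storage.mode(pts) <- "integer"
  pts <- unique(pts)
  shape <- as.integer(shape)
  if (nrow(pts) > 0L) {
    if (any(pts[, 1L] < 1L | pts[, 1L] > shape[1L] |
            pts[, 2L] < 1L | pts[, 2L] > shape[2L])) {
      stop("points fall outside the source frame")
    }
  }
  dimnames(pts) <- list(NULL, c("row", "col"))
  structure(pts, shape = shape, class = c("point_set", "matrix", "array"))
}

#' @export
print.point_set <- function(x, ...) {
  s <- attr(x, "shape")
  cat(sprintf("<point_set: %d points in %d x %d frame>\n", nrow(x), s[1], s[2]))
  invisible(x)
}

is_point_set <- function(x) inherits(x, "point_set")

ps_points <- function(x) {
  p <- x
  attributes(p) <- list(dim = dim(x))
  p
}

# Zhang-Suen neighbourhood, clockwise from north:
#   P2 = (r-1, c), P3 = (r-1, c+1), P4 = (r, c+1), P5 = (r+1, c+1),
#   P6 = (r+1, c), P7 = (r+1, c-1), P8 = (r, c-1), P9 = (r-1, c-1)
zs_offsets <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                    dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# one parallel sub-iteration; returns the mask with flagged pixels deleted
zs_subiter <- function(m, first) {
  h <- nrow(m); w <- ncol(m)
  nb <- vector("list", 8L)
  for (k in 1:8) nb[[k]] <- shift_mat(m, -zs_offsets[k, 1L], -zs_offsets[k, 2L])
  b <- Reduce(`+`, nb)
  # A(p): 0 -> 1 transitions in the cyclic sequence P2..P9
  a <- matrix(0L, h, w)
  for (k in 1:8) {
    nxt <- if (k == 8L) 1L else k + 1L
    a <- a + (nb[[k]] == 0L & nb[[nxt]] == 1L)
  }
  if (first) {
    c3 <- nb[[1L]] * nb[[3L]] * nb[[5L]]   # P2 * P4 * P6
    c4 <- nb[[3L]] * nb[[5L]] * nb[[7L]]   # P4 * P6 * P8
  } else {
    c3 <- nb[[1L]] * nb[[3L]] * nb[[7L]]   # P2 * P4 * P8
    c4 <- nb[[1L]] * nb[[5L]] * nb[[7L]]   # P2 * P6 * P8
  }
  del <- m == 1L & b >= 2L & b <= 6L & a == 1L & c3 == 0L & c4 == 0L
  m[del] <- 0L
  m
}

#' Zhang-Suen thinning
#'
#' Classical two-sub-iteration parallel thinning: boundary pixels satisfying
#' the deletion conditions of each sub-iteration are removed simultaneously,
#' and the pair of passes repeats until no pixel changes. The frame is
#' treated as padded with background, output foreground is a subset of input
#' foreground, and 8-connectivity of each component is preserved.
#'
#' @param mask a [binary_mask()].
#' @return The thinned [binary_mask()] (idempotent: thinning twice changes
#'   nothing).
#' @export
zhang_suen_thin <- function(mask) {
  stopifnot(is_binary_mask(mask))
  m <- as_matrix_plain(mask)
  repeat {
    before <- m
    m <- zs_subiter(m, first = TRUE)
    m <- zs_subiter(m, first = FALSE)
    if (identical(m, before)) break
  }
  binary_mask(m)
}

#' Convert a mask to a skeleton point set
#'
#' Optionally thins the mask first ([zhang_suen_thin()]), then returns the
#' foreground pixel coordinates. This is the structure-extraction step of the
#' perceptual Hausdorff distance.
#'
#' @param mask a [binary_mask()].
#' @param skeletonize thin before extracting coordinates? Default `TRUE`.
#' @return A [point_set()] (possibly empty).
#' @export
mask_to_pointset <- function(mask, skeletonize = TRUE) {
  stopifnot(is_binary_mask(mask))
  if (skeletonize) mask <- zhang_suen_thin(mask)
  m <- as_matrix_plain(mask)
  idx <- which(m == 1L)
  point_set(cbind(((idx - 1L) %% nrow(m)) + 1L, ((idx - 1L) %/% nrow(m)) + 1L),
            shape = dim(m))
}

#' Skeleton extraction with a gradient contract
#'
#' Forward pass: binarize the probability map at `threshold` and extract the
#' thinned skeleton point set — identical to
#' `mask_to_pointset(binarize(p), skeletonize = TRUE)`. The hard
#' binarize/thin composition has no usable analytic derivative, so training
#' code pairs this forward value with a straight-through subgradient on the
#' probability map (see [phd_loss_grad()]): thinning acts as a selection
#' mask and gradient flows only through surviving-pixel probabilities.
#'
#' @param p a [prob_map()].
#' @param threshold binarization threshold, default 0.5.
#' @return A list with `points` (the [point_set()]) and `support` (integer
#'   matrix marking the surviving skeleton pixels, the gradient support).
#' @export
soft_skeleton <- function(p, threshold = 0.5) {
  skel <- zhang_suen_thin(binarize(p, threshold))
  list(points = mask_to_pointset(skel, skeletonize = FALSE),
       support = as_matrix_plain(skel))
}
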