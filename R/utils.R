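# Shared raster helpers: shifts, morphology, connected-component labeling.

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# integer offsets of a Euclidean disk of the given radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Morphological dilation by a Euclidean disk
#'
#' @param mask a [binary_mask()].
#' @param radius disk radius in pixels (>= 0; 0 returns the input).
#' @return The dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(is_binary_mask(mask), radius >= 0)
  if (radius == 0) return(mask)
  m <- as_matrix_plain(mask)
  off <- disk_offsets(radius)
  acc <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    acc <- acc | shift_mat(m, off$dr[i], off$dc[i])
  }
  binary_mask(acc * 1L)
}

# offsets of the 4- or 8-neighbourhood
neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
  } else {
    stop("connectivity must be 4 or 8")
  }
}

#' Label connected components of a binary mask
#'
#' Builds the pixel adjacency graph under the requested connectivity and
#' labels its connected components (membrane curves are 8-connected;
#' cell-interior regions use 4-connectivity, the standard dual pairing).
#'
#' @param mask a [binary_mask()]; foreground pixels are labeled.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape: 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is_binary_mask(mask))
  m <- as_matrix_plain(mask)
  h <- nrow(m); w <- ncol(m)
  idx <- which(m == 1L)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  pos <- integer(h * w)       # linear index -> vertex id
  pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  off <- neighbour_offsets(as.integer(connectivity))
  ef <- integer(0); et <- integer(0)
  for (k in seq_len(nrow(off))) {
    nr <- rows + off[k, 1L]; nc <- cols + off[k, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- pos[nidx] > 0L
    ef <- c(ef, pos[idx[ok]][hit])
    et <- c(et, pos[nidx][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Count connected components
#'
#' @inheritParams label_components
#' @return Number of foreground components (0 for an empty mask).
#' @export
count_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}

#' Translate a mask within its frame
#'
#' Pixels shifted out of the frame are dropped; vacated pixels become
#' background. Errors if a non-empty mask is shifted entirely out of frame.
#'
#' @param mask a [binary_mask()].
#' @param dr,dc integer row/column shift (positive = down/right).
#' @return The translated [binary_mask()].
#' @export
translate_mask <- function(mask, dr, dc) {
  stopifnot(is_binary_mask(mask))
  out <- shift_mat(as_matrix_plain(mask), as.integer(dr), as.integer(dc))
  if (sum(mask) > 0L && sum(out) == 0L) {
    stop("translation moved the mask entirely out of frame")
  }
  binary_mask(out)
}
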