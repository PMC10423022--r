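# Fixtures and independent reference implementations used across the suite.
# Everything is built in code; no binary fixtures.

# --- literal Zhang-Suen reference: pixel-by-pixel transcription of the two
# sub-iteration deletion conditions, scanning every pixel with explicit loops
zs_reference <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  h <- nrow(m); w <- ncol(m)
  at <- function(mm, r, c) {
    if (r < 1 || r > h || c < 1 || c > w) 0L else mm[r, c]
  }
  # P2..P9 clockwise from north
  nbrs <- function(mm, r, c) {
    c(at(mm, r - 1, c), at(mm, r - 1, c + 1), at(mm, r, c + 1),
      at(mm, r + 1, c + 1), at(mm, r + 1, c), at(mm, r + 1, c - 1),
      at(mm, r, c - 1), at(mm, r - 1, c - 1))
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- matrix(FALSE, h, w)
      for (r in seq_len(h)) {
        for (c in seq_len(w)) {
          if (m[r, c] != 1L) next
          p <- nbrs(m, r, c)
          b <- sum(p)
          if (b < 2L || b > 6L) next
          a <- sum(p == 0L & c(p[-1], p[1]) == 1L)
          if (a != 1L) next
          if (pass == 1L) {
            if (p[1] * p[3] * p[5] != 0L) next
            if (p[3] * p[5] * p[7] != 0L) next
          } else {
            if (p[1] * p[3] * p[7] != 0L) next
            if (p[1] * p[5] * p[7] != 0L) next
          }
          del[r, c] <- TRUE
        }
      }
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# --- square ring (closed 1-px loop) with top-left corner at (r0, c0)
ring_mask <- function(n, r0 = 2L, c0 = 2L, side = 8L) {
  m <- matrix(0L, n, n)
  r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
  m[r0:r1, c(c0, c1)] <- 1L
  m[c(r0, r1), c0:c1] <- 1L
  binary_mask(m)
}

# --- two parallel 1-px horizontal lines, vertical offset `off`
parallel_lines <- function(frame = 32L, len = 20L, off = 6L) {
  m1 <- matrix(0L, frame, frame)
  m2 <- matrix(0L, frame, frame)
  r <- (frame - off) %/% 2L
  cols <- seq(6L, 6L + len - 1L)
  m1[r, cols] <- 1L
  m2[r + off, cols] <- 1L
  list(a = binary_mask(m1), b = binary_mask(m2))
}

# --- random point set within a frame
rand_pointset <- function(n, frame = c(50L, 50L)) {
  pts <- unique(cbind(sample.int(frame[1L], n, replace = TRUE),
                      sample.int(frame[2L], n, replace = TRUE)))
  point_set(pts, frame)
}

# --- random sparse mask with at least one foreground pixel
rand_mask <- function(h = 16L, w = 16L, p = 0.2) {
  m <- matrix(rbinom(h * w, 1L, p), h, w)
  if (sum(m) == 0L) m[sample.int(h, 1L), sample.int(w, 1L)] <- 1L
  binary_mask(m)
}

# --- probability map with foreground 1 at the given (row, col) points
prob_with_points <- function(shape, pts) {
  m <- matrix(0, shape[1L], shape[2L])
  for (i in seq_len(nrow(pts))) m[pts[i, 1L], pts[i, 2L]] <- 1
  prob_map(m)
}
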