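# Synthetic membrane phantoms: Voronoi cell mosaics whose boundaries are thin
# connected curves, plus controlled perturbations emulating the error types
# seen in EM membrane predictions (thickness change, misalignment, missing
# edges, spurious edges). Deterministic per seed; stands in for EM data in
# tests and the consistency benchmark.

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic membrane phantom
#'
#' Seeds `n_cells` random sites in the frame, labels every pixel by its
#' nearest site (a Voronoi mosaic — the simplest geometry with the closed-
#' cell topology of EM membrane images), marks label transitions as the
#' 1-pixel membrane skeleton, and dilates to the requested thickness. Sites
#' are rejection-sampled to keep a minimum separation so every cell has an
#' interior. Fully deterministic per seed.
#'
#' @param seed integer RNG seed.
#' @param frame integer (H, W); default c(64, 64).
#' @param n_cells number of cells, >= 2.
#' @param thickness membrane thickness in pixels (>= 1; the mask is the
#'   skeleton dilated by a disk of radius (thickness - 1) / 2).
#' @return A `membrane_phantom`: list with `seed`, `frame`, `n_cells`,
#'   `thickness`, `gt` ([binary_mask()]), `skeleton` ([point_set()]) and
#'   `skeleton_mask` (the thickness-1 [binary_mask()]).
#' @export
generate_phantom <- function(seed, frame = c(64L, 64L), n_cells = 4L,
                             thickness = 3L) {
  frame <- as.integer(frame)
  if (n_cells < 2L) stop("n_cells must be >= 2")
  if (prod(frame) < 16L * n_cells) stop("frame too small for ", n_cells, " cells")
  h <- frame[1L]; w <- frame[2L]
  min_sep <- 0.5 * sqrt(h * w / n_cells)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  built <- with_seed(seed, {
    res <- NULL
    for (attempt in 1:200) {
      sites <- cbind(runif(n_cells, 1, h), runif(n_cells, 1, w))
      if (min(stats::dist(sites)) < min_sep) next
      best_d <- matrix(Inf, h, w)
      lab <- matrix(0L, h, w)
      for (i in seq_len(n_cells)) {
        d <- (rows - sites[i, 1L])^2 + (cols - sites[i, 2L])^2
        upd <- d < best_d
        best_d[upd] <- d[upd]
        lab[upd] <- i
      }
      # mark one side of every label transition -> 1-px boundary curves
      memb <- (lab != shift_mat(lab, 0L, -1L, fill = NA)) |
              (lab != shift_mat(lab, -1L, 0L, fill = NA))
      memb[is.na(memb)] <- FALSE
      skel_mask <- binary_mask(memb * 1L)
      gt <- if (thickness > 1L) {
        dilate_mask(skel_mask, (thickness - 1) / 2)
      } else {
        skel_mask
      }
      # thick membranes can pinch off a sliver cell; accept only mosaics
      # whose interior keeps exactly n_cells 4-connected regions
      if (count_components(invert_mask(gt), 4L) == n_cells) {
        res <- list(skel_mask = skel_mask, gt = gt, lab = lab)
        break
      }
    }
    if (is.null(res)) stop("could not place ", n_cells, " well-separated cells")
    res
  })
  skel_mask <- built$skel_mask
  gt <- built$gt
  lab <- built$lab
  structure(list(seed = seed, frame = frame, n_cells = n_cells,
                 thickness = as.integer(thickness), gt = gt,
                 skeleton = mask_to_pointset(skel_mask, skeletonize = FALSE),
                 skeleton_mask = skel_mask, labels = lab),
            class = "membrane_phantom")
}

#' @export
print.membrane_phantom <- function(x, ...) {
  cat(sprintf("<membrane_phantom seed %d: %d cells, %d x %d, thickness %d>\n",
              x$seed, x$n_cells, x$frame[1], x$frame[2], x$thickness))
  invisible(x)
}

# split the phantom skeleton into branches (components after removing
# junction pixels, i.e. skeleton pixels with >= 3 skeleton neighbours)
skeleton_branches <- function(phantom) {
  m <- as_matrix_plain(phantom$skeleton_mask)
  off <- neighbour_offsets(8L)
  nb <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) nb <- nb + shift_mat(m, -off[k, 1L], -off[k, 2L])
  junction <- m == 1L & nb >= 3L
  pruned <- m
  pruned[junction] <- 0L
  list(branch_labels = label_components(binary_mask(pruned), 8L),
       junction = junction)
}

#' Perturb a phantom's ground truth
#'
#' Controlled error models: `dilate` thickens the membrane (a tolerated,
#' non-structural change); `shift` translates the whole mask (small
#' misalignment); `delete_edges` removes a fraction of skeleton branches and
#' re-dilates (structural damage — missing membrane); `add_spurs` attaches
#' short random false-positive branches.
#'
#' @param phantom a [generate_phantom()] result.
#' @param kind one of `"dilate"`, `"shift"`, `"delete_edges"`, `"add_spurs"`.
#' @param r dilation radius (kind `"dilate"`).
#' @param dr,dc translation (kind `"shift"`).
#' @param fraction fraction of skeleton branches to delete in \[0, 1\]
#'   (kind `"delete_edges"`); 1 deletes everything.
#' @param k number of spurs (kind `"add_spurs"`).
#' @param seed RNG seed for the random choices; deterministic per seed.
#' @return A [binary_mask()].
#' @export
perturb <- function(phantom, kind = c("dilate", "shift", "delete_edges",
                                      "add_spurs"),
                    r = 1, dr = 0L, dc = 0L, fraction = 0.3, k = 3L,
                    seed = 1L) {
  stopifnot(inherits(phantom, "membrane_phantom"))
  kind <- match.arg(kind)
  switch(kind,
    dilate = dilate_mask(phantom$gt, r),
    shift = translate_mask(phantom$gt, dr, dc),
    delete_edges = {
      if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
      if (fraction >= 1) {
        return(binary_mask(matrix(0L, phantom$frame[1L], phantom$frame[2L])))
      }
      br <- skeleton_branches(phantom)
      nb <- max(br$branch_labels)
      keep <- as_matrix_plain(phantom$skeleton_mask)
      if (fraction > 0 && nb > 0L) {
        # drop whole branches in random order until the requested fraction
        # of the skeleton's length is gone (branches vary greatly in size,
        # so a length budget, not a branch count, measures the damage)
        sizes <- tabulate(br$branch_labels[br$branch_labels > 0L], nb)
        order_ids <- with_seed(seed, sample.int(nb))
        budget <- fraction * sum(keep)
        removed <- 0
        for (id in order_ids) {
          if (removed >= budget) break
          keep[br$branch_labels == id] <- 0L
          removed <- removed + sizes[id]
        }
      }
      out <- binary_mask(keep)
      if (phantom$thickness > 1L) out <- dilate_mask(out, (phantom$thickness - 1) / 2)
      out
    },
    add_spurs = {
      skel <- as_matrix_plain(phantom$skeleton_mask)
      pts <- ps_points(phantom$skeleton)
      h <- phantom$frame[1L]; w <- phantom$frame[2L]
      spur <- matrix(0L, h, w)
      with_seed(seed, {
        dirs <- neighbour_offsets(8L)
        for (s in seq_len(k)) {
          p <- pts[sample.int(nrow(pts), 1L), ]
          d <- dirs[sample.int(8L, 1L), ]
          len <- sample(4:8, 1L)
          for (step in seq_len(len)) {
            p <- p + d
            if (p[1L] < 1L || p[1L] > h || p[2L] < 1L || p[2L] > w) break
            spur[p[1L], p[2L]] <- 1L
          }
        }
      })
      spur_mask <- binary_mask(spur)
      if (phantom$thickness > 1L) {
        spur_mask <- dilate_mask(spur_mask, (phantom$thickness - 1) / 2)
      }
      binary_mask((as_matrix_plain(phantom$gt) | as_matrix_plain(spur_mask)) * 1L)
    }
  )
}

#' Render a phantom as a noisy grayscale image
#'
#' Membranes dark, cell interiors bright (the EM convention), plus Gaussian
#' pixel noise, clipped to \[0, 1\]. Used as the input image for training
#' smoke tests; it emulates intensity contrast only, not EM texture.
#'
#' @param mask a [binary_mask()] (typically a phantom's `gt`).
#' @param seed RNG seed.
#' @param fg,bg mean intensity of membrane / background pixels.
#' @param noise_sd Gaussian noise standard deviation.
#' @return A [prob_map()] used as an intensity image.
#' @export
render_intensity <- function(mask, seed = 1L, fg = 0.25, bg = 0.75,
                             noise_sd = 0.08) {
  stopifnot(is_binary_mask(mask))
  m <- as_matrix_plain(mask)
  img <- with_seed(seed, {
    base <- ifelse(m == 1L, fg, bg)
    base + matrix(rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  })
  prob_map(pmin(pmax(img, 0), 1))
}

#' Build a synthetic two-alternative preference benchmark
#'
#' Each trial pairs a phantom ground truth with a tolerated perturbation
#' (prediction A: small shift, optionally also 1-px dilation) and a
#' structural perturbation (prediction B: branch deletion). The oracle
#' answer is always A — structure loss is the damage humans penalize —
#' and simulated subjects agree with the oracle independently with
#' probability `reliability`.
#'
#' @param n number of trials.
#' @param seed RNG seed; all phantom and vote randomness derives from it.
#' @param frame,n_cells,thickness phantom parameters (see
#'   [generate_phantom()]).
#' @param shift_max maximum Euclidean shift of prediction A, pixels.
#' @param delete_range range of the branch-deletion fraction for B.
#' @param n_subjects simulated subjects per trial.
#' @param reliability per-subject probability of agreeing with the oracle.
#' @return A `preference_trials` list; each element has `trial_id`, `gt`,
#'   `pred_a`, `pred_b` (in-memory [binary_mask()]s), `votes_a`, `votes_b`
#'   and `oracle` ("A").
#' @export
make_trials <- function(n, seed = 1L, frame = c(64L, 64L), n_cells = 4L,
                        thickness = 3L, shift_max = 3, delete_range = c(0.2, 0.4),
                        n_subjects = 20L, reliability = 0.9) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    list(phantom_seeds = sample.int(2^20, n),
         perturb_seeds = sample.int(2^20, n),
         dil = runif(n) < 0.5,
         frac = runif(n, delete_range[1L], delete_range[2L]),
         votes = rbinom(n, n_subjects, reliability))
  })
  shifts <- with_seed(seed + 1L, {
    # non-zero integer shifts with Euclidean norm <= shift_max
    cand <- expand.grid(dr = -floor(shift_max):floor(shift_max),
                        dc = -floor(shift_max):floor(shift_max))
    cand <- cand[cand$dr^2 + cand$dc^2 <= shift_max^2 &
                 (cand$dr != 0 | cand$dc != 0), ]
    cand[sample.int(nrow(cand), n, replace = TRUE), ]
  })
  trials <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(draws$phantom_seeds[i], frame, n_cells, thickness)
    a <- perturb(ph, "shift", dr = shifts$dr[i], dc = shifts$dc[i])
    if (draws$dil[i]) {
      a <- dilate_mask(a, 1)
    }
    b <- perturb(ph, "delete_edges", fraction = draws$frac[i],
                 seed = draws$perturb_seeds[i])
    list(trial_id = sprintf("trial_%03d", i), gt = ph$gt,
         pred_a = a, pred_b = b,
         votes_a = draws$votes[i], votes_b = n_subjects - draws$votes[i],
         oracle = "A")
  })
  structure(trials, class = "preference_trials")
}

#' @export
print.preference_trials <- function(x, ...) {
  cat(sprintf("<preference_trials: %d trials>\n", length(x)))
  invisible(x)
}

#' Write trials to disk as rasters plus a TSV manifest
#'
#' @param trials a [make_trials()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path (`manifest.tsv` with columns
#'   trial_id, gt, pred_a, pred_b, votes_a, votes_b).
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    paths <- file.path(dir, paste0(tr$trial_id, c("_gt", "_a", "_b"), ".png"))
    write_raster(tr$gt, paths[1L])
    write_raster(tr$pred_a, paths[2L])
    write_raster(tr$pred_b, paths[3L])
    data.frame(trial_id = tr$trial_id, gt = basename(paths[1L]),
               pred_a = basename(paths[2L]), pred_b = basename(paths[3L]),
               votes_a = tr$votes_a, votes_b = tr$votes_b)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Read a TSV trial manifest
#'
#' @param manifest path to a TSV with columns trial_id, gt, pred_a, pred_b,
#'   votes_a, votes_b; raster paths are resolved relative to the manifest.
#' @return A `preference_trials` list with masks loaded.
#' @export
read_trials <- function(manifest) {
  df <- read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("trial_id", "gt", "pred_a", "pred_b", "votes_a", "votes_b")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest)
  as_mask <- function(p) {
    x <- read_raster(file.path(base, p))
    if (is_prob_map(x)) x <- binarize(x)
    x
  }
  trials <- lapply(seq_len(nrow(df)), function(i) {
    list(trial_id = df$trial_id[i], gt = as_mask(df$gt[i]),
         pred_a = as_mask(df$pred_a[i]), pred_b = as_mask(df$pred_b[i]),
         votes_a = df$votes_a[i], votes_b = df$votes_b[i], oracle = NA)
  })
  structure(trials, class = "preference_trials")
}
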