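# Minimal dense-prediction network machinery: same-padded convolutions via
# im2col, 2x2 mean pooling, nearest-neighbour upsampling, ReLU, two-class
# softmax, and Adam. All arrays are (H, W, C); everything is deterministic
# given the RNG state at initialization.

conv_pad <- function(x, ph, pw) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * ph, d[2L] + 2L * pw, d[3L]))
  out[ph + seq_len(d[1L]), pw + seq_len(d[2L]), ] <- x
  out
}

# im2col for a kh x kw same-padded convolution: (H*W) x (kh*kw*Cin)
im2col <- function(x, kh, kw) {
  d <- dim(x)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- conv_pad(x, ph, pw)
  cols <- matrix(0, d[1L] * d[2L], kh * kw * d[3L])
  k <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      patch <- xp[di - 1L + seq_len(d[1L]), dj - 1L + seq_len(d[2L]), ,
                  drop = FALSE]
      cols[, k + seq_len(d[3L])] <- matrix(patch, d[1L] * d[2L], d[3L])
      k <- k + d[3L]
    }
  }
  cols
}

conv_forward <- function(x, w, b) {
  dw <- dim(w)  # kh, kw, Cin, Cout
  xc <- im2col(x, dw[1L], dw[2L])
  wm <- matrix(w, dw[1L] * dw[2L] * dw[3L], dw[4L])
  out <- sweep(xc %*% wm, 2L, b, `+`)
  d <- dim(x)
  list(out = array(out, c(d[1L], d[2L], dw[4L])),
       cache = list(xc = xc, wdim = dw, xdim = d))
}

conv_backward <- function(dout, cache) {
  dw_dim <- cache$wdim; d <- cache$xdim
  dmat <- matrix(dout, d[1L] * d[2L], dw_dim[4L])
  wm_grad <- crossprod(cache$xc, dmat)
  db <- colSums(dmat)
  list(dw = array(wm_grad, dw_dim), db = db, dmat = dmat)
}

# gradient w.r.t. the conv input (col2im scatter-add)
conv_backward_input <- function(dmat, w, xdim) {
  dw <- dim(w)
  wm <- matrix(w, dw[1L] * dw[2L] * dw[3L], dw[4L])
  dxc <- tcrossprod(dmat, wm)  # (H*W) x (kh*kw*Cin)
  kh <- dw[1L]; kw <- dw[2L]; cin <- dw[3L]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dxp <- array(0, c(xdim[1L] + 2L * ph, xdim[2L] + 2L * pw, cin))
  k <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      blk <- array(dxc[, k + seq_len(cin)], c(xdim[1L], xdim[2L], cin))
      ri <- di - 1L + seq_len(xdim[1L]); ci <- dj - 1L + seq_len(xdim[2L])
      dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] + blk
      k <- k + cin
    }
  }
  dxp[ph + seq_len(xdim[1L]), pw + seq_len(xdim[2L]), , drop = FALSE]
}

pool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  (x[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
   x[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
   x[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE] +
   x[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE]) / 4
}

pool2_backward <- function(dout, xdim) {
  dx <- array(0, xdim)
  q <- dout / 4
  dx[seq(1L, xdim[1L], 2L), seq(1L, xdim[2L], 2L), ] <- q
  dx[seq(2L, xdim[1L], 2L), seq(1L, xdim[2L], 2L), ] <- q
  dx[seq(1L, xdim[1L], 2L), seq(2L, xdim[2L], 2L), ] <- q
  dx[seq(2L, xdim[1L], 2L), seq(2L, xdim[2L], 2L), ] <- q
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  pool2_forward(dout) * 4
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Initialize the compact two-level encoder-decoder
#'
#' A u-shaped network at desk scale: 3x3 conv (1 -> ch1), 2x2 mean-pool,
#' 3x3 conv (ch1 -> ch2), nearest-neighbour upsample, skip concatenation,
#' 3x3 conv (ch1 + ch2 -> ch1), 1x1 conv to 2 class logits, softmax. One
#' parameter set serves both the global and the local branch (shared
#' weights). Initialization consumes the current RNG state.
#'
#' @param ch1,ch2 channel widths of the two levels; defaults 8 and 16.
#' @return A `branch_model`: list of weight arrays and biases.
#' @export
branch_model <- function(ch1 = 8L, ch2 = 16L) {
  params <- list(
    w1 = he_init(3L, 3L, 1L, ch1), b1 = numeric(ch1),
    w2 = he_init(3L, 3L, ch1, ch2), b2 = numeric(ch2),
    w3 = he_init(3L, 3L, ch1 + ch2, ch1), b3 = numeric(ch1),
    w4 = he_init(1L, 1L, ch1, 2L), b4 = numeric(2L)
  )
  structure(params, class = "branch_model")
}

#' @export
print.branch_model <- function(x, ...) {
  n <- sum(vapply(unclass(x), length, numeric(1)))
  cat(sprintf("<branch_model: %d parameters>\n", n))
  invisible(x)
}

# leaky rectifier: small negative slope keeps gradients alive in collapsed
# channels (plain ReLU lets whole layers die under the class-weighted loss)
relu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
relu_factor <- function(pre) (pre > 0) + 0.1 * (pre <= 0)

# forward pass; keeps every intermediate needed for the backward pass
net_forward <- function(params, img) {
  x0 <- array(as_matrix_plain(img), c(dim(img), 1L))
  c1 <- conv_forward(x0, params$w1, params$b1)
  a1 <- relu(c1$out)
  p1 <- pool2_forward(a1)
  c2 <- conv_forward(p1, params$w2, params$b2)
  a2 <- relu(c2$out)
  u2 <- upsample2_forward(a2)
  cat12 <- array(c(a1, u2), c(dim(a1)[1:2], dim(a1)[3L] + dim(u2)[3L]))
  c3 <- conv_forward(cat12, params$w3, params$b3)
  a3 <- relu(c3$out)
  c4 <- conv_forward(a3, params$w4, params$b4)
  z <- c4$out
  zs <- z - array(pmax(z[, , 1L], z[, , 2L]), dim(z))  # stabilized
  ez <- exp(zs)
  denom <- ez[, , 1L] + ez[, , 2L]
  sfg <- ez[, , 2L] / denom
  list(prob = prob_map(pmin(pmax(sfg, 0), 1)),
       cache = list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, u2 = u2,
                    cat12 = cat12, c3 = c3, a3 = a3, c4 = c4, sfg = sfg))
}

# backward pass from dL/d(membrane probability); returns parameter gradients
net_backward <- function(params, fwd, dprob) {
  cc <- fwd$cache
  s <- cc$sfg
  dz2 <- dprob * s * (1 - s)
  dz <- array(c(-dz2, dz2), c(dim(dz2), 2L))
  g4 <- conv_backward(dz, cc$c4$cache)
  da3 <- conv_backward_input(g4$dmat, params$w4, dim(cc$a3))
  da3 <- da3 * relu_factor(cc$c3$out)
  g3 <- conv_backward(da3, cc$c3$cache)
  dcat <- conv_backward_input(g3$dmat, params$w3, dim(cc$cat12))
  ch1 <- dim(cc$a1)[3L]
  da1 <- dcat[, , seq_len(ch1), drop = FALSE]
  du2 <- dcat[, , -seq_len(ch1), drop = FALSE]
  da2 <- upsample2_backward(du2)
  da2 <- da2 * relu_factor(cc$c2$out)
  g2 <- conv_backward(da2, cc$c2$cache)
  dp1 <- conv_backward_input(g2$dmat, params$w2, dim(cc$p1))
  da1 <- da1 + pool2_backward(dp1, dim(cc$a1))
  da1 <- da1 * relu_factor(cc$c1$out)
  g1 <- conv_backward(da1, cc$c1$cache)
  list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db,
       w3 = g3$dw, b3 = g3$db, w4 = g4$dw, b4 = g4$db)
}

adam_init <- function(params) {
  list(m = lapply(unclass(params), function(p) p * 0),
       v = lapply(unclass(params), function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
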