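# Numeric engine ----------------------------------------------------------------
#
# Minimal double-precision forward/backward machinery for the model family.
# Batch tensors are arrays laid out (C, H, W, N) -- channel fastest -- so
# per-channel statistics and 1x1 convolutions reduce to plain matrix ops with
# column-major recycling, and k x k convolutions become one GEMM against an
# im2col patch matrix built in C++.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

tensor_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# Parameter initialisation ------------------------------------------------------

init_leaf <- function(l) {
  par <- switch(
    l$kind,
    conv = {
      fan_in <- l$k^2 * (l$in_ch %/% l$groups)
      if (l$groups > 1L) {
        stopifnot(l$groups == l$in_ch, l$out_ch == l$in_ch)
        list(W = array(stats::rnorm(l$in_ch * l$k^2, sd = sqrt(2 / fan_in)),
                       dim = c(l$in_ch, l$k, l$k)))
      } else {
        list(W = matrix(stats::rnorm(l$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                        nrow = l$out_ch))
      }
    },
    bn = list(gamma = rep(1, l$ch), beta = rep(0, l$ch)),
    act = if (l$fun == "prelu") list(alpha = 0.25) else list(),
    eca = list(w = stats::runif(l$k, -1, 1) / sqrt(l$k)),
    fc = list(W = matrix(stats::rnorm(l$out_n * l$in_n, sd = sqrt(2 / l$in_n)),
                         nrow = l$out_n),
              b = rep(0, l$out_n)),
    list()
  )
  l$par <- par
  if (l$kind == "bn") {
    l$buf <- list(rm = rep(0, l$ch), rv = rep(1, l$ch), n = 0L)
  }
  l
}

n_leaf_params <- function(leaf) {
  sum(vapply(leaf$par, length, numeric(1)))
}

# Forward -----------------------------------------------------------------------

leaf_fw <- function(l, x, training) {
  d <- tensor_dims(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  switch(
    l$kind,
    conv = {
      if (l$groups > 1L) {
        out <- depthwise_fw_cpp(x, C, H, W, N, as.numeric(l$par$W),
                                l$k, l$stride, l$pad)
        oH <- (H + 2L * l$pad - l$k) %/% l$stride + 1L
        dim(out) <- c(C, oH, oH, N)
        list(out = out, cache = list(x = x, d = d))
      } else if (l$k == 1L && l$stride == 1L) {
        xm <- matrix(x, nrow = C)
        out <- l$par$W %*% xm
        dim(out) <- c(l$out_ch, H, W, N)
        list(out = out, cache = list(xm = xm, d = d))
      } else if (l$k == 1L) {
        ih <- seq(1L, H, by = l$stride); iw <- seq(1L, W, by = l$stride)
        xs <- x[, ih, iw, , drop = FALSE]
        xm <- matrix(xs, nrow = C)
        out <- l$par$W %*% xm
        dim(out) <- c(l$out_ch, length(ih), length(iw), N)
        list(out = out, cache = list(xm = xm, d = d, ih = ih, iw = iw))
      } else {
        cols <- im2col_cpp(x, C, H, W, N, l$k, l$stride, l$pad)
        out <- l$par$W %*% cols
        oH <- (H + 2L * l$pad - l$k) %/% l$stride + 1L
        oW <- (W + 2L * l$pad - l$k) %/% l$stride + 1L
        dim(out) <- c(l$out_ch, oH, oW, N)
        list(out = out, cache = list(cols = cols, d = d))
      }
    },
    bn = {
      m <- matrix(x, nrow = C)
      if (isTRUE(training) || identical(training, "cumulative")) {
        mu <- rowMeans(m)
        xc <- m - mu
        v <- rowMeans(xc * xc)
        inv <- 1 / sqrt(v + BN_EPS)
        xhat <- xc * inv
        if (identical(training, "cumulative")) {
          # precise-BN pass: accumulate exact population moments E[x], E[x^2]
          # (batch-composition independent); rv temporarily holds E[x^2] and
          # is finalised to a variance by recalibrate_bn().
          mb <- ncol(m)
          w <- mb / (l$buf$n + mb)
          l$buf$rm <- (1 - w) * l$buf$rm + w * mu
          l$buf$rv <- (1 - w) * l$buf$rv + w * (v + mu^2)
          l$buf$n <- l$buf$n + mb
        } else {
          l$buf$rm <- (1 - BN_MOMENTUM) * l$buf$rm + BN_MOMENTUM * mu
          l$buf$rv <- (1 - BN_MOMENTUM) * l$buf$rv + BN_MOMENTUM * v
        }
      } else {
        inv <- 1 / sqrt(l$buf$rv + BN_EPS)
        xhat <- (m - l$buf$rm) * inv
      }
      out <- l$par$gamma * xhat + l$par$beta
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, inv = inv, d = d,
                                   training = isTRUE(training)),
           leaf = l)
    },
    act = {
      out <- switch(l$fun,
                    relu = pmax(x, 0),
                    prelu = ifelse(x > 0, x, l$par$alpha * x),
                    swish = x * sigmoid(x))
      dim(out) <- d
      list(out = out, cache = list(x = x))
    },
    eca = {
      y <- gap_cn(x)                       # C x N channel descriptors
      ypad <- rbind(matrix(0, (l$k - 1L) %/% 2L, N), y,
                    matrix(0, (l$k - 1L) %/% 2L, N))
      z <- matrix(0, C, N)
      for (j in seq_len(l$k)) z <- z + l$par$w[j] * ypad[seq_len(C) + j - 1L, , drop = FALSE]
      om <- sigmoid(z)
      mult <- om[, rep(seq_len(N), each = H * W), drop = FALSE]
      out <- matrix(x, nrow = C) * mult
      dim(out) <- d
      list(out = out, cache = list(x = x, ypad = ypad, om = om, d = d))
    },
    maxpool = {
      r <- maxpool_fw_cpp(x, C, H, W, N, l$k, l$stride, l$pad)
      oH <- (H + 2L * l$pad - l$k) %/% l$stride + 1L
      out <- r$out
      dim(out) <- c(C, oH, oH, N)
      list(out = out, cache = list(argmax = r$argmax, in_len = length(x), d = d))
    },
    gap = {
      out <- gap_cn(x)
      dim(out) <- c(C, 1L, 1L, N)
      list(out = out, cache = list(d = d))
    },
    fc = {
      xm <- matrix(x, nrow = C)
      out <- l$par$W %*% xm + l$par$b
      dim(out) <- c(l$out_n, 1L, 1L, N)
      list(out = out, cache = list(xm = xm))
    },
    stop("no forward for leaf kind ", l$kind, call. = FALSE)
  )
}

# Global average over the spatial dimensions -> C x N matrix.
gap_cn <- function(x) {
  d <- tensor_dims(x)
  hw <- d[2] * d[3]
  m <- matrix(x, nrow = d[1] * hw)
  y <- vapply(seq_len(d[4]), function(n) {
    rowMeans(matrix(m[, n], nrow = d[1]))
  }, numeric(d[1]))
  matrix(y, nrow = d[1])
}

# Backward ----------------------------------------------------------------------
# Returns list(dx = ..., grads = named list matching leaf$par).

leaf_bw <- function(l, cache, dout) {
  switch(
    l$kind,
    conv = {
      d <- cache$d
      C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
      dm <- matrix(dout, nrow = if (l$groups > 1L) C else l$out_ch)
      if (l$groups > 1L) {
        r <- depthwise_bw_cpp(as.numeric(dout), as.numeric(cache$x),
                              C, H, W, N, as.numeric(l$par$W),
                              l$k, l$stride, l$pad)
        dx <- r$dx; dim(dx) <- d
        dW <- r$dw; dim(dW) <- c(C, l$k, l$k)
        list(dx = dx, grads = list(W = dW))
      } else if (l$k == 1L && l$stride == 1L) {
        dW <- tcrossprod(dm, cache$xm)
        dx <- crossprod(l$par$W, dm)
        dim(dx) <- d
        list(dx = dx, grads = list(W = dW))
      } else if (l$k == 1L) {
        dW <- tcrossprod(dm, cache$xm)
        dxs <- crossprod(l$par$W, dm)
        dx <- array(0, dim = d)
        dim(dxs) <- c(C, length(cache$ih), length(cache$iw), N)
        dx[, cache$ih, cache$iw, ] <- dxs
        list(dx = dx, grads = list(W = dW))
      } else {
        dW <- tcrossprod(dm, cache$cols)
        dcols <- crossprod(l$par$W, dm)
        dx <- col2im_cpp(dcols, C, H, W, N, l$k, l$stride, l$pad)
        dim(dx) <- d
        list(dx = dx, grads = list(W = dW))
      }
    },
    bn = {
      C <- cache$d[1]
      m <- matrix(dout, nrow = C)
      dgamma <- rowSums(m * cache$xhat)
      dbeta <- rowSums(m)
      dxhat <- m * l$par$gamma
      if (cache$training) {
        M <- ncol(m)
        dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                             cache$xhat * rowMeans(dxhat * cache$xhat))
      } else {
        dx <- dxhat * cache$inv
      }
      dim(dx) <- cache$d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      x <- cache$x
      switch(
        l$fun,
        relu = list(dx = dout * (x > 0), grads = list()),
        prelu = {
          neg <- x <= 0
          dx <- dout * ifelse(neg, l$par$alpha, 1)
          dim(dx) <- dim(x)
          list(dx = dx, grads = list(alpha = sum(dout * x * neg)))
        },
        swish = {
          s <- sigmoid(x)
          dx <- dout * (s + x * s * (1 - s))
          dim(dx) <- dim(x)
          list(dx = dx, grads = list())
        }
      )
    },
    eca = {
      d <- cache$d
      C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
      mult <- cache$om[, rep(seq_len(N), each = HW), drop = FALSE]
      dm <- matrix(dout, nrow = C)
      dx <- dm * mult
      dom <- gap_cn(array(dm * matrix(cache$x, nrow = C), dim = d)) * HW
      dz <- dom * cache$om * (1 - cache$om)
      half <- (l$k - 1L) %/% 2L
      dw <- numeric(l$k)
      for (j in seq_len(l$k)) {
        dw[j] <- sum(dz * cache$ypad[seq_len(C) + j - 1L, , drop = FALSE])
      }
      # transpose of the zero-padded correlation = correlation with the
      # reversed kernel
      dzpad <- rbind(matrix(0, half, N), dz, matrix(0, half, N))
      dy <- matrix(0, C, N)
      for (j in seq_len(l$k)) {
        dy <- dy + rev(l$par$w)[j] * dzpad[seq_len(C) + j - 1L, , drop = FALSE]
      }
      dx <- dx + (dy / HW)[, rep(seq_len(N), each = HW), drop = FALSE]
      dim(dx) <- d
      list(dx = dx, grads = list(w = dw))
    },
    maxpool = {
      dx <- maxpool_bw_cpp(as.numeric(dout), cache$argmax, cache$in_len)
      dim(dx) <- cache$d
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$d
      HW <- d[2] * d[3]
      dm <- matrix(dout, nrow = d[1])
      dx <- (dm / HW)[, rep(seq_len(d[4]), each = HW), drop = FALSE]
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    fc = {
      dm <- matrix(dout, nrow = l$out_n)
      dW <- tcrossprod(dm, cache$xm)
      db <- rowSums(dm)
      dx <- crossprod(l$par$W, dm)
      dim(dx) <- c(l$in_n, 1L, 1L, ncol(dm))
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("no backward for leaf kind ", l$kind, call. = FALSE)
  )
}

# Materialise weights for a block specification (used standalone in tests and
# by build_model through the same init path).
init_block <- function(blk) {
  blk$branch <- lapply(blk$branch, init_leaf)
  blk$shortcut <- lapply(blk$shortcut, init_leaf)
  blk$post <- lapply(blk$post, init_leaf)
  blk
}

# Sequences and residual blocks --------------------------------------------------

seq_fw <- function(layers, x, training, capture_id = NULL, prefix = "") {
  caches <- vector("list", length(layers))
  captured <- NULL
  for (i in seq_along(layers)) {
    r <- leaf_fw(layers[[i]], x, training)
    if (!is.null(r$leaf)) layers[[i]] <- r$leaf  # BN running-stat update
    x <- r$out
    caches[[i]] <- r$cache
    id <- paste0(prefix, i)
    if (!is.null(capture_id) && identical(id, capture_id)) {
      captured <- list(id = id, out = x)
    }
  }
  list(out = x, caches = caches, layers = layers, captured = captured)
}

seq_bw <- function(layers, caches, dout, capture_id = NULL, prefix = "") {
  grads <- vector("list", length(layers))
  captured_grad <- NULL
  for (i in rev(seq_along(layers))) {
    id <- paste0(prefix, i)
    if (!is.null(capture_id) && identical(id, capture_id)) {
      captured_grad <- dout
    }
    r <- leaf_bw(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads, captured_grad = captured_grad)
}

block_fw <- function(blk, x, training, capture_id = NULL, prefix = "") {
  br <- seq_fw(blk$branch, x, training, capture_id, paste0(prefix, "branch."))
  blk$branch <- br$layers
  if (length(blk$shortcut)) {
    sc <- seq_fw(blk$shortcut, x, training, capture_id, paste0(prefix, "shortcut."))
    blk$shortcut <- sc$layers
    s_out <- sc$out; s_caches <- sc$caches
  } else {
    s_out <- x; s_caches <- NULL
  }
  added <- br$out + s_out
  po <- seq_fw(blk$post, added, training, capture_id, paste0(prefix, "post."))
  blk$post <- po$layers
  captured <- br$captured
  if (is.null(captured) && length(blk$shortcut) && !is.null(sc$captured)) captured <- sc$captured
  if (is.null(captured)) captured <- po$captured
  list(out = po$out, blk = blk,
       cache = list(branch = br$caches, shortcut = s_caches, post = po$caches),
       captured = captured)
}

block_bw <- function(blk, cache, dout, capture_id = NULL, prefix = "") {
  po <- seq_bw(blk$post, cache$post, dout, capture_id, paste0(prefix, "post."))
  dadd <- po$dx
  br <- seq_bw(blk$branch, cache$branch, dadd, capture_id, paste0(prefix, "branch."))
  if (length(blk$shortcut)) {
    sc <- seq_bw(blk$shortcut, cache$shortcut, dadd, capture_id,
                 paste0(prefix, "shortcut."))
    dx <- br$dx + sc$dx
    sgrads <- sc$grads
  } else {
    dx <- br$dx + dadd
    sgrads <- NULL
  }
  cg <- po$captured_grad
  if (is.null(cg)) cg <- br$captured_grad
  if (is.null(cg) && length(blk$shortcut)) cg <- sc$captured_grad
  list(dx = dx, grads = list(branch = br$grads, shortcut = sgrads,
                             post = po$grads),
       captured_grad = cg)
}
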