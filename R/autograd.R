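# Minimal reverse-mode automatic differentiation over 4-D arrays.
#
# Internal tensors are plain R arrays with dim (H, W, N, C): channel-last,
# so that a (H*W*N, C) matrix view is a free reshape and all channel-wise
# operations (softmax, batch norm, bias, concatenation) are cheap matrix
# column operations.  During a recorded forward pass every operation pushes
# a node (an environment) onto a global tape; backwardFromNode() replays
# the tape in reverse creation order and accumulates gradients into
# parameter environments.  Outside a tape the same op functions execute on
# raw arrays with no bookkeeping, which is the evaluation path.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$nodes <- NULL
.ag$n <- 0L
.ag$uid <- 0L

startTape <- function() {
  .ag$recording <- TRUE
  .ag$nodes <- vector("list", 256L)
  .ag$n <- 0L
}

stopTape <- function() {
  .ag$recording <- FALSE
  .ag$nodes <- NULL
  .ag$n <- 0L
}

agPush <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
  node$id <- n
  .ag$nodes[[n]] <- node
  .ag$n <- n
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a

agVal <- function(x) if (is.environment(x)) x$v else x

agNode <- function(v, parents = list(), bw = NULL) {
  if (!.ag$recording) return(v)
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$parents <- parents
  node$bw <- bw
  agPush(node)
}

agLeaf <- function(v) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$parents <- list()
  node$bw <- NULL
  if (.ag$recording) agPush(node) else node$id <- 0L
  node
}

isParam <- function(x) is.environment(x) && isTRUE(x$is_param)

newParam <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$grad <- array(0, dim(v) %||% length(v))
  p$is_param <- TRUE
  .ag$uid <- .ag$uid + 1L
  p$uid <- .ag$uid
  p
}

zeroGrad <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# Backpropagate from a scalar loss node.  Parameter parents accumulate into
# $grad; ordinary nodes are resolved through the tape in reverse order.
# `wrt` is an optional list of (leaf) nodes whose gradients are returned.
backwardFromNode <- function(loss, wrt = list()) {
  stopifnot(is.environment(loss), length(loss$v) == 1L)
  n <- .ag$n
  grads <- vector("list", n)
  grads[[loss$id]] <- 1
  for (i in seq.int(n, 1L)) {
    node <- .ag$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(node$bw)) next
    pg <- node$bw(g)
    for (j in seq_along(node$parents)) {
      par <- node$parents[[j]]
      gj <- pg[[j]]
      if (is.null(gj)) next
      if (isParam(par)) {
        par$grad <- par$grad + gj
      } else if (is.environment(par) && par$id > 0L) {
        grads[[par$id]] <- if (is.null(grads[[par$id]])) gj else grads[[par$id]] + gj
      }
    }
    grads[i] <- list(NULL)  # release as we walk back
  }
  if (length(wrt) == 0L) return(invisible(NULL))
  lapply(wrt, function(nd) grads[[nd$id]])
}

# shape helpers ---------------------------------------------------------------

# public arrays are (H, W[, C[, N]]); internal layout is (H, W, N, C)
pubToInt <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L, 1L); return(x) }
  if (length(d) == 3L) { dim(x) <- c(d, 1L) }
  aperm(x, c(1L, 2L, 4L, 3L))
}

intToPub <- function(x, like = NULL) {
  y <- aperm(x, c(1L, 2L, 4L, 3L))  # (H, W, C, N)
  if (!is.null(like)) dim(y) <- dim(like)
  y
}

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensional input")
  x
}

convOutSize <- function(n, k, stride, dil, pad) {
  as.integer((n + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L)
}

# matrix view over pixels x channels (free reshape)
pixMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

# core ops --------------------------------------------------------------------

# y = conv2d(x, w) + b; w has dim (kh, kw, Cin, Cout), b length Cout.
opConv <- function(x, w, b = NULL, stride = 1L, dil = 1L, pad = 0L) {
  xv <- agVal(x); wv <- agVal(w)
  d <- dim(xv); kd <- dim(wv)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  if (kd[3] != C) stop("channel mismatch in convolution: ", C, " vs ", kd[3])
  Ho <- convOutSize(H, kh, stride, dil, pad)
  Wo <- convOutSize(W, kw, stride, dil, pad)
  one <- kh == 1L && kw == 1L && stride == 1L && pad == 0L
  cols <- if (one) pixMat(xv)
          else im2col_cpp(xv, H, W, N, C, kh, kw, stride, dil, pad, Ho, Wo)
  wmat <- matrix(wv, nrow = kh * kw * C, ncol = Cout)
  y <- cols %*% wmat
  if (!is.null(b)) y <- sweep(y, 2L, agVal(b), "+")
  dim(y) <- c(Ho, Wo, N, Cout)
  if (!.ag$recording) return(y)
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  agNode(y, parents, function(g) {
    gmat <- g
    dim(gmat) <- c(Ho * Wo * N, Cout)
    dw <- array(crossprod(cols, gmat), dim = kd)
    dx <- if (one) {
      v <- gmat %*% t(wmat)
      dim(v) <- d
      v
    } else {
      col2im_cpp(gmat %*% t(wmat), H, W, N, C, kh, kw, stride, dil, pad, Ho, Wo)
    }
    out <- list(dx, dw)
    if (!is.null(b)) out <- c(out, list(colSums(gmat)))
    out
  })
}

# Transposed convolution fixed to the decoder geometry: kernel 3x3, stride 2,
# pad 1, output padding 1 -- exact spatial doubling.  w: (kh, kw, Cout, Cin).
opConvT <- function(x, w, b = NULL) {
  xv <- agVal(x); wv <- agVal(w)
  d <- dim(xv); kd <- dim(wv)
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[3]
  if (kd[4] != Cin) stop("channel mismatch in transposed convolution")
  Ho <- 2L * H; Wo <- 2L * W
  xmat <- pixMat(xv)
  wmat <- matrix(wv, nrow = kh * kw * Cout, ncol = Cin)
  y <- col2im_cpp(xmat %*% t(wmat), Ho, Wo, N, Cout, kh, kw, 2L, 1L, 1L, H, W)
  if (!is.null(b)) {
    ym <- pixMat(y)
    ym <- sweep(ym, 2L, agVal(b), "+")
    dim(ym) <- dim(y)
    y <- ym
  }
  if (!.ag$recording) return(y)
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  agNode(y, parents, function(g) {
    gcols <- im2col_cpp(g, Ho, Wo, N, Cout, kh, kw, 2L, 1L, 1L, H, W)
    dx <- gcols %*% wmat
    dim(dx) <- d
    dw <- array(crossprod(gcols, xmat), dim = kd)
    out <- list(dx, dw)
    if (!is.null(b)) out <- c(out, list(colSums(pixMat(g))))
    out
  })
}

opRelu <- function(x) {
  xv <- agVal(x)
  y <- pmax(xv, 0)
  if (!.ag$recording) return(y)
  agNode(y, list(x), function(g) list(g * (xv > 0)))
}

opAdd <- function(x, y) {
  v <- agVal(x) + agVal(y)
  if (!.ag$recording) return(v)
  agNode(v, list(x, y), function(g) list(g, g))
}

# Concatenate along the channel (last) dimension: a plain vector append.
opConcat <- function(xs) {
  vs <- lapply(xs, agVal)
  d <- dim(vs[[1]])
  chs <- vapply(vs, function(v) dim(v)[4], numeric(1))
  y <- array(unlist(vs, use.names = FALSE), c(d[1], d[2], d[3], sum(chs)))
  if (!.ag$recording) return(y)
  block <- d[1] * d[2] * d[3]
  ends <- cumsum(chs)
  agNode(y, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      v <- g[seq.int((ends[i] - chs[i]) * block + 1L, ends[i] * block)]
      dim(v) <- c(d[1], d[2], d[3], chs[i])
      v
    })
  })
}

# y[,,,k] = f[,,,k] * plane for every channel k (attention weighting);
# plane has a singleton channel dimension.
opScaleChannels <- function(f, plane) {
  fv <- agVal(f); pv <- agVal(plane)
  pvec <- as.numeric(pv)
  y <- pixMat(fv) * pvec  # column-wise recycling over channels
  dim(y) <- dim(fv)
  if (!.ag$recording) return(y)
  agNode(y, list(f, plane), function(g) {
    gm <- pixMat(g)
    df <- gm * pvec
    dim(df) <- dim(fv)
    dp <- rowSums(gm * pixMat(fv))
    dim(dp) <- dim(pv)
    list(df, dp)
  })
}

# Select one channel, keeping a singleton channel dimension.
opSliceChannel <- function(x, k) {
  xv <- agVal(x)
  d <- dim(xv)
  y <- xv[, , , k, drop = FALSE]
  if (!.ag$recording) return(y)
  agNode(y, list(x), function(g) {
    dx <- array(0, d)
    dx[, , , k] <- g
    list(dx)
  })
}

# Channel softmax (per-pixel probability simplex over C classes).
opSoftmax <- function(x) {
  xv <- agVal(x)
  d <- dim(xv)
  m <- pixMat(xv)
  mx <- m[, 1L]
  for (k in seq_len(d[4])[-1L]) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  if (!.ag$recording) return(p)
  pm <- p
  dim(pm) <- dim(m)
  agNode(p, list(x), function(g) {
    gm <- g
    dim(gm) <- dim(m)
    gp <- gm * pm
    dx <- gp - pm * rowSums(gp)
    dim(dx) <- d
    list(dx)
  })
}

# Inverted dropout; identity when not training.
opDropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- agVal(x)
  keep <- array(stats::rbinom(length(xv), 1L, 1 - rate), dim(xv)) / (1 - rate)
  y <- xv * keep
  if (!.ag$recording) return(y)
  agNode(y, list(x), function(g) list(g * keep))
}

# Nearest-neighbour upsampling by an integer factor (brings auxiliary
# decoder maps back to input resolution).
opUpsample <- function(x, factor) {
  xv <- agVal(x)
  d <- dim(xv)
  y <- xv[rep(seq_len(d[1]), each = factor),
          rep(seq_len(d[2]), each = factor), , , drop = FALSE]
  if (!.ag$recording) return(y)
  agNode(y, list(x), function(g) {
    dx <- array(0, d)
    for (a in seq_len(factor)) for (b in seq_len(factor)) {
      dx <- dx + g[seq(a, by = factor, length.out = d[1]),
                   seq(b, by = factor, length.out = d[2]), , , drop = FALSE]
    }
    list(dx)
  })
}

# Batch normalisation with running statistics (channel-wise over H, W, N).
# layer carries g/b parameters and plain-array running moments rm/rv.
opBatchNorm <- function(x, layer, training) {
  xv <- agVal(x)
  d <- dim(xv)
  eps <- 1e-5
  m <- pixMat(xv)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu, "-")
    va <- colMeans(xc^2)
    layer$rm <- 0.9 * layer$rm + 0.1 * mu
    layer$rv <- 0.9 * layer$rv + 0.1 * va
  } else {
    mu <- layer$rm
    va <- layer$rv
    xc <- sweep(m, 2L, mu, "-")
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, agVal(layer$g), "*"), 2L, agVal(layer$b), "+")
  dim(y) <- d
  if (!.ag$recording) return(y)
  n <- nrow(m)
  agNode(y, list(x, layer$g, layer$b), function(g) {
    gm <- g
    dim(gm) <- c(n, d[4])
    dg <- colSums(gm * xhat)
    db <- colSums(gm)
    gw <- sweep(gm, 2L, agVal(layer$g), "*")  # dL/dxhat
    if (training) {
      s1 <- colSums(gw)
      s2 <- colSums(gw * xhat)
      dx <- sweep(gw - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n),
                  2L, istd, "*")
    } else {
      dx <- sweep(gw, 2L, istd, "*")
    }
    dim(dx) <- d
    list(dx, dg, db)
  })
}

# Per-pixel, per-category binary cross entropy against one-hot labels,
# averaged over categories, pixels and batch; probabilities clamped to
# [eps, 1 - eps] before the logarithms.
opPixelCE <- function(p, onehot, eps = 1e-7) {
  pv <- agVal(p)
  q <- pmin(pmax(pv, eps), 1 - eps)
  nn <- length(q)
  v <- -sum(onehot * log(q) + (1 - onehot) * log(1 - q)) / nn
  if (!.ag$recording) return(v)
  inside <- (pv > eps) & (pv < 1 - eps)
  agNode(v, list(p), function(g) {
    list(g * (-(onehot / q - (1 - onehot) / (1 - q)) / nn) * inside)
  })
}

# Weighted sum of scalar loss nodes.
opScalarComb <- function(xs, wts) {
  v <- 0
  for (i in seq_along(xs)) v <- v + wts[i] * agVal(xs[[i]])
  if (!.ag$recording) return(v)
  agNode(v, xs, function(g) lapply(wts, function(w) g * w))
}
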