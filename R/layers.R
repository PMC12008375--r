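# Layer and block constructors for the segmentation network.  A layer is a
# list tagged with $kind whose parameter environments are discovered
# recursively by collectParams(); weight sharing between branches therefore
# falls out of reusing the same layer list in two places.

heInit <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

newConv <- function(kh, kw, cin, cout, stride = 1L, dil = 1L, pad = NULL) {
  if (is.null(pad)) pad <- dil * (kh - 1L) %/% 2L  # 'same' padding
  list(kind = "conv",
       w = newParam(heInit(kh, kw, cin, cout)),
       b = newParam(numeric(cout)),
       stride = as.integer(stride), dil = as.integer(dil), pad = as.integer(pad),
       cin = cin, cout = cout)
}

# transposed 3x3, stride 2: exact spatial doubling
newConvT <- function(cin, cout) {
  list(kind = "convT",
       w = newParam(heInit(3L, 3L, cout, cin)),
       b = newParam(numeric(cout)),
       cin = cin, cout = cout)
}

newBN <- function(ch) {
  e <- new.env(parent = emptyenv())
  e$g <- newParam(rep(1, ch))
  e$b <- newParam(numeric(ch))
  e$rm <- numeric(ch)
  e$rv <- rep(1, ch)
  list(kind = "bn", env = e, ch = ch)
}

fwdConv <- function(layer, x) opConv(x, layer$w, layer$b, layer$stride, layer$dil, layer$pad)
fwdConvT <- function(layer, x) opConvT(x, layer$w, layer$b)
fwdBN <- function(layer, x, training) opBatchNorm(x, layer$env, training)

# Conv(1x1) + BN + ReLU
newCBR <- function(cin, cout) {
  list(kind = "cbr", conv = newConv(1L, 1L, cin, cout), bn = newBN(cout))
}
fwdCBR <- function(blk, x, training) opRelu(fwdBN(blk$bn, fwdConv(blk$conv, x), training))

# Conv(3x3, dilated) + BN + ReLU + Dropout
newCBRD <- function(cin, cout, dil, dropout) {
  list(kind = "cbrd", conv = newConv(3L, 3L, cin, cout, dil = dil),
       bn = newBN(cout), dropout = dropout)
}
fwdCBRD <- function(blk, x, training) {
  opDropout(opRelu(fwdBN(blk$bn, fwdConv(blk$conv, x), training)), blk$dropout, training)
}

# Two 3x3 conv+BN+ReLU stages (the plain U-Net block).
newDoubleConv <- function(cin, cout) {
  list(kind = "double",
       c1 = newConv(3L, 3L, cin, cout), b1 = newBN(cout),
       c2 = newConv(3L, 3L, cout, cout), b2 = newBN(cout))
}
fwdDoubleConv <- function(blk, x, training) {
  h <- opRelu(fwdBN(blk$b1, fwdConv(blk$c1, x), training))
  opRelu(fwdBN(blk$b2, fwdConv(blk$c2, h), training))
}

# Residual block: two 3x3 convs with identity shortcut.
newResidual <- function(ch) {
  list(kind = "residual",
       c1 = newConv(3L, 3L, ch, ch), b1 = newBN(ch),
       c2 = newConv(3L, 3L, ch, ch), b2 = newBN(ch))
}
fwdResidual <- function(blk, x, training) {
  h <- opRelu(fwdBN(blk$b1, fwdConv(blk$c1, x), training))
  h <- fwdBN(blk$b2, fwdConv(blk$c2, h), training)
  opRelu(opAdd(h, x))
}

# 2x2 stride-2 convolution used for downsampling between encoder stages.
newDown <- function(cin, cout) {
  list(kind = "down", conv = newConv(2L, 2L, cin, cout, stride = 2L, pad = 0L),
       bn = newBN(cout))
}
fwdDown <- function(blk, x, training) opRelu(fwdBN(blk$bn, fwdConv(blk$conv, x), training))

# parameter bookkeeping -------------------------------------------------------

# Depth-first walk over nested lists/environments collecting unique
# parameter environments (shared layers are collected once, keyed by uid).
collectParams <- function(obj) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  walk <- function(x) {
    if (isParam(x)) {
      key <- as.character(x$uid)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- x
      }
    } else if (is.environment(x)) {
      for (nm in ls(x)) if (nm %in% c("g", "b")) walk(x[[nm]])
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(obj)
  out
}

# All batch-norm environments (for running-statistics checkpointing).
collectBNs <- function(obj) {
  out <- list()
  walk <- function(x) {
    if (is.list(x)) {
      if (identical(x$kind, "bn")) out[[length(out) + 1L]] <<- x$env
      for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(obj)
  out
}

# Adam ------------------------------------------------------------------------

newAdam <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$kind <- "adam"
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st
}

newSGD <- function(params, lr = 5e-4) {
  st <- new.env(parent = emptyenv())
  st$kind <- "sgd"
  st$params <- params
  st$lr <- lr
  st
}

optStep <- function(st) {
  if (st$kind == "sgd") {
    for (p in st$params) p$v <- p$v - st$lr * p$grad
    return(invisible(NULL))
  }
  adamStep(st)
}

adamStep <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$v <- p$v - st$lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + st$eps)
  }
  invisible(NULL)
}
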