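#' @useDynLib vesselseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---- reverse-mode tape -------------------------------------------------------
#
# Activations are numeric arrays dim c(H, W, C, N). A tape records operation
# nodes in execution order; backward() walks them in reverse. Each node is an
# environment with $val, $grad, $parents and $bwd so gradients accumulate by
# reference without copying the graph.

newTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

tnode <- function(tape, val, parents = list(), bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tvar <- function(tape, val) tnode(tape, val)

accumGrad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation over a tape
#'
#' Seeds the terminal node with gradient 1 and propagates gradients to every
#' recorded node in reverse execution order.
#' @param tape tape created by the forward pass
#' @param node terminal (scalar loss) node
#' @keywords internal
backwardTape <- function(tape, node) {
  node$grad <- array(1, dim = dim(node$val))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd)
  }
  invisible(NULL)
}

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# ---- primitive ops -----------------------------------------------------------

agConv2d <- function(tape, x, w, stride = 1L, pad = 0L, groups = 1L) {
  y <- cpp_conv2d_fwd(x$val, w$val, as.integer(stride), as.integer(pad),
                      as.integer(groups))
  tnode(tape, y, list(x = x, w = w), bwd = function(nd) {
    g <- cpp_conv2d_bwd(nd$parents$x$val, nd$parents$w$val, nd$grad,
                        as.integer(stride), as.integer(pad), as.integer(groups))
    accumGrad(nd$parents$x, g$gx)
    accumGrad(nd$parents$w, g$gw)
  })
}

# per-output-channel bias; b is a length-Cout vector node
agBias <- function(tape, x, b) {
  d <- dim4(x$val)
  y <- x$val + rep(b$val, each = d[1] * d[2])
  tnode(tape, y, list(x = x, b = b), bwd = function(nd) {
    d <- dim4(nd$grad)
    accumGrad(nd$parents$x, nd$grad)
    gb <- colSums(matrix(nd$grad, nrow = d[1] * d[2]))
    gb <- rowSums(matrix(gb, nrow = d[3]))
    accumGrad(nd$parents$b, gb)
  })
}

agRelu <- function(tape, x) {
  y <- x$val * (x$val > 0)
  tnode(tape, y, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, nd$grad * (nd$parents$x$val > 0))
  })
}

agSigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$val))
  nd <- tnode(tape, y, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, nd$grad * nd$val * (1 - nd$val))
  })
  nd
}

agAdd <- function(tape, a, b) {
  tnode(tape, a$val + b$val, list(a = a, b = b), bwd = function(nd) {
    accumGrad(nd$parents$a, nd$grad)
    accumGrad(nd$parents$b, nd$grad)
  })
}

# elementwise product with broadcasting of s over dims where dim(s) == 1
broadcastTo <- function(s, d) {
  ds <- dim4(s)
  if (all(ds == d)) return(s)
  out <- s
  if (ds[1] == 1L && d[1] > 1L || ds[2] == 1L && d[2] > 1L) {
    # spatial broadcast: s is (1,1,C,N)
    out <- array(rep(as.vector(s), each = d[1] * d[2]), dim = d)
  } else if (ds[3] == 1L && d[3] > 1L) {
    # channel broadcast: s is (H,W,1,N)
    out <- array(0, dim = d)
    for (n in seq_len(d[4])) out[, , , n] <- array(s[, , 1, n], dim = d[1:3])
  } else stop("unsupported broadcast")
  out
}

reduceToShape <- function(g, ds) {
  d <- dim4(g)
  if (all(ds == d)) return(g)
  if (ds[1] == 1L && ds[2] == 1L) {
    r <- colSums(matrix(g, nrow = d[1] * d[2]))
    return(array(r, dim = c(1L, 1L, d[3], d[4])))
  }
  if (ds[3] == 1L) {
    r <- array(0, dim = c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) r[, , 1, n] <- apply(g[, , , n, drop = FALSE], c(1, 2), sum)
    return(r)
  }
  stop("unsupported broadcast reduction")
}

agMulB <- function(tape, x, s) {
  d <- dim4(x$val)
  sb <- broadcastTo(s$val, d)
  tnode(tape, x$val * sb, list(x = x, s = s), bwd = function(nd) {
    d <- dim4(nd$parents$x$val)
    sb <- broadcastTo(nd$parents$s$val, d)
    accumGrad(nd$parents$x, nd$grad * sb)
    gs <- reduceToShape(nd$grad * nd$parents$x$val, dim4(nd$parents$s$val))
    accumGrad(nd$parents$s, gs)
  })
}

agAddB <- function(tape, x, s) {
  d <- dim4(x$val)
  sb <- broadcastTo(s$val, d)
  tnode(tape, x$val + sb, list(x = x, s = s), bwd = function(nd) {
    accumGrad(nd$parents$x, nd$grad)
    accumGrad(nd$parents$s, reduceToShape(nd$grad, dim4(nd$parents$s$val)))
  })
}

agMaxPool2 <- function(tape, x) {
  r <- cpp_maxpool2_fwd(x$val)
  xdim <- dim4(x$val)
  tnode(tape, r$y, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, cpp_maxpool2_bwd(nd$grad, r$idx, as.integer(xdim)))
  })
}

agAdaptiveAvgPool <- function(tape, x, oh, ow) {
  xdim <- dim4(x$val)
  y <- cpp_adaptive_avgpool_fwd(x$val, as.integer(oh), as.integer(ow))
  tnode(tape, y, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, cpp_adaptive_avgpool_bwd(nd$grad, as.integer(xdim)))
  })
}

agBilinear <- function(tape, x, oh, ow) {
  xdim <- dim4(x$val)
  y <- cpp_bilinear_fwd(x$val, as.integer(oh), as.integer(ow))
  tnode(tape, y, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, cpp_bilinear_bwd(nd$grad, as.integer(xdim)))
  })
}

agConcatC <- function(tape, xs) {
  d1 <- dim4(xs[[1]]$val)
  cs <- vapply(xs, function(x) dim4(x$val)[3], integer(1))
  Ct <- sum(cs)
  y <- array(0, dim = c(d1[1], d1[2], Ct, d1[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim4(x$val)[3]
    y[, , off + seq_len(ci), ] <- x$val
    off <- off + ci
  }
  tnode(tape, y, xs, bwd = function(nd) {
    off <- 0L
    for (x in nd$parents) {
      ci <- dim4(x$val)[3]
      accumGrad(x, nd$grad[, , off + seq_len(ci), , drop = FALSE])
      off <- off + ci
    }
  })
}

# Batch normalization. `state` is an environment carrying running_mean,
# running_var and momentum; training mode uses batch statistics and updates
# the running estimates, eval mode uses the stored ones.
agBatchNorm <- function(tape, x, gamma, beta, state, training, eps = 1e-5) {
  d <- dim4(x$val)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x$val, c(1, 2, 4, 3)), ncol = d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2) # biased variance, as used for normalization
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    unb <- if (m > 1) va * m / (m - 1) else va
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma$val, `*`), 2, beta$val, `+`)
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  tnode(tape, y, list(x = x, gamma = gamma, beta = beta), bwd = function(nd) {
    gym <- matrix(aperm(nd$grad, c(1, 2, 4, 3)), ncol = d[3])
    dgamma <- colSums(gym * xhat)
    dbeta <- colSums(gym)
    accumGrad(nd$parents$gamma, dgamma)
    accumGrad(nd$parents$beta, dbeta)
    if (training) {
      gxh <- sweep(gym, 2, gamma$val, `*`)
      t1 <- sweep(gxh, 2, colMeans(gxh))
      t2 <- sweep(xhat, 2, colMeans(gxh * xhat), `*`)
      gxm <- sweep(t1 - t2, 2, istd, `*`)
    } else {
      gxm <- sweep(sweep(gym, 2, gamma$val, `*`), 2, istd, `*`)
    }
    gx <- aperm(array(gxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    accumGrad(nd$parents$x, gx)
  })
}

# Pixelwise softmax cross-entropy against an integer class map (H,W,N) with
# values in 0..C-1; returns a scalar node (mean over pixels and batch).
agSoftmaxCE <- function(tape, logits, target) {
  d <- dim4(logits$val)
  C <- d[3]
  lm <- matrix(aperm(logits$val, c(1, 2, 4, 3)), ncol = C)
  mx <- do.call(pmax, lapply(seq_len(C), function(j) lm[, j]))
  ex <- exp(lm - mx)
  se <- rowSums(ex)
  p <- ex / se
  ti <- as.integer(target) + 1L
  npix <- nrow(lm)
  picked <- p[cbind(seq_len(npix), ti)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  tnode(tape, array(loss, dim = c(1, 1, 1, 1)), list(x = logits), bwd = function(nd) {
    g <- p
    g[cbind(seq_len(npix), ti)] <- g[cbind(seq_len(npix), ti)] - 1
    g <- g * (as.numeric(nd$grad) / npix)
    gx <- aperm(array(g, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    accumGrad(nd$parents$x, gx)
  })
}

# scale a node by a fixed scalar constant
agScale <- function(tape, x, k) {
  tnode(tape, x$val * k, list(x = x), bwd = function(nd) {
    accumGrad(nd$parents$x, nd$grad * k)
  })
}

# broadcast a (1,1,C,N) or (H,W,1,N) node to full shape d
agBroadcast <- function(tape, s, d) {
  tnode(tape, broadcastTo(s$val, d), list(s = s), bwd = function(nd) {
    accumGrad(nd$parents$s, reduceToShape(nd$grad, dim4(nd$parents$s$val)))
  })
}
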