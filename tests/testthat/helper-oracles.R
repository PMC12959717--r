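# Independent scalar-loop reference implementations used as oracles.
# These deliberately avoid the package's C++ kernels: plain R loops only.

naiveConv2d <- function(x, w, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x) # H W C N
  kh <- dim(w)[1]; kw <- dim(w)[2]; cg <- dim(w)[3]; cout <- dim(w)[4]
  coutg <- cout / groups
  Ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    g <- (co - 1) %/% coutg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cg)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
        hi <- (ho - 1) * stride - pad + i
        wi <- (wo - 1) * stride - pad + j
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          acc <- acc + x[hi, wi, g * cg + ci, n] * w[i, j, ci, co]
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

naiveBilinear <- function(x, oh, ow) {
  d <- dim(x)
  y <- array(0, c(oh, ow, d[3], d[4]))
  coef <- function(i, In, Out) {
    src <- max((i - 0.5) * In / Out - 0.5, 0)
    i0 <- min(floor(src), In - 1)
    i1 <- min(i0 + 1, In - 1)
    l <- if (i1 == i0) 0 else src - i0
    c(i0 + 1, i1 + 1, l)
  }
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      a <- coef(i, d[1], oh); b <- coef(j, d[2], ow)
      y[i, j, c, n] <-
        (1 - a[3]) * (1 - b[3]) * x[a[1], b[1], c, n] +
        a[3] * (1 - b[3]) * x[a[2], b[1], c, n] +
        (1 - a[3]) * b[3] * x[a[1], b[2], c, n] +
        a[3] * b[3] * x[a[2], b[2], c, n]
    }
  y
}

naiveAdaptivePool <- function(x, oh, ow) {
  d <- dim(x)
  y <- array(0, c(oh, ow, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      h0 <- floor((i - 1) * d[1] / oh) + 1
      h1 <- ceiling(i * d[1] / oh)
      w0 <- floor((j - 1) * d[2] / ow) + 1
      w1 <- ceiling(j * d[2] / ow)
      y[i, j, c, n] <- mean(x[h0:h1, w0:w1, c, n])
    }
  y
}

naiveBnEval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3]))
    y[, , c, ] <- gamma[c] * (x[, , c, , drop = FALSE] - rm[c]) /
      sqrt(rv[c] + eps) + beta[c]
  y
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full DSCAM pipeline (pool 2x2 -> depthwise 2x2 -> pointwise -> BN eval ->
# sigmoid -> rescale) in scalar loops, for a raw (unwrapped) dscamLayer.
dscamOracle <- function(layer, x) {
  p <- naiveAdaptivePool(x, 2L, 2L)
  dlog <- naiveConv2d(p, layer$dw$par$w, groups = layer$c)
  plog <- naiveConv2d(dlog, layer$pw$par$w)
  st <- layer$bn$state
  blog <- naiveBnEval(plog, layer$bn$par$gamma, layer$bn$par$beta,
                      st$running_mean, st$running_var)
  s <- sigmoid(blog) # 1 x 1 x C x N
  y <- x
  for (n in seq_len(dim(x)[4])) for (c in seq_len(dim(x)[3]))
    y[, , c, n] <- x[, , c, n] * s[1, 1, c, n]
  y
}

dscamLogitsOracle <- function(layer, x) {
  p <- naiveAdaptivePool(x, 2L, 2L)
  dlog <- naiveConv2d(p, layer$dw$par$w, groups = layer$c)
  plog <- naiveConv2d(dlog, layer$pw$par$w)
  st <- layer$bn$state
  naiveBnEval(plog, layer$bn$par$gamma, layer$bn$par$beta,
              st$running_mean, st$running_var)
}

# Parallel-sum DSCBAM pipeline in scalar loops.
dscbamOracle <- function(layer, x) {
  cl <- dscamLogitsOracle(layer$ch, x) # 1 x 1 x C x N
  sp <- naiveConv2d(x, layer$sdw$par$w, pad = 1L, groups = layer$c)
  sp <- naiveConv2d(sp, layer$spw$par$w) # H x W x 1 x N
  st <- layer$sbn$state
  sl <- naiveBnEval(sp, layer$sbn$par$gamma, layer$sbn$par$beta,
                    st$running_mean, st$running_var)
  y <- x
  d <- dim(x)
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      wgt <- sigmoid(cl[1, 1, c, n] + sl[i, j, 1, n])
      y[i, j, c, n] <- x[i, j, c, n] * wgt
    }
  y
}

# Plain ResNet basic block (no attention), scalar composition.
plainBlockOracle <- function(layer, x) {
  h <- naiveConv2d(x, layer$conv1$par$w, stride = layer$stride, pad = 1L)
  st <- layer$bn1$state
  h <- naiveBnEval(h, layer$bn1$par$gamma, layer$bn1$par$beta,
                   st$running_mean, st$running_var)
  h <- pmax(h, 0)
  h <- naiveConv2d(h, layer$conv2$par$w, pad = 1L)
  st <- layer$bn2$state
  h <- naiveBnEval(h, layer$bn2$par$gamma, layer$bn2$par$beta,
                   st$running_mean, st$running_var)
  s <- if (layer$projected) {
    p <- naiveConv2d(x, layer$proj$par$w, stride = layer$stride)
    st <- layer$bnp$state
    naiveBnEval(p, layer$bnp$par$gamma, layer$bnp$par$beta,
                st$running_mean, st$running_var)
  } else x
  pmax(h + s, 0)
}

# set every parameter array of a layer tree to a constant (default 0)
zeroParams <- function(layer, value = 0) {
  ps <- vesselseg:::collectParams(layer)
  for (nm in names(ps)) ps[[nm]] <- ps[[nm]] * 0 + value
  vesselseg:::assignParams(layer, ps)
}
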