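#' @include ops-autograd.R
NULL

# Layer constructors and forward passes for the building blocks:
# DSCAM channel attention, DSCAM-enhanced residual blocks and the parallel
# channel/spatial skip attention (DSCBAM).
#
# A layer is a plain list: $type, structural metadata, $par (named list of
# numeric arrays holding learnable parameters) and optionally $state
# (environment with batch-norm running statistics). Before a forward pass the
# parameter arrays are wrapped into tape nodes (see wrapParams) so that one
# persistent node per parameter collects gradients.

heInit <- function(k, cinpg, cout, groups = 1L) {
  fan_in <- k * k * cinpg
  array(stats::rnorm(k * k * cinpg * cout, sd = sqrt(2 / fan_in)),
        dim = c(k, k, cinpg, cout))
}

convLayer <- function(cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                      bias = FALSE) {
  par <- list(w = heInit(k, cin %/% groups, cout))
  if (bias) par$b <- numeric(cout)
  list(type = "conv", cin = cin, cout = cout, k = k, stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups), bias = bias, par = par)
}

bnLayer <- function(c) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(c)
  state$running_var <- rep(1, c)
  state$momentum <- 0.1
  list(type = "bn", c = c, par = list(gamma = rep(1, c), beta = numeric(c)),
       state = state)
}

#' Depthwise-separable channel attention module (DSCAM)
#'
#' Builds the channel-attention block used inside the enhanced residual
#' blocks: adaptive average pooling to 2x2, a depthwise 2x2 convolution
#' collapsing the pooled patch to one value per channel, a pointwise 1x1
#' convolution restoring cross-channel interaction, batch normalization and a
#' sigmoid. The resulting per-channel weights rescale the input map.
#'
#' @param channels number of feature channels the module attends over
#' @return a layer list usable with [dscamForward()]
#' @export
dscamLayer <- function(channels) {
  list(type = "dscam", c = channels,
       dw = convLayer(channels, channels, 2L, groups = channels),
       pw = convLayer(channels, channels, 1L),
       bn = bnLayer(channels))
}

# Shared DSCAM pipeline up to the pre-sigmoid logits (steps a-d).
dscamLogits <- function(tape, layer, x, training) {
  p <- agAdaptiveAvgPool(tape, x, 2L, 2L)
  d <- convApply(tape, layer$dw, p)
  z <- convApply(tape, layer$pw, d)
  bnApply(tape, layer$bn, z, training)
}

#' Apply DSCAM channel attention to a feature map
#'
#' @param tape autodiff tape (or NULL outside training)
#' @param layer layer built by [dscamLayer()] whose parameters were wrapped
#'   into tape nodes
#' @param x input node with value dim c(H, W, C, N); H, W >= 2
#' @param training logical; batch-norm mode
#' @return node whose value is the attended feature map, same shape as `x`
#' @keywords internal
dscamApply <- function(tape, layer, x, training) {
  d <- dim4(x$val)
  if (d[1] < 2L || d[2] < 2L)
    stop("DSCAM requires spatial dimensions >= 2, got ", d[1], "x", d[2])
  if (d[3] != layer$c)
    stop("DSCAM channel mismatch: input has ", d[3], ", module expects ", layer$c)
  s <- agSigmoid(tape, dscamLogits(tape, layer, x, training))
  agMulB(tape, x, s)
}

#' Enhanced residual basic block
#'
#' A ResNet basic block (two 3x3 convolutions with batch normalization) whose
#' main branch is rescaled by DSCAM channel attention before the residual
#' addition. `stride = 1` with equal channel counts gives the identity
#' shortcut form (BasicBlock1); `stride = 2` or a channel change gives the
#' projection shortcut form (BasicBlock2).
#'
#' @param cin,cout input/output channel counts
#' @param stride 1 or 2
#' @param attention logical; disable to recover the plain ResNet block
#' @return a layer list usable with [blockForward()]
#' @export
basicBlock <- function(cin, cout, stride = 1L, attention = TRUE) {
  projected <- (stride != 1L || cin != cout)
  l <- list(type = "block", cin = cin, cout = cout, stride = as.integer(stride),
            projected = projected, attention = attention,
            conv1 = convLayer(cin, cout, 3L, stride = stride, pad = 1L),
            bn1 = bnLayer(cout),
            conv2 = convLayer(cout, cout, 3L, pad = 1L),
            bn2 = bnLayer(cout))
  if (attention) l$att <- dscamLayer(cout)
  if (projected) {
    l$proj <- convLayer(cin, cout, 1L, stride = stride)
    l$bnp <- bnLayer(cout)
  }
  l
}

blockApply <- function(tape, layer, x, training) {
  if (dim4(x$val)[3] != layer$cin)
    stop("basic block expects ", layer$cin, " input channels")
  h <- convApply(tape, layer$conv1, x)
  h <- agRelu(tape, bnApply(tape, layer$bn1, h, training))
  h <- convApply(tape, layer$conv2, h)
  h <- bnApply(tape, layer$bn2, h, training)
  if (layer$attention) h <- dscamApply(tape, layer$att, h, training)
  s <- if (layer$projected) {
    bnApply(tape, layer$bnp, convApply(tape, layer$proj, x), training)
  } else x
  agRelu(tape, agAdd(tape, h, s))
}

#' Parallel channel/spatial skip attention (DSCBAM)
#'
#' Skip-connection attention combining a DSCAM-style channel branch with a
#' depthwise-separable spatial branch (depthwise 3x3, pointwise to one
#' channel, batch normalization). The two pre-sigmoid logit maps are broadcast
#' to the input shape, summed point-to-point, passed through a single sigmoid
#' and multiplied with the input. No channel concatenation is involved.
#'
#' @param channels number of feature channels
#' @return a layer list usable with [dscbamForward()]
#' @export
dscbamLayer <- function(channels) {
  list(type = "dscbam", c = channels,
       ch = dscamLayer(channels),
       sdw = convLayer(channels, channels, 3L, pad = 1L, groups = channels),
       spw = convLayer(channels, 1L, 1L),
       sbn = bnLayer(1L))
}

dscbamApply <- function(tape, layer, x, training) {
  d <- dim4(x$val)
  if (d[1] < 2L || d[2] < 2L)
    stop("DSCBAM requires spatial dimensions >= 2")
  cl <- dscamLogits(tape, layer$ch, x, training)              # (1,1,C,N)
  s <- convApply(tape, layer$sdw, x)
  s <- convApply(tape, layer$spw, s)                          # (H,W,1,N)
  sl <- bnApply(tape, layer$sbn, s, training)
  z <- agAdd(tape, agBroadcast(tape, cl, d), agBroadcast(tape, sl, d))
  agMulB(tape, x, agSigmoid(tape, z))
}

convApply <- function(tape, layer, x) {
  qmode <- layer$qmode
  if (identical(qmode, "int8")) {
    qs <- layer$qstate
    xq <- pmin(pmax(round(x$val / qs$sx) + qs$zx, 0), 255)
    acc <- cpp_conv2d_fwd(xq - qs$zx, layer$qint, layer$stride, layer$pad,
                          layer$groups)
    y <- acc * (qs$sx * qs$sw)
    if (!is.null(layer$qbias)) {
      d <- dim4(y)
      y <- y + rep(layer$qbias, each = d[1] * d[2])
    }
    return(tnode(tape, y))
  }
  if (identical(qmode, "collect")) {
    qs <- layer$qstate
    qs$min <- min(qs$min, min(x$val))
    qs$max <- max(qs$max, max(x$val))
  }
  y <- agConv2d(tape, x, layer$par$w, stride = layer$stride, pad = layer$pad,
                groups = layer$groups)
  if (isTRUE(layer$bias)) y <- agBias(tape, y, layer$par$b)
  y
}

bnApply <- function(tape, layer, x, training) {
  if (isTRUE(layer$identity)) return(x)
  agBatchNorm(tape, x, layer$par$gamma, layer$par$beta, layer$state, training)
}

# ---- parameter bookkeeping ---------------------------------------------------

# Child keys of a layer list: element names where present, indices otherwise;
# $par, $state and scalar metadata are handled separately by each walker.
childKeys <- function(layer) {
  nms <- names(layer)
  keys <- as.list(seq_along(layer))
  if (!is.null(nms)) {
    for (i in seq_along(layer)) if (nzchar(nms[i])) keys[[i]] <- nms[i]
  }
  keys
}

isChild <- function(layer, key) {
  if (is.character(key) && key %in% c("par", "state", "type")) return(FALSE)
  is.list(layer[[key]])
}

# Recursively wrap every array under $par into a tape node, in place.
# Returns the list of created nodes (named by path) via the `reg` environment.
wrapParams <- function(tape, layer, reg, path = "") {
  if (!is.list(layer)) return(layer)
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) {
      nd <- tvar(tape, layer$par[[nm]])
      reg$nodes[[paste0(path, "/", nm)]] <- nd
      layer$par[[nm]] <- nd
    }
  }
  for (key in childKeys(layer)) {
    if (isChild(layer, key))
      layer[[key]] <- wrapParams(tape, layer[[key]], reg, paste0(path, "/", key))
  }
  layer
}

# Collect all parameter arrays of a (nested) layer list, named by path.
collectParams <- function(layer, path = "") {
  out <- list()
  if (!is.list(layer)) return(out)
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) out[[paste0(path, "/", nm)]] <- layer$par[[nm]]
  }
  for (key in childKeys(layer)) {
    if (isChild(layer, key))
      out <- c(out, collectParams(layer[[key]], paste0(path, "/", key)))
  }
  out
}

# Write updated arrays (same naming scheme) back into a layer list.
assignParams <- function(layer, values, path = "") {
  if (!is.list(layer)) return(layer)
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) {
      key <- paste0(path, "/", nm)
      if (!is.null(values[[key]])) layer$par[[nm]] <- values[[key]]
    }
  }
  for (key in childKeys(layer)) {
    if (isChild(layer, key))
      layer[[key]] <- assignParams(layer[[key]], values, paste0(path, "/", key))
  }
  layer
}

# Deep-copy batch-norm state environments so that model copies are independent.
cloneStates <- function(layer) {
  if (!is.list(layer)) return(layer)
  if (!is.null(layer$state)) {
    s <- new.env(parent = emptyenv())
    for (nm in ls(layer$state)) assign(nm, get(nm, layer$state), s)
    layer$state <- s
  }
  for (key in childKeys(layer)) {
    if (isChild(layer, key)) layer[[key]] <- cloneStates(layer[[key]])
  }
  layer
}
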