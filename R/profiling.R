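#' @include network.R
NULL

# Analytic parameter and multiply-accumulate profiling.
#
# Counting convention: a convolution contributes
#   params = Cout * (Cin/groups) * kh * kw (+ Cout if biased)
#   MACs   = Cout * Hout * Wout * (Cin/groups) * kh * kw
# (transposed convolutions analogously, output-based). Batch normalization
# contributes 2C parameters and no MACs; biases, activations, pooling,
# bilinear resizing and elementwise operations contribute no MACs. Under this
# convention the classic U-Net baseline at 512x512 anchors the scale
# ("FLOPs" in the reference tables are MACs).

emptyGraph <- function() {
  data.frame(layer = character(), type = character(), cin = integer(),
             cout = integer(), k = integer(), stride = integer(),
             groups = integer(), bias = logical(), hout = integer(),
             wout = integer(), params = numeric(), macs = numeric(),
             stringsAsFactors = FALSE)
}

gConv <- function(name, cin, cout, k, h, w, stride = 1L, groups = 1L,
                  bias = FALSE, type = "conv") {
  p <- cout * (cin %/% groups) * k * k + if (bias) cout else 0L
  m <- as.numeric(cout) * h * w * (cin %/% groups) * k * k
  data.frame(layer = name, type = type, cin = cin, cout = cout, k = k,
             stride = stride, groups = groups, bias = bias, hout = h, wout = w,
             params = p, macs = m, stringsAsFactors = FALSE)
}

gBn <- function(name, c, h, w) {
  data.frame(layer = name, type = "bn", cin = c, cout = c, k = 0L, stride = 1L,
             groups = 1L, bias = FALSE, hout = h, wout = w, params = 2 * c,
             macs = 0, stringsAsFactors = FALSE)
}

gDscam <- function(name, c, h, w) {
  rbind(gConv(paste0(name, ".dw"), c, c, 2L, 1L, 1L, groups = c),
        gConv(paste0(name, ".pw"), c, c, 1L, 1L, 1L),
        gBn(paste0(name, ".bn"), c, 1L, 1L))
}

gBlock <- function(name, cin, cout, h, w, stride, attention) {
  g <- rbind(gConv(paste0(name, ".conv1"), cin, cout, 3L, h, w, stride = stride),
             gBn(paste0(name, ".bn1"), cout, h, w),
             gConv(paste0(name, ".conv2"), cout, cout, 3L, h, w),
             gBn(paste0(name, ".bn2"), cout, h, w))
  if (attention) g <- rbind(g, gDscam(paste0(name, ".att"), cout, h, w))
  if (stride != 1L || cin != cout) {
    g <- rbind(g, gConv(paste0(name, ".proj"), cin, cout, 1L, h, w,
                        stride = stride),
               gBn(paste0(name, ".bnp"), cout, h, w))
  }
  g
}

gDscbam <- function(name, c, h, w) {
  rbind(gDscam(paste0(name, ".ch"), c, h, w),
        gConv(paste0(name, ".sdw"), c, c, 3L, h, w, groups = c),
        gConv(paste0(name, ".spw"), c, 1L, 1L, h, w),
        gBn(paste0(name, ".sbn"), 1L, h, w))
}

#' Layer graph of a network configuration
#'
#' Enumerates every parameterized layer of the network variant described by
#' `config` for a given input size, with per-layer parameter and MAC counts.
#' The auxiliary branch is excluded unless `includeAux = TRUE` because it is
#' detached at inference.
#'
#' @param config a [NetworkConfig-class]
#' @param inputSize input height/width (divisible by 32); a single number or
#'   length-2 vector
#' @param includeAux include the train-only auxiliary head
#' @return data.frame with one row per layer and columns `params`, `macs`
#' @export
layerGraph <- function(config, inputSize = 512L, includeAux = FALSE) {
  sz <- as.integer(rep(inputSize, length.out = 2L))
  H <- sz[1]; W <- sz[2]
  sw <- config@stageWidths
  g <- rbind(
    gConv("stem.conv1", config@inputChannels, config@stemWidth, 3L, H, W),
    gBn("stem.bn1", config@stemWidth, H, W),
    gConv("stem.conv2", config@stemWidth, config@stemWidth, 3L, H, W),
    gBn("stem.bn2", config@stemWidth, H, W))
  cin <- config@stemWidth
  h <- H; w <- W
  for (i in 1:4) {
    h <- h %/% 2L; w <- w %/% 2L
    g <- rbind(g, gBlock(sprintf("stage%d.block1", i), cin, sw[i], h, w, 2L,
                         config@blockAttention))
    if (config@blocksPerStage > 1L) {
      for (b in 2:config@blocksPerStage) {
        g <- rbind(g, gBlock(sprintf("stage%d.block%d", i, b), sw[i], sw[i],
                             h, w, 1L, config@blockAttention))
      }
    }
    cin <- sw[i]
  }
  h <- h %/% 2L; w <- w %/% 2L
  if (config@enableHighSemantic) {
    Whs <- config@highSemanticWidth
    g <- rbind(g, gBlock("highsem.block1", sw[4], Whs, h, w, 2L,
                         config@blockAttention),
               gConv("highsem.fc1", Whs, config@contextWidth, 1L, 1L, 1L,
                     bias = TRUE),
               gConv("highsem.fc2", config@contextWidth, Whs, 1L, 1L, 1L,
                     bias = TRUE))
    c32 <- Whs
  } else {
    c32 <- sw[4] # plain max-pool reduction, no parameters
  }
  if (config@enableSkipAttention) {
    hh <- H; ww <- W
    for (i in 1:4) {
      hh <- hh %/% 2L; ww <- ww %/% 2L
      g <- rbind(g, gDscbam(sprintf("skipatt%d", i), sw[i], hh, ww))
    }
    if (config@enableHighSemantic)
      g <- rbind(g, gDscbam("skipatt.deep", c32, hh %/% 2L, ww %/% 2L))
  }
  cprev <- c32
  dw <- config@decoderWidths
  hh <- H %/% 32L; ww <- W %/% 32L
  for (j in 1:4) {
    s <- 5L - j
    hh <- hh * 2L; ww <- ww * 2L
    g <- rbind(g,
               gConv(sprintf("decoder%d.lat", j), cprev, sw[s], 1L, hh, ww),
               gBn(sprintf("decoder%d.bnl", j), sw[s], hh, ww),
               gConv(sprintf("decoder%d.ref", j), sw[s], dw[j], 3L, hh, ww),
               gBn(sprintf("decoder%d.bnr", j), dw[j], hh, ww))
    cprev <- dw[j]
  }
  g <- rbind(g, gConv("head", dw[4], config@numClasses, 1L, H, W, bias = TRUE))
  if (includeAux && config@enableAux) {
    auxin <- sum(sw) + c32 + dw[4]
    g <- rbind(g, gConv("aux", auxin, config@numClasses, 1L, H, W, bias = TRUE))
  }
  g
}

#' Layer graph of the classic U-Net baseline
#'
#' The 4-level U-Net used as the profiling baseline: two 3x3 convolutions
#' (batch-normalized, bias-free) per level with widths 64/128/256/512/1024,
#' 2x2 max pooling, 2x2-stride-2 transposed-convolution upsampling (biased),
#' channel concatenation, and a biased 1x1 two-class head.
#'
#' @param inputSize input height/width
#' @param numClasses classes of the 1x1 head
#' @param widths encoder widths per level
#' @return data.frame as in [layerGraph()]
#' @export
unetGraph <- function(inputSize = 512L, numClasses = 2L,
                      widths = c(64L, 128L, 256L, 512L, 1024L)) {
  sz <- as.integer(rep(inputSize, length.out = 2L))
  H <- sz[1]; W <- sz[2]
  g <- emptyGraph()
  cin <- 3L
  h <- H; w <- W
  for (i in seq_along(widths)) {
    if (i > 1L) { h <- h %/% 2L; w <- w %/% 2L }
    wd <- widths[i]
    g <- rbind(g,
               gConv(sprintf("enc%d.conv1", i), cin, wd, 3L, h, w),
               gBn(sprintf("enc%d.bn1", i), wd, h, w),
               gConv(sprintf("enc%d.conv2", i), wd, wd, 3L, h, w),
               gBn(sprintf("enc%d.bn2", i), wd, h, w))
    cin <- wd
  }
  up <- rev(widths[-length(widths)])
  for (j in seq_along(up)) {
    wd <- up[j]
    h <- h * 2L; w <- w * 2L
    g <- rbind(g,
               gConv(sprintf("up%d.tconv", j), cin, wd, 2L, h, w, stride = 2L,
                     bias = TRUE, type = "tconv"),
               gConv(sprintf("dec%d.conv1", j), 2L * wd, wd, 3L, h, w),
               gBn(sprintf("dec%d.bn1", j), wd, h, w),
               gConv(sprintf("dec%d.conv2", j), wd, wd, 3L, h, w),
               gBn(sprintf("dec%d.bn2", j), wd, h, w))
    cin <- wd
  }
  rbind(g, gConv("head", cin, numClasses, 1L, H, W, bias = TRUE))
}

#' @title Model profile
#' @description Parameter and MAC totals with the per-layer breakdown for a
#' stated input size.
#' @slot params total trainable parameters
#' @slot macs total multiply-accumulates for the stated input
#' @slot inputSize input height and width
#' @slot perLayer per-layer table
#' @export
setClass("ModelProfile", representation(params = "numeric", macs = "numeric",
                                        inputSize = "integer",
                                        perLayer = "data.frame"))

setValidity("ModelProfile", function(object) {
  ok1 <- isTRUE(all.equal(object@params, sum(object@perLayer$params)))
  ok2 <- isTRUE(all.equal(object@macs, sum(object@perLayer$macs)))
  if (ok1 && ok2) TRUE else "totals must equal the per-layer sums"
})

setMethod("show", "ModelProfile", function(object) {
  cat(sprintf("ModelProfile @ %dx%d: %.2fM params, %.2fG MACs (%d layers)\n",
              object@inputSize[1], object@inputSize[2], object@params / 1e6,
              object@macs / 1e9, nrow(object@perLayer)))
})

#' Profile a model or layer graph
#'
#' @param x a [VesselNet-class], [NetworkConfig-class] or a layer-graph
#'   data.frame from [layerGraph()] / [unetGraph()]
#' @param inputSize input height/width used for MAC counting
#' @param includeAux include the train-only auxiliary branch (profiles are
#'   inference-mode by default)
#' @return a [ModelProfile-class]
#' @examples
#' p <- modelProfile(unetGraph(64L))
#' p@params
#' @export
modelProfile <- function(x, inputSize = 512L, includeAux = FALSE) {
  g <- if (is.data.frame(x)) {
    x
  } else if (is(x, "VesselNet")) {
    layerGraph(x@config, inputSize, includeAux)
  } else if (is(x, "NetworkConfig")) {
    layerGraph(x, inputSize, includeAux)
  } else stop("cannot profile object of class ", class(x)[1])
  sz <- if (is.data.frame(x)) {
    as.integer(rep(max(x$hout), 2L))
  } else as.integer(rep(inputSize, length.out = 2L))
  new("ModelProfile", params = sum(g$params), macs = sum(g$macs),
      inputSize = sz, perLayer = g)
}

#' Count trainable parameters
#'
#' For a fitted [VesselNet-class] the count sums the actual parameter arrays
#' (weights, biases, batch-norm affine terms), excluding the auxiliary head
#' unless requested; the result equals the analytic [layerGraph()] total.
#'
#' @param model a [VesselNet-class], [NetworkConfig-class] or layer graph
#' @param includeAux include the train-only auxiliary branch
#' @return parameter count (numeric)
#' @export
countParams <- function(model, includeAux = FALSE) {
  if (is(model, "VesselNet")) {
    L <- model@layers
    if (!includeAux) L$aux <- NULL
    return(sum(vapply(collectParams(L), length, numeric(1))))
  }
  modelProfile(model, includeAux = includeAux)@params
}

#' Count multiply-accumulates for a stated input size
#'
#' @inheritParams countParams
#' @param inputSize input height/width (single number or length-2)
#' @return MAC count (numeric)
#' @export
countMacs <- function(model, inputSize = 512L, includeAux = FALSE) {
  if (is(model, "VesselNet")) model <- model@config
  modelProfile(model, inputSize = inputSize, includeAux = includeAux)@macs
}
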