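#' @include layers.R
NULL

# Assembly of the full segmentation network: encoder with enhanced residual
# stages and the high-semantic 1/32 stage, attention-gated skips, bilinear
# add-fusion decoder and the train-only auxiliary multi-scale branch.

#' @title Network configuration
#'
#' @description S4 container describing one network variant. The three
#' `enable*` switches reproduce the structural ablation grid: the base
#' encoder-decoder (all off), the added high-semantic 32x stage with global
#' context, the skip attention gates, and the train-only auxiliary branch.
#'
#' @slot inputChannels number of image channels (3 for RGB histology tiles)
#' @slot numClasses number of output classes (2: background / vessel)
#' @slot stemWidth width of the full-resolution stem
#' @slot stageWidths widths of the four strided residual stages (strides 2-16)
#' @slot blocksPerStage residual blocks per stage
#' @slot highSemanticWidth width of the added 1/32 high-semantic stage
#' @slot contextWidth bottleneck width of the global-context MLP
#' @slot decoderWidths decoder refinement widths at strides 16, 8, 4, 2
#' @slot enableHighSemantic use the high-semantic stage (else plain max-pool)
#' @slot enableSkipAttention gate skip connections with DSCBAM
#' @slot enableAux build the auxiliary segmentation branch (training only)
#' @slot blockAttention use DSCAM inside residual blocks (FALSE recovers the
#'   plain ResNet block, used for regression tests)
#' @export
setClass("NetworkConfig", representation(
  inputChannels = "integer", numClasses = "integer", stemWidth = "integer",
  stageWidths = "integer", blocksPerStage = "integer",
  highSemanticWidth = "integer", contextWidth = "integer",
  decoderWidths = "integer", enableHighSemantic = "logical",
  enableSkipAttention = "logical", enableAux = "logical",
  blockAttention = "logical"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@stageWidths) != 4L) msg <- c(msg, "stageWidths must have length 4")
  if (length(object@decoderWidths) != 4L) msg <- c(msg, "decoderWidths must have length 4")
  if (any(c(object@stageWidths, object@decoderWidths, object@stemWidth,
            object@highSemanticWidth, object@contextWidth) <= 0L))
    msg <- c(msg, "all widths must be positive")
  if (object@numClasses < 2L) msg <- c(msg, "numClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Create a network configuration
#'
#' Defaults are the reference configuration whose inference-mode profile
#' reproduces the published budget table (28.37M parameters / 65.23G MACs at
#' 512x512 with everything enabled; 13.28M / 61.79G for the base
#' encoder-decoder). The widths were calibrated against those budgets; see the
#' methods vignette.
#'
#' @param inputChannels,numClasses,stemWidth,stageWidths,blocksPerStage
#'   architecture sizes, see [NetworkConfig-class]
#' @param highSemanticWidth,contextWidth,decoderWidths calibrated widths
#' @param enableHighSemantic,enableSkipAttention,enableAux ablation switches
#' @param blockAttention DSCAM inside residual blocks
#' @return a [NetworkConfig-class] object
#' @examples
#' cfg <- networkConfig(stageWidths = c(8L, 12L, 16L, 24L),
#'                      stemWidth = 8L, highSemanticWidth = 32L,
#'                      contextWidth = 8L, decoderWidths = c(16L, 12L, 8L, 8L))
#' cfg
#' @export
networkConfig <- function(inputChannels = 3L, numClasses = 2L,
                          stemWidth = 64L,
                          stageWidths = c(64L, 128L, 256L, 450L),
                          blocksPerStage = 2L,
                          highSemanticWidth = 942L,
                          contextWidth = 286L,
                          decoderWidths = c(472L, 304L, 112L, 236L),
                          enableHighSemantic = TRUE,
                          enableSkipAttention = TRUE,
                          enableAux = TRUE,
                          blockAttention = TRUE) {
  new("NetworkConfig",
      inputChannels = as.integer(inputChannels),
      numClasses = as.integer(numClasses),
      stemWidth = as.integer(stemWidth),
      stageWidths = as.integer(stageWidths),
      blocksPerStage = as.integer(blocksPerStage),
      highSemanticWidth = as.integer(highSemanticWidth),
      contextWidth = as.integer(contextWidth),
      decoderWidths = as.integer(decoderWidths),
      enableHighSemantic = isTRUE(enableHighSemantic),
      enableSkipAttention = isTRUE(enableSkipAttention),
      enableAux = isTRUE(enableAux),
      blockAttention = isTRUE(blockAttention))
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", object@inputChannels, "->", object@numClasses, "classes\n")
  cat("  stem", object@stemWidth, "| stages",
      paste(object@stageWidths, collapse = "/"),
      "x", object@blocksPerStage, "blocks\n")
  cat("  high-semantic", object@highSemanticWidth,
      "(context", object@contextWidth, ")",
      if (object@enableHighSemantic) "on" else "off", "\n")
  cat("  decoder", paste(object@decoderWidths, collapse = "/"),
      "| skip attention", if (object@enableSkipAttention) "on" else "off",
      "| aux", if (object@enableAux) "on" else "off", "\n")
})

#' @title Segmentation network
#' @description S4 wrapper around the layer tree of one network instance.
#' Use [vesselNet()] to construct, [netForward()] / [predictMask()] to run,
#' [trainNet()] to fit, and [countParams()] / [countMacs()] to profile.
#' @slot config the [NetworkConfig-class] used to build the model
#' @slot layers nested list of layers with parameter arrays
#' @export
setClass("VesselNet", representation(config = "NetworkConfig", layers = "list"))

#' Build a segmentation network
#'
#' @param config a [NetworkConfig-class]; defaults to the reference
#'   configuration
#' @param seed integer seed for weight initialization
#' @return a [VesselNet-class] model
#' @examples
#' cfg <- networkConfig(stageWidths = c(4L, 8L, 8L, 8L), stemWidth = 4L,
#'                      highSemanticWidth = 8L, contextWidth = 4L,
#'                      decoderWidths = c(8L, 8L, 4L, 4L))
#' net <- vesselNet(cfg, seed = 1)
#' out <- netForward(net, array(0.5, c(64, 64, 3, 1)))
#' dim(out$logits)
#' @export
vesselNet <- function(config = networkConfig(), seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  set.seed(seed)
  sw <- config@stageWidths
  L <- list()
  L$stem <- list(
    conv1 = convLayer(config@inputChannels, config@stemWidth, 3L, pad = 1L),
    bn1 = bnLayer(config@stemWidth),
    conv2 = convLayer(config@stemWidth, config@stemWidth, 3L, pad = 1L),
    bn2 = bnLayer(config@stemWidth))
  cin <- config@stemWidth
  stages <- list()
  for (i in 1:4) {
    blocks <- list(basicBlock(cin, sw[i], stride = 2L,
                              attention = config@blockAttention))
    if (config@blocksPerStage > 1L) {
      for (b in 2:config@blocksPerStage) {
        blocks[[b]] <- basicBlock(sw[i], sw[i],
                                  attention = config@blockAttention)
      }
    }
    stages[[i]] <- blocks
    cin <- sw[i]
  }
  L$stages <- stages
  if (config@enableHighSemantic) {
    W <- config@highSemanticWidth
    L$hs <- list(block = basicBlock(sw[4], W, stride = 2L,
                                    attention = config@blockAttention),
                 fc1 = convLayer(W, config@contextWidth, 1L, bias = TRUE),
                 fc2 = convLayer(config@contextWidth, W, 1L, bias = TRUE))
  }
  c32 <- if (config@enableHighSemantic) config@highSemanticWidth else sw[4]
  if (config@enableSkipAttention) {
    L$skipatt <- lapply(sw, dscbamLayer)
    if (config@enableHighSemantic) L$skipatt$deep <- dscbamLayer(c32)
  }
  dw <- config@decoderWidths
  dec <- list()
  cprev <- c32
  for (s in 4:1) {
    dec[[5 - s]] <- list(
      lat = convLayer(cprev, sw[s], 1L), bnl = bnLayer(sw[s]),
      ref = convLayer(sw[s], dw[5 - s], 3L, pad = 1L), bnr = bnLayer(dw[5 - s]))
    cprev <- dw[5 - s]
  }
  L$decoder <- dec
  L$head <- convLayer(dw[4], config@numClasses, 1L, bias = TRUE)
  if (config@enableAux) {
    auxin <- sum(sw) + c32 + dw[4]
    L$aux <- convLayer(auxin, config@numClasses, 1L, bias = TRUE)
  }
  new("VesselNet", config = config, layers = L)
}

setMethod("show", "VesselNet", function(object) {
  np <- sum(vapply(collectParams(object@layers), length, numeric(1)))
  cat("VesselNet with", format(np, big.mark = ","), "parameters\n")
  show(object@config)
})

# ---- forward pass ------------------------------------------------------------

# Encoder: returns list of skip maps p1..p4 (strides 2..16), the deepest map
# p5 (stride 32) and, with the high-semantic stage, the pooled global context.
encodeNodes <- function(tape, L, config, x, training) {
  h <- convApply(tape, L$stem$conv1, x)
  h <- agRelu(tape, bnApply(tape, L$stem$bn1, h, training))
  h <- convApply(tape, L$stem$conv2, h)
  h <- agRelu(tape, bnApply(tape, L$stem$bn2, h, training))
  pyr <- list()
  for (i in 1:4) {
    for (blk in L$stages[[i]]) h <- blockApply(tape, blk, h, training)
    pyr[[i]] <- h
  }
  ctx <- NULL
  if (config@enableHighSemantic) {
    h <- blockApply(tape, L$hs$block, h, training)
    ctx <- agAdaptiveAvgPool(tape, h, 1L, 1L) # global context = channel means
    g <- agRelu(tape, convApply(tape, L$hs$fc1, ctx))
    h <- agAddB(tape, h, convApply(tape, L$hs$fc2, g))
  } else {
    h <- agMaxPool2(tape, h)
  }
  pyr[[5]] <- h
  list(pyramid = pyr, context = ctx)
}

attendNodes <- function(tape, L, config, pyr, training) {
  if (!config@enableSkipAttention) return(pyr)
  for (i in 1:4) pyr[[i]] <- dscbamApply(tape, L$skipatt[[i]], pyr[[i]], training)
  if (config@enableHighSemantic)
    pyr[[5]] <- dscbamApply(tape, L$skipatt$deep, pyr[[5]], training)
  pyr
}

# Decoder: repeated [bilinear 2x -> 1x1 channel match -> BN -> ReLU -> add
# skip -> 3x3 refine -> BN -> ReLU], then a final bilinear 2x and 1x1 head.
# Returns full-resolution class logits plus the last decoder feature map
# (input to the auxiliary branch). No transposed convolutions anywhere.
decodeNodes <- function(tape, L, config, pyr, training, H, W) {
  h <- pyr[[5]]
  for (j in 1:4) {
    s <- 5 - j
    skip <- pyr[[s]]
    d <- dim4(skip$val)
    h <- agBilinear(tape, h, d[1], d[2])
    h <- convApply(tape, L$decoder[[j]]$lat, h)
    h <- agRelu(tape, bnApply(tape, L$decoder[[j]]$bnl, h, training))
    h <- agAdd(tape, h, skip)
    h <- convApply(tape, L$decoder[[j]]$ref, h)
    h <- agRelu(tape, bnApply(tape, L$decoder[[j]]$bnr, h, training))
  }
  feat <- h
  h <- agBilinear(tape, h, H, W)
  logits <- convApply(tape, L$head, h)
  list(logits = logits, feat = feat)
}

auxNodes <- function(tape, L, pyr, feat, H, W) {
  maps <- c(pyr, list(feat))
  up <- lapply(maps, function(m) agBilinear(tape, m, H, W))
  convApply(tape, L$aux, agConcatC(tape, up))
}

#' Run the network forward
#'
#' Composes encoder, skip attention, decoder and (in training mode, when
#' enabled) the auxiliary multi-scale branch. In inference mode the auxiliary
#' branch is detached and contributes neither compute nor parameters.
#'
#' @param model a [VesselNet-class]
#' @param x numeric array dim c(H, W, C, N) (or c(H, W, C) for one image)
#'   with H and W divisible by 32
#' @param training logical; enables batch-statistics normalization and the
#'   auxiliary branch
#' @return list with `logits` (H x W x numClasses x N array) and, in training
#'   mode with the branch enabled, `aux` of the same shape
#' @export
netForward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim4(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial dimensions must be divisible by 32; pad ",
         d[1], "x", d[2], " up to ",
         32L * ceiling(d[1] / 32), "x", 32L * ceiling(d[2] / 32))
  if (d[1] < 64L || d[2] < 64L)
    stop("input spatial dimensions must be at least 64 so the deepest ",
         "(1/32-scale) map keeps the 2x2 support the attention pooling needs")
  cfg <- model@config
  if (d[3] != cfg@inputChannels) stop("input channel mismatch")
  tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  L <- wrapParams(tape, model@layers, reg)
  xn <- tvar(tape, x)
  enc <- encodeNodes(tape, L, cfg, xn, training)
  att <- attendNodes(tape, L, cfg, enc$pyramid, training)
  dec <- decodeNodes(tape, L, cfg, att, training, d[1], d[2])
  out <- list(logits = dec$logits$val)
  if (training && cfg@enableAux)
    out$aux <- auxNodes(tape, L, att, dec$feat, d[1], d[2])$val
  out
}

# Internal graph-building variant used by the training loop: returns nodes.
netForwardNodes <- function(tape, model, x, training, reg) {
  d <- dim4(x)
  cfg <- model@config
  L <- wrapParams(tape, model@layers, reg)
  xn <- tvar(tape, x)
  enc <- encodeNodes(tape, L, cfg, xn, training)
  att <- attendNodes(tape, L, cfg, enc$pyramid, training)
  dec <- decodeNodes(tape, L, cfg, att, training, d[1], d[2])
  aux <- NULL
  if (training && cfg@enableAux) aux <- auxNodes(tape, L, att, dec$feat, d[1], d[2])
  list(logits = dec$logits, aux = aux, pyramid = att, context = enc$context)
}

#' Encode an image into the feature pyramid
#'
#' Exposes the encoder alone: maps at strides 2, 4, 8, 16, 32 plus the global
#' context vector when the high-semantic stage is enabled.
#'
#' @inheritParams netForward
#' @return list with `pyramid` (list of 5 arrays) and `context` (1 x 1 x
#'   highSemanticWidth x N array or NULL)
#' @export
encodeFeatures <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  L <- wrapParams(tape, model@layers, reg)
  enc <- encodeNodes(tape, L, model@config, tvar(tape, x), training)
  list(pyramid = lapply(enc$pyramid, function(n) n$val),
       context = if (is.null(enc$context)) NULL else enc$context$val)
}

#' Apply skip attention to a feature pyramid
#'
#' @param model a [VesselNet-class]
#' @param pyramid list of 5 arrays as returned by [encodeFeatures()]
#' @param training logical
#' @return the attended pyramid (identical when skip attention is disabled)
#' @export
attendSkips <- function(model, pyramid, training = FALSE) {
  tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  L <- wrapParams(tape, model@layers, reg)
  nodes <- lapply(pyramid, function(p) {
    if (length(dim(p)) == 3L) dim(p) <- c(dim(p), 1L)
    tvar(tape, p)
  })
  att <- attendNodes(tape, L, model@config, nodes, training)
  lapply(att, function(n) n$val)
}

# ---- user-facing single-module forwards -------------------------------------

asBatch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Run a DSCAM module on a feature map
#' @param layer module from [dscamLayer()]
#' @param x array dim c(H, W, C) or c(H, W, C, N)
#' @param training logical batch-norm mode
#' @return attended array, same shape as input
#' @export
dscamForward <- function(layer, x, training = FALSE) {
  xb <- asBatch(x); tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  lw <- wrapParams(tape, layer, reg)
  y <- dscamApply(tape, lw, tvar(tape, xb), training)$val
  if (length(dim(x)) == 3L) dim(y) <- dim(x)
  y
}

#' Run a DSCBAM module on a feature map
#' @inheritParams dscamForward
#' @param layer module from [dscbamLayer()]
#' @return attended array, same shape as input
#' @export
dscbamForward <- function(layer, x, training = FALSE) {
  xb <- asBatch(x); tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  lw <- wrapParams(tape, layer, reg)
  y <- dscbamApply(tape, lw, tvar(tape, xb), training)$val
  if (length(dim(x)) == 3L) dim(y) <- dim(x)
  y
}

#' Run an enhanced residual block on a feature map
#' @inheritParams dscamForward
#' @param layer block from [basicBlock()]
#' @return output array; spatial size divided by the block stride
#' @export
blockForward <- function(layer, x, training = FALSE) {
  xb <- asBatch(x); tape <- newTape()
  reg <- new.env(); reg$nodes <- list()
  lw <- wrapParams(tape, layer, reg)
  y <- blockApply(tape, lw, tvar(tape, xb), training)$val
  if (length(dim(x)) == 3L) dim(y) <- dim(y)[1:3]
  y
}
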