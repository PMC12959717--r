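#' @include network.R
NULL

# Model compression: L2-ranked structured channel pruning (deepest layers
# first), conv-BN fusion, and INT8 post-training static quantization with
# min/max calibration.

# Paths into the layer tree are lists mixing names and integer indices.
getByPath <- function(L, path) Reduce(function(a, k) a[[k]], path, L)

setByPath <- function(L, path, value) {
  if (length(path) == 1L) {
    L[[path[[1]]]] <- value
    return(L)
  }
  L[[path[[1]]]] <- setByPath(L[[path[[1]]]], path[-1], value)
  L
}

pathLeaf <- function(path) path[[length(path)]]

#' Rank convolution output channels by L2 norm
#'
#' Channel importance for structured pruning: output channels sorted by
#' decreasing L2 norm of their filter slice, ties broken by lower index.
#'
#' @param w convolution weight array dim c(kh, kw, cin/groups, cout)
#' @return integer vector of channel indices (1-based), most important first
#' @examples
#' w <- array(0, c(1, 1, 1, 3)); w[1, 1, 1, ] <- c(3, 1, 2)
#' channelImportanceL2(w) # 1 3 2
#' @export
channelImportanceL2 <- function(w) {
  stopifnot(length(dim(w)) == 4L)
  cout <- dim(w)[4]
  norms <- vapply(seq_len(cout), function(co) sqrt(sum(w[, , , co]^2)),
                  numeric(1))
  order(-norms, seq_len(cout))
}

# Enumerate the prunable convolutions of a model in topological order
# (input to output). A convolution is prunable when its output width is a
# free internal width: the first convolution of each residual block, the
# context bottleneck, and the decoder refinement convolutions. Widths tied to
# residual shortcuts or to the add-fusion with skip maps are skipped.
# Each entry: conv path, associated BN path (or NULL), consumer conv paths
# (convs whose input channels must be remapped), and optional aux-offset.
prunableLayers <- function(model) {
  cfg <- model@config
  L <- model@layers
  out <- list()
  add <- function(conv, bn, consumers, auxOffset = NULL) {
    out[[length(out) + 1L]] <<- list(conv = conv, bn = bn,
                                     consumers = consumers,
                                     auxOffset = auxOffset)
  }
  add(list("stem", "conv1"), list("stem", "bn1"), list(list("stem", "conv2")))
  for (i in 1:4) {
    for (b in seq_along(L$stages[[i]])) {
      add(list("stages", i, b, "conv1"), list("stages", i, b, "bn1"),
          list(list("stages", i, b, "conv2")))
    }
  }
  if (cfg@enableHighSemantic) {
    add(list("hs", "block", "conv1"), list("hs", "block", "bn1"),
        list(list("hs", "block", "conv2")))
    add(list("hs", "fc1"), NULL, list(list("hs", "fc2")))
  }
  for (j in 1:4) {
    cons <- if (j < 4L) list(list("decoder", j + 1L, "lat")) else {
      cs <- list(list("head"))
      if (cfg@enableAux) cs <- c(cs, list(list("aux")))
      cs
    }
    auxOff <- if (j == 4L && cfg@enableAux) {
      sum(cfg@stageWidths) +
        (if (cfg@enableHighSemantic) cfg@highSemanticWidth else cfg@stageWidths[4])
    } else NULL
    add(list("decoder", j, "ref"), list("decoder", j, "bnr"), cons, auxOff)
  }
  out
}

#' @title Structured pruning plan
#' @description Per-layer kept-channel indices for the selected deepest
#' prunable layers, at a global keep ratio.
#' @slot layers list of prunable-layer descriptors (conv/bn/consumer paths)
#' @slot keep list of sorted kept-channel index vectors, parallel to `layers`
#' @slot keepRatio the global keep ratio in (0, 1]
#' @export
setClass("PruningPlan", representation(layers = "list", keep = "list",
                                       keepRatio = "numeric"))

setMethod("show", "PruningPlan", function(object) {
  cat(sprintf("PruningPlan: %d layers at keep ratio %.2f\n",
              length(object@layers), object@keepRatio))
  for (i in seq_along(object@layers)) {
    cat("  ", paste(object@layers[[i]]$conv, collapse = "$"), ": keep",
        length(object@keep[[i]]), "channels\n")
  }
})

#' Build a structured pruning plan
#'
#' Selects the `nLayers` prunable convolutions deepest in topological order
#' (farthest from the input) and keeps the top `ceil(keepRatio * C)` output
#' channels of each by L2 importance.
#'
#' @param model a [VesselNet-class]
#' @param keepRatio fraction of channels to keep, in (0, 1]
#' @param nLayers how many of the deepest prunable layers to prune
#' @return a [PruningPlan-class]
#' @export
buildPrunePlan <- function(model, keepRatio, nLayers = 4L) {
  if (keepRatio <= 0 || keepRatio > 1)
    stop("keepRatio must be in (0, 1]")
  pl <- prunableLayers(model)
  nLayers <- min(nLayers, length(pl))
  sel <- pl[seq(length(pl) - nLayers + 1L, length(pl))]
  keep <- lapply(sel, function(e) {
    w <- getByPath(model@layers, e$conv)$par$w
    C <- dim(w)[4]
    if (C < 2L) stop("cannot prune a layer with fewer than 2 channels")
    k <- ceiling(keepRatio * C)
    sort(channelImportanceL2(w)[seq_len(k)])
  })
  new("PruningPlan", layers = sel, keep = keep, keepRatio = keepRatio)
}

sliceBn <- function(bn, keep) {
  bn$par$gamma <- bn$par$gamma[keep]
  bn$par$beta <- bn$par$beta[keep]
  bn$c <- length(keep)
  s <- new.env(parent = emptyenv())
  s$running_mean <- bn$state$running_mean[keep]
  s$running_var <- bn$state$running_var[keep]
  s$momentum <- bn$state$momentum
  bn$state <- s
  bn
}

#' Apply a pruning plan (dense rebuild)
#'
#' Physically removes the dropped output channels of each planned layer,
#' slices the associated batch-norm parameters and running statistics, and
#' remaps the input channels of every consumer convolution. The result is a
#' smaller dense, runnable model; with `keepRatio = 1` the model is
#' unchanged.
#'
#' @param model a [VesselNet-class]
#' @param plan a [PruningPlan-class] from [buildPrunePlan()]
#' @return the pruned [VesselNet-class]
#' @export
applyPrune <- function(model, plan) {
  L <- cloneStates(model@layers)
  for (i in seq_along(plan@layers)) {
    e <- plan@layers[[i]]
    keep <- plan@keep[[i]]
    conv <- getByPath(L, e$conv)
    conv$par$w <- conv$par$w[, , , keep, drop = FALSE]
    if (isTRUE(conv$bias)) conv$par$b <- conv$par$b[keep]
    conv$cout <- length(keep)
    L <- setByPath(L, e$conv, conv)
    if (!is.null(e$bn)) L <- setByPath(L, e$bn, sliceBn(getByPath(L, e$bn), keep))
    for (cp in e$consumers) {
      cons <- getByPath(L, cp)
      newIn <- if (identical(pathLeaf(cp), "aux")) {
        # concatenated input: remap only this map's channel span
        oldC <- dim(getByPath(model@layers, e$conv)$par$w)[4]
        span <- e$auxOffset + seq_len(oldC)
        sort(c(setdiff(seq_len(cons$cin), span), e$auxOffset + keep))
      } else keep
      cons$par$w <- cons$par$w[, , newIn, , drop = FALSE]
      cons$cin <- length(newIn)
      L <- setByPath(L, cp, cons)
    }
  }
  new("VesselNet", config = model@config, layers = L)
}

# ---- conv-BN fusion ----------------------------------------------------------

#' Fuse a convolution with its following batch normalization
#'
#' Folds the normalization into the convolution using the stored running
#' statistics: `W' = W * gamma / sqrt(var + eps)` per output channel and
#' `b' = (b - mean) * gamma / sqrt(var + eps) + beta`. The fused layer
#' reproduces conv->BN (inference mode) within floating tolerance.
#'
#' @param conv a convolution layer list
#' @param bn the batch-norm layer that follows it
#' @param eps batch-norm epsilon
#' @return the fused convolution layer (biased)
#' @export
fuseConvBn <- function(conv, bn, eps = 1e-5) {
  s <- bn$par$gamma / sqrt(bn$state$running_var + eps)
  w <- conv$par$w
  for (co in seq_len(dim(w)[4])) w[, , , co] <- w[, , , co] * s[co]
  b0 <- if (isTRUE(conv$bias)) conv$par$b else numeric(dim(w)[4])
  conv$par$w <- w
  conv$par$b <- (b0 - bn$state$running_mean) * s + bn$par$beta
  conv$bias <- TRUE
  conv
}

# conv -> following-BN sibling name map used to enumerate fusable pairs
.bnPartner <- c(conv1 = "bn1", conv2 = "bn2", proj = "bnp", pw = "bn",
                spw = "sbn", lat = "bnl", ref = "bnr")

fuseTree <- function(L) {
  if (!is.list(L)) return(L)
  nms <- names(L)
  if (!is.null(nms)) {
    for (nm in nms) {
      bnName <- .bnPartner[nm]
      if (!is.na(bnName) && is.list(L[[nm]]) &&
          identical(L[[nm]]$type, "conv") && !is.null(L[[bnName]]) &&
          identical(L[[bnName]]$type, "bn")) {
        L[[nm]] <- fuseConvBn(L[[nm]], L[[bnName]])
        L[[bnName]] <- list(type = "bn", c = L[[bnName]]$c, identity = TRUE,
                            par = NULL)
      }
    }
  }
  for (i in seq_along(L)) {
    if (is.list(L[[i]]) && !identical(L[[i]]$identity, TRUE))
      L[[i]] <- fuseTree(L[[i]])
  }
  L
}

#' Fuse every conv-BN pair of a model
#'
#' Produces an inference-only model in which all batch normalizations that
#' directly follow a convolution are folded into the convolution weights;
#' the remaining BN layers become identities.
#'
#' @param model a [VesselNet-class]
#' @return the fused model (inference mode only)
#' @export
fuseModel <- function(model) {
  # stem naming differs from the generic partner map only in that conv1/bn1
  # and conv2/bn2 match it already; the recursive walk covers the full tree
  new("VesselNet", config = model@config, layers = fuseTree(cloneStates(model@layers)))
}

# ---- INT8 post-training static quantization ---------------------------------

#' Quantize a tensor to 8-bit integers
#'
#' Symmetric signed quantization for weights (`zero = 0`, values in
#' \[-127, 127\], `scale = max|x| / 127`) or asymmetric affine quantization
#' for activations (values in \[0, 255\], `scale = (max - min) / 255`,
#' `zero = round(-min / scale)`). Degenerate ranges are guarded with a
#' minimum scale.
#'
#' @param x numeric array
#' @param symmetric logical; symmetric signed (weights) vs affine unsigned
#'   (activations)
#' @param lo,hi optional calibration range for the affine scheme (defaults to
#'   the observed range of `x`)
#' @return list with `q` (integer values), `scale`, `zero`
#' @export
quantizeTensor <- function(x, symmetric = TRUE, lo = NULL, hi = NULL) {
  if (symmetric) {
    scale <- max(max(abs(x)), 1e-8) / 127
    q <- pmin(pmax(round(x / scale), -127), 127)
    list(q = q, scale = scale, zero = 0)
  } else {
    if (is.null(lo)) lo <- min(x)
    if (is.null(hi)) hi <- max(x)
    lo <- min(lo, 0); hi <- max(hi, 0)
    scale <- max((hi - lo) / 255, 1e-8)
    zero <- round(-lo / scale)
    zero <- min(max(zero, 0), 255)
    q <- pmin(pmax(round(x / scale) + zero, 0), 255)
    list(q = q, scale = scale, zero = zero)
  }
}

#' Dequantize an integer tensor
#' @param q integer values
#' @param scale,zero quantization parameters from [quantizeTensor()]
#' @return numeric array
#' @export
dequantizeTensor <- function(q, scale, zero = 0) (q - zero) * scale

walkConvs <- function(L, f, path = character()) {
  if (!is.list(L)) return(L)
  if (identical(L$type, "conv")) return(f(L, path))
  for (nm in seq_along(L)) {
    if (is.list(L[[nm]]))
      L[[nm]] <- walkConvs(L[[nm]], f, c(path, nm))
  }
  L
}

#' @title Quantized network
#' @description An INT8-quantized, conv-BN-fused segmentation network. The
#' convolutions run in the integer domain (inputs affinely quantized to
#' \[0, 255\] with calibration ranges, weights symmetric int8) and results are
#' dequantized before the float nonlinearities.
#' @slot net the fused [VesselNet-class] with quantized convolution layers
#' @slot bits bit width (8)
#' @slot calibration per-layer calibration table
#' @export
setClass("QuantizedNet", representation(net = "VesselNet", bits = "integer",
                                        calibration = "data.frame"))

setMethod("show", "QuantizedNet", function(object) {
  cat(sprintf("QuantizedNet: INT%d, %d quantized convolutions\n",
              object@bits, nrow(object@calibration)))
})

#' Calibrate and quantize a model (INT8 post-training static quantization)
#'
#' Fuses conv-BN chains, records per-convolution input activation ranges
#' over the calibration batches (min/max calibration, typically training
#' tiles), computes per-tensor affine scale/zero-point for activations and
#' symmetric int8 scales for weights, and returns a model whose convolutions
#' execute in the integer domain.
#'
#' @param model a trained [VesselNet-class]
#' @param calibration list of samples (each with an `image`) used to record
#'   activation ranges
#' @return a [QuantizedNet-class]
#' @export
calibrateQuantize <- function(model, calibration) {
  if (length(calibration) == 0L) stop("empty calibration set")
  fused <- fuseModel(model)
  # attach collection state to every convolution
  fused@layers <- walkConvs(fused@layers, function(l, path) {
    qs <- new.env(parent = emptyenv())
    qs$min <- Inf; qs$max <- -Inf
    l$qstate <- qs
    l$qmode <- "collect"
    l
  })
  for (s in calibration) {
    x <- s$image
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    invisible(netForward(fused, x, training = FALSE))
  }
  cal <- data.frame(layer = character(0), inMin = numeric(0), inMax = numeric(0),
                    inScale = numeric(0), inZero = numeric(0),
                    wScale = numeric(0), stringsAsFactors = FALSE)
  fused@layers <- walkConvs(fused@layers, function(l, path) {
    qs <- l$qstate
    aq <- quantizeTensor(array(0, c(1, 1, 1, 1)), symmetric = FALSE,
                         lo = qs$min, hi = qs$max)
    wq <- quantizeTensor(l$par$w, symmetric = TRUE)
    qs$sx <- aq$scale; qs$zx <- aq$zero; qs$sw <- wq$scale
    l$qint <- wq$q
    l$qbias <- if (isTRUE(l$bias)) l$par$b else NULL
    l$qmode <- "int8"
    cal[nrow(cal) + 1L, ] <<- list(paste(path, collapse = "/"), qs$min, qs$max,
                                   aq$scale, aq$zero, wq$scale)
    l
  })
  new("QuantizedNet", net = fused, bits = 8L, calibration = cal)
}

#' Predict with a quantized network
#' @param qnet a [QuantizedNet-class]
#' @param image H x W x C array in \[0, 1\]
#' @return H x W integer mask, as [predictMask()]
#' @export
predictQuantized <- function(qnet, image) predictMask(qnet@net, image)

#' Serialize quantized weights to raw bytes
#'
#' One byte per weight; compared to 4-byte single-precision storage the
#' quantized checkpoint occupies about a quarter of the space.
#'
#' @param qnet a [QuantizedNet-class]
#' @return raw vector of int8 weight bytes
#' @export
quantizedWeightBytes <- function(qnet) {
  bytes <- raw(0)
  walkConvs(qnet@net@layers, function(l, path) {
    q <- as.integer(l$qint)
    bytes <<- c(bytes, as.raw(bitwAnd(q + 256L, 255L)))
    l
  })
  bytes
}
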