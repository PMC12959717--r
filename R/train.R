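#' @include network.R
NULL

# Training loop (Adam, pixelwise cross-entropy with auxiliary deep
# supervision) and prediction.

softmaxCE <- function(logits, target) {
  d <- dim4(logits)
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  mx <- do.call(pmax, lapply(seq_len(d[3]), function(j) lm[, j]))
  ex <- exp(lm - mx)
  p <- ex / rowSums(ex)
  ti <- as.integer(target) + 1L
  -mean(log(pmax(p[cbind(seq_len(nrow(lm)), ti)], 1e-12)))
}

#' Segmentation loss with auxiliary supervision
#'
#' Pixelwise cross-entropy of the main logits against the mask, plus
#' `auxWeight` times the cross-entropy of the auxiliary logits when present:
#' `L = CE(main, mask) + lambda * CE(aux, mask)`. With `auxWeight = 0` (or
#' `auxLogits = NULL`, as at validation) this is the main loss alone.
#'
#' @param mainLogits array dim c(H, W, C, N) (or c(H, W, C))
#' @param auxLogits same shape or NULL
#' @param mask integer array (H, W) or (H, W, N) with class labels 0..C-1
#' @param auxWeight non-negative auxiliary weight (default 0.4)
#' @return scalar loss
#' @export
computeLoss <- function(mainLogits, auxLogits = NULL, mask, auxWeight = 0.4) {
  stopifnot(auxWeight >= 0)
  if (length(dim(mainLogits)) == 3L) dim(mainLogits) <- c(dim(mainLogits), 1L)
  l <- softmaxCE(mainLogits, mask)
  if (!is.null(auxLogits) && auxWeight > 0) {
    if (length(dim(auxLogits)) == 3L) dim(auxLogits) <- c(dim(auxLogits), 1L)
    l <- l + auxWeight * softmaxCE(auxLogits, mask)
  }
  l
}

stackBatch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], length(idx)))
  m <- array(0L, dim = c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]$image
    m[, , j] <- samples[[idx[j]]]$mask
  }
  list(x = x, mask = m)
}

#' Train a segmentation network
#'
#' Standard supervised loop: Adam, pixelwise cross-entropy with the
#' auxiliary multi-scale branch weighted by `auxWeight` during training and
#' ignored for validation/prediction. Deterministic given `seed` (data order
#' and all arithmetic are seeded and single-threaded).
#'
#' @param model a [VesselNet-class]
#' @param samples list of training samples, each a list with `image`
#'   (H x W x C array in \[0, 1\]) and `mask` (H x W integer matrix)
#' @param epochs,batchSize,lr loop hyperparameters
#' @param auxWeight weight of the auxiliary loss term (0.4 by default, a
#'   common deep-supervision choice; the loss family and optimizer are
#'   package choices)
#' @param seed integer seed controlling shuffling
#' @param validation optional list of samples evaluated after each epoch
#' @param verbose print per-epoch loss
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, loss, and validation IoU/F1 when validation data are given)
#' @export
trainNet <- function(model, samples, epochs = 10L, batchSize = 4L, lr = 1e-3,
                     auxWeight = 0.4, seed = 1L, validation = NULL,
                     verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set")
  set.seed(seed)
  adam <- new.env(parent = emptyenv())
  adam$m <- list(); adam$v <- list(); adam$t <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     valIoU = numeric(0), valF1 = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(length(samples))
    epLoss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, length(ord))]
      batch <- stackBatch(samples, idx)
      tape <- newTape()
      reg <- new.env(); reg$nodes <- list()
      out <- netForwardNodes(tape, model, batch$x, training = TRUE, reg)
      loss <- agSoftmaxCE(tape, out$logits, batch$mask)
      if (!is.null(out$aux) && auxWeight > 0) {
        auxl <- agSoftmaxCE(tape, out$aux, batch$mask)
        loss <- agAdd(tape, loss, agScale(tape, auxl, auxWeight))
      }
      lv <- as.numeric(loss$val)
      if (!is.finite(lv))
        stop("non-finite training loss at epoch ", ep, "; last batch ",
             paste(idx, collapse = ","))
      backwardTape(tape, loss)
      adam$t <- adam$t + 1
      upd <- list()
      for (nm in names(reg$nodes)) {
        g <- reg$nodes[[nm]]$grad
        if (is.null(g)) next
        if (is.null(adam$m[[nm]])) {
          adam$m[[nm]] <- g * 0
          adam$v[[nm]] <- g * 0
        }
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2^adam$t)
        upd[[nm]] <- reg$nodes[[nm]]$val - lr * mhat / (sqrt(vhat) + eps)
      }
      model@layers <- assignParams(model@layers, upd)
      epLoss <- epLoss + lv; nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, loss = epLoss / nb, valIoU = NA_real_,
                      valF1 = NA_real_)
    if (!is.null(validation)) {
      preds <- lapply(validation, function(s) predictMask(model, s$image))
      ev <- evaluateDataset(preds, lapply(validation, `[[`, "mask"))
      row$valIoU <- ev$iou; row$valF1 <- ev$f1
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, row$loss,
                      if (!is.na(row$valIoU)) sprintf(" val IoU %.3f", row$valIoU) else ""))
  }
  list(model = model, history = hist)
}

#' Predict a segmentation mask
#'
#' Inference mode: the auxiliary branch is off; the mask is the pixelwise
#' argmax over class logits.
#'
#' @param model a [VesselNet-class]
#' @param image H x W x C array in \[0, 1\]
#' @return H x W integer matrix of class labels (0 background, 1 vessel)
#' @export
predictMask <- function(model, image) {
  out <- netForward(model, image, training = FALSE)
  lg <- out$logits
  d <- dim(lg)
  cls <- apply(array(lg, dim = d[1:3]), c(1, 2), which.max) - 1L
  matrix(as.integer(cls), d[1], d[2])
}
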