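# Pixel-level segmentation evaluation: confusion counts, IoU, precision,
# recall, F1 and dataset-level aggregation.

#' Pixel confusion counts between a predicted and a reference mask
#'
#' Masks are binary matrices (1 = vessel foreground). `tp` is the size of the
#' foreground intersection; `tp + fp + fn` the union.
#'
#' @param pred,mask binary integer matrices of identical shape
#' @return list with `tp`, `fp`, `fn`, `tn` (their sum is the pixel count)
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1] <- 1L
#' confusionCounts(m, m)
#' @export
confusionCounts <- function(pred, mask) {
  if (!all(dim(pred) == dim(mask)))
    stop("prediction and reference masks must have the same shape")
  pv <- as.integer(pred); mv <- as.integer(mask)
  if (!all(pv %in% c(0L, 1L)) || !all(mv %in% c(0L, 1L)))
    stop("masks must be binary (0/1)")
  tp <- sum(pv == 1L & mv == 1L)
  fp <- sum(pv == 1L & mv == 0L)
  fn <- sum(pv == 0L & mv == 1L)
  tn <- sum(pv == 0L & mv == 0L)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Intersection-over-union (Jaccard) score
#'
#' `tp / (tp + fp + fn)`; defined as 1 when both masks are empty (empty
#' union), so that degenerate tiles without any vessel remain scored.
#'
#' @param counts confusion counts from [confusionCounts()]
#' @return IoU in \[0, 1\]
#' @export
iouScore <- function(counts) {
  u <- counts$tp + counts$fp + counts$fn
  if (u == 0) 1 else counts$tp / u
}

#' Precision and recall
#'
#' `tp/(tp+fp)` and `tp/(tp+fn)`. An empty denominator yields 1 when both
#' prediction and reference are empty, otherwise 0.
#'
#' @inheritParams iouScore
#' @return named numeric vector with `precision` and `recall`
#' @export
precisionRecall <- function(counts) {
  bothEmpty <- (counts$tp + counts$fp + counts$fn) == 0
  prec <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp)
          else if (bothEmpty) 1 else 0
  rec <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
         else if (bothEmpty) 1 else 0
  c(precision = prec, recall = rec)
}

#' F1 score (Dice) from precision and recall
#'
#' The harmonic mean `2PR/(P+R)`, 0 when both are 0. For metrics derived from
#' a single confusion table, `IoU = F1 / (2 - F1)`.
#'
#' @param precision,recall values in \[0, 1\]
#' @return F1 in \[0, 1\]
#' @examples
#' f1Score(0.7267, 0.6303) # 0.6751 to four decimals
#' @export
f1Score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Evaluate a set of predictions against references
#'
#' Aggregation convention: IoU, precision and recall are averaged per image;
#' the dataset F1 is the harmonic mean of the aggregated precision and recall
#' (so the reported F1 satisfies the F1 formula on the reported P and R,
#' while IoU is averaged independently). Micro-averaging over pooled pixel
#' counts is available via `micro = TRUE` and equals the metrics of the
#' mosaic of all images.
#'
#' @param predictions,references lists of binary masks (pairwise same shape)
#' @param micro use pooled pixel counts instead of per-image averaging
#' @return list with `iou`, `precision`, `recall`, `f1` and the per-image
#'   table `perImage`
#' @export
evaluateDataset <- function(predictions, references, micro = FALSE) {
  stopifnot(length(predictions) == length(references),
            length(predictions) >= 1L)
  per <- data.frame(iou = numeric(0), precision = numeric(0),
                    recall = numeric(0), f1 = numeric(0))
  tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(predictions)) {
    cc <- confusionCounts(predictions[[i]], references[[i]])
    pr <- precisionRecall(cc)
    per[i, ] <- c(iouScore(cc), pr["precision"], pr["recall"],
                  f1Score(pr["precision"], pr["recall"]))
    for (k in names(tot)) tot[[k]] <- tot[[k]] + cc[[k]]
  }
  if (micro) {
    pr <- precisionRecall(tot)
    list(iou = iouScore(tot), precision = unname(pr["precision"]),
         recall = unname(pr["recall"]),
         f1 = unname(f1Score(pr["precision"], pr["recall"])), perImage = per)
  } else {
    p <- mean(per$precision); r <- mean(per$recall)
    list(iou = mean(per$iou), precision = p, recall = r,
         f1 = unname(f1Score(p, r)), perImage = per)
  }
}
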