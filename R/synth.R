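# Synthetic PAS-like kidney tile generator: thin curvilinear vessels and
# ring/lumen structures of low contrast on a textured pink-purple background,
# paired with exact binary masks. Everything is deterministic given
# (configuration, seed), so the whole pipeline is testable offline.

#' @title Synthetic tile configuration
#' @description Parameters of the synthetic vessel-tile generator.
#' @slot tileSize tile side in pixels (divisible by 32)
#' @slot nVessels integer range (min, max) of structures per tile
#' @slot vesselWidth pixel range (min, max) of vessel diameters
#' @slot ringFraction proportion of ring/lumen structures among vessels
#' @slot contrast foreground-background intensity offset in \[0, 1\]
#' @slot noiseSd per-pixel noise standard deviation
#' @export
setClass("SynthConfig", representation(
  tileSize = "integer", nVessels = "integer", vesselWidth = "numeric",
  ringFraction = "numeric", contrast = "numeric", noiseSd = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@tileSize %% 32L != 0L) msg <- c(msg, "tileSize must be divisible by 32")
  if (length(object@nVessels) != 2L || any(object@nVessels < 1L) ||
      diff(object@nVessels) < 0) msg <- c(msg, "nVessels must be a valid range")
  if (length(object@vesselWidth) != 2L || any(object@vesselWidth <= 0) ||
      diff(object@vesselWidth) < 0) msg <- c(msg, "vesselWidth must be a valid range")
  if (object@ringFraction < 0 || object@ringFraction > 1)
    msg <- c(msg, "ringFraction must be in [0,1]")
  if (object@contrast < 0 || object@contrast > 1)
    msg <- c(msg, "contrast must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic tile configuration
#'
#' Defaults emulate 512x512 RGB PAS-stained kidney tiles: a textured
#' pink-purple background and 4-12 thin (2-12 px) curvilinear or ring-shaped
#' vessel structures at low contrast.
#'
#' @param tileSize tile side in pixels, divisible by 32
#' @param nVessels range of structure counts per tile
#' @param vesselWidth range of vessel diameters in pixels
#' @param ringFraction proportion of ring/lumen structures
#' @param contrast foreground-background offset in \[0, 1\]
#' @param noiseSd background texture scale
#' @return a [SynthConfig-class]
#' @export
synthConfig <- function(tileSize = 512L, nVessels = c(4L, 12L),
                        vesselWidth = c(2, 12), ringFraction = 0.3,
                        contrast = 0.25, noiseSd = 0.04) {
  new("SynthConfig", tileSize = as.integer(tileSize),
      nVessels = as.integer(nVessels), vesselWidth = as.numeric(vesselWidth),
      ringFraction = ringFraction, contrast = contrast, noiseSd = noiseSd)
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig %dx%d: %d-%d vessels, width %.1f-%.1f px, %.0f%% rings, contrast %.2f\n",
              object@tileSize, object@tileSize, object@nVessels[1],
              object@nVessels[2], object@vesselWidth[1], object@vesselWidth[2],
              100 * object@ringFraction, object@contrast))
})

# smooth low-frequency field in [0,1]-ish range via bilinear upsampling of a
# coarse Gaussian grid
lowFreqField <- function(n, coarse = 16L, sd = 1) {
  g <- array(stats::rnorm(coarse * coarse, sd = sd), dim = c(coarse, coarse, 1L, 1L))
  drop(cpp_bilinear_fwd(g, as.integer(n), as.integer(n)))
}

stampDisc <- function(mask, cx, cy, r) {
  n <- nrow(mask)
  ri <- ceiling(r)
  xs <- max(1L, floor(cx) - ri):min(n, ceiling(cx) + ri)
  ys <- max(1L, floor(cy) - ri):min(n, ceiling(cy) + ri)
  if (!length(xs) || !length(ys)) return(mask)
  dx <- (xs - cx)^2
  dy <- (ys - cy)^2
  hit <- outer(dx, dy, `+`) <= r^2
  mask[xs, ys][hit] <- 1L
  mask
}

drawTube <- function(mask, n, width) {
  len <- stats::runif(1, 0.3, 1.2) * n
  steps <- max(10L, ceiling(len))
  x <- stats::runif(1, 1, n); y <- stats::runif(1, 1, n)
  th <- stats::runif(1, 0, 2 * pi)
  r <- width / 2
  for (s in seq_len(steps)) {
    mask <- stampDisc(mask, x, y, r)
    th <- th + stats::rnorm(1, sd = 0.15)
    x <- x + cos(th); y <- y + sin(th)
    if (x < -r || x > n + r || y < -r || y > n + r) break
  }
  mask
}

drawRing <- function(mask, lumen, n, width) {
  cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
  rad <- stats::runif(1, 2 * width, 6 * width) + 2
  ri <- ceiling(rad + width / 2)
  xs <- max(1L, floor(cx) - ri):min(n, ceiling(cx) + ri)
  ys <- max(1L, floor(cy) - ri):min(n, ceiling(cy) + ri)
  if (!length(xs) || !length(ys)) return(list(mask = mask, lumen = lumen))
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  ring <- d >= rad - width / 2 & d <= rad + width / 2
  inner <- d < rad - width / 2
  mask[xs, ys][ring] <- 1L
  lumen[xs, ys][inner] <- 1L
  list(mask = mask, lumen = lumen)
}

#' Generate one synthetic tile with its mask
#'
#' The background is smoothed correlated noise tinted to a PAS-like
#' pink-purple palette; the foreground consists of random curvilinear tubes
#' (smoothed random-walk centerlines of varying width) and rings with bright
#' lumina, rendered at the configured low contrast. The mask is the exact
#' foreground support. Fully deterministic given `(config, seed)`.
#'
#' @param config a [SynthConfig-class]
#' @param seed integer seed
#' @return list with `image` (H x W x 3 array in \[0, 1\], 8-bit quantized)
#'   and `mask` (H x W integer matrix in \{0, 1\})
#' @examples
#' s <- generateSample(synthConfig(tileSize = 64L), seed = 7)
#' range(s$mask)
#' @export
generateSample <- function(config, seed = 1L) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(seed)
  n <- config@tileSize
  mask <- matrix(0L, n, n)
  lumen <- matrix(0L, n, n)
  nv <- if (config@nVessels[1] == config@nVessels[2]) config@nVessels[1]
        else sample(config@nVessels[1]:config@nVessels[2], 1L)
  for (v in seq_len(nv)) {
    wd <- stats::runif(1, config@vesselWidth[1], config@vesselWidth[2])
    if (stats::runif(1) < config@ringFraction) {
      r <- drawRing(mask, lumen, n, wd)
      mask <- r$mask; lumen <- r$lumen
    } else {
      mask <- drawTube(mask, n, wd)
    }
  }
  lumen[mask == 1L] <- 0L
  # PAS-like palette: light pink background, deeper magenta vessel walls,
  # near-white lumina
  bg <- c(0.91, 0.79, 0.86)
  fg <- c(0.62, 0.28, 0.52)
  lu <- c(0.97, 0.94, 0.96)
  tex <- lowFreqField(n, coarse = max(8L, n %/% 32L))
  tex2 <- lowFreqField(n, coarse = max(8L, n %/% 8L))
  img <- array(0, dim = c(n, n, 3L))
  a <- config@contrast
  for (ch in 1:3) {
    base <- bg[ch] + 0.05 * tex + 0.03 * tex2
    base[mask == 1L] <- base[mask == 1L] + (fg[ch] - bg[ch]) * (a / 0.25)
    base[lumen == 1L] <- base[lumen == 1L] + (lu[ch] - bg[ch]) * (a / 0.25)
    img[, , ch] <- base
  }
  img <- img + array(stats::rnorm(n * n * 3, sd = config@noiseSd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255 # 8-bit quantization for lossless PNG round-trip
  list(image = img, mask = mask)
}

#' Write a sample pair as PNG files
#'
#' The image is written as 8-bit RGB, the mask as 8-bit grayscale with
#' values \{0, 255\}.
#' @param sample list with `image` and `mask` as from [generateSample()]
#' @param imagePath,maskPath output PNG paths
#' @return invisibly, the two paths
#' @export
writeSample <- function(sample, imagePath, maskPath) {
  png::writePNG(aperm(sample$image, c(2, 1, 3)), imagePath)
  png::writePNG(t(sample$mask * 1.0), maskPath)
  invisible(c(imagePath, maskPath))
}

#' Read a sample pair from PNG files
#'
#' Loads an RGB image and a single-channel mask; any non-zero mask value is
#' binarized to 1. Errors if the two sizes disagree.
#' @param imagePath,maskPath PNG paths
#' @return list with `image` and `mask` as in [generateSample()]
#' @export
readSample <- function(imagePath, maskPath) {
  img <- png::readPNG(imagePath)
  if (length(dim(img)) == 2L) stop("image must be RGB, got grayscale: ", imagePath)
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  img <- aperm(img, c(2, 1, 3))
  m <- png::readPNG(maskPath)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- t(m)
  if (!all(dim(m) == dim(img)[1:2]))
    stop("image/mask size mismatch: ", imagePath, " vs ", maskPath)
  list(image = img, mask = matrix(as.integer(m > 0), nrow(m), ncol(m)))
}

#' Generate a dataset split 6:2:2 on disk
#'
#' Writes image/mask PNG pairs into `train/`, `val/` and `test/`
#' subdirectories plus a manifest TSV. The 20% shares are rounded to nearest
#' and the training share takes the remainder, matching the reference split
#' of 1633 tiles into 979/327/327.
#'
#' @param config a [SynthConfig-class]
#' @param nTotal total number of tiles
#' @param seed integer seed; tile i uses seed `seed + i`
#' @param outDir output directory (created if missing)
#' @return data.frame manifest with columns id, split, image, mask
#' @export
generateDataset <- function(config, nTotal, seed = 1L, outDir) {
  stopifnot(nTotal >= 3L)
  counts <- datasetSplit(nTotal)
  splits <- rep(c("train", "val", "test"), counts)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(splits)) dir.create(file.path(outDir, s), showWarnings = FALSE)
  man <- data.frame(id = integer(0), split = character(0), image = character(0),
                    mask = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nTotal)) {
    sm <- generateSample(config, seed = seed + i)
    ip <- file.path(outDir, splits[i], sprintf("tile%04d_image.png", i))
    mp <- file.path(outDir, splits[i], sprintf("tile%04d_mask.png", i))
    writeSample(sm, ip, mp)
    man[i, ] <- list(i, splits[i], ip, mp)
  }
  utils::write.table(man, file.path(outDir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  man
}

#' 6:2:2 split counts
#' @param nTotal total number of tiles
#' @return integer vector c(train, val, test)
#' @export
datasetSplit <- function(nTotal) {
  v <- round(0.2 * nTotal)
  te <- round(0.2 * nTotal)
  tr <- nTotal - v - te
  c(train = tr, val = v, test = te)
}
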