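# Structured pruning, conv-BN fusion and INT8 quantization.

test_that("L2 channel ranking sorts descending with index tie-breaks", {
  w <- array(0, c(1, 1, 1, 3)); w[1, 1, 1, ] <- c(3, 1, 2)
  expect_equal(channelImportanceL2(w), c(1L, 3L, 2L))
  weq <- array(1, c(2, 2, 1, 4))
  expect_equal(channelImportanceL2(weq), 1:4) # ties keep the lower index
  set.seed(40)
  wr <- array(rnorm(3 * 3 * 2 * 8), c(3, 3, 2, 8))
  norms <- apply(wr, 4, function(s) sqrt(sum(s^2)))
  expect_equal(channelImportanceL2(wr), order(-norms))
})

test_that("pruning plans select a suffix of the topological layer order", {
  net <- vesselNet(tinyConfig(), seed = 15)
  all <- vesselseg:::prunableLayers(net)
  plan <- buildPrunePlan(net, 0.5, nLayers = 3)
  tailPaths <- lapply(all[seq(length(all) - 2L, length(all))], `[[`, "conv")
  expect_identical(lapply(plan@layers, `[[`, "conv"), tailPaths)
  expect_error(buildPrunePlan(net, 0), "keepRatio")
  expect_error(buildPrunePlan(net, 1.2), "keepRatio")
})

test_that("keep ratio 1 is a bitwise no-op and lower ratios shrink the model", {
  net <- vesselNet(tinyConfig(), seed = 16)
  x <- randImage(64, 64, 3, 1, seed = 41)
  ref <- netForward(net, x)$logits
  id <- applyPrune(net, buildPrunePlan(net, 1, nLayers = 4))
  expect_identical(netForward(id, x)$logits, ref)
  expect_identical(countParams(id), countParams(net))
  ps <- vapply(c(0.4, 0.6, 0.8), function(r) {
    countParams(applyPrune(net, buildPrunePlan(net, r, nLayers = 4)))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(ps[3], countParams(net))
})

test_that("pruned parameter counts match the closed-form prediction", {
  net <- vesselNet(tinyConfig(), seed = 17)
  plan <- buildPrunePlan(net, 0.5, nLayers = 2)
  pruned <- applyPrune(net, plan)
  drop <- 0
  for (i in seq_along(plan@layers)) {
    conv <- vesselseg:::getByPath(net@layers, plan@layers[[i]]$conv)
    removed <- conv$cout - length(plan@keep[[i]])
    perChan <- dim(conv$par$w)[1] * dim(conv$par$w)[2] * dim(conv$par$w)[3]
    drop <- drop + removed * (perChan + if (isTRUE(conv$bias)) 1 else 0)
    if (!is.null(plan@layers[[i]]$bn)) drop <- drop + 2 * removed
    for (cp in plan@layers[[i]]$consumers) {
      cons <- vesselseg:::getByPath(net@layers, cp)
      perIn <- dim(cons$par$w)[1] * dim(cons$par$w)[2] * dim(cons$par$w)[4]
      drop <- drop + removed * perIn
    }
  }
  expect_equal(countParams(net, includeAux = TRUE) - drop,
               countParams(pruned, includeAux = TRUE))
  # the pruned model remains runnable, in both modes
  x <- randImage(64, 64, 3, 1, seed = 42)
  expect_identical(dim(netForward(pruned, x, training = TRUE)$logits),
                   c(64L, 64L, 2L, 1L))
})

test_that("dropping the weakest channel hurts less than the strongest", {
  set.seed(43)
  w <- array(rnorm(3 * 3 * 2 * 4, sd = 0.2), c(3, 3, 2, 4))
  w[, , , 2] <- w[, , , 2] * 8 # dominant channel
  x <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  head <- array(rnorm(1 * 1 * 4 * 1), c(1, 1, 4, 1)) # linear read-out
  outWith <- function(keep) {
    h <- vesselseg:::cpp_conv2d_fwd(x, w[, , , keep, drop = FALSE], 1L, 1L, 1L)
    vesselseg:::cpp_conv2d_fwd(h, head[, , keep, , drop = FALSE], 1L, 0L, 1L)
  }
  full <- outWith(1:4)
  rank <- channelImportanceL2(w)
  weakest <- rank[4]; strongest <- rank[1]
  dWeak <- sum((outWith(setdiff(1:4, weakest)) - full)^2)
  dStrong <- sum((outWith(setdiff(1:4, strongest)) - full)^2)
  expect_lt(dWeak, dStrong)
})

test_that("conv-BN fusion reproduces the unfused pair", {
  set.seed(44)
  conv <- vesselseg:::convLayer(3L, 5L, 3L, pad = 1L)
  bn <- vesselseg:::bnLayer(5L)
  bn$par$gamma <- runif(5, 0.5, 1.5)
  bn$par$beta <- rnorm(5)
  bn$state$running_mean <- rnorm(5)
  bn$state$running_var <- runif(5, 0.5, 2)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y0 <- vesselseg:::cpp_conv2d_fwd(x, conv$par$w, 1L, 1L, 1L)
  yb <- naiveBnEval(y0, bn$par$gamma, bn$par$beta, bn$state$running_mean,
                    bn$state$running_var)
  fused <- fuseConvBn(conv, bn)
  yf <- vesselseg:::cpp_conv2d_fwd(x, fused$par$w, 1L, 1L, 1L)
  yf <- yf + rep(fused$par$b, each = 64)
  expect_equal(yf, yb, tolerance = 1e-5, ignore_attr = TRUE)
  # identity-statistics BN leaves the kernel unchanged
  bnId <- vesselseg:::bnLayer(5L)
  bnId$state$running_var <- rep(1 - 1e-5, 5)
  expect_equal(fuseConvBn(conv, bnId)$par$w, conv$par$w, tolerance = 1e-12)
})

test_that("whole-model fusion is equivalent at inference", {
  net <- vesselNet(tinyConfig(), seed = 18)
  x <- randImage(64, 64, 3, 2, seed = 45)
  # two training passes give the BN states non-trivial running statistics
  invisible(netForward(net, x, training = TRUE))
  invisible(netForward(net, 0.5 * x + 0.1, training = TRUE))
  ref <- netForward(net, x)$logits
  fused <- fuseModel(net)
  got <- netForward(fused, x)$logits
  expect_equal(got, ref, tolerance = 1e-4)
  expect_lt(max(abs(got - ref)), 1e-6)
  # every fusable BN became an identity
  expect_true(isTRUE(fused@layers$stem$bn1$identity))
  expect_true(isTRUE(fused@layers$decoder[[1]]$bnr$identity))
})

test_that("weight quantization follows the symmetric int8 scheme", {
  w <- array(c(1.27, -0.5, 0.005, 0), c(1, 1, 1, 4))
  q <- quantizeTensor(w, symmetric = TRUE)
  expect_equal(q$scale, 0.01)
  expect_equal(q$q[1, 1, 1, 1], 127)
  expect_equal(q$zero, 0)
  set.seed(46)
  wr <- array(rnorm(200), c(5, 5, 2, 4))
  qr <- quantizeTensor(wr, symmetric = TRUE)
  err <- abs(dequantizeTensor(qr$q, qr$scale) - wr)
  expect_true(all(err <= qr$scale / 2 + 1e-12))
  # affine activation scheme round-trips within half a step inside the range
  a <- array(runif(100, -0.3, 1.7), c(10, 10, 1, 1))
  qa <- quantizeTensor(a, symmetric = FALSE)
  erra <- abs(dequantizeTensor(qa$q, qa$scale, qa$zero) - a)
  expect_true(all(erra <= qa$scale / 2 + 1e-12))
  # degenerate constant tensor keeps a positive guarded scale
  qc <- quantizeTensor(array(0.42, c(2, 2, 1, 1)) * 0, symmetric = FALSE,
                       lo = 0, hi = 0)
  expect_gt(qc$scale, 0)
})

test_that("quantized inference runs in the integer domain and stays close", {
  net <- vesselNet(tinyConfig(), seed = 19)
  calib <- makeSamples(2, seedBase = 90, tileSize = 64L,
                       scfg = synthConfig(tileSize = 64L, nVessels = c(2L, 3L)))
  invisible(netForward(net, calib[[1]]$image, training = TRUE))
  qn <- calibrateQuantize(net, calib)
  expect_s4_class(qn, "QuantizedNet")
  expect_gt(nrow(qn@calibration), 50)
  expect_true(all(qn@calibration$inScale > 0))
  # stored weights are integers in [-127, 127]
  someConv <- qn@net@layers$stem$conv1
  expect_true(all(someConv$qint == round(someConv$qint)))
  expect_true(all(abs(someConv$qint) <= 127))
  m <- predictQuantized(qn, calib[[1]]$image)
  expect_true(all(m %in% c(0L, 1L)))
  # agreement with the float model on most pixels (the network is untrained,
  # so many logit margins sit near zero; trained-model accuracy is covered by
  # the end-to-end acceptance check)
  mf <- predictMask(net, calib[[1]]$image)
  expect_gt(mean(m == mf), 0.9)
  expect_error(calibrateQuantize(net, list()), "empty")
})

test_that("int8 serialization needs a quarter of single-precision bytes", {
  net <- vesselNet(tinyConfig(), seed = 20)
  qn <- calibrateQuantize(net, makeSamples(1, seedBase = 95, tileSize = 64L,
                                           scfg = synthConfig(tileSize = 64L)))
  bytes <- quantizedWeightBytes(qn)
  nw <- 0
  vesselseg:::walkConvs(qn@net@layers, function(l, p) {
    nw <<- nw + length(l$qint); l
  })
  expect_equal(length(bytes), nw) # 1 byte per weight vs 4 for float32
})
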