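# Primitive tensor kernels against scalar-loop oracles and finite differences.

fdCheck <- function(fwd, x, gx, eps = 1e-5, n = 6L, tol = 1e-4) {
  # compare analytic gradient gx against central differences of sum(fwd(x))
  set.seed(42)
  idx <- sample(length(x), min(n, length(x)))
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(fwd(xp)) - sum(fwd(xm))) / (2 * eps)
    expect_equal(gx[i], num, tolerance = tol)
  }
}

test_that("convolution forward matches the scalar-loop oracle", {
  set.seed(1)
  cases <- list(
    list(h = 5, w = 6, cin = 3, cout = 4, k = 3, stride = 1, pad = 1, groups = 1),
    list(h = 6, w = 6, cin = 4, cout = 6, k = 3, stride = 2, pad = 1, groups = 1),
    list(h = 4, w = 4, cin = 4, cout = 4, k = 2, stride = 1, pad = 0, groups = 4),
    list(h = 5, w = 5, cin = 6, cout = 2, k = 1, stride = 1, pad = 0, groups = 2))
  for (cs in cases) {
    x <- array(rnorm(cs$h * cs$w * cs$cin * 2), c(cs$h, cs$w, cs$cin, 2))
    w <- array(rnorm(cs$k^2 * (cs$cin / cs$groups) * cs$cout),
               c(cs$k, cs$k, cs$cin / cs$groups, cs$cout))
    got <- vesselseg:::cpp_conv2d_fwd(x, w, cs$stride, cs$pad, cs$groups)
    ref <- naiveConv2d(x, w, cs$stride, cs$pad, cs$groups)
    expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("convolution backward agrees with finite differences", {
  set.seed(2)
  x <- array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  gy <- array(1, dim(vesselseg:::cpp_conv2d_fwd(x, w, 1L, 1L, 1L)))
  g <- vesselseg:::cpp_conv2d_bwd(x, w, gy, 1L, 1L, 1L)
  fdCheck(function(xx) vesselseg:::cpp_conv2d_fwd(xx, w, 1L, 1L, 1L), x, g$gx)
  fdCheck(function(ww) vesselseg:::cpp_conv2d_fwd(x, ww, 1L, 1L, 1L), w, g$gw)
  # strided grouped case
  w2 <- array(rnorm(2 * 2 * 1 * 2), c(2, 2, 1, 2))
  gy2 <- array(1, dim(vesselseg:::cpp_conv2d_fwd(x, w2, 2L, 0L, 2L)))
  g2 <- vesselseg:::cpp_conv2d_bwd(x, w2, gy2, 2L, 0L, 2L)
  fdCheck(function(xx) vesselseg:::cpp_conv2d_fwd(xx, w2, 2L, 0L, 2L), x, g2$gx)
  fdCheck(function(ww) vesselseg:::cpp_conv2d_fwd(x, ww, 2L, 0L, 2L), w2, g2$gw)
})

test_that("bilinear resize matches the corner-excluding oracle, both ways", {
  set.seed(3)
  x <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
  up <- vesselseg:::cpp_bilinear_fwd(x, 8L, 12L)
  expect_equal(up, naiveBilinear(x, 8L, 12L), tolerance = 1e-12,
               ignore_attr = TRUE)
  down <- vesselseg:::cpp_bilinear_fwd(x, 2L, 3L)
  expect_equal(down, naiveBilinear(x, 2L, 3L), tolerance = 1e-12,
               ignore_attr = TRUE)
  gy <- array(rnorm(8 * 12 * 2 * 2), c(8, 12, 2, 2))
  gx <- vesselseg:::cpp_bilinear_bwd(gy, dim(x))
  # adjoint identity: <up(x), gy> == <x, bwd(gy)>
  expect_equal(sum(up * gy), sum(x * gx), tolerance = 1e-10)
})

test_that("adaptive average pooling uses floor/ceil windows and sums back", {
  set.seed(4)
  x <- array(rnorm(5 * 7 * 2 * 1), c(5, 7, 2, 1))
  y <- vesselseg:::cpp_adaptive_avgpool_fwd(x, 2L, 2L)
  expect_equal(y, naiveAdaptivePool(x, 2L, 2L), tolerance = 1e-12,
               ignore_attr = TRUE)
  y1 <- vesselseg:::cpp_adaptive_avgpool_fwd(x, 1L, 1L)
  expect_equal(as.numeric(y1[1, 1, , 1]), c(mean(x[, , 1, 1]), mean(x[, , 2, 1])))
  gy <- array(rnorm(length(y)), dim(y))
  gx <- vesselseg:::cpp_adaptive_avgpool_bwd(gy, dim(x))
  expect_equal(sum(y * gy), sum(x * gx), tolerance = 1e-10)
})

test_that("max pooling forwards maxima and routes gradients to argmax", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  r <- vesselseg:::cpp_maxpool2_fwd(x)
  expect_equal(as.numeric(r$y[, , 1, 1]), c(6, 8, 14, 16))
  gy <- array(1, c(2, 2, 1, 1))
  gx <- vesselseg:::cpp_maxpool2_bwd(gy, r$idx, dim(x))
  expect_equal(sum(gx), 4)
  expect_equal(gx[2, 2, 1, 1], 1) # position of value 6
})

test_that("batch normalization forward/backward are correct in both modes", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 3 * 2, mean = 2), c(4, 4, 3, 2))
  tape <- vesselseg:::newTape()
  xn <- vesselseg:::tvar(tape, x)
  gamma <- vesselseg:::tvar(tape, c(1.5, 0.5, 2))
  beta <- vesselseg:::tvar(tape, c(0.1, -0.2, 0))
  st <- new.env(); st$running_mean <- numeric(3); st$running_var <- rep(1, 3)
  st$momentum <- 0.1
  # training mode: per-channel standardization
  y <- vesselseg:::agBatchNorm(tape, xn, gamma, beta, st, training = TRUE)
  for (c in 1:3) {
    v <- y$val[, , c, ]
    expect_equal(mean(v), beta$val[c], tolerance = 1e-8)
    expect_equal(sd(as.vector(v)) * sqrt(31 / 32), abs(gamma$val[c]),
                 tolerance = 1e-3)
  }
  expect_false(all(st$running_mean == 0)) # running stats updated
  # eval mode matches the scalar reference
  tape2 <- vesselseg:::newTape()
  y2 <- vesselseg:::agBatchNorm(tape2, vesselseg:::tvar(tape2, x), gamma, beta,
                                st, training = FALSE)
  expect_equal(y2$val, naiveBnEval(x, gamma$val, beta$val, st$running_mean,
                                   st$running_var), tolerance = 1e-12)
  # training-mode gradient via finite differences on a scalar functional
  lossOf <- function(xx) {
    st2 <- new.env(); st2$running_mean <- numeric(3)
    st2$running_var <- rep(1, 3); st2$momentum <- 0.1
    tp <- vesselseg:::newTape()
    yy <- vesselseg:::agBatchNorm(tp, vesselseg:::tvar(tp, xx), gamma, beta,
                                  st2, training = TRUE)
    sum(yy$val * seq_along(yy$val))
  }
  tp <- vesselseg:::newTape()
  xn3 <- vesselseg:::tvar(tp, x)
  y3 <- vesselseg:::agBatchNorm(tp, xn3, gamma, beta, st, training = TRUE)
  y3$grad <- array(seq_along(y3$val), dim(y3$val))
  y3$bwd(y3)
  fdCheck(function(xx) lossOf(xx), x, xn3$grad, eps = 1e-5, tol = 1e-3)
})

test_that("softmax cross-entropy value and gradient are correct", {
  logits <- array(0, c(2, 2, 2, 1))
  logits[, , 2, 1] <- matrix(c(2, -1, 0, 3), 2, 2)
  target <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  # hand computation: per-pixel CE of a 2-class softmax
  p1 <- exp(logits[, , 2, 1]) / (1 + exp(logits[, , 2, 1]))
  ref <- -mean(log(ifelse(target == 1L, p1, 1 - p1)))
  tape <- vesselseg:::newTape()
  ln <- vesselseg:::tvar(tape, logits)
  loss <- vesselseg:::agSoftmaxCE(tape, ln, target)
  expect_equal(as.numeric(loss$val), ref, tolerance = 1e-12)
  vesselseg:::backwardTape(tape, loss)
  fdCheck(function(ll) {
    tp <- vesselseg:::newTape()
    vesselseg:::agSoftmaxCE(tp, vesselseg:::tvar(tp, ll), target)$val
  }, logits, ln$grad, tol = 1e-5)
})

test_that("a composed attention graph backpropagates to every parameter", {
  set.seed(7)
  lay <- dscbamLayer(3L)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  tape <- vesselseg:::newTape()
  reg <- new.env(); reg$nodes <- list()
  lw <- vesselseg:::wrapParams(tape, lay, reg)
  y <- vesselseg:::dscbamApply(tape, lw, vesselseg:::tvar(tape, x), TRUE)
  loss <- vesselseg:::tnode(tape, array(sum(y$val^2), c(1, 1, 1, 1)),
                            list(x = y), bwd = function(nd) {
                              vesselseg:::accumGrad(nd$parents$x,
                                                    2 * nd$parents$x$val *
                                                      as.numeric(nd$grad))
                            })
  vesselseg:::backwardTape(tape, loss)
  grads <- vapply(reg$nodes, function(nd) {
    if (is.null(nd$grad)) 0 else max(abs(nd$grad))
  }, numeric(1))
  expect_true(all(grads > 0))
})
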