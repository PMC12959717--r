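# Attention modules and enhanced residual blocks.

test_that("zero-weight channel attention halves the input exactly", {
  lay <- zeroParams(dscamLayer(3L))
  lay$bn$par$gamma <- rep(1, 3) # identity-mode normalization
  x <- randImage(4, 4, 3, 2, seed = 10)
  y <- dscamForward(lay, x)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)
})

test_that("channel attention preserves shape and contracts magnitudes", {
  set.seed(11)
  for (d in list(c(2, 2, 1), c(5, 7, 4), c(8, 3, 2))) {
    lay <- dscamLayer(d[3])
    x <- array(rnorm(prod(d)), dim = d)
    y <- dscamForward(lay, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(abs(y) <= abs(x) + 1e-12)) # multipliers lie in (0,1)
    nz <- abs(x) > 1e-8
    expect_true(all(abs(y)[nz] > 0)) # and never reach 0 exactly
  }
})

test_that("channel attention matches the scalar-loop oracle", {
  set.seed(12)
  lay <- dscamLayer(2L)
  # fixed small integer weights, non-trivial running stats
  lay$dw$par$w[] <- c(1, -1, 2, 1, 0, 1, -2, 1) / 4
  lay$pw$par$w[] <- c(1, 2, -1, 1) / 2
  lay$bn$par$gamma <- c(1.5, 0.8)
  lay$bn$par$beta <- c(0.1, -0.1)
  lay$bn$state$running_mean <- c(0.2, -0.3)
  lay$bn$state$running_var <- c(1.2, 0.7)
  x <- array(round(rnorm(4 * 4 * 2 * 1), 1), c(4, 4, 2, 1))
  expect_equal(dscamForward(lay, x), dscamOracle(lay, x), tolerance = 1e-10)
})

test_that("channel attention rejects undersized or mismatched inputs", {
  lay <- dscamLayer(3L)
  expect_error(dscamForward(lay, array(0, c(1, 4, 3))), "spatial")
  expect_error(dscamForward(lay, array(0, c(4, 4, 2))), "channel mismatch")
})

test_that("zero-weight residual block reduces to ReLU(x)", {
  lay <- zeroParams(basicBlock(3L, 3L, stride = 1L))
  lay$bn1$par$gamma <- rep(1, 3); lay$bn2$par$gamma <- rep(1, 3)
  lay$att$bn$par$gamma <- rep(1, 3)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_equal(blockForward(lay, x), pmax(x, 0), tolerance = 1e-12)
})

test_that("projection block halves spatial size and maps channels", {
  lay <- basicBlock(6L, 10L, stride = 2L)
  x <- randImage(32, 32, 6, 1, seed = 13)
  y <- blockForward(lay, x[, , , 1])
  expect_identical(dim(y), c(16L, 16L, 10L))
  expect_error(blockForward(lay, array(0, c(16, 16, 4))), "input channels")
})

test_that("block without attention equals a plain ResNet block", {
  set.seed(14)
  for (cs in list(list(cin = 3L, cout = 3L, stride = 1L),
                  list(cin = 3L, cout = 5L, stride = 2L))) {
    lay <- basicBlock(cs$cin, cs$cout, stride = cs$stride, attention = FALSE)
    # non-trivial normalization statistics
    for (nm in c("bn1", "bn2", "bnp")) {
      if (is.null(lay[[nm]])) next
      lay[[nm]]$state$running_mean <- rnorm(cs$cout, sd = 0.2)
      lay[[nm]]$state$running_var <- runif(cs$cout, 0.5, 1.5)
    }
    x <- array(rnorm(8 * 8 * cs$cin * 1), c(8, 8, cs$cin, 1))
    expect_equal(blockForward(lay, x), plainBlockOracle(lay, x),
                 tolerance = 1e-10)
  }
})

test_that("zero-weight skip attention halves the input exactly", {
  lay <- zeroParams(dscbamLayer(4L))
  lay$ch$bn$par$gamma <- rep(1, 4)
  lay$sbn$par$gamma <- 1
  x <- randImage(6, 6, 4, 1, seed = 15)
  expect_equal(dscbamForward(lay, x), 0.5 * x, tolerance = 1e-12)
})

test_that("skip attention matches the parallel-sum scalar oracle", {
  set.seed(16)
  lay <- dscbamLayer(2L)
  lay$ch$bn$state$running_mean <- c(0.1, -0.2)
  lay$ch$bn$state$running_var <- c(0.9, 1.1)
  lay$sbn$state$running_mean <- 0.05
  lay$sbn$state$running_var <- 1.3
  x <- array(round(rnorm(4 * 4 * 2 * 1), 1), c(4, 4, 2, 1))
  expect_equal(dscbamForward(lay, x), dscbamOracle(lay, x), tolerance = 1e-10)
  # shape preservation across sizes
  x2 <- randImage(6, 10, 2, 3, seed = 17)
  expect_identical(dim(dscbamForward(lay, x2)), dim(x2))
})

test_that("skip attention combines logits before the single sigmoid", {
  # multipliers must stay below 1 even when both branches saturate positive:
  # summing post-sigmoid maps would allow multipliers up to 2
  lay <- zeroParams(dscbamLayer(2L), value = 0)
  lay$ch$bn$par$beta <- c(10, 10) # large positive channel logits
  lay$sbn$par$beta <- 10          # large positive spatial logits
  x <- array(1, c(4, 4, 2, 1))
  y <- dscbamForward(lay, x)
  expect_true(all(y <= 1 + 1e-12))
  expect_true(all(y > 0.99))
})

test_that("gradients reach both attention branches of the skip module", {
  set.seed(18)
  lay <- dscbamLayer(3L)
  x <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 3, 1))
  lossAt <- function(l) sum(dscbamForward(l, x)^2)
  base <- lossAt(lay)
  eps <- 1e-4
  # perturb a spatial-branch weight
  l2 <- lay; l2$sdw$par$w[1, 1, 1, 1] <- l2$sdw$par$w[1, 1, 1, 1] + eps
  expect_gt(abs(lossAt(l2) - base), 0)
  # perturb a channel-branch weight
  l3 <- lay; l3$ch$pw$par$w[1, 1, 1, 1] <- l3$ch$pw$par$w[1, 1, 1, 1] + eps
  expect_gt(abs(lossAt(l3) - base), 0)
})
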