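test_that("closed-form parameter counts match hand-derived pieces", {
  # first conv alone: 1*5*49 + 5
  first <- architectureSpec(kernel_sizes = 7L, channels = c(1L, 5L),
                            classifier_widths = integer(0))
  expect_identical(countParameters(first) - (5L * 1L + 1L), 250L)
  # classifier alone on 100 channels: 12928 + 4128 + 33
  expect_identical(12928L + 4128L + 33L, 17089L)
  # full default spec
  expect_identical(countParameters(architectureSpec()), 167899L)
})

test_that("closed form equals enumeration over the built network", {
  spec <- architectureSpec()
  net <- buildNetwork(spec, c(779L, 427L))
  expect_identical(countParameters(spec),
                   bowheadPAM:::enumerateParameters(net))

  set.seed(31)
  for (i in 1:20) {
    n_conv <- sample(1:3, 1)
    spec_i <- architectureSpec(
      kernel_sizes = sample(c(3L, 5L, 7L), n_conv, replace = TRUE),
      channels = c(1L, sample(2:12, n_conv)),
      classifier_widths = sample(2:20, sample(0:2, 1)),
      dropout_rate = runif(1, 0, 0.5))
    net_i <- buildNetwork(spec_i, c(64L, 64L), seed = i)
    expect_identical(countParameters(spec_i),
                     bowheadPAM:::enumerateParameters(net_i))
  }
})

test_that("the frequency-axis stage trace matches the per-stage formula", {
  tr <- convStageTrace(architectureSpec(), 779L)
  expect_identical(tr$pooled, c(386L, 191L, 93L, 45L, 21L, 9L, 3L))
})

test_that("too-small inputs are rejected with the failing stage named", {
  spec <- architectureSpec()
  expect_error(buildNetwork(spec, c(333L, 2141L)), "stage 7")
  expect_error(buildNetwork(spec, c(334L, 400L)), NA)
})

test_that("an all-zeros tile scores a finite probability in [0, 1]", {
  net <- buildNetwork(architectureSpec(), c(334L, 334L), seed = 5L)
  p <- predictScores(net, matrix(0, 334, 334),
                     norm_stats = list(mean = 0, sd = 1))
  expect_true(is.finite(p) && p >= 0 && p <= 1)
})

test_that("evaluation-mode scoring is deterministic and batch-consistent", {
  spec <- architectureSpec(kernel_sizes = c(3L, 3L),
                           channels = c(1L, 4L, 8L),
                           classifier_widths = 6L)
  net <- buildNetwork(spec, c(30L, 30L), seed = 2L)
  set.seed(9)
  tiles <- array(rnorm(30 * 30 * 4), dim = c(30, 30, 4))
  p1 <- predictScores(net, tiles, norm_stats = list(mean = 0, sd = 1))
  p2 <- predictScores(net, tiles, norm_stats = list(mean = 0, sd = 1))
  expect_identical(p1, p2)
  singles <- vapply(1:4, function(i)
    predictScores(net, tiles[, , i], norm_stats = list(mean = 0, sd = 1)),
    numeric(1))
  expect_lt(max(abs(p1 - singles)), 1e-6)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("scoring without normalization statistics is rejected", {
  net <- buildNetwork(architectureSpec(kernel_sizes = 3L,
                                       channels = c(1L, 2L),
                                       classifier_widths = integer(0)),
                      c(10L, 10L))
  expect_error(predictScores(net, matrix(0, 10, 10)), "norm_stats")
})

test_that("time extent changes parameter count not at all (GAP contract)", {
  spec <- architectureSpec(kernel_sizes = c(3L, 3L),
                           channels = c(1L, 4L, 8L),
                           classifier_widths = 6L)
  a <- buildNetwork(spec, c(40L, 40L), seed = 1L)
  b <- buildNetwork(spec, c(40L, 80L), seed = 1L)
  expect_identical(bowheadPAM:::enumerateParameters(a),
                   bowheadPAM:::enumerateParameters(b))
  # and identical weights score different-length tiles without error
  p <- predictScores(b, matrix(rnorm(40 * 80), 40, 80),
                     norm_stats = list(mean = 0, sd = 1))
  expect_true(p >= 0 && p <= 1)
})

test_that("analytic gradients match finite differences on a small net", {
  spec <- architectureSpec(kernel_sizes = c(3L, 3L),
                           channels = c(1L, 5L, 10L),  # both conv paths
                           classifier_widths = 4L, dropout_rate = 0)
  net <- buildNetwork(spec, c(18L, 16L), seed = 2L)
  set.seed(7)
  n <- 3
  a <- array(rnorm(18 * 16 * n), dim = c(18, 16, n))
  y <- c(1, 0, 1)
  sw <- c(1.2, 0.8, 1.0)
  g <- bowheadPAM:::.cnn_grad_cpp(a, dim(a), 1:n, y, sw, net@weights, 0, 42)
  lossAt <- function(w)
    bowheadPAM:::.cnn_grad_cpp(a, dim(a), 1:n, y, sw, w, 0, 42)$loss
  eps <- 1e-3  # single-precision core: coarse finite-difference step
  for (part in c("conv", "dense")) {
    for (l in seq_along(net@weights[[part]])) {
      for (nm in c("W", "b")) {
        arr <- net@weights[[part]][[l]][[nm]]
        for (k in sample(length(arr), min(5, length(arr)))) {
          wp <- net@weights; wp[[part]][[l]][[nm]][k] <- arr[k] + eps
          wm <- net@weights; wm[[part]][[l]][[nm]][k] <- arr[k] - eps
          num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
          ana <- g$grads[[part]][[l]][[nm]][k]
          expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-3), 0.05)
        }
      }
    }
  }
})

test_that("probabilities are dropout-seed invariant in evaluation mode", {
  spec <- architectureSpec(kernel_sizes = 3L, channels = c(1L, 3L),
                           classifier_widths = 4L, dropout_rate = 0.4)
  net <- buildNetwork(spec, c(12L, 12L), seed = 3L)
  tile <- array(rnorm(12 * 12), dim = c(12, 12, 1))
  p <- replicate(3, bowheadPAM:::.cnn_predict_cpp(tile, dim(tile), 1L,
                                                  net@weights))
  expect_identical(p[1], p[2])
  expect_identical(p[2], p[3])
})

test_that("architecture specs survive JSON round trips and checkpoints", {
  spec <- architectureSpec()
  back <- archSpecFromJSON(archSpecToJSON(spec))
  expect_identical(back@kernel_sizes, spec@kernel_sizes)
  expect_identical(back@channels, spec@channels)
  expect_identical(back@classifier_widths, spec@classifier_widths)
  expect_equal(back@dropout_rate, spec@dropout_rate)

  small <- architectureSpec(kernel_sizes = 3L, channels = c(1L, 2L),
                            classifier_widths = integer(0))
  net <- buildNetwork(small, c(10L, 10L), seed = 4L)
  net@norm_stats <- list(mean = 1.5, sd = 2)
  p <- file.path(tempdir(), "net.rds")
  saveNetwork(net, p)
  net2 <- loadNetwork(p)
  expect_identical(net2@weights, net@weights)
  expect_identical(net2@norm_stats, net@norm_stats)
  expect_identical(net2@spec@kernel_sizes, small@kernel_sizes)
})
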