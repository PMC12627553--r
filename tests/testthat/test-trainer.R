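test_that("splits are disjoint, exhaustive and reproducible", {
  m <- data.frame(clip_id = sprintf("c%02d", 1:10),
                  label = rep(c(0L, 1L), 5))
  s <- splitDataset(m, 0.8, seed = 3L)
  expect_length(s$train, 8L)
  expect_length(s$val, 2L)
  expect_length(intersect(s$train, s$val), 0L)
  expect_setequal(c(s$train, s$val), m$clip_id)
  expect_identical(splitDataset(m, 0.8, seed = 3L), s)
  expect_false(identical(splitDataset(m, 0.8, seed = 4L)$train, s$train))
})

test_that("a single-class validation split warns", {
  m <- data.frame(clip_id = sprintf("c%02d", 1:10),
                  label = c(rep(1L, 9), 0L))
  # find a seed that puts the lone negative into training
  s <- 1L
  repeat {
    sp <- suppressWarnings(splitDataset(m, 0.8, seed = s))
    if (!"c10" %in% sp$val) break
    s <- s + 1L
  }
  expect_warning(splitDataset(m, 0.8, seed = s), "undefined")
})

test_that("normalization statistics standardize the training set exactly", {
  a <- array(c(0, 2), dim = c(1, 2, 1))
  st <- fitNormStats(a)
  expect_equal(st$mean, 1)
  expect_equal(st$sd, sqrt(2))  # sample sd over {0, 2}
  z <- applyNorm(a, st)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sd(z), 1, tolerance = 1e-6)

  set.seed(8)
  big <- array(rnorm(20 * 20 * 5, mean = 3, sd = 2), dim = c(20, 20, 5))
  st2 <- fitNormStats(big)
  zb <- applyNorm(big, st2)
  expect_equal(mean(zb), 0, tolerance = 1e-6)
  expect_equal(sd(as.vector(zb)), 1, tolerance = 1e-6)
})

test_that("normalization is not idempotent and rejects constant input", {
  a <- array(c(0, 2, 4, 6), dim = c(2, 2, 1))
  st <- fitNormStats(a)
  once <- applyNorm(a, st)
  twice <- applyNorm(once, st)
  expect_false(isTRUE(all.equal(once, twice)))
  expect_error(fitNormStats(array(5, dim = c(2, 2, 2))), "constant")
})

test_that("validation tiles keep the training statistics (no leakage)", {
  set.seed(10)
  train <- array(rnorm(10 * 10 * 4, mean = 1), dim = c(10, 10, 4))
  val <- array(rnorm(10 * 10 * 4, mean = 2), dim = c(10, 10, 4))
  st <- fitNormStats(train)
  zv <- applyNorm(val, st)
  expect_gt(abs(mean(zv)), 0.2)  # validation mean generally not 0
})

test_that("class weights follow the balanced inverse-frequency form", {
  expect_equal(classWeights(rep(c(0L, 1L), 50)), c("0" = 1, "1" = 1))
  w <- classWeights(rep(c(0L, 1L), c(75, 25)))
  expect_equal(unname(w), c(100 / 150, 100 / 50), tolerance = 1e-12)
  expect_equal(unname(w["1"]), 2)
  expect_error(classWeights(rep(1L, 5)), "both classes")
})

test_that("weighted sample count sums to N for any class mix", {
  set.seed(4)
  for (i in 1:5) {
    n1 <- sample(1:40, 1)
    labels <- sample(rep(c(0L, 1L), c(50 - n1, n1)))
    w <- classWeights(labels)
    expect_equal(sum(w[as.character(labels)]), 50)
  }
})

test_that("the save rule replays hand-simulated metric traces", {
  cfg <- trainConfig(max_epochs = 10L)
  h <- simulateSaveSchedule(c(0.90, 0.85, 0.90), c(0.02, 0.005, 0.004), cfg)
  expect_identical(h@epochs$saved, c(FALSE, TRUE, TRUE))
  expect_identical(h@best_epoch, 3L)

  # sensitivity gate: perfect FP rate never saves below the threshold
  h2 <- simulateSaveSchedule(rep(0.79, 20), rep(0, 20), cfg)
  expect_true(all(!h2@epochs$saved))
  expect_true(is.na(h2@best_epoch))

  # FP-rate gate is strict: exactly 0.01 never saves
  h3 <- simulateSaveSchedule(rep(0.9, 3), rep(0.01, 3), cfg)
  expect_true(all(!h3@epochs$saved))

  # an equal FP rate does not replace the incumbent
  h4 <- simulateSaveSchedule(c(0.9, 0.95), c(0.004, 0.004), cfg)
  expect_identical(h4@epochs$saved, c(TRUE, FALSE))
  expect_identical(h4@best_epoch, 1L)
})

test_that("patience stops training after 15 epochs without a save", {
  cfg <- trainConfig(patience = 15L)
  h <- simulateSaveSchedule(rep(0.5, 40), rep(0.5, 40), cfg)
  expect_identical(h@stop_epoch, 15L)
  expect_true(is.na(h@best_epoch))

  # a save resets the patience counter
  sens <- c(rep(0.5, 5), 0.9, rep(0.5, 40))
  fp <- c(rep(0.5, 5), 0.001, rep(0.5, 40))
  h2 <- simulateSaveSchedule(sens, fp, cfg)
  expect_identical(h2@stop_epoch, 21L)
  expect_identical(h2@best_epoch, 6L)
})

test_that("saved epochs have strictly decreasing validation FP rates", {
  set.seed(12)
  for (i in 1:10) {
    sens <- runif(30, 0.7, 1)
    fp <- runif(30, 0, 0.02)
    h <- simulateSaveSchedule(sens, fp, trainConfig(patience = 100L))
    fps <- h@epochs$val_fp_rate[h@epochs$saved]
    if (length(fps) > 1) expect_true(all(diff(fps) < 0))
    # and the gap between consecutive saves never exceeds patience
    saves <- h@epochs$epoch[h@epochs$saved]
    if (length(saves) > 1) expect_true(all(diff(saves) <= 100L))
  }
})

test_that("training reduces loss and can meet the save criterion on an easy task", {
  # tiny high-contrast surrogate: tiles whose class differs by a strong
  # in-band tone; a small net should separate them within a few epochs
  set.seed(20)
  makeTiny <- function(n, seed) {
    drawn <- sampleSceneSpecs(n, n, clip_duration = 15, seed = seed)
    tiles <- lapply(seq_along(drawn$specs), function(i) {
      cl <- synthClip(drawn$specs[[i]],
                      clip_id = drawn$manifest$clip_id[i],
                      start_time = drawn$manifest$start_time[i])
      tv <- tileSpectrogram(waveform(cl), 5000, target_duration = 15,
                            clip_id = cl@clip_id,
                            start_time = cl@start_time,
                            label = clipLabel(cl))
      tv
    })
    makeTileSet(tiles, target_duration = 15)
  }
  train <- makeTiny(12, 100L)
  val <- makeTiny(6, 200L)
  # crop tiles to a small square window in the call band to keep this fast
  crop <- function(ts) {
    ts@values <- ts@values[100:199, 1:40, , drop = FALSE]
    ts
  }
  train <- crop(train); val <- crop(val)
  spec <- architectureSpec(kernel_sizes = c(5L, 3L),
                           channels = c(1L, 4L, 8L),
                           classifier_widths = 8L, dropout_rate = 0.1)
  net <- buildNetwork(spec, dim(train@values)[1:2], seed = 1L)
  cfg <- trainConfig(max_epochs = 15L, batch_size = 8L,
                     learning_rate = 2e-3, seed = 1L, patience = 15L)
  fit <- suppressWarnings(trainDetector(net, train, val, config = cfg))
  h <- trainHistory(fit)@epochs
  expect_lt(h$loss[nrow(h)], h$loss[1])
  # norm stats embedded in the returned network
  expect_true(is.numeric(bestNetwork(fit)@norm_stats$mean))
})

test_that("training rejects an empty validation set", {
  ts <- quickTileSet(2, 2, duration = 10)
  net <- buildNetwork(architectureSpec(kernel_sizes = 3L,
                                       channels = c(1L, 2L),
                                       classifier_widths = integer(0)),
                      dim(ts@values)[1:2])
  expect_error(trainDetector(net, ts, ts[integer(0)],
                             config = trainConfig(max_epochs = 1L)),
               "empty")
})
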