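#' Construct a training configuration
#'
#' @param train_fraction fraction of files used for training (study: 0.8).
#' @param save_min_sensitivity minimum validation sensitivity for a model
#'   to be saved (study: 0.8).
#' @param save_max_fp_rate validation false-positive rate must be strictly
#'   below this for a save (study: 0.01).
#' @param patience epochs without a new saved model before training stops
#'   (study: 15).
#' @param max_epochs hard epoch cap.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling shuffling, initial weights and
#'   dropout.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(train_fraction = 0.8, save_min_sensitivity = 0.8,
                        save_max_fp_rate = 0.01, patience = 15L,
                        max_epochs = 100L, batch_size = 32L,
                        learning_rate = 1e-3, seed = 1L) {
  new("TrainConfig", train_fraction = train_fraction,
      save_min_sensitivity = save_min_sensitivity,
      save_max_fp_rate = save_max_fp_rate, patience = as.integer(patience),
      max_epochs = as.integer(max_epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed))
}

#' Split a manifest into training and validation sets
#'
#' Uniform random permutation under `seed`; the first
#' `floor(n * train_fraction)` entries train, the rest validate. The split
#' is disjoint and exhaustive. A warning is raised when the validation set
#' lacks one of the classes, since sensitivity or false-positive rate is
#' then undefined downstream.
#'
#' @param manifest data.frame with at least `clip_id` and `label` columns.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer.
#' @return list with `train` and `val` character vectors of clip ids.
#' @export
splitDataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  stopifnot(nrow(manifest) > 0, train_fraction > 0, train_fraction < 1)
  withSeed(seed, {
    perm <- sample.int(nrow(manifest))
    n_train <- floor(nrow(manifest) * train_fraction)
    train <- manifest$clip_id[perm[seq_len(n_train)]]
    val <- manifest$clip_id[perm[-seq_len(n_train)]]
    if (!is.null(manifest$label)) {
      val_labels <- manifest$label[match(val, manifest$clip_id)]
      if (length(unique(val_labels)) < 2L)
        warning("validation split lacks a class: ",
                "sensitivity or false-positive rate will be undefined")
    }
    list(train = train, val = val)
  })
}

#' Fit Z-score normalization statistics on the training split
#'
#' A single global mean and standard deviation over all training tile
#' values. Statistics must come exclusively from the training split;
#' validation and inference tiles reuse them unchanged.
#'
#' @param tiles a [TileSet-class], matrix or 3-d array of training tiles.
#' @return list with `mean` and `sd`.
#' @export
fitNormStats <- function(tiles) {
  a <- tilesAsArray(tiles)
  mo <- arrayMoments(a)
  if (!is.finite(mo$sd) || mo$sd <= 0)
    stop("training tiles are constant-valued: Z-score normalization ",
         "is undefined (sd = 0)")
  list(mean = mo$mean, sd = mo$sd)
}

#' Apply Z-score normalization
#'
#' `(x - mean) / sd` elementwise. Not idempotent: applying the statistics
#' twice standardizes twice.
#'
#' @param tiles a [TileSet-class], matrix or 3-d array.
#' @param stats list with `mean` and `sd` from [fitNormStats()].
#' @return object of the same kind as `tiles`.
#' @export
applyNorm <- function(tiles, stats) {
  stopifnot(!is.null(stats$mean), !is.null(stats$sd), stats$sd > 0)
  if (is(tiles, "TileSet")) {
    tiles@values <- (tiles@values - stats$mean) / stats$sd
    return(tiles)
  }
  (tiles - stats$mean) / stats$sd
}

#' Balanced inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)` with K = 2 classes, applied as per-sample loss
#' weights so the weighted sample count sums to N for any class mix.
#'
#' @param labels integer vector of 0/1 labels; both classes must be
#'   present.
#' @return named numeric vector with weights for classes `"0"` and `"1"`.
#' @export
classWeights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present to compute class weights")
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

# an incumbent with a zero false-positive rate can never be replaced
# (replacement requires a strictly lower rate), so training past it cannot
# change the returned model; both the trainer and the replay end early
saturated <- function(state) {
  !is.na(state$best_fp) && state$best_fp == 0
}

# one step of the save/patience state machine.
# state: list(best_fp, best_epoch, since_save)
saveRuleStep <- function(state, epoch, sens, fp, config) {
  meets <- !is.na(sens) && !is.na(fp) &&
    sens >= config@save_min_sensitivity && fp < config@save_max_fp_rate
  improves <- is.na(state$best_fp) || fp < state$best_fp
  saved <- meets && improves
  if (saved) {
    state$best_fp <- fp
    state$best_epoch <- epoch
    state$since_save <- 0L
  } else {
    state$since_save <- state$since_save + 1L
  }
  state$saved <- saved
  state
}

#' Replay the save/early-stopping protocol on a metric trace
#'
#' Pure replay of the training protocol: at each epoch the incumbent best
#' model is replaced when validation sensitivity meets the threshold, the
#' false-positive rate is below its cap, and the false-positive rate
#' improves on the incumbent; training stops after `patience` consecutive
#' epochs without a save, or when the trace ends.
#'
#' The replay (like the trainer) also ends once the incumbent reaches a
#' zero false-positive rate: a save requires a strictly lower rate, so no
#' later epoch could replace it.
#'
#' @param sensitivity,fp_rate numeric vectors of per-epoch validation
#'   metrics.
#' @param config a [TrainConfig-class] (only the save thresholds and
#'   patience are consulted).
#' @return a [TrainHistory-class].
#' @export
simulateSaveSchedule <- function(sensitivity, fp_rate, config = trainConfig()) {
  stopifnot(length(sensitivity) == length(fp_rate))
  state <- list(best_fp = NA_real_, best_epoch = NA_integer_,
                since_save = 0L)
  rows <- list()
  stop_epoch <- length(sensitivity)
  for (e in seq_along(sensitivity)) {
    state <- saveRuleStep(state, e, sensitivity[e], fp_rate[e], config)
    rows[[e]] <- data.frame(epoch = e, loss = NA_real_,
                            val_sensitivity = sensitivity[e],
                            val_fp_rate = fp_rate[e], saved = state$saved)
    if (state$since_save >= config@patience || saturated(state)) {
      stop_epoch <- e
      break
    }
  }
  new("TrainHistory", epochs = do.call(rbind, rows),
      best_epoch = state$best_epoch, stop_epoch = as.integer(stop_epoch))
}

# Adam update over the nested weight list; m/v share its structure
adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (part in c("conv", "dense")) {
    for (l in seq_along(weights[[part]])) {
      for (nm in c("W", "b")) {
        r <- upd(weights[[part]][[l]][[nm]], grads[[part]][[l]][[nm]],
                 state$m[[part]][[l]][[nm]], state$v[[part]][[l]][[nm]])
        weights[[part]][[l]][[nm]] <- r$w
        state$m[[part]][[l]][[nm]] <- r$m
        state$v[[part]][[l]][[nm]] <- r$v
      }
    }
  }
  list(weights = weights, state = state)
}

zeroLike <- function(weights) {
  for (part in c("conv", "dense"))
    for (l in seq_along(weights[[part]]))
      for (nm in c("W", "b"))
        weights[[part]][[l]][[nm]][] <- 0
  weights
}

#' Train the detector under the study protocol
#'
#' Minimizes class-weighted binary cross-entropy with Adam. Inputs are
#' standardized with statistics fitted on the training tiles only (unless
#' `norm_stats` is supplied). After every epoch the validation set is
#' scored in evaluation mode and thresholded at 0.5; the incumbent best
#' model is replaced when validation sensitivity is at least
#' `save_min_sensitivity`, the false-positive rate is strictly below
#' `save_max_fp_rate`, and the false-positive rate improves on the
#' incumbent. Training stops after `patience` consecutive epochs without a
#' save, at `max_epochs`, or as soon as the incumbent reaches a zero
#' false-positive rate (a save requires a strictly lower rate, so no later
#' epoch could replace it).
#'
#' @param network an initialized [Network-class].
#' @param train_tiles,val_tiles [TileSet-class] objects or 3-d arrays.
#' @param train_labels,val_labels 0/1 integer vectors (defaults taken from
#'   the TileSets).
#' @param config a [TrainConfig-class].
#' @param norm_stats optional precomputed normalization statistics.
#' @param verbose print per-epoch progress.
#' @return a [DetectorFit-class]. When no epoch meets the save criterion
#'   the fit carries the final weights and `saved_any` is FALSE.
#' @export
trainDetector <- function(network, train_tiles, val_tiles,
                          train_labels = NULL, val_labels = NULL,
                          config = trainConfig(), norm_stats = NULL,
                          verbose = FALSE) {
  stopifnot(is(network, "Network"), is(config, "TrainConfig"))
  validObject(config)
  if (is.null(train_labels) && is(train_tiles, "TileSet"))
    train_labels <- train_tiles@labels
  if (is.null(val_labels) && is(val_tiles, "TileSet"))
    val_labels <- val_tiles@labels
  train_labels <- as.integer(train_labels)
  val_labels <- as.integer(val_labels)
  if (length(val_labels) == 0L) stop("validation set is empty")
  xa <- tilesAsArray(train_tiles)
  va <- tilesAsArray(val_tiles)
  if (is.null(norm_stats)) norm_stats <- fitNormStats(xa)
  xa <- (xa - norm_stats$mean) / norm_stats$sd
  va <- (va - norm_stats$mean) / norm_stats$sd
  n <- dim(xa)[3]
  stopifnot(length(train_labels) == n, length(val_labels) == dim(va)[3])

  cw <- classWeights(train_labels)
  sw_all <- unname(cw[as.character(train_labels)])

  weights <- network@weights
  adam <- list(t = 0L, m = zeroLike(weights), v = zeroLike(weights))
  state <- list(best_fp = NA_real_, best_epoch = NA_integer_,
                since_save = 0L)
  best_weights <- NULL
  rows <- list()
  stop_epoch <- config@max_epochs
  dims_x <- as.integer(dim(xa))

  withSeed(config@seed, {
    for (epoch in seq_len(config@max_epochs)) {
      perm <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (b0 in seq(1L, n, by = config@batch_size)) {
        idx <- perm[b0:min(b0 + config@batch_size - 1L, n)]
        drop_seed <- sample.int(.Machine$integer.max - 1L, 1)
        res <- .cnn_grad_cpp(xa, dims_x, idx, as.numeric(train_labels[idx]),
                             sw_all[idx], weights,
                             network@spec@dropout_rate, drop_seed)
        st <- adamStep(weights, res$grads, adam, config@learning_rate)
        weights <- st$weights
        adam <- st$state
        epoch_loss <- epoch_loss + res$loss
        n_batches <- n_batches + 1L
      }
      probs <- .cnn_predict_cpp(va, as.integer(dim(va)),
                                seq_len(dim(va)[3]), weights)
      pred <- thresholdScores(probs)
      perf <- confusionSummary(pred, val_labels, level = "file")
      sens <- sensitivity(perf)
      fp <- fpRate(perf)
      state <- saveRuleStep(state, epoch, sens, fp, config)
      if (state$saved) best_weights <- weights
      rows[[epoch]] <- data.frame(epoch = epoch,
                                  loss = epoch_loss / n_batches,
                                  val_sensitivity = sens, val_fp_rate = fp,
                                  saved = state$saved)
      if (verbose)
        message(sprintf(
          "epoch %d: loss %.4f, val sens %.3f, val fp %.4f%s", epoch,
          epoch_loss / n_batches, sens, fp,
          if (state$saved) " [saved]" else ""))
      if (state$since_save >= config@patience || saturated(state)) {
        stop_epoch <- epoch
        break
      }
      stop_epoch <- epoch
    }
  })

  saved_any <- !is.na(state$best_epoch)
  out_net <- network
  out_net@weights <- if (saved_any) best_weights else weights
  out_net@norm_stats <- norm_stats
  history <- new("TrainHistory", epochs = do.call(rbind, rows),
                 best_epoch = state$best_epoch,
                 stop_epoch = as.integer(stop_epoch))
  if (!saved_any)
    warning("no model met the save criterion; returning final weights")
  new("DetectorFit", network = out_net, history = history,
      norm_stats = norm_stats, saved_any = saved_any)
}

#' Generate a tile set of synthetic labelled scenes
#'
#' Convenience pipeline: draws scene recipes, synthesizes each clip and
#' computes its spectrogram tile. The default 120-s clips give a 779 x 427
#' tile, the smallest extent on which the full detector architecture is
#' valid while keeping a desk-scale study tractable.
#'
#' @param n_pos,n_neg clip counts per class.
#' @param clip_duration seconds.
#' @param seed master seed.
#' @param pool template pool ([defaultTemplatePool()]).
#' @return a [TileSet-class] with ground-truth labels.
#' @export
synthTileSet <- function(n_pos, n_neg, clip_duration = 120, seed = 1L,
                         pool = defaultTemplatePool()) {
  drawn <- sampleSceneSpecs(n_pos, n_neg, pool = pool,
                            clip_duration = clip_duration, seed = seed)
  tiles <- vector("list", nrow(drawn$manifest))
  for (i in seq_along(drawn$specs)) {
    cl <- synthClip(drawn$specs[[i]], clip_id = drawn$manifest$clip_id[i],
                    start_time = drawn$manifest$start_time[i])
    tiles[[i]] <- tileSpectrogram(waveform(cl), cl@sample_rate,
                                  target_duration = clip_duration,
                                  clip_id = cl@clip_id,
                                  start_time = cl@start_time,
                                  label = clipLabel(cl))
  }
  makeTileSet(tiles, target_duration = clip_duration)
}

#' Run the desk-scale synthetic training study
#'
#' End-to-end surrogate for the full training protocol at a size that runs
#' on one CPU: 120-s scenes (the shortest clips the full architecture
#' accepts), 150 + 150 training and 50 + 50 validation clips at moderate
#' SNR, spectrogram tiles, Z-score standardization, class weights, the
#' sensitivity/false-positive save criterion, and up to `restarts` seeded
#' re-initializations when no epoch meets the save criterion. The
#' validation metrics of the returned model are recomputed from its scores
#' on the held-out split.
#'
#' @param seed master seed for data and the first attempt.
#' @param n_train,n_val length-2 vectors (positives, negatives).
#' @param clip_duration seconds.
#' @param snr_range bowhead-event SNR range (dB) for the study scenes; the
#'   calibration that makes the save criterion attainable within the
#'   surrogate's epoch budget (see the methods vignette).
#' @param max_epochs epoch cap per attempt.
#' @param batch_size,learning_rate optimizer settings.
#' @param restarts maximum number of seeded attempts.
#' @param verbose print per-epoch progress.
#' @return list with `fit` (a [DetectorFit-class]), `val_sensitivity`,
#'   `val_fp_rate`, `attempts`, and the tile sets used.
#' @export
syntheticStudy <- function(seed = 1L, n_train = c(150L, 150L),
                           n_val = c(50L, 50L), clip_duration = 120,
                           snr_range = c(24, 30), max_epochs = 6L,
                           batch_size = 4L, learning_rate = 1e-3,
                           restarts = 3L, verbose = FALSE) {
  pool <- defaultTemplatePool()
  pool$bowhead$simple_fm$snr <- snr_range
  pool$bowhead$song_unit$snr <- snr_range
  train <- synthTileSet(n_train[1], n_train[2], clip_duration, seed = seed,
                        pool = pool)
  val <- synthTileSet(n_val[1], n_val[2], clip_duration,
                      seed = seed + 500L, pool = pool)
  fit <- NULL
  attempts <- 0L
  for (attempt in seq_len(restarts)) {
    attempts <- attempt
    attempt_seed <- as.integer(seed + (attempt - 1L) * 1000L)
    net <- buildNetwork(architectureSpec(), dim(train@values)[1:2],
                        seed = attempt_seed)
    cfg <- trainConfig(max_epochs = as.integer(max_epochs),
                       batch_size = as.integer(batch_size),
                       learning_rate = learning_rate, seed = attempt_seed)
    fit <- suppressWarnings(trainDetector(net, train, val, config = cfg,
                                          verbose = verbose))
    if (fit@saved_any) break
  }
  probs <- predictScores(bestNetwork(fit), val)
  perf <- confusionSummary(thresholdScores(probs), tileLabels(val))
  list(fit = fit, val_sensitivity = sensitivity(perf),
       val_fp_rate = fpRate(perf), attempts = attempts,
       train = train, val = val)
}

#' @describeIn DetectorFit-class best network.
#' @export
setMethod("bestNetwork", "DetectorFit", function(object) object@network)

#' @describeIn DetectorFit-class training history.
#' @export
setMethod("trainHistory", "DetectorFit", function(object) object@history)

#' @describeIn DetectorFit-class normalization statistics.
#' @export
setMethod("normStats", "DetectorFit", function(object) object@norm_stats)

setMethod("show", "DetectorFit", function(object) {
  h <- object@history
  cat(sprintf("DetectorFit: %d epochs run, best epoch %s\n",
              h@stop_epoch,
              ifelse(is.na(h@best_epoch), "none (no save)", h@best_epoch)))
  if (!is.na(h@best_epoch)) {
    row <- h@epochs[h@epochs$epoch == h@best_epoch, ]
    cat(sprintf("  best: val sensitivity %.3f, val FP rate %.4f\n",
                row$val_sensitivity, row$val_fp_rate))
  }
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs, best %s\n", nrow(object@epochs),
              ifelse(is.na(object@best_epoch), "none", object@best_epoch)))
  print(utils::head(object@epochs, 10))
  if (nrow(object@epochs) > 10) cat("  ...\n")
})
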