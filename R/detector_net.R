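#' Construct a CNN architecture specification
#'
#' Defaults describe the study detector: seven valid square convolutions
#' with kernel sizes (7, 5, 5, 3, 3, 3, 3), stride 1, channels growing
#' 1 to 100, each stage followed by ReLU, 2x2 max pooling and dropout at
#' rate 0.2; global average pooling to one value per channel; a classifier
#' with hidden widths 128 and 32; one logistic output unit.
#'
#' @param kernel_sizes integer vector of odd kernel sizes.
#' @param channels integer vector of channel counts (first entry 1).
#' @param classifier_widths hidden dense-layer widths.
#' @param dropout_rate dropout rate in \[0, 1).
#' @return an [ArchitectureSpec-class].
#' @export
architectureSpec <- function(kernel_sizes = c(7L, 5L, 5L, 3L, 3L, 3L, 3L),
                             channels = c(1L, 5L, 10L, 20L, 40L, 60L, 80L,
                                          100L),
                             classifier_widths = c(128L, 32L),
                             dropout_rate = 0.2) {
  new("ArchitectureSpec", kernel_sizes = as.integer(kernel_sizes),
      stride = 1L, pool_size = 2L, dropout_rate = dropout_rate,
      channels = as.integer(channels),
      classifier_widths = as.integer(classifier_widths), output_units = 1L)
}

# pooled extent convention shared with the C++ side: floor(d/2), keeping a
# partial window only when the extent is below the pool size
poolExtent <- function(d) ifelse(d >= 2L, d %/% 2L, 1L)

#' Per-stage spatial extents of the convolution stack
#'
#' For each convolutional stage, the extent after the valid convolution
#' (`d - k + 1`) and after 2x2 max pooling, along one axis.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param extent input extent along the axis.
#' @return data.frame with columns stage, kernel, conv (extent after the
#'   convolution) and pooled.
#' @export
convStageTrace <- function(spec, extent) {
  d <- as.integer(extent)
  rows <- lapply(seq_along(spec@kernel_sizes), function(i) {
    k <- spec@kernel_sizes[i]
    conv <- d - k + 1L
    pooled <- if (conv >= 1L) poolExtent(conv) else NA_integer_
    r <- data.frame(stage = i, kernel = k, conv = conv, pooled = pooled)
    d <<- if (conv >= 1L) pooled else conv
    r
  })
  do.call(rbind, rows)
}

#' Closed-form trainable parameter count
#'
#' Sums `c_in * c_out * k^2 + c_out` over the convolutional layers and
#' `n_in * n_out + n_out` over the classifier (including the output unit).
#' For the default architecture this is 167,899.
#'
#' @param spec an [ArchitectureSpec-class].
#' @return integer parameter count.
#' @export
countParameters <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  n <- 0
  for (i in seq_along(spec@kernel_sizes)) {
    n <- n + spec@channels[i] * spec@channels[i + 1] *
      spec@kernel_sizes[i]^2 + spec@channels[i + 1]
  }
  widths <- c(spec@channels[length(spec@channels)], spec@classifier_widths,
              spec@output_units)
  for (i in seq_len(length(widths) - 1L)) {
    n <- n + widths[i] * widths[i + 1] + widths[i + 1]
  }
  as.integer(n)
}

# enumeration over the built network's parameter arrays (the brute-force
# counterpart of countParameters)
enumerateParameters <- function(network) {
  s <- 0L
  for (l in network@weights$conv) s <- s + length(l$W) + length(l$b)
  for (l in network@weights$dense) s <- s + length(l$W) + length(l$b)
  s
}

#' Build a network from an architecture specification
#'
#' Validates that every convolution stage has positive extent for the given
#' input shape (identifying the failing stage otherwise) and initializes
#' weights (He-scaled normal draws for conv/dense kernels, zero biases).
#'
#' @param spec an [ArchitectureSpec-class].
#' @param input_shape integer length 2: (frequency bins, time frames). For
#'   the default architecture both extents must be at least 334.
#' @param seed integer seed for weight initialization.
#' @return a [Network-class].
#' @export
buildNetwork <- function(spec, input_shape, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  input_shape <- as.integer(input_shape)
  for (axis in 1:2) {
    tr <- convStageTrace(spec, input_shape[axis])
    bad <- which(tr$conv < 1L)
    if (length(bad))
      stop(sprintf(
        "input_shape %s too small: stage %d convolution has extent %d on the %s axis",
        paste(input_shape, collapse = "x"), bad[1], tr$conv[bad[1]],
        c("frequency", "time")[axis]))
  }
  withSeed(seed, {
    conv <- list()
    for (i in seq_along(spec@kernel_sizes)) {
      k <- spec@kernel_sizes[i]
      cin <- spec@channels[i]
      cout <- spec@channels[i + 1]
      sd <- sqrt(2 / (k * k * cin))
      conv[[i]] <- list(
        W = array(stats::rnorm(k * k * cin * cout, sd = sd),
                  dim = c(k, k, cin, cout)),
        b = numeric(cout))
    }
    widths <- c(spec@channels[length(spec@channels)],
                spec@classifier_widths, spec@output_units)
    dense <- list()
    for (i in seq_len(length(widths) - 1L)) {
      # He-scaled hidden layers; the output layer starts near zero so the
      # initial prediction sits at the class prior rather than a saturated
      # probability
      sd <- if (i == length(widths) - 1L) 0.01 else sqrt(2 / widths[i])
      dense[[i]] <- list(
        W = matrix(stats::rnorm(widths[i] * widths[i + 1], sd = sd),
                   nrow = widths[i], ncol = widths[i + 1]),
        b = numeric(widths[i + 1]))
    }
    new("Network", spec = spec, weights = list(conv = conv, dense = dense),
        input_shape = input_shape, norm_stats = list())
  })
}

# coerce tiles to an F x T x n array
tilesAsArray <- function(tiles) {
  if (is(tiles, "TileSet")) return(tiles@values)
  if (is(tiles, "SpectrogramTile"))
    return(array(tiles@values, dim = c(dim(tiles@values), 1L)))
  if (is.matrix(tiles)) return(array(tiles, dim = c(dim(tiles), 1L)))
  if (is.array(tiles) && length(dim(tiles)) == 3) return(tiles)
  stop("tiles must be a TileSet, SpectrogramTile, matrix or 3-d array")
}

#' Score tiles with a network
#'
#' Standardizes the tiles with the supplied training-set statistics and
#' runs the forward pass in evaluation mode (dropout off), returning one
#' probability per tile. Scoring is deterministic given fixed weights.
#'
#' @param network a [Network-class].
#' @param tiles a [TileSet-class], matrix or 3-d array.
#' @param norm_stats list with `mean` and `sd` fitted on the training split
#'   ([fitNormStats()]). Defaults to the statistics embedded in the network
#'   after training; scoring unstandardized input is rejected.
#' @param standardized set TRUE if `tiles` are already standardized, in
#'   which case `norm_stats` is not consulted.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predictScores <- function(network, tiles, norm_stats = network@norm_stats,
                          standardized = FALSE) {
  stopifnot(is(network, "Network"))
  a <- tilesAsArray(tiles)
  if (!standardized) {
    if (is.null(norm_stats$mean) || is.null(norm_stats$sd))
      stop("norm_stats missing: tiles must be standardized with the ",
           "training-set statistics before scoring")
    a <- (a - norm_stats$mean) / norm_stats$sd
  }
  d <- dim(a)
  .cnn_predict_cpp(a, as.integer(d), seq_len(d[3]), network@weights)
}

#' Save a trained network checkpoint
#'
#' Writes an RDS checkpoint holding the weights, the architecture
#' specification embedded as a JSON block, the input shape and any
#' normalization statistics.
#'
#' @param network a [Network-class].
#' @param path output file.
#' @export
saveNetwork <- function(network, path) {
  saveRDS(list(spec_json = archSpecToJSON(network@spec),
               weights = network@weights,
               input_shape = network@input_shape,
               norm_stats = network@norm_stats), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path file written by [saveNetwork()].
#' @return a [Network-class].
#' @export
loadNetwork <- function(path) {
  x <- readRDS(path)
  new("Network", spec = archSpecFromJSON(x$spec_json), weights = x$weights,
      input_shape = as.integer(x$input_shape),
      norm_stats = if (is.null(x$norm_stats)) list() else x$norm_stats)
}

#' Serialize an architecture specification to JSON
#'
#' @param spec an [ArchitectureSpec-class].
#' @return a JSON string.
#' @export
archSpecToJSON <- function(spec) {
  as.character(jsonlite::toJSON(list(
    kernel_sizes = spec@kernel_sizes, stride = spec@stride,
    pool_size = spec@pool_size, dropout_rate = spec@dropout_rate,
    channels = spec@channels, classifier_widths = spec@classifier_widths,
    output_units = spec@output_units), auto_unbox = TRUE, digits = NA))
}

#' Deserialize an architecture specification from JSON
#'
#' @param json string produced by [archSpecToJSON()].
#' @return an [ArchitectureSpec-class].
#' @export
archSpecFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  architectureSpec(kernel_sizes = x$kernel_sizes, channels = x$channels,
                   classifier_widths = x$classifier_widths,
                   dropout_rate = x$dropout_rate)
}

#' @describeIn Network-class architecture specification.
#' @export
setMethod("archSpec", "Network", function(object) object@spec)

#' @describeIn Network-class weight list.
#' @export
setMethod("netWeights", "Network", function(object) object@weights)

setMethod("show", "Network", function(object) {
  cat(sprintf(
    "Network: %d conv stages, channels %s, input %s, %s parameters\n",
    length(object@spec@kernel_sizes),
    paste(object@spec@channels, collapse = ">"),
    paste(object@input_shape, collapse = "x"),
    format(countParameters(object@spec), big.mark = ",")))
  if (!is.null(object@norm_stats$mean))
    cat(sprintf("  norm stats: mean %.4g, sd %.4g\n",
                object@norm_stats$mean, object@norm_stats$sd))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf(
    "ArchitectureSpec: kernels (%s), channels (%s), classifier (%s), dropout %.2g\n",
    paste(object@kernel_sizes, collapse = ", "),
    paste(object@channels, collapse = ", "),
    paste(object@classifier_widths, collapse = ", "),
    object@dropout_rate))
})
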