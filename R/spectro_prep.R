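#' Resample audio to the 5 kHz analysis rate
#'
#' Anti-aliased polyphase resampling to the pipeline's common 5 kHz rate
#' followed by peak normalization (max |x| = 1). Recorders in this kind of
#' deployment sample at 5.333--96 kHz, so only downsampling is supported.
#'
#' @param audio numeric amplitude series.
#' @param orig_rate original sampling rate, Hz (must be >= 5000).
#' @param target_rate target rate, Hz (default 5000).
#' @return numeric series of length `round(length(audio) * target_rate /
#'   orig_rate)`, peak-normalized.
#' @export
prepareWaveform <- function(audio, orig_rate, target_rate = 5000) {
  if (length(audio) == 0) stop("audio is empty")
  if (orig_rate < target_rate)
    stop("orig_rate below the target rate: upsampling is unsupported")
  n_out <- round(length(audio) * target_rate / orig_rate)
  if (orig_rate == target_rate) {
    y <- audio
  } else {
    # rational approximation of the rate ratio for the polyphase filter
    frac <- MASS::fractions(target_rate / orig_rate, max.denominator = 1000)
    pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
    if (length(pq) == 1L) pq <- c(pq, 1L)
    y <- signal::resample(audio, pq[1], pq[2])
  }
  # enforce the length contract exactly
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak
  y
}

#' Frequency-bin centres retained by the analysis band
#'
#' Bin k (0-based) of a `dft`-point DFT at `sample_rate` has centre
#' frequency `k * sample_rate / dft`; bins whose centre lies in the closed
#' band are retained. With the study parameters (5 kHz, DFT 4096, band
#' 50--1000 Hz) that is k = 41, ..., 819: 779 bins.
#'
#' @param sample_rate Hz.
#' @param dft DFT size, samples.
#' @param band closed frequency band, Hz.
#' @return numeric vector of retained bin-centre frequencies (Hz), low to
#'   high; 0-based bin indices in attribute `"bins"`.
#' @export
bandBinFrequencies <- function(sample_rate = 5000, dft = 4096L,
                               band = c(50, 1000)) {
  k <- 0:(dft %/% 2)
  f <- k * sample_rate / dft
  keep <- f >= band[1] & f <= band[2]
  structure(f[keep], bins = k[keep])
}

# number of full analysis frames in a waveform of length L
fullFrameCount <- function(L, window = 2800L, hop = 1400L) {
  if (L < window) 0L else 1L + (L - window) %/% hop
}

#' Compute the band-limited log-magnitude spectrogram tile of a clip
#'
#' Short-time transform with a 2800-sample Hann window zero-padded to a
#' 4096-point DFT, hop 1400 samples, frames starting at sample 1 with no
#' centring. The magnitude is log-scaled as `log10(magnitude + 1e-10)`
#' (the floor makes digital silence well defined), rows are restricted to
#' bins whose centre frequency lies in the closed 50--1000 Hz band (low to
#' high), and the frame axis is padded with the log floor up to the frame
#' count of a full `target_duration` clip.
#'
#' @param waveform numeric series at `sample_rate`.
#' @param sample_rate must equal the analysis rate (5000 Hz).
#' @param target_duration padding target in seconds (600 for study files);
#'   longer waveforms are rejected.
#' @param window,dft,hop STFT parameters in samples.
#' @param band closed frequency band, Hz.
#' @param clip_id,start_time,label metadata stored on the tile.
#' @return a [SpectrogramTile-class].
#' @export
tileSpectrogram <- function(waveform, sample_rate = 5000,
                            target_duration = 600, window = 2800L,
                            dft = 4096L, hop = 1400L, band = c(50, 1000),
                            clip_id = "clip", start_time = NULL,
                            label = NA_integer_) {
  if (sample_rate != 5000)
    stop("waveform must be at the 5 kHz analysis rate; see prepareWaveform()")
  L <- length(waveform)
  if (L > round(target_duration * sample_rate))
    stop("waveform longer than target_duration")
  n_frames <- fullFrameCount(L, window, hop)
  target_frames <- fullFrameCount(round(target_duration * sample_rate),
                                  window, hop)
  fsel <- bandBinFrequencies(sample_rate, dft, band)
  bins <- attr(fsel, "bins")
  log_floor <- log10(1e-10)
  vals <- matrix(log_floor, nrow = length(bins), ncol = target_frames)
  if (n_frames > 0) {
    hann <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1L)) / window)
    starts <- 1L + (seq_len(n_frames) - 1L) * hop
    frames <- matrix(0, nrow = dft, ncol = n_frames)
    idx <- outer(0:(window - 1L), starts, "+")
    frames[seq_len(window), ] <- waveform[idx] * hann
    spec <- stats::mvfft(frames)
    mag <- Mod(spec[bins + 1L, , drop = FALSE])
    vals[, seq_len(n_frames)] <- log10(mag + 1e-10)
  }
  new("SpectrogramTile", values = vals, band = band,
      bin_width = sample_rate / dft, hop = as.integer(hop),
      window = as.integer(window), dft = as.integer(dft),
      sample_rate = sample_rate, clip_id = clip_id,
      start_time = start_time, label = as.integer(label))
}

#' Stack tiles into a TileSet
#'
#' @param tiles list of [SpectrogramTile-class] objects sharing shape and
#'   band.
#' @param target_duration stored in the parameter list.
#' @return a [TileSet-class].
#' @export
makeTileSet <- function(tiles, target_duration = 600) {
  stopifnot(length(tiles) > 0)
  d <- dim(tiles[[1]]@values)
  for (t in tiles) {
    if (!identical(dim(t@values), d) ||
        !identical(t@band, tiles[[1]]@band))
      stop("all tiles must share shape and band")
  }
  vals <- array(0, dim = c(d, length(tiles)))
  for (i in seq_along(tiles)) vals[, , i] <- tiles[[i]]@values
  st <- do.call(c, lapply(tiles, function(t)
    if (is.null(t@start_time)) as.POSIXct(NA) else t@start_time))
  t1 <- tiles[[1]]
  new("TileSet", values = vals,
      labels = vapply(tiles, function(t) t@label, integer(1)),
      clip_ids = vapply(tiles, function(t) t@clip_id, character(1)),
      start_times = st,
      params = list(band = t1@band, bin_width = t1@bin_width, hop = t1@hop,
                    window = t1@window, dft = t1@dft,
                    sample_rate = t1@sample_rate,
                    target_duration = target_duration))
}

#' @describeIn SpectrogramTile-class log-magnitude matrix.
#' @export
setMethod("tileValues", "SpectrogramTile", function(object) object@values)

#' @describeIn TileSet-class label vector.
#' @export
setMethod("tileLabels", "TileSet", function(object) object@labels)

#' @describeIn TileSet-class number of tiles.
#' @param x a TileSet.
#' @export
setMethod("length", "TileSet", function(x) dim(x@values)[3])

#' @describeIn TileSet-class subset tiles by index.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TileSet", function(x, i, j, ..., drop = FALSE) {
  new("TileSet", values = x@values[, , i, drop = FALSE],
      labels = x@labels[i], clip_ids = x@clip_ids[i],
      start_times = x@start_times[i], params = x@params)
})

setMethod("show", "TileSet", function(object) {
  d <- dim(object@values)
  cat(sprintf("TileSet: %d tiles of %d freq bins x %d frames\n",
              d[3], d[1], d[2]))
  cat(sprintf("  band %g-%g Hz, labels: %d pos / %d neg / %d NA\n",
              object@params$band[1], object@params$band[2],
              sum(object@labels == 1L, na.rm = TRUE),
              sum(object@labels == 0L, na.rm = TRUE),
              sum(is.na(object@labels))))
})

setMethod("show", "SpectrogramTile", function(object) {
  cat(sprintf("SpectrogramTile '%s': %d bins x %d frames, band %g-%g Hz\n",
              object@clip_id, nrow(object@values), ncol(object@values),
              object@band[1], object@band[2]))
})

setMethod("show", "LabeledClip", function(object) {
  cat(sprintf("LabeledClip '%s': %.1f s at %g Hz, label %d, %d events\n",
              object@clip_id,
              length(object@waveform) / object@sample_rate,
              object@sample_rate, object@label, nrow(object@events)))
})

#' @describeIn LabeledClip-class amplitude series.
#' @export
setMethod("waveform", "LabeledClip", function(object) object@waveform)

#' @describeIn LabeledClip-class binary label.
#' @export
setMethod("clipLabel", "LabeledClip", function(object) object@label)

#' @describeIn LabeledClip-class event table.
#' @export
setMethod("clipEvents", "LabeledClip", function(object) object@events)
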