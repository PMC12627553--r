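#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer for mono audio, supporting 16-bit integer PCM
#' and IEEE float32 encodings. Samples are expected in \[-1, 1\]; 16-bit
#' output clips and rounds to the integer grid.
#'
#' @param x numeric amplitude series in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @param bits `16L` for integer PCM or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(x, sample_rate, path, bits = 16L) {
  stopifnot(is.numeric(x), length(x) > 0, sample_rate > 0)
  float <- identical(bits, "float32")
  if (!float && !identical(as.integer(bits), 16L))
    stop("bits must be 16 or 'float32'")
  bytes_per <- if (float) 4L else 2L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (float) 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")  # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (float) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Counterpart of [writeWav()]: parses the RIFF chunk structure (skipping
#' unknown chunks) and decodes mono 16-bit PCM or float32 data.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, 16-bit data rescaled to
#'   \[-1, 1\]) and `sample_rate`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", size = 2, endian = "little")
      n_channels <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
      fmt <- list(format = audio_format, channels = n_channels,
                  rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n = size / 2, size = 2,
                       endian = "little")
        samples <- raw / 32767
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding")
      }
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
    if (!is.null(samples) && !is.null(fmt)) break
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, sample_rate = fmt$rate)
}
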