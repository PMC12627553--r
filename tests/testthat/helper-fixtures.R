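# shared fixtures, built in code

# a short scene with one bowhead call, for fast pipeline tests
quickClip <- function(seed = 3L, duration = 30, events = NULL,
                      onsets = NULL) {
  if (is.null(events)) {
    events <- list(callTemplate("simple_fm", 600, 250, 1.5, snr_db = 12))
    onsets <- c(duration / 3)
  }
  synthClip(sceneSpec(clip_duration = duration, events = events,
                      onsets = onsets, seed = seed))
}

# small tile set of labelled short clips (for store/trainer tests)
quickTileSet <- function(n_pos = 3, n_neg = 3, duration = 20, seed = 11L) {
  drawn <- sampleSceneSpecs(n_pos, n_neg, clip_duration = duration,
                            seed = seed)
  tiles <- lapply(seq_along(drawn$specs), function(i) {
    cl <- synthClip(drawn$specs[[i]], clip_id = drawn$manifest$clip_id[i],
                    start_time = drawn$manifest$start_time[i])
    tileSpectrogram(waveform(cl), 5000, target_duration = duration,
                    clip_id = cl@clip_id, start_time = cl@start_time,
                    label = clipLabel(cl))
  })
  makeTileSet(tiles, target_duration = duration)
}

# mean-square power within a frequency band: independent DFT-based oracle
oracleBandPower <- function(x, sr, lo, hi) {
  X <- stats::fft(x)
  f <- (seq_along(x) - 1) * sr / length(x)
  keep <- f >= lo & f <= hi
  2 * sum(Mod(X[keep])^2) / length(x)^2
}

# zero-crossing-based instantaneous frequency estimate over windows
zeroCrossingFreq <- function(x, sr, n_windows = 8) {
  splits <- split(x, cut(seq_along(x), n_windows, labels = FALSE))
  vapply(splits, function(w) {
    zc <- sum(diff(sign(w)) != 0)
    zc / 2 / (length(w) / sr)
  }, numeric(1))
}

# exhaustive brute-force edge distance (independent of the implementation)
bruteEdgeDistance <- function(conc, cell_size, rec, threshold = 15,
                              max_patch = 50) {
  nr <- nrow(conc); nc <- ncol(conc)
  ice <- conc >= threshold
  # flood-fill component labelling, 4-connectivity
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(ice[r0, c0]) || lab[r0, c0] != 0L) next
    nextlab <- nextlab + 1L
    cls <- ice[r0, c0]
    queue <- list(c(r0, c0)); lab[r0, c0] <- nextlab
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- cell[1] + d[1]; cc <- cell[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(ice[rr, cc]) && ice[rr, cc] == cls &&
            lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextlab
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  rec_ice <- ice[rec[1], rec[2]]
  if (is.na(rec_ice)) return(list(defined = FALSE))
  best <- Inf
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(ice[r, c]) || ice[r, c] == rec_ice) next
    if (sizes[lab[r, c]] <= max_patch) next
    d <- sqrt(((r - rec[1]) * cell_size)^2 + ((c - rec[2]) * cell_size)^2)
    if (d < best) best <- d
  }
  if (!is.finite(best)) return(list(defined = FALSE))
  list(defined = TRUE, value = if (rec_ice) -best else best,
       rec_ice = rec_ice)
}

# exhaustive brute-force mean concentration within a radius
bruteMeanConcentration <- function(conc, cell_size, rec, radius = 35) {
  vals <- c()
  for (r in seq_len(nrow(conc))) for (c in seq_len(ncol(conc))) {
    d <- sqrt(((r - rec[1]) * cell_size)^2 + ((c - rec[2]) * cell_size)^2)
    if (d <= radius && !is.na(conc[r, c])) vals <- c(vals, conc[r, c])
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# random ice field with mixed patch sizes for oracle-equivalence tests
randomIceField <- function(seed, nr = 64, nc = 64) {
  spec <- iceGeometrySpec(nr, nc, geometry = "noise_threshold",
                          params = list(smooth = sample(2:6, 1)),
                          recorder = c(sample(nr, 1), sample(nc, 1)),
                          seed = seed)
  synthIceField(spec)
}
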