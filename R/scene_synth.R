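#' Construct a call template
#'
#' @param kind one of `"simple_fm"`, `"song_unit"`, `"ice_transient"`,
#'   `"seal_trill"`.
#' @param f_start,f_end sweep start/end frequency, Hz. For
#'   `"ice_transient"` these bound the burst's frequency band.
#' @param duration event duration, s.
#' @param n_harmonics number of overtones (harmonics above the Nyquist
#'   frequency are clipped at synthesis time).
#' @param harmonic_decay per-harmonic amplitude ratio in (0, 1].
#' @param snr_db event SNR in dB, measured in the 50--1000 Hz band relative
#'   to the scene background.
#' @return a [CallTemplate-class].
#' @examples
#' callTemplate("simple_fm", f_start = 800, f_end = 200, duration = 1.5)
#' @export
callTemplate <- function(kind, f_start, f_end, duration, n_harmonics = 0L,
                         harmonic_decay = 1, snr_db = 10) {
  new("CallTemplate", kind = kind, f_start = f_start, f_end = f_end,
      duration = duration, n_harmonics = as.integer(n_harmonics),
      harmonic_decay = harmonic_decay, snr_db = snr_db)
}

#' Construct a scene specification
#'
#' @param clip_duration clip length in seconds; study recordings are 600 s
#'   files.
#' @param sample_rate Hz.
#' @param noise_model `"white"` or `"pink"` background.
#' @param noise_level background RMS amplitude.
#' @param events list of [CallTemplate-class] objects.
#' @param onsets numeric onset times (s), one per event. Overlapping events
#'   are allowed (two-voiced song occurs in real data); events extending
#'   past the clip end are rejected.
#' @param seed integer; fully determines the generated waveform.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(clip_duration = 600, sample_rate = 5000,
                      noise_model = "white", noise_level = 0.1,
                      events = list(), onsets = numeric(), seed = 1L) {
  new("SceneSpec", clip_duration = clip_duration, sample_rate = sample_rate,
      noise_model = noise_model, noise_level = noise_level, events = events,
      onsets = as.numeric(onsets), seed = as.integer(seed))
}

# Tukey taper with `frac` of the duration ramped at each end
tukeyWindow <- function(n, frac = 0.1) {
  w <- rep(1, n)
  r <- max(1L, floor(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  w[seq_len(r)] <- ramp
  w[n + 1L - seq_len(r)] <- rev(ramp)
  w
}

#' Synthesize one sound event
#'
#' Tonal kinds (`simple_fm`, `song_unit`, `seal_trill`) produce a tapered
#' tone whose instantaneous frequency sweeps linearly from `f_start` to
#' `f_end` over the duration, with `n_harmonics` overtones at integer
#' multiples of the fundamental, the k-th scaled by `harmonic_decay^k`;
#' harmonics that would exceed the Nyquist frequency anywhere in the sweep
#' are clipped. `ice_transient` produces a short band-limited noise burst
#' (it draws from the current RNG stream). Peak amplitude is 1 before
#' mixing; SNR scaling happens in [synthClip()].
#'
#' @param template a [CallTemplate-class].
#' @param sample_rate target rate, Hz.
#' @return numeric waveform of length `round(duration * sample_rate)`.
#' @export
synthCall <- function(template, sample_rate) {
  stopifnot(is(template, "CallTemplate"))
  nyq <- sample_rate / 2
  if (template@f_start >= nyq || template@f_end >= nyq)
    stop("f_start and f_end must be below the Nyquist frequency")
  n <- round(template@duration * sample_rate)
  if (template@kind == "ice_transient") {
    lo <- min(template@f_start, template@f_end)
    hi <- max(template@f_start, template@f_end)
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) * sample_rate / n
    f <- pmin(f, sample_rate - f)  # fold to physical frequency
    X[f < lo | f > hi] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  } else {
    t <- (seq_len(n) - 1) / sample_rate
    phase <- 2 * pi * (template@f_start * t +
      (template@f_end - template@f_start) * t^2 / (2 * template@duration))
    fmax <- max(template@f_start, template@f_end)
    x <- numeric(n)
    for (h in 0:template@n_harmonics) {
      if ((h + 1) * fmax >= nyq) break  # clip harmonics above Nyquist
      x <- x + template@harmonic_decay^h * sin((h + 1) * phase)
    }
  }
  x <- x * tukeyWindow(n)
  x / max(abs(x))
}

#' Synthesize one labelled acoustic scene
#'
#' Generates the background noise, mixes each event at its onset scaled so
#' that its 50--1000 Hz band power sits `snr_db` dB above the background's,
#' and sets the clip label from bowhead-kind events only (`simple_fm`,
#' `song_unit`); ice transients and seal trills are confounders and never
#' set the label. The same spec (including seed) always yields a
#' bit-identical waveform.
#'
#' @param spec a [SceneSpec-class].
#' @param clip_id identifier stored on the clip.
#' @param start_time nominal recording start (POSIXct).
#' @return a [LabeledClip-class].
#' @export
synthClip <- function(spec, clip_id = "clip",
                      start_time = as.POSIXct("2022-10-01 00:00:00",
                                              tz = "UTC")) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  sr <- spec@sample_rate
  n <- round(spec@clip_duration * sr)
  withSeed(spec@seed, {
    noise <- stats::rnorm(n)
    if (spec@noise_model == "pink") {
      X <- stats::fft(noise)
      f <- (seq_len(n) - 1) * sr / n
      f <- pmin(f, sr - f)
      shape <- ifelse(f > 0, 1 / sqrt(f), 0)
      noise <- Re(stats::fft(X * shape, inverse = TRUE)) / n
    }
    noise <- noise * spec@noise_level / sqrt(mean(noise^2))
    x <- noise
    p_noise <- bandPower(noise, sr)
    ev_rows <- list()
    for (i in seq_along(spec@events)) {
      tpl <- spec@events[[i]]
      call <- synthCall(tpl, sr)
      p_call <- bandPower(call, sr)
      a <- sqrt(10^(tpl@snr_db / 10) * p_noise / p_call)
      i0 <- round(spec@onsets[i] * sr) + 1L
      idx <- i0:(i0 + length(call) - 1L)
      x[idx] <- x[idx] + a * call
      ev_rows[[i]] <- data.frame(kind = tpl@kind, onset = spec@onsets[i],
                                 duration = tpl@duration,
                                 f_start = tpl@f_start, f_end = tpl@f_end,
                                 snr_db = tpl@snr_db)
    }
    events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(kind = character(), onset = numeric(), duration = numeric(),
                 f_start = numeric(), f_end = numeric(), snr_db = numeric())
    peak <- max(abs(x))
    if (peak > 1) x <- x / peak
    label <- as.integer(any(events$kind %in% c("simple_fm", "song_unit")))
    new("LabeledClip", waveform = x, sample_rate = sr, label = label,
        events = events, clip_id = clip_id, start_time = start_time)
  })
}

#' Default template pool for scene sampling
#'
#' Parameter ranges emulating the two study regimes: Fram-Strait-like
#' simple FM calls mainly below 1 kHz, Svalbard-like repeated song units
#' with harmonics, plus the two confounder kinds named as false-positive
#' sources (short broadband ice transients and slow seal-like downsweeps
#' longer than 10 s). SNR ranges are free parameters of the simulation
#' (the source data give no quantitative amplitude distributions); the
#' defaults are a moderate 6--12 dB in the 50--1000 Hz analysis band.
#'
#' @param region `"mixed"`, `"fram"` (FM calls only) or `"svalbard"` (song
#'   units only) for the bowhead event mix.
#' @return nested list of parameter ranges consumed by
#'   [sampleSceneSpecs()].
#' @export
defaultTemplatePool <- function(region = c("mixed", "fram", "svalbard")) {
  region <- match.arg(region)
  bowhead <- list(
    simple_fm = list(f_hi = c(300, 900), sweep_frac = c(0.3, 0.7),
                     dur = c(0.8, 2.5), harm = c(0L, 1L), decay = 0.5,
                     snr = c(6, 12)),
    song_unit = list(f_hi = c(200, 800), sweep_frac = c(0.1, 0.5),
                     dur = c(0.5, 1.5), harm = c(2L, 4L), decay = 0.6,
                     snr = c(6, 12), n_repeat = c(4L, 8L), gap = c(0.5, 1.5))
  )
  if (region == "fram") bowhead$song_unit <- NULL
  if (region == "svalbard") bowhead$simple_fm <- NULL
  list(
    bowhead = bowhead,
    confounders = list(
      ice_transient = list(band = c(50, 2400), dur = c(0.05, 0.2),
                           snr = c(8, 15)),
      seal_trill = list(f_hi = c(600, 950), f_lo = c(80, 250),
                        dur = c(12, 20), harm = c(0L, 1L), decay = 0.5,
                        snr = c(6, 12))
    )
  )
}

runifIn <- function(r) stats::runif(1, r[1], r[2])
sampleIn <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

# draw the events of one scene; returns list(events=, onsets=)
sampleSceneEvents <- function(label, pool, clip_duration, nyquist) {
  events <- list()
  onsets <- numeric()
  addEvent <- function(tpl, onset) {
    events[[length(events) + 1L]] <<- tpl
    onsets <<- c(onsets, onset)
  }
  if (label == 1L) {
    kinds <- names(pool$bowhead)
    kind <- if (length(kinds) == 1L) kinds else sample(kinds, 1)
    p <- pool$bowhead[[kind]]
    if (kind == "song_unit") {
      # a song bout: one unit repeated with gaps
      f_hi <- runifIn(p$f_hi)
      f_lo <- f_hi * (1 - runifIn(p$sweep_frac))
      dur <- runifIn(p$dur)
      nh <- sampleIn(p$harm)
      snr <- runifIn(p$snr)
      nrep <- sampleIn(p$n_repeat)
      gap <- runifIn(p$gap)
      span <- nrep * (dur + gap)
      t0 <- stats::runif(1, 0, max(clip_duration - span, 0.01))
      for (r in seq_len(nrep)) {
        on <- t0 + (r - 1) * (dur + gap)
        if (on + dur <= clip_duration)
          addEvent(callTemplate("song_unit", f_hi, f_lo, dur, nh, p$decay,
                                snr), on)
      }
    } else {
      n_calls <- sample(3:8, 1)
      for (r in seq_len(n_calls)) {
        f_hi <- runifIn(p$f_hi)
        f_lo <- f_hi * (1 - runifIn(p$sweep_frac))
        dur <- runifIn(p$dur)
        addEvent(callTemplate("simple_fm", f_hi, f_lo, dur, sampleIn(p$harm),
                              p$decay, runifIn(p$snr)),
                 stats::runif(1, 0, clip_duration - dur))
      }
    }
    # positives may also contain confounders, as in real scenes
    n_ice <- sample(0:3, 1)
  } else {
    # half of the negatives are plain noise, half carry confounders
    n_ice <- if (stats::runif(1) < 0.5) 0L else sample(2:6, 1)
    if (n_ice > 0L) {
      p <- pool$confounders$seal_trill
      for (r in seq_len(sample(0:2, 1))) {
        dur <- runifIn(p$dur)
        if (dur < clip_duration)
          addEvent(callTemplate("seal_trill", runifIn(p$f_hi),
                                runifIn(p$f_lo), dur, sampleIn(p$harm),
                                p$decay, runifIn(p$snr)),
                   stats::runif(1, 0, clip_duration - dur))
      }
    }
  }
  pice <- pool$confounders$ice_transient
  for (r in seq_len(n_ice)) {
    dur <- runifIn(pice$dur)
    addEvent(callTemplate("ice_transient", pice$band[1],
                          min(pice$band[2], nyquist * 0.96), dur, 0L, 1,
                          runifIn(pice$snr)),
             stats::runif(1, 0, clip_duration - dur))
  }
  list(events = events, onsets = onsets)
}

#' Sample scene specifications for a labelled dataset
#'
#' Draws `n_pos` bowhead-positive and `n_neg` negative scene recipes from a
#' template pool, assigns clip identifiers and timestamps on a regular
#' 10-minute grid, and shuffles label order. Deterministic given `seed`.
#'
#' @param n_pos,n_neg counts of positive / negative clips.
#' @param pool template pool, see [defaultTemplatePool()].
#' @param clip_duration,sample_rate scene parameters.
#' @param noise_model,noise_level background parameters.
#' @param seed master seed.
#' @param epoch POSIXct start of the 10-minute timestamp grid.
#' @return list with `specs` (list of [SceneSpec-class]) and `manifest`
#'   (data.frame clip_id, start_time, label, path).
#' @export
sampleSceneSpecs <- function(n_pos, n_neg, pool = defaultTemplatePool(),
                             clip_duration = 600, sample_rate = 5000,
                             noise_model = "white", noise_level = 0.1,
                             seed = 1L,
                             epoch = as.POSIXct("2022-10-01 00:00:00",
                                                tz = "UTC")) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg > 0)
  n <- n_pos + n_neg
  withSeed(seed, {
    labels <- sample(rep(c(1L, 0L), c(n_pos, n_neg)))
    clip_seeds <- sample.int(.Machine$integer.max - 1L, n)
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      drawn <- withSeed(clip_seeds[i],
        sampleSceneEvents(labels[i], pool, clip_duration, sample_rate / 2))
      specs[[i]] <- sceneSpec(clip_duration, sample_rate, noise_model,
                              noise_level, drawn$events, drawn$onsets,
                              seed = clip_seeds[i])
    }
    manifest <- data.frame(
      clip_id = sprintf("clip_%04d", seq_len(n)),
      start_time = epoch + (seq_len(n) - 1) * 600,
      label = labels,
      path = NA_character_,
      stringsAsFactors = FALSE)
    list(specs = specs, manifest = manifest)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Realizes the scenes drawn by [sampleSceneSpecs()]. With `dir = NULL`
#' clips are returned in memory; otherwise each clip is written as a
#' 16-bit PCM WAV and the manifest gains the file paths.
#'
#' @inheritParams sampleSceneSpecs
#' @param dir output directory for WAV files, or NULL for in-memory clips.
#' @param ... passed to [sampleSceneSpecs()].
#' @return list with `clips` (list of [LabeledClip-class], or NULL when
#'   written to disk) and `manifest`.
#' @export
synthDataset <- function(n_pos, n_neg, pool = defaultTemplatePool(),
                         clip_duration = 600, sample_rate = 5000,
                         seed = 1L, dir = NULL, ...) {
  drawn <- sampleSceneSpecs(n_pos, n_neg, pool, clip_duration, sample_rate,
                            seed = seed, ...)
  manifest <- drawn$manifest
  clips <- vector("list", nrow(manifest))
  for (i in seq_along(drawn$specs)) {
    clip <- synthClip(drawn$specs[[i]], clip_id = manifest$clip_id[i],
                      start_time = manifest$start_time[i])
    stopifnot(clip@label == manifest$label[i])
    if (is.null(dir)) {
      clips[[i]] <- clip
    } else {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, paste0(manifest$clip_id[i], ".wav"))
      writeWav(clip@waveform, sample_rate, p)
      manifest$path[i] <- p
    }
  }
  list(clips = if (is.null(dir)) clips else NULL, manifest = manifest)
}

#' Write a dataset manifest as CSV
#'
#' Columns: clip_id, start_time (ISO-8601 UTC), label, path.
#'
#' @param manifest manifest data.frame.
#' @param path output CSV path.
#' @export
writeManifest <- function(manifest, path) {
  out <- manifest
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#'
#' @param path CSV written by [writeManifest()].
#' @return manifest data.frame with POSIXct start_time.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$start_time <- as.POSIXct(m$start_time, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  m
}

#' Construct an ice-field geometry specification
#'
#' @param nrow,ncol grid shape.
#' @param cell_size km per cell (3.125 km matches the study grid).
#' @param geometry `"half_plane"`, `"disk_patch"`, `"noise_threshold"` or
#'   `"uniform"`.
#' @param params geometry parameters:
#'   half_plane: `edge_col` (first ice column), `ice_conc`, `water_conc`;
#'   disk_patch: `n_cells`, `center` (row, col), `ice_conc`, `water_conc`;
#'   noise_threshold: `smooth` (blur iterations);
#'   uniform: `conc`.
#' @param recorder (row, col) of the recorder cell.
#' @param seed integer.
#' @return an [IceGeometrySpec-class].
#' @export
iceGeometrySpec <- function(nrow, ncol, cell_size = 3.125,
                            geometry = "half_plane", params = list(),
                            recorder = c(1L, 1L), seed = 1L) {
  new("IceGeometrySpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cell_size = cell_size, geometry = geometry, params = params,
      recorder = as.integer(recorder), seed = as.integer(seed))
}

#' Generate a synthetic sea-ice concentration field
#'
#' Builds a gridded concentration field with known geometry and attaches
#' analytic ground truth where it exists: for `half_plane`, the signed
#' recorder-to-edge distance (positive in water, negative in ice); for
#' `disk_patch`, the patch area in km^2. A `uniform` field below the ice
#' threshold has no edge and is flagged undefined.
#'
#' @param spec an [IceGeometrySpec-class].
#' @return an [IceField-class].
#' @export
synthIceField <- function(spec) {
  stopifnot(is(spec, "IceGeometrySpec"))
  validObject(spec)
  p <- spec@params
  nr <- spec@nrow
  nc <- spec@ncol
  cs <- spec@cell_size
  rec <- spec@recorder
  truth <- list()
  conc <- switch(spec@geometry,
    uniform = {
      v <- if (is.null(p$conc)) 0 else p$conc
      truth <- list(defined = FALSE)
      matrix(v, nr, nc)
    },
    half_plane = {
      ice_conc <- if (is.null(p$ice_conc)) 90 else p$ice_conc
      water_conc <- if (is.null(p$water_conc)) 0 else p$water_conc
      edge_col <- p$edge_col
      stopifnot(!is.null(edge_col))
      m <- matrix(water_conc, nr, nc)
      if (edge_col <= nc) m[, edge_col:nc] <- ice_conc
      in_ice <- rec[2] >= edge_col
      d_cells <- if (in_ice) rec[2] - (edge_col - 1L) else edge_col - rec[2]
      truth <- list(defined = TRUE,
                    edge_distance_km = (if (in_ice) -1 else 1) * d_cells * cs)
      m
    },
    disk_patch = {
      ice_conc <- if (is.null(p$ice_conc)) 90 else p$ice_conc
      water_conc <- if (is.null(p$water_conc)) 0 else p$water_conc
      n_cells <- p$n_cells
      stopifnot(!is.null(n_cells))
      center <- if (is.null(p$center)) c((nr + 1) %/% 2, (nc + 1) %/% 2) else
        p$center
      rows <- rep(seq_len(nr), nc)
      cols <- rep(seq_len(nc), each = nr)
      d2 <- (rows - center[1])^2 + (cols - center[2])^2
      ord <- order(d2, rows, cols)
      m <- matrix(water_conc, nr, nc)
      m[cbind(rows[ord[seq_len(n_cells)]], cols[ord[seq_len(n_cells)]])] <-
        ice_conc
      truth <- list(patch_area_km2 = n_cells * cs^2, patch_cells = n_cells)
      m
    },
    noise_threshold = {
      smooth <- if (is.null(p$smooth)) 8L else p$smooth
      withSeed(spec@seed, {
        z <- matrix(stats::rnorm(nr * nc), nr, nc)
        for (i in seq_len(smooth)) {
          up <- rbind(z[1, ], z[-nr, ])
          dn <- rbind(z[-1, ], z[nr, ])
          lf <- cbind(z[, 1], z[, -nc])
          rt <- cbind(z[, -1], z[, nc])
          z <- (z + up + dn + lf + rt) / 5
        }
        zv <- as.vector(scale(as.vector(z)))
        matrix(100 * stats::pnorm(zv), nr, nc)
      })
    })
  new("IceField", concentration = conc, cell_size = cs, recorder = rec,
      lon = matrix(numeric(0), 0, 0), lat = matrix(numeric(0), 0, 0),
      recorder_lonlat = numeric(0), truth = truth)
}
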