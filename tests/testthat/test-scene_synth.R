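test_that("a degenerate sweep is a pure tone with the right spectral peak", {
  tpl <- callTemplate("simple_fm", 500, 500, 1)
  w <- synthCall(tpl, 5000)
  expect_length(w, 5000)
  expect_equal(max(abs(w)), 1)
  X <- Mod(stats::fft(w))[1:2500]
  f_peak <- (which.max(X) - 1) * 5000 / 5000
  expect_lt(abs(f_peak - 500), 5000 / 4096 + 1e-9)
})

test_that("a downsweep has strictly decreasing instantaneous frequency", {
  tpl <- callTemplate("simple_fm", 800, 200, 2)
  w <- synthCall(tpl, 5000)
  # drop tapered edges before estimating zero-crossing frequency
  core <- w[500:(length(w) - 500)]
  f_est <- zeroCrossingFreq(core, 5000, n_windows = 6)
  expect_true(all(diff(f_est) < 0))
  expect_true(all(f_est > 150 & f_est < 850))
})

test_that("harmonics carry the configured power ratio", {
  tpl <- callTemplate("song_unit", 400, 400, 2, n_harmonics = 2L,
                      harmonic_decay = 0.5)
  w <- synthCall(tpl, 5000)
  p1 <- oracleBandPower(w, 5000, 380, 420)
  p2 <- oracleBandPower(w, 5000, 780, 820)
  # decay 0.5 in amplitude -> power ratio 0.25 (-6 dB)
  expect_equal(p2 / p1, 0.25, tolerance = 0.02)
})

test_that("calls reject frequencies at or above Nyquist", {
  expect_error(synthCall(callTemplate("simple_fm", 2600, 200, 1), 5000),
               "Nyquist")
  expect_error(synthCall(callTemplate("simple_fm", 200, 2500, 1), 5000),
               "Nyquist")
})

test_that("harmonics above Nyquist are clipped, not aliased", {
  tpl <- callTemplate("song_unit", 2000, 2000, 1, n_harmonics = 3L,
                      harmonic_decay = 0.9)
  w <- synthCall(tpl, 5000)
  # only the fundamental survives: no power near alias positions
  p_fund <- oracleBandPower(w, 5000, 1950, 2050)
  p_alias <- oracleBandPower(w, 5000, 950, 1050)
  expect_gt(p_fund / (p_alias + 1e-12), 1e3)
})

test_that("clip labels follow bowhead-kind events only", {
  empty <- synthClip(sceneSpec(clip_duration = 10, seed = 1L))
  expect_identical(clipLabel(empty), 0L)

  confounded <- synthClip(sceneSpec(
    clip_duration = 30,
    events = list(callTemplate("simple_fm", 500, 300, 1),
                  callTemplate("ice_transient", 100, 2000, 0.1),
                  callTemplate("ice_transient", 100, 2000, 0.1),
                  callTemplate("ice_transient", 100, 2000, 0.1)),
    onsets = c(5, 10, 15, 20), seed = 2L))
  expect_identical(clipLabel(confounded), 1L)

  only_confounders <- synthClip(sceneSpec(
    clip_duration = 30,
    events = list(callTemplate("seal_trill", 900, 200, 12),
                  callTemplate("ice_transient", 100, 2000, 0.1)),
    onsets = c(5, 20), seed = 2L))
  expect_identical(clipLabel(only_confounders), 0L)
})

test_that("the same spec yields a bit-identical clip", {
  sp <- sceneSpec(clip_duration = 20,
                  events = list(callTemplate("simple_fm", 600, 300, 1.5)),
                  onsets = c(8), seed = 77L)
  a <- synthClip(sp)
  b <- synthClip(sp)
  expect_identical(waveform(a), waveform(b))
})

test_that("events extending past the clip end are rejected", {
  expect_error(sceneSpec(clip_duration = 10,
                         events = list(callTemplate("simple_fm", 500, 300,
                                                    5)),
                         onsets = c(8), seed = 1L),
               "extends past")
})

test_that("event SNR calibration puts band power where requested", {
  for (snr in c(0, 10)) {
    sp <- sceneSpec(clip_duration = 20, noise_level = 0.1,
                    events = list(callTemplate("simple_fm", 500, 300, 2,
                                               snr_db = snr)),
                    onsets = c(9), seed = 5L)
    clip <- synthClip(sp)
    x <- waveform(clip)
    noise_seg <- x[1:(5 * 5000)]          # event-free
    event_seg <- x[(9 * 5000):(11 * 5000)]
    p_noise <- oracleBandPower(noise_seg, 5000, 50, 1000)
    p_event <- oracleBandPower(event_seg, 5000, 50, 1000) - p_noise
    expect_equal(10 * log10(p_event / p_noise), snr, tolerance = 1.5)
  }
})

test_that("synthetic datasets honour counts, grid timestamps and determinism", {
  ds <- synthDataset(3, 7, clip_duration = 10, seed = 21L)
  m <- ds$manifest
  expect_identical(nrow(m), 10L)
  expect_identical(sum(m$label), 3L)
  expect_identical(mean(m$label), 3 / 10)
  expect_identical(as.numeric(diff(m$start_time), units = "secs"),
                   rep(600, 9))
  labels <- vapply(ds$clips, clipLabel, integer(1))
  expect_identical(labels, m$label)

  ds2 <- synthDataset(3, 7, clip_duration = 10, seed = 21L)
  expect_identical(ds2$manifest, m)
  expect_identical(waveform(ds2$clips[[5]]), waveform(ds$clips[[5]]))
})

test_that("manifests survive a CSV round trip", {
  ds <- synthDataset(2, 2, clip_duration = 10, seed = 4L)
  p <- file.path(tempdir(), "manifest.csv")
  writeManifest(ds$manifest, p)
  m <- readManifest(p)
  expect_identical(m$clip_id, ds$manifest$clip_id)
  expect_identical(m$label, ds$manifest$label)
  expect_equal(as.numeric(m$start_time), as.numeric(ds$manifest$start_time))
})

test_that("WAV files round trip clips to 16-bit precision", {
  clip <- quickClip(duration = 5)
  p <- file.path(tempdir(), "clip.wav")
  writeWav(waveform(clip), 5000, p)
  back <- readWav(p)
  expect_identical(back$sample_rate, 5000L)
  expect_length(back$samples, length(waveform(clip)))
  expect_lt(max(abs(back$samples - waveform(clip))), 1 / 32767)
  # float32 is exact to single precision
  writeWav(waveform(clip), 5000, p, bits = "float32")
  back32 <- readWav(p)
  expect_lt(max(abs(back32$samples - waveform(clip))), 1e-7)
})

test_that("half-plane ice fields carry analytic edge-distance truth", {
  water_side <- synthIceField(iceGeometrySpec(
    64, 64, geometry = "half_plane", params = list(edge_col = 45),
    recorder = c(32L, 33L)))
  expect_true(water_side@truth$defined)
  expect_identical(water_side@truth$edge_distance_km, 12 * 3.125)

  ice_side <- synthIceField(iceGeometrySpec(
    64, 64, geometry = "half_plane", params = list(edge_col = 20),
    recorder = c(32L, 27L)))
  expect_identical(ice_side@truth$edge_distance_km, -8 * 3.125)
})

test_that("uniform open-water fields flag the edge distance undefined", {
  f <- synthIceField(iceGeometrySpec(16, 16, geometry = "uniform",
                                     params = list(conc = 0),
                                     recorder = c(8L, 8L)))
  expect_false(f@truth$defined)
  expect_false(edgeDistance(f)@defined)
})

test_that("disk patches have exact cell counts and area", {
  f <- synthIceField(iceGeometrySpec(64, 64, geometry = "disk_patch",
                                     params = list(n_cells = 50),
                                     recorder = c(5L, 5L)))
  expect_identical(sum(concentration(f) >= 15), 50L)
  expect_equal(f@truth$patch_area_km2, 488.28125)
})

test_that("single tones land within one spectrogram bin of their frequency", {
  set.seed(42)
  for (freq in round(runif(5, 80, 950))) {
    sp <- sceneSpec(clip_duration = 10,
                    events = list(callTemplate("simple_fm", freq, freq, 3,
                                               snr_db = 25)),
                    onsets = c(3), seed = freq)
    tile <- tileSpectrogram(waveform(synthClip(sp)), 5000,
                            target_duration = 10)
    fsel <- bandBinFrequencies()
    peak_bin <- which.max(tileValues(tile)[, 15])  # frame inside the event
    expect_lt(abs(fsel[peak_bin] - freq), 5000 / 4096 + 1e-9)
  }
})
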