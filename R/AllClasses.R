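#' @import methods
NULL

setClassUnion("POSIXctOrNULL", c("POSIXct", "NULL"))

#' Call template
#'
#' Parametric description of one synthetic sound event. `kind` selects the
#' event family: `"simple_fm"` (a single frequency-modulated bowhead call,
#' Fram-Strait-like), `"song_unit"` (a harmonic-rich song unit,
#' Svalbard-like), `"ice_transient"` (a short broadband ice noise burst) or
#' `"seal_trill"` (a long, slow seal-like downsweep). Only the first two
#' count as bowhead events when labelling a clip.
#'
#' @slot kind character, one of the four event kinds.
#' @slot f_start,f_end numeric, sweep start/end frequency in Hz.
#' @slot duration numeric, event duration in seconds.
#' @slot n_harmonics integer, number of overtones above the fundamental.
#' @slot harmonic_decay numeric in (0, 1], per-harmonic amplitude ratio.
#' @slot snr_db numeric, signal-to-noise ratio in dB measured in the
#'   50--1000 Hz band relative to the scene background.
#' @export
setClass("CallTemplate",
  slots = c(kind = "character", f_start = "numeric", f_end = "numeric",
            duration = "numeric", n_harmonics = "integer",
            harmonic_decay = "numeric", snr_db = "numeric"),
  validity = function(object) {
    kinds <- c("simple_fm", "song_unit", "ice_transient", "seal_trill")
    if (!object@kind %in% kinds)
      return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
    if (object@duration <= 0) return("duration must be positive")
    if (object@f_start <= 0 || object@f_end <= 0)
      return("frequencies must be positive")
    if (object@n_harmonics < 0L) return("n_harmonics must be >= 0")
    if (object@harmonic_decay <= 0 || object@harmonic_decay > 1)
      return("harmonic_decay must be in (0, 1]")
    TRUE
  })

#' Scene specification
#'
#' Complete, seedable recipe for one synthetic acoustic scene. The seed
#' fully determines the output waveform.
#'
#' @slot clip_duration numeric, clip length in seconds (study files are
#'   600 s).
#' @slot sample_rate numeric, Hz.
#' @slot noise_model character, `"white"` or `"pink"`.
#' @slot noise_level numeric, background RMS amplitude.
#' @slot events list of [CallTemplate-class] objects.
#' @slot onsets numeric, event onset times in seconds (same length as
#'   `events`).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  slots = c(clip_duration = "numeric", sample_rate = "numeric",
            noise_model = "character", noise_level = "numeric",
            events = "list", onsets = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@clip_duration <= 0) return("clip_duration must be positive")
    if (!object@noise_model %in% c("white", "pink"))
      return("noise_model must be 'white' or 'pink'")
    if (length(object@events) != length(object@onsets))
      return("events and onsets must have the same length")
    for (i in seq_along(object@events)) {
      ev <- object@events[[i]]
      if (!is(ev, "CallTemplate")) return("events must be CallTemplate objects")
      if (object@onsets[i] < 0)
        return("onsets must be non-negative")
      if (object@onsets[i] + ev@duration > object@clip_duration)
        return(sprintf("event %d extends past the clip end", i))
    }
    TRUE
  })

#' Labelled audio clip
#'
#' One synthetic (or real) recording unit with its binary bowhead-presence
#' label and, for synthetic scenes, the ground-truth event table.
#'
#' @slot waveform numeric amplitude series, peak at most 1.
#' @slot sample_rate numeric, Hz.
#' @slot label integer, 1 iff at least one bowhead-kind event is present.
#' @slot events data.frame of ground-truth annotations
#'   (kind, onset, duration, f_start, f_end, snr_db).
#' @slot clip_id character identifier.
#' @slot start_time POSIXct nominal recording start.
#' @export
setClass("LabeledClip",
  slots = c(waveform = "numeric", sample_rate = "numeric", label = "integer",
            events = "data.frame", clip_id = "character",
            start_time = "POSIXct"),
  validity = function(object) {
    if (length(object@waveform) == 0) return("waveform is empty")
    if (!all(is.finite(object@waveform))) return("waveform must be finite")
    if (max(abs(object@waveform)) > 1 + 1e-9)
      return("waveform peak must be <= 1")
    if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
    bow <- object@events$kind %in% c("simple_fm", "song_unit")
    if (object@label != as.integer(any(bow)))
      return("label must be 1 iff a bowhead-kind event is present")
    TRUE
  })

#' Spectrogram tile
#'
#' Band-limited log-magnitude spectrogram of one clip: the image the CNN
#' classifies. Rows are frequency bins ordered low to high, columns are
#' time frames.
#'
#' @slot values numeric matrix, `n_freq_bins x n_frames`, log10 magnitude.
#' @slot band numeric length 2, retained frequency band in Hz.
#' @slot bin_width numeric, DFT bin width in Hz.
#' @slot hop integer, hop size in samples.
#' @slot window integer, analysis window length in samples.
#' @slot dft integer, DFT size in samples.
#' @slot sample_rate numeric, Hz of the analysed waveform.
#' @slot clip_id character.
#' @slot start_time POSIXct or NULL.
#' @slot label integer, may be NA for unlabelled inference tiles.
#' @export
setClass("SpectrogramTile",
  slots = c(values = "matrix", band = "numeric", bin_width = "numeric",
            hop = "integer", window = "integer", dft = "integer",
            sample_rate = "numeric", clip_id = "character",
            start_time = "POSIXctOrNULL", label = "integer"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("tile values must be finite")
    if (length(object@band) != 2 || object@band[1] >= object@band[2])
      return("band must be (low, high) with low < high")
    TRUE
  })

#' Tile set
#'
#' A stack of equally shaped spectrogram tiles with labels and metadata,
#' stored as an `F x T x n` array. The container used for training,
#' validation and inference.
#'
#' @slot values numeric 3-d array, frequency x time x tile.
#' @slot labels integer vector (NA allowed for unlabelled tiles).
#' @slot clip_ids character vector.
#' @slot start_times POSIXct vector.
#' @slot params list of DSP parameters (band, bin_width, hop, window, dft,
#'   sample_rate, target_duration).
#' @export
setClass("TileSet",
  slots = c(values = "array", labels = "integer", clip_ids = "character",
            start_times = "POSIXct", params = "list"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be a 3-d array")
    n <- d[3]
    if (length(object@labels) != n || length(object@clip_ids) != n ||
        length(object@start_times) != n)
      return("labels, clip_ids and start_times must match the tile count")
    TRUE
  })

#' Ice field geometry specification
#'
#' Seedable recipe for a synthetic gridded sea-ice concentration field with
#' known geometry, so that edge-distance ground truth has a closed form.
#'
#' @slot nrow,ncol integer grid shape.
#' @slot cell_size numeric, km per cell side (3.125 for the study grid).
#' @slot geometry character: `"half_plane"`, `"disk_patch"`,
#'   `"noise_threshold"` or `"uniform"`.
#' @slot params list of geometry parameters.
#' @slot recorder integer length 2, (row, col) of the recorder cell.
#' @slot seed integer.
#' @export
setClass("IceGeometrySpec",
  slots = c(nrow = "integer", ncol = "integer", cell_size = "numeric",
            geometry = "character", params = "list", recorder = "integer",
            seed = "integer"),
  validity = function(object) {
    if (!object@geometry %in%
        c("half_plane", "disk_patch", "noise_threshold", "uniform"))
      return("unknown geometry")
    if (object@recorder[1] < 1L || object@recorder[1] > object@nrow ||
        object@recorder[2] < 1L || object@recorder[2] > object@ncol)
      return("recorder cell outside grid")
    if (object@cell_size <= 0) return("cell_size must be positive")
    TRUE
  })

#' Gridded sea-ice concentration field
#'
#' Daily sea-ice concentration raster plus the recorder location. Synthetic
#' fields use planar cell-centre coordinates (km); geolocated fields carry
#' per-cell longitude/latitude matrices and distances are great-circle.
#'
#' @slot concentration numeric matrix, percent in \[0, 100\] (NA = missing).
#' @slot cell_size numeric, km.
#' @slot recorder integer length 2 (row, col) of the recorder cell.
#' @slot lon,lat numeric matrices of cell-centre coordinates (may be empty
#'   for planar synthetic fields).
#' @slot recorder_lonlat numeric length 2 (lon, lat) or empty.
#' @slot truth list of analytic ground truth attached by the generator
#'   (e.g. `edge_distance_km`, `defined`, `patch_area_km2`).
#' @export
setClass("IceField",
  slots = c(concentration = "matrix", cell_size = "numeric",
            recorder = "integer", lon = "matrix", lat = "matrix",
            recorder_lonlat = "numeric", truth = "list"),
  validity = function(object) {
    cc <- object@concentration
    if (any(!is.na(cc) & (cc < 0 | cc > 100)))
      return("concentrations must be in [0, 100] or NA")
    if (length(object@recorder) != 2 ||
        object@recorder[1] < 1L || object@recorder[1] > nrow(cc) ||
        object@recorder[2] < 1L || object@recorder[2] > ncol(cc))
      return("recorder must index exactly one grid cell")
    if (object@cell_size <= 0) return("cell_size must be positive")
    TRUE
  })

#' Signed distance to the ice edge
#'
#' Result of [edgeDistance()]. Negative values mean the recorder sits
#' inside the ice (concentration at or above the ice threshold), positive
#' values mean open water. Undefined when no opposite-class cell survives
#' small-patch filtering.
#'
#' @slot value numeric, signed km (NA when undefined).
#' @slot defined logical.
#' @slot recorder_in_ice logical.
#' @export
setClass("EdgeDistance",
  slots = c(value = "numeric", defined = "logical",
            recorder_in_ice = "logical"))

#' CNN architecture specification
#'
#' Declarative description of the detector: a stack of valid square
#' convolutions (stride 1) each followed by ReLU, 2x2 max pooling and
#' dropout, then global average pooling and a fully connected classifier
#' ending in one logistic output unit.
#'
#' @slot kernel_sizes integer vector of odd square kernel sizes, one per
#'   convolutional layer.
#' @slot stride integer, always 1.
#' @slot pool_size integer, always 2.
#' @slot dropout_rate numeric in \[0, 1).
#' @slot channels integer vector of channel counts, starting at 1 (input);
#'   length is one more than `kernel_sizes`.
#' @slot classifier_widths integer vector of hidden dense-layer widths.
#' @slot output_units integer, 1.
#' @export
setClass("ArchitectureSpec",
  slots = c(kernel_sizes = "integer", stride = "integer",
            pool_size = "integer", dropout_rate = "numeric",
            channels = "integer", classifier_widths = "integer",
            output_units = "integer"),
  validity = function(object) {
    if (length(object@kernel_sizes) != length(object@channels) - 1L)
      return("length(kernel_sizes) must equal length(channels) - 1")
    if (any(object@kernel_sizes %% 2L == 0L))
      return("all kernels must be odd")
    if (object@dropout_rate < 0 || object@dropout_rate >= 1)
      return("dropout_rate must be in [0, 1)")
    if (object@channels[1] != 1L) return("input channel count must be 1")
    if (object@output_units != 1L) return("output_units must be 1")
    TRUE
  })

#' Built detector network
#'
#' An [ArchitectureSpec-class] instantiated with weights for a given input
#' tile shape. Weights live in a nested list (`conv`, `dense`), each entry
#' holding `W` and `b` arrays.
#'
#' @slot spec the architecture specification.
#' @slot weights nested list of parameter arrays.
#' @slot input_shape integer length 2, (frequency bins, time frames) the
#'   network was built for.
#' @slot norm_stats list with `mean` and `sd` (set after training) or empty.
#' @export
setClass("Network",
  slots = c(spec = "ArchitectureSpec", weights = "list",
            input_shape = "integer", norm_stats = "list"))

#' Training configuration
#'
#' The training protocol's tunables: the 80/20 split fraction, the model
#' save criterion (validation sensitivity at least `save_min_sensitivity`
#' and false-positive rate below `save_max_fp_rate`, with further
#' false-positive improvements replacing the incumbent), and patience-based
#' early stopping counted in epochs since the last save.
#'
#' @slot train_fraction numeric in (0, 1).
#' @slot save_min_sensitivity numeric in \[0, 1\].
#' @slot save_max_fp_rate numeric in \[0, 1\].
#' @slot patience integer >= 1, epochs without a save before stopping.
#' @slot max_epochs integer.
#' @slot batch_size integer.
#' @slot learning_rate numeric.
#' @slot seed integer.
#' @export
setClass("TrainConfig",
  slots = c(train_fraction = "numeric", save_min_sensitivity = "numeric",
            save_max_fp_rate = "numeric", patience = "integer",
            max_epochs = "integer", batch_size = "integer",
            learning_rate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@train_fraction <= 0 || object@train_fraction >= 1)
      return("train_fraction must be in (0, 1)")
    if (object@save_min_sensitivity < 0 || object@save_min_sensitivity > 1 ||
        object@save_max_fp_rate < 0 || object@save_max_fp_rate > 1)
      return("save thresholds must be in [0, 1]")
    if (object@patience < 1L) return("patience must be >= 1")
    if (object@max_epochs < 1L) return("max_epochs must be >= 1")
    TRUE
  })

#' Training history
#'
#' Per-epoch record of the training protocol: loss, validation sensitivity
#' and false-positive rate, and whether the epoch's model was saved as the
#' new incumbent.
#'
#' @slot epochs data.frame with columns epoch, loss, val_sensitivity,
#'   val_fp_rate, saved.
#' @slot best_epoch integer, epoch of the final incumbent (NA if no model
#'   ever met the save criterion).
#' @slot stop_epoch integer, last epoch run.
#' @export
setClass("TrainHistory",
  slots = c(epochs = "data.frame", best_epoch = "integer",
            stop_epoch = "integer"))

#' Fitted detector
#'
#' Return value of [trainDetector()]: the incumbent best network (or the
#' final weights when no epoch met the save criterion), the training
#' history, and the training-set normalization statistics.
#'
#' @slot network the best [Network-class].
#' @slot history a [TrainHistory-class].
#' @slot norm_stats list with `mean` and `sd` fitted on the training split.
#' @slot saved_any logical, whether any epoch met the save criterion.
#' @export
setClass("DetectorFit",
  slots = c(network = "Network", history = "TrainHistory",
            norm_stats = "list", saved_any = "logical"))

#' Detection performance summary
#'
#' Confusion counts at file or hour level with derived sensitivity
#' TP/(TP+FN) and false-positive rate FP/(FP+TN). Rates with a zero
#' denominator are undefined and reported as NA.
#'
#' @slot tp,tn,fp,fn integer counts.
#' @slot level character, `"file"` or `"hour"`.
#' @export
setClass("PerformanceSummary",
  slots = c(tp = "integer", tn = "integer", fp = "integer", fn = "integer",
            level = "character"),
  validity = function(object) {
    if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
      return("counts must be non-negative")
    if (!object@level %in% c("file", "hour"))
      return("level must be 'file' or 'hour'")
    TRUE
  })

#' Review window definition
#'
#' The seasonal window for partial false-positive control: detections from
#' `season_start` (March 1 in the study) are reviewed until the first
#' reviewer-confirmed detection at or after `autumn_search_from`. The
#' autumn anchor is a parameter because the source protocol states it
#' ambiguously (November in one place, September in another).
#'
#' @slot season_start character `"MM-DD"`.
#' @slot autumn_search_from character `"MM-DD"`.
#' @export
setClass("ReviewWindow",
  slots = c(season_start = "character", autumn_search_from = "character"))

#' Acoustic presence series
#'
#' Daily counts of hours with bowhead acoustic presence, duty-cycle aware:
#' hours with no recorded files are missing, not negative.
#'
#' @slot daily data.frame with columns date, presence_hours, recorded_hours.
#' @slot total_presence_hours integer.
#' @slot days_with_presence integer.
#' @export
setClass("PresenceSeries",
  slots = c(daily = "data.frame", total_presence_hours = "integer",
            days_with_presence = "integer"),
  validity = function(object) {
    d <- object@daily
    if (nrow(d) && any(d$presence_hours > 24))
      return("daily presence hours cannot exceed 24")
    if (nrow(d) && any(d$presence_hours > d$recorded_hours))
      return("daily presence hours cannot exceed recorded hours")
    TRUE
  })
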