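# Chunked on-disk tile store.
#
# Layout mirrors a chunked-array store: one directory per recorder group,
# one binary chunk per tile (little-endian doubles), plus a JSON attribute
# file recording shape, labels, clip ids, timestamps and DSP parameters.
# Round trips are bit-identical and single tiles can be read without
# touching the rest of the store.

storeAttrPath <- function(store_path, group) {
  file.path(store_path, group, "attrs.json")
}

#' Persist a TileSet to a chunked store
#'
#' @param tiles a [TileSet-class].
#' @param store_path store root directory (created if missing).
#' @param group group name, typically the recorder id.
#' @return `store_path`, invisibly.
#' @export
persistTiles <- function(tiles, store_path, group = "recorder") {
  stopifnot(is(tiles, "TileSet"))
  validObject(tiles)
  gdir <- file.path(store_path, group, "tiles")
  if (!dir.exists(gdir)) dir.create(gdir, recursive = TRUE)
  d <- dim(tiles@values)
  for (i in seq_len(d[3])) {
    con <- file(file.path(gdir, sprintf("%06d.bin", i)), "wb")
    writeBin(as.vector(tiles@values[, , i]), con, size = 8,
             endian = "little")
    close(con)
  }
  attrs <- list(
    n = d[3], n_freq = d[1], n_frames = d[2],
    labels = tiles@labels,
    clip_ids = tiles@clip_ids,
    start_times = format(tiles@start_times, "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"),
    params = tiles@params)
  writeLines(jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             storeAttrPath(store_path, group))
  invisible(store_path)
}

#' Load tiles from a chunked store
#'
#' @param store_path store root directory.
#' @param group group name.
#' @param index optional integer vector of tile indices to read (defaults
#'   to all); partial reads touch only the requested chunks.
#' @return a [TileSet-class].
#' @export
loadTiles <- function(store_path, group = "recorder", index = NULL) {
  ap <- storeAttrPath(store_path, group)
  if (!file.exists(ap)) stop("no such group in store: ", group)
  attrs <- jsonlite::fromJSON(readLines(ap))
  if (is.null(index)) index <- seq_len(attrs$n)
  stopifnot(all(index >= 1L), all(index <= attrs$n))
  vals <- array(0, dim = c(attrs$n_freq, attrs$n_frames, length(index)))
  gdir <- file.path(store_path, group, "tiles")
  for (j in seq_along(index)) {
    con <- file(file.path(gdir, sprintf("%06d.bin", index[j])), "rb")
    vals[, , j] <- readBin(con, "numeric",
                           n = attrs$n_freq * attrs$n_frames, size = 8,
                           endian = "little")
    close(con)
  }
  params <- attrs$params
  params$band <- as.numeric(params$band)
  labels <- as.integer(attrs$labels)
  new("TileSet", values = vals, labels = labels[index],
      clip_ids = as.character(attrs$clip_ids)[index],
      start_times = as.POSIXct(attrs$start_times[index],
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      params = params)
}

#' List groups in a tile store
#'
#' @param store_path store root directory.
#' @return character vector of group names.
#' @export
storeGroups <- function(store_path) {
  dirs <- list.dirs(store_path, recursive = FALSE, full.names = FALSE)
  dirs[vapply(dirs, function(g) file.exists(storeAttrPath(store_path, g)),
              logical(1))]
}
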