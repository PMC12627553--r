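#' Construct an ice field
#'
#' @param concentration numeric matrix of percent concentrations (NA =
#'   missing).
#' @param cell_size km per cell side.
#' @param recorder (row, col) of the recorder cell.
#' @param lon,lat optional matrices of cell-centre coordinates for
#'   geolocated grids (distances then use great circles on a spherical
#'   Earth of radius 6371 km).
#' @param recorder_lonlat recorder (lon, lat) for geolocated grids.
#' @return an [IceField-class].
#' @export
iceField <- function(concentration, cell_size = 3.125,
                     recorder = c(1L, 1L), lon = NULL, lat = NULL,
                     recorder_lonlat = NULL) {
  new("IceField", concentration = concentration, cell_size = cell_size,
      recorder = as.integer(recorder),
      lon = if (is.null(lon)) matrix(numeric(0), 0, 0) else lon,
      lat = if (is.null(lat)) matrix(numeric(0), 0, 0) else lat,
      recorder_lonlat = if (is.null(recorder_lonlat)) numeric(0) else
        as.numeric(recorder_lonlat),
      truth = list())
}

#' @describeIn IceField-class concentration matrix.
#' @export
setMethod("concentration", "IceField", function(object) object@concentration)

setMethod("show", "IceField", function(object) {
  cc <- object@concentration
  cat(sprintf(
    "IceField: %d x %d cells of %.3f km, recorder at (%d, %d)\n",
    nrow(cc), ncol(cc), object@cell_size, object@recorder[1],
    object@recorder[2]))
  cat(sprintf("  concentration %.1f-%.1f%%, %d missing cells\n",
              min(cc, na.rm = TRUE), max(cc, na.rm = TRUE), sum(is.na(cc))))
})

geolocated <- function(field) length(field@lon) > 0

# distances (km) from the recorder to every cell centre
cellDistances <- function(field) {
  cc <- field@concentration
  if (geolocated(field)) {
    d <- geosphere::distHaversine(
      cbind(as.vector(field@lon), as.vector(field@lat)),
      field@recorder_lonlat, r = 6371)
    matrix(d, nrow(cc), ncol(cc))
  } else {
    rows <- (seq_len(nrow(cc)) - field@recorder[1]) * field@cell_size
    cols <- (seq_len(ncol(cc)) - field@recorder[2]) * field@cell_size
    sqrt(outer(rows^2, cols^2, "+"))
  }
}

#' Mean sea-ice concentration around the recorder
#'
#' Unweighted mean of concentration over cells whose centres lie within
#' `radius` of the recorder position (35 km in the study, the estimated
#' maximum sound propagation range of the calls). Euclidean distances on
#' planar synthetic grids, great circles on geolocated grids; missing cells
#' are excluded.
#'
#' @param field an [IceField-class].
#' @param radius km.
#' @return mean concentration in percent, or NA when no non-missing cell
#'   centre falls inside the radius.
#' @export
meanConcentration <- function(field, radius = 35) {
  stopifnot(is(field, "IceField"))
  d <- cellDistances(field)
  sel <- d <= radius & !is.na(field@concentration)
  if (!any(sel)) {
    warning("no non-missing cells within radius: mean undefined")
    return(NA_real_)
  }
  mean(field@concentration[sel])
}

#' Classify ice vs water and filter small patches
#'
#' Cells at or above `ice_threshold` percent concentration are ice, below
#' it water. Connected components (4-connectivity, edge-sharing) of BOTH
#' classes are computed on the original mask in a single pass, and
#' components of at most `max_patch` cells are excluded from edge-distance
#' candidacy (a 50-cell patch on the 3.125 km study grid is about
#' 488 km^2). Missing cells belong to neither class.
#'
#' @param field an [IceField-class].
#' @param ice_threshold percent; at or above is ice.
#' @param max_patch maximum component size (cells) to exclude.
#' @return list with `ice` (logical matrix, NA for missing cells) and
#'   `eligible` (logical matrix: cell survives patch filtering).
#' @export
classifyAndFilter <- function(field, ice_threshold = 15, max_patch = 50) {
  stopifnot(is(field, "IceField"))
  cc <- field@concentration
  ice <- cc >= ice_threshold  # NA stays NA
  eligible <- matrix(FALSE, nrow(cc), ncol(cc))
  for (cls in c(TRUE, FALSE)) {
    mask <- !is.na(ice) & ice == cls
    if (!any(mask)) next
    lab <- as.integer(EBImage::bwlabel(mask * 1L))
    sizes <- tabulate(lab[lab > 0L])
    keep <- lab %in% which(sizes > max_patch)
    eligible[keep & as.vector(mask)] <- TRUE
  }
  list(ice = ice, eligible = eligible)
}

#' Signed shortest distance to the ice edge
#'
#' Magnitude is the minimum distance from the recorder position to the
#' centre of any non-excluded opposite-class cell: nearest sea ice (at or
#' above the threshold) when the recorder sits in open water, nearest open
#' water when it sits in ice. The sign is negative inside the ice and
#' positive in open water. Undefined -- a value, not an error -- when the
#' recorder cell is missing or no opposite-class cell survives small-patch
#' filtering.
#'
#' @param field an [IceField-class].
#' @param ice_threshold percent; at or above is ice.
#' @param max_patch component size (cells) at or below which patches are
#'   excluded.
#' @return an [EdgeDistance-class].
#' @export
edgeDistance <- function(field, ice_threshold = 15, max_patch = 50) {
  stopifnot(is(field, "IceField"))
  cf <- classifyAndFilter(field, ice_threshold, max_patch)
  rec <- field@recorder
  rec_ice <- cf$ice[rec[1], rec[2]]
  if (is.na(rec_ice))
    return(new("EdgeDistance", value = NA_real_, defined = FALSE,
               recorder_in_ice = NA))
  opposite <- !is.na(cf$ice) & cf$ice != rec_ice & cf$eligible
  if (!any(opposite))
    return(new("EdgeDistance", value = NA_real_, defined = FALSE,
               recorder_in_ice = rec_ice))
  d <- cellDistances(field)
  mag <- min(d[opposite])
  new("EdgeDistance", value = if (rec_ice) -mag else mag, defined = TRUE,
      recorder_in_ice = rec_ice)
}

setMethod("show", "EdgeDistance", function(object) {
  if (!object@defined) {
    cat("EdgeDistance: undefined\n")
  } else {
    cat(sprintf("EdgeDistance: %+.2f km (recorder in %s)\n", object@value,
                if (object@recorder_in_ice) "ice" else "open water"))
  }
})

#' Write an ice field as a plain gridded array with a JSON sidecar
#'
#' The grid goes to `<path>.csv` (rows x cols, no headers, NA for missing
#' cells) and the metadata (cell size, recorder cell, optional ground
#' truth) to `<path>.json`.
#'
#' @param field an [IceField-class] (planar).
#' @param path output path stem (without extension).
#' @return `path`, invisibly.
#' @export
writeIceField <- function(field, path) {
  stopifnot(is(field, "IceField"))
  utils::write.table(field@concentration, paste0(path, ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(cell_size_km = field@cell_size,
               recorder_row = field@recorder[1],
               recorder_col = field@recorder[2],
               truth = field@truth)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read an ice field written by [writeIceField()]
#'
#' @param path path stem (without extension).
#' @return an [IceField-class].
#' @export
readIceField <- function(path) {
  conc <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ",",
                                      header = FALSE))
  dimnames(conc) <- NULL
  meta <- jsonlite::fromJSON(readLines(paste0(path, ".json")))
  f <- iceField(conc, cell_size = meta$cell_size_km,
                recorder = c(meta$recorder_row, meta$recorder_col))
  if (length(meta$truth)) f@truth <- as.list(meta$truth)
  f
}

#' Daily ice covariates for a set of fields
#'
#' Convenience wrapper producing the per-day covariate table used alongside
#' presence series: mean concentration within the radius and signed edge
#' distance.
#'
#' @param fields named list of [IceField-class] objects (names are dates).
#' @param radius km for [meanConcentration()].
#' @param ice_threshold,max_patch passed to [edgeDistance()].
#' @return data.frame with columns date, mean_concentration_pct,
#'   edge_distance_km, defined.
#' @export
iceCovariates <- function(fields, radius = 35, ice_threshold = 15,
                          max_patch = 50) {
  rows <- lapply(names(fields), function(nm) {
    ed <- edgeDistance(fields[[nm]], ice_threshold, max_patch)
    data.frame(date = nm,
               mean_concentration_pct = meanConcentration(fields[[nm]],
                                                          radius),
               edge_distance_km = ed@value,
               defined = ed@defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
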