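#' Confusion summary at file or hour level
#'
#' Counts TP/TN/FP/FN over evaluation units and derives sensitivity
#' TP/(TP+FN) and false-positive rate FP/(FP+TN). Given two aligned 0/1
#' vectors the units are whatever the vectors index (files, hours). Given
#' detection records and `level = "hour"`, predictions and truth are first
#' rolled up independently with [hourlyRollup()].
#'
#' @param predicted 0/1 vector, or a detection-record data.frame with
#'   start_time, predicted and truth columns.
#' @param truth 0/1 vector (ignored when `predicted` is a data.frame).
#' @param level `"file"` or `"hour"`.
#' @return a [PerformanceSummary-class].
#' @export
confusionSummary <- function(predicted, truth = NULL, level = "file") {
  if (is.data.frame(predicted)) {
    records <- predicted
    if (identical(level, "hour")) {
      h <- hourlyRollup(records)
      predicted <- h$predicted
      truth <- h$truth
    } else {
      predicted <- records$predicted
      truth <- records$truth
    }
  }
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  ok <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[ok]
  truth <- truth[ok]
  new("PerformanceSummary",
      tp = sum(predicted == 1L & truth == 1L),
      tn = sum(predicted == 0L & truth == 0L),
      fp = sum(predicted == 1L & truth == 0L),
      fn = sum(predicted == 0L & truth == 1L),
      level = level)
}

#' @describeIn PerformanceSummary-class sensitivity TP/(TP+FN); NA when the
#'   denominator is zero (undefined, not propagated as an error).
#' @export
setMethod("sensitivity", "PerformanceSummary", function(object) {
  d <- object@tp + object@fn
  if (d == 0L) NA_real_ else object@tp / d
})

#' @describeIn PerformanceSummary-class false-positive rate FP/(FP+TN); NA
#'   when the denominator is zero.
#' @export
setMethod("fpRate", "PerformanceSummary", function(object) {
  d <- object@fp + object@tn
  if (d == 0L) NA_real_ else object@fp / d
})

setMethod("show", "PerformanceSummary", function(object) {
  s <- sensitivity(object)
  f <- fpRate(object)
  cat(sprintf(
    "PerformanceSummary (%s level): TP %d, TN %d, FP %d, FN %d\n",
    object@level, object@tp, object@tn, object@fp, object@fn))
  cat(sprintf("  sensitivity %s, FP rate %s\n",
              ifelse(is.na(s), "undefined", sprintf("%.2f", s)),
              ifelse(is.na(f), "undefined", sprintf("%.2f", f))))
})

#' Roll detections up to hourly presence flags
#'
#' Each file is assigned to the full hour in which it starts. An hour is
#' positive -- for predictions and ground truth independently -- if at
#' least one positive record starts within it. Hours with no recorded files
#' are missing from the output (duty cycles make missing different from
#' absent), never negative.
#'
#' @param records data.frame with start_time plus predicted and/or truth
#'   columns.
#' @return data.frame with one row per recorded hour: `hour` (POSIXct,
#'   truncated), plus rolled-up `predicted` / `truth` flags where the
#'   corresponding column exists.
#' @export
hourlyRollup <- function(records) {
  stopifnot("start_time" %in% names(records))
  hour <- as.POSIXct(trunc(records$start_time, units = "hours"))
  key <- format(hour, "%Y-%m-%d %H", tz = "UTC")
  uk <- !duplicated(key)
  out <- data.frame(hour = hour[uk])
  ord <- order(out$hour)
  out <- data.frame(hour = out$hour[ord])
  okey <- format(out$hour, "%Y-%m-%d %H", tz = "UTC")
  for (col in intersect(c("predicted", "truth"), names(records))) {
    v <- records[[col]]
    agg <- tapply(v, key, function(z) as.integer(any(z == 1L, na.rm = TRUE)))
    out[[col]] <- as.integer(agg[okey])
  }
  out
}

#' Daily acoustic presence from hourly flags
#'
#' Counts positive hours per day and totals them into the headline
#' presence metrics: total presence hours and number of days with at least
#' one presence hour. Recorded hours per day are carried along so missing
#' (duty-cycled) hours never count as absence.
#'
#' @param hourly data.frame from [hourlyRollup()].
#' @param flag_col which flag to aggregate (`"predicted"` or `"truth"`).
#' @return a [PresenceSeries-class].
#' @export
dailyPresence <- function(hourly, flag_col = "predicted") {
  stopifnot(flag_col %in% names(hourly))
  date <- as.Date(hourly$hour, tz = "UTC")
  flags <- hourly[[flag_col]]
  daily <- data.frame(
    date = sort(unique(date)))
  daily$presence_hours <- as.integer(
    tapply(flags, date, function(z) sum(z == 1L, na.rm = TRUE))[
      as.character(daily$date)])
  daily$recorded_hours <- as.integer(
    tapply(flags, date, length)[as.character(daily$date)])
  new("PresenceSeries", daily = daily,
      total_presence_hours = sum(daily$presence_hours),
      days_with_presence = sum(daily$presence_hours > 0L))
}

setMethod("show", "PresenceSeries", function(object) {
  cat(sprintf(
    "PresenceSeries: %d h of acoustic presence across %d days (%d days recorded)\n",
    object@total_presence_hours, object@days_with_presence,
    nrow(object@daily)))
})

#' Select the sample days of a date range
#'
#' The manual-labelling protocol samples the 5th, 10th, 15th, 20th and 25th
#' day of each month, whenever available in the range.
#'
#' @param from,to inclusive `Date` range bounds.
#' @param days_of_month integer days to select.
#' @return Date vector.
#' @export
selectSampleDays <- function(from, to, days_of_month = c(5L, 10L, 15L, 20L,
                                                         25L)) {
  from <- as.Date(from)
  to <- as.Date(to)
  stopifnot(from <= to)
  all_days <- seq(from, to, by = "day")
  all_days[as.integer(format(all_days, "%d")) %in% days_of_month]
}

#' Tabulate song occurrence
#'
#' Songs are renumbered 1..K in the order of their first occurrence date.
#' Returns per-day and per-month unique-song counts and each song's span of
#' active days.
#'
#' @param annotations data.frame with columns `date` (Date or coercible)
#'   and `song_label` (reviewer-assigned identifier).
#' @return list with `numbering` (song_label, song_number, first_date,
#'   active_days), `per_day` (date, n_unique) and `per_month` (month,
#'   n_unique).
#' @export
songTally <- function(annotations) {
  stopifnot(all(c("date", "song_label") %in% names(annotations)))
  a <- annotations
  a$date <- as.Date(a$date)
  a <- a[order(a$date), ]
  first_seen <- a[!duplicated(a$song_label), c("song_label", "date")]
  numbering <- data.frame(
    song_label = first_seen$song_label,
    song_number = seq_len(nrow(first_seen)),
    first_date = first_seen$date,
    stringsAsFactors = FALSE)
  numbering$active_days <- vapply(numbering$song_label, function(s)
    length(unique(a$date[a$song_label == s])), integer(1))
  per_day <- stats::aggregate(song_label ~ date, data = unique(a),
                              FUN = length)
  names(per_day)[2] <- "n_unique"
  am <- unique(data.frame(month = format(a$date, "%Y-%m"),
                          song_label = a$song_label))
  per_month <- stats::aggregate(song_label ~ month, data = am, FUN = length)
  names(per_month)[2] <- "n_unique"
  list(numbering = numbering, per_day = per_day, per_month = per_month)
}
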