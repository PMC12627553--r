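#' Threshold model probabilities into binary detections
#'
#' Probabilities strictly above the threshold become positive; values at or
#' below it negative. The tie at exactly the threshold is classified
#' negative, the conservative detection stance.
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param threshold decision threshold (study: 0.5).
#' @return integer vector of 0/1 predictions.
#' @export
thresholdScores <- function(probabilities, threshold = 0.5) {
  if (any(!is.finite(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  as.integer(probabilities > threshold)
}

#' Assemble detection records
#'
#' The atom of all presence statistics: one row per scored file.
#'
#' @param clip_id character vector.
#' @param start_time POSIXct vector.
#' @param probability numeric vector in \[0, 1\].
#' @param truth optional 0/1 ground-truth labels.
#' @param threshold decision threshold.
#' @return data.frame with columns clip_id, start_time, probability,
#'   predicted, truth (NA when unknown), review_status (`"auto"`) and
#'   flagged (FALSE).
#' @export
detectionRecords <- function(clip_id, start_time, probability, truth = NULL,
                             threshold = 0.5) {
  n <- length(clip_id)
  data.frame(clip_id = clip_id, start_time = start_time,
             probability = probability,
             predicted = thresholdScores(probability, threshold),
             truth = if (is.null(truth)) rep(NA_integer_, n) else
               as.integer(truth),
             review_status = rep("auto", n), flagged = rep(FALSE, n),
             stringsAsFactors = FALSE)
}

#' Construct a review-window definition
#'
#' @param season_start `"MM-DD"`; review starts here each calendar year
#'   (study: March 1).
#' @param autumn_search_from `"MM-DD"`; the window closes at the first
#'   reviewer-confirmed detection at or after this anchor. The protocol
#'   source states the anchor inconsistently (November in the methods text,
#'   September in the performance-table footnote), so it is a parameter;
#'   September 1 is the default.
#' @return a [ReviewWindow-class].
#' @export
reviewWindow <- function(season_start = "03-01",
                         autumn_search_from = "09-01") {
  new("ReviewWindow", season_start = season_start,
      autumn_search_from = autumn_search_from)
}

#' Flag detections that fall inside the manual-review window
#'
#' Implements partial false-positive control: every positive detection
#' between `season_start` and the first confirmed detection at or after the
#' autumn anchor (inclusive) is flagged for manual review; detections
#' outside the window keep `review_status = "auto"`. Records before the
#' first season start are also reviewed (a deployment may begin outside the
#' calling period). When no autumn detection is confirmed, the window
#' extends to the end of the records.
#'
#' The reviewer's confirmations are taken from the `truth` column when
#' present (in tests and simulations ground truth plays the reviewer); with
#' no truth available the window never closes.
#'
#' @param records detection records ([detectionRecords()]).
#' @param window a [ReviewWindow-class].
#' @return `records` with the logical `flagged` column set.
#' @export
flagReviewWindow <- function(records, window = reviewWindow()) {
  stopifnot(all(c("start_time", "predicted") %in% names(records)))
  ord <- order(records$start_time)
  flagged <- logical(nrow(records))
  reviewing <- TRUE  # conservative: review until the first autumn close
  reopen_at <- NULL  # season_start after a close
  have_truth <- "truth" %in% names(records)
  for (j in ord) {
    t <- records$start_time[j]
    yr <- as.integer(format(t, "%Y"))
    if (!reviewing && t >= reopen_at) reviewing <- TRUE
    if (reviewing && records$predicted[j] == 1L) {
      flagged[j] <- TRUE
      confirmed <- have_truth && !is.na(records$truth[j]) &&
        records$truth[j] == 1L
      # a confirmed detection at/after the autumn anchor closes the window
      # until the next season start
      if (confirmed && t >= monthDay(window@autumn_search_from, yr)) {
        reviewing <- FALSE
        reopen_at <- monthDay(window@season_start, yr + 1L)
      }
    }
  }
  records$flagged <- flagged
  records
}

#' Apply reviewer decisions to flagged detections
#'
#' Rejected detections become negative (`predicted = 0`,
#' `review_status = "rejected"`); confirmed detections keep their positive
#' prediction (`review_status = "confirmed"`). Unflagged records are
#' untouched and may not be referenced by a decision. The operation is
#' idempotent. Review can only flip predictions 1 to 0, never 0 to 1, so
#' with fixed ground truth the true-positive and false-negative counts --
#' and hence sensitivity -- are invariant when the reviewer is correct.
#'
#' @param records flagged detection records ([flagReviewWindow()]).
#' @param decisions data.frame with columns `clip_id` and `decision`
#'   (`"confirm"` or `"reject"`).
#' @return updated records.
#' @export
applyReview <- function(records, decisions) {
  stopifnot("flagged" %in% names(records))
  if (nrow(decisions) == 0) return(records)
  stopifnot(all(c("clip_id", "decision") %in% names(decisions)),
            all(decisions$decision %in% c("confirm", "reject")))
  m <- match(decisions$clip_id, records$clip_id)
  if (any(is.na(m)))
    stop("decisions reference unknown clip_ids")
  if (any(!records$flagged[m]))
    stop("decisions may only reference flagged records")
  rej <- m[decisions$decision == "reject"]
  con <- m[decisions$decision == "confirm"]
  records$predicted[rej] <- 0L
  records$review_status[rej] <- "rejected"
  records$review_status[con] <- "confirmed"
  records
}

#' Oracle reviewer decisions from ground truth
#'
#' Builds the decision table a perfectly accurate reviewer would produce
#' for the flagged records: confirm where truth is positive, reject where
#' it is negative.
#'
#' @param records flagged detection records with a `truth` column.
#' @return data.frame with columns clip_id, decision.
#' @export
oracleDecisions <- function(records) {
  f <- records[records$flagged & !is.na(records$truth), ]
  data.frame(clip_id = f$clip_id,
             decision = ifelse(f$truth == 1L, "confirm", "reject"),
             stringsAsFactors = FALSE)
}

#' Write detections as CSV
#'
#' Columns: clip_id, start_time (ISO-8601), probability, predicted,
#' review_status.
#'
#' @param records detection records.
#' @param path output path.
#' @export
writeDetections <- function(records, path) {
  out <- records[, c("clip_id", "start_time", "probability", "predicted",
                     "review_status")]
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
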