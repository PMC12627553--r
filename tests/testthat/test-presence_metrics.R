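hts <- function(day, hm, year = 2022) {
  as.POSIXct(paste0(year, "-", day, " ", hm), tz = "UTC")
}

test_that("confusion summaries reproduce the recorder performance arithmetic", {
  # hourly counts published for one ice-covered-site recorder
  a <- new("PerformanceSummary", tp = 537L, tn = 677L, fp = 77L, fn = 29L,
           level = "hour")
  expect_equal(round(sensitivity(a), 2), 0.95)
  expect_equal(round(fpRate(a), 2), 0.10)
  expect_identical(a@tp + a@tn + a@fp + a@fn, 1320L)

  # and for an open-water-site recorder
  b <- new("PerformanceSummary", tp = 97L, tn = 1663L, fp = 23L, fn = 17L,
           level = "hour")
  expect_equal(round(sensitivity(b), 2), 0.85)
  expect_equal(round(fpRate(b), 2), 0.01)
})

test_that("confusion counts come out of aligned prediction vectors", {
  pred <- c(1L, 1L, 0L, 0L, 1L)
  truth <- c(1L, 0L, 0L, 1L, 1L)
  s <- confusionSummary(pred, truth)
  expect_identical(c(s@tp, s@tn, s@fp, s@fn), c(2L, 1L, 1L, 1L))
  perfect <- confusionSummary(truth, truth)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(fpRate(perfect), 0)
  expect_error(confusionSummary(pred, truth[-1]), "same length")
})

test_that("undefined rates are NA-flagged, not errors", {
  s <- confusionSummary(c(0L, 1L), c(1L, 1L))
  expect_true(is.na(fpRate(s)))  # no negatives
  expect_equal(sensitivity(s), 0.5)
  s2 <- confusionSummary(c(0L, 0L), c(0L, 0L))
  expect_true(is.na(sensitivity(s2)))
})

test_that("files are assigned to the full hour in which they start", {
  rec <- data.frame(
    start_time = c(hts("01-01", "13:05:00"), hts("01-01", "13:55:00"),
                   hts("01-01", "13:59:59"), hts("01-01", "15:10:00")),
    predicted = c(1L, 1L, 1L, 0L),
    truth = c(1L, 0L, 1L, 0L))
  h <- hourlyRollup(rec)
  expect_identical(nrow(h), 2L)  # hours 13 and 15; hour 14 missing
  expect_identical(format(h$hour, "%H"), c("13", "15"))
  expect_identical(h$predicted, c(1L, 0L))
  expect_identical(h$truth, c(1L, 0L))
})

test_that("duty-cycled gaps are missing hours, not negatives", {
  rec <- data.frame(
    start_time = c(hts("01-01", "01:00:00"), hts("01-01", "03:00:00")),
    predicted = c(0L, 1L))
  h <- hourlyRollup(rec)
  expect_identical(format(h$hour, "%H"), c("01", "03"))
  expect_false("02" %in% format(h$hour, "%H"))
})

test_that("hour-level summaries roll predictions and truth up independently", {
  rec <- data.frame(
    start_time = c(hts("01-01", "10:00:00"), hts("01-01", "10:10:00"),
                   hts("01-01", "11:00:00"), hts("01-01", "12:00:00")),
    predicted = c(1L, 0L, 0L, 1L),
    truth = c(0L, 1L, 0L, 0L))
  s <- confusionSummary(rec, level = "hour")
  # hour 10: pred 1 truth 1 (one positive file each) -> TP
  # hour 11: 0/0 -> TN; hour 12: 1/0 -> FP
  expect_identical(c(s@tp, s@tn, s@fp, s@fn), c(1L, 1L, 1L, 0L))
  expect_identical(s@level, "hour")
})

test_that("daily presence totals count planted hours exactly", {
  # 10-day synthetic series with known plantings
  set.seed(33)
  days <- sprintf("2022-11-%02d", 1:10)
  planted <- c(24L, 0L, 3L, 12L, 0L, 7L, 1L, 24L, 5L, 0L)
  rows <- list()
  for (d in seq_along(days)) {
    pos_hours <- if (planted[d] > 0) sort(sample(0:23, planted[d])) else
      integer(0)
    for (h in 0:23) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_time = as.POSIXct(sprintf("%s %02d:00:00", days[d], h),
                                tz = "UTC"),
        predicted = as.integer(h %in% pos_hours))
    }
  }
  rec <- do.call(rbind, rows)
  ps <- dailyPresence(hourlyRollup(rec))
  expect_identical(ps@daily$presence_hours, planted)
  expect_identical(ps@total_presence_hours, sum(planted))
  expect_identical(ps@days_with_presence, sum(planted > 0L))
  expect_true(all(ps@daily$presence_hours <= 24))
  expect_identical(max(ps@daily$presence_hours), 24L)

  none <- dailyPresence(hourlyRollup(
    data.frame(start_time = rec$start_time[1:5], predicted = rep(0L, 5))))
  expect_identical(none@total_presence_hours, 0L)
  expect_identical(none@days_with_presence, 0L)
})

test_that("hour-level sensitivity dominates file level under full coverage", {
  # every truth-positive hour holds at least one predicted-positive file
  rec <- data.frame(
    start_time = hts("02-01", "08:00:00") + rep(0:5, each = 3) * 3600 +
      rep(c(0, 600, 1200), 6),
    predicted = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L,
                  1L, 0L, 0L, 0L, 0L, 0L),
    truth = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L,
              1L, 0L, 0L, 0L, 0L, 0L))
  file_s <- sensitivity(confusionSummary(rec$predicted, rec$truth))
  hour_s <- sensitivity(confusionSummary(rec, level = "hour"))
  expect_gte(hour_s, file_s)
})

test_that("sample-day selection returns exactly the 5/10/15/20/25 days", {
  full <- selectSampleDays("2022-10-01", "2022-10-31")
  expect_identical(as.integer(format(full, "%d")), c(5L, 10L, 15L, 20L, 25L))

  clipped <- selectSampleDays("2022-10-12", "2022-10-31")
  expect_identical(as.integer(format(clipped, "%d")), c(15L, 20L, 25L))

  year <- selectSampleDays("2022-01-01", "2022-12-31")
  expect_length(year, 60L)
})

test_that("songs are numbered by first occurrence and tallied per day/month", {
  ann <- data.frame(
    date = as.Date(c("2022-10-03", "2022-10-20", "2022-11-01", "2022-10-20",
                     "2022-11-05", "2022-10-03")),
    song_label = c("B", "A", "C", "B", "B", "A"))
  tally <- songTally(ann)
  # first occurrences: B and A on Oct 3, C on Nov 1; ties keep table order
  expect_identical(tally$numbering$song_label, c("B", "A", "C"))
  expect_identical(tally$numbering$song_number, 1:3)
  expect_identical(tally$numbering$active_days[1], 3L)  # B on 3 days
  expect_identical(tally$per_day$n_unique[tally$per_day$date ==
                                            as.Date("2022-10-03")], 2L)
  expect_identical(
    tally$per_month$n_unique[tally$per_month$month == "2022-10"], 2L)

  # a song seen on 65 distinct days reports 65 active days
  long <- data.frame(date = as.Date("2022-10-01") + c(0:64, 0:9),
                     song_label = rep(c("S3", "S1"), c(65, 10)))
  expect_identical(
    songTally(long)$numbering$active_days[
      songTally(long)$numbering$song_label == "S3"], 65L)

  # monthly unique count collapses repeats
  m <- data.frame(date = as.Date(c("2023-02-01", "2023-02-02", "2023-02-03",
                                   "2023-02-04")),
                  song_label = c("S1", "S2", "S1", "S3"))
  expect_identical(songTally(m)$per_month$n_unique, 3L)
})
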