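# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of their spec
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# mean-square power of x restricted to a frequency band, via the DFT
# (Parseval); used to calibrate event SNR where the detector looks
bandPower <- function(x, sample_rate, band = c(50, 1000)) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  keep <- f >= band[1] & f <= band[2]
  # one-sided: double everything except DC/Nyquist, but band excludes DC
  2 * sum(Mod(X[keep])^2) / n^2
}

# streaming mean and sd over a big 3-d array without a full copy
arrayMoments <- function(a) {
  n3 <- dim(a)[3]
  total <- 0
  count <- 0
  for (i in seq_len(n3)) {
    total <- total + sum(a[, , i])
    count <- count + length(a[, , i])
  }
  m <- total / count
  ss <- 0
  for (i in seq_len(n3)) ss <- ss + sum((a[, , i] - m)^2)
  list(mean = m, sd = sqrt(ss / (count - 1)))
}

# "MM-DD" anchored in year y -> POSIXct at midnight UTC
monthDay <- function(md, year) {
  as.POSIXct(paste0(year, "-", md), tz = "UTC")
}
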