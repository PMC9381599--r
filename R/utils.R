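# Internal helpers shared across modules.

# Decimal hour-of-day of a POSIXct in its own timezone.
tod_hours <- function(x) {
  lt <- as.POSIXlt(x)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# Total overlap (seconds) of intervals [s, e) with window [ws, we).
overlap_seconds <- function(s, e, ws, we) {
  lo <- pmax(as.numeric(s), as.numeric(ws))
  hi <- pmin(as.numeric(e), as.numeric(we))
  sum(pmax(hi - lo, 0))
}

# Clip intervals to a window, dropping empties; start/end come back as
# numeric seconds.
clip_intervals <- function(df, ws, we) {
  ws <- as.numeric(ws)
  we <- as.numeric(we)
  s <- as.numeric(df$start)
  e <- as.numeric(df$end)
  keep <- e > ws & s < we
  df <- df[keep, , drop = FALSE]
  df$start <- pmax(s[keep], ws)
  df$end <- pmin(e[keep], we)
  df
}

# Merge possibly-overlapping intervals into a disjoint union (numeric
# seconds in, numeric out), vectorized.
merge_intervals <- function(start, end) {
  s <- as.numeric(start)
  e <- as.numeric(end)
  if (length(s) == 0L) return(list(start = s, end = e))
  o <- order(s, e)
  s <- s[o]
  e <- e[o]
  n <- length(s)
  run_max_e <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1] > run_max_e[-n]))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  list(start = s[first], end = run_max_e[last])
}

# Rolling mean over a fixed window that tolerates NA, via cumulative sums.
# Returns one value per complete window position; windows with no finite
# sample yield NA.
rolling_mean_na <- function(x, width) {
  n <- length(x)
  if (n < width) return(numeric(0))
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- cumsum(v)
  cc <- cumsum(cnt)
  idx <- width:n
  sums <- cs[idx] - c(0, cs)[idx - width + 1L]
  cnts <- cc[idx] - c(0, cc)[idx - width + 1L]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

# Draw from Normal(mean, sd) truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- rlang::`%||%`
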