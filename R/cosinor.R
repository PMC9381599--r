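#' Cosinor rest-activity rhythm fit
#'
#' Fits the single-component cosinor model
#' \deqn{y(t) = M + A \cos(2\pi t / P - \phi)}
#' to a time-stamped signal (typically per-10-minute PIR activity over one
#' bi-weekly segment) by the usual linearization
#' `y = M + b1 cos(wt) + b2 sin(wt)`, with `amplitude = sqrt(b1^2 + b2^2)`,
#' `acrophase = atan2(b2, b1) * P / (2*pi)` wrapped to `[0, P)` (so the
#' acrophase is the local clock time of the fitted peak), and
#' `r_squared = 1 - RSS/TSS`.
#'
#' @param signal Tibble with columns `time` (POSIXct) and `value`; `NA`
#'   values are dropped. Values are binned to `bin_min`-minute means first.
#' @param period_h Rhythm period in hours (default 24).
#' @param bin_min Bin width in minutes (default 10).
#' @param min_days Minimum number of distinct dates required (default 10,
#'   the same floor used for segment aggregation); fewer yields an all-`NA`
#'   fit.
#' @param tz Timezone anchoring `t = 0` at local midnight.
#' @return Object of class `cosinor_fit` with elements `mesor`,
#'   `amplitude`, `acrophase` (hours), `r_squared`, `n_days`, `n_bins`.
#'   A zero-variance signal yields `amplitude = 0`, `acrophase = NA`,
#'   `r_squared = 0`.
#' @export
#' @examples
#' tt <- as.POSIXct("2021-03-01", tz = "UTC") + seq(0, 14 * 86400 - 600, by = 600)
#' y <- 5 + 2 * cos(2 * pi * (tod_hours_of(tt) - 15) / 24)
#' fit_cosinor(tibble::tibble(time = tt, value = y))
fit_cosinor <- function(signal, period_h = 24, bin_min = 10, min_days = 10, tz = "UTC") {
  na_fit <- new_cosinor_fit(NA_real_, NA_real_, NA_real_, NA_real_, 0L, 0L, period_h)
  if (nrow(signal) == 0L) return(na_fit)
  sig <- signal[!is.na(signal$value), , drop = FALSE]
  if (nrow(sig) == 0L) return(na_fit)
  lt <- lubridate::with_tz(sig$time, tz)
  n_days <- length(unique(as.Date(format(lt, "%Y-%m-%d", tz = tz))))
  if (n_days < min_days) {
    na_fit$n_days <- n_days
    return(na_fit)
  }
  origin <- as.POSIXct(paste(min(as.Date(format(lt, "%Y-%m-%d", tz = tz))), "00:00:00"), tz = tz)
  t_h <- as.numeric(difftime(lt, origin, units = "hours"))
  bin <- floor(t_h * 60 / bin_min + 1e-9) # epsilon guards exact bin edges
  y <- as.numeric(tapply(sig$value, bin, mean))
  t_b <- as.numeric(tapply(t_h, bin, mean)) # mean sample time per bin
  if (sd(y) < 1e-12) {
    return(new_cosinor_fit(mean(y), 0, NA_real_, 0, n_days, length(y), period_h))
  }
  w <- 2 * pi / period_h
  fit <- lm(y ~ cos(w * t_b) + sin(w * t_b))
  b <- coef(fit)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  acro <- (atan2(b[3], b[2]) * period_h / (2 * pi)) %% period_h
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  new_cosinor_fit(
    unname(b[1]), unname(amplitude), unname(acro),
    max(0, min(1, 1 - rss / tss)), n_days, length(y), period_h
  )
}

new_cosinor_fit <- function(mesor, amplitude, acrophase, r_squared, n_days, n_bins, period_h) {
  structure(
    list(
      mesor = mesor, amplitude = amplitude, acrophase = acrophase,
      r_squared = r_squared, n_days = n_days, n_bins = n_bins, period_h = period_h
    ),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.3f, amplitude %.3f, acrophase %.2f h, R^2 %.3f (%d days, %d bins)\n",
    x$mesor, x$amplitude, x$acrophase, x$r_squared, x$n_days, x$n_bins
  ))
  invisible(x)
}

#' @rdname fit_cosinor
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble(
    term = c("mesor", "amplitude", "acrophase"),
    estimate = c(x$mesor, x$amplitude, x$acrophase)
  )
}

#' @rdname fit_cosinor
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_days = x$n_days, n_bins = x$n_bins, period_h = x$period_h)
}

#' Convenience: decimal hour-of-day of POSIXct times
#'
#' @param x POSIXct vector.
#' @return Numeric decimal hours in the vector's own timezone.
#' @export
tod_hours_of <- function(x) tod_hours(x)
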