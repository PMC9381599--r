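#' Band-limited spectral measures of a uniform nightly channel
#'
#' Welch averaged-periodogram analysis of one uniformly sampled channel
#' (heart rate, respiration, in-bed activity). Gaps up to `max_gap_s`
#' seconds are linearly interpolated; longer gaps split the channel into
#' independent segments whose windows are pooled. Each window is demeaned
#' and Hann-tapered. Band powers are reported as fractions of total
#' (non-DC) power, so they lie in `[0, 1]`; `spectral_entropy` is the
#' Shannon entropy of the normalized spectrum divided by `log(n_bins)`,
#' also in `[0, 1]`.
#'
#' @param x Numeric channel on a uniform grid (`NA` = missing).
#' @param fs Sampling frequency in Hz (default 0.25, the bed-sensor grid).
#' @param bands List of `c(low, high)` band edges in Hz; power is assigned
#'   to a band when `low < f <= high`. Defaults to `(0, 0.01]`,
#'   `(0.01, 0.04]`, `(0.04, 0.125]`.
#' @param band_names Names for the band measures.
#' @param nfft Window length in samples (default 256).
#' @param overlap Window overlap fraction (default 0.5).
#' @param max_gap_s Longest gap (seconds) bridged by linear interpolation.
#' @param min_samples Minimum usable samples; fewer yields all-`NA`.
#' @return Named list: one `power_<band>` entry per band,
#'   `spectral_entropy`, and `total_power` (raw Welch power, channel
#'   units squared). A constant channel has `total_power` 0 and `NA` band
#'   fractions/entropy.
#' @export
spectral_measures <- function(x, fs = 0.25,
                              bands = list(c(0, 0.01), c(0.01, 0.04), c(0.04, 0.125)),
                              band_names = c("low", "mid", "high"),
                              nfft = 256, overlap = 0.5,
                              max_gap_s = 60, min_samples = 256) {
  ids <- c(paste0("power_", band_names), "spectral_entropy", "total_power")
  out <- setNames(as.list(rep(NA_real_, length(ids))), ids)
  if (length(x) == 0L) return(out)
  xi <- zoo::na.approx(x, maxgap = as.integer(max_gap_s * fs), na.rm = FALSE)
  segs <- split(xi, cumsum(is.na(xi)))
  segs <- lapply(segs, function(s) s[!is.na(s)])
  segs <- segs[vapply(segs, length, integer(1)) >= nfft]
  if (sum(vapply(segs, length, integer(1))) < min_samples || length(segs) == 0L) {
    return(out)
  }
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1))) # Hann
  step <- max(1L, as.integer(nfft * (1 - overlap)))
  psd_sum <- numeric(nfft %/% 2)
  n_win <- 0L
  for (s in segs) {
    starts <- seq(1L, length(s) - nfft + 1L, by = step)
    for (st in starts) {
      seg <- s[st:(st + nfft - 1L)]
      seg <- (seg - mean(seg)) * win
      sp <- Mod(fft(seg))^2
      psd_sum <- psd_sum + sp[2:(nfft %/% 2 + 1L)]
      n_win <- n_win + 1L
    }
  }
  psd <- psd_sum / (n_win * sum(win^2) * fs)
  freqs <- (1:(nfft %/% 2)) * fs / nfft
  total <- sum(psd)
  out$total_power <- total
  if (total < 1e-20) return(out)
  p <- psd / total
  for (i in seq_along(bands)) {
    sel <- freqs > bands[[i]][1] & freqs <= bands[[i]][2]
    out[[paste0("power_", band_names[i])]] <- sum(p[sel])
  }
  pp <- p[p > 0]
  out$spectral_entropy <- -sum(pp * log(pp)) / log(length(p))
  out
}
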