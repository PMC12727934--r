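#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero
#' phase).  Forward-backward application doubles the effective order,
#' giving attenuation far beyond 20 dB one octave outside the band, and
#' removes phase distortion, which matters for the symbolic complexity
#' analysis downstream.
#'
#' The first and last second contain filter transients; the returned vector
#' carries attribute `edge_s = 1` so downstream epoching can discard them.
#'
#' @param x Numeric signal (vector).
#' @param fs Sampling rate in Hz.
#' @param band A [band_definition()] with `hi < fs / 2`.
#' @return Filtered signal, same length as `x`, with attribute `edge_s`.
#' @export
bandpass <- function(x, fs, band) {
  stopifnot(inherits(band, "band_definition"), is.numeric(x))
  if (band$hi >= fs / 2) {
    stop("invalid band: upper edge ", band$hi,
         " Hz is not below Nyquist (", fs / 2, " Hz)", call. = FALSE)
  }
  if (length(x) < 10 * fs / band$lo) {
    stop("signal too short for band ", band$name, ": need at least ",
         ceiling(10 * fs / band$lo), " samples, got ", length(x),
         call. = FALSE)
  }
  bf <- signal::butter(4, c(band$lo, band$hi) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  attr(y, "edge_s") <- 1
  y
}

#' Welch averaged-periodogram spectral estimate
#'
#' Mean-detrended, Hann-tapered modified periodograms averaged over
#' 50%-overlapping windows (defaults: 2 s windows).  One-sided density
#' scaling: the integral of the PSD over `[0, fs/2]` approximates the signal
#' variance (Parseval).
#'
#' @param x Numeric signal (vector).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return A `spectral_estimate`: list with `freqs` (Hz), `psd`
#'   (units^2/Hz), `fs` and `method_params`.
#' @export
estimate_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  stopifnot(is.numeric(x))
  nper <- round(window_s * fs)
  if (length(x) < 2 * nper) {
    stop("signal too short: need at least 2 windows (",
         2 * nper, " samples), got ", length(x), call. = FALSE)
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann taper
  scale <- fs * sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    acc <- acc + P
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  structure(
    list(freqs = seq(0, by = fs / nper, length.out = nfreq), psd = psd,
         fs = fs,
         method_params = list(window_s = window_s, overlap = overlap,
                              taper = "hann", n_windows = length(starts))),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins, 0-%g Hz, %d x %gs Hann windows\n",
              length(x$freqs), max(x$freqs), x$method_params$n_windows,
              x$method_params$window_s))
  invisible(x)
}

#' Relative power of a band
#'
#' Fraction of spectral power in `(band$lo, band$hi]` relative to the power
#' in `total_range` (default the 1-20 Hz union of the four canonical
#' analysis bands, so canonical-band relative powers sum to 1).  Frequency
#' bins are assigned by the half-open convention `(lo, hi]`, making adjacent
#' bands disjoint and exhaustive over their union.
#'
#' @param est A [estimate_psd()] result.
#' @param band A [band_definition()], contained in `total_range`.
#' @param total_range Length-2 numeric, the reference range in Hz.
#' @return Relative power in `[0, 1]`.
#' @export
relative_power <- function(est, band, total_range = c(1, 20)) {
  stopifnot(inherits(est, "spectral_estimate"),
            inherits(band, "band_definition"))
  if (band$lo < total_range[1] || band$hi > total_range[2]) {
    stop("band (", band$lo, ", ", band$hi, "] not contained in total_range",
         call. = FALSE)
  }
  f <- est$freqs
  in_band <- f > band$lo & f <= band$hi
  in_total <- f > total_range[1] & f <= total_range[2]
  den <- sum(est$psd[in_total])
  if (den <= 0) {
    stop("undefined relative power: zero total power in reference range",
         call. = FALSE)
  }
  sum(est$psd[in_band]) / den
}

# Split sample indices 1..n into non-overlapping epochs of epoch_len samples,
# discarding edge_s seconds at both ends first.  Returns list of index vectors.
epoch_indices <- function(n, fs, epoch_s, edge_s = 0) {
  drop <- round(edge_s * fs)
  lo <- drop + 1L
  hi <- n - drop
  epoch_len <- round(epoch_s * fs)
  if (hi - lo + 1L < epoch_len) {
    stop("signal too short for a single ", epoch_s, " s epoch after edge ",
         "discard", call. = FALSE)
  }
  starts <- seq(lo, hi - epoch_len + 1L, by = epoch_len)
  lapply(starts, function(s) s:(s + epoch_len - 1L))
}

#' Per-subject, per-band relative power table
#'
#' Each record is split into non-overlapping epochs; relative power is
#' computed per epoch and band from a Welch spectrum of the raw (unfiltered)
#' epoch and averaged across epochs, then across channels.
#'
#' @param cohort List of [eeg_record()]s.
#' @param bands Band set (default [canonical_bands()]).
#' @param total_range Reference range in Hz for the denominator.
#' @param epoch_s Epoch length in seconds (default 4).
#' @param window_s Welch window length within each epoch (default 2 s).
#' @return A tibble with columns `subject_id`, `group`, `band`, `value`
#'   (fraction in `[0, 1]`) and attribute `metric_name = "RP"`.
#' @export
rp_table <- function(cohort, bands = canonical_bands(),
                     total_range = c(1, 20), epoch_s = 4, window_s = 2) {
  bands <- as_band_list(bands)
  rows <- lapply(cohort, function(rec) {
    vals <- tryCatch({
      per_channel <- apply(rec$samples, 2, function(ch) {
        idx <- epoch_indices(length(ch), rec$fs, epoch_s)
        per_epoch <- vapply(idx, function(ii) {
          est <- estimate_psd(ch[ii], rec$fs, window_s = window_s)
          vapply(bands, relative_power, numeric(1), est = est,
                 total_range = total_range)
        }, numeric(length(bands)))
        if (is.null(dim(per_epoch))) per_epoch <- matrix(per_epoch, nrow = 1)
        rowMeans(per_epoch)
      })
      if (is.null(dim(per_channel))) per_channel <- matrix(per_channel, nrow = 1)
      rowMeans(per_channel)
    }, error = function(e) {
      stop("subject ", rec$subject_id, ": ", conditionMessage(e),
           call. = FALSE)
    })
    tibble::tibble(subject_id = rec$subject_id, group = rec$group,
                   band = names(bands), value = as.numeric(vals))
  })
  out <- do.call(rbind, rows)
  attr(out, "metric_name") <- "RP"
  out
}
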