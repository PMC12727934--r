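#' Symbolize a real-valued epoch
#'
#' Maps an epoch to an integer symbol sequence over the alphabet
#' `0 .. alphabet_size - 1` by amplitude quantile binning.  The default
#' binary rule assigns 1 where a sample exceeds the epoch median and 0
#' otherwise — the usual convention for EEG Lempel-Ziv analysis, robust to
#' amplitude drift and rescaling.  For `alphabet_size > 2` the cut points
#' are the corresponding sample quantiles.
#'
#' A constant epoch yields an all-zero sequence with attribute
#' `degenerate = TRUE`.
#'
#' @param epoch Numeric vector, length >= 2, finite values.
#' @param alphabet_size Number of symbols, >= 2 (default 2).
#' @return Integer vector of symbols with attribute `degenerate`.
#' @export
symbolize <- function(epoch, alphabet_size = 2) {
  stopifnot(is.numeric(epoch), alphabet_size >= 2)
  if (length(epoch) < 2) stop("epoch too short to symbolize", call. = FALSE)
  if (any(!is.finite(epoch))) stop("epoch contains non-finite values",
                                   call. = FALSE)
  degenerate <- FALSE
  if (max(epoch) == min(epoch)) {
    s <- integer(length(epoch))
    degenerate <- TRUE
  } else if (alphabet_size == 2) {
    s <- as.integer(epoch > stats::median(epoch))
  } else {
    cuts <- stats::quantile(epoch, probs = seq_len(alphabet_size - 1) /
                              alphabet_size, names = FALSE)
    s <- as.integer(findInterval(epoch, cuts, left.open = TRUE))
  }
  attr(s, "degenerate") <- degenerate
  s
}

#' Lempel-Ziv 1976 phrase count c(n)
#'
#' Number of phrases in the exhaustive-history parse of a symbol sequence:
#' scanning left to right, each phrase is extended while it can be copied
#' from somewhere in the sequence seen so far, and closed at the first
#' symbol that makes it novel.  More novel phrases mean a less predictable
#' sequence.
#'
#' @param s Integer vector of symbols (or a character string of single-digit
#'   symbols, e.g. `"0101"`).
#' @return Integer phrase count `c(n) >= 1`.
#' @export
lzc_raw <- function(s) {
  s <- as_symbols(s)
  if (length(s) == 0) stop("empty symbol sequence", call. = FALSE)
  .lzc_raw_cpp(s)
}

as_symbols <- function(s) {
  if (is.character(s)) {
    stopifnot(length(s) == 1L)
    s <- as.integer(strsplit(s, "")[[1]])
  }
  as.integer(s)
}

#' Normalized Lempel-Ziv complexity
#'
#' `c(n) * log_alpha(n) / n`, the phrase count normalized by the asymptotic
#' phrase count `n / log_alpha(n)` of an i.i.d. uniform random sequence over
#' an alphabet of size `alpha`.  Values near 1 indicate maximal complexity;
#' periodic sequences tend to 0 as `n` grows.
#'
#' @param s Symbol sequence as in [lzc_raw()], length >= 10.
#' @param alphabet_size Alphabet cardinality (default 2).
#' @return Normalized complexity, typically in `(0, ~1.2]`.
#' @export
lzc_normalized <- function(s, alphabet_size = 2) {
  s <- as_symbols(s)
  n <- length(s)
  if (n < 10) stop("sequence too short for normalized LZC: n = ", n,
                   call. = FALSE)
  .lzc_raw_cpp(s) * (log(n) / log(alphabet_size)) / n
}

#' Parameters for sample entropy
#'
#' @param m Embedding dimension, >= 1 (default 2).
#' @param r Tolerance as a fraction of the epoch standard deviation
#'   (default 0.2).
#' @return A `sampen_params` list.  Distance is Chebyshev (max coordinate
#'   difference); self-matches are excluded.
#' @export
sampen_params <- function(m = 2, r = 0.2) {
  stopifnot(m >= 1, r > 0)
  structure(list(m = as.integer(m), r = r, distance = "chebyshev"),
            class = "sampen_params")
}

#' Parameters for Lempel-Ziv complexity
#'
#' @param alphabet_size Alphabet cardinality for [symbolize()] and the
#'   normalization log base (default 2, median symbolization).
#' @return An `lzc_params` list.
#' @export
lzc_params <- function(alphabet_size = 2) {
  stopifnot(alphabet_size >= 2)
  structure(list(symbolization = "quantile", alphabet_size =
                   as.integer(alphabet_size)), class = "lzc_params")
}

#' Sample entropy of an epoch
#'
#' `-ln(A / B)` where `B` counts pairs of `m`-length templates within
#' Chebyshev distance `r` of each other and `A` the pairs still within `r`
#' when extended to length `m + 1`; self-matches are excluded.  The
#' tolerance `r` is supplied as a fraction of the epoch standard deviation
#' and converted to absolute units internally, making the metric invariant
#' to positive affine rescaling.  A constant epoch returns 0 (every template
#' matches at both lengths).  If no template pairs match (`A = 0` or
#' `B = 0`) the entropy is undefined and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param epoch Numeric vector, length >= 100.
#' @param params A [sampen_params()].
#' @return Non-negative entropy, or flagged `NA` when undefined.
#' @export
sampen <- function(epoch, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"), is.numeric(epoch))
  if (length(epoch) < 100) {
    stop("epoch too short for sample entropy: N = ", length(epoch),
         call. = FALSE)
  }
  r_abs <- params$r * stats::sd(epoch)
  cts <- .sampen_counts_cpp(as.numeric(epoch), params$m, r_abs)
  if (cts$B == 0 || cts$A == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(cts$A / cts$B)
}

# Epoch length for a band: at least epoch_s, lengthened so each epoch holds
# min_cycles cycles of the band's low edge (delta at the 8-cycle default
# gets 8 s epochs; theta/alpha/beta keep 4 s).
band_epoch_s <- function(band, epoch_s, min_cycles = 8) {
  max(epoch_s, min_cycles / band$lo)
}

#' Per-subject, per-band complexity table (LZC or SampEn)
#'
#' For each subject, channel and band: zero-phase band-pass filter
#' ([bandpass()]), discard 1 s of filter transient at each end, split into
#' non-overlapping epochs, compute the metric per epoch and average.  Delta
#' epochs are lengthened so every epoch holds at least `min_cycles` cycles
#' of the band's low edge.  Epochs with undefined sample entropy are
#' excluded from the average; their count is recorded in attribute
#' `n_excluded`.
#'
#' @param cohort List of [eeg_record()]s.
#' @param bands Band set (default [canonical_bands()]).
#' @param metric `"LZC"` or `"SampEn"`.
#' @param params [lzc_params()] or [sampen_params()] matching `metric`.
#' @param epoch_s Baseline epoch length in seconds (default 4).
#' @param min_cycles Minimum low-edge cycles per epoch (default 8).
#' @return A tibble with columns `subject_id`, `group`, `band`, `value`,
#'   attributes `metric_name` and `n_excluded`.
#' @export
complexity_table <- function(cohort, bands = canonical_bands(),
                             metric = c("LZC", "SampEn"), params = NULL,
                             epoch_s = 4, min_cycles = 8) {
  metric <- match.arg(metric)
  lzc <- se <- NULL
  if (metric == "LZC") lzc <- params %||% lzc_params()
  if (metric == "SampEn") se <- params %||% sampen_params()
  complexity_tables(cohort, bands = bands, lzc = lzc, se = se,
                    epoch_s = epoch_s, min_cycles = min_cycles)[[metric]]
}

# Compute LZC and/or SampEn tables in one band-filtering pass over the
# cohort (filtering dominates runtime, so the two metrics share it).
# Pass NULL params to skip a metric.
complexity_tables <- function(cohort, bands = canonical_bands(),
                              lzc = lzc_params(), se = sampen_params(),
                              epoch_s = 4, min_cycles = 8) {
  bands <- as_band_list(bands)
  metrics <- c(if (!is.null(lzc)) "LZC", if (!is.null(se)) "SampEn")
  stopifnot(length(metrics) > 0)
  n_excluded <- stats::setNames(integer(length(metrics)), metrics)
  rows <- lapply(cohort, function(rec) {
    per_band <- lapply(bands, function(band) {
      ep_s <- band_epoch_s(band, epoch_s, min_cycles)
      per_channel <- lapply(seq_len(ncol(rec$samples)), function(ci) {
        y <- tryCatch(bandpass(rec$samples[, ci], rec$fs, band),
                      error = function(e) {
                        stop("subject ", rec$subject_id, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
        idx <- epoch_indices(length(y), rec$fs, ep_s,
                             edge_s = attr(y, "edge_s") %||% 0)
        vapply(metrics, function(metric) {
          per_epoch <- vapply(idx, function(ii) {
            ep <- y[ii]
            if (metric == "LZC") {
              lzc_normalized(symbolize(ep, lzc$alphabet_size),
                             lzc$alphabet_size)
            } else {
              sampen(ep, se)
            }
          }, numeric(1))
          bad <- is.na(per_epoch)
          n_excluded[metric] <<- n_excluded[metric] + sum(bad)
          if (all(bad)) NA_real_ else mean(per_epoch[!bad])
        }, numeric(1))
      })
      rowMeans(do.call(cbind, per_channel))   # average over channels
    })
    vals <- do.call(rbind, per_band)          # bands x metrics
    lapply(stats::setNames(metrics, metrics), function(metric) {
      tibble::tibble(subject_id = rec$subject_id, group = rec$group,
                     band = names(bands), value = as.numeric(vals[, metric]))
    })
  })
  out <- lapply(stats::setNames(metrics, metrics), function(metric) {
    tab <- do.call(rbind, lapply(rows, `[[`, metric))
    attr(tab, "metric_name") <- metric
    attr(tab, "n_excluded") <- unname(n_excluded[metric])
    tab
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
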