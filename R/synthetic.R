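#' EEG record container
#'
#' Holds one subject's signal as a time-by-channel numeric matrix together
#' with its sampling rate, channel labels, group label and subject id.
#'
#' @param samples Numeric vector or time-by-channel matrix, no missing
#'   values, at least 1000 samples.
#' @param fs Sampling rate in Hz, > 0.
#' @param channels Character vector of channel labels (default `"ch1"`, ...).
#' @param group Group label.
#' @param subject_id Subject identifier.
#' @return An `eeg_record` object.
#' @export
eeg_record <- function(samples, fs, channels = NULL, group = NA_character_,
                       subject_id = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples contain missing or non-finite values", call. = FALSE)
  }
  if (nrow(samples) < 1000L) {
    stop("record too short: need at least 1000 samples, got ", nrow(samples),
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  stopifnot(length(channels) == ncol(samples))
  colnames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         group = group, subject_id = subject_id),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s [%s]: %d samples x %d channel(s) @ %g Hz\n",
              x$subject_id, x$group, nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' Simulation profile for one experimental group
#'
#' Parameters of the generative signal model for one group: per-band
#' oscillation amplitude weights, the fraction of total oscillatory variance
#' contributed by a 1/f-shaped broadband component, and the standard
#' deviation of additive white measurement noise.
#'
#' @param name Group label (e.g. `"Control"`, `"MCAO"`).
#' @param band_weights Named non-negative numeric vector of amplitude weights,
#'   one per band; at least one must be positive unless `broadband_frac == 1`.
#' @param broadband_frac Fraction in `[0, 1]` of signal variance contributed
#'   by the 1/f broadband component.
#' @param noise_sd White measurement-noise standard deviation (amplitude
#'   units), >= 0.
#' @param osc_bandwidth Fraction in `(0, 1]` of each band's width occupied
#'   by its oscillation carrier, centered mid-band (default 1, the full
#'   band).  Narrow carriers produce more rhythmic, regular in-band dynamics
#'   and hence lower Lempel-Ziv complexity and sample entropy without
#'   changing the band's power; this is the model's regularity axis,
#'   mimicking the pathologically synchronized oscillations of the ischemic
#'   brain.
#' @return A `group_profile` object.
#' @export
group_profile <- function(name, band_weights, broadband_frac, noise_sd,
                          osc_bandwidth = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(band_weights) || is.null(names(band_weights)) ||
      any(band_weights < 0)) {
    stop("band_weights must be a named non-negative numeric vector",
         call. = FALSE)
  }
  if (!is.numeric(broadband_frac) || broadband_frac < 0 || broadband_frac > 1) {
    stop("broadband_frac must lie in [0, 1]", call. = FALSE)
  }
  if (all(band_weights == 0) && broadband_frac < 1) {
    stop("at least one band weight must be positive when broadband_frac < 1",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(osc_bandwidth) || osc_bandwidth <= 0 || osc_bandwidth > 1) {
    stop("osc_bandwidth must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, band_weights = band_weights,
         broadband_frac = broadband_frac, noise_sd = noise_sd,
         osc_bandwidth = osc_bandwidth),
    class = "group_profile"
  )
}

#' Default group profiles for the four-arm stroke cohort
#'
#' Calibrated constants for the Control, MCAO (ischemic stroke),
#' MCAO + tDCS and MCAO + Sham groups.  Relative to Control, the MCAO
#' profile doubles the delta weight and shrinks the theta/alpha/beta
#' weights (elevated delta relative power at the expense of the faster
#' bands), cuts the broadband fraction and measurement noise, and narrows
#' the oscillation carriers to the low-anchored quarter of each band — the
#' slow, regular, overly synchronized rhythms of the ischemic brain, which
#' depress Lempel-Ziv complexity and sample entropy in every band.  The
#' tDCS profile lies `recovery` of the way back toward Control on every
#' parameter (partial restoration, default 75%); Sham is identical to MCAO,
#' differing only through random seeds.
#'
#' @param recovery Fractional recovery of the tDCS group toward Control.
#' @return Named list of four [group_profile()] objects.
#' @export
default_profiles <- function(recovery = 0.75) {
  w_control <- c(delta = 1.0, theta = 1.0, alpha = 1.2, beta = 0.8)
  w_mcao    <- c(delta = 2.0, theta = 0.65, alpha = 0.6, beta = 0.55)
  control <- list(w = w_control, bb = 0.50, noise = 0.30, q = 1)
  mcao    <- list(w = w_mcao, bb = 0.05, noise = 0.05, q = 0.25)
  tdcs <- Map(function(m, c) m + recovery * (c - m), mcao, control)
  list(
    Control   = group_profile("Control", control$w, control$bb,
                              control$noise, control$q),
    MCAO      = group_profile("MCAO", mcao$w, mcao$bb, mcao$noise, mcao$q),
    MCAO_tDCS = group_profile("MCAO_tDCS", tdcs$w, tdcs$bb, tdcs$noise,
                              tdcs$q),
    MCAO_Sham = group_profile("MCAO_Sham", mcao$w, mcao$bb, mcao$noise,
                              mcao$q)
  )
}

#' Cohort simulation configuration
#'
#' @param n_subjects_per_group Subjects per group.
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz; must be at least twice the highest band
#'   edge of `bands`.
#' @param master_seed Integer master seed; per-subject seeds are derived
#'   deterministically from it (see [subject_seed()]).
#' @param profiles Named list of [group_profile()] objects with distinct
#'   group names.
#' @param bands Band set the profiles' weights refer to.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_subjects_per_group = 10, duration_s = 60, fs = 250,
                       master_seed = 42, profiles = default_profiles(),
                       bands = canonical_bands()) {
  bands <- as_band_list(bands)
  hi_edge <- max(vapply(bands, `[[`, numeric(1), "hi"))
  if (fs < 2 * hi_edge) {
    stop("fs must be >= 2 x highest band edge (", 2 * hi_edge, " Hz)",
         call. = FALSE)
  }
  if (duration_s * fs < 1000) {
    stop("duration_s x fs must be at least 1000 samples", call. = FALSE)
  }
  nm <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate group names in profiles: ",
         paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         duration_s = duration_s, fs = fs,
         master_seed = as.integer(master_seed),
         profiles = stats::setNames(profiles, nm), bands = bands),
    class = "sim_config"
  )
}

#' Per-subject seed derivation
#'
#' Deterministic, platform-independent seed for subject `subject_index` of
#' group `group_index`:
#' `(master_seed * 69069 + 10007 * group_index + subject_index) mod (2^31 - 1)`.
#' The multiplier decorrelates cohorts generated from consecutive master
#' seeds, so Monte-Carlo replicates over master seeds are effectively
#' independent.
#'
#' @param master_seed,group_index,subject_index Integers (indices 1-based).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(master_seed, group_index, subject_index) {
  as.integer((as.numeric(master_seed) * 69069 +
                10007 * group_index + subject_index) %% 2147483647)
}

#' Band-limited unit-variance oscillation
#'
#' Gaussian white noise zero-phase band-pass filtered to the band and
#' rescaled to sample variance 1.  Deterministic given `seed`.
#'
#' @param band A [band_definition()].
#' @param n Number of samples.
#' @param fs Sampling rate in Hz; the band must lie below `fs / 2`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` with sample variance 1.
#' @export
make_band_oscillation <- function(band, n, fs, seed) {
  stopifnot(inherits(band, "band_definition"))
  if (band$hi >= fs / 2) {
    stop("invalid band: upper edge ", band$hi,
         " Hz is not below Nyquist (", fs / 2, " Hz)", call. = FALSE)
  }
  x <- withr::with_seed(seed, stats::rnorm(n))
  y <- bandpass(x, fs, band)
  y <- as.numeric(y)
  as.numeric(y / stats::sd(y))
}

#' 1/f-spectrum broadband noise
#'
#' Unit-variance noise with power spectral density proportional to 1/f
#' between `f_min` and Nyquist (zero below `f_min`, avoiding unbounded
#' low-frequency drift), synthesized by spectral shaping of seeded Gaussian
#' white noise.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param f_min Low-frequency cutoff in Hz (default 0.5).
#' @return Numeric vector of length `n` with sample variance 1.
#' @export
one_over_f_noise <- function(n, fs, seed, f_min = 0.5) {
  w <- withr::with_seed(seed, stats::rnorm(n))
  X <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)               # frequency of each FFT bin (two-sided)
  amp <- ifelse(f >= f_min, 1 / sqrt(f), 0)
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  as.numeric(y / stats::sd(y))
}

#' Generate one synthetic subject
#'
#' Signal model: sum over bands of `band_weights[b]` times a unit-variance
#' band-limited oscillation, plus a 1/f broadband component scaled so its
#' variance fraction of the noise-free signal equals `broadband_frac`, plus
#' white noise of standard deviation `noise_sd`.  Component seeds are fixed
#' offsets of `seed`, so the record is fully reproducible.
#'
#' @param profile A [group_profile()].
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param bands Band set matching `names(profile$band_weights)`.
#' @param subject_id Subject identifier (default derived from group and seed).
#' @return An [eeg_record()].
#' @export
generate_subject <- function(profile, duration_s, fs, seed,
                             bands = canonical_bands(), subject_id = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  bands <- as_band_list(bands)
  w <- profile$band_weights
  missing_bands <- setdiff(names(w), names(bands))
  if (length(missing_bands)) {
    stop("band_weights name unknown bands: ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  n <- round(duration_s * fs)
  q <- profile$osc_bandwidth %||% 1
  osc <- numeric(n)
  for (b in seq_along(w)) {
    if (w[[b]] == 0) next
    band <- bands[[names(w)[b]]]
    if (q < 1) {
      # Narrow the carrier to the low-anchored fraction q of the band:
      # power stays in-band (relative power unchanged) while the dynamics
      # slow and regularize, lowering complexity within the band.
      band <- band_definition(band$name, band$lo,
                              band$lo + q * (band$hi - band$lo))
    }
    sb <- (seed + 1009 * b) %% 2147483647
    osc <- osc + w[[b]] * make_band_oscillation(band, n, fs, sb)
  }
  bb <- one_over_f_noise(n, fs, (seed + 104729) %% 2147483647)
  f <- profile$broadband_frac
  v_osc <- stats::var(osc)
  if (f >= 1 || v_osc == 0) {
    x <- if (f > 0) bb else osc
  } else if (f == 0) {
    x <- osc
  } else {
    g <- sqrt(f / (1 - f) * v_osc)   # bb already unit variance
    x <- osc + g * bb
  }
  if (profile$noise_sd > 0) {
    x <- x + profile$noise_sd *
      withr::with_seed((seed + 224737) %% 2147483647, stats::rnorm(n))
  }
  if (is.null(subject_id)) subject_id <- sprintf("%s_s%d", profile$name, seed)
  eeg_record(x, fs, group = profile$name, subject_id = subject_id)
}

#' Generate a full synthetic cohort
#'
#' One record per subject per group, with per-subject seeds derived from the
#' master seed via [subject_seed()].  Two runs with the same configuration
#' produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List of [eeg_record()] objects (class `eeg_cohort`), ordered by
#'   group then subject.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  records <- list()
  for (g in seq_along(config$profiles)) {
    profile <- config$profiles[[g]]
    for (i in seq_len(config$n_subjects_per_group)) {
      sd_gi <- subject_seed(config$master_seed, g, i)
      rec <- generate_subject(profile, config$duration_s, config$fs, sd_gi,
                              bands = config$bands,
                              subject_id = sprintf("%s_%02d", profile$name, i))
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(records, class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<eeg_cohort> %d records: %s\n", length(x),
              paste(sprintf("%s (n=%d)", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to CSV files plus a manifest
#'
#' One CSV per subject (header row of channel labels, one row per sample)
#' and a `manifest.tsv` with columns subject_id, group, fs, file.
#'
#' @param cohort An `eeg_cohort` or list of [eeg_record()]s.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    file <- paste0(rec$subject_id, ".csv")
    utils::write.csv(as.data.frame(rec$samples),
                     file.path(dir, file), row.names = FALSE)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               fs = rec$fs, file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
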