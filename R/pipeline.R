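#' Load a cohort from a manifest directory
#'
#' Reads `manifest.tsv` (columns `subject_id`, `group`, `fs`, `file`) from
#' `dir` and loads each referenced file.  CSV files are numeric tables with
#' a header row of channel labels (one row per sample); `.edf` files are
#' read with [read_edf()], in which case the manifest `fs` must match the
#' file header.
#'
#' @param dir Directory containing `manifest.tsv` and the data files.
#' @param channels Optional channel labels to select (EDF and CSV).
#' @return An `eeg_cohort` list of [eeg_record()]s.
#' @export
load_cohort <- function(dir, channels = NULL) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.tsv in ", dir, call. = FALSE)
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "fs", "file")
  if (!all(needed %in% names(manifest))) {
    stop("manifest.tsv must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    path <- file.path(dir, row$file)
    if (!file.exists(path)) {
      stop("manifest references missing file: ", row$file, call. = FALSE)
    }
    if (grepl("\\.edf$", row$file, ignore.case = TRUE)) {
      edf <- read_edf(path, channels = channels)
      if (abs(edf$fs - row$fs) > 1e-6) {
        stop("manifest fs (", row$fs, ") disagrees with EDF header fs (",
             edf$fs, ") for ", row$file, call. = FALSE)
      }
      samples <- edf$samples
      labels <- edf$channels
    } else {
      tab <- utils::read.csv(path)
      if (!all(vapply(tab, is.numeric, logical(1)))) {
        stop("non-numeric values in ", row$file, call. = FALSE)
      }
      if (!is.null(channels)) {
        missing_ch <- setdiff(channels, names(tab))
        if (length(missing_ch)) {
          stop("channel label(s) not in ", row$file, ": ",
               paste(missing_ch, collapse = ", "), call. = FALSE)
        }
        tab <- tab[, channels, drop = FALSE]
      }
      samples <- as.matrix(tab)
      labels <- colnames(samples)
    }
    if (row$fs <= 40) {
      stop("sampling rate ", row$fs, " Hz too low for the 13-20 Hz beta ",
           "band (need > 40 Hz): ", row$file, call. = FALSE)
    }
    eeg_record(samples, row$fs, channels = labels, group = row$group,
               subject_id = row$subject_id)
  })
  structure(records, class = "eeg_cohort")
}

#' Run the full analysis pipeline
#'
#' Computes the requested metric tables (relative power, Lempel-Ziv
#' complexity, sample entropy) for a cohort, compares groups per band, and
#' optionally writes one TSV per metric table, one combined comparison TSV,
#' and a JSON run report with configuration hash and warnings.
#'
#' @param cohort An `eeg_cohort` (e.g. from [generate_cohort()] or
#'   [load_cohort()]).
#' @param metrics Subset of `c("RP", "LZC", "SampEn")`.
#' @param bands Band set (default [canonical_bands()]).
#' @param total_range Relative-power reference range in Hz.
#' @param epoch_s Baseline epoch length in seconds.
#' @param lzc LZC parameters ([lzc_params()]).
#' @param se Sample-entropy parameters ([sampen_params()]).
#' @param group_order Group labels for the comparison.
#' @param out_dir Output directory; `NULL` for in-memory results only.
#' @return List with `tables` (named list of metric tibbles), `comparisons`
#'   (named list of [compare_groups()] tibbles), and `report`.
#' @export
run_pipeline <- function(cohort, metrics = c("RP", "LZC", "SampEn"),
                         bands = canonical_bands(), total_range = c(1, 20),
                         epoch_s = 4, lzc = lzc_params(),
                         se = sampen_params(),
                         group_order = c("Control", "MCAO", "MCAO_tDCS",
                                         "MCAO_Sham"),
                         out_dir = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  bands <- as_band_list(bands)
  tables <- list()
  comparisons <- list()
  warnings <- character(0)
  if (any(c("LZC", "SampEn") %in% metrics)) {
    cx <- complexity_tables(
      cohort, bands = bands,
      lzc = if ("LZC" %in% metrics) lzc else NULL,
      se = if ("SampEn" %in% metrics) se else NULL,
      epoch_s = epoch_s
    )
  }
  for (metric in metrics) {
    tab <- switch(metric,
      RP = rp_table(cohort, bands = bands, total_range = total_range,
                    epoch_s = epoch_s),
      LZC = cx$LZC,
      SampEn = cx$SampEn
    )
    nex <- attr(tab, "n_excluded")
    if (!is.null(nex) && nex > 0) {
      warnings <- c(warnings,
                    sprintf("%s: %d undefined epoch(s) excluded", metric, nex))
    }
    tables[[metric]] <- tab
    comparisons[[metric]] <- compare_groups(tab, group_order = group_order)
  }
  config <- list(metrics = metrics,
                 bands = lapply(bands, unclass),
                 total_range = total_range, epoch_s = epoch_s,
                 lzc = unclass(lzc), sampen = unclass(se),
                 group_order = group_order)
  report <- list(
    tool = "strokeeg",
    version = as.character(utils::packageVersion("strokeeg")),
    config = config,
    config_hash = rlang::hash(config),
    n_subjects = length(cohort),
    warnings = warnings
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- list()
    for (metric in metrics) {
      path <- file.path(out_dir, paste0(tolower(metric), ".tsv"))
      utils::write.table(tables[[metric]], path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files[[paste0(metric, "_table")]] <- path
    }
    comp_all <- do.call(rbind, comparisons)
    comp_path <- file.path(out_dir, "comparison.tsv")
    utils::write.table(comp_all, comp_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files$comparison <- comp_path
    report$files <- files
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(tables = tables, comparisons = comparisons, report = report)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [sim_config()] field for field; `profiles` is a list of
#' maps with `name`, `band_weights`, `broadband_frac`, `noise_sd`.  Missing
#' fields take the package defaults.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- if (is.null(y$profiles)) default_profiles() else {
    lapply(y$profiles, function(p) {
      group_profile(p$name, unlist(p$band_weights), p$broadband_frac,
                    p$noise_sd, p$osc_bandwidth %||% 1)
    })
  }
  sim_config(
    n_subjects_per_group = y$n_subjects_per_group %||% 10,
    duration_s = y$duration_s %||% 60,
    fs = y$fs %||% 250,
    master_seed = y$master_seed %||% 42,
    profiles = profiles
  )
}
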