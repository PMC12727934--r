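#' Group-by-band mean matrix of a metric table
#'
#' @param table Metric table (`subject_id`, `group`, `band`, `value`).
#' @return Matrix of group means, groups x bands (canonical band order).
#' @export
group_band_means <- function(table) {
  bands <- intersect(canonical_band_order(), unique(table$band))
  bands <- c(bands, setdiff(unique(table$band), bands))
  groups <- unique(table$group)
  out <- matrix(NA_real_, length(groups), length(bands),
                dimnames = list(groups, bands))
  for (g in groups) for (b in bands) {
    out[g, b] <- mean(table$value[table$group == g & table$band == b])
  }
  out
}

# Per-seed direction checks on precomputed metric tables.
direction_checks_one_seed <- function(rp, lzc, se) {
  m_rp <- group_band_means(rp)
  m_lz <- group_band_means(lzc)
  m_se <- group_band_means(se)
  low_bands <- c("theta", "alpha", "beta")
  rec <- function(m, bands) {
    all(m["MCAO", bands] < m["Control", bands]) &&
      all(m["MCAO_tDCS", bands] > m["MCAO", bands])
  }
  sham_close <- function(tab) {
    vapply(colnames(group_band_means(tab)), function(b) {
      mc <- tab$value[tab$group == "MCAO" & tab$band == b]
      sh <- tab$value[tab$group == "MCAO_Sham" & tab$band == b]
      # pooled within-group SD: stabler than a single group's n=10 SD
      abs(mean(sh) - mean(mc)) <=
        sqrt((stats::var(mc) + stats::var(sh)) / 2)
    }, logical(1))
  }
  sham_ns <- function(tab) {
    vapply(unique(tab$band), function(b) {
      mc <- tab$value[tab$group == "MCAO" & tab$band == b]
      sh <- tab$value[tab$group == "MCAO_Sham" & tab$band == b]
      one_way_anova(list(MCAO = mc, Sham = sh))$p > 0.05
    }, logical(1))
  }
  delta_anova <- one_way_anova(split(
    rp$value[rp$band == "delta"], rp$group[rp$band == "delta"]))
  list(
    rp_delta_mcao_gt_control = m_rp["MCAO", "delta"] > m_rp["Control", "delta"],
    rp_delta_tdcs_lt_mcao = m_rp["MCAO_tDCS", "delta"] < m_rp["MCAO", "delta"],
    rp_low_bands_recovery = rec(m_rp, low_bands),
    lzc_recovery_all_bands = rec(m_lz, colnames(m_lz)),
    sampen_recovery_all_bands = rec(m_se, colnames(m_se)),
    delta_rp_anova_sig = delta_anova$p < 0.05,
    delta_rp_eta_squared = delta_anova$eta_squared,
    sham_within_sd = c(RP = sham_close(rp), LZC = sham_close(lzc),
                       SampEn = sham_close(se)),
    sham_ns = c(RP = sham_ns(rp), LZC = sham_ns(lzc), SampEn = sham_ns(se))
  )
}

#' Monte-Carlo direction-of-effect recovery over master seeds
#'
#' For each master seed, generates the default four-group cohort, runs the
#' full metric pipeline (relative power, LZC, sample entropy) and records
#' whether every reported group contrast holds in the expected direction:
#' delta relative power elevated in MCAO and reduced by tDCS; theta, alpha
#' and beta relative power depressed in MCAO with tDCS recovery; LZC and
#' sample entropy depressed in MCAO in every band with tDCS recovery; Sham
#' indistinguishable from MCAO.  Returns per-seed results and success
#' fractions.
#'
#' @param n_seeds Number of master seeds (default 100).
#' @param first_seed First master seed; seeds are consecutive integers.
#' @param config Template [sim_config()]; its `master_seed` is replaced per
#'   replicate.
#' @param metrics Not user-facing; all three metrics are always computed.
#' @param progress Print one line per seed block.
#' @return List with `fractions` (named success fractions over seeds),
#'   `all_directions_fraction` (joint recovery), `sham_within_sd_fraction`
#'   and `sham_ns_fraction` (per metric x band), `mean_delta_rp_eta_squared`
#'   and `per_seed` (logical data frame).
#' @export
evaluate_direction_recovery <- function(n_seeds = 100, first_seed = 1,
                                        config = sim_config(),
                                        metrics = NULL, progress = FALSE) {
  seeds <- first_seed + seq_len(n_seeds) - 1
  per_seed <- vector("list", n_seeds)
  sham_sd <- NULL; sham_ns <- NULL
  for (k in seq_along(seeds)) {
    cfg <- config
    cfg$master_seed <- as.integer(seeds[k] %% 2147483647)
    cohort <- generate_cohort(cfg)
    rp <- rp_table(cohort, bands = cfg$bands)
    cx <- complexity_tables(cohort, bands = cfg$bands)
    chk <- direction_checks_one_seed(rp, cx$LZC, cx$SampEn)
    sham_sd <- rbind(sham_sd, chk$sham_within_sd)
    sham_ns <- rbind(sham_ns, chk$sham_ns)
    per_seed[[k]] <- data.frame(
      seed = seeds[k],
      rp_delta_mcao_gt_control = chk$rp_delta_mcao_gt_control,
      rp_delta_tdcs_lt_mcao = chk$rp_delta_tdcs_lt_mcao,
      rp_low_bands_recovery = chk$rp_low_bands_recovery,
      lzc_recovery_all_bands = chk$lzc_recovery_all_bands,
      sampen_recovery_all_bands = chk$sampen_recovery_all_bands,
      delta_rp_anova_sig = chk$delta_rp_anova_sig,
      delta_rp_eta_squared = chk$delta_rp_eta_squared
    )
    if (progress && k %% 10 == 0) {
      message("direction recovery: ", k, "/", n_seeds, " seeds")
    }
  }
  per_seed <- do.call(rbind, per_seed)
  dir_cols <- c("rp_delta_mcao_gt_control", "rp_delta_tdcs_lt_mcao",
                "rp_low_bands_recovery", "lzc_recovery_all_bands",
                "sampen_recovery_all_bands")
  fractions <- colMeans(per_seed[, c(dir_cols, "delta_rp_anova_sig")])
  list(
    fractions = fractions,
    all_directions_fraction = mean(apply(per_seed[, dir_cols], 1, all)),
    sham_within_sd_fraction = colMeans(sham_sd),
    sham_ns_fraction = colMeans(sham_ns),
    mean_delta_rp_eta_squared = mean(per_seed$delta_rp_eta_squared),
    per_seed = per_seed
  )
}
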