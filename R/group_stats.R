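#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test (Brown-Forsythe, median-centered)
#' across groups.  The checks are advisory: results are reported but never
#' gate the ANOVA, mirroring a fixed analysis path in which assumptions are
#' confirmed up front.
#'
#' @param groups Named list of numeric vectors, >= 2 groups, each n >= 3.
#' @return List with `normality_p` (named vector, `NA` with a flag for
#'   constant groups), `levene_p`, and `flags`.
#' @export
assumption_checks <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 3)) {
    stop("insufficient data: every group needs n >= 3", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  flags <- character(0)
  normality_p <- vapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    if (max(x) == min(x)) {
      flags <<- c(flags, paste0("constant sample in group ", names(groups)[i],
                                ": normality undefined"))
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(normality_p) <- names(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns))
  )
  levene_p <- car::leveneTest(value ~ group, data = df,
                              center = stats::median)[["Pr(>F)"]][1]
  list(normality_p = normality_p, levene_p = levene_p, flags = flags)
}

#' One-way fixed-effects ANOVA with eta-squared
#'
#' Classical decomposition: `F = (SS_between / df_b) / (SS_within / df_w)`
#' and effect size `eta_squared = SS_between / SS_total`.
#'
#' @param groups List of numeric vectors, >= 2 groups, each n >= 2, not all
#'   values identical.
#' @return List with `F`, `p`, `eta_squared`, `df` (length 2), `ss_between`,
#'   `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (max(values) == min(values)) {
    stop("zero variance: all values identical", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = values,
                   group = factor(rep(names(groups), lengths(groups))))
  tab <- stats::anova(stats::aov(value ~ group, data = df))
  ssb <- tab[["Sum Sq"]][1]
  ssw <- tab[["Sum Sq"]][2]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       eta_squared = ssb / (ssb + ssw),
       df = tab[["Df"]], ss_between = ssb, ss_within = ssw)
}

#' Significance star code
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p P-value.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
star_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Per-band four-group comparison of a metric table
#'
#' For each band (canonical order delta, theta, alpha, beta): group
#' summaries (n, mean, SEM), one-way ANOVA F and p, eta-squared, and a
#' significance star code.  Stars come from the unadjusted p-value; an
#' optional Holm adjustment across bands is available but off by default,
#' and Welch's ANOVA (not assuming equal variances) can be selected.
#'
#' @param table Metric table as returned by [rp_table()] /
#'   [complexity_table()]: columns `subject_id`, `group`, `band`, `value`.
#' @param group_order Character vector of expected group labels.
#' @param band_order Band order for the output (default canonical order,
#'   restricted to bands present).
#' @param adjust `"none"` (default) or `"holm"` across bands.
#' @param welch If `TRUE` use Welch's ANOVA (`var.equal = FALSE`);
#'   eta-squared is still reported from the classical SS decomposition.
#' @return Tibble, one row per band: `metric`, `band`,
#'   `mean_<group>`, `sem_<group>`, `n_<group>` for each group, then `F`,
#'   `p`, `p_adj`, `eta_squared`, `stars`.
#' @export
compare_groups <- function(table,
                           group_order = c("Control", "MCAO", "MCAO_tDCS",
                                           "MCAO_Sham"),
                           band_order = NULL, adjust = c("none", "holm"),
                           welch = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("subject_id", "group", "band", "value") %in% names(table)))
  missing_groups <- setdiff(group_order, unique(table$group))
  if (length(missing_groups)) {
    stop("missing group(s) in table: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  metric <- attr(table, "metric_name") %||% "metric"
  if (is.null(band_order)) {
    band_order <- intersect(canonical_band_order(), unique(table$band))
    band_order <- c(band_order, setdiff(unique(table$band), band_order))
  }
  rows <- lapply(band_order, function(b) {
    sub <- table[table$band == b & table$group %in% group_order, ]
    if (anyNA(sub$value)) {
      stop("missing metric values in band ", b, call. = FALSE)
    }
    groups <- lapply(group_order, function(g) sub$value[sub$group == g])
    names(groups) <- group_order
    aov_res <- one_way_anova(groups)
    if (welch) {
      w <- stats::oneway.test(value ~ factor(group), data = sub,
                              var.equal = FALSE)
      aov_res$F <- unname(w$statistic)
      aov_res$p <- unname(w$p.value)
    }
    summ <- lapply(groups, function(x) {
      list(n = length(x), mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
    })
    row <- c(list(metric = metric, band = b),
             stats::setNames(lapply(summ, `[[`, "mean"),
                             paste0("mean_", group_order)),
             stats::setNames(lapply(summ, `[[`, "sem"),
                             paste0("sem_", group_order)),
             stats::setNames(lapply(summ, `[[`, "n"),
                             paste0("n_", group_order)),
             list(F = aov_res$F, p = aov_res$p,
                  eta_squared = aov_res$eta_squared))
    tibble::as_tibble(row)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$stars <- vapply(out$p, star_code, character(1))
  out
}
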