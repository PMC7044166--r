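# Group-level interaction statistics: relative bioavailability and
# metabolite/parent exposure ratios, two-sample t-tests on NCA parameters,
# and the study summary table.

#' Relative bioavailability
#'
#' `R.B.% = 100 * AUC0-inf(co-administered) / AUC0-inf(single)`.  With the
#' default `"ratio_of_means"` mode the point estimate is the ratio of the
#' group mean AUCs.  Because the two arms contain different animals, no
#' natural pairing exists; `"bootstrap_pairs"` repeatedly pairs the arms at
#' random to attach a dispersion to the ratio.
#'
#' @param auc_treated,auc_control AUC0-inf values (scalars or per-subject
#'   vectors), all `> 0`.
#' @param mode `"ratio_of_means"` (default) or `"bootstrap_pairs"`.
#' @param n_boot Random pairings used in bootstrap mode.
#' @return List with `pct` (point estimate), `sd` (NA in ratio-of-means
#'   mode) and `mode`.
#' @export
relative_bioavailability <- function(auc_treated, auc_control,
                                     mode = c("ratio_of_means", "bootstrap_pairs"),
                                     n_boot = 500) {
  mode <- match.arg(mode)
  if (any(auc_treated <= 0) || any(auc_control <= 0))
    stop("AUC values must be positive")
  if (mode == "ratio_of_means")
    return(list(pct = 100 * mean(auc_treated) / mean(auc_control),
                sd = NA_real_, mode = mode))
  ratios <- unlist(lapply(seq_len(n_boot), function(b) {
    100 * sample(auc_treated, replace = TRUE) /
      sample(auc_control, replace = TRUE)
  }))
  list(pct = mean(ratios), sd = stats::sd(ratios), mode = mode)
}

#' Metabolite/parent exposure ratio
#'
#' `M.R.% = 100 * AUC0-inf(metabolite) / AUC0-inf(parent)`.  When vectors
#' for the same animals are supplied the ratio is formed per animal
#' (metabolite and parent are measured in the same subject) and summarized
#' as mean +/- SD; the ratio of group means is also returned.
#'
#' @param auc_metabolite,auc_parent AUC0-inf values, `> 0`; equal-length
#'   vectors are treated as animal-paired.
#' @return List with `pct` (per-animal mean, equal to the scalar ratio for
#'   scalar input), `sd`, and `pct_rom` (ratio of means).
#' @export
metabolite_ratio <- function(auc_metabolite, auc_parent) {
  if (any(auc_metabolite <= 0) || any(auc_parent <= 0))
    stop("AUC values must be positive")
  if (length(auc_metabolite) != length(auc_parent))
    stop("metabolite and parent AUC vectors must be animal-paired")
  per <- 100 * auc_metabolite / auc_parent
  list(pct = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       pct_rom = 100 * mean(auc_metabolite) / mean(auc_parent))
}

#' Two-sample comparison of an NCA parameter between groups
#'
#' Student's t-test, pooled-variance by default (`welch = TRUE` for the
#' unequal-variance form).  Zero pooled variance with equal means yields
#' `t = 0, p = 1` by convention.
#'
#' @param results_a,results_b Numeric vectors, or data frames from
#'   [nca_table()] (the `parameter` column is extracted).
#' @param parameter Column name when data frames are supplied; also used as
#'   the label.
#' @param welch Use the Welch unequal-variance test.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_comparison`: means, SDs, `t_stat`,
#'   `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(results_a, results_b, parameter = "value",
                           welch = FALSE, alpha = 0.05) {
  pull <- function(x) if (is.data.frame(x)) x[[parameter]] else as.numeric(x)
  a <- pull(results_a); b <- pull(results_b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 subjects per group")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b); va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- if (se2 == 0) na + nb - 2 else
      se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  if (se == 0) {
    t_stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
  } else {
    t_stat <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(parameter = parameter,
                 mean_a = ma, sd_a = sqrt(va), n_a = na,
                 mean_b = mb, sd_b = sqrt(vb), n_b = nb,
                 t_stat = t_stat, df = df, p_value = p,
                 significant = p < alpha, alpha = alpha, welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\n",
              x$parameter, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4g (df %.3g), p = %.4g%s  [%s]\n", x$t_stat, x$df,
              x$p_value, if (x$significant) " *" else "",
              if (x$welch) "Welch" else "pooled"))
  invisible(x)
}

#' Study summary table: single vs co-administration
#'
#' For every analyte present in both arms, summarizes Cmax, tmax, t1/2,
#' AUC0-inf and CL/F as mean +/- SD with a two-sample t-test, and appends
#' relative-bioavailability and metabolite/parent-ratio rows.
#'
#' @param nca_single NCA table ([nca_table()]) of the single-administration
#'   arms.
#' @param nca_combo NCA table of the combination arm.
#' @param parent,metabolite Analyte labels forming the metabolite/parent
#'   ratio (default TAM/TOH).
#' @param alpha Significance level.
#' @param welch Use Welch's t-test.
#' @return Data frame with one row per analyte x parameter, columns
#'   `analyte`, `parameter`, `single_mean`, `single_sd`, `combo_mean`,
#'   `combo_sd`, `p_value`, `significant`.
#' @export
build_summary_table <- function(nca_single, nca_combo,
                                parent = "TAM", metabolite = "TOH",
                                alpha = 0.05, welch = FALSE) {
  params <- c(cmax = "Cmax (ng/mL)", tmax = "tmax (h)", t_half = "t1/2 (h)",
              auc_0_inf = "AUC0-inf (ng.h/mL)", cl_f = "CL/F (mL/h/kg)")
  rows <- list()
  for (an in intersect(unique(nca_single$analyte), unique(nca_combo$analyte))) {
    s <- nca_single[nca_single$analyte == an, ]
    c_ <- nca_combo[nca_combo$analyte == an, ]
    for (p in names(params)) {
      if (all(!is.finite(s[[p]]))) next
      cmp <- compare_groups(c_[[p]], s[[p]], parameter = p,
                            welch = welch, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, parameter = params[[p]],
        single_mean = cmp$mean_b, single_sd = cmp$sd_b,
        combo_mean = cmp$mean_a, combo_sd = cmp$sd_a,
        p_value = cmp$p_value, significant = cmp$significant)
    }
    rb <- relative_bioavailability(c_$auc_0_inf, s$auc_0_inf)
    rows[[length(rows) + 1L]] <- data.frame(
      analyte = an, parameter = "R.B. (%)",
      single_mean = NA_real_, single_sd = NA_real_,
      combo_mean = rb$pct, combo_sd = rb$sd,
      p_value = NA_real_, significant = NA)
  }
  for (arm in list(c("single", "nca_single"), c("combo", "nca_combo"))) {
    tab <- if (arm[1] == "single") nca_single else nca_combo
    met <- tab[tab$analyte == metabolite, ]
    par <- tab[tab$analyte == parent, ]
    if (!nrow(met) || !nrow(par)) next
    met <- met[order(met$subject_id), ]; par <- par[order(par$subject_id), ]
    shared <- intersect(met$subject_id, par$subject_id)
    if (!length(shared)) next
    mr <- metabolite_ratio(met$auc_0_inf[match(shared, met$subject_id)],
                           par$auc_0_inf[match(shared, par$subject_id)])
    rows[[length(rows) + 1L]] <- data.frame(
      analyte = paste0(metabolite, "/", parent),
      parameter = paste0("M.R. (%), ", arm[1]),
      single_mean = if (arm[1] == "single") mr$pct else NA_real_,
      single_sd = if (arm[1] == "single") mr$sd else NA_real_,
      combo_mean = if (arm[1] == "combo") mr$pct else NA_real_,
      combo_sd = if (arm[1] == "combo") mr$sd else NA_real_,
      p_value = NA_real_, significant = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render the summary table as aligned text
#'
#' @param summary_table Output of [build_summary_table()].
#' @return Character vector of lines (also printed with `cat` via
#'   [write_report()]); values rounded to 2 decimals, significant
#'   differences starred.
#' @export
format_summary_table <- function(summary_table) {
  fmt <- function(m, s) ifelse(is.na(m), "-",
                               ifelse(is.na(s), sprintf("%.2f", m),
                                      sprintf("%.2f +/- %.2f", m, s)))
  lines <- sprintf("%-8s %-22s %24s %24s %8s%s",
                   summary_table$analyte, summary_table$parameter,
                   fmt(summary_table$single_mean, summary_table$single_sd),
                   fmt(summary_table$combo_mean, summary_table$combo_sd),
                   ifelse(is.na(summary_table$p_value), "-",
                          sprintf("%.4f", summary_table$p_value)),
                   ifelse(!is.na(summary_table$significant) &
                            summary_table$significant, " *", ""))
  c(sprintf("%-8s %-22s %24s %24s %8s", "analyte", "parameter",
            "single (mean +/- SD)", "combo (mean +/- SD)", "p"),
    lines)
}
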