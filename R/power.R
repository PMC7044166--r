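# Operating characteristics of the whole pipeline: repeated simulated
# studies quantify ratio recovery, the t-test's null rejection rate, and
# power against a known interaction.

#' Replicate simulated interaction studies
#'
#' Runs the full pipeline (simulate -> NCA -> group statistics) `n_rep`
#' times, each replicate with its own derived seed, and collects for every
#' analyte the relative bioavailability (combination vs single arm, ratio
#' of group means) and the pooled t-test p-values for Cmax, t1/2, AUC0-inf
#' and CL/F.  tmax is omitted: on a sparse discrete schedule it collapses
#' onto few grid values and the t-test is degenerate.
#'
#' @param n_rep Number of replicate studies.
#' @param config A `study_config` (defaults, with its noise/IIV settings).
#' @param effect A [ddi_effect()]; the default means no true interaction,
#'   so rejection rates estimate the type-I error.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Data frame with columns `rep`, `analyte`, `rb_pct`, `p_cmax`,
#'   `p_t_half`, `p_auc_0_inf`, `p_cl_f` (NA where CL/F is undefined).
#' @export
replicate_studies <- function(n_rep, config = default_config(),
                              effect = ddi_effect(), seed = config$seed) {
  sim <- config_simulation(config)
  combo <- names(config$groups)[length(config$groups)]
  single_arm <- function(an) {
    if (an == .metabolite_label) an <- "TAM"
    for (g in setdiff(names(config$groups), combo))
      if (identical(config$groups[[g]], an)) return(g)
    NA_character_
  }
  params <- c("cmax", "t_half", "auc_0_inf", "cl_f")
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    design <- sim$design
    design$seed <- as.integer(seed + r)
    ds <- simulate_study(design, sim$base_params, effect)
    tab <- nca_table(ds, partial = TRUE)
    res <- lapply(unique(tab$analyte), function(an) {
      s <- tab[tab$group == single_arm(an) & tab$analyte == an, ]
      c_ <- tab[tab$group == combo & tab$analyte == an, ]
      p <- sapply(params, function(pp) {
        if (all(!is.finite(s[[pp]])) || all(!is.finite(c_[[pp]])))
          return(NA_real_)
        compare_groups(c_[[pp]], s[[pp]], parameter = pp)$p_value
      })
      data.frame(rep = r, analyte = an,
                 rb_pct = relative_bioavailability(
                   c_$auc_0_inf[is.finite(c_$auc_0_inf)],
                   s$auc_0_inf[is.finite(s$auc_0_inf)])$pct,
                 p_cmax = p[["cmax"]], p_t_half = p[["t_half"]],
                 p_auc_0_inf = p[["auc_0_inf"]], p_cl_f = p[["cl_f"]])
    })
    rows[[r]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize replicate studies
#'
#' @param reps Output of [replicate_studies()].
#' @param alpha Significance level for the rejection rates.
#' @return Data frame, one row per analyte: mean relative bioavailability
#'   and per-parameter rejection rates (percent).
#' @export
summarize_replicates <- function(reps, alpha = 0.05) {
  out <- do.call(rbind, lapply(split(reps, reps$analyte), function(d) {
    rej <- function(p) if (all(is.na(p))) NA_real_ else
      100 * mean(p < alpha, na.rm = TRUE)
    data.frame(analyte = d$analyte[1], n_rep = nrow(d),
               mean_rb_pct = mean(d$rb_pct),
               reject_cmax_pct = rej(d$p_cmax),
               reject_t_half_pct = rej(d$p_t_half),
               reject_auc_pct = rej(d$p_auc_0_inf),
               reject_cl_f_pct = rej(d$p_cl_f))
  }))
  rownames(out) <- NULL
  out
}
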