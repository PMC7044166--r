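# FDA-style bioanalytical validation metrics and their acceptance rules.
# Conventions: sample (n-1) SD throughout; ratio-of-means as the default
# aggregation for recovery/matrix-effect comparisons; "at least k times" is
# inclusive (>=) while "less than p%" is strict (<).

#' Acceptance policy for the validation battery
#'
#' @param limit_lloq Accuracy/precision limit at the LLOQ level (percent).
#' @param limit_other Limit at all higher levels and for stability /
#'   dilution integrity (percent).
#' @param selectivity_ratio_analyte Minimum LLOQ-to-blank signal fold.
#' @param selectivity_ratio_is Minimum IS-to-blank signal fold.
#' @param carryover_analyte_pct Maximum blank peak after a high sample, as a
#'   percent of the LLOQ response (strict).
#' @param carryover_is_pct Maximum IS blank peak, percent of the IS response
#'   (strict).
#' @return An object of class `acceptance_policy`.
#' @export
acceptance_policy <- function(limit_lloq = 20, limit_other = 15,
                              selectivity_ratio_analyte = 5,
                              selectivity_ratio_is = 20,
                              carryover_analyte_pct = 20,
                              carryover_is_pct = 5) {
  vals <- c(limit_lloq, limit_other, selectivity_ratio_analyte,
            selectivity_ratio_is, carryover_analyte_pct, carryover_is_pct)
  stopifnot(all(vals > 0))
  structure(list(limit_lloq = limit_lloq, limit_other = limit_other,
                 selectivity_ratio_analyte = selectivity_ratio_analyte,
                 selectivity_ratio_is = selectivity_ratio_is,
                 carryover_analyte_pct = carryover_analyte_pct,
                 carryover_is_pct = carryover_is_pct),
            class = "acceptance_policy")
}

.validation_record <- function(metric, analyte, level, value, dispersion,
                               limit, passed, note = "") {
  data.frame(metric = metric, analyte = analyte, level = as.character(level),
             value = value, dispersion = dispersion, limit = limit,
             passed = passed, note = note, stringsAsFactors = FALSE)
}

#' Accuracy and precision of replicate determinations
#'
#' `recovery% = 100 * mean(found) / nominal`,
#' `Er% = 100 * (mean(found) - nominal) / nominal`,
#' `RSD% = 100 * sd(found) / mean(found)` with the sample (n-1) SD.
#'
#' @param found Replicate found concentrations (>= 2 values).
#' @param nominal Nominal (spiked) concentration, `> 0`.
#' @return List with `recovery_pct`, `er_pct`, `rsd_pct`, `n`.
#' @export
accuracy_precision <- function(found, nominal) {
  if (length(found) < 2) stop("need at least 2 replicates")
  if (nominal <= 0) stop("nominal must be positive")
  m <- mean(found)
  rsd <- if (m == 0) NA_real_ else 100 * stats::sd(found) / m
  list(recovery_pct = 100 * m / nominal,
       er_pct = 100 * (m - nominal) / nominal,
       rsd_pct = rsd, n = length(found))
}

.ratio_pct <- function(num, den, mode) {
  if (mode == "mean_of_ratios") {
    if (length(num) != length(den))
      stop("mean_of_ratios requires paired responses of equal length")
    if (any(den == 0)) stop("zero denominator response")
    100 * mean(num / den)
  } else {
    if (mean(den) == 0) stop("zero mean denominator response")
    100 * mean(num) / mean(den)
  }
}

#' Extraction recovery
#'
#' Compares responses of samples spiked before extraction with samples
#' spiked into blank extract after extraction.
#'
#' @param pre_extraction_responses,post_extraction_responses Peak responses.
#' @param mode `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return Recovery in percent.
#' @export
extraction_recovery <- function(pre_extraction_responses,
                                post_extraction_responses,
                                mode = c("ratio_of_means", "mean_of_ratios")) {
  .ratio_pct(pre_extraction_responses, post_extraction_responses,
             match.arg(mode))
}

#' Matrix effect
#'
#' Compares post-extraction spiked responses with neat-solvent standards of
#' the same nominal concentration; 100% means no ionization suppression or
#' enhancement.
#'
#' @param post_extraction_responses,neat_solution_responses Peak responses.
#' @param mode `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return Matrix effect in percent.
#' @export
matrix_effect <- function(post_extraction_responses, neat_solution_responses,
                          mode = c("ratio_of_means", "mean_of_ratios")) {
  .ratio_pct(post_extraction_responses, neat_solution_responses,
             match.arg(mode))
}

#' Selectivity check at the LLOQ
#'
#' Passes when the LLOQ signal is at least `selectivity_ratio_analyte` times
#' the blank signal and the IS signal at least `selectivity_ratio_is` times
#' its blank (both inclusive); a blank of exactly zero passes vacuously.
#'
#' @param blank_signal,lloq_signal Analyte responses at the analyte's
#'   retention slot in blank and LLOQ-spiked samples.
#' @param is_signal,is_blank_signal Internal-standard responses in spiked
#'   and blank samples.
#' @param policy An [acceptance_policy()].
#' @param analyte Label for the record.
#' @return A one-row validation record data frame.
#' @export
selectivity_check <- function(blank_signal, lloq_signal, is_signal,
                              is_blank_signal, policy = acceptance_policy(),
                              analyte = "analyte") {
  if (any(c(blank_signal, lloq_signal, is_signal, is_blank_signal) < 0))
    stop("signals must be non-negative")
  ok_analyte <- lloq_signal >= policy$selectivity_ratio_analyte * blank_signal
  ok_is <- is_signal >= policy$selectivity_ratio_is * is_blank_signal
  ratio <- if (blank_signal > 0) lloq_signal / blank_signal else Inf
  .validation_record("selectivity", analyte, "LLOQ", ratio, NA_real_,
                     policy$selectivity_ratio_analyte, ok_analyte && ok_is,
                     if (!ok_is) "IS signal below required blank fold" else "")
}

#' Carryover check
#'
#' Evaluates the blank injected directly after a high-concentration sample:
#' passes when the analyte blank peak is strictly below
#' `carryover_analyte_pct`% of the LLOQ response and the IS blank peak
#' strictly below `carryover_is_pct`% of the IS response.
#'
#' @param analyte_blank_peak,is_blank_peak Peak areas in the post-high blank.
#' @param lloq_response,is_response Reference responses.
#' @param policy An [acceptance_policy()].
#' @param analyte Label for the record.
#' @return A one-row validation record data frame.
#' @export
carryover_check <- function(analyte_blank_peak, is_blank_peak, lloq_response,
                            is_response, policy = acceptance_policy(),
                            analyte = "analyte") {
  pct_analyte <- 100 * analyte_blank_peak / lloq_response
  pct_is <- 100 * is_blank_peak / is_response
  ok <- pct_analyte < policy$carryover_analyte_pct &&
    pct_is < policy$carryover_is_pct
  .validation_record("carryover", analyte, "blank", pct_analyte, pct_is,
                     policy$carryover_analyte_pct, ok,
                     if (pct_is >= policy$carryover_is_pct)
                       "IS carryover at/above limit" else "")
}

#' Stability as percent recovery against fresh nominal
#'
#' @param stored_found Replicate found concentrations after storage.
#' @param fresh_nominal Nominal concentration (ng/mL).
#' @param condition Storage condition label (e.g. "freeze-thaw, 3 cycles").
#' @param policy An [acceptance_policy()]; pass iff recovery within
#'   `100 +/- limit_other`.
#' @param analyte,level Labels for the record.
#' @return A one-row validation record data frame.
#' @export
stability_recovery <- function(stored_found, fresh_nominal, condition,
                               policy = acceptance_policy(),
                               analyte = "analyte", level = fresh_nominal) {
  ap <- accuracy_precision(stored_found, fresh_nominal)
  .validation_record("stability", analyte, level, ap$recovery_pct, ap$rsd_pct,
                     policy$limit_other,
                     abs(ap$recovery_pct - 100) <= policy$limit_other,
                     condition)
}

#' Dilution integrity
#'
#' @param found_after_dilution_correction Replicate concentrations after
#'   multiplying by the dilution factor (see [apply_dilution()]).
#' @param nominal Spiked concentration before dilution (ng/mL).
#' @param policy An [acceptance_policy()]; pass iff `|Er%| <= limit_other`.
#' @param analyte,level Labels for the record.
#' @return A one-row validation record data frame.
#' @export
dilution_integrity <- function(found_after_dilution_correction, nominal,
                               policy = acceptance_policy(),
                               analyte = "analyte", level = nominal) {
  ap <- accuracy_precision(found_after_dilution_correction, nominal)
  .validation_record("dilution_integrity", analyte, level, ap$recovery_pct,
                     ap$rsd_pct, policy$limit_other,
                     abs(ap$er_pct) <= policy$limit_other, "")
}

.ap_record <- function(metric, found, nominal, is_lloq, policy, analyte) {
  ap <- accuracy_precision(found, nominal)
  lim <- if (is_lloq) policy$limit_lloq else policy$limit_other
  .validation_record(metric, analyte, nominal, ap$recovery_pct, ap$rsd_pct,
                     lim, abs(ap$er_pct) <= lim &
                       (!is.na(ap$rsd_pct) && ap$rsd_pct <= lim), "")
}

#' Run the full validation battery
#'
#' Evaluates every metric for which the dataset supplies the required table;
#' missing tables yield "not evaluable" records rather than aborting.  The
#' overall verdict (attribute `"verdict"`) is the conjunction of all
#' evaluable records.
#'
#' @param dataset A named list; recognized elements (all data frames):
#'   \describe{
#'     \item{qc_intraday / qc_interday}{`analyte`, `nominal`, `found`, one
#'       row per replicate; `is_lloq` logical optional (defaults to nominal
#'       equalling the analyte's minimum).}
#'     \item{recovery}{`analyte`, `level`, `stage` in `pre`/`post`/`neat`,
#'       `response`; used for extraction recovery (pre vs post) and matrix
#'       effect (post vs neat).}
#'     \item{selectivity}{`analyte`, `blank_signal`, `lloq_signal`,
#'       `is_signal`, `is_blank_signal`.}
#'     \item{carryover}{`analyte`, `blank_peak`, `is_blank_peak`,
#'       `lloq_response`, `is_response`.}
#'     \item{dilution}{`analyte`, `nominal`, `factor`, `found` (already
#'       dilution-corrected).}
#'     \item{stability}{`analyte`, `condition`, `nominal`, `found`.}
#'   }
#' @param policy An [acceptance_policy()].
#' @return Data frame of validation records with attribute `"verdict"`.
#' @export
run_validation_battery <- function(dataset, policy = acceptance_policy()) {
  recs <- list()
  add <- function(r) recs[[length(recs) + 1L]] <<- r
  not_eval <- function(metric)
    add(.validation_record(metric, NA_character_, NA_character_, NA_real_,
                           NA_real_, NA_real_, NA, "not evaluable"))

  for (metric in c("precision_intraday", "precision_interday")) {
    tab <- dataset[[sub("precision_", "qc_", metric)]]
    if (is.null(tab)) { not_eval(metric); next }
    for (an in unique(tab$analyte)) {
      d <- tab[tab$analyte == an, ]
      for (nom in unique(d$nominal)) {
        dd <- d[d$nominal == nom, ]
        is_lloq <- if ("is_lloq" %in% names(dd)) dd$is_lloq[1]
                   else nom == min(d$nominal)
        add(.ap_record(metric, dd$found, nom, is_lloq, policy, an))
      }
    }
  }

  rec <- dataset$recovery
  if (is.null(rec)) { not_eval("recovery"); not_eval("matrix_effect") }
  else {
    for (an in unique(rec$analyte)) {
      d <- rec[rec$analyte == an, ]
      for (lv in unique(d$level)) {
        dd <- d[d$level == lv, ]
        pre <- dd$response[dd$stage == "pre"]
        post <- dd$response[dd$stage == "post"]
        neat <- dd$response[dd$stage == "neat"]
        if (length(pre) && length(post))
          add(.validation_record("recovery", an, lv,
                                 extraction_recovery(pre, post), NA_real_,
                                 NA_real_, TRUE, "reported, no limit"))
        if (length(post) && length(neat)) {
          me <- matrix_effect(post, neat)
          add(.validation_record("matrix_effect", an, lv, me, NA_real_,
                                 policy$limit_other,
                                 abs(me - 100) <= policy$limit_other, ""))
        }
      }
    }
  }

  sel <- dataset$selectivity
  if (is.null(sel)) not_eval("selectivity")
  else for (i in seq_len(nrow(sel)))
    add(selectivity_check(sel$blank_signal[i], sel$lloq_signal[i],
                          sel$is_signal[i], sel$is_blank_signal[i],
                          policy, sel$analyte[i]))

  co <- dataset$carryover
  if (is.null(co)) not_eval("carryover")
  else for (i in seq_len(nrow(co)))
    add(carryover_check(co$blank_peak[i], co$is_blank_peak[i],
                        co$lloq_response[i], co$is_response[i],
                        policy, co$analyte[i]))

  dil <- dataset$dilution
  if (is.null(dil)) not_eval("dilution_integrity")
  else for (an in unique(dil$analyte)) {
    d <- dil[dil$analyte == an, ]
    for (f in unique(d$factor)) {
      dd <- d[d$factor == f, ]
      add(dilution_integrity(dd$found, dd$nominal[1], policy, an,
                             paste0(dd$nominal[1], " (1:", f, ")")))
    }
  }

  st <- dataset$stability
  if (is.null(st)) not_eval("stability")
  else for (an in unique(st$analyte)) {
    d <- st[st$analyte == an, ]
    for (cond in unique(d$condition)) {
      dc <- d[d$condition == cond, ]
      for (nom in unique(dc$nominal))
        add(stability_recovery(dc$found[dc$nominal == nom], nom, cond,
                               policy, an, nom))
    }
  }

  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "verdict") <- all(out$passed[!is.na(out$passed)])
  out
}
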