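# Non-compartmental analysis of single-dose concentration-time profiles.
# Model-free throughout: maxima by inspection, terminal slope by log-linear
# regression over an adjusted-R^2-selected window, areas by the linear
# trapezoidal rule with C_last/Kel extrapolation.

#' A single subject x analyte concentration-time profile
#'
#' @param subject_id,group,analyte Labels.
#' @param times Hours, strictly increasing, first element 0.
#' @param concs Reported concentrations (ng/mL); 0 at BLQ points.
#' @param blq Logical BLQ flags, same length as `times`.
#' @param dose Dose of the administered parent (ng/kg); for a metabolite the
#'   parent dose is carried for bookkeeping only.
#' @param true_concs Optional noise-free truth (simulator provenance).
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, group, analyte, times, concs, blq = NULL,
                         dose = NA_real_, true_concs = NULL) {
  if (is.null(blq)) blq <- rep(FALSE, length(times))
  stopifnot(length(times) == length(concs), length(times) == length(blq),
            times[1] == 0, all(diff(times) > 0),
            all(concs[!blq] >= 0))
  structure(list(subject_id = subject_id, group = group, analyte = analyte,
                 times = as.numeric(times), concs = as.numeric(concs),
                 blq = as.logical(blq), dose = dose, true_concs = true_concs),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s / %s / %s: %d samples, %d BLQ\n",
              x$subject_id, x$group, x$analyte, length(x$times), sum(x$blq)))
  invisible(x)
}

#' Maximum observed concentration and its time
#'
#' Taken by inspection over the quantifiable (non-BLQ) points; ties are
#' broken in favour of the earliest time.
#'
#' @param profile A [conc_profile()].
#' @return List with `cmax` (ng/mL) and `tmax` (h).
#' @export
cmax_tmax <- function(profile) {
  ok <- !profile$blq
  if (!any(ok)) stop("profile ", profile$subject_id, "/", profile$analyte,
                     ": all points are BLQ")
  i <- which(ok)[which.max(profile$concs[ok])]
  list(cmax = profile$concs[i], tmax = profile$times[i])
}

# BLQ convention: pre-tmax BLQ contributes zero, post-tmax BLQ is excluded
# from both the trapezoid and the terminal fit.  Returns the usable series.
.usable_series <- function(profile) {
  tm <- cmax_tmax(profile)$tmax
  keep <- !profile$blq | profile$times < tm
  conc <- ifelse(profile$blq, 0, profile$concs)[keep]
  t <- profile$times[keep]
  last_q <- max(profile$times[!profile$blq])
  keep2 <- t <= last_q
  list(times = t[keep2], concs = conc[keep2], tmax = tm)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression of `ln(C)` on time over a terminal window.  The
#' default window search considers every run of `>= 3` quantifiable points
#' ending at the last quantifiable time and starting strictly after tmax
#' (the Cmax point itself is excluded), and keeps the window with the best
#' adjusted R-squared; windows within 1e-4 of the best are resolved in
#' favour of more points.  When fewer than 3 quantifiable points lie
#' strictly after tmax (sparse schedules where noise pushes the observed
#' maximum late), the observed-peak point is admitted into the window
#' rather than failing the profile.
#'
#' @param profile A [conc_profile()].
#' @param window Optional integer: fixed number of terminal points to use
#'   instead of the adjusted-R^2 search.
#' @return List with `kel` (1/h), `n_terminal`, `r2` and the window times.
#' @export
terminal_kel <- function(profile, window = NULL) {
  u <- .usable_series(profile)
  cand <- which(u$times > u$tmax & u$concs > 0)
  if (length(cand) < 3)   # sparse-tail fallback: admit the observed peak
    cand <- which(u$times >= u$tmax & u$concs > 0)
  if (length(cand) < 3)
    stop("profile ", profile$subject_id, "/", profile$analyte,
         ": fewer than 3 quantifiable points after tmax")
  t <- u$times[cand]; y <- log(u$concs[cand])
  n_all <- length(t)

  fit1 <- function(idx) {
    tt <- t[idx]; yy <- y[idx]; n <- length(idx)
    tm <- mean(tt); ym <- mean(yy)
    sxx <- sum((tt - tm)^2)
    b <- sum((tt - tm) * (yy - ym)) / sxx
    ssres <- sum((yy - ym - b * (tt - tm))^2)
    sstot <- sum((yy - ym)^2)
    r2 <- if (sstot == 0) 1 else 1 - ssres / sstot
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    list(slope = b, r2 = r2, adj = adj, n = n)
  }

  if (!is.null(window)) {
    stopifnot(window >= 3, window <= n_all)
    best <- fit1(seq.int(n_all - window + 1L, n_all))
  } else {
    fits <- lapply(seq_len(n_all - 2L),
                   function(s) fit1(seq.int(s, n_all)))
    adj <- vapply(fits, `[[`, numeric(1), "adj")
    ok <- which(adj >= max(adj) - 1e-4)
    best <- fits[[ok[which.max(vapply(fits[ok], `[[`, numeric(1), "n"))]]]
  }
  if (best$slope >= 0)
    stop("profile ", profile$subject_id, "/", profile$analyte,
         ": terminal phase not declining (slope ", signif(best$slope, 3), ")")
  list(kel = -best$slope, n_terminal = best$n, r2 = best$r2)
}

#' Elimination half-life
#'
#' Uses the bioanalytical convention `t1/2 = 0.693 / Kel`; `exact = TRUE`
#' substitutes `log(2)` for 0.693.
#'
#' @param kel Terminal elimination rate constant (1/h), `> 0`.
#' @param exact Use `log(2)` instead of the rounded constant.
#' @return Half-life in hours.
#' @export
half_life <- function(kel, exact = FALSE) {
  if (any(kel <= 0)) stop("kel must be positive")
  (if (exact) log(2) else 0.693) / kel
}

#' Linear trapezoidal AUC to the last quantifiable time
#'
#' @param profile A [conc_profile()].
#' @return AUC0-t in ng.h/mL.
#' @export
auc_trapezoid <- function(profile) {
  u <- .usable_series(profile)
  if (length(u$times) < 2) stop("fewer than 2 usable points for AUC")
  dt <- diff(u$times)
  sum(dt * (u$concs[-length(u$concs)] + u$concs[-1]) / 2)
}

#' Extrapolate AUC to infinity
#'
#' `AUC0-inf = AUC0-t + C_last / Kel`; also returns the extrapolated
#' percentage, with a warning flag above 20%.
#'
#' @param auc_0_t AUC to the last quantifiable time (ng.h/mL).
#' @param c_last Last quantifiable concentration (ng/mL), `>= 0`.
#' @param kel Terminal elimination rate constant (1/h), `> 0`.
#' @return List with `auc_0_inf`, `extrap_pct` and logical `extrap_warn`.
#' @export
auc_extrapolate <- function(auc_0_t, c_last, kel) {
  if (kel <= 0) stop("kel must be positive")
  if (c_last < 0) stop("c_last must be non-negative")
  auc_inf <- auc_0_t + c_last / kel
  extrap <- 100 * (c_last / kel) / auc_inf
  list(auc_0_inf = auc_inf, extrap_pct = extrap, extrap_warn = extrap > 20)
}

#' Apparent oral clearance
#'
#' @param dose Dose in ng/kg, `> 0`.
#' @param auc_0_inf AUC0-inf in ng.h/mL, `> 0`.
#' @return CL/F in mL/h/kg.
#' @export
clearance <- function(dose, auc_0_inf) {
  if (dose <= 0 || auc_0_inf <= 0) stop("dose and auc_0_inf must be positive")
  dose / auc_0_inf
}

# analytes regarded as administered parents (CL/F defined)
.parent_analytes <- c("DSV", "TAM")

#' Full non-compartmental analysis of one profile
#'
#' @param profile A [conc_profile()].
#' @param exact_half_life Passed to [half_life()].
#' @param window Passed to [terminal_kel()].
#' @param partial When `TRUE`, a profile whose terminal phase cannot be
#'   estimated (too few declining points) yields NA for the slope-dependent
#'   parameters instead of an error; Cmax, tmax and AUC0-t are always
#'   reported.
#' @return An `nca_result` list: `cmax`, `tmax`, `kel`, `t_half`, `auc_0_t`,
#'   `auc_0_inf`, `cl_f` (NA for metabolites), `extrap_pct`, `n_terminal`,
#'   `r2_terminal`, plus the profile labels.
#' @export
run_nca <- function(profile, exact_half_life = FALSE, window = NULL,
                    partial = FALSE) {
  ct <- cmax_tmax(profile)
  auc_t <- auc_trapezoid(profile)
  kel <- if (partial)
    tryCatch(terminal_kel(profile, window = window), error = function(e)
      list(kel = NA_real_, n_terminal = NA_integer_, r2 = NA_real_))
  else terminal_kel(profile, window = window)
  if (is.finite(kel$kel)) {
    u <- .usable_series(profile)
    ext <- auc_extrapolate(auc_t, u$concs[length(u$concs)], kel$kel)
    t_half <- half_life(kel$kel, exact = exact_half_life)
  } else {
    ext <- list(auc_0_inf = NA_real_, extrap_pct = NA_real_)
    t_half <- NA_real_
  }
  cl <- if (profile$analyte %in% .parent_analytes && is.finite(profile$dose) &&
            is.finite(ext$auc_0_inf))
    clearance(profile$dose, ext$auc_0_inf) else NA_real_
  structure(list(subject_id = profile$subject_id, group = profile$group,
                 analyte = profile$analyte,
                 cmax = ct$cmax, tmax = ct$tmax,
                 kel = kel$kel, t_half = t_half,
                 auc_0_t = auc_t, auc_0_inf = ext$auc_0_inf,
                 cl_f = cl, extrap_pct = ext$extrap_pct,
                 n_terminal = kel$n_terminal, r2_terminal = kel$r2),
            class = "nca_result")
}

#' Tabulate NCA results for a set of profiles
#'
#' @param profiles A list of [conc_profile()] objects or a
#'   `simulated_dataset`.
#' @param ... Passed to [run_nca()].
#' @return One data-frame row per profile.
#' @export
nca_table <- function(profiles, ...) {
  if (inherits(profiles, "simulated_dataset")) profiles <- profiles$profiles
  rows <- lapply(profiles, function(p) {
    r <- run_nca(p, ...)
    as.data.frame(r[c("subject_id", "group", "analyte", "cmax", "tmax",
                      "kel", "t_half", "auc_0_t", "auc_0_inf", "cl_f",
                      "extrap_pct", "n_terminal", "r2_terminal")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
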