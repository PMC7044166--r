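# One-compartment oral-absorption kinetics with first-order metabolite
# formation.  These closed forms generate the synthetic "truth" the
# non-compartmental pipeline is exercised against; the analysis never fits
# them back.

#' Kinetic parameters of a simulated analyte
#'
#' Bundles the rate constants of a one-compartment oral-absorption model with
#' optional first-order conversion to a single measured metabolite.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param ke First-order elimination rate constant of the parent (1/h).
#' @param v_f Apparent volume of distribution V/F (mL/kg).
#' @param dose Oral dose (ng/kg).
#' @param fm Fraction of the eliminated parent converted to the measured
#'   metabolite, in `[0, 1]`.  Zero disables the metabolite.
#' @param kem Metabolite elimination rate constant (1/h); required when
#'   `fm > 0`.
#' @param vm_f Apparent metabolite volume Vm/F (mL/kg); required when
#'   `fm > 0`.
#'
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ka, ke, v_f, dose, fm = 0, kem = NA_real_, vm_f = NA_real_) {
  stopifnot(is.numeric(ka), ka > 0, is.numeric(ke), ke > 0,
            is.numeric(v_f), v_f > 0, is.numeric(dose), dose > 0,
            is.numeric(fm), fm >= 0, fm <= 1)
  if (fm > 0 && (!is.finite(kem) || kem <= 0 || !is.finite(vm_f) || vm_f <= 0))
    stop("metabolite parameters 'kem' and 'vm_f' must be positive when fm > 0")
  structure(list(ka = ka, ke = ke, v_f = v_f, dose = dose,
                 fm = fm, kem = kem, vm_f = vm_f),
            class = "pk_params")
}

# Relative tolerance below which two rate constants are treated as equal and
# the confluent (L'Hopital) limit of the exponential formulas is used.
.rate_tol <- 1e-6

# Divided difference of f(x) = exp(-x * t) over two rate nodes, with the
# confluent limit f'(l) = -t exp(-l t) when the nodes (nearly) coincide.
.exp_dd2 <- function(l1, l2, t) {
  if (abs(l1 - l2) <= .rate_tol * max(l1, l2)) {
    l <- (l1 + l2) / 2
    -t * exp(-l * t)
  } else {
    (exp(-l1 * t) - exp(-l2 * t)) / (l1 - l2)
  }
}

# Divided difference of exp(-x * t) over three rate nodes; handles any
# pattern of (near-)coincident nodes analytically.
.exp_dd3 <- function(l, t) {
  eq <- function(a, b) abs(a - b) <= .rate_tol * max(a, b)
  l <- sort(l)
  if (eq(l[1], l[3])) {                      # all three equal
    a <- mean(l)
    t^2 * exp(-a * t) / 2
  } else if (eq(l[1], l[2]) || eq(l[2], l[3])) {
    # two equal: f[a, a, c] = (f'(a) - f[a, c]) / (a - c)
    if (eq(l[1], l[2])) { a <- (l[1] + l[2]) / 2; c <- l[3] }
    else                { a <- (l[2] + l[3]) / 2; c <- l[1] }
    (-t * exp(-a * t) - .exp_dd2(a, c, t)) / (a - c)
  } else {
    exp(-l[1] * t) / ((l[1] - l[2]) * (l[1] - l[3])) +
      exp(-l[2] * t) / ((l[2] - l[1]) * (l[2] - l[3])) +
      exp(-l[3] * t) / ((l[3] - l[1]) * (l[3] - l[2]))
  }
}

#' Noise-free parent concentration-time curve
#'
#' Bateman equation for a single oral dose:
#' `C(t) = dose * ka / (V_F * (ka - ke)) * (exp(-ke t) - exp(-ka t))`,
#' with the analytic limit `C(t) = dose * k * t / V_F * exp(-k t)` when
#' `ka` and `ke` (nearly) coincide.
#'
#' @param params A [pk_params()] object.
#' @param times Sampling times in hours, all `>= 0`.
#' @return Concentrations in ng/mL, one per element of `times`.
#' @export
simulate_parent <- function(params, times) {
  stopifnot(inherits(params, "pk_params"), is.numeric(times), all(times >= 0))
  pmax(0, -params$dose * params$ka / params$v_f *
         vapply(times, function(t) .exp_dd2(params$ka, params$ke, t),
                numeric(1)))
}

#' Noise-free metabolite concentration-time curve
#'
#' Sum-of-three-exponentials solution of the absorption -> parent ->
#' metabolite cascade (rates `ka`, `ke`, `kem`, formation fraction `fm`).
#' Its total area satisfies `AUC0-inf = fm * dose / (Vm_F * kem)`.
#'
#' @inheritParams simulate_parent
#' @return Concentrations in ng/mL.
#' @export
simulate_metabolite <- function(params, times) {
  stopifnot(inherits(params, "pk_params"), is.numeric(times), all(times >= 0))
  if (params$fm == 0) return(rep(0, length(times)))
  pmax(0, params$fm * params$ka * params$ke * params$dose / params$vm_f *
         vapply(times,
                function(t) .exp_dd3(c(params$ka, params$ke, params$kem), t),
                numeric(1)))
}

#' Apply proportional + additive assay noise and LLOQ censoring
#'
#' `measured = true * (1 + eps_prop) + eps_add`, truncated at zero.  Values
#' below the lower limit of quantification are flagged BLQ and the reported
#' value is censored to zero; the uncensored measurement is retained so the
#' censoring bias is quantifiable.
#'
#' @param true_conc True concentrations (ng/mL), `>= 0`.
#' @param noise_cv Proportional noise CV (fraction, e.g. 0.05).
#' @param noise_sd_add Additive noise SD (ng/mL).
#' @param lloq Lower limit of quantification (ng/mL).
#' @return A data frame with columns `measured`, `reported` (censored to 0
#'   when BLQ) and `blq`.
#' @export
add_assay_noise <- function(true_conc, noise_cv, noise_sd_add, lloq) {
  stopifnot(all(true_conc >= 0), noise_cv >= 0, noise_sd_add >= 0, lloq >= 0)
  n <- length(true_conc)
  measured <- true_conc * (1 + stats::rnorm(n, 0, noise_cv)) +
    stats::rnorm(n, 0, noise_sd_add)
  measured <- pmax(measured, 0)
  blq <- measured < lloq
  data.frame(measured = measured,
             reported = ifelse(blq, 0, measured),
             blq = blq)
}

#' Study design for the interaction simulator
#'
#' Defaults mirror a three-arm rat cross-comparison: group I receives the
#' perpetrator-candidate alone, group II the victim-candidate alone (its
#' metabolite is measured alongside), and group III the combination; five
#' animals per arm, sampled pre-dose and at nine post-dose times to 48 h.
#'
#' @param groups Named list mapping group label to the character vector of
#'   dosed parent analytes.
#' @param n_per_group Animals per group (`>= 2`).
#' @param sampling_times Hours; strictly increasing, first element 0.
#' @param lloq Named numeric, LLOQ in ng/mL per measured analyte.
#' @param noise_cv Proportional assay CV (fraction).
#' @param noise_sd_add Additive assay SD (ng/mL).
#' @param iiv_cv Log-normal inter-animal CV applied to the kinetic
#'   parameters (fraction).
#' @param seed Integer seed; every simulated quantity is reproducible from it.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = list(I = "DSV", II = "TAM", III = c("DSV", "TAM")),
                         n_per_group = 5,
                         sampling_times = c(0, 0.25, 0.5, 1, 2, 4, 5, 12, 24, 48),
                         lloq = c(DSV = 20, TAM = 0.1, TOH = 0.5),
                         noise_cv = 0.05, noise_sd_add = 0,
                         iiv_cv = 0.2, seed = 20200226L) {
  stopifnot(is.list(groups), length(groups) >= 1,
            n_per_group >= 2,
            length(sampling_times) >= 2,
            sampling_times[1] == 0,
            all(diff(sampling_times) > 0),
            noise_cv >= 0, noise_sd_add >= 0, iiv_cv >= 0)
  structure(list(groups = groups, n_per_group = n_per_group,
                 sampling_times = sampling_times, lloq = lloq,
                 noise_cv = noise_cv, noise_sd_add = noise_sd_add,
                 iiv_cv = iiv_cv, seed = as.integer(seed)),
            class = "study_design")
}

#' Interaction effect applied to the victim analyte in the combination arm
#'
#' @param victim Analyte label whose kinetics the co-administered drug
#'   perturbs in the combination group.
#' @param f_scale Multiplicative factor on the effective (bioavailable) dose;
#'   scales exposure proportionally.  1 = no interaction.
#' @param ke_scale Multiplicative factor on the victim's elimination rate.
#' @return An object of class `ddi_effect`.
#' @export
ddi_effect <- function(victim = "TAM", f_scale = 1, ke_scale = 1) {
  stopifnot(f_scale > 0, ke_scale > 0)
  structure(list(victim = victim, f_scale = f_scale, ke_scale = ke_scale),
            class = "ddi_effect")
}

# log-normal multipliers with unit mean and coefficient of variation cv
.lnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sig <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sig^2 / 2, sig))
}

.metabolite_label <- "TOH"

#' Simulate a complete interaction study
#'
#' Draws per-animal kinetic parameters log-normally around the base values,
#' generates parent (and, where `fm > 0`, metabolite) profiles on the design's
#' sampling schedule, applies assay noise and LLOQ censoring, and applies the
#' interaction effect to the victim analyte in the last (combination) group.
#'
#' @param design A [study_design()].
#' @param base_params Named list of [pk_params()], one per dosed analyte.
#' @param effect A [ddi_effect()]; the default (all factors 1) corresponds to
#'   no interaction.
#' @return A list of class `simulated_dataset` with elements `profiles`
#'   (list of `conc_profile`), `true_params` (per subject x analyte) and
#'   `design`.
#' @export
simulate_study <- function(design, base_params, effect = ddi_effect()) {
  stopifnot(inherits(design, "study_design"), is.list(base_params))
  dosed <- unique(unlist(design$groups))
  missing <- setdiff(dosed, names(base_params))
  if (length(missing))
    stop("no base parameters for analyte(s): ", paste(missing, collapse = ", "))
  set.seed(design$seed)
  combo_label <- names(design$groups)[length(design$groups)]

  profiles <- list()
  true_params <- list()
  for (g in names(design$groups)) {
    for (i in seq_len(design$n_per_group)) {
      sid <- paste0(g, "-", i)
      for (analyte in design$groups[[g]]) {
        bp <- base_params[[analyte]]
        m <- .lnorm_mult(5, design$iiv_cv)
        p <- bp
        p$ka <- bp$ka * m[1]; p$ke <- bp$ke * m[2]; p$v_f <- bp$v_f * m[3]
        if (bp$fm > 0) { p$kem <- bp$kem * m[4]; p$vm_f <- bp$vm_f * m[5] }
        if (g == combo_label && length(design$groups[[g]]) > 1 &&
            analyte == effect$victim) {
          p$dose <- p$dose * effect$f_scale
          p$ke <- p$ke * effect$ke_scale
        }
        true_params[[sid]][[analyte]] <- p

        emit <- function(label, true) {
          lloq <- if (label %in% names(design$lloq)) design$lloq[[label]] else 0
          noisy <- add_assay_noise(true, design$noise_cv,
                                   design$noise_sd_add, lloq)
          conc_profile(subject_id = sid, group = g, analyte = label,
                       times = design$sampling_times,
                       concs = noisy$reported, blq = noisy$blq,
                       dose = bp$dose, true_concs = true)
        }
        profiles[[length(profiles) + 1L]] <-
          emit(analyte, simulate_parent(p, design$sampling_times))
        if (bp$fm > 0)
          profiles[[length(profiles) + 1L]] <-
            emit(.metabolite_label, simulate_metabolite(p, design$sampling_times))
      }
    }
  }
  structure(list(profiles = profiles, true_params = true_params,
                 design = design),
            class = "simulated_dataset")
}

#' Simulate a calibration / QC response batch
#'
#' Generates instrument responses `intercept + slope * conc`, perturbed by
#' proportional noise, for each requested concentration level and replicate,
#' at each spiking stage.  Stage-specific attenuation factors let extraction
#' recovery (pre vs post) and matrix effect (post vs neat) be exercised with
#' known truth.
#'
#' @param slope,intercept Truth of the response line (response per ng/mL,
#'   response units).
#' @param levels Concentration levels (ng/mL).
#' @param replicates Replicates per level and stage (`>= 1`).
#' @param noise_cv Proportional response CV (fraction).
#' @param stage_factors Named numeric attenuation per stage, e.g.
#'   `c(pre = 0.95, post = 1, neat = 1)`.
#' @param blank_mean Mean blank response (same units as `response`).
#' @param analyte Label copied into the output.
#' @return Data frame with columns `analyte`, `level`, `replicate`, `stage`,
#'   `response`, `is_response`; blank rows have `level = 0`, `stage = "blank"`.
#' @export
simulate_calibration_batch <- function(slope, intercept, levels,
                                       replicates = 6, noise_cv = 0,
                                       stage_factors = c(pre = 0.95, post = 1, neat = 1),
                                       blank_mean = 0, analyte = "analyte") {
  stopifnot(replicates >= 1, noise_cv >= 0, all(levels > 0),
            !is.null(names(stage_factors)))
  rows <- list()
  for (stage in names(stage_factors)) {
    for (lv in levels) {
      mu <- (intercept + slope * lv) * stage_factors[[stage]]
      resp <- mu * (1 + stats::rnorm(replicates, 0, noise_cv))
      rows[[length(rows) + 1L]] <-
        data.frame(analyte = analyte, level = lv,
                   replicate = seq_len(replicates), stage = stage,
                   response = resp, is_response = 1)
    }
  }
  blank <- data.frame(analyte = analyte, level = 0,
                      replicate = seq_len(replicates), stage = "blank",
                      response = pmax(blank_mean *
                                        (1 + stats::rnorm(replicates, 0, noise_cv)), 0),
                      is_response = 1)
  out <- do.call(rbind, c(rows, list(blank)))
  rownames(out) <- NULL
  out
}
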