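# Delimited-text I/O.  Concentration-time tables use the fixed schema
# subject_id, group, analyte, time_h, conc_ng_per_mL, blq (0/1); the same
# schema is accepted for user-supplied data.  Concentrations are serialized
# at full precision; report tables are rounded to 2 decimals.

.profile_cols <- c("subject_id", "group", "analyte", "time_h",
                   "conc_ng_per_mL", "blq")

#' Flatten profiles to a data frame
#'
#' @param profiles List of [conc_profile()] objects or a `simulated_dataset`.
#' @return Data frame in the canonical column order.
#' @export
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "simulated_dataset")) profiles <- profiles$profiles
  out <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, group = p$group,
               analyte = p$analyte, time_h = p$times,
               conc_ng_per_mL = p$concs, blq = as.integer(p$blq))))
  rownames(out) <- NULL
  out
}

#' Write concentration-time profiles as CSV
#'
#' @param profiles List of [conc_profile()] objects or a `simulated_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles_to_df(profiles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read concentration-time profiles from CSV
#'
#' Validates the schema and per-profile invariants (strictly increasing
#' times starting at 0, non-negative quantifiable concentrations); every
#' violation is reported with the offending subject/analyte and file rows.
#'
#' @param path CSV file with the canonical columns.
#' @param doses Optional named vector, dose in ng/kg per analyte, attached
#'   to the profiles (needed for CL/F).
#' @return List of [conc_profile()] objects.
#' @export
read_profiles <- function(path, doses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.profile_cols, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df$.row <- seq_len(nrow(df)) + 1L   # header is line 1
  errors <- character()
  profiles <- list()
  for (key in unique(paste(df$subject_id, df$analyte, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- df[df$subject_id == parts[1] & df$analyte == parts[2], ]
    d <- d[order(d$time_h), ]
    lab <- paste0(parts[1], "/", parts[2])
    if (d$time_h[1] != 0)
      errors <- c(errors, paste0(lab, ": first sampling time is not 0 (rows ",
                                 paste(d$.row, collapse = ","), ")"))
    dup <- duplicated(d$time_h)
    if (any(dup))
      errors <- c(errors, paste0(lab, ": duplicated times at rows ",
                                 paste(d$.row[dup], collapse = ",")))
    bad <- d$conc_ng_per_mL < 0 & d$blq == 0
    if (any(bad))
      errors <- c(errors, paste0(lab, ": negative concentration at rows ",
                                 paste(d$.row[bad], collapse = ",")))
    if (length(errors)) next
    dose <- if (!is.null(doses) && parts[2] %in% names(doses))
      doses[[parts[2]]] else NA_real_
    profiles[[length(profiles) + 1L]] <-
      conc_profile(parts[1], d$group[1], parts[2], d$time_h,
                   d$conc_ng_per_mL, as.logical(d$blq), dose = dose)
  }
  if (length(errors))
    stop("invalid profile file:\n  ", paste(errors, collapse = "\n  "))
  profiles
}

#' Write a study report
#'
#' Emits per-subject NCA results, the group summary table (CSV at full
#' precision plus an aligned text rendition rounded to 2 decimals), optional
#' validation records, and a reproducibility header carrying the seed,
#' package version and full configuration.
#'
#' @param results Named list; recognized elements `nca` (data frame from
#'   [nca_table()]), `summary` (from [build_summary_table()]), `validation`
#'   (from [run_validation_battery()]).
#' @param dir Output directory (created if absent).
#' @param config The `study_config` used, recorded in the header.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  if (!is.null(results$nca)) emit(results$nca, "nca_subjects.csv")
  if (!is.null(results$summary)) {
    emit(results$summary, "group_summary.csv")
    f <- file.path(dir, "group_summary.txt")
    writeLines(format_summary_table(results$summary), f)
    written <- c(written, f)
  }
  if (!is.null(results$validation)) {
    emit(results$validation, "validation_records.csv")
    f <- file.path(dir, "validation_verdict.txt")
    writeLines(paste0("overall verdict: ",
                      if (isTRUE(attr(results$validation, "verdict")))
                        "PASS" else "FAIL"), f)
    written <- c(written, f)
  }
  hdr <- file.path(dir, "run_header.json")
  jsonlite::write_json(
    list(package = "pkddi",
         version = as.character(utils::packageVersion("pkddi")),
         seed = config$seed,
         generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config)),
    hdr, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, hdr)
  invisible(written)
}
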