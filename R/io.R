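# CSV readers/writers for cohort data.
#
# Schema:
#   measurements CSV: subject_id, isotope ("2H"/"18O"), time_days, delta_permil
#   subjects CSV:     subject_id, sex ("F"/"M"), weight_kg, and per isotope
#                     (suffix _2h / _18o): dose_g_*, aliquot_g_*,
#                     tapwater_g_*, delta_dose_*, delta_tap_*, basal_*

iso_suffix <- c("2H" = "2h", "18O" = "18o")

meta_cols <- function() {
  per_iso <- c("dose_g", "aliquot_g", "tapwater_g", "delta_dose", "delta_tap",
               "basal")
  c("subject_id", "sex", "weight_kg",
    as.vector(outer(per_iso, unname(iso_suffix), paste, sep = "_")))
}

#' Read a DLW cohort from CSV
#'
#' Reads the per-measurement and per-subject CSV files (or equivalent
#' data.frames) and assembles validated [subject_record()]s.  Malformed
#' measurement rows (negative time, non-finite delta, unknown isotope) abort
#' with data-line numbers; a subject missing either isotope's measurements
#' or metadata is skipped with a warning.  Duplicate timepoints are averaged
#' and times sorted before the curve is built.
#'
#' @param measurements path to the measurements CSV, or a data.frame.
#' @param subjects path to the subject metadata CSV, or a data.frame.
#' @return list of [subject_record()]s, named by subject id.
#' @export
read_cohort <- function(measurements, subjects) {
  meas <- if (is.character(measurements))
    utils::read.csv(measurements, stringsAsFactors = FALSE) else measurements
  meta <- if (is.character(subjects))
    utils::read.csv(subjects, stringsAsFactors = FALSE) else subjects
  if (nrow(meas) == 0) stop("measurements file is empty")
  need_m <- c("subject_id", "isotope", "time_days", "delta_permil")
  if (!all(need_m %in% names(meas)))
    stop("measurements must have columns: ", paste(need_m, collapse = ", "))
  missing_meta <- setdiff(meta_cols(), names(meta))
  if (length(missing_meta))
    stop("subject metadata missing columns: ",
         paste(missing_meta, collapse = ", "))
  # line numbers count the header as line 1
  bad <- which(!is.finite(meas$time_days) | meas$time_days < 0 |
                 !is.finite(meas$delta_permil) |
                 !meas$isotope %in% c("2H", "18O"))
  if (length(bad))
    stop("malformed measurement row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "),
         " (negative/missing time, non-finite delta, or unknown isotope)")
  out <- list()
  for (sid in unique(meas$subject_id)) {
    mrow <- meta[meta$subject_id == sid, , drop = FALSE]
    if (nrow(mrow) != 1) {
      warning("subject ", sid, ": no (or duplicated) metadata row; skipped")
      next
    }
    sub_meas <- meas[meas$subject_id == sid, , drop = FALSE]
    doses <- list(); curves <- list(); ok <- TRUE
    for (iso in c("2H", "18O")) {
      m <- sub_meas[sub_meas$isotope == iso, , drop = FALSE]
      if (nrow(m) == 0) {
        warning("subject ", sid, ": no ", iso, " measurements; skipped")
        ok <- FALSE; break
      }
      sfx <- iso_suffix[[iso]]
      g <- function(col) mrow[[paste0(col, "_", sfx)]]
      doses[[iso]] <- dose_prep(g("dose_g"), g("aliquot_g"), g("tapwater_g"),
                                g("delta_dose"), g("delta_tap"))
      agg <- stats::aggregate(delta_permil ~ time_days, data = m, FUN = mean)
      agg <- agg[order(agg$time_days), ]
      curves[[iso]] <- isotope_curve(iso, agg$time_days, agg$delta_permil,
                                     g("basal"))
    }
    if (!ok) next
    out[[sid]] <- subject_record(sid, mrow$sex, mrow$weight_kg, doses, curves)
  }
  if (length(out) == 0) stop("no complete subjects could be read")
  out
}

#' Write a DLW cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the measurements and subject-metadata
#' CSVs for a list of [subject_record()]s.
#'
#' @param subjects list of [subject_record()]s.
#' @param measurements_path,subjects_path output CSV paths.
#' @return invisibly, a list with the two data.frames written.
#' @export
write_cohort <- function(subjects, measurements_path, subjects_path) {
  meas <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(c("2H", "18O"), function(iso) {
      cv <- s$curves[[iso]]
      data.frame(subject_id = s$id, isotope = iso, time_days = cv$times,
                 delta_permil = cv$deltas)
    }))
  }))
  meta <- do.call(rbind, lapply(subjects, function(s) {
    row <- data.frame(subject_id = s$id, sex = s$sex, weight_kg = s$weight_kg)
    for (iso in c("2H", "18O")) {
      d <- s$doses[[iso]]; sfx <- iso_suffix[[iso]]
      add <- data.frame(d$dose_g, d$aliquot_g, d$tapwater_g, d$delta_dd,
                        d$delta_tap, s$curves[[iso]]$basal)
      names(add) <- paste0(c("dose_g", "aliquot_g", "tapwater_g",
                             "delta_dose", "delta_tap", "basal"), "_", sfx)
      row <- cbind(row, add)
    }
    row
  }))
  utils::write.csv(meas, measurements_path, row.names = FALSE)
  utils::write.csv(meta, subjects_path, row.names = FALSE)
  invisible(list(measurements = meas, subjects = meta))
}
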