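#' Restrict encounters to the analysis age window
#'
#' Keeps records with `age_min <= encounter_age <= age_max` (both
#' boundaries inclusive). Lung-function data below age 6 are considered
#' unreliable and rapid decline is primarily a paediatric/adolescent
#' phenomenon, hence the default 6-21 window.
#'
#' @param records encounter data.frame.
#' @param age_min,age_max window boundaries in years.
#' @return filtered data.frame (warns if empty).
#' @export
restrict_age_window <- function(records, age_min = 6, age_max = 21) {
  stopifnot(is.data.frame(records), "encounter_age" %in% names(records))
  out <- records[records$encounter_age >= age_min &
                   records$encounter_age <= age_max, , drop = FALSE]
  if (nrow(out) == 0) warning("no encounters left after age restriction")
  rownames(out) <- NULL
  out
}

#' Drop patients with too few measurements
#'
#' Removes entirely any patient with fewer than `min_encounters` records.
#' Counts are taken on the records as passed in, i.e. after the age
#' restriction, since sparse-FPCA estimation is unstable for very short
#' series.
#'
#' @param records encounter data.frame (age filter already applied).
#' @param min_encounters minimum number of FEV1 measurements to retain a
#'   patient.
#' @return filtered data.frame.
#' @export
filter_min_encounters <- function(records, min_encounters = 7) {
  stopifnot(is.data.frame(records), "patient_id" %in% names(records))
  counts <- table(records$patient_id)
  keep <- names(counts)[counts >= min_encounters]
  out <- records[records$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Drop duplicated (patient, age) measurements, keeping the first occurrence.
dedupe_encounters <- function(records) {
  key <- paste(records$patient_id, records$encounter_age, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each patient a primary care center
#'
#' The primary center is the one with the largest number of distinct
#' designated years of follow-up. Ties are broken deterministically in
#' favour of the center attended earliest (smallest first year), then by
#' lexicographic center id.
#'
#' @param records encounter data.frame with `patient_id`, `year`,
#'   `center_id`.
#' @return data.frame with columns `patient_id`, `center_id`.
#' @export
assign_primary_center <- function(records) {
  stopifnot(all(c("patient_id", "year", "center_id") %in% names(records)))
  py <- unique(records[, c("patient_id", "year", "center_id")])
  out <- lapply(split(py, py$patient_id), function(d) {
    n_years <- tapply(d$year, d$center_id, function(y) length(unique(y)))
    first_year <- tapply(d$year, d$center_id, min)
    ids <- names(n_years)
    ord <- order(-n_years, first_year, ids)
    data.frame(patient_id = d$patient_id[1], center_id = ids[ord[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Categorise centers by patient count
#'
#' Small: fewer than 30 patients; medium: 30 to 150 inclusive; large:
#' more than 150.
#'
#' @param center_counts named vector (or data.frame with `center_id`,
#'   `n_patients`) of patients per primary center.
#' @return data.frame with `center_id`, `n_patients`, `size_category`.
#' @export
categorize_center_size <- function(center_counts) {
  if (is.data.frame(center_counts)) {
    ids <- center_counts$center_id
    n <- center_counts$n_patients
  } else {
    ids <- names(center_counts)
    n <- as.numeric(center_counts)
  }
  cat <- ifelse(n < 30, "small", ifelse(n <= 150, "medium", "large"))
  data.frame(center_id = ids, n_patients = n,
             size_category = factor(cat, levels = c("small", "medium", "large")),
             stringsAsFactors = FALSE)
}

#' Build the analysis cohort
#'
#' Applies, in order: de-duplication of (patient, age) records, the age
#' window restriction, the minimum-measurement filter, primary-center
#' assignment, and center size categorisation.
#'
#' @param records raw encounter data.frame.
#' @param age_min,age_max analysis age window (years).
#' @param min_encounters minimum measurements per retained patient.
#' @return list of class `cohort_table`: `encounters` (filtered),
#'   `primary` (patient_id, center_id), `centers` (center_id, n_patients,
#'   size_category).
#' @export
build_cohort <- function(records, age_min = 6, age_max = 21, min_encounters = 7) {
  enc <- dedupe_encounters(records)
  enc <- restrict_age_window(enc, age_min, age_max)
  enc <- filter_min_encounters(enc, min_encounters)
  primary <- assign_primary_center(enc)
  counts <- table(primary$center_id)
  centers <- categorize_center_size(counts)
  structure(list(encounters = enc, primary = primary, centers = centers,
                 age_window = c(age_min, age_max),
                 min_encounters = min_encounters),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Analysis cohort: %d patients, %d encounters, %d centers\n",
              nrow(x$primary), nrow(x$encounters), nrow(x$centers)))
  print(table(x$centers$size_category))
  invisible(x)
}

#' Write the cohort summary table
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path; columns center_id, n_patients, size_category.
#' @export
write_cohort_summary <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$centers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
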