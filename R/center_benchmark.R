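PHENOTYPE_LEVELS <- c("early", "middle", "late")

# Normalise a labels argument to a patient_id -> label lookup.
label_lookup <- function(labels) {
  stopifnot(all(c("patient_id", "label") %in% names(labels)))
  stats::setNames(as.character(labels$label), labels$patient_id)
}

# Normalise a primary-centers argument to a patient_id -> center lookup.
center_lookup <- function(primary) {
  stopifnot(all(c("patient_id", "center_id") %in% names(primary)))
  stats::setNames(as.character(primary$center_id), primary$patient_id)
}

# Pointwise means of grid curves within center x phenotype cells.
cell_means <- function(curves, grid, labels, primary, value_name) {
  ids <- colnames(curves)
  lab <- label_lookup(labels)[ids]
  ctr <- center_lookup(primary)[ids]
  if (any(is.na(lab)) || any(is.na(ctr)))
    stop("every curve needs a label and a primary center")
  key <- paste(ctr, lab, sep = "\r")
  out <- lapply(unique(key), function(kk) {
    cols <- which(key == kk)
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    d <- data.frame(center_id = parts[1], phenotype = parts[2], age = grid,
                    value = rowMeans(curves[, cols, drop = FALSE]),
                    n = length(cols), stringsAsFactors = FALSE)
    names(d)[names(d) == "value"] <- value_name
    d
  })
  out <- do.call(rbind, out)
  out <- out[order(out$center_id, out$phenotype, out$age), ]
  rownames(out) <- NULL
  out
}

#' Center-level functional means of fitted trajectories
#'
#' Pointwise mean, on the common grid, of the fitted FEV1 curves of
#' patients in each primary-center by decline-phenotype cell. Cells
#' without patients are simply absent from the output (no zero curves).
#'
#' @param curves G x n matrix of fitted curves (columns named by
#'   patient), e.g. `fitted_curves(model)$fit`.
#' @param grid ages for the G rows.
#' @param labels a `phenotype_assignment` (or data.frame with
#'   patient_id, label).
#' @param primary data.frame with patient_id, center_id.
#' @return long data.frame: center_id, phenotype, age, mean_fev1pp, n.
#' @export
center_functional_mean <- function(curves, grid, labels, primary) {
  cell_means(curves, grid, labels, primary, "mean_fev1pp")
}

#' Center-level mean rate-of-change curves
#'
#' As [center_functional_mean()], applied to derivative curves; yields
#' each cell's mean rate of FEV1 change (percent predicted per year).
#'
#' @param deriv_curves G x n matrix of derivative curves,
#'   e.g. `fitted_curves(model)$deriv`.
#' @inheritParams center_functional_mean
#' @return long data.frame: center_id, phenotype, age, mean_rate, n.
#' @export
center_rate_mean <- function(deriv_curves, grid, labels, primary) {
  cell_means(deriv_curves, grid, labels, primary, "mean_rate")
}

#' Phenotype prevalence by center
#'
#' @inheritParams center_functional_mean
#' @return data.frame: center_id, n_patients, early, middle, late
#'   (percentages summing to 100 per center).
#' @export
prevalence_by_center <- function(labels, primary) {
  lab <- label_lookup(labels)
  ctr <- center_lookup(primary)
  ids <- intersect(names(lab), names(ctr))
  tab <- table(center = ctr[ids],
               label = factor(lab[ids], levels = PHENOTYPE_LEVELS))
  pct <- 100 * prop.table(tab, 1)
  out <- data.frame(center_id = rownames(tab),
                    n_patients = as.integer(rowSums(tab)),
                    early = as.numeric(pct[, "early"]),
                    middle = as.numeric(pct[, "middle"]),
                    late = as.numeric(pct[, "late"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-patient analysis table
#'
#' One row per patient: primary center and its size category, baseline
#' age and baseline FEV1 (earliest in-window encounter), first-component
#' score, phenotype label, and peak-decline extent and age. This is the
#' patient-level data frame handed to the dashboard alongside the curve
#' table.
#'
#' @param cohort a `cohort_table`.
#' @param model an `fpca_model` fitted to the cohort.
#' @param labels a `phenotype_assignment`.
#' @return data.frame keyed by patient_id.
#' @export
patient_table <- function(cohort, model, labels) {
  enc <- cohort$encounters
  ord <- order(enc$patient_id, enc$encounter_age)
  enc <- enc[ord, ]
  first <- enc[!duplicated(enc$patient_id), ]
  pk <- peak_decline_all(model)
  out <- data.frame(patient_id = first$patient_id,
                    baseline_age = first$encounter_age,
                    baseline_fev1 = first$fev1pp,
                    stringsAsFactors = FALSE)
  out <- merge(out, cohort$primary, by = "patient_id")
  out <- merge(out, cohort$centers[, c("center_id", "size_category")],
               by = "center_id")
  out <- merge(out, as.data.frame(labels)[, c("patient_id", "fpc1_score", "label")],
               by = "patient_id")
  out <- merge(out, pk, by = "patient_id")
  out[order(out$patient_id), ]
}

#' Center profiles
#'
#' Per-center aggregates: size category, patient count, phenotype
#' prevalences, mean first-component score, and mean (over patients) of
#' the patient-level peak-decline extent and age.
#'
#' @param ptab a [patient_table()].
#' @return data.frame, one row per center.
#' @export
center_profiles <- function(ptab) {
  prev <- prevalence_by_center(ptab, ptab)
  agg <- do.call(rbind, lapply(split(ptab, ptab$center_id), function(d) {
    data.frame(center_id = d$center_id[1],
               size_category = as.character(d$size_category[1]),
               baseline_age = mean(d$baseline_age),
               baseline_fev1 = mean(d$baseline_fev1),
               fpc1_score = mean(d$fpc1_score),
               peak_extent = mean(d$extent),
               peak_age = mean(d$age_at_peak),
               stringsAsFactors = FALSE)
  }))
  out <- merge(prev, agg, by = "center_id")
  out$size_category <- factor(out$size_category,
                              levels = c("small", "medium", "large"))
  rownames(out) <- NULL
  out
}

#' Summary of decline features by center size category
#'
#' For each size category: number of centers (and % of all centers),
#' mean (SD) of patients per center, patients across centers (and % of
#' cohort), and the mean (SD) across centers of the center-level means
#' of baseline age, baseline FEV1, first-component score, phenotype
#' prevalences, and peak-decline extent and age. Centers are weighted
#' equally within a category; the SD is absent (NA) for categories with
#' fewer than two centers.
#'
#' @param profiles a [center_profiles()] data.frame.
#' @return long data.frame: feature, category, mean, sd.
#' @export
summarize_table1 <- function(profiles) {
  feats <- c(baseline_age = "Age at baseline, years",
             baseline_fev1 = "FEV1 at baseline, % predicted",
             fpc1_score = "FPC1 score",
             early = "Early decliners, %",
             middle = "Middle decliners, %",
             late = "Late decliners, %",
             peak_extent = "Peak decline extent, % predicted/year",
             peak_age = "Peak decline age, years")
  n_centers_all <- nrow(profiles)
  n_patients_all <- sum(profiles$n_patients)
  rows <- list()
  for (cat in levels(profiles$size_category)) {
    d <- profiles[profiles$size_category == cat, , drop = FALSE]
    nc <- nrow(d)
    sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      feature = "No. of centers", category = cat,
      mean = nc, sd = NA_real_,
      pct = 100 * nc / n_centers_all, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      feature = "No. of patients per center", category = cat,
      mean = if (nc) mean(d$n_patients) else NA_real_,
      sd = sd_or_na(d$n_patients), pct = NA_real_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      feature = "No. of patients across centers", category = cat,
      mean = sum(d$n_patients), sd = NA_real_,
      pct = 100 * sum(d$n_patients) / n_patients_all, stringsAsFactors = FALSE)
    for (f in names(feats)) {
      rows[[length(rows) + 1]] <- data.frame(
        feature = feats[[f]], category = cat,
        mean = if (nc) mean(d[[f]]) else NA_real_,
        sd = sd_or_na(d[[f]]), pct = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Welch comparisons between center size categories
#'
#' Two-sample Welch (unequal-variance) t-tests of center-level values
#' between each pair of size categories (small-medium, medium-large,
#' small-large), with two-sided p-values and Bonferroni adjustment for
#' the three comparisons (adjusted p = min(1, 3p)).
#'
#' @param values numeric vector of one center-level value per center.
#' @param categories factor/character of size categories, same length.
#' @param variable optional variable name carried into the output.
#' @return data.frame of class `category_comparison`: variable, group1,
#'   group2, t, df, p, p_adj.
#' @export
compare_categories <- function(values, categories, variable = "value") {
  categories <- factor(as.character(categories),
                       levels = c("small", "medium", "large"))
  stopifnot(length(values) == length(categories))
  pairs <- list(c("small", "medium"), c("medium", "large"), c("small", "large"))
  ## pairs with an entirely absent category are not comparable and are
  ## dropped; a category present with a single center is an error
  pairs <- Filter(function(pr) all(table(categories)[pr] > 0), pairs)
  if (length(pairs) == 0) stop("need at least two categories to compare")
  out <- lapply(pairs, function(pr) {
    x <- values[categories == pr[1]]
    y <- values[categories == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need at least 2 centers per compared category (",
           pr[1], " vs ", pr[2], ")")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) {
        tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                   p.value = 1)
      } else stop("zero variance in both groups (", pr[1], " vs ", pr[2], ")")
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    data.frame(variable = variable, group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, 3 * tt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("category_comparison", class(out))
  out
}

#' Write the benchmarking CSV outputs
#'
#' Emits the two analysis data frames handed to the dashboard — the
#' long-format curve table (center, phenotype, age, mean trajectory and
#' mean rate) and the patient table — plus the category summary.
#'
#' @param traj_means output of [center_functional_mean()].
#' @param rate_means output of [center_rate_mean()].
#' @param ptab a [patient_table()].
#' @param table1 a [summarize_table1()] data.frame.
#' @param dir output directory.
#' @export
write_benchmark_tables <- function(traj_means, rate_means, ptab, table1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- merge(traj_means,
                  rate_means[, c("center_id", "phenotype", "age", "mean_rate")],
                  by = c("center_id", "phenotype", "age"))
  curves <- curves[order(curves$center_id, curves$phenotype, curves$age), ]
  utils::write.csv(curves, file.path(dir, "center_curves.csv"), row.names = FALSE)
  utils::write.csv(ptab, file.path(dir, "patient_table.csv"), row.names = FALSE)
  utils::write.csv(table1, file.path(dir, "table1.csv"), row.names = FALSE)
  invisible(dir)
}
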