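test_that("center functional means average curves pointwise", {
  grid <- fpca_grid()
  curves <- cbind(P1 = 90 - 0.5 * (grid - 6),
                  P2 = 95 - 1.0 * (grid - 6),
                  P3 = 85 + sin(grid),
                  P4 = 80 + cos(grid))
  labels <- data.frame(patient_id = paste0("P", 1:4),
                       label = c("early", "early", "early", "middle"))
  primary <- data.frame(patient_id = paste0("P", 1:4),
                        center_id = c("A", "A", "A", "B"))
  out <- center_functional_mean(curves, grid, labels, primary)

  ## three-curve cell: hand-computed pointwise mean at five ages
  cellA <- out[out$center_id == "A" & out$phenotype == "early", ]
  for (a in c(6, 9.75, 13.5, 17.25, 21)) {
    expect_equal(cellA$mean_fev1pp[cellA$age == a],
                 mean(curves[match(a, grid), 1:3]))
  }
  ## single-patient cell equals that patient's curve
  cellB <- out[out$center_id == "B" & out$phenotype == "middle", ]
  expect_equal(cellB$mean_fev1pp, unname(curves[, 4]))
  ## absent cells are absent, not zero
  expect_false(any(out$center_id == "B" & out$phenotype == "late"))

  ## two identical curves average to themselves
  curves2 <- cbind(P1 = curves[, 1], P2 = curves[, 1])
  out2 <- center_functional_mean(curves2, grid,
                                 data.frame(patient_id = c("P1", "P2"),
                                            label = "late"),
                                 data.frame(patient_id = c("P1", "P2"),
                                            center_id = "C"))
  expect_equal(out2$mean_fev1pp, unname(curves[, 1]))
})

test_that("mean of derivatives equals derivative of the mean curve", {
  fx <- fx_dashboard()
  fc <- fitted_curves(fx$mod)
  primary <- fx$coh$primary
  rate <- center_rate_mean(fc$deriv, fx$mod$grid, fx$lab, primary)
  traj <- center_functional_mean(fc$fit, fx$mod$grid, fx$lab, primary)
  cell <- traj[traj$center_id == traj$center_id[1] &
                 traj$phenotype == traj$phenotype[1], ]
  rcell <- rate[rate$center_id == cell$center_id[1] &
                  rate$phenotype == cell$phenotype[1], ]
  ## the natural-spline derivative is linear in the data, so averaging
  ## commutes with differentiation
  d_of_mean <- stats::splinefun(fx$mod$grid, cell$mean_fev1pp,
                                method = "natural")(fx$mod$grid, deriv = 1)
  expect_equal(rcell$mean_rate, d_of_mean, tolerance = 1e-8)
})

test_that("prevalences are percentages that sum to one hundred", {
  labels <- data.frame(patient_id = paste0("P", 1:4),
                       label = c("early", "middle", "middle", "late"))
  primary <- data.frame(patient_id = paste0("P", 1:4), center_id = "A")
  prev <- prevalence_by_center(labels, primary)
  expect_equal(prev$early, 25)
  expect_equal(prev$middle, 50)
  expect_equal(prev$late, 25)

  ## a center without late decliners reports zero, and rows always sum to 100
  labels2 <- data.frame(patient_id = paste0("Q", 1:3),
                        label = c("early", "middle", "middle"))
  primary2 <- data.frame(patient_id = paste0("Q", 1:3), center_id = "B")
  prev2 <- prevalence_by_center(labels2, primary2)
  expect_equal(prev2$late, 0)

  fx <- fx_dashboard()
  prev3 <- prevalence_by_center(fx$lab, fx$coh$primary)
  expect_equal(prev3$early + prev3$middle + prev3$late,
               rep(100, nrow(prev3)), tolerance = 1e-9)
})

test_that("count-weighted cell means reproduce the cohort phenotype mean", {
  fx <- fx_dashboard()
  fc <- fitted_curves(fx$mod)
  traj <- center_functional_mean(fc$fit, fx$mod$grid, fx$lab, fx$coh$primary)
  lab_lookup <- stats::setNames(as.character(fx$lab$label), fx$lab$patient_id)
  for (ph in c("early", "middle", "late")) {
    cohort_mean <- rowMeans(fc$fit[, lab_lookup[colnames(fc$fit)] == ph,
                                   drop = FALSE])
    cells <- traj[traj$phenotype == ph, ]
    num <- tapply(cells$mean_fev1pp * cells$n, cells$age, sum)
    tot <- tapply(cells$n, cells$age, sum)
    weighted <- (num / tot)[as.character(fx$mod$grid)]
    expect_equal(as.numeric(weighted), cohort_mean,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("category summaries average center-level means", {
  profiles <- data.frame(
    center_id = c("A", "B", "C", "D"),
    n_patients = c(10, 20, 60, 200),
    early = c(20, 30, 25, 25), middle = c(50, 50, 50, 50),
    late = c(30, 20, 25, 25),
    size_category = factor(c("small", "small", "medium", "large"),
                           levels = c("small", "medium", "large")),
    baseline_age = c(10, 20, 9, 8.5), baseline_fev1 = c(90, 80, 88, 91),
    fpc1_score = c(1, 2, 0, -1), peak_extent = c(-5, -6, -6.5, -6.2),
    peak_age = c(15, 16, 14.8, 14.9))
  t1 <- summarize_table1(profiles)

  ## two centers with means 10 and 20 -> mean 15, sd ~7.07
  row <- t1[t1$feature == "Age at baseline, years" & t1$category == "small", ]
  expect_equal(row$mean, 15)
  expect_equal(row$sd, sqrt(50), tolerance = 1e-9)

  ## one-center categories have no dispersion to report
  row1 <- t1[t1$feature == "Age at baseline, years" & t1$category == "large", ]
  expect_true(is.na(row1$sd))

  ## patient totals are conserved across categories
  totals <- t1[t1$feature == "No. of patients across centers", ]
  expect_equal(sum(totals$mean), sum(profiles$n_patients))
  expect_equal(sum(totals$pct), 100, tolerance = 1e-9)
})

test_that("Welch comparisons match the textbook formula", {
  values <- c(1, 2, 3, 4, 5, 6)
  cats <- c("small", "small", "small", "medium", "medium", "medium")
  cmp <- compare_categories(values, cats)
  row <- cmp[cmp$group1 == "small" & cmp$group2 == "medium", ]

  ## independent textbook evaluation of the Welch statistic
  x <- values[1:3]; y <- values[4:6]
  se2 <- stats::var(x) / 3 + stats::var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((stats::var(x) / 3)^2 / 2 + (stats::var(y) / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(row$t, t_hand, tolerance = 1e-9)
  expect_equal(row$t, -3.674, tolerance = 1e-3)
  expect_equal(row$df, 4, tolerance = 1e-9)
  expect_equal(row$p, p_hand, tolerance = 1e-9)
  expect_equal(row$p_adj, min(1, 3 * p_hand), tolerance = 1e-12)
})

test_that("degenerate Welch inputs follow the stated rules", {
  ## identical groups: t = 0, adjusted p = 1
  v <- c(5, 6, 7, 5, 6, 7, 5, 6, 7)
  cats <- rep(c("small", "medium", "large"), each = 3)
  cmp <- compare_categories(v, cats)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p_adj == 1))

  ## raw p above 1/3 caps at 1 after the Bonferroni factor
  set.seed(9)
  v2 <- c(rnorm(4), rnorm(4, 0.01), rnorm(4))
  cmp2 <- compare_categories(v2, rep(c("small", "medium", "large"), each = 4))
  expect_true(all(cmp2$p_adj == pmin(1, 3 * cmp2$p)))

  ## zero variance in both groups with different means is an error
  expect_error(compare_categories(c(1, 1, 2, 2, 3, 4),
                                  rep(c("small", "medium", "large"), each = 2)),
               "zero variance")
  ## too few centers in a category is an error
  expect_error(compare_categories(c(1, 2, 3, 4),
                                  c("small", "medium", "medium", "large")),
               "at least 2")
})

test_that("scenario cohorts reproduce the small-center ordering pattern", {
  fx <- fx_scenario()
  ptab <- patient_table(fx$coh, fx$mod, fx$lab)
  prof <- center_profiles(ptab)
  expect_true(all(table(prof$size_category) >= 2))
  t1 <- summarize_table1(prof)
  get <- function(feat) {
    d <- t1[t1$feature == feat, ]
    stats::setNames(d$mean, d$category)
  }
  age <- get("Age at baseline, years")
  fev <- get("FEV1 at baseline, % predicted")
  early <- get("Early decliners, %")
  ext <- get("Peak decline extent, % predicted/year")
  page <- get("Peak decline age, years")

  ## small centers: older patients with lower baseline lung function,
  ## fewer early decliners, milder and later peak decline
  expect_gt(age[["small"]], max(age[c("medium", "large")]))
  expect_lt(fev[["small"]], min(fev[c("medium", "large")]))
  expect_lt(early[["small"]], min(early[c("medium", "large")]))
  expect_gt(ext[["small"]], max(ext[c("medium", "large")]))
  expect_gt(page[["small"]], max(page[c("medium", "large")]))
})

test_that("benchmark tables write the two analysis data frames", {
  fx <- fx_dashboard()
  fc <- fitted_curves(fx$mod)
  traj <- center_functional_mean(fc$fit, fx$mod$grid, fx$lab, fx$coh$primary)
  rate <- center_rate_mean(fc$deriv, fx$mod$grid, fx$lab, fx$coh$primary)
  ptab <- patient_table(fx$coh, fx$mod, fx$lab)
  t1 <- summarize_table1(center_profiles(ptab))
  dir <- withr::local_tempdir()
  write_benchmark_tables(traj, rate, ptab, t1, dir)
  curves <- utils::read.csv(file.path(dir, "center_curves.csv"))
  expect_true(all(c("center_id", "phenotype", "age", "mean_fev1pp", "mean_rate")
                  %in% names(curves)))
  expect_equal(nrow(utils::read.csv(file.path(dir, "patient_table.csv"))),
               nrow(ptab))
  expect_true(file.exists(file.path(dir, "table1.csv")))
})
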