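#' @keywords internal
"_PACKAGE"

#' Default declining population mean curve
#'
#' Smooth logistic decline on the percent-predicted scale: roughly 95
#' at age 6 falling to about 70 at age 21, with the steepest loss
#' (`-drop / (4 * scale)` percent predicted per year, about -6 at the
#' defaults) at `midage`. Differentiable everywhere.
#'
#' @param params list with elements `upper`, `drop`, `midage`, `scale`.
#' @return function of age returning FEV1 percent predicted.
#' @export
make_mean_curve <- function(params = list(upper = 95, drop = 25,
                                          midage = 14, scale = 1)) {
  force(params)
  function(t) params$upper - params$drop / (1 + exp(-(t - params$midage) / params$scale))
}

#' Default principal-component shapes
#'
#' Raw (un-normalised) shapes for the latent components. The first is a
#' smooth downward logistic step centred at age 12.5, so a larger first
#' score produces an earlier and steeper decline; the second is a
#' Gaussian bump near age 14.5 tilting depth against timing. Shapes are
#' orthonormalised on the reference grid before use.
#'
#' @return list of functions of age.
#' @export
default_eigenfunctions <- function() {
  list(
    function(t) -1 / (1 + exp(-(t - 12.5) / 1.5)),
    function(t) exp(-(t - 14.5)^2 / (2 * 1.5^2))
  )
}

# Trapezoid quadrature weights for an equally or unequally spaced grid.
quad_weights <- function(grid) {
  G <- length(grid)
  if (G < 2) stop("grid must have at least 2 points")
  w <- numeric(G)
  d <- diff(grid)
  w[1] <- d[1] / 2
  w[G] <- d[G - 1] / 2
  if (G > 2) w[2:(G - 1)] <- (d[-(G - 1)] + d[-1]) / 2
  w
}

# Gram-Schmidt orthonormalisation of functions under L2 quadrature on a
# fine grid; returns natural-spline interpolants of the orthonormal shapes.
orthonormalize_functions <- function(funs, grid = seq(6, 21, length.out = 601)) {
  w <- quad_weights(grid)
  mat <- vapply(funs, function(f) f(grid), numeric(length(grid)))
  for (k in seq_len(ncol(mat))) {
    v <- mat[, k]
    if (k > 1) {
      for (j in seq_len(k - 1)) v <- v - sum(w * v * mat[, j]) * mat[, j]
    }
    nrm <- sqrt(sum(w * v^2))
    if (nrm < 1e-10) stop("eigenfunction shapes are linearly dependent")
    mat[, k] <- v / nrm
  }
  lapply(seq_len(ncol(mat)), function(k) {
    stats::splinefun(grid, mat[, k], method = "natural")
  })
}

#' Configuration of the synthetic registry generator
#'
#' Collects and validates all parameters of the latent trajectory model
#' \deqn{Y_{ij} = \mu(t_{ij}) + \sum_k \xi_{ik}\phi_k(t_{ij}) + \epsilon_{ij}}
#' and of the registry structure around it (centers of three size
#' classes, annual center designation with occasional transfers,
#' irregular visit ages).
#'
#' @param n_patients number of patients to simulate.
#' @param center_size_mix named proportions of small/medium/large centers;
#'   must sum to 1.
#' @param visits_per_year mean clinic visits (with spirometry) per year of
#'   follow-up; per-year counts are Poisson, visit ages jittered uniformly
#'   within the year.
#' @param age_entry_range range of entry ages (years, inside \[6, 21\]).
#' @param followup_years_range range of follow-up duration (years);
#'   truncated so no encounter exceeds age 21.
#' @param mean_curve_params parameters passed to [make_mean_curve()].
#' @param eigenfunctions list of K raw component shape functions;
#'   orthonormalised internally.
#' @param score_sds K positive, strictly decreasing standard deviations of
#'   the component scores (percent-predicted scale).
#' @param noise_sd measurement-error SD in percent predicted (> 0).
#' @param transfer_prob annual probability that a patient's designated
#'   center changes.
#' @param study_years first and last calendar year of the observation
#'   window.
#' @param center_age_shift named per-size-class shift (years) added to
#'   entry ages; used to build scenario cohorts where e.g. small centers
#'   see older patients.
#' @param center_score_shift named per-size-class shift added to the mean
#'   of the first component score; negative values give milder decline.
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             center_size_mix = c(small = 0.35, medium = 0.45, large = 0.20),
                             visits_per_year = 1.0,
                             age_entry_range = c(6, 8),
                             followup_years_range = c(11, 15),
                             mean_curve_params = list(upper = 95, drop = 25,
                                                      midage = 14, scale = 1),
                             eigenfunctions = default_eigenfunctions(),
                             score_sds = c(25, 10),
                             noise_sd = 5,
                             transfer_prob = 0.02,
                             study_years = c(1997, 2013),
                             center_age_shift = c(small = 0, medium = 0, large = 0),
                             center_score_shift = c(small = 0, medium = 0, large = 0),
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              center_size_mix = center_size_mix,
              visits_per_year = visits_per_year,
              age_entry_range = age_entry_range,
              followup_years_range = followup_years_range,
              mean_curve_params = mean_curve_params,
              eigenfunctions = eigenfunctions,
              score_sds = score_sds,
              noise_sd = noise_sd,
              transfer_prob = transfer_prob,
              study_years = study_years,
              center_age_shift = center_age_shift,
              center_score_shift = center_score_shift,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients < 1) stop("invalid config: n_patients must be >= 1")
  mix <- cfg$center_size_mix
  if (length(mix) != 3 || !all(c("small", "medium", "large") %in% names(mix)))
    stop("invalid config: center_size_mix needs named small/medium/large entries")
  if (abs(sum(mix) - 1) > 1e-8)
    stop("invalid config: center_size_mix must sum to 1")
  if (any(mix < 0)) stop("invalid config: center_size_mix entries must be >= 0")
  if (cfg$visits_per_year <= 0) stop("invalid config: visits_per_year must be > 0")
  aer <- cfg$age_entry_range
  if (length(aer) != 2 || aer[1] > aer[2] || aer[1] < 6 || aer[2] > 21)
    stop("invalid config: age_entry_range must lie within [6, 21]")
  shifted_max <- aer[2] + max(cfg$center_age_shift)
  if (shifted_max > 21)
    stop("invalid config: age_entry_range plus center_age_shift exceeds 21")
  fur <- cfg$followup_years_range
  if (length(fur) != 2 || fur[1] > fur[2] || fur[1] < 0)
    stop("invalid config: followup_years_range must be nonnegative and ordered")
  K <- length(cfg$eigenfunctions)
  if (length(cfg$score_sds) != K)
    stop("invalid config: score_sds length must match eigenfunctions")
  if (K > 0) {
    if (any(cfg$score_sds <= 0))
      stop("invalid config: score_sds must be positive")
    if (K > 1 && any(diff(cfg$score_sds) >= 0))
      stop("invalid config: score_sds must be strictly decreasing")
  }
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (cfg$transfer_prob < 0 || cfg$transfer_prob > 1)
    stop("invalid config: transfer_prob must be in [0, 1]")
  invisible(cfg)
}

#' Generate a synthetic registry cohort
#'
#' Simulates encounter-level records from the latent model held in the
#' config: per-patient smooth true trajectories (declining population
#' mean plus K orthonormal principal-component shapes with independent
#' Gaussian scores), additive i.i.d. Gaussian measurement error,
#' irregular visit ages (Poisson per-year counts, uniform jitter), and an
#' annual center designation with occasional transfers. Patients are
#' nested in small/medium/large centers. Deterministic given the config
#' (which includes the seed).
#'
#' @param config a [generator_config()].
#' @return list with `encounters` (data.frame: patient_id, year,
#'   center_id, encounter_age, fev1pp) and `truth` (class
#'   `synthetic_truth`: per-patient true scores, true quartile labels
#'   from the first score, true primary center, the generating curves on
#'   a reference grid, and the config).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  cfg <- config
  K <- length(cfg$score_sds)

  mu_fun <- make_mean_curve(cfg$mean_curve_params)
  phi_funs <- if (K > 0) orthonormalize_functions(cfg$eigenfunctions) else list()

  ## centers: the number of centers per size class follows the config mix
  ## as closely as the patient budget allows; per-center target patient
  ## counts are drawn to straddle the 30 and 150 category boundaries
  ## (with headroom for downstream cohort filtering), then reconciled so
  ## targets sum exactly to n_patients
  n <- cfg$n_patients
  mix <- cfg$center_size_mix[c("small", "medium", "large")]
  typical <- c(small = 18, medium = 85, large = 210)
  min_band <- c(small = 8, medium = 35, large = 160)
  ncf <- n / sum(mix * typical)
  cnt <- pmax(round(mix * ncf), ifelse(mix > 0, 1L, 0L))
  while (sum(cnt * min_band) > n && sum(cnt) > 1) {
    if (cnt[3] > 0) cnt[3] <- cnt[3] - 1L
    else if (cnt[2] > 0) cnt[2] <- cnt[2] - 1L
    else cnt[1] <- cnt[1] - 1L
  }
  if (sum(cnt) == 0) cnt[1] <- 1L
  targets <- c(round(stats::runif(cnt[1], 10, 26)),
               round(stats::runif(cnt[2], 40, 135)),
               round(stats::runif(cnt[3], 185, 240)))
  categories <- rep(c("small", "medium", "large"), times = cnt)
  targets <- round(targets * n / sum(targets))
  lo <- c(small = 6, medium = 32, large = 155)[categories]
  hi <- c(small = 28, medium = 145, large = Inf)[categories]
  targets <- pmin(pmax(targets, lo), hi)
  drift <- n - sum(targets)
  ord <- order(targets, decreasing = TRUE)
  i <- 0L
  while (drift != 0) {
    c0 <- ord[i %% length(targets) + 1L]
    step <- sign(drift)
    if (targets[c0] + step >= 1) {
      targets[c0] <- targets[c0] + step
      drift <- drift - step
    }
    i <- i + 1L
  }
  n_centers <- length(categories)
  center_ids <- sprintf("C%03d", seq_len(n_centers))
  centers <- data.frame(center_id = center_ids, size_class = categories,
                        target_size = targets, stringsAsFactors = FALSE)

  patient_ids <- sprintf("P%05d", seq_len(n))
  home <- rep.int(seq_len(n_centers), times = targets)
  home_class <- categories[home]

  entry_age <- stats::runif(n, cfg$age_entry_range[1], cfg$age_entry_range[2]) +
    cfg$center_age_shift[home_class]
  followup <- stats::runif(n, cfg$followup_years_range[1], cfg$followup_years_range[2])
  followup <- pmin(followup, 21 - entry_age)

  max_entry_year <- cfg$study_years[2] - ceiling(followup)
  entry_year <- cfg$study_years[1] +
    floor(stats::runif(n) * pmax(1, max_entry_year - cfg$study_years[1] + 1))

  scores <- matrix(0, n, max(K, 1))
  if (K > 0) {
    for (k in seq_len(K)) scores[, k] <- stats::rnorm(n, 0, cfg$score_sds[k])
    scores[, 1] <- scores[, 1] + cfg$center_score_shift[home_class]
  }
  colnames(scores) <- paste0("xi", seq_len(ncol(scores)))
  rownames(scores) <- patient_ids

  rec <- vector("list", n)
  for (i in seq_len(n)) {
    fu <- followup[i]
    n_years <- ceiling(fu)
    if (n_years < 1) { rec[[i]] <- NULL; next }
    ages <- numeric(0)
    years <- integer(0)
    for (y in seq_len(n_years) - 1L) {
      frac <- min(1, fu - y)
      m <- stats::rpois(1, cfg$visits_per_year * frac)
      if (m > 0) {
        a <- entry_age[i] + y + sort(stats::runif(m)) * frac
        ages <- c(ages, a)
        years <- c(years, rep.int(entry_year[i] + y, m))
      }
    }
    if (length(ages) == 0) { rec[[i]] <- NULL; next }
    ## annual center designation: start at the home center, transfer with
    ## prob transfer_prob at each year boundary
    ctr_by_year <- integer(n_years)
    ctr_by_year[1] <- home[i]
    if (n_years > 1) {
      for (y in 2:n_years) {
        if (stats::runif(1) < cfg$transfer_prob && n_centers > 1) {
          ## destination proportional to center size (larger programmes
          ## receive more transfers), never the current center
          cand <- setdiff(seq_len(n_centers), ctr_by_year[y - 1])
          ctr_by_year[y] <- cand[sample.int(length(cand), 1,
                                            prob = targets[cand])]
        } else ctr_by_year[y] <- ctr_by_year[y - 1]
      }
    }
    yr_idx <- years - entry_year[i] + 1L
    latent <- mu_fun(ages)
    if (K > 0) {
      for (k in seq_len(K)) latent <- latent + scores[i, k] * phi_funs[[k]](ages)
    }
    y_obs <- latent + stats::rnorm(length(ages), 0, cfg$noise_sd)
    rec[[i]] <- data.frame(patient_id = patient_ids[i],
                           year = years,
                           center_id = center_ids[ctr_by_year[yr_idx]],
                           encounter_age = ages,
                           fev1pp = pmax(y_obs, 1),
                           stringsAsFactors = FALSE)
  }
  encounters <- do.call(rbind, rec)
  rownames(encounters) <- NULL

  ref_grid <- fpca_grid()
  phi_mat <- if (K > 0) vapply(phi_funs, function(f) f(ref_grid), numeric(length(ref_grid)))
             else matrix(0, length(ref_grid), 0)

  true_label <- rep("middle", n)
  if (K > 0 && n >= 4) {
    q <- stats::quantile(scores[, 1], c(0.25, 0.75), type = 7)
    true_label[scores[, 1] < q[1]] <- "late"
    true_label[scores[, 1] > q[2]] <- "early"
  }

  truth <- structure(list(
    patients = data.frame(patient_id = patient_ids,
                          primary_center = center_ids[home],
                          size_class = home_class,
                          entry_age = entry_age,
                          followup_years = followup,
                          true_label = true_label,
                          stringsAsFactors = FALSE),
    scores = scores[, seq_len(K), drop = FALSE],
    centers = centers,
    grid = ref_grid,
    mu = mu_fun(ref_grid),
    phi = phi_mat,
    lambda = cfg$score_sds^2,
    noise_sd = cfg$noise_sd,
    mu_fun = mu_fun,
    phi_funs = phi_funs,
    config = cfg
  ), class = "synthetic_truth")

  list(encounters = encounters, truth = truth)
}

#' Evaluate a patient's true (noiseless) trajectory
#'
#' @param truth a `synthetic_truth` object from [generate_cohort()].
#' @param patient_id patient identifier present in the truth.
#' @param grid ages at which to evaluate.
#' @return numeric vector of FEV1 percent predicted, `mu + sum_k xi_k phi_k`.
#' @export
true_trajectory <- function(truth, patient_id, grid = truth$grid) {
  stopifnot(inherits(truth, "synthetic_truth"))
  i <- match(patient_id, truth$patients$patient_id)
  if (is.na(i)) stop("unknown patient: ", patient_id)
  y <- truth$mu_fun(grid)
  K <- length(truth$phi_funs)
  if (K > 0) {
    for (k in seq_len(K)) y <- y + truth$scores[i, k] * truth$phi_funs[[k]](grid)
  }
  y
}

#' True derivative of a patient's latent trajectory
#'
#' Central finite differences of [true_trajectory()] on a fine grid;
#' used as the oracle for peak-decline recovery.
#'
#' @inheritParams true_trajectory
#' @return numeric vector of derivatives (percent predicted per year).
#' @export
true_derivative <- function(truth, patient_id, grid = truth$grid) {
  h <- 1e-4
  (true_trajectory(truth, patient_id, grid + h) -
     true_trajectory(truth, patient_id, grid - h)) / (2 * h)
}

#' Write / read encounter tables
#'
#' CSV dialect used throughout the pipeline, with header
#' `patient_id, year, center_id, encounter_age, fev1pp`.
#'
#' @param encounters encounter data.frame.
#' @param path file path.
#' @export
write_encounters <- function(encounters, path) {
  need <- c("patient_id", "year", "center_id", "encounter_age", "fev1pp")
  stopifnot(all(need %in% names(encounters)))
  utils::write.csv(encounters[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_encounters
#' @export
read_encounters <- function(path) {
  enc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "year", "center_id", "encounter_age", "fev1pp")
  if (!all(need %in% names(enc)))
    stop("encounter file lacks required columns: ",
         paste(setdiff(need, names(enc)), collapse = ", "))
  enc
}

#' Write generator ground truth
#'
#' Patient-level truth as CSV plus a key-value text sidecar holding the
#' generating parameters and the reference-grid curves.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- cbind(truth$patients, as.data.frame(truth$scores))
  utils::write.csv(pt, file.path(dir, "truth_patients.csv"), row.names = FALSE)
  curves <- data.frame(age = truth$grid, mu = truth$mu)
  if (ncol(truth$phi) > 0) {
    colnames(truth$phi) <- paste0("phi", seq_len(ncol(truth$phi)))
    curves <- cbind(curves, truth$phi)
  }
  utils::write.csv(curves, file.path(dir, "truth_curves.csv"), row.names = FALSE)
  meta <- c(
    sprintf("n_patients=%d", truth$config$n_patients),
    sprintf("noise_sd=%g", truth$noise_sd),
    sprintf("score_sds=%s", paste(truth$config$score_sds, collapse = ",")),
    sprintf("seed=%d", truth$config$seed),
    sprintf("transfer_prob=%g", truth$config$transfer_prob)
  )
  writeLines(meta, file.path(dir, "truth_meta.txt"))
  invisible(dir)
}
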