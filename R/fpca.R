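#' Reference age grid
#'
#' All fitted curves are reported on an equally spaced grid spanning the
#' analysis age window; the default is 61 points on \[6, 21\] (0.25-year
#' step).
#'
#' @param age_min,age_max window boundaries (years).
#' @param length number of grid points.
#' @return numeric vector of ages.
#' @export
fpca_grid <- function(age_min = 6, age_max = 21, length = 61) {
  seq(age_min, age_max, length.out = length)
}

#' Estimate the population mean curve
#'
#' Penalised cubic smoothing spline (GCV-selected smoothness unless
#' `spar` is given) fitted to the pooled (age, FEV1) scatter across all
#' patients, evaluated on the grid.
#'
#' @param records encounter data.frame.
#' @param grid evaluation ages; must lie inside the observed age range.
#' @param spar optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` selects by GCV.
#' @param max_extrapolation how far (years) the grid may extend beyond
#'   the observed age range before fitting is refused; cohort visit ages
#'   rarely land exactly on the window boundaries, so a small margin of
#'   spline extrapolation at the edges is tolerated.
#' @return numeric vector, mean FEV1 percent predicted on `grid`.
#' @export
estimate_mean <- function(records, grid = fpca_grid(), spar = NULL,
                          max_extrapolation = 1) {
  x <- records$encounter_age
  y <- records$fev1pp
  if (length(unique(x)) < 2) stop("need at least 2 distinct ages")
  if (min(grid) < min(x) - max_extrapolation ||
      max(grid) > max(x) + max_extrapolation)
    stop("grid extends outside the observed age range")
  if (stats::sd(y) < 1e-12) return(rep(y[1], length(grid)))
  fit <- if (is.null(spar)) stats::smooth.spline(x, y, cv = FALSE)
         else stats::smooth.spline(x, y, spar = spar)
  as.numeric(stats::predict(fit, grid)$y)
}

# Linear interpolation of a grid curve at arbitrary ages (rule = 2 keeps
# boundary values for ages marginally outside the grid).
interp_curve <- function(grid, values, ages) {
  stats::approx(grid, values, xout = ages, rule = 2)$y
}

#' Estimate the covariance surface and measurement-error variance
#'
#' Raw covariances are the products of within-patient residual pairs at
#' distinct ages; same-point pairs are excluded so the white measurement
#' error does not contaminate the smooth surface. The off-diagonal cloud
#' is smoothed with a tensor-product spline surface (REML smoothness).
#' The error variance is the average gap, over the central half of the
#' age window, between a 1-d smooth of the raw squared residuals (the
#' raw diagonal, which includes the noise) and the diagonal of the
#' smoothed surface (which does not), truncated at zero.
#'
#' @param records encounter data.frame.
#' @param mean_curve mean on `grid` (from [estimate_mean()]).
#' @param grid evaluation ages.
#' @param k per-margin basis dimension of the tensor-product smooth.
#' @return list: `surface` (G x G, symmetric), `raw_diag` (smoothed raw
#'   variance on the grid), `sigma2` (error variance), `n_pairs`.
#' @export
estimate_covariance <- function(records, mean_curve, grid = fpca_grid(), k = 8) {
  resid <- records$fev1pp - interp_curve(grid, mean_curve, records$encounter_age)
  by_pat <- split(data.frame(t = records$encounter_age, r = resid),
                  records$patient_id)
  pairs <- lapply(by_pat, function(d) {
    m <- nrow(d)
    if (m < 2) return(NULL)
    idx <- expand.grid(j = seq_len(m), l = seq_len(m))
    idx <- idx[idx$j != idx$l, ]
    data.frame(s = d$t[idx$j], t = d$t[idx$l], c = d$r[idx$j] * d$r[idx$l])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no within-patient pairs: every patient has a single visit")

  big <- nrow(pairs) > 30000
  form <- c ~ te(s, t, k = c(k, k))
  fit <- if (big) mgcv::bam(form, data = pairs, method = "fREML", discrete = TRUE)
         else mgcv::gam(form, data = pairs, method = "REML")
  gg <- expand.grid(s = grid, t = grid)
  surf <- matrix(as.numeric(mgcv::predict.gam(fit, newdata = gg)),
                 length(grid), length(grid))
  surf <- (surf + t(surf)) / 2

  ## raw diagonal: smooth of squared residuals over age
  vfit <- stats::smooth.spline(records$encounter_age, resid^2, cv = FALSE)
  raw_diag <- as.numeric(stats::predict(vfit, grid)$y)

  rng <- range(grid)
  central <- grid >= rng[1] + 0.25 * diff(rng) & grid <= rng[1] + 0.75 * diff(rng)
  sigma2 <- max(0, mean(raw_diag[central] - diag(surf)[central]))

  list(surface = surf, raw_diag = raw_diag, sigma2 = sigma2,
       n_pairs = nrow(pairs))
}

#' Eigendecompose a covariance surface
#'
#' Quadrature-weighted (trapezoid) eigen-analysis: eigenfunctions are
#' normalised to unit L2 norm on the grid and eigenvalues carry the
#' integral scaling. Negative eigenvalues are truncated to zero.
#'
#' @param surface symmetric G x G covariance matrix on `grid`.
#' @param grid evaluation ages.
#' @param K number of components to return (at most G).
#' @return list: `phi` (G x K matrix), `lambda` (length K, descending,
#'   nonnegative), `lambda_all` (all truncated eigenvalues, for
#'   variance-fraction computations).
#' @export
eigendecompose <- function(surface, grid = fpca_grid(), K = 2) {
  G <- length(grid)
  stopifnot(nrow(surface) == G, ncol(surface) == G)
  if (K > G) stop("K cannot exceed the grid size")
  if (max(abs(surface - t(surface))) > 1e-8)
    stop("covariance surface must be symmetric")
  w <- quad_weights(grid)
  sw <- sqrt(w)
  A <- sweep(sweep(surface, 1, sw, "*"), 2, sw, "*")
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda_all <- pmax(eg$values, 0)
  phi <- sweep(eg$vectors[, seq_len(K), drop = FALSE], 1, sw, "/")
  ## unit quadrature norm (already implied, enforce numerically)
  for (j in seq_len(K)) {
    nrm <- sqrt(sum(w * phi[, j]^2))
    if (nrm > 0) phi[, j] <- phi[, j] / nrm
  }
  list(phi = phi, lambda = lambda_all[seq_len(K)], lambda_all = lambda_all)
}

#' Predict principal-component scores for one patient
#'
#' Conditional-expectation (BLUP) scoring for sparse data:
#' \deqn{\hat\xi_i = \Lambda \Phi_i^\top (\Phi_i \Lambda \Phi_i^\top +
#' \hat\sigma^2 I)^{-1} (Y_i - \hat\mu_i)}
#' where \eqn{\Phi_i} holds the eigenfunctions linearly interpolated at
#' the patient's visit ages. The error variance is floored at 1e-8 in
#' the solve; if the system is still numerically singular a small ridge
#' is added with a warning.
#'
#' @param model an `fpca_model` (or a list with `grid`, `mu`, `phi`,
#'   `lambda`, `sigma2`).
#' @param ages visit ages.
#' @param values observed FEV1 percent predicted at those ages.
#' @return numeric score vector of length K.
#' @export
predict_scores <- function(model, ages, values) {
  stopifnot(length(ages) == length(values), length(ages) >= 1)
  K <- length(model$lambda)
  Phi <- vapply(seq_len(K),
                function(k) interp_curve(model$grid, model$phi[, k], ages),
                numeric(length(ages)))
  Phi <- matrix(Phi, nrow = length(ages), ncol = K)
  r <- values - interp_curve(model$grid, model$mu, ages)
  Lam <- diag(model$lambda, K)
  s2 <- max(model$sigma2, 1e-8)
  M <- Phi %*% Lam %*% t(Phi) + diag(s2, length(ages))
  sol <- tryCatch(solve(M, r), error = function(e) {
    warning("near-singular scoring system; adding ridge")
    solve(M + diag(1e-6 * mean(diag(M)), nrow(M)), r)
  })
  as.numeric(Lam %*% t(Phi) %*% sol)
}

# Score every patient in a record set against a fitted model.
predict_scores_all <- function(model, records) {
  by_pat <- split(records[, c("encounter_age", "fev1pp")], records$patient_id)
  out <- t(vapply(by_pat,
                  function(d) predict_scores(model, d$encounter_age, d$fev1pp),
                  numeric(length(model$lambda))))
  out <- matrix(out, nrow = length(by_pat), ncol = length(model$lambda),
                dimnames = list(names(by_pat),
                                paste0("xi", seq_len(length(model$lambda)))))
  out
}

#' Fit sparse FPCA to irregular longitudinal data
#'
#' Orchestrates mean smoothing, covariance-surface smoothing,
#' quadrature eigendecomposition, component-number selection by the
#' fraction of variance explained, conditional-expectation scoring of
#' every patient, and sign orientation of the components (larger first
#' score = more rapid decline). Fitting is fully deterministic.
#'
#' @param records filtered encounter data.frame (see [build_cohort()]).
#' @param grid reference age grid.
#' @param K fixed number of components, or `NULL` to choose the smallest
#'   K whose cumulative eigenvalue fraction reaches `pve`.
#' @param pve fraction-of-variance threshold used when `K` is `NULL`.
#' @param mean_spar optional fixed smoothing parameter for the mean.
#' @param cov_k per-margin basis dimension of the covariance smooth.
#' @return object of class `fpca_model` with elements `grid`, `mu`,
#'   `phi`, `lambda`, `lambda_all`, `sigma2`, `scores`, `pve`, `K`,
#'   `settings`.
#' @export
fit_fpca <- function(records, grid = fpca_grid(), K = NULL, pve = 0.90,
                     mean_spar = NULL, cov_k = 8) {
  mu <- estimate_mean(records, grid, spar = mean_spar)
  cov <- estimate_covariance(records, mu, grid, k = cov_k)
  Kmax <- min(10, length(grid))
  eig <- eigendecompose(cov$surface, grid, Kmax)
  tot <- sum(eig$lambda_all)
  fve <- if (tot > 0) cumsum(eig$lambda_all) / tot else rep(1, Kmax)
  Ksel <- if (is.null(K)) max(1L, which(fve >= pve)[1]) else as.integer(K)
  if (is.na(Ksel)) Ksel <- Kmax
  model <- structure(list(
    grid = grid,
    mu = mu,
    phi = eig$phi[, seq_len(Ksel), drop = FALSE],
    lambda = eig$lambda[seq_len(Ksel)],
    lambda_all = eig$lambda_all,
    sigma2 = cov$sigma2,
    raw_diag = cov$raw_diag,
    fve = fve[seq_len(Ksel)],
    K = Ksel,
    settings = list(pve = pve, K_fixed = !is.null(K), mean_spar = mean_spar,
                    cov_k = cov_k, quantile_type = 7)
  ), class = "fpca_model")
  model$scores <- predict_scores_all(model, records)
  orient_components(model)
}

#' Orient component signs
#'
#' Flips the sign of the first eigenfunction/score pair, if needed, so
#' that the correlation between the first score and each patient's
#' fitted total change over the age window is negative: a higher first
#' score then always means greater (more rapid) decline. Higher-order
#' components get a fixed convention (nonnegative integral) so refits
#' are reproducible. Reconstructions are invariant to these sign flips.
#'
#' @param model an `fpca_model`.
#' @return the model, possibly with flipped signs.
#' @export
orient_components <- function(model) {
  stopifnot(inherits(model, "fpca_model"))
  G <- length(model$grid)
  K <- model$K
  n <- nrow(model$scores)
  dphi <- model$phi[G, ] - model$phi[1, ]
  if (n >= 2 && stats::sd(model$scores[, 1]) > 0) {
    total_change <- as.numeric(model$scores %*% dphi)
    if (stats::sd(total_change) > 0) {
      if (stats::cor(model$scores[, 1], total_change) > 0) {
        model$phi[, 1] <- -model$phi[, 1]
        model$scores[, 1] <- -model$scores[, 1]
      }
    } else if (dphi[1] > 0) {
      model$phi[, 1] <- -model$phi[, 1]
      model$scores[, 1] <- -model$scores[, 1]
    }
  } else {
    warning("zero-variance scores; component orientation left unchanged")
  }
  if (K > 1) {
    w <- quad_weights(model$grid)
    for (k in 2:K) {
      if (sum(w * model$phi[, k]) < 0) {
        model$phi[, k] <- -model$phi[, k]
        model$scores[, k] <- -model$scores[, k]
      }
    }
  }
  model
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("Sparse FPCA model: %d patients, K = %d components\n",
              nrow(x$scores), x$K))
  cat(sprintf("  eigenvalues: %s\n", paste(signif(x$lambda, 4), collapse = ", ")))
  cat(sprintf("  error variance: %.3f  (SD %.2f %% predicted)\n",
              x$sigma2, sqrt(x$sigma2)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$fve), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a patient's fitted curve and rate of change
#'
#' The fitted trajectory is the exact reconstruction
#' \eqn{\hat f_i = \hat\mu + \sum_k \hat\xi_{ik}\hat\phi_k} on the grid
#' (the smooth curve standing for true lung function without measurement
#' error). The rate-of-change curve is the derivative of a natural-spline
#' interpolant of the reconstruction.
#'
#' @param model an `fpca_model`.
#' @param patient_id patient with scores in the model.
#' @return list of class `fitted_curve`: `patient_id`, `grid`, `fit`,
#'   `deriv` (percent predicted per year).
#' @export
fitted_curve <- function(model, patient_id) {
  i <- match(patient_id, rownames(model$scores))
  if (is.na(i)) stop("unknown patient: ", patient_id)
  fit <- model$mu + as.numeric(model$phi %*% model$scores[i, ])
  sf <- stats::splinefun(model$grid, fit, method = "natural")
  structure(list(patient_id = patient_id, grid = model$grid, fit = fit,
                 deriv = sf(model$grid, deriv = 1)),
            class = "fitted_curve")
}

#' All fitted curves (and derivatives) as matrices
#'
#' @param model an `fpca_model`.
#' @return list with `fit` and `deriv`, each a G x n matrix with patient
#'   ids as column names.
#' @export
fitted_curves <- function(model) {
  ids <- rownames(model$scores)
  fit <- model$phi %*% t(model$scores) + model$mu
  deriv <- apply(fit, 2, function(y) {
    stats::splinefun(model$grid, y, method = "natural")(model$grid, deriv = 1)
  })
  colnames(fit) <- ids
  colnames(deriv) <- ids
  list(fit = fit, deriv = deriv)
}

#' Export / import a fitted model as plain-text files
#'
#' Writes the grid+mean+eigenfunctions as one CSV, per-patient scores as
#' another, and scalar metadata (eigenvalues, error variance, settings)
#' as a key-value text file; `import_fpca_model` reads them back.
#'
#' @param model an `fpca_model`.
#' @param dir directory to write into (created if needed).
#' @export
export_fpca_model <- function(model, dir) {
  stopifnot(inherits(model, "fpca_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- data.frame(age = model$grid, mu = model$mu)
  phi <- model$phi
  colnames(phi) <- paste0("phi", seq_len(ncol(phi)))
  utils::write.csv(cbind(curves, phi), file.path(dir, "model_curves.csv"),
                   row.names = FALSE)
  scores <- data.frame(patient_id = rownames(model$scores), model$scores,
                       stringsAsFactors = FALSE)
  utils::write.csv(scores, file.path(dir, "model_scores.csv"), row.names = FALSE)
  meta <- c(
    sprintf("K=%d", model$K),
    sprintf("lambda=%s", paste(format(model$lambda, digits = 17), collapse = ",")),
    sprintf("sigma2=%s", format(model$sigma2, digits = 17)),
    sprintf("fve=%s", paste(format(model$fve, digits = 17), collapse = ",")),
    sprintf("quantile_type=%d", model$settings$quantile_type)
  )
  writeLines(meta, file.path(dir, "model_meta.txt"))
  invisible(dir)
}

#' @rdname export_fpca_model
#' @export
import_fpca_model <- function(dir) {
  curves <- utils::read.csv(file.path(dir, "model_curves.csv"))
  scores <- utils::read.csv(file.path(dir, "model_scores.csv"),
                            stringsAsFactors = FALSE)
  meta <- readLines(file.path(dir, "model_meta.txt"))
  getval <- function(key) sub(paste0("^", key, "="), "",
                              meta[startsWith(meta, paste0(key, "="))])
  K <- as.integer(getval("K"))
  sc <- as.matrix(scores[, paste0("xi", seq_len(K)), drop = FALSE])
  rownames(sc) <- scores$patient_id
  lambda <- as.numeric(strsplit(getval("lambda"), ",")[[1]])
  structure(list(
    grid = curves$age,
    mu = curves$mu,
    phi = as.matrix(curves[, paste0("phi", seq_len(K)), drop = FALSE]),
    lambda = lambda,
    lambda_all = lambda,
    sigma2 = as.numeric(getval("sigma2")),
    fve = as.numeric(strsplit(getval("fve"), ",")[[1]]),
    K = K,
    scores = sc,
    settings = list(quantile_type = as.integer(getval("quantile_type")))
  ), class = "fpca_model")
}
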