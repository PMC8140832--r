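test_that("mean estimation reproduces constants and straight lines", {
  ages <- rep(seq(6, 21, length.out = 40), 5)
  const <- data.frame(patient_id = rep(sprintf("P%d", 1:5), each = 40),
                      encounter_age = ages, fev1pp = 87)
  expect_equal(estimate_mean(const), rep(87, 61), tolerance = 1e-9)

  lin <- const
  lin$fev1pp <- 100 - 1.2 * lin$encounter_age + rep(rnorm(5, 0, 0), each = 40)
  mu <- estimate_mean(lin)
  expect_lt(max(abs(mu - (100 - 1.2 * fpca_grid()))), 1e-3)

  narrow <- data.frame(patient_id = "P1", encounter_age = c(8, 9, 10),
                       fev1pp = c(90, 88, 86))
  expect_error(estimate_mean(narrow), "outside the observed age range")
})

test_that("covariance estimation separates signal surface from noise", {
  grid <- fpca_grid()

  ## single-component noiseless cohort: surface is Var(xi) phi phi^T
  cfg <- generator_config(n_patients = 150,
                          eigenfunctions = list(function(t) -1 / (1 + exp(-(t - 12.5) / 1.5))),
                          score_sds = 8, noise_sd = 0, visits_per_year = 4,
                          seed = 2)
  gen <- generate_cohort(cfg)
  coh <- build_cohort(gen$encounters)
  mu <- estimate_mean(coh$encounters, grid)
  cv <- estimate_covariance(coh$encounters, mu, grid)
  ids <- unique(coh$encounters$patient_id)
  target <- gen$truth$phi %*% matrix(stats::var(gen$truth$scores[ids, 1])) %*%
    t(gen$truth$phi)
  expect_lt(norm(cv$surface - target, "F") / norm(target, "F"), 0.15)
  expect_lt(cv$sigma2, 0.5)
  expect_identical(cv$surface, t(cv$surface))

  ## pure-noise cohort: flat surface, sigma2 recovers the noise variance
  cfg0 <- generator_config(n_patients = 150, eigenfunctions = list(),
                           score_sds = numeric(0), noise_sd = 5,
                           visits_per_year = 4, seed = 2)
  gen0 <- generate_cohort(cfg0)
  coh0 <- build_cohort(gen0$encounters)
  mu0 <- estimate_mean(coh0$encounters, grid)
  cv0 <- estimate_covariance(coh0$encounters, mu0, grid)
  expect_lt(max(abs(cv0$surface)), 2)
  expect_lt(abs(cv0$sigma2 - 25) / 25, 0.25)

  ## no within-patient pairs at all
  singles <- data.frame(patient_id = c("A", "B"), encounter_age = c(8, 9),
                        fev1pp = c(90, 85))
  expect_error(estimate_covariance(singles, rep(90, 61), grid), "single visit")
})

test_that("eigendecomposition satisfies the rank-1 and trace identities", {
  grid <- fpca_grid()
  w <- diff(grid)[1]
  phi <- sin(pi * (grid - 6) / 15)
  phi <- phi / sqrt(sum(w * phi^2))
  surface <- 7.5 * outer(phi, phi)
  eig <- eigendecompose(surface, grid, K = 3)
  expect_equal(eig$lambda[1], 7.5, tolerance = 1e-6)
  expect_lt(min(max(abs(eig$phi[, 1] - phi)), max(abs(eig$phi[, 1] + phi))), 1e-6)
  expect_lt(eig$lambda[2], 1e-8)

  ## trace identity: on a PSD surface the eigenvalue mass cannot exceed
  ## the integrated diagonal
  wq0 <- declinefpca:::quad_weights(grid)
  psi <- cos(2 * pi * (grid - 6) / 15)
  psi <- psi - sum(wq0 * psi * phi) * phi / sum(wq0 * phi^2)
  psi <- psi / sqrt(sum(wq0 * psi^2))
  surf2 <- 7.5 * outer(phi, phi) + 2 * outer(psi, psi)
  eig2 <- eigendecompose(surf2, grid, K = 5)
  wq <- declinefpca:::quad_weights(grid)
  expect_lte(sum(eig2$lambda_all), sum(wq * diag(surf2)) + 1e-6)
  expect_equal(sort(eig2$lambda[1:2], decreasing = TRUE), c(7.5, 2),
               tolerance = 1e-6)

  expect_error(eigendecompose(surface, grid, K = 100), "exceed")
  expect_error(eigendecompose(surface + matrix(rnorm(61 * 61), 61), grid, 2),
               "symmetric")
})

test_that("score prediction matches the closed form and its limits", {
  grid <- fpca_grid()
  ## hand-evaluated single-visit case: lambda=4, sigma2=1, phi(t0)=0.5,
  ## residual 2 -> xi = 4*0.5*2 / (0.25*4 + 1) = 2
  model <- list(grid = grid, mu = rep(0, 61),
                phi = matrix(0.5, 61, 1), lambda = 4, sigma2 = 1)
  expect_equal(predict_scores(model, ages = 10, values = 2), 2, tolerance = 1e-12)

  ## zero residual gives zero scores
  fx <- fx_default()
  p <- rownames(fx$mod$scores)[5]
  ages <- c(8, 11, 14, 17)
  mu_at <- approx(fx$mod$grid, fx$mod$mu, ages)$y
  expect_equal(predict_scores(fx$mod, ages, mu_at), c(0, 0),
               tolerance = 1e-10, ignore_attr = TRUE)

  ## vanishing noise with dense visits: scores converge to the ordinary
  ## least-squares projection of residuals on the eigenfunctions
  w <- diff(grid)[1]
  phi1 <- sin(pi * (grid - 6) / 15); phi1 <- phi1 / sqrt(sum(w * phi1^2))
  phi2 <- cos(pi * (grid - 6) / 15); phi2 <- phi2 - sum(w * phi2 * phi1) * phi1
  phi2 <- phi2 / sqrt(sum(w * phi2^2))
  model2 <- list(grid = grid, mu = rep(0, 61), phi = cbind(phi1, phi2),
                 lambda = c(9, 4), sigma2 = 1e-8)
  ages2 <- grid[seq(1, 61, by = 3)]
  Phi <- cbind(approx(grid, phi1, ages2)$y, approx(grid, phi2, ages2)$y)
  xi_true <- c(2.3, -1.1)
  y <- as.numeric(Phi %*% xi_true)
  ols <- solve(crossprod(Phi), crossprod(Phi, y))
  expect_equal(predict_scores(model2, ages2, y), as.numeric(ols), tolerance = 1e-4)
})

test_that("scores equal a brute-force joint-Gaussian conditional mean", {
  fx <- fx_default()
  mod <- fx$mod
  enc <- fx$coh$encounters
  ids <- rownames(mod$scores)[seq(1, 400, by = 50)]
  for (p in ids) {
    d <- enc[enc$patient_id == p, ]
    d <- d[seq_len(min(5, nrow(d))), ]
    ## oracle: assemble the full joint covariance of (xi, Y) and apply the
    ## generic conditional-mean formula
    Phi <- vapply(seq_len(mod$K),
                  function(k) approx(mod$grid, mod$phi[, k],
                                     d$encounter_age, rule = 2)$y,
                  numeric(nrow(d)))
    Lam <- diag(mod$lambda)
    S11 <- Lam
    S12 <- Lam %*% t(Phi)
    S22 <- Phi %*% Lam %*% t(Phi) + diag(max(mod$sigma2, 1e-8), nrow(d))
    r <- d$fev1pp - approx(mod$grid, mod$mu, d$encounter_age, rule = 2)$y
    oracle <- as.numeric(S12 %*% solve(S22, r))
    expect_equal(predict_scores(mod, d$encounter_age, d$fev1pp), oracle,
                 tolerance = 1e-8)
  }
})

test_that("fitting selects the true component count and is deterministic", {
  fx <- fx_default()
  expect_equal(fx$mod$K, 2)
  refit <- fit_fpca(fx$coh$encounters)
  expect_equal(refit$phi, fx$mod$phi, tolerance = 1e-12)
  expect_equal(refit$scores, fx$mod$scores, tolerance = 1e-12)

  ## residual-based scores are centred
  s1 <- fx$mod$scores[, 1]
  expect_lt(abs(mean(s1)), 0.05 * stats::sd(s1))
})

test_that("orientation makes higher first scores mean faster decline", {
  fx <- fx_default()
  mod <- fx$mod
  G <- length(mod$grid)
  total_change <- as.numeric(mod$scores %*% (mod$phi[G, ] - mod$phi[1, ]))
  expect_lt(stats::cor(mod$scores[, 1], total_change), 0)

  ## idempotence
  expect_equal(orient_components(mod)$phi, mod$phi)

  ## sign flips leave reconstructions unchanged and are undone
  flipped <- mod
  flipped$phi[, 1] <- -flipped$phi[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  back <- orient_components(flipped)
  expect_equal(back$phi, mod$phi)
  p <- rownames(mod$scores)[3]
  expect_equal(fitted_curve(back, p)$fit, fitted_curve(mod, p)$fit)
})

test_that("eigenfunctions are orthonormal and reconstructions exact", {
  fx <- fx_default()
  mod <- fx$mod
  w <- declinefpca:::quad_weights(mod$grid)
  gram <- t(mod$phi) %*% (w * mod$phi)
  expect_lt(max(abs(gram - diag(mod$K))), 1e-6)

  p <- rownames(mod$scores)[10]
  fc <- fitted_curve(mod, p)
  manual <- mod$mu + as.numeric(mod$phi %*% mod$scores[p, ])
  expect_identical(fc$fit, manual)
  expect_error(fitted_curve(mod, "nobody"), "unknown patient")
})

test_that("derivatives agree with central finite differences", {
  fx <- fx_default()
  mod <- fx$mod
  ## fine-step differences of the interpolant; the coarse 0.25-year grid
  ## step carries visible h^2 truncation error for the steepest curves
  h <- 0.05
  interior <- mod$grid[2:(length(mod$grid) - 1)]
  for (p in rownames(mod$scores)[c(2, 50, 200)]) {
    fc <- fitted_curve(mod, p)
    sf <- stats::splinefun(mod$grid, fc$fit, method = "natural")
    central <- (sf(interior + h) - sf(interior - h)) / (2 * h)
    expect_lt(max(abs(sf(interior, deriv = 1) - central)), 0.1)
    expect_equal(sf(interior, deriv = 1),
                 fc$deriv[2:(length(mod$grid) - 1)], tolerance = 1e-10)
  }
})

test_that("fitted curves recover true trajectories at low noise", {
  fx <- fx_lownoise()
  interior <- fx$mod$grid >= 7 & fx$mod$grid <= 20
  errs <- vapply(rownames(fx$mod$scores), function(p) {
    max(abs((fitted_curve(fx$mod, p)$fit -
               true_trajectory(fx$gen$truth, p, fx$mod$grid))[interior]))
  }, numeric(1))
  expect_lt(median(errs), 2)
  expect_gt(mean(errs < 3), 0.9)
})

test_that("visit-level residuals are centred with variance near sigma2", {
  fx <- fx_default()
  fc <- fitted_curves(fx$mod)
  enc <- fx$coh$encounters
  fitted_at <- mapply(function(p, a) approx(fx$mod$grid, fc$fit[, p], a, rule = 2)$y,
                      enc$patient_id, enc$encounter_age)
  res <- enc$fev1pp - fitted_at
  expect_lt(abs(mean(res)), 0.2)
  expect_lt(abs(stats::var(res) - fx$mod$sigma2) / fx$mod$sigma2, 0.2)
})

test_that("model export and import round-trip", {
  fx <- fx_default()
  dir <- withr::local_tempdir()
  export_fpca_model(fx$mod, dir)
  back <- import_fpca_model(dir)
  expect_equal(back$mu, fx$mod$mu, tolerance = 1e-9)
  expect_equal(unname(back$phi), unname(fx$mod$phi), tolerance = 1e-9)
  expect_equal(back$lambda, fx$mod$lambda, tolerance = 1e-12)
  expect_equal(back$sigma2, fx$mod$sigma2, tolerance = 1e-12)
  expect_equal(back$scores, fx$mod$scores, tolerance = 1e-9)
  p <- rownames(fx$mod$scores)[7]
  expect_equal(fitted_curve(back, p)$fit, fitted_curve(fx$mod, p)$fit,
               tolerance = 1e-8)
})
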