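test_that("build_matrix truncates, sorts, and validates the series", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 1)
  m <- build_matrix(fx$series, s_max = 2)
  expect_identical(nrow(m$a), 6L)
  expect_true(all(m$s_grid <= 2))
  expect_gte(ncol(m$a), 50L)
  expect_identical(m$conditions$salt_mM, c(0, 100, 200, 400, 600, 800))
  expect_false(is.null(m$weights))

  # a permuted input series produces the identical matrix
  perm <- fx$series[c(4, 1, 6, 2, 5, 3), ]
  class(perm) <- class(fx$series)
  m2 <- build_matrix(scattering_series(perm$curve, perm$salt_mM,
                                       perm$conc_mg_ml, perm$label),
                     s_max = 2)
  expect_equal(unname(m2$a), unname(m$a))

  # s_max beyond the measured range keeps the full width with a warning
  expect_warning(m3 <- build_matrix(fx$series, s_max = 99), "full width")
  expect_equal(max(m3$s_grid), max(fx$series$curve[[1]]$s))

  one <- suppressWarnings(scattering_series(fx$series$curve[1],
                                            salt_mM = 0, conc_mg_ml = 2))
  expect_error(build_matrix(one), class = "saxsmix_not_decomposable")
})

test_that("per-concentration row scaling divides out the loading differences", {
  fx <- make_fixture("fullength_like", noise_level = 0, seed = 1)
  m_raw <- build_matrix(fx$series, s_max = 2)
  m_sc <- build_matrix(fx$series, s_max = 2, scale_by_conc = TRUE)
  expect_equal(m_sc$a, m_raw$a / fx$series$conc_mg_ml)
})

test_that("component counting finds the construction rank", {
  # rank 1: one species observed at six different scalings
  s <- seq(0.06, 2, by = 0.01)
  pure <- sphere_form_factor(s, 2.1)
  scalings <- seq(1, 0.5, length.out = 6)
  ser <- scattering_series(
    lapply(1:6, function(i) saxs_curve(s, scalings[i] * pure,
                                       label = sprintf("x%d", i))),
    salt_mM = c(0, 100, 200, 400, 600, 800)
  )
  sv1 <- svd_analysis(build_matrix(ser, s_max = 2))
  expect_identical(sv1$n_significant, 1L)
  expect_true(all(diff(sv1$d) <= 0))

  # rank 2: the two-species titration (across several seeds and noise)
  n_two <- vapply(1:8, function(sd) {
    fx <- make_fixture("tpr_like", noise_level = 0.005 + 0.003 * (sd %% 4),
                       seed = sd)
    svd_analysis(build_matrix(fx$series, s_max = 2))$n_significant
  }, integer(1))
  expect_gte(sum(n_two == 2L), 7L)

  # rank 3: three well-separated species
  fx3 <- make_fixture("three_species", noise_level = 0.01, seed = 5)
  expect_identical(svd_analysis(build_matrix(fx3$series, s_max = 2))$n_significant,
                   3L)
})

test_that("the right-vector sign convention and autocorrelations are canonical", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 2)
  sv <- svd_analysis(build_matrix(fx$series, s_max = 2))
  for (k in seq_along(sv$d)) {
    expect_gt(sv$v[which.max(abs(sv$v[, k])), k], 0)
  }
  expect_true(all(sv$autocorrelations >= -1 & sv$autocorrelations <= 1))
  expect_true(all(sv$autocorrelations[1:2] > 0.9))
})

test_that("EFA locates emergence windows and seeds a usable initial estimate", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 3)
  m <- build_matrix(fx$series, s_max = 2)
  ef <- suppressWarnings(efa(m, 2))
  expect_true(all(ef$initial_c >= 0 & ef$initial_c <= 1))
  expect_equal(rowSums(ef$initial_c), rep(1, 6), tolerance = 1e-12)
  # component order on an ordered titration: column 2 matches the species
  # emerging late (the monomer); RMSE vs truth before refinement
  init <- ef$initial_c[, c(2, 1)]
  expect_lt(sqrt(mean((init - fx$truth$fractions)^2)), 0.15)

  # a species present only in the trailing rows gets its window there
  s <- seq(0.06, 2, by = 0.01)
  p1 <- sphere_form_factor(s, 2.1)
  p2 <- 2 * sphere_form_factor(s, 2.65)
  fr2 <- c(0, 0, 0, 0.4, 0.6, 0.8)
  ser <- scattering_series(
    lapply(1:6, function(i) {
      clean <- (1 - fr2[i]) * p1 + fr2[i] * p2
      sig <- 0.005 * sqrt((clean + 1e-6) * clean[1])
      saxs_curve(s, withr::with_seed(100 + i, clean + stats::rnorm(length(s), 0, sig)),
                 sigma = sig, label = sprintf("r%d", i), subtracted = TRUE)
    }),
    salt_mM = c(0, 100, 200, 400, 600, 800)
  )
  ef2 <- suppressWarnings(efa(build_matrix(ser, s_max = 2), 2))
  expect_true(abs(ef2$windows$first[2] - 4L) <= 1L)

  # single-species matrix with n = 1 gives the all-ones column
  fx1 <- make_fixture("single_species", noise_level = 0.01, seed = 1)
  ef1 <- efa(build_matrix(fx1$series, s_max = 2), 1)
  expect_equal(as.numeric(ef1$initial_c), rep(1, 6))

  expect_error(efa(m, 9), class = "saxsmix_dimension_error")
})

test_that("noiseless factorization is recovered from a perturbed-truth start", {
  fx <- make_fixture("tpr_like", noise_level = 0, seed = 1)
  m <- build_matrix(fx$series, s_max = 2)
  C0 <- withr::with_seed(3, fx$truth$fractions *
                           matrix(stats::runif(12, 0.9, 1.1), 6, 2))
  C0 <- C0 / rowSums(C0)
  mr <- mcr_als(m, C0)
  met <- recovery_metrics(mr, fx$truth, m)
  expect_gte(met$min_cosine, 0.9999)
  expect_lte(sqrt(mean((mr$c[, c(2, 1)] - fx$truth$fractions)^2)), 0.005)
})

test_that("closure, the factorization identity and monotone descent hold", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 6)
  m <- build_matrix(fx$series, s_max = 2)
  init <- suppressWarnings(efa(m, 2))$initial_c
  # closure holds at every iteration, not only at convergence
  for (it in c(1L, 2L, 5L)) {
    part <- suppressWarnings(mcr_als(m, init, max_iter = it))
    expect_lt(max(abs(rowSums(part$c) - 1)), 1e-12)
    expect_true(all(part$c >= 0))
    expect_true(all(part$s_pure >= 0))
  }
  mr <- mcr_als(m, init)
  expect_lt(max(abs(rowSums(mr$c) - 1)), 1e-12)
  # identity by definition of the residual
  expect_equal(unname(mr$c %*% mr$s_pure + mr$e), unname(m$a),
               tolerance = 1e-12)
  # monotone lack of fit up to numerical jitter
  lof <- mr$lof_trace
  expect_true(all(diff(lof) <= 1e-9 * pmax(lof[-length(lof)], 1e-300)))
  expect_true(mr$converged)
})

test_that("recovery at 1% noise meets the parameter-recovery bar", {
  for (sd in 1:5) {
    fx <- make_fixture("tpr_like", noise_level = 0.01, seed = sd)
    dec <- decompose_series(fx$series)
    met <- recovery_metrics(dec$mcr, fx$truth, dec$matrix)
    expect_lte(met$fraction_rmse, 0.02)
    expect_gte(met$min_pearson, 0.999)
  }
})

test_that("the factorization is scale invariant", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 7)
  m <- build_matrix(fx$series, s_max = 2)
  init <- suppressWarnings(efa(m, 2))$initial_c
  mr1 <- mcr_als(m, init)
  k <- 137.5
  m2 <- m
  m2$a <- k * m$a
  mr2 <- mcr_als(m2, init)
  expect_equal(mr2$c, mr1$c, tolerance = 1e-8)
  expect_equal(mr2$s_pure, k * mr1$s_pure, tolerance = 1e-8)
})

test_that("fractions are labeled by species size and trend with salt", {
  mono <- make_species("sphere", radius = 2.1)
  dimr <- make_species("sphere", radius = 2.1 * 2^(1 / 3),
                       n_beads = 2L * nrow(mono$coords))
  sim <- simulate_series(mono, dimr, salts = c(0, 100, 200, 300, 400, 600, 800),
                         noise_level = 0.01, seed = 11)
  dec <- decompose_series(sim$series)
  vf <- volume_fractions(dec$mcr, sim$series)
  # the logistic midpoint forces a 50/50 split at 300 mM
  expect_lt(abs(vf$fraction_dimer[vf$salt_mM == 300] - 0.5), 0.03)
  rg <- attr(vf, "species_rg_nm")
  expect_gt(rg[["dimer"]], rg[["monomer"]])

  # noiseless monotone construction gives a perfect Spearman trend
  fx0 <- make_fixture("tpr_like", noise_level = 0, seed = 1)
  dec0 <- decompose_series(fx0$series)
  vf0 <- volume_fractions(dec0$mcr, fx0$series)
  expect_identical(attr(vf0, "spearman_dimer_vs_salt"), -1)

  # three components have no monomer/dimer labeling but tidy still works
  fx3 <- make_fixture("three_species", noise_level = 0.01, seed = 5)
  dec3 <- decompose_series(fx3$series, n = 3)
  expect_error(volume_fractions(dec3$mcr), class = "saxsmix_labeling_error")
  td <- generics::tidy(dec3$mcr)
  expect_identical(nrow(td), 18L)
})

test_that("a monomer-only series forced to two components flags degeneracy", {
  fx <- make_fixture("single_species", noise_level = 0, seed = 2)
  dec <- suppressWarnings(decompose_series(fx$series, n = 2))
  expect_warning(vf <- volume_fractions(dec$mcr),
                 class = "saxsmix_degenerate_component")
  expect_true(attr(vf, "degenerate"))
  expect_lt(min(max(vf$fraction_monomer), max(vf$fraction_dimer)), 0.02)
})

test_that("extracted pure curves feed the shape analyses coherently", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 1)
  dec <- decompose_series(fx$series)
  pure <- extract_pure_curves(dec$mcr, dec$matrix)
  expect_named(pure, c("monomer", "dimer"))
  expect_true(all(vapply(pure, has_sigma, logical(1))))

  rg_d <- fit_guinier(pure$dimer)$rg_nm
  expect_equal(rg_d, fx$truth$species_rg_nm[["dimer"]], tolerance = 0.03)

  scan_m <- suppressWarnings(dmax_scan(pure$monomer, c(2, 8), step = 0.25))
  scan_d <- suppressWarnings(dmax_scan(pure$dimer, c(2, 8), step = 0.25))
  expect_gt(scan_d$d_max_nm, scan_m$d_max_nm)

  # row-wise reconstruction identity
  recon <- dec$mcr$c %*% dec$mcr$s_pure + dec$mcr$e
  for (i in 1:6) expect_equal(recon[i, ], unname(dec$matrix$a[i, ]),
                              tolerance = 1e-12)
})

test_that("reduced chi-square behaves as its closed forms require", {
  s <- seq(0.1, 2, by = 0.01)
  I <- exp(-s^2)
  data <- saxs_curve(s, I, sigma = rep(0.01, length(s)))
  expect_equal(as.numeric(chi2_fit(saxs_curve(s, I), data)), 0)
  J <- length(s)
  expect_equal(as.numeric(chi2_fit(saxs_curve(s, I + 0.01), data, scale = FALSE)),
               J / (J - 1), tolerance = 1e-9)
  # a proportionally scaled model is absorbed by the fitted scale
  expect_lt(as.numeric(chi2_fit(saxs_curve(s, 3.7 * I), data)), 1e-18)

  # noisy realizations against their own truth sit at chi2 ~ 1
  chis <- vapply(1:20, function(sd) {
    crv <- sphere_curve(3, noise_level = 0.01, seed = sd)
    truth <- saxs_curve(crv$s, sphere_form_factor(crv$s, 3))
    as.numeric(chi2_fit(truth, crv, scale = FALSE))
  }, numeric(1))
  expect_true(all(abs(chis - 1) <= 0.2))

  expect_error(chi2_fit(saxs_curve(s, I), saxs_curve(s, I)),
               class = "saxsmix_requires_uncertainty")
})
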