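test_that("bead models realise their target geometry", {
  sph <- make_species("sphere", radius = 3, spacing = 0.4)
  expect_equal(model_rg(sph), sqrt(3 / 5) * 3, tolerance = 0.05 / (sqrt(3 / 5) * 3))
  expect_true(min(stats::dist(sph$coords)) > 1e-6)

  di <- make_species("dimer_of", model = sph)
  expect_identical(nrow(di$coords), 2L * nrow(sph$coords))
  expect_equal(model_dmax(di), 12, tolerance = 0.06)

  bos <- make_species("beads_on_string", cluster_radii = c(1.6, 1.2, 1.2),
                      end_to_end = 15)
  expect_gte(model_rg(bos), 3.5)
  expect_lte(model_rg(bos), 5.5)

  db <- make_species("dumbbell", radius = 2, separation = 4)
  expect_equal(model_rg(db), sqrt((3 / 5) * 4 + 4), tolerance = 0.01)

  expect_error(make_species("dimer_of", model = sph, offset = c(0.2, 0, 0)),
               class = "saxsmix_geometry_error")
  # exact bead counts trim deterministically
  sph2 <- make_species("sphere", radius = 3, n_beads = 500L)
  expect_identical(nrow(sph2$coords), 500L)
})

test_that("the Debye evaluator honours its closed forms", {
  one <- structure(list(coords = matrix(0, 1, 3), bead_radius = 0.2,
                        label = "one"), class = "bead_model")
  s <- seq(0, 3, by = 0.5)
  expect_equal(debye_intensity(one, s)$intensity, rep(1, length(s)))

  # two beads at separation d: I(pi/d)/I(0) = (2 + 2 sinc(pi)) / 4 = 1/2
  two <- structure(list(coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                        bead_radius = 0.2, label = "two"),
                   class = "bead_model")
  expect_equal(debye_intensity(two, pi / 2)$intensity / 4, 0.5,
               tolerance = 1e-12)

  # I(0) = M^2 exactly on both evaluation paths
  mdl <- make_species("sphere", radius = 1.5)
  M <- nrow(mdl$coords)
  expect_identical(debye_intensity(mdl, 0, method = "exact")$intensity[1], M^2)
  expect_identical(debye_intensity(mdl, 0, method = "histogram")$intensity[1],
                   M^2)

  # the binned path tracks the exact double sum
  s <- seq(0.02, 2, by = 0.01)
  ie <- debye_intensity(mdl, s, method = "exact")$intensity
  ih <- debye_intensity(mdl, s, method = "histogram")$intensity
  expect_lt(max(abs(ih - ie)) / ie[1], 1e-3)
})

test_that("bead-sphere scattering matches the analytic form factor", {
  mdl <- make_species("sphere", radius = 3, spacing = 0.3)
  s <- seq(0.05, 1.5, by = 0.05)
  curve <- debye_intensity(mdl, s, method = "exact")
  r_eff <- sqrt(5 / 3) * model_rg(mdl)
  analytic <- sphere_form_factor(s, r_eff)
  rel <- abs(curve$intensity / nrow(mdl$coords)^2 - analytic) / analytic
  # compared away from the first form-factor zero, where a fraction of a
  # percent of discretisation shifts the ratio without bound
  expect_lt(max(rel[analytic > 1e-3]), 0.02)
})

test_that("coordinate-space and Guinier radii agree for generated species", {
  s <- seq(0.005, 1, by = 0.005)
  species <- list(
    make_species("sphere", radius = 2.1),
    make_species("sphere", radius = 2.1 * 2^(1 / 3)),
    make_species("dumbbell", radius = 2, separation = 4),
    make_species("beads_on_string", cluster_radii = c(1.6, 1.2, 1.2),
                 end_to_end = 15)
  )
  for (mdl in species) {
    rg_fit <- fit_guinier(debye_intensity(mdl, s), srg_limit = 1.0)$rg_nm
    expect_equal(rg_fit, model_rg(mdl), tolerance = 0.01)
  }
})

test_that("simulated titrations obey closure, the logistic law and the seed", {
  mono <- make_species("sphere", radius = 2.1)
  dimr <- make_species("sphere", radius = 2.1 * 2^(1 / 3),
                       n_beads = 2L * nrow(mono$coords))
  sim <- simulate_series(mono, dimr, salts = c(0, 150, 300, 450, 800),
                         noise_level = 0.01, seed = 21)
  expect_equal(rowSums(sim$truth$fractions), rep(1, 5), tolerance = 1e-14)
  expect_identical(unname(sim$truth$fractions[sim$truth$salt_mM == 300, "dimer"]), 0.5)

  # noiseless rows equal the exact mixture C S
  sim0 <- simulate_series(mono, dimr, salts = c(0, 300, 800), noise_level = 0,
                          seed = 1)
  clean <- sim0$truth$fractions %*% sim0$truth$pure_curves
  for (i in 1:3) {
    expect_equal(sim0$series$curve[[i]]$intensity, unname(clean[i, ]),
                 tolerance = 1e-14)
  }

  # identical seeds give byte-identical series files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_series(simulate_series(mono, dimr, salts = c(0, 400, 800),
                               noise_level = 0.02, seed = 5)$series, d1)
  write_series(simulate_series(mono, dimr, salts = c(0, 400, 800),
                               noise_level = 0.02, seed = 5)$series, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  expect_error(simulate_series(mono, dimr, salts = c(0, 800),
                               noise_level = 0.5),
               class = "saxsmix_domain_error")
  expect_error(simulate_series(mono, dimr, salts = c(0, 800), width_mM = -3),
               class = "saxsmix_domain_error")
})

test_that("per-particle and per-mass forward scattering scale as mass demands", {
  mono <- make_species("sphere", radius = 2.1)
  dimr <- make_species("sphere", radius = 2.1 * 2^(1 / 3),
                       n_beads = 2L * nrow(mono$coords))
  i0_m <- debye_intensity(mono, 0)$intensity
  i0_d <- debye_intensity(dimr, 0)$intensity
  expect_identical(i0_m, nrow(mono$coords)^2)
  expect_identical(i0_d / i0_m, 4)         # per particle: mass squared
  expect_identical((i0_d / 2) / i0_m, 2)   # per equal mass: twice
})

test_that("fixtures land on their documented design targets", {
  fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 1)
  rg <- fx$truth$species_rg_nm
  expect_gte(rg[["monomer"]], 1.4); expect_lte(rg[["monomer"]], 1.9)
  expect_gte(rg[["dimer"]], 1.8); expect_lte(rg[["dimer"]], 2.3)
  expect_identical(fx$series$salt_mM, c(0, 100, 200, 400, 600, 800))

  ffl <- make_fixture("fullength_like", noise_level = 0.01, seed = 1)
  expect_gt(ffl$truth$species_dmax_nm[["dimer"]],
            ffl$truth$species_dmax_nm[["monomer"]])
  expect_identical(ffl$series$conc_mg_ml, c(3.46, 3.41, 2.71))

  fx1 <- make_fixture("single_species", noise_level = 0, seed = 1)
  d <- svd(do.call(rbind, lapply(fx1$series$curve, function(cv) cv$intensity)))$d
  expect_lt(d[2] / d[1], 1e-10)

  expect_error(make_fixture("nonsense"))
})
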