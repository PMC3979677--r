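test_that("curve construction enforces the grid and uncertainty invariants", {
  expect_s3_class(saxs_curve(1:5 / 10, rep(1, 5)), "saxs_curve")
  expect_error(saxs_curve(c(0.2, 0.1), c(1, 1)), class = "saxsmix_invalid_curve")
  expect_error(saxs_curve(c(-0.1, 0.1), c(1, 1)), class = "saxsmix_invalid_curve")
  expect_error(saxs_curve(1:3 / 10, c(1, -1, 1)), class = "saxsmix_invalid_curve")
  expect_error(saxs_curve(1:3 / 10, rep(1, 3), sigma = c(1, 0, 1)),
               class = "saxsmix_invalid_curve")
  # negative intensities are fine once flagged background-subtracted
  expect_silent(saxs_curve(1:3 / 10, c(1, -1, 1), subtracted = TRUE))
})

test_that("read/write round-trips curves losslessly to stated precision", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(50:400, 1)
      s <- sort(runif(n, 0.01, 5))
      crv <- saxs_curve(s, rexp(n), sigma = if (rep %% 2) runif(n, 0.01, 1),
                        label = sprintf("case_%d", rep))
      path <- withr::local_tempfile(fileext = ".dat")
      write_dat(crv, path)
      back <- read_dat(path)
      expect_equal(back$s, crv$s, tolerance = 1e-6)
      expect_equal(back$intensity, crv$intensity, tolerance = 1e-6)
      expect_identical(has_sigma(back), has_sigma(crv))
      if (has_sigma(crv)) expect_equal(back$sigma, crv$sigma, tolerance = 1e-6)
      expect_identical(curve_label(back), sprintf("case_%d", rep))
    }
  })
})

test_that("read_dat tolerates headers and comments and reports bad input", {
  path <- withr::local_tempfile(fileext = ".dat")
  s <- seq(0.01, 5, length.out = 500)
  body <- sprintf("%.6e %.6e %.6e", s, exp(-s), rep(0.01, 500))
  writeLines(c("Sample description free text", "# a comment", body), path)
  crv <- read_dat(path)
  expect_equal(nrow(crv), 500L)
  expect_true(has_sigma(crv))

  # two columns -> sigma absent
  writeLines(sprintf("%.6e %.6e", s, exp(-s)), path)
  expect_false(has_sigma(read_dat(path)))

  # non-finite rows dropped with a message
  writeLines(c(body, "2.5e+00 NaN 1e-2"), path)
  expect_message(crv2 <- read_dat(path), "dropped 1")
  expect_equal(nrow(crv2), 500L)

  # garbage after data started names the offending line
  writeLines(c(body[1:10], "not numbers here"), path)
  expect_error(read_dat(path), "line", class = "saxsmix_format_error")

  # too few rows
  writeLines(body[1:3], path)
  expect_error(read_dat(path), class = "saxsmix_insufficient_data")

  # empty label written as unnamed
  write_dat(saxs_curve(s[1:10], exp(-s[1:10])), path)
  expect_identical(readLines(path)[1], "# unnamed")
})

test_that("angstrom input converts the grid by a factor of ten", {
  path <- withr::local_tempfile(fileext = ".dat")
  s_ang <- seq(0.005, 0.2, length.out = 40)
  writeLines(sprintf("%.6e %.6e", s_ang, rep(1, 40)), path)
  crv <- read_dat(path, angstrom = TRUE)
  expect_equal(crv$s, s_ang * 10, tolerance = 1e-6)
})

test_that("load_series sorts by salt, validates labels, aggregates missing files", {
  dir <- withr::local_tempdir()
  salts <- c(400, 0, 800, 100, 600, 200)
  for (i in seq_along(salts)) {
    write_dat(sphere_curve(3), file.path(dir, sprintf("c%d.dat", i)))
  }
  man <- file.path(dir, "manifest.csv")
  tab <- data.frame(path = sprintf("c%d.dat", 1:6),
                    label = sprintf("s%d", salts),
                    salt_mM = salts, conc_mg_ml = 2)
  readr::write_csv(tab, man)
  ser <- load_series(man)
  expect_s3_class(ser, "scattering_series")
  expect_identical(ser$salt_mM, c(0, 100, 200, 400, 600, 800))
  expect_true(attr(ser, "decomposable"))

  # shuffled manifest rows give the identical series
  readr::write_csv(tab[sample(6), ], man)
  ser2 <- load_series(man)
  expect_identical(ser2$salt_mM, ser$salt_mM)
  expect_identical(ser2$label, ser$label)

  # JSON manifest equivalent
  jman <- file.path(dir, "manifest.json")
  jsonlite::write_json(tab, jman, dataframe = "rows")
  expect_identical(load_series(jman)$salt_mM, ser$salt_mM)

  tab_bad <- tab; tab_bad$label <- "same"
  readr::write_csv(tab_bad, man)
  expect_error(load_series(man), class = "saxsmix_validation_error")

  tab_missing <- tab
  tab_missing$path[c(2, 5)] <- c("absent_a.dat", "absent_b.dat")
  readr::write_csv(tab_missing, man)
  err <- tryCatch(load_series(man), error = identity)
  expect_s3_class(err, "saxsmix_io_error")
  expect_match(conditionMessage(err), "absent_a.dat")
  expect_match(conditionMessage(err), "absent_b.dat")
})

test_that("a single-entry series loads but is flagged not decomposable", {
  crv <- sphere_curve(3)
  expect_warning(ser <- scattering_series(list(crv), salt_mM = 0),
                 class = "saxsmix_not_decomposable")
  expect_false(attr(ser, "decomposable"))
})

test_that("common_grid restricts, never extrapolates, and is idempotent", {
  s1 <- seq(0.06, 6, by = 0.01)
  s2 <- s1 + 0.005  # half-step offset
  curves <- list(saxs_curve(s1, exp(-s1), label = "a"),
                 saxs_curve(s2, exp(-s2), label = "b"))
  ser <- scattering_series(curves, salt_mM = c(0, 100))
  out <- common_grid(ser)
  rng <- range(out$curve[[1]]$s)
  expect_true(rng[1] >= max(min(s1), min(s2)))
  expect_true(rng[2] <= min(max(s1), max(s2)))
  expect_identical(out$curve[[1]]$s, out$curve[[2]]$s)

  # truncation to the conventional 2 nm^-1 analysis window
  out2 <- common_grid(ser, s_max = 2)
  expect_true(all(out2$curve[[1]]$s <= 2))

  # idempotency
  again <- common_grid(out2, s_max = 2)
  expect_identical(again$curve[[1]]$s, out2$curve[[1]]$s)
  expect_identical(again$curve[[2]]$intensity, out2$curve[[2]]$intensity)

  # identical grids pass through untouched
  ser_same <- scattering_series(list(saxs_curve(s1, exp(-s1), label = "a"),
                                     saxs_curve(s1, 2 * exp(-s1), label = "b")),
                                salt_mM = c(0, 100))
  expect_identical(common_grid(ser_same)$curve[[2]]$intensity, 2 * exp(-s1))

  # disjoint ranges
  far <- scattering_series(list(saxs_curve(s1, exp(-s1), label = "a"),
                                saxs_curve(s1 + 10, exp(-s1), label = "b")),
                           salt_mM = c(0, 100))
  expect_error(common_grid(far), class = "saxsmix_range_error")
})
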