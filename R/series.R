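#' Assemble a scattering series from curves and sample conditions
#'
#' A `scattering_series` is a tibble with one row per measured
#' condition: columns `label`, `salt_mM` (monovalent salt, mM),
#' `conc_mg_ml` (protein mass concentration, mg/mL) and a `curve`
#' list-column of [saxs_curve()] objects. Rows are kept sorted by
#' ascending salt; the sort is stable, so the result is independent of
#' input order.
#'
#' @param curves List of [saxs_curve()] objects.
#' @param salt_mM Numeric vector of salt concentrations, mM, >= 0.
#' @param conc_mg_ml Numeric vector (or scalar) of protein
#'   concentrations, mg/mL, > 0.
#' @param labels Optional character vector of unique sample labels;
#'   defaults to the curve labels.
#' @return A tibble of class `scattering_series`, sorted by salt.
#' @export
scattering_series <- function(curves, salt_mM, conc_mg_ml = 1,
                              labels = NULL) {
  stopifnot(is.list(curves), all(vapply(curves, is_saxs_curve, logical(1))))
  n <- length(curves)
  salt_mM <- as.numeric(salt_mM)
  conc_mg_ml <- rep_len(as.numeric(conc_mg_ml), n)
  if (length(salt_mM) != n) {
    stop_saxsmix("one salt concentration per curve is required",
                 "saxsmix_validation_error")
  }
  if (any(salt_mM < 0) || any(conc_mg_ml <= 0)) {
    stop_saxsmix("salt_mM must be >= 0 and conc_mg_ml > 0",
                 "saxsmix_validation_error")
  }
  labels <- labels %||% vapply(curves, curve_label, character(1))
  labels <- as.character(rep_len(labels, n))
  if (anyDuplicated(labels[nzchar(labels)])) {
    stop_saxsmix("sample labels must be unique", "saxsmix_validation_error")
  }
  out <- tibble::tibble(
    label = labels, salt_mM = salt_mM, conc_mg_ml = conc_mg_ml,
    curve = curves
  )
  out <- out[order(out$salt_mM), ]
  if (n < 2L) {
    warn("series has a single entry; it cannot be decomposed",
         class = "saxsmix_not_decomposable")
  }
  structure(out,
            class = c("scattering_series", class(tibble::tibble())),
            sorted_by = "salt_mM",
            decomposable = n >= 2L)
}

#' @rdname scattering_series
#' @param x Object to test.
#' @export
is_scattering_series <- function(x) inherits(x, "scattering_series")

#' @export
print.scattering_series <- function(x, ...) {
  cat(sprintf("<scattering_series> %d condition(s), salt %s mM\n",
              nrow(x), paste(x$salt_mM, collapse = "/")))
  NextMethod()
}

#' Load a scattering series from a manifest file
#'
#' The manifest is a CSV table (or a JSON array of records) with
#' columns `path`, `label`, `salt_mM`, `conc_mg_ml`; curve paths are
#' resolved relative to the manifest location. All missing curve files
#' are reported together in a single error.
#'
#' @param manifest Path to the manifest (`.csv` or `.json`).
#' @param angstrom Passed through to [read_dat()].
#' @return A [scattering_series()], sorted by ascending salt.
#' @export
load_series <- function(manifest, angstrom = FALSE) {
  if (!file.exists(manifest)) {
    stop_saxsmix(paste0("manifest not found: ", manifest), "saxsmix_io_error")
  }
  if (grepl("\\.json$", manifest, ignore.case = TRUE)) {
    tab <- tibble::as_tibble(jsonlite::fromJSON(manifest))
  } else {
    tab <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  need <- c("path", "label", "salt_mM", "conc_mg_ml")
  if (!all(need %in% names(tab))) {
    stop_saxsmix(
      paste0("manifest must provide columns: ", paste(need, collapse = ", ")),
      "saxsmix_validation_error"
    )
  }
  if (anyDuplicated(tab$label)) {
    stop_saxsmix("duplicate labels in manifest", "saxsmix_validation_error")
  }
  paths <- ifelse(file.exists(tab$path), tab$path,
                  file.path(dirname(manifest), tab$path))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_saxsmix(
      paste0("missing curve file(s): ",
             paste(tab$path[missing], collapse = ", ")),
      "saxsmix_io_error"
    )
  }
  curves <- purrr::map2(paths, tab$label, read_dat, angstrom = angstrom)
  scattering_series(curves, salt_mM = tab$salt_mM,
                    conc_mg_ml = tab$conc_mg_ml, labels = tab$label)
}

#' Write a series (curve files plus manifest) to a directory
#'
#' Companion to [load_series()]: one `.dat` file per condition and a
#' `manifest.csv` indexing them. Output is deterministic byte-for-byte
#' for identical input.
#'
#' @param series A [scattering_series()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(is_scattering_series(series))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.dat", ifelse(nzchar(series$label), series$label,
                                    sprintf("curve_%02d", seq_len(nrow(series)))))
  purrr::walk2(series$curve, file.path(dir, files), write_dat)
  man <- tibble::tibble(path = files, label = series$label,
                        salt_mM = series$salt_mM,
                        conc_mg_ml = series$conc_mg_ml)
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Interpolate a series onto a common momentum-transfer grid
#'
#' All curves are linearly interpolated onto the grid of the first
#' curve restricted to the intersection of every curve's range and the
#' requested `[s_min, s_max]` window; no point is ever extrapolated.
#' Uncertainties are interpolated alongside the intensities. The
#' operation is idempotent: a series already on a common grid inside
#' the window passes through unchanged.
#'
#' @param series A [scattering_series()].
#' @param s_min,s_max Optional window bounds, nm^-1. The default
#'   `s_max = NULL` keeps the full common range; decomposition
#'   conventionally truncates at 2 nm^-1 where the signal-to-noise of
#'   protein solution scattering degrades.
#' @return The series with all curves on one grid.
#' @export
common_grid <- function(series, s_min = NULL, s_max = NULL) {
  stopifnot(is_scattering_series(series))
  lo <- max(vapply(series$curve, function(cv) min(cv$s), numeric(1)))
  hi <- min(vapply(series$curve, function(cv) max(cv$s), numeric(1)))
  lo <- max(lo, s_min %||% -Inf)
  hi <- min(hi, s_max %||% Inf)
  if (lo >= hi) {
    stop_saxsmix("curve grids have no common overlap in the requested window",
                 "saxsmix_range_error")
  }
  grid <- series$curve[[1]]$s
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) {
    stop_saxsmix("fewer than 2 grid points remain in the window",
                 "saxsmix_range_error")
  }
  out <- series
  out$curve <- purrr::map(series$curve, function(cv) {
    if (isTRUE(all.equal(cv$s, grid))) return(cv)
    intensity <- approx(cv$s, cv$intensity, xout = grid)$y
    sigma <- if (has_sigma(cv)) approx(cv$s, cv$sigma, xout = grid)$y
    saxs_curve(grid, intensity, sigma, label = curve_label(cv),
               subtracted = attr(cv, "subtracted"))
  })
  attr(out, "common_grid") <- TRUE
  out
}
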