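#' Construct a SAXS scattering curve
#'
#' A `saxs_curve` is a tibble with columns `s` (momentum transfer,
#' \eqn{s = 4\pi \sin\theta / \lambda}, in nm\eqn{^{-1}}), `intensity`
#' (scattered intensity, arbitrary units) and optionally `sigma`
#' (1-sigma point uncertainty, same units as the intensity). The `s`
#' grid must be non-negative and strictly increasing. Negative
#' intensities are only admitted on curves flagged as
#' background-subtracted, where statistical fluctuation around zero is
#' expected.
#'
#' @param s Numeric vector of momentum-transfer values, nm^-1,
#'   strictly increasing, all >= 0.
#' @param intensity Numeric vector of intensities, same length as `s`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties,
#'   strictly positive, same length as `s`.
#' @param label Free-text sample identifier.
#' @param subtracted Logical; `TRUE` marks a buffer-subtracted curve,
#'   on which negative intensities are permitted.
#' @return A tibble of class `saxs_curve`.
#' @examples
#' crv <- saxs_curve(s = seq(0.1, 2, 0.1), intensity = exp(-seq(0.1, 2, 0.1)))
#' crv
#' @export
saxs_curve <- function(s, intensity, sigma = NULL, label = "",
                       subtracted = FALSE) {
  s <- as.numeric(s)
  intensity <- as.numeric(intensity)
  if (length(s) != length(intensity)) {
    stop_saxsmix("`s` and `intensity` must have the same length",
                 "saxsmix_invalid_curve")
  }
  if (anyNA(s) || anyNA(intensity)) {
    stop_saxsmix("curve values must be finite", "saxsmix_invalid_curve")
  }
  if (any(s < 0)) {
    stop_saxsmix("all `s` values must be >= 0", "saxsmix_invalid_curve")
  }
  if (length(s) > 1L && any(diff(s) <= 0)) {
    stop_saxsmix("`s` must be strictly increasing", "saxsmix_invalid_curve")
  }
  if (!subtracted && any(intensity < 0)) {
    stop_saxsmix(
      "negative intensities are only valid on background-subtracted curves",
      "saxsmix_invalid_curve"
    )
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s)) {
      stop_saxsmix("`sigma` must match the grid length",
                   "saxsmix_invalid_curve")
    }
    if (anyNA(sigma) || any(sigma <= 0)) {
      stop_saxsmix("all `sigma` must be finite and > 0",
                   "saxsmix_invalid_curve")
    }
    out <- tibble::tibble(s = s, intensity = intensity, sigma = sigma)
  } else {
    out <- tibble::tibble(s = s, intensity = intensity)
  }
  structure(out,
            class = c("saxs_curve", class(tibble::tibble())),
            label = as.character(label)[1],
            subtracted = isTRUE(subtracted))
}

#' @rdname saxs_curve
#' @param x Object to test.
#' @export
is_saxs_curve <- function(x) inherits(x, "saxs_curve")

#' @rdname saxs_curve
#' @param curve A `saxs_curve`.
#' @export
has_sigma <- function(curve) "sigma" %in% names(curve)

#' @rdname saxs_curve
#' @export
curve_label <- function(curve) attr(curve, "label") %||% ""

#' @export
print.saxs_curve <- function(x, ...) {
  lab <- curve_label(x)
  cat(sprintf(
    "<saxs_curve> %s: %d points, s in [%.4g, %.4g] nm^-1, sigma %s%s\n",
    if (nzchar(lab)) lab else "(unnamed)", nrow(x), min(x$s), max(x$s),
    if (has_sigma(x)) "present" else "absent",
    if (isTRUE(attr(x, "subtracted"))) ", buffer-subtracted" else ""
  ))
  NextMethod()
}

same_grid <- function(a, b, tol = 1e-8) {
  nrow(a) == nrow(b) && all(abs(a$s - b$s) <= tol * pmax(1, abs(a$s)))
}

#' Read a three-column scattering curve file
#'
#' Parses the plain-text `.dat` convention used throughout solution
#' scattering: whitespace-separated columns `s`, `I(s)` and optionally
#' `sigma`, with free-text header lines and `#` comments. Rows holding
#' non-finite values are dropped (with a message). Internal units are
#' nm^-1; use `angstrom = TRUE` for files with `s` in inverse Angstrom,
#' which are converted by a factor of 10 on read.
#'
#' @param path Path to the curve file.
#' @param label Sample label; defaults to the file name.
#' @param angstrom If `TRUE`, interpret the first column as Angstrom^-1
#'   and convert to nm^-1.
#' @return A [saxs_curve()].
#' @export
read_dat <- function(path, label = NULL, angstrom = FALSE) {
  if (!file.exists(path)) {
    stop_saxsmix(paste0("file not found: ", path), "saxsmix_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (is.null(label) && length(lines) && grepl("^#\\s*\\S", lines[1])) {
    header_label <- trimws(sub("^#\\s*", "", lines[1]))
    if (nzchar(header_label) && header_label != "unnamed") label <- header_label
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- list()
  seen_numeric <- FALSE
  # a token counts as numeric if it parses, including non-finite
  # spellings, which are legal rows to be dropped later with a message
  tok_ok <- function(tok, val) {
    !is.na(val) | tolower(tok) %in% c("nan", "-nan", "inf", "-inf", "na")
  }
  for (i in idx) {
    tokens <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    ok <- tok_ok(tokens, vals)
    if (length(vals) >= 2L && ok[1] && ok[2]) {
      rows[[length(rows) + 1L]] <- vals[seq_len(min(3L, length(vals)))]
      seen_numeric <- TRUE
    } else if (seen_numeric) {
      stop_saxsmix(
        sprintf("cannot parse line %d of %s: \"%s\"", i, path, lines[i]),
        "saxsmix_format_error"
      )
    }
    # non-numeric lines before the first data row are headers; skip
  }
  if (!seen_numeric) {
    first_bad <- if (length(idx)) lines[idx[1]] else "(empty file)"
    stop_saxsmix(
      sprintf("no numeric data in %s; first line: \"%s\"", path, first_bad),
      "saxsmix_format_error"
    )
  }
  ncols <- min(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncols)]))
  finite <- rowSums(!is.finite(m)) == 0
  if (ncols >= 3L) finite <- finite & m[, 3] > 0
  if (any(!finite)) {
    inform(sprintf("read_dat: dropped %d non-finite row(s) from %s",
                   sum(!finite), path))
    m <- m[finite, , drop = FALSE]
  }
  if (nrow(m) < 5L) {
    stop_saxsmix(
      sprintf("%s holds only %d valid data rows (>= 5 required)",
              path, nrow(m)),
      "saxsmix_insufficient_data"
    )
  }
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (anyDuplicated(m[, 1])) {
    stop_saxsmix(sprintf("duplicate s values in %s", path),
                 "saxsmix_format_error")
  }
  s <- m[, 1] * if (isTRUE(angstrom)) 10 else 1
  saxs_curve(
    s = s, intensity = m[, 2],
    sigma = if (ncols >= 3L) m[, 3] else NULL,
    label = label %||% sub("\\.[^.]*$", "", basename(path)),
    subtracted = any(m[, 2] < 0)
  )
}

#' Write a scattering curve to a three-column text file
#'
#' Writes fixed-width ASCII readable by [read_dat()]: one `#` header
#' line carrying the curve label, then `s I(s) [sigma]` columns.
#'
#' @param curve A [saxs_curve()].
#' @param path Output path.
#' @return `path`, invisibly usable in pipes.
#' @export
write_dat <- function(curve, path) {
  stopifnot(is_saxs_curve(curve))
  lab <- curve_label(curve)
  header <- paste0("# ", if (nzchar(lab)) lab else "unnamed")
  fmt <- function(x) formatC(x, format = "e", digits = 8, width = 16)
  body <- paste0(fmt(curve$s), fmt(curve$intensity),
                 if (has_sigma(curve)) fmt(curve$sigma) else "")
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_saxsmix(paste0("cannot write ", path), "saxsmix_io_error")
  }
  invisible(path)
}
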