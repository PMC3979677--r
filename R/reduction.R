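#' Average successive exposure frames with a radiation-damage guard
#'
#' Frames sharing one grid are averaged pointwise; uncertainties
#' combine as \eqn{\sqrt{\sum \sigma_i^2} / n}. A frame whose intensity
#' deviates from the mean of the remaining frames by more than
#' `k` sigma over more than `max_bad_frac` of its points is excluded
#' from the average (typical cause: radiation damage in later frames)
#' and reported via a warning and the `excluded` attribute.
#'
#' @param frames List of [saxs_curve()] objects on identical grids.
#' @param k Outlier threshold in sigma units (default 4).
#' @param max_bad_frac Fraction of deviant points above which a frame
#'   is excluded (default 0.10).
#' @return A [saxs_curve()]; attribute `excluded` lists dropped frames.
#' @export
average_frames <- function(frames, k = 4, max_bad_frac = 0.10) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, is_saxs_curve, logical(1))))
  if (length(frames) == 1L) {
    out <- frames[[1]]
    attr(out, "excluded") <- integer(0)
    return(out)
  }
  ref <- frames[[1]]
  if (!all(vapply(frames[-1], same_grid, logical(1), b = ref))) {
    stop_saxsmix("frames are not on identical grids", "saxsmix_grid_error")
  }
  imat <- vapply(frames, function(f) f$intensity, numeric(nrow(ref)))
  with_sigma <- all(vapply(frames, has_sigma, logical(1)))
  smat <- if (with_sigma) {
    vapply(frames, function(f) f$sigma, numeric(nrow(ref)))
  }
  n <- ncol(imat)
  scale_ref <- if (with_sigma) smat else {
    # no stated uncertainties: use the per-point spread across frames
    matrix(apply(imat, 1, sd), nrow(imat), n)
  }
  # robust reference: the per-point median over frames is immune to a
  # single damaged frame, unlike a leave-one-out mean
  ref_med <- apply(imat, 1, median)
  bad <- vapply(seq_len(n), function(j) {
    dev <- abs(imat[, j] - ref_med)
    mean(dev > k * pmax(scale_ref[, j], .Machine$double.eps)) > max_bad_frac
  }, logical(1))
  if (all(bad)) bad[] <- FALSE  # never drop everything
  if (any(bad)) {
    warn(sprintf("average_frames: excluded %d outlier frame(s): %s",
                 sum(bad), paste(which(bad), collapse = ", ")),
         class = "saxsmix_frame_excluded")
  }
  keep <- which(!bad)
  m <- length(keep)
  intensity <- rowMeans(imat[, keep, drop = FALSE])
  sigma <- if (with_sigma) {
    sqrt(rowSums(smat[, keep, drop = FALSE]^2)) / m
  }
  out <- saxs_curve(ref$s, intensity, sigma,
                    label = curve_label(ref),
                    subtracted = attr(ref, "subtracted"))
  attr(out, "excluded") <- which(bad)
  out
}

#' Subtract buffer scattering from a sample curve
#'
#' Pointwise subtraction on identical grids with Gaussian error
#' propagation, \eqn{\sigma = \sqrt{\sigma_s^2 + \sigma_b^2}}. The
#' result is flagged background-subtracted, so negative intensities
#' (noise around zero at high angle) become admissible.
#'
#' @param sample,buffer [saxs_curve()] objects on the same grid.
#' @return A background-subtracted [saxs_curve()].
#' @export
subtract_buffer <- function(sample, buffer) {
  stopifnot(is_saxs_curve(sample), is_saxs_curve(buffer))
  if (!same_grid(sample, buffer)) {
    stop_saxsmix("sample and buffer are not on the same grid",
                 "saxsmix_grid_error")
  }
  sigma <- if (has_sigma(sample) && has_sigma(buffer)) {
    sqrt(sample$sigma^2 + buffer$sigma^2)
  } else if (has_sigma(sample)) {
    sample$sigma
  } else if (has_sigma(buffer)) {
    buffer$sigma
  }
  saxs_curve(sample$s, sample$intensity - buffer$intensity, sigma,
             label = curve_label(sample), subtracted = TRUE)
}

#' Molecular weight from forward scattering against a reference standard
#'
#' At matched contrast, forward scattering per unit mass concentration
#' is proportional to molecular mass, so
#' \deqn{MW = MW_{ref} \cdot \frac{I(0)/c}{I(0)_{ref}/c_{ref}}.}
#' Classic standards are BSA (66.4 kDa) and tetrameric xylose/glucose
#' isomerase (173 kDa); the reference is supplied, never assumed.
#'
#' @param sample_i0 Forward scattering I(0) of the sample (from a
#'   Guinier fit), arbitrary units.
#' @param sample_conc Sample mass concentration, mg/mL.
#' @param reference List or one-row data frame with fields `label`,
#'   `mw_kDa`, `i0`, `conc_mg_ml` describing the calibration standard
#'   measured on the same scale.
#' @return One-row tibble: `mw_kDa`, `i0_over_c`, `reference_label`,
#'   `reference_mw_kDa`.
#' @export
estimate_mw <- function(sample_i0, sample_conc, reference) {
  reference <- as.list(reference)
  need <- c("label", "mw_kDa", "i0", "conc_mg_ml")
  if (!all(need %in% names(reference))) {
    stop_saxsmix(paste0("reference must provide: ",
                        paste(need, collapse = ", ")),
                 "saxsmix_validation_error")
  }
  vals <- c(sample_i0, sample_conc, reference$mw_kDa, reference$i0,
            reference$conc_mg_ml)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_saxsmix("all intensities, masses and concentrations must be > 0",
                 "saxsmix_domain_error")
  }
  ratio <- (sample_i0 / sample_conc) / (reference$i0 / reference$conc_mg_ml)
  tibble::tibble(
    mw_kDa = reference$mw_kDa * ratio,
    i0_over_c = sample_i0 / sample_conc,
    reference_label = as.character(reference$label),
    reference_mw_kDa = reference$mw_kDa
  )
}
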