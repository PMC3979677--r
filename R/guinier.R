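#' Guinier analysis with automated linear-range selection
#'
#' Fits the Guinier law \eqn{\ln I(s) = \ln I(0) - (R_G^2/3)\, s^2} by
#' weighted least squares (weights \eqn{1/\sigma_{\ln I}^2} when
#' uncertainties are present) on a low-angle window chosen
#' automatically. Candidate starting points skip non-positive
#' intensities and a beamstop-shadowed head (detected as a rising
#' leading segment, i.e. the fit starts no earlier than the first
#' local maximum of the leading points). For each candidate start the
#' window's upper end is determined self-consistently so that
#' \eqn{s \cdot R_G \le} `srg_limit` with \eqn{R_G} estimated from the
#' same window; among admissible windows (at least `min_points`
#' points) the fit with the highest coefficient of determination wins.
#'
#' A runs test on the fit residuals flags systematic curvature
#' (p < 0.01), the classic signature of aggregation or interparticle
#' repulsion.
#'
#' @param curve A [saxs_curve()].
#' @param srg_limit Upper limit on s*R_G at the window end
#'   (default 1.3, the community convention for globular particles;
#'   elongated particles may warrant 1.0).
#' @param min_points Minimum number of points in the fit window.
#' @return An object of class `guinier_fit` with elements `rg_nm`,
#'   `i0`, `fit_window`, `srg_max`, `r_squared`, `residual_pattern`
#'   (runs-test p-value), `slope`, `intercept`, `below_resolution`,
#'   `curvature_warning`, and the fitted window data.
#' @export
fit_guinier <- function(curve, srg_limit = 1.3, min_points = 10L) {
  stopifnot(is_saxs_curve(curve))
  pos <- which(curve$intensity > 0)
  if (length(pos) < min_points) {
    stop_saxsmix("fewer than `min_points` positive intensities",
                 "saxsmix_domain_error")
  }
  first_pos <- pos[1]
  # beamstop-shadow heuristic: if the leading intensities rise, start at
  # the first local maximum of the head region
  head_n <- min(first_pos + 14L, nrow(curve))
  head_i <- curve$intensity[first_pos:head_n]
  start0 <- first_pos
  if (length(head_i) > 2L && head_i[2] > head_i[1]) {
    turn <- which(diff(head_i) <= 0)
    if (length(turn)) start0 <- first_pos + turn[1] - 1L
  }
  n <- nrow(curve)
  candidates <- start0:min(start0 + 9L, n - min_points + 1L)
  candidates <- candidates[candidates >= 1L]

  best <- NULL
  for (i0idx in candidates) {
    fit <- guinier_window_fit(curve, i0idx, srg_limit, min_points)
    if (is.null(fit)) next
    if (is.null(best) || fit$r_squared > best$r_squared) best <- fit
  }
  if (is.null(best)) {
    stop_saxsmix(
      sprintf("no window of >= %d points satisfies s*Rg <= %.3g",
              min_points, srg_limit),
      "saxsmix_no_linear_range"
    )
  }
  best$label <- curve_label(curve)
  structure(best, class = "guinier_fit")
}

# Weighted linear fit of ln I on s^2 over one index window; NULL when
# the window is unusable (non-positive intensities).
guinier_eval <- function(curve, first, last) {
  idx <- first:last
  if (any(curve$intensity[idx] <= 0)) return(NULL)
  s2 <- curve$s[idx]^2
  y <- log(curve$intensity[idx])
  w <- if (has_sigma(curve)) {
    (curve$intensity[idx] / curve$sigma[idx])^2
  } else {
    rep(1, length(idx))
  }
  fit <- stats::lm.wfit(cbind(1, s2), y, w)
  slope <- unname(fit$coefficients[2])
  rg <- if (is.na(slope) || slope >= 0) 0 else sqrt(-3 * slope)
  res <- fit$residuals
  wmean <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - wmean)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else 1
  list(slope = slope, intercept = unname(fit$coefficients[1]),
       rg = rg, r2 = r2, residuals = res, weights = w,
       s2 = s2, y = y)
}

# Self-consistent Guinier fit from a fixed starting index: the maximal
# upper index is iterated until s_max * Rg(window) stabilises at the
# limit, then candidate windows ending at or inside that bound compete
# on fit quality (R^2). Noiseless data favours the tightest window,
# where the Guinier law is most nearly exact; noisy data favours wide
# windows, where the signal dominates the variance.
guinier_window_fit <- function(curve, first, srg_limit, min_points) {
  n <- nrow(curve)
  last <- min(first + min_points - 1L, n)
  if (last - first + 1L < min_points) return(NULL)
  prev_last <- -1L
  for (iter in 1:40) {
    ev <- guinier_eval(curve, first, last)
    if (is.null(ev)) {
      # shrink below the first non-positive point
      idx <- first:last
      bad <- idx[which(curve$intensity[idx] <= 0)[1]]
      last <- bad - 1L
      if (last - first + 1L < min_points) return(NULL)
      next
    }
    if (ev$rg == 0) {
      last_new <- n  # flat / rising curve: constraint is vacuous
    } else {
      last_new <- max(findInterval(srg_limit / ev$rg, curve$s),
                      first + min_points - 1L)
      last_new <- min(last_new, n)
    }
    if (last_new == last || last_new == prev_last) {
      last <- min(last, last_new)  # on a 2-cycle keep the tighter window
      break
    }
    prev_last <- last
    last <- last_new
  }
  # compete windows ending inside the admissible range
  ends <- unique(round(seq(first + min_points - 1L, last, length.out = 12L)))
  best <- NULL
  best_last <- NULL
  for (e in ends) {
    ev <- guinier_eval(curve, first, e)
    if (is.null(ev)) next
    if (ev$rg > 0 && curve$s[e] * ev$rg > srg_limit * (1 + 1e-9)) next
    if (is.null(best) || ev$r2 > best$r2) {
      best <- ev
      best_last <- e
    }
  }
  if (is.null(best)) return(NULL)
  last <- best_last
  idx <- first:last
  rg <- best$rg
  intercept <- best$intercept
  slope <- best$slope
  res <- best$residuals
  r2 <- best$r2
  y <- best$y
  s2 <- best$s2
  p_runs <- runs_test_pvalue(res)
  list(
    rg_nm = rg,
    i0 = exp(intercept),
    fit_window = c(first = first, last = last),
    srg_max = curve$s[last] * rg,
    r_squared = r2,
    residual_pattern = p_runs,
    slope = slope,
    intercept = intercept,
    n_points = length(idx),
    weighted = has_sigma(curve),
    below_resolution = rg == 0,
    curvature_warning = is.finite(p_runs) && p_runs < 0.01,
    window_data = tibble::tibble(
      s = curve$s[idx], s2 = s2, log_i = y, fitted = y - res, residual = res
    )
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit>%s Rg = %.4g nm, I(0) = %.4g, window %d..%d (s*Rg <= %.3g), R^2 = %.5f\n",
    if (nzchar(x$label %||% "")) paste0(" ", x$label, ":") else "",
    x$rg_nm, x$i0, x$fit_window[1], x$fit_window[2], x$srg_max, x$r_squared
  ))
  if (x$below_resolution) {
    cat("  note: zero slope - particle size below resolution\n")
  }
  if (x$curvature_warning) {
    cat(sprintf("  warning: systematic residual pattern (runs test p = %.2g)\n",
                x$residual_pattern))
  }
  invisible(x)
}

#' Guinier analysis across a scattering series
#'
#' Runs [fit_guinier()] on every curve of a series and tabulates the
#' results against salt concentration. Per-curve failures are
#' collected in the `failures` attribute rather than aborting the
#' whole series.
#'
#' @inheritParams fit_guinier
#' @param series A [scattering_series()].
#' @return Tibble with columns `label`, `salt_mM`, `rg_nm`, `i0`,
#'   `srg_max`, `r_squared`, sorted by salt.
#' @export
guinier_series <- function(series, srg_limit = 1.3, min_points = 10L) {
  stopifnot(is_scattering_series(series))
  fits <- purrr::map(series$curve, function(cv) {
    tryCatch(fit_guinier(cv, srg_limit, min_points),
             saxsmix_error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), what = "error")
  out <- tibble::tibble(
    label = series$label,
    salt_mM = series$salt_mM,
    rg_nm = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$rg_nm, 1),
    i0 = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$i0, 1),
    srg_max = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$srg_max, 1),
    r_squared = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$r_squared, 1)
  )
  attr(out, "fits") <- fits
  attr(out, "failures") <- setNames(
    lapply(fits[failed], conditionMessage), series$label[failed]
  )
  out
}
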