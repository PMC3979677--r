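#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_y_log10 geom_hline facet_wrap theme_minimal geom_col
#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()`
#' returns the per-element table (per component, per condition or per
#' grid point), `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name saxsmix-tidiers
NULL

#' @rdname saxsmix-tidiers
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg_nm", "i0"),
    estimate = c(x$rg_nm, x$i0)
  )
}

#' @rdname saxsmix-tidiers
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(
    rg_nm = x$rg_nm, i0 = x$i0,
    window_first = x$fit_window[1], window_last = x$fit_window[2],
    n_points = x$n_points, srg_max = x$srg_max,
    r_squared = x$r_squared, residual_pattern = x$residual_pattern,
    below_resolution = x$below_resolution,
    curvature_warning = x$curvature_warning
  )
}

#' @rdname saxsmix-tidiers
#' @export
tidy.pddf <- function(x, ...) {
  tibble::tibble(r_nm = x$r_nm, p_r = x$p_r, p_raw = x$p_raw)
}

#' @rdname saxsmix-tidiers
#' @export
glance.pddf <- function(x, ...) {
  tibble::tibble(d_max_nm = x$d_max_nm, rg_nm = x$rg_nm, i0 = x$i0,
                 alpha = x$alpha, fit_chi2 = x$fit_chi2)
}

#' @rdname saxsmix-tidiers
#' @export
tidy.saxs_svd <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$d),
    singular_value = x$d,
    autocorrelation = x$autocorrelations,
    significant = x$autocorrelations > x$threshold & x$d > x$noise_floor
  )
}

#' @rdname saxsmix-tidiers
#' @export
glance.saxs_svd <- function(x, ...) {
  tibble::tibble(n_significant = x$n_significant,
                 noise_floor = x$noise_floor, threshold = x$threshold)
}

#' @rdname saxsmix-tidiers
#' @export
tidy.efa_result <- function(x, ...) {
  I <- nrow(x$forward_sv)
  n <- ncol(x$forward_sv)
  tidyr::pivot_longer(
    tibble::tibble(
      row = rep(seq_len(I), 2L),
      direction = rep(c("forward", "backward"), each = I),
      as.data.frame(rbind(x$forward_sv, x$backward_sv)) |>
        setNames(paste0("sv", seq_len(n)))
    ),
    cols = dplyr::starts_with("sv"),
    names_to = "component", names_prefix = "sv",
    values_to = "singular_value"
  )
}

#' @rdname saxsmix-tidiers
#' @export
tidy.mcr_result <- function(x, ...) {
  I <- nrow(x$c)
  N <- ncol(x$c)
  tibble::tibble(
    label = rep(x$conditions$label, N),
    salt_mM = rep(x$conditions$salt_mM, N),
    component = rep(seq_len(N), each = I),
    fraction = as.numeric(x$c)
  )
}

#' @rdname saxsmix-tidiers
#' @export
glance.mcr_result <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$c),
    lack_of_fit_pct = x$lack_of_fit,
    iterations = x$iterations,
    converged = x$converged
  )
}

# --- plotting -----------------------------------------------------------

#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: log-intensity curve
#' plots, Guinier plots with the fitted window, p(r) profiles,
#' singular-value/autocorrelation diagnostics and fraction-versus-salt
#' profiles.
#'
#' @param object A saxsmix result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name saxsmix-autoplot
NULL

#' @rdname saxsmix-autoplot
#' @export
autoplot.saxs_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df[df$intensity > 0, ], aes(x = .data$s, y = .data$intensity)) +
    geom_line() +
    scale_y_log10() +
    labs(x = expression(s ~ (nm^-1)), y = "I(s) (a.u., log)",
         title = curve_label(object)) +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.scattering_series <- function(object, ...) {
  df <- tidyr::unnest(
    tibble::tibble(
      salt_mM = object$salt_mM,
      data = purrr::map(object$curve, tibble::as_tibble)
    ),
    "data"
  )
  ggplot(df[df$intensity > 0, ],
         aes(x = .data$s, y = .data$intensity,
             colour = factor(.data$salt_mM), group = .data$salt_mM)) +
    geom_line() +
    scale_y_log10() +
    labs(x = expression(s ~ (nm^-1)), y = "I(s) (a.u., log)",
         colour = "salt (mM)") +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.guinier_fit <- function(object, ...) {
  ggplot(object$window_data, aes(x = .data$s2)) +
    geom_point(aes(y = .data$log_i)) +
    geom_line(aes(y = .data$fitted), colour = "red") +
    labs(x = expression(s^2 ~ (nm^-2)), y = "ln I(s)",
         title = sprintf("Guinier fit: Rg = %.3g nm", object$rg_nm)) +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.pddf <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$r_nm, y = .data$p_r)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "r (nm)", y = "p(r) (normalized)",
         title = sprintf("p(r), Dmax = %.3g nm", object$d_max_nm)) +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.saxs_svd <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("singular_value", "autocorrelation"),
                              names_to = "metric")
  ggplot(long, aes(x = .data$component, y = .data$value,
                   fill = .data$significant)) +
    geom_col() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "component", y = NULL) +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.mcr_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$salt_mM, y = .data$fraction,
                 colour = factor(.data$component))) +
    geom_line() +
    geom_point() +
    labs(x = "salt (mM)", y = "fraction", colour = "component") +
    theme_minimal()
}

#' @rdname saxsmix-autoplot
#' @export
autoplot.dmax_scan <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$d_max, y = .data$chi2)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = min(object$scan$chi2) * 1.05,
               linetype = "dashed") +
    labs(x = expression(D[max] ~ (nm)), y = expression(chi^2),
         title = sprintf("Dmax scan: chosen %.3g nm", object$d_max_nm)) +
    theme_minimal()
}
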