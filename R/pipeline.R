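#' Pipeline configuration
#'
#' Bundles and validates every tunable of the analysis chain. The
#' effective configuration is echoed into each report so that any
#' output directory is self-describing.
#'
#' @param s_max Column truncation for decomposition, nm^-1.
#' @param srg_limit Guinier window limit on s*R_G.
#' @param autocorr_threshold SVD component-count threshold.
#' @param n_components `"auto"` (use the SVD estimate) or an integer.
#' @param als_tol,als_max_iter MCR-ALS convergence controls.
#' @param dmax_range Length-2 scan range for [dmax_scan()], nm, or
#'   `NULL` to derive it from the Guinier radius (2 to 5 R_G).
#' @param dmax_step Scan step, nm.
#' @param scale_by_conc Divide rows by protein concentration before
#'   decomposition.
#' @param seed Integer seed recorded with every output.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(s_max = 2.0, srg_limit = 1.3,
                       autocorr_threshold = 0.6, n_components = "auto",
                       als_tol = 1e-9, als_max_iter = 500L,
                       dmax_range = NULL, dmax_step = 0.25,
                       scale_by_conc = FALSE, seed = 1L) {
  stopifnot(s_max > 0, srg_limit > 0,
            autocorr_threshold >= 0, autocorr_threshold <= 1,
            als_tol > 0, als_max_iter >= 1,
            dmax_step > 0,
            is.null(dmax_range) ||
              (length(dmax_range) == 2L && dmax_range[1] > 0 &&
                 dmax_range[2] > dmax_range[1]))
  if (!identical(n_components, "auto")) {
    n_components <- as.integer(n_components)
    stopifnot(n_components >= 1L)
  }
  structure(list(
    s_max = s_max, srg_limit = srg_limit,
    autocorr_threshold = autocorr_threshold,
    n_components = n_components,
    als_tol = als_tol, als_max_iter = as.integer(als_max_iter),
    dmax_range = dmax_range, dmax_step = dmax_step,
    scale_by_conc = scale_by_conc, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full decomposition pipeline on a scattering series
#'
#' Chains the whole analysis: matrix building, SVD component count,
#' EFA initialisation, constrained MCR-ALS, monomer/dimer labeling
#' with volume fractions, pure-curve extraction, and Guinier plus
#' maximum-diameter analysis of each pure curve. When the component
#' count resolves to one the pipeline stops after the SVD stage — a
#' single-species series has nothing to decompose. A stage failure
#' aborts with the stage name; results of completed stages are kept
#' in the partial report attached to the error condition.
#'
#' @param x A [scattering_series()] or the path of a series manifest
#'   for [load_series()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes pure-curve
#'   `.dat` files, `fractions.csv`, `svd_report.csv`,
#'   `convergence.csv` and a machine-readable `summary.json`.
#' @return Object of class `saxs_pipeline` with elements `matrix`,
#'   `svd`, `efa`, `mcr`, `fractions`, `pure_curves`, `guinier`,
#'   `dmax`, `config`, `summary`.
#' @export
run_pipeline <- function(x, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  series <- if (is.character(x)) load_series(x) else x
  stopifnot(is_scattering_series(series))
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "saxsmix_pipeline_error", partial = res)
    })
  }
  res$matrix <- stage("build_matrix",
                      build_matrix(series, s_max = config$s_max,
                                   scale_by_conc = config$scale_by_conc))
  res$svd <- stage("svd_analysis",
                   svd_analysis(res$matrix, config$autocorr_threshold))
  n <- if (identical(config$n_components, "auto")) {
    res$svd$n_significant
  } else {
    config$n_components
  }
  res$n_components <- n
  if (n <= 1L) {
    inform(sprintf("SVD finds %d significant component(s); nothing to decompose",
                   n))
    res$summary <- pipeline_summary(res, series)
    out <- structure(res, class = "saxs_pipeline")
    if (!is.null(out_dir)) write_pipeline(out, out_dir)
    return(out)
  }
  res$efa <- stage("efa", efa(res$matrix, n))
  res$mcr <- stage("mcr_als",
                   mcr_als(res$matrix, res$efa$initial_c,
                           tol = config$als_tol,
                           max_iter = config$als_max_iter))
  if (n == 2L) {
    res$fractions <- stage("volume_fractions",
                           volume_fractions(res$mcr, series))
    res$pure_curves <- stage("extract_pure_curves",
                             extract_pure_curves(res$mcr, res$matrix))
    res$guinier <- stage("guinier", purrr::map(
      res$pure_curves, fit_guinier, srg_limit = config$srg_limit))
    res$dmax <- stage("dmax_scan", purrr::map(
      res$pure_curves, function(cv) {
        rng <- config$dmax_range
        if (is.null(rng)) {
          rg <- fit_guinier(cv, config$srg_limit)$rg_nm
          rng <- c(max(config$dmax_step, 2 * rg), 5 * rg)
        }
        dmax_scan(cv, rng, step = config$dmax_step)
      }))
  }
  res$summary <- pipeline_summary(res, series)
  out <- structure(res, class = "saxs_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

pipeline_summary <- function(res, series) {
  s <- list(
    n_conditions = nrow(series),
    salt_mM = series$salt_mM,
    s_max = res$config$s_max,
    seed = res$config$seed,
    n_components = res$n_components,
    singular_values = res$svd$d,
    autocorrelations = res$svd$autocorrelations,
    config = unclass(res$config)
  )
  if (!is.null(res$mcr)) {
    s$lack_of_fit_pct <- res$mcr$lack_of_fit
    s$iterations <- res$mcr$iterations
    s$converged <- res$mcr$converged
  }
  if (!is.null(res$fractions)) {
    s$fractions <- as.data.frame(res$fractions)
    s$spearman_dimer_vs_salt <- attr(res$fractions, "spearman_dimer_vs_salt")
  }
  if (!is.null(res$guinier)) {
    s$species_rg_nm <- purrr::map_dbl(res$guinier, "rg_nm")
    s$species_i0 <- purrr::map_dbl(res$guinier, "i0")
  }
  if (!is.null(res$dmax)) {
    s$species_dmax_nm <- purrr::map_dbl(res$dmax, "d_max_nm")
  }
  s
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble::tibble(component = seq_along(x$svd$d),
                   singular_value = x$svd$d,
                   autocorrelation = x$svd$autocorrelations),
    file.path(out_dir, "svd_report.csv")
  )
  if (!is.null(x$mcr)) {
    readr::write_csv(
      tibble::tibble(iteration = seq_along(x$mcr$lof_trace),
                     lack_of_fit_pct = x$mcr$lof_trace),
      file.path(out_dir, "convergence.csv")
    )
  }
  if (!is.null(x$fractions)) {
    readr::write_csv(x$fractions, file.path(out_dir, "fractions.csv"))
  }
  if (!is.null(x$pure_curves)) {
    purrr::iwalk(x$pure_curves, function(cv, nm) {
      write_dat(cv, file.path(out_dir, paste0(nm, ".dat")))
    })
  }
  jsonlite::write_json(x$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.saxs_pipeline <- function(x, ...) {
  cat(sprintf("<saxs_pipeline> %d component(s)\n", x$n_components))
  if (!is.null(x$mcr)) print(x$mcr)
  if (!is.null(x$fractions)) print(x$fractions)
  if (!is.null(x$guinier)) {
    for (nm in names(x$guinier)) {
      cat(sprintf("  %s: Rg = %.3g nm, Dmax = %.3g nm\n", nm,
                  x$guinier[[nm]]$rg_nm,
                  if (!is.null(x$dmax)) x$dmax[[nm]]$d_max_nm else NA))
    }
  }
  invisible(x)
}
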