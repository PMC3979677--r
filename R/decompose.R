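#' Build the conditions-by-s data matrix of a scattering series
#'
#' Stacks the curves of a series, sorted by ascending salt, into the
#' I x J matrix that the factor-analysis stages operate on, with
#' columns truncated at `s_max` (default 2 nm^-1, past which the
#' signal-to-noise of protein solution scattering is too poor for
#' factor analysis). Weights derived from the per-point uncertainties
#' are carried along when every curve provides them. Optional per-row
#' scaling divides each curve by its protein concentration so that
#' concentration differences between conditions do not masquerade as
#' fraction changes.
#'
#' @param series A [scattering_series()].
#' @param s_max Column truncation, nm^-1 (default 2.0). A value beyond
#'   the measured range keeps the full width, with a warning.
#' @param scale_by_conc Divide each row by its `conc_mg_ml`.
#' @return Object of class `scattering_matrix`: intensity matrix `a`
#'   (rows = conditions in salt order), `s_grid`, `conditions` tibble,
#'   and optional `weights` (1/sigma).
#' @export
build_matrix <- function(series, s_max = 2.0, scale_by_conc = FALSE) {
  stopifnot(is_scattering_series(series))
  if (nrow(series) < 2L) {
    stop_saxsmix("at least 2 conditions are required for decomposition",
                 "saxsmix_not_decomposable")
  }
  data_max <- min(vapply(series$curve, function(cv) max(cv$s), numeric(1)))
  if (s_max > data_max) {
    warn(sprintf("s_max = %.3g exceeds the measured range (%.3g); using the full width",
                 s_max, data_max))
  }
  series <- common_grid(series, s_max = s_max)
  grid <- series$curve[[1]]$s
  a <- do.call(rbind, lapply(series$curve, function(cv) cv$intensity))
  weights <- if (all(vapply(series$curve, has_sigma, logical(1)))) {
    do.call(rbind, lapply(series$curve, function(cv) 1 / cv$sigma))
  }
  if (isTRUE(scale_by_conc)) {
    a <- a / series$conc_mg_ml
    if (!is.null(weights)) weights <- weights * series$conc_mg_ml
  }
  if (ncol(a) < 50L) {
    warn(sprintf("only %d s points after truncation; factor analysis may be unstable",
                 ncol(a)))
  }
  rownames(a) <- series$label
  structure(list(
    a = a,
    s_grid = grid,
    conditions = tibble::tibble(label = series$label,
                                salt_mM = series$salt_mM,
                                conc_mg_ml = series$conc_mg_ml),
    weights = weights,
    s_max = s_max,
    scaled_by_conc = isTRUE(scale_by_conc)
  ), class = "scattering_matrix")
}

#' @export
print.scattering_matrix <- function(x, ...) {
  cat(sprintf("<scattering_matrix> %d conditions x %d s points (s <= %.3g nm^-1)\n",
              nrow(x$a), ncol(x$a), max(x$s_grid)))
  invisible(x)
}

# noise floor for singular values: 3x the median of the trailing half
# (strictly past the midpoint, so that for small series the last
# plausible signal component never contaminates its own floor)
sv_noise_floor <- function(d) {
  r <- length(d)
  if (r < 2L) return(0)
  trailing <- d[(ceiling(r / 2) + 1L):r]
  3 * median(trailing)
}

#' Singular value decomposition with eigenvector-autocorrelation
#' component counting
#'
#' Decomposes the data matrix as \eqn{A = U \Sigma V^T} and estimates
#' the number of independently scattering species as the number of
#' components that pass a dual criterion: the lag-1 autocorrelation of
#' the right (spectral) singular vector exceeds
#' `autocorr_threshold` (smooth, signal-like vectors score near 1,
#' white noise near 0) and the singular value sits above a noise
#' floor of three times the median trailing singular value. The sign
#' of each component is fixed so that the largest-magnitude element of
#' its right vector is positive.
#'
#' @param m A [build_matrix()] result.
#' @param autocorr_threshold Autocorrelation cut-off (default 0.6).
#' @return Object of class `saxs_svd`: `u`, `d` (singular values,
#'   descending), `v`, `autocorrelations`, `n_significant`,
#'   `noise_floor`, `threshold`.
#' @export
svd_analysis <- function(m, autocorr_threshold = 0.6) {
  stopifnot(inherits(m, "scattering_matrix"))
  dec <- svd(m$a)
  # canonical sign: largest |element| of each right vector positive
  for (k in seq_along(dec$d)) {
    j <- which.max(abs(dec$v[, k]))
    if (dec$v[j, k] < 0) {
      dec$v[, k] <- -dec$v[, k]
      dec$u[, k] <- -dec$u[, k]
    }
  }
  ac <- apply(dec$v, 2, lag1_autocorr)
  floor_val <- sv_noise_floor(dec$d)
  n_sig <- sum(ac > autocorr_threshold & dec$d > floor_val)
  structure(list(
    u = dec$u, d = dec$d, v = dec$v,
    autocorrelations = ac,
    n_significant = as.integer(n_sig),
    noise_floor = floor_val,
    threshold = autocorr_threshold
  ), class = "saxs_svd")
}

#' @export
print.saxs_svd <- function(x, ...) {
  cat(sprintf("<saxs_svd> %d significant component(s) of %d\n",
              x$n_significant, length(x$d)))
  print(tibble::tibble(component = seq_along(x$d),
                       singular_value = x$d,
                       autocorrelation = x$autocorrelations,
                       significant = x$autocorrelations > x$threshold &
                         x$d > x$noise_floor))
  invisible(x)
}

#' Evolving factor analysis of an ordered scattering series
#'
#' Computes singular values of the growing leading submatrices (rows
#' 1..i, "forward") and growing trailing submatrices (rows i..I,
#' "backward") of the ordered series. Component k's support window
#' runs from the first forward position where its singular value
#' emerges above the noise floor to the last backward position where
#' it persists; the classic min(forward, reversed-backward)
#' combination of the singular-value profiles, renormalized to row
#' sums of one, gives the initial concentration estimate handed to
#' [mcr_als()].
#'
#' @param m A [build_matrix()] result.
#' @param n Number of components to profile.
#' @return Object of class `efa_result`: `forward_sv` and
#'   `backward_sv` (I x n), `initial_c` (I x n, row-stochastic),
#'   `windows` tibble.
#' @export
efa <- function(m, n) {
  stopifnot(inherits(m, "scattering_matrix"))
  I <- nrow(m$a)
  n <- as.integer(n)
  if (n > I) {
    stop_saxsmix(sprintf("n = %d components exceed the %d conditions", n, I),
                 "saxsmix_dimension_error")
  }
  full_d <- svd(m$a, nu = 0, nv = 0)$d
  nsig <- svd_analysis(m)$n_significant
  if (n > nsig) {
    warn(sprintf("requesting n = %d components but only %d look significant",
                 n, nsig))
  }
  floor_val <- sv_noise_floor(full_d)
  pad_sv <- function(a_sub) {
    d <- svd(a_sub, nu = 0, nv = 0)$d
    c(d, numeric(n))[seq_len(n)]
  }
  forward <- t(matrix(vapply(seq_len(I),
                             function(i) pad_sv(m$a[1:i, , drop = FALSE]),
                             numeric(n)), nrow = n))
  backward <- t(matrix(vapply(seq_len(I),
                              function(i) pad_sv(m$a[i:I, , drop = FALSE]),
                              numeric(n)), nrow = n))
  profile <- vapply(seq_len(n), function(k) {
    pmin(forward[, k], backward[, n - k + 1L])
  }, numeric(I))
  profile <- matrix(profile, nrow = I)
  profile[profile < floor_val] <- 0
  windows <- tibble::tibble(
    component = seq_len(n),
    first = vapply(seq_len(n), function(k) {
      w <- which(forward[, k] > floor_val)
      if (length(w)) w[1] else NA_integer_
    }, integer(1)),
    last = vapply(seq_len(n), function(k) {
      w <- which(backward[, n - k + 1L] > floor_val)
      if (length(w)) w[length(w)] else NA_integer_
    }, integer(1))
  )
  rs <- rowSums(profile)
  initial_c <- profile
  zero <- rs == 0
  initial_c[!zero, ] <- profile[!zero, , drop = FALSE] / rs[!zero]
  if (any(zero)) {
    # no transient window covers these rows (fewer real species than
    # requested components): seed from the forward singular-value
    # magnitudes so that a spurious component starts near zero weight
    # instead of an arbitrary uniform split
    fb <- forward[zero, , drop = FALSE] + .Machine$double.eps
    initial_c[zero, ] <- fb / rowSums(fb)
  }
  structure(list(
    forward_sv = forward,
    backward_sv = backward,
    initial_c = initial_c,
    windows = windows,
    noise_floor = floor_val
  ), class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("<efa_result> %d component(s) over %d conditions\n",
              ncol(x$initial_c), nrow(x$initial_c)))
  print(x$windows)
  invisible(x)
}

# Column-wise non-negative least squares min ||A X - B||_F, X >= 0,
# exact and vectorized across columns for small ncol(A): every support
# set is solved by normal equations for all columns at once and a
# column adopts the first support whose solution is feasible (x >= 0)
# and KKT-optimal (gradient <= 0 off the support).
nnls_columns <- function(A, B) {
  n <- ncol(A)
  k <- ncol(B)
  tol <- 1e-10 * max(1, norm(A, "F"))^2
  X <- matrix(0, n, k)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  assigned <- colSums(abs(AtB)) <= tol  # b orthogonal-ish: x = 0 optimal
  for (mask in seq_len(2^n - 1L)) {
    if (all(assigned)) break
    P <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    sol <- tryCatch(
      solve(AtA[P, P, drop = FALSE], AtB[P, , drop = FALSE]),
      error = function(e) NULL
    )
    if (is.null(sol)) next
    feasible <- colSums(sol < -1e-12) == 0
    grad <- AtB - AtA[, P, drop = FALSE] %*% sol  # n x k
    optimal <- colSums(grad[-P, , drop = FALSE] > tol) == 0
    take <- which(!assigned & feasible & optimal)
    if (length(take)) {
      Xp <- matrix(0, n, length(take))
      Xp[P, ] <- pmax(sol[, take, drop = FALSE], 0)
      X[, take] <- Xp
      assigned[take] <- TRUE
    }
  }
  for (j in which(!assigned)) {
    X[, j] <- nnls_solve(A, B[, j])
  }
  X
}

# Exact closure-constrained non-negative least squares for one row:
# min ||A x - b||  s.t.  x >= 0, sum(x) = 1.  Solved by enumerating
# the support set (N is small) and solving the equality-constrained
# KKT system on each support; exactness keeps the ALS descent
# monotone, which row renormalization would not.
nnls_closure <- function(A, b) {
  n <- ncol(A)
  # rescale so the KKT blocks (A^T A vs the closure row of ones) are
  # commensurate; the argmin under sum(x) = 1 is scale-invariant
  sc <- norm(A, "F")
  if (sc > 0) {
    A <- A / sc
    b <- b / sc
  }
  best_x <- rep(1 / n, n)
  best_obj <- Inf
  for (mask in seq_len(2^n - 1L)) {
    P <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    Ap <- A[, P, drop = FALSE]
    k <- length(P)
    kkt <- rbind(cbind(crossprod(Ap), rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(crossprod(Ap, b), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    xp <- sol[seq_len(k)]
    if (any(xp < -1e-12)) next
    x <- numeric(n)
    x[P] <- pmax(xp, 0)
    x <- x / sum(x)
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best_x <- x
    }
  }
  best_x
}

#' Multivariate curve resolution by alternating least squares
#'
#' Factorizes the data matrix as \eqn{D = C S + E} where the rows of
#' `C` are per-condition component weights and the rows of `S` are
#' pure species scattering functions, under three constraints:
#' \eqn{S \ge 0}, \eqn{C \ge 0}, and closure (each row of `C` sums to
#' one, the weights being interpreted as scattering-weight "volume"
#' fractions). Each half-step is a true constrained least squares
#' solve: per-column non-negative least squares for `S`, and an exact
#' closure-constrained non-negative solve per row for `C`, so the
#' lack of fit descends monotonically (row renormalization, the
#' common shortcut, is not a descent step).
#' Iteration stops when the relative change of the lack of fit,
#' \eqn{100\sqrt{\sum E^2 / \sum D^2}} percent, falls below `tol`.
#' Components are canonically ordered by descending forward scattering
#' of the pure curves, removing permutation ambiguity.
#'
#' @param m A [build_matrix()] result.
#' @param initial_c I x N initial weight matrix, rows summing to one
#'   (typically `efa(m, n)$initial_c`).
#' @param tol Relative lack-of-fit change declaring convergence
#'   (default 1e-9).
#' @param max_iter Iteration cap (default 500).
#' @param weighted Use the sigma-derived weights of `m` in both
#'   half-steps (default `FALSE`, matching common MCR-ALS practice).
#' @return Object of class `mcr_result`: `c` (I x N), `s_pure`
#'   (N x J), `e` (I x J residuals), `lack_of_fit` (percent),
#'   `lof_trace`, `iterations`, `converged`, plus the grid and
#'   conditions for downstream use.
#' @export
mcr_als <- function(m, initial_c, tol = 1e-9, max_iter = 500L,
                    weighted = FALSE) {
  stopifnot(inherits(m, "scattering_matrix"))
  D <- m$a
  C <- as.matrix(initial_c)
  if (nrow(C) != nrow(D)) {
    stop_saxsmix("initial_c must have one row per condition",
                 "saxsmix_dimension_error")
  }
  if (any(C < 0) || any(abs(rowSums(C) - 1) > 1e-6)) {
    warn("initial_c is not row-stochastic; renormalizing")
    C[C < 0] <- 0
    C <- C / pmax(rowSums(C), .Machine$double.eps)
  }
  N <- ncol(C)
  W <- if (isTRUE(weighted) && !is.null(m$weights)) m$weights
  denom <- sum(D^2)
  lof <- function(E) 100 * sqrt(sum(E^2) / denom)
  lof_trace <- numeric(0)
  lof_prev <- Inf
  n_up <- 0L
  converged <- FALSE
  S <- NULL
  for (it in seq_len(max_iter)) {
    # S-step: per s-column NNLS given C
    S <- if (is.null(W)) {
      nnls_columns(C, D)
    } else {
      vapply(seq_len(ncol(D)), function(j) {
        nnls_solve(C * W[, j], D[, j] * W[, j])
      }, numeric(N))
    }
    S <- matrix(S, N, ncol(D))
    E <- D - C %*% S
    lof_now <- lof(E)
    lof_trace <- c(lof_trace, lof_now)
    # both half-steps are exact constrained solves, so beyond numerical
    # jitter the lack of fit cannot rise
    if (lof_now > lof_prev * (1 + 1e-9)) {
      n_up <- n_up + 1L
      if (n_up > 10L) {
        stop_saxsmix(
          sprintf("MCR-ALS diverging: lack of fit rose over %d consecutive iterations (%.4g%% at iteration %d)",
                  n_up, lof_now, it),
          "saxsmix_convergence_error"
        )
      }
    } else {
      n_up <- 0L
    }
    if (is.finite(lof_prev) &&
        abs(lof_prev - lof_now) < tol * max(lof_now, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    lof_prev <- lof_now
    # C-step: exact closure-constrained NNLS per condition row
    C <- t(vapply(seq_len(nrow(D)), function(i) {
      if (is.null(W)) {
        nnls_closure(t(S), D[i, ])
      } else {
        nnls_closure(t(S) * W[i, ], D[i, ] * W[i, ])
      }
    }, numeric(N)))
  }
  E <- D - C %*% S
  # canonical component order: descending I(0) (first-column intensity)
  ord <- order(S[, 1], decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  structure(list(
    c = C,
    s_pure = S,
    e = E,
    lack_of_fit = lof(E),
    lof_trace = lof_trace,
    iterations = length(lof_trace),
    converged = converged,
    s_grid = m$s_grid,
    conditions = m$conditions
  ), class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf(
    "<mcr_result> %d component(s) x %d condition(s); lack of fit %.4g%%; %d iteration(s)%s\n",
    ncol(x$c), nrow(x$c), x$lack_of_fit, x$iterations,
    if (x$converged) " (converged)" else " (NOT converged)"
  ))
  invisible(x)
}

# assign monomer/dimer identity to a 2-component result via Guinier Rg
# (larger Rg -> dimer); falls back to I(0) when a fit fails
assign_species_labels <- function(r) {
  stopifnot(inherits(r, "mcr_result"), ncol(r$c) == 2L)
  rg <- vapply(1:2, function(k) {
    crv <- saxs_curve(r$s_grid, pmax(r$s_pure[k, ], 0))
    tryCatch(fit_guinier(crv)$rg_nm, error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(rg) || diff(rg) == 0) {
    i0 <- r$s_pure[, 1]
    dimer <- which.max(i0)
  } else {
    dimer <- which.max(rg)
  }
  labels <- c("monomer", "monomer")
  labels[dimer] <- "dimer"
  list(labels = labels, rg = rg)
}

#' Per-condition volume fractions of monomer and dimer
#'
#' For a two-component factorization, identifies which pure curve is
#' the monomer and which the dimer by their Guinier radii (the larger
#' \eqn{R_G} is the dimer; forward scattering breaks ties) and tables
#' the closure-constrained weights of `C` against salt concentration.
#' The Spearman correlation of the dimer fraction with salt is
#' attached as a monotonic-trend statistic. A component whose fraction
#' never exceeds 0.02 is flagged degenerate (the series is effectively
#' single-species).
#'
#' @param r An [mcr_als()] result with N = 2.
#' @param series Optional [scattering_series()] supplying salt values;
#'   defaults to the conditions stored in `r`.
#' @return Tibble `salt_mM`, `fraction_monomer`, `fraction_dimer` with
#'   attributes `spearman_dimer_vs_salt`, `species_rg_nm`,
#'   `degenerate`.
#' @export
volume_fractions <- function(r, series = NULL) {
  stopifnot(inherits(r, "mcr_result"))
  if (ncol(r$c) != 2L) {
    stop_saxsmix(
      sprintf("monomer/dimer labeling needs exactly 2 components, got %d (use tidy() for the generic table)",
              ncol(r$c)),
      "saxsmix_labeling_error"
    )
  }
  salt <- if (!is.null(series)) series$salt_mM else r$conditions$salt_mM
  lab <- assign_species_labels(r)
  mono <- which(lab$labels == "monomer")
  dim_ <- which(lab$labels == "dimer")
  out <- tibble::tibble(
    salt_mM = salt,
    fraction_monomer = r$c[, mono],
    fraction_dimer = r$c[, dim_]
  )
  degenerate <- vapply(1:2, function(k) max(r$c[, k]) < 0.02, logical(1))
  if (any(degenerate)) {
    warn(sprintf("component '%s' is degenerate (fraction < 0.02 everywhere)",
                 lab$labels[degenerate][1]),
         class = "saxsmix_degenerate_component")
  }
  sp <- suppressWarnings(cor(out$fraction_dimer, out$salt_mM,
                             method = "spearman"))
  attr(out, "spearman_dimer_vs_salt") <- sp
  attr(out, "species_rg_nm") <- setNames(lab$rg, lab$labels)
  attr(out, "degenerate") <- any(degenerate)
  out
}

#' Re-attach the pure component curves to the momentum-transfer grid
#'
#' Converts the rows of `S` from a labeled two-component factorization
#' back into [saxs_curve()] objects, with per-point uncertainties
#' taken from the column residual variance of the factorization, so
#' they can feed straight into [fit_guinier()] and [pr_transform()].
#'
#' @param r An [mcr_als()] result with N = 2.
#' @param m The [build_matrix()] input (for the grid; optional).
#' @return Named list with elements `monomer` and `dimer`.
#' @export
extract_pure_curves <- function(r, m = NULL) {
  stopifnot(inherits(r, "mcr_result"))
  if (ncol(r$c) != 2L) {
    stop_saxsmix("pure-curve extraction is defined for 2 labeled components",
                 "saxsmix_labeling_error")
  }
  grid <- if (!is.null(m)) m$s_grid else r$s_grid
  lab <- assign_species_labels(r)
  dof <- max(1L, nrow(r$e) - ncol(r$c))
  sigma <- sqrt(colSums(r$e^2) / dof)
  sigma <- pmax(sigma, 1e-12 * max(abs(r$s_pure)))
  curves <- lapply(1:2, function(k) {
    saxs_curve(grid, pmax(r$s_pure[k, ], 0), sigma,
               label = lab$labels[k])
  })
  setNames(curves, lab$labels)[c("monomer", "dimer")]
}

#' Reduced chi-square between a model curve and measured data
#'
#' \deqn{\chi^2_{red} = \frac{1}{J-1}\sum_j
#'   \left(\frac{c\,I_{model}(s_j) - I_{data}(s_j)}{\sigma_j}\right)^2}
#' after the optimal scalar scaling `c` of the model onto the data.
#'
#' @param model,data [saxs_curve()] objects on a common grid; `data`
#'   must carry uncertainties.
#' @param scale Fit the optimal scalar scaling of the model first
#'   (default `TRUE`); `FALSE` compares on the absolute scale.
#' @return The reduced chi-square (scalar), with the fitted scale as
#'   attribute `scale`.
#' @export
chi2_fit <- function(model, data, scale = TRUE) {
  stopifnot(is_saxs_curve(model), is_saxs_curve(data))
  if (!same_grid(model, data)) {
    stop_saxsmix("model and data are not on the same grid",
                 "saxsmix_grid_error")
  }
  if (!has_sigma(data)) {
    stop_saxsmix("chi-square requires data uncertainties",
                 "saxsmix_requires_uncertainty")
  }
  w <- 1 / data$sigma^2
  sc <- if (scale) {
    sum(w * model$intensity * data$intensity) / sum(w * model$intensity^2)
  } else {
    1
  }
  J <- nrow(data)
  chi2 <- sum(w * (sc * model$intensity - data$intensity)^2) / (J - 1L)
  structure(chi2, scale = sc)
}
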