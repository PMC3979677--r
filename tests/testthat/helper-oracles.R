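# closed-form sphere form factor, normalized to I(0) = 1
sphere_form_factor <- function(s, radius) {
  x <- s * radius
  out <- rep(1, length(s))
  nz <- x != 0
  out[nz] <- (3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3)^2
  out
}

# analytic sphere curve with counting-like nominal uncertainties
sphere_curve <- function(radius = 3, s = seq(0.02, 2, by = 0.01),
                         noise_level = 0, sigma_level = 0.01, seed = 1) {
  intensity <- sphere_form_factor(s, radius)
  sigma <- sigma_level * sqrt((intensity + 1e-6) * intensity[1])
  if (noise_level > 0) {
    intensity <- withr::with_seed(seed, {
      intensity + stats::rnorm(length(s), 0, noise_level *
                                 sqrt((intensity + 1e-6) * intensity[1]))
    })
  }
  saxs_curve(s, pmax(intensity, 0), sigma = sigma, label = "sphere",
             subtracted = noise_level > 0)
}

# Monte-Carlo oracle for the sphere pair-distance distribution:
# histogram of distances between uniform random point pairs in a ball
mc_sphere_pddf <- function(radius = 3, n = 2e5, breaks = 102, seed = 1) {
  withr::with_seed(seed, {
    draw <- function() {
      m <- matrix(stats::runif(3 * 2 * n, -1, 1) * radius, ncol = 3)
      m <- m[rowSums(m^2) <= radius^2, , drop = FALSE]
      m[seq_len(n), ]
    }
    d <- sqrt(rowSums((draw() - draw())^2))
    h <- graphics::hist(d, breaks = seq(0, 2 * radius, length.out = breaks),
                        plot = FALSE)
    list(r = h$mids, p = h$density)
  })
}

cosine_similarity <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# truth-aligned recovery metrics for a 2-component factorization
recovery_metrics <- function(mr, truth, m) {
  keep <- truth$s_grid %in% m$s_grid
  vf <- suppressWarnings(volume_fractions(mr))
  list(
    fraction_rmse = sqrt(mean((vf$fraction_dimer - truth$fractions[, "dimer"])^2)),
    min_pearson = min(
      stats::cor(mr$s_pure[1, ], truth$pure_curves["dimer", keep]),
      stats::cor(mr$s_pure[2, ], truth$pure_curves["monomer", keep])
    ),
    min_cosine = min(
      cosine_similarity(mr$s_pure[1, ], truth$pure_curves["dimer", keep]),
      cosine_similarity(mr$s_pure[2, ], truth$pure_curves["monomer", keep])
    )
  )
}

# decompose a series end to end (matrix -> EFA -> MCR)
decompose_series <- function(series, n = 2, s_max = 2) {
  m <- suppressWarnings(build_matrix(series, s_max = s_max))
  mr <- mcr_als(m, suppressWarnings(efa(m, n))$initial_c)
  list(matrix = m, mcr = mr)
}
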