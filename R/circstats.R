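# Circular statistics: Hermans-Rasson omnibus test, Rayleigh test, von Mises
# goodness of fit, the uniform/multimodal/unimodal decision procedure, and
# group comparisons (Watson-Williams, angular-dispersion Kruskal-Wallis).
# Angles are degrees at the interface and radians internally.

#' Circular mean and angular variance
#'
#' Mean direction `arg(sum(exp(i*theta)))` in degrees `[0, 360)` and angular
#' variance `1 - Rbar` (0 = all angles identical, 1 = no concentration).
#'
#' @param deg angles in degrees.
#' @return list `mean_deg`, `ang_var`, `r_bar`, `n`.
#' @export
circular_mean_variance <- function(deg) {
  if (length(deg) < 1L) stop_field("deg", "needs at least one angle")
  if (any(!is.finite(deg))) stop_field("deg", "angles must be finite")
  th <- deg2rad(deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  r_bar <- sqrt(C^2 + S^2)
  if (r_bar < 1e-12) stop("mean direction undefined: resultant length is zero", call. = FALSE)
  list(mean_deg = wrap360(rad2deg(atan2(S, C))), ang_var = 1 - r_bar,
       r_bar = r_bar, n = length(deg))
}

#' Rayleigh test for a unimodal departure from uniformity
#'
#' Mean resultant length `Rbar` with the standard large-sample p-value
#' including the second-order small-n correction.
#'
#' @param deg angles in degrees, n >= 3.
#' @return list `r_bar`, `p`, `n`.
#' @export
rayleigh_test <- function(deg) {
  n <- length(deg)
  if (n < 3L) stop_field("deg", "needs n >= 3")
  th <- deg2rad(deg)
  r_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * r_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(r_bar = r_bar, p = max(0, min(1, p)), n = n)
}

#' Hermans-Rasson statistic
#'
#' Pairwise angular-difference form (all ordered pairs, O(n^2)); large values
#' indicate departure from circular uniformity, including non-axial bimodal
#' alternatives that the Rayleigh statistic misses.
#'
#' @param deg angles in degrees.
#' @return the statistic.
#' @export
hr_statistic <- function(deg) {
  th <- deg2rad(deg)
  n <- length(th)
  D <- outer(th, th, "-")
  tot <- sum(abs(abs(D) - pi) - pi / 2 - 2.895 * (abs(sin(D)) - 2 / pi))
  tot / n
}

#' Hermans-Rasson test for non-uniformity
#'
#' Monte-Carlo p-value: the proportion of uniform-sample statistics at least
#' as large as the observed one, with the +1/(n_mc+1) correction.
#' Deterministic for a fixed `seed`.
#'
#' @param deg angles in degrees, n >= 4.
#' @param n_mc Monte-Carlo replicates (>= 999; default 9999).
#' @param seed RNG seed for the Monte-Carlo sample.
#' @param null_stats optional pre-computed vector of null statistics for this
#'   n (e.g. shared across many tests at the same sample size); overrides
#'   `n_mc`.
#' @return list `statistic`, `p`, `n`, `n_mc`.
#' @export
hermans_rasson_test <- function(deg, n_mc = 9999L, seed = NULL,
                                null_stats = NULL) {
  n <- length(deg)
  if (n < 4L) stop_field("deg", "needs n >= 4")
  if (is.null(null_stats) && n_mc < 999L) stop_field("n_mc", "needs >= 999 replicates")
  obs <- hr_statistic(deg)
  if (is.null(null_stats)) {
    null_stats <- with_seed(seed, function() {
      vapply(seq_len(n_mc), function(i) hr_statistic(stats::runif(n, 0, 360)),
             numeric(1))
    })
  }
  p <- (1 + sum(null_stats >= obs)) / (length(null_stats) + 1)
  list(statistic = obs, p = p, n = n, n_mc = length(null_stats))
}

# --- von Mises distribution ----------------------------------------------

# A1(kappa) = I1(kappa)/I0(kappa), computed stably.
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of A1 by the standard piecewise approximation plus Newton polish.
vm_a1inv <- function(r) {
  if (r >= 1) return(Inf)
  if (r <= 0) return(0)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:4) {
    a <- vm_a1(k)
    da <- 1 - a^2 - a / k  # d A1/d kappa
    if (!is.finite(da) || da <= 0) break
    k <- max(k - (a - r) / da, 1e-8)
  }
  k
}

#' Maximum-likelihood von Mises fit
#'
#' @param deg angles in degrees.
#' @return list `mu_deg`, `kappa`.
#' @export
fit_vonmises <- function(deg) {
  cm <- circular_mean_variance(deg)
  list(mu_deg = cm$mean_deg, kappa = vm_a1inv(cm$r_bar))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives circular uniformity.
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop_field("kappa", "must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
    }
  }
  wrap360(rad2deg(out))
}

# von Mises CDF (probability integral transform used by the Watson U^2
# goodness of fit): trapezoid integration of the density on a fine grid for
# moderate concentration, and the wrapped-normal limit N(mu, 1/kappa) for
# high concentration where the grid would be too coarse. The transform is
# anchored at the antimode (mu + pi), so u is continuous at the mode.
vm_cdf <- function(theta, mu, kappa) {
  d <- (theta - mu) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi  # signed distance to the mode in (-pi, pi]
  if (kappa > 200) {
    return(stats::pnorm(d * sqrt(kappa)))
  }
  ngrid <- 4096L
  grid <- seq(-pi, pi, length.out = ngrid + 1L)
  dens <- exp(kappa * (cos(grid) - 1))
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2)) * (2 * pi / ngrid)
  cum <- cum / cum[length(cum)]
  stats::approx(grid, cum, xout = d)$y
}

watson_u2 <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

#' Von Mises goodness-of-fit check
#'
#' Watson U^2 statistic against the ML-fitted von Mises distribution, with a
#' parametric-bootstrap p-value (the von Mises family is the circular
#' analogue of the normal and is a prerequisite for Rayleigh's unimodality
#' interpretation).
#'
#' @param deg angles in degrees, n >= 5.
#' @param alpha significance level for the accept/reject decision.
#' @param n_boot bootstrap replicates (default 199).
#' @param seed RNG seed.
#' @return list `ok` (fit not rejected at `alpha`), `u2`, `p`, `mu_deg`,
#'   `kappa`.
#' @export
vonmises_check <- function(deg, alpha = 0.05, n_boot = 199L, seed = NULL) {
  n <- length(deg)
  if (n < 5L) stop_field("deg", "needs n >= 5")
  fit <- fit_vonmises(deg)
  if (!is.finite(fit$kappa) || fit$kappa > 1e6) {
    # effectively a point mass: the kappa -> Inf limit of the family
    return(list(ok = TRUE, u2 = 0, p = 1, mu_deg = fit$mu_deg, kappa = fit$kappa))
  }
  obs <- watson_u2(vm_cdf(deg2rad(deg), deg2rad(fit$mu_deg), fit$kappa))
  boot <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      x <- rvonmises(n, fit$mu_deg, fit$kappa)
      f <- fit_vonmises(x)
      watson_u2(vm_cdf(deg2rad(x), deg2rad(f$mu_deg), f$kappa))
    }, numeric(1))
  })
  p <- (1 + sum(boot >= obs)) / (n_boot + 1)
  list(ok = p >= alpha, u2 = obs, p = p, mu_deg = fit$mu_deg, kappa = fit$kappa)
}

#' Classify a circular sample as uniform, multimodal or unimodal
#'
#' The sequential decision procedure: (1) Hermans-Rasson test; not
#' significant = `uniform` (no mean reported). (2) If non-uniform, von Mises
#' goodness of fit; (3) if the fit holds, Rayleigh's test; significant =
#' `nonuniform_unimodal` with circular mean and angular variance, otherwise
#' `nonuniform_multimodal` with mean and variance withheld. A failed von
#' Mises fit is treated as non-unimodal. With `skip_hr = TRUE` (within-trial
#' screening for purely in-sync or out-of-sync behaviour) the procedure
#' starts at step 2 and `uniform` is never returned.
#'
#' @param deg angles in degrees, n >= 5.
#' @param alpha significance level (default 0.05).
#' @param n_mc Hermans-Rasson Monte-Carlo replicates.
#' @param n_boot von Mises bootstrap replicates.
#' @param seed RNG seed (sub-seeds are derived per test).
#' @param skip_hr skip the Hermans-Rasson step.
#' @param hr_null optional pre-computed null statistics for
#'   [hermans_rasson_test()].
#' @return object of class `circ_test_result`: list with `n`, `hr_stat`,
#'   `hr_p`, `vonmises_ok`, `rayleigh_r`, `rayleigh_p`, `classification`,
#'   `mean_deg`, `ang_var` (mean/variance non-`NA` only for
#'   `nonuniform_unimodal`).
#' @export
classify_distribution <- function(deg, alpha = 0.05, n_mc = 9999L,
                                  n_boot = 199L, seed = NULL, skip_hr = FALSE,
                                  hr_null = NULL) {
  n <- length(deg)
  if (n < 5L) stop_field("deg", "needs n >= 5")
  res <- list(n = n, hr_stat = NA_real_, hr_p = NA_real_, vonmises_ok = NA,
              rayleigh_r = NA_real_, rayleigh_p = NA_real_,
              classification = NA_character_, mean_deg = NA_real_,
              ang_var = NA_real_)
  seed1 <- if (is.null(seed)) NULL else seed
  seed2 <- if (is.null(seed)) NULL else (seed + 1L) %% 2147483647L
  if (!skip_hr) {
    hr <- hermans_rasson_test(deg, n_mc = n_mc, seed = seed1, null_stats = hr_null)
    res$hr_stat <- hr$statistic
    res$hr_p <- hr$p
    if (hr$p >= alpha) {
      res$classification <- "uniform"
      class(res) <- "circ_test_result"
      return(res)
    }
  }
  vm <- vonmises_check(deg, alpha = alpha, n_boot = n_boot, seed = seed2)
  res$vonmises_ok <- vm$ok
  if (vm$ok) {
    rl <- rayleigh_test(deg)
    res$rayleigh_r <- rl$r_bar
    res$rayleigh_p <- rl$p
    if (rl$p < alpha) {
      cm <- circular_mean_variance(deg)
      res$classification <- "nonuniform_unimodal"
      res$mean_deg <- cm$mean_deg
      res$ang_var <- cm$ang_var
      class(res) <- "circ_test_result"
      return(res)
    }
  }
  res$classification <- if (skip_hr) "not_unimodal" else "nonuniform_multimodal"
  class(res) <- "circ_test_result"
  res
}

#' @export
print.circ_test_result <- function(x, ...) {
  cat(sprintf("<circ_test_result> n = %d, %s\n", x$n, x$classification))
  if (!is.na(x$hr_p)) cat(sprintf("  HR: stat = %.3f, p = %.4g\n", x$hr_stat, x$hr_p))
  if (!is.na(x$vonmises_ok)) cat(sprintf("  von Mises fit ok: %s\n", x$vonmises_ok))
  if (!is.na(x$rayleigh_p)) {
    cat(sprintf("  Rayleigh: Rbar = %.3f, p = %.4g\n", x$rayleigh_r, x$rayleigh_p))
  }
  if (!is.na(x$mean_deg)) {
    cat(sprintf("  circular mean = %.1f deg, angular variance = %.3f\n",
                x$mean_deg, x$ang_var))
  }
  invisible(x)
}

#' Watson-Williams test for equal angular means
#'
#' Multi-sample F-test with the standard concentration correction factor
#' `1 + 3/(8*kappa)`. A warning is issued when the pooled mean resultant
#' length suggests the concentration assumption is doubtful.
#'
#' @param groups list of angle vectors (degrees), each n >= 5.
#' @return list `F`, `p`, `df1`, `df2`, `kappa`.
#' @export
watson_williams <- function(groups) {
  if (length(groups) < 2L) stop_field("groups", "needs >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 5L)) {
    stop_field("groups", "each group needs n >= 5")
  }
  Rs <- vapply(groups, function(g) {
    th <- deg2rad(g)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2)
  }, numeric(1))
  if (any(Rs < 1e-12)) stop("a group has undefined mean direction", call. = FALSE)
  all_th <- deg2rad(unlist(groups))
  N <- length(all_th)
  k <- length(groups)
  R <- sqrt(sum(cos(all_th))^2 + sum(sin(all_th))^2)
  rw <- sum(Rs) / N
  kap <- vm_a1inv(rw)
  if (rw < 0.45) {
    warning("pooled mean resultant length < 0.45: Watson-Williams concentration assumption doubtful")
  }
  Fstat <- (1 + 3 / (8 * kap)) * ((N - k) * (sum(Rs) - R)) / ((k - 1) * (N - sum(Rs)))
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k, kappa = kap)
}

#' Compare angular dispersion between groups
#'
#' Per-observation dispersion is the absolute circular distance (degrees,
#' <= 180) to the observation's own group circular mean; dispersions are
#' compared across groups with a Kruskal-Wallis test, followed by pairwise
#' Wilcoxon rank-sum comparisons Bonferroni-corrected over the number of
#' pairs.
#'
#' @param groups named list of angle vectors (degrees); each group must have
#'   a defined circular mean.
#' @return list `H`, `df`, `p`, `pairwise` (data.frame `group1`, `group2`,
#'   `p_raw`, `p_adj`), `dispersion` (data.frame `group`, `disp_deg`).
#' @export
dispersion_compare <- function(groups) {
  if (length(groups) < 2L) stop_field("groups", "needs >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  disp <- lapply(groups, function(g) {
    cm <- circular_mean_variance(g)
    circ_dist_deg(g, cm$mean_deg)
  })
  dd <- data.frame(group = rep(names(groups), lengths(disp)),
                   disp_deg = unlist(disp))
  kw <- stats::kruskal.test(disp_deg ~ group, data = dd)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  p_raw <- vapply(seq_len(m), function(j) {
    a <- dd$disp_deg[dd$group == pairs[1, j]]
    b <- dd$disp_deg[dd$group == pairs[2, j]]
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = p_raw,
                   p_adj = bonferroni_adjust(p_raw, m))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw, dispersion = dd)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * family_size)` per value, so the family can be larger than the
#' number of p-values passed (comparisons counted per variable).
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param family_size number of comparisons in the family (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, family_size) {
  if (family_size < 1) stop_field("family_size", "must be >= 1")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_field("pvalues", "must lie in [0, 1]")
  }
  pmin(1, pvalues * family_size)
}
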