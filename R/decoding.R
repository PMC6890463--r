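#' Probability density over response probability on [0, 1]
#'
#' Fits a smooth density to a sample of response probabilities on a
#' fixed, evenly spaced grid over [0, 1], renormalized to integrate to
#' one (trapezoidal rule) after edge truncation. The default family is
#' a Gaussian kernel density with Silverman's bandwidth — the least
#' committal smooth choice; truncated-normal and beta
#' (method-of-moments) families are available.
#'
#' @param values Sample of response probabilities in [0, 1].
#' @param family \code{"kde"} (default), \code{"normal"} or
#'   \code{"beta"}.
#' @param grid_n Number of grid points (default 1001).
#' @param bandwidth Optional KDE bandwidth override.
#' @return An object of class \code{"density_estimate"}: \code{grid},
#'   \code{density}, \code{bandwidth}, \code{n_source}.
#' @export
response_probability_density <- function(values,
                                         family = c("kde", "normal", "beta"),
                                         grid_n = 1001L,
                                         bandwidth = NULL) {
  family <- match.arg(family)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to fit")
  if (any(values < 0 | values > 1))
    stop("response probabilities must lie in [0, 1]")
  grid <- seq(0, 1, length.out = grid_n)
  step <- grid[2L] - grid[1L]
  bw <- NA_real_
  if (family == "kde") {
    bw <- if (!is.null(bandwidth)) bandwidth else
      tryCatch(stats::bw.nrd0(values), error = function(e) NA_real_)
    # degenerate samples (zero spread) collapse to one grid step;
    # bw.nrd0 falls back to |x[1]| there, which is not a scale
    if (!is.finite(bw) || bw <= 0 || stats::sd(values) == 0)
      bw <- step / 2
    dens <- vapply(grid, function(g)
      mean(stats::dnorm(g, mean = values, sd = bw)), numeric(1))
  } else if (family == "normal") {
    mu <- mean(values); s <- stats::sd(values)
    if (!is.finite(s) || s <= 0) s <- step / 2
    dens <- stats::dnorm(grid, mu, s)
  } else {
    mu <- mean(values); v <- stats::var(values)
    if (!is.finite(v) || v <= 0 || v >= mu * (1 - mu)) {
      # fall back to a narrow kernel when moments are degenerate
      return(response_probability_density(values, "kde", grid_n))
    }
    common <- mu * (1 - mu) / v - 1
    dens <- stats::dbeta(grid, mu * common, (1 - mu) * common)
    dens[!is.finite(dens)] <- 0
  }
  z <- trapezoid(grid, dens)
  if (z <= 0) stop("degenerate density (zero mass on the grid)")
  structure(list(grid = grid, density = dens / z, bandwidth = bw,
                 n_source = length(values)),
            class = "density_estimate")
}

trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density on [0,1]: %d grid points, bandwidth %s, n = %d\n",
              length(x$grid), format(signif(x$bandwidth, 3)), x$n_source))
  invisible(x)
}

#' @export
plot.density_estimate <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "response probability", ylab = "density", ...)
  invisible(x)
}

#' Bootstrap response-probability distribution of one animal
#'
#' Pools all non-missing trials across sessions (160 per concentration
#' in the mouse two-concentration design), draws \code{n_boot}
#' resamples of \code{boot_size} trials with replacement, records each
#' resample's mean response probability, and fits a density to those
#' bootstrap means. Defaults (1000 bootstraps of 20 trials) follow the
#' original decoding procedure.
#'
#' @param s A \code{\link{trial_series}}.
#' @param n_boot Number of bootstrap resamples.
#' @param boot_size Trials per resample.
#' @param seed Optional integer seed.
#' @param family,grid_n Passed to
#'   \code{\link{response_probability_density}}.
#' @return A \code{"density_estimate"} with the bootstrap means in
#'   attribute \code{"boot_means"}.
#' @export
bootstrap_response_distribution <- function(s, n_boot = 1000L,
                                            boot_size = 20L, seed = NULL,
                                            family = "kde",
                                            grid_n = 1001L) {
  stopifnot(inherits(s, "trial_series"))
  x <- pooled_trials(s, drop_na = TRUE)
  if (length(x) < boot_size)
    stop("series '", s$animal_id, "' has ", length(x),
         " non-missing trials; need at least boot_size = ", boot_size)
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(k)
      mean(sample(x, boot_size, replace = TRUE)), numeric(1))
    out <- response_probability_density(means, family, grid_n)
    attr(out, "boot_means") <- means
    out
  })
}

#' Overlap coefficient of two densities
#'
#' Trapezoidal integral of the pointwise minimum of two densities on a
#' common grid; 1 for identical densities, near 0 for disjoint
#' supports. Quantifies how indistinguishable responsiveness is at two
#' drug concentrations.
#'
#' @param f,g \code{"density_estimate"} objects on the same grid.
#' @return Fraction in [0, 1].
#' @export
overlap_coefficient <- function(f, g) {
  stopifnot(inherits(f, "density_estimate"), inherits(g, "density_estimate"))
  if (length(f$grid) != length(g$grid) ||
      any(abs(f$grid - g$grid) > 1e-12))
    stop("densities must share one grid")
  min(1, trapezoid(f$grid, pmin(f$density, g$density)))
}

#' Posterior probability of drug condition given responsiveness
#'
#' Bayes' theorem applied pointwise on the response-probability grid:
#' posterior_1(p) = f1(p) pi1 / (f1(p) pi1 + f2(p) pi2). Where both
#' likelihoods underflow (< 1e-12) the posterior is reported as
#' \code{NA} (undefined) rather than 0/0.
#'
#' @param f1,f2 \code{"density_estimate"}s for the two conditions on a
#'   common grid.
#' @param priors Pair of prior probabilities summing to 1 (default
#'   uniform).
#' @return An object of class \code{"posterior_curve"}: \code{grid},
#'   \code{posterior} (P(condition 1 | response probability)),
#'   \code{priors}.
#' @export
bayes_posterior <- function(f1, f2, priors = c(0.5, 0.5)) {
  stopifnot(inherits(f1, "density_estimate"), inherits(f2, "density_estimate"))
  if (length(priors) != 2L || any(priors < 0) || sum(priors) == 0)
    stop("'priors' must be two non-negative values, not both zero")
  priors <- priors / sum(priors)
  if (length(f1$grid) != length(f2$grid) ||
      any(abs(f1$grid - f2$grid) > 1e-12))
    stop("densities must share one grid")
  num <- f1$density * priors[1L]
  den <- num + f2$density * priors[2L]
  post <- ifelse(f1$density < 1e-12 & f2$density < 1e-12,
                 NA_real_, num / den)
  structure(list(grid = f1$grid, posterior = post, priors = priors),
            class = "posterior_curve")
}

#' @export
print.posterior_curve <- function(x, ...) {
  cat(sprintf("Posterior curve on %d grid points (priors %.2f / %.2f), %d undefined\n",
              length(x$grid), x$priors[1L], x$priors[2L],
              sum(is.na(x$posterior))))
  invisible(x)
}

#' Per-animal overlap of bootstrap densities at two concentrations
#'
#' For each animal observed at both concentrations (matched by id),
#' computes the overlap of its two bootstrap response-probability
#' densities and summarizes the distribution of overlaps across
#' animals (median, interquartile range, extremes).
#'
#' @param c1,c2 \code{\link{cohort}}s at the two concentrations with
#'   matching animal ids.
#' @param n_boot,boot_size,seed,family Passed to
#'   \code{\link{bootstrap_response_distribution}}.
#' @return List with per-animal \code{table} (animal_id, overlap),
#'   \code{median}, \code{iqr} (named length-2), \code{range}.
#' @export
per_animal_overlap_summary <- function(c1, c2, n_boot = 1000L,
                                       boot_size = 20L, seed = NULL,
                                       family = "kde") {
  stopifnot(inherits(c1, "cohort"), inherits(c2, "cohort"))
  ids <- animal_ids(c1)
  if (!setequal(ids, animal_ids(c2)))
    stop("the two cohorts must contain the same animals")
  with_seed(seed, {
    ov <- vapply(ids, function(id) {
      f1 <- bootstrap_response_distribution(c1$series[[id]], n_boot,
                                            boot_size, family = family)
      f2 <- bootstrap_response_distribution(c2$series[[id]], n_boot,
                                            boot_size, family = family)
      overlap_coefficient(f1, f2)
    }, numeric(1))
    q <- stats::quantile(ov, c(0.25, 0.75), names = FALSE)
    list(table = data.frame(animal_id = ids, overlap = unname(ov),
                            stringsAsFactors = FALSE),
         median = stats::median(ov),
         iqr = c(lower = q[1L], upper = q[2L]),
         range = range(ov))
  })
}

#' Population-level response-probability density of a cohort
#'
#' Density over the per-animal across-trial response probabilities —
#' the population-level distribution whose overlap across
#' concentrations limits concentration decoding.
#'
#' @param c A \code{\link{cohort}}.
#' @param family,grid_n Passed to
#'   \code{\link{response_probability_density}}.
#' @return A \code{"density_estimate"}.
#' @export
population_response_density <- function(c, family = "kde",
                                        grid_n = 1001L) {
  stopifnot(inherits(c, "cohort"))
  vals <- vapply(c$series, function(s)
    mean(pooled_trials(s, drop_na = TRUE)), numeric(1))
  response_probability_density(vals, family, grid_n)
}
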