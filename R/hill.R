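#' Anchor pseudo-observations for a constrained Hill fit
#'
#' The sigmoid 1 - R = 1 / (1 + (EC50/Iso)^H) tends to R = 1 as
#' Iso -> 0 automatically, but only reaches R = 0 asymptotically; a
#' hard "R = 0 at 0.9%" equality is impossible for a Hill form. The
#' constraint is therefore implemented as a heavily weighted anchor
#' pseudo-observation in the least-squares objective.
#'
#' @param concentration Anchor concentration (default 0.9% atm).
#' @param righting Anchor righting probability (default 0).
#' @param weight Weight relative to one data point (default 100).
#' @return A list usable as the \code{constraints} argument of
#'   \code{\link{hill_fit}}.
#' @export
hill_anchor <- function(concentration = 0.9, righting = 0, weight = 100) {
  stopifnot(concentration > 0, righting >= 0, righting <= 1, weight > 0)
  list(concentration = concentration, righting = righting, weight = weight)
}

hill_curve <- function(iso, ec50, h) {
  # righting probability; Iso = 0 gives R = 1 (fully responsive)
  ifelse(iso <= 0, 1, 1 - 1 / (1 + (ec50 / iso)^h))
}

#' Constrained Hill fit of a population dose-response curve
#'
#' Least-squares fit of the righting probability
#' R(Iso) = 1 - 1 / (1 + (EC50/Iso)^H) to per-animal righting
#' probabilities pooled per concentration, with optional weighted
#' anchor pseudo-observations (default: R = 0 at 0.9% isoflurane,
#' weight 100; R = 1 at Iso = 0 is automatic). Optimization is
#' multi-start over a log grid of (EC50, H) initial values with
#' Nelder-Mead on the log-parameters; the best residual wins, ties
#' broken toward the smaller Hill slope.
#'
#' @param d A data.frame with columns \code{concentration},
#'   \code{animal_id}, \code{righting_probability} (>= 2 distinct
#'   concentrations).
#' @param constraints A \code{\link{hill_anchor}} (or list of them), or
#'   \code{NULL} for an unconstrained fit.
#' @return An object of class \code{"hill_fit"} with \code{ec50},
#'   \code{hill_slope}, \code{residual} (weighted SSE) and the data.
#' @examples
#' d <- expand.grid(concentration = c(0.2, 0.4, 0.5, 0.6, 0.8),
#'                  animal_id = "m1")
#' d$righting_probability <- 1 - 1 / (1 + (0.5 / d$concentration)^5)
#' fit <- hill_fit(d, constraints = NULL)
#' coef(fit)  # EC50 ~ 0.5, H ~ 5
#' @export
hill_fit <- function(d, constraints = hill_anchor()) {
  d <- validate_dose_response(d)
  if (!is.null(constraints) && !is.null(constraints$concentration))
    constraints <- list(constraints)
  iso <- d$concentration
  r <- d$righting_probability
  w <- rep(1, length(iso))
  for (an in constraints) {
    iso <- c(iso, an$concentration)
    r <- c(r, an$righting)
    w <- c(w, an$weight)
  }
  obj <- function(par) {
    pred <- hill_curve(iso, exp(par[1L]), exp(par[2L]))
    sum(w * (r - pred)^2)
  }
  starts <- expand.grid(
    log_ec50 = log(stats::quantile(iso[iso > 0], c(0.1, 0.35, 0.6, 0.9),
                                   names = FALSE)),
    log_h = log(c(0.5, 1, 2, 5, 10, 25)))
  fits <- lapply(seq_len(nrow(starts)), function(k)
    tryCatch(stats::optim(as.numeric(starts[k, ]), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits))
    stop("Hill fit failed to converge from any start; check the data range")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  hs <- vapply(fits, function(f) exp(f$par[2L]), numeric(1))
  best <- fits[[order(vals, hs)[1L]]]
  structure(list(ec50 = exp(best$par[1L]), hill_slope = exp(best$par[2L]),
                 residual = best$value, constraints = constraints,
                 data = d, call = match.call()),
            class = "hill_fit")
}

validate_dose_response <- function(d) {
  if (!is.data.frame(d) ||
      !all(c("concentration", "righting_probability") %in% names(d)))
    stop("need a data.frame with columns concentration, animal_id, ",
         "righting_probability")
  if (!"animal_id" %in% names(d))
    d$animal_id <- sprintf("a%03d", seq_len(nrow(d)))
  if (any(d$righting_probability < 0 | d$righting_probability > 1,
          na.rm = TRUE))
    stop("righting probabilities must lie in [0, 1]")
  if (length(unique(d$concentration)) < 2L)
    stop("need at least 2 distinct concentrations")
  d[!is.na(d$righting_probability), , drop = FALSE]
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dose-response fit: EC50 = %.4g, H = %.4g (weighted SSE %.4g)\n",
              x$ec50, x$hill_slope, x$residual))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_slope = object$hill_slope)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  iso <- if (is.null(newdata)) object$data$concentration
         else if (is.data.frame(newdata)) newdata$concentration
         else newdata
  hill_curve(iso, object$ec50, object$hill_slope)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$righting_probability,
                 xlab = "concentration", ylab = "righting probability",
                 ylim = c(0, 1), ...)
  iso <- seq(max(1e-4, min(d$concentration) / 4),
             max(d$concentration) * 1.2, length.out = 200)
  graphics::lines(iso, hill_curve(iso, x$ec50, x$hill_slope))
  invisible(x)
}

#' Jackknifed Hill fit with confidence intervals
#'
#' Refits the constrained sigmoid on leave-one-animal-out subsamples:
#' for subsample j, the j-th animal (in index order within each
#' concentration) is removed at every concentration simultaneously.
#' Returns the mean of EC50 and the Hill slope across subsamples with
#' 95% confidence intervals from the jackknife standard error
#' (sqrt((n - 1)/n * sum((theta_j - theta_bar)^2))).
#'
#' @param d Dose-response data.frame as in \code{\link{hill_fit}}
#'   (>= 2 animals per concentration).
#' @param constraints Passed to \code{\link{hill_fit}}.
#' @return List with \code{ec50_mean}, \code{ec50_ci},
#'   \code{hill_mean}, \code{hill_ci}, \code{n_subsamples} and the
#'   per-subsample \code{fits} table.
#' @export
jackknife_hill <- function(d, constraints = hill_anchor()) {
  d <- validate_dose_response(d)
  split_c <- split(d, d$concentration)
  counts <- vapply(split_c, nrow, integer(1))
  if (any(counts < 2L))
    stop("need at least 2 animals per concentration")
  n_sub <- max(counts)
  est <- lapply(seq_len(n_sub), function(j) {
    sub <- do.call(rbind, lapply(split_c, function(dc)
      if (j <= nrow(dc)) dc[-j, , drop = FALSE] else dc))
    f <- hill_fit(sub, constraints)
    c(ec50 = f$ec50, hill_slope = f$hill_slope)
  })
  est <- do.call(rbind, est)
  ci <- function(x) {
    se <- sqrt((length(x) - 1) / length(x) * sum((x - mean(x))^2))
    mean(x) + c(-1.96, 1.96) * se
  }
  list(ec50_mean = mean(est[, "ec50"]),
       ec50_ci = ci(est[, "ec50"]),
       hill_mean = mean(est[, "hill_slope"]),
       hill_ci = ci(est[, "hill_slope"]),
       n_subsamples = n_sub,
       fits = as.data.frame(est))
}
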