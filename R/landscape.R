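#' Double-well energy of the bistable network
#'
#' E(x, i) = x^2 (x^2/2 - 2) + i (x - 1)^2 + (1 - i)(x + 1)^2, where
#' x = Activity_alpha - Activity_beta is the difference between the
#' wake-active and sleep-active population activities and i in [0, 1]
#' is the drug effect in arbitrary units. Increasing i deepens the
#' anesthetized well (near x = -1) and proportionally shallows the
#' awake well (near x = +1), which is what ties the two diagonal
#' transition probabilities together across individuals. At i = 0.5
#' the full potential has equal-depth minima at x = +/-1 (the bare
#' quartic alone has minima at +/-sqrt(2); the added quadratic terms
#' move them).
#'
#' @param x Network coordinate (vectorized).
#' @param i Drug effect in [0, 1].
#' @return Energy values.
#' @examples
#' well_energy(c(-1, 0, 1), 0.5)  # 0.5, 1, 0.5
#' @export
well_energy <- function(x, i) {
  x^2 * (x^2 / 2 - 2) + i * (x - 1)^2 + (1 - i) * (x + 1)^2
}

#' Gradient of the double-well energy
#'
#' Closed form dE/dx = 2 x^3 - 2 x + 2 (1 - 2 i).
#'
#' @param x Network coordinate (vectorized).
#' @param i Drug effect in [0, 1].
#' @return Gradient values.
#' @export
well_gradient <- function(x, i) {
  2 * x^3 - 2 * x + 2 * (1 - 2 * i)
}

#' Parameters of the bistable landscape simulation
#'
#' @param i Drug effect in [0, 1] (0.5 = population EC50, equal wells).
#' @param sigma Noise standard deviation per step.
#' @param D Diffusion constant (1 in all reference simulations).
#' @param dt Integration step (dimensionless time).
#' @param n_steps Raw simulation steps (default 1e6).
#' @param decimation Keep-every factor applied after binarization
#'   (default 100), mimicking intermittent behavioral testing.
#' @param threshold Binarization level on x (default 0).
#' @param x0 Initial coordinate (default +1, awake well).
#' @param burn_in Raw steps discarded before decimation (default 1e4).
#' @param noise_scaling \code{"per_step"} (noise SD is sigma at every
#'   step, the literal reference procedure) or \code{"sqrt_dt"}
#'   (SD sigma * sqrt(dt), the conventional diffusion scaling).
#' @param drift_cap Maximum magnitude of the deterministic displacement
#'   per step (default 2, about the inter-well distance). The quartic
#'   drift grows superlinearly, so an explicit update is unstable once
#'   noise kicks the state far outside the wells; capping the drift
#'   step (a tamed explicit scheme) leaves the dynamics inside
#'   |x| < ~2.5 untouched — where the cap never binds at the default
#'   dt — while keeping noise-dominated runs finite. Set to \code{Inf}
#'   for the raw update.
#' @param seed Optional integer seed.
#' @return An object of class \code{"landscape_params"}.
#' @export
landscape_params <- function(i = 0.5, sigma = 0.4, D = 1, dt = 0.1,
                             n_steps = 1e6, decimation = 100L,
                             threshold = 0, x0 = 1, burn_in = 1e4,
                             noise_scaling = c("per_step", "sqrt_dt"),
                             drift_cap = 2, seed = NULL) {
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(sigma >= 0, dt > 0, decimation >= 1L, n_steps >= 1,
            burn_in >= 0, burn_in < n_steps, drift_cap > 0)
  structure(list(i = i, sigma = sigma, D = D, dt = dt,
                 n_steps = as.integer(n_steps),
                 decimation = as.integer(decimation),
                 threshold = threshold, x0 = x0,
                 burn_in = as.integer(burn_in),
                 noise_scaling = noise_scaling,
                 drift_cap = drift_cap, seed = seed),
            class = "landscape_params")
}

#' Simulate Langevin diffusion on the double-well landscape
#'
#' Iterates x <- x - D * dE/dx * dt + eps with eps ~ Normal(0, sd)
#' per step, where sd is sigma (per-step mode) or sigma * sqrt(dt).
#' Reproducible given a seed.
#'
#' @param p A \code{\link{landscape_params}}.
#' @return Numeric trajectory of length \code{n_steps} (the state
#'   after each update).
#' @export
simulate_langevin <- function(p) {
  stopifnot(inherits(p, "landscape_params"))
  sd_step <- if (p$noise_scaling == "per_step") p$sigma
             else p$sigma * sqrt(p$dt)
  with_seed(p$seed, {
    eps <- if (sd_step > 0) stats::rnorm(p$n_steps, 0, sd_step)
           else numeric(p$n_steps)
    traj <- numeric(p$n_steps)
    x <- p$x0
    Ddt <- p$D * p$dt
    i2 <- 2 * (1 - 2 * p$i)
    cap <- p$drift_cap
    for (t in seq_len(p$n_steps)) {
      step <- Ddt * (2 * x^3 - 2 * x + i2)
      if (is.finite(step)) {
        if (step > cap) step <- cap else if (step < -cap) step <- -cap
      }
      x <- x - step + eps[t]
      if (!is.finite(x) || abs(x) > 1e3)
        stop("trajectory overflow (|x| > 1e3); use a smaller dt")
      traj[t] <- x
    }
    traj
  })
}

#' Binarize and decimate a landscape trajectory into a trial series
#'
#' After discarding \code{burn_in} raw steps, keeps every
#' \code{decimation}-th sample and maps x > threshold to anesthetized
#' (unresponsive, 0) and x <= threshold to awake (responsive, 1) —
#' the boundary sample counts as responsive.
#'
#' @param traj Numeric trajectory from \code{\link{simulate_langevin}}.
#' @param threshold Binarization level (default 0).
#' @param decimation Keep-every factor (default 100).
#' @param burn_in Leading raw steps to discard (default 0).
#' @param animal_id Series id.
#' @return A single-session \code{\link{trial_series}}.
#' @export
binarize_decimate <- function(traj, threshold = 0, decimation = 100L,
                              burn_in = 0L, animal_id = "landscape") {
  stopifnot(decimation >= 1L, burn_in >= 0, burn_in < length(traj))
  x <- traj[(burn_in + 1L):length(traj)]
  x <- x[seq(1L, length(x), by = decimation)]
  trial_series(animal_id, list(as.integer(x <= threshold)),
               NA_real_, "zebrafish")
}

#' Simulate, binarize and decimate in one call
#'
#' @param p A \code{\link{landscape_params}}.
#' @param animal_id Series id.
#' @return A \code{\link{trial_series}}.
#' @export
simulate_landscape_series <- function(p, animal_id = "landscape") {
  traj <- simulate_langevin(p)
  binarize_decimate(traj, p$threshold, p$decimation, p$burn_in,
                    animal_id)
}

#' Sweep drug effect and noise on the bistable landscape
#'
#' For each (i, sigma) combination: simulate, binarize/decimate,
#' fit the two-state chain and record its diagonals, the transition
#' fraction and the fraction of responsive trials. Low noise places
#' points at the periphery of the (P(U|U), P(R|R)) plane (rare
#' switching); very high noise drives them toward (0.5, 0.5), the
#' Bernoulli point at EC50; sweeping i at fixed sigma traces the
#' anti-diagonal seen across real individuals.
#'
#' @param i_values Drug-effect grid.
#' @param sigma_values Noise grid.
#' @param base A \code{\link{landscape_params}} providing all other
#'   settings; its seed (plus an offset per combination) makes the
#'   sweep reproducible.
#' @return A data.frame with columns \code{i}, \code{sigma}, \code{a},
#'   \code{b}, \code{transition_fraction},
#'   \code{responsive_fraction}.
#' @export
landscape_sweep <- function(i_values, sigma_values,
                            base = landscape_params()) {
  stopifnot(length(i_values) >= 1L, length(sigma_values) >= 1L)
  grid <- expand.grid(i = i_values, sigma = sigma_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- base
    p$i <- grid$i[k]
    p$sigma <- grid$sigma[k]
    if (!is.null(base$seed)) p$seed <- base$seed + k
    s <- simulate_landscape_series(p, sprintf("sweep%03d", k))
    f <- tryCatch(markov_fit(s), error = function(e) NULL)
    data.frame(
      i = grid$i[k], sigma = grid$sigma[k],
      a = if (is.null(f)) NA_real_ else f$matrix$a,
      b = if (is.null(f)) NA_real_ else f$matrix$b,
      transition_fraction = if (is.null(f)) NA_real_
                            else f$transition_fraction,
      responsive_fraction = mean(pooled_trials(s, drop_na = TRUE)))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
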