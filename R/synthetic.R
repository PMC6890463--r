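#' Specification of a synthetic cohort
#'
#' The generator emulates the structured inter-individual variability
#' seen in real cohorts: each animal's transition-matrix trace
#' s = a + b is drawn tightly around \code{trace_mean} (conserved
#' noise / spectral gap) while the asymmetry d = (b - a) / 2 — the
#' animal's anesthetic sensitivity — spreads widely. Defaults mirror
#' the mouse design: 20 animals, 4 exposures of 40 trials (160 trials
#' per animal), trace 1.4 with SD 0.05 and sensitivity spread 0.15,
#' which reproduces the strong negative diagonal correlation with
#' a PC1 capturing most of the variance.
#'
#' @param n_animals Number of animals.
#' @param n_sessions Sessions (exposures) per animal.
#' @param trials_per_session Trials per session.
#' @param trace_mean Target a + b across animals.
#' @param trace_sd Across-animal SD of the trace.
#' @param sensitivity_spread Across-animal SD of (b - a) / 2.
#' @param seed Optional integer seed.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_animals = 20L, n_sessions = 4L,
                        trials_per_session = 40L, trace_mean = 1.4,
                        trace_sd = 0.05, sensitivity_spread = 0.15,
                        seed = NULL) {
  stopifnot(n_animals >= 1L, n_sessions >= 1L, trials_per_session >= 2L,
            trace_mean > 0, trace_mean < 2, trace_sd >= 0,
            sensitivity_spread >= 0)
  structure(list(n_animals = as.integer(n_animals),
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 trace_mean = trace_mean, trace_sd = trace_sd,
                 sensitivity_spread = sensitivity_spread, seed = seed),
            class = "cohort_spec")
}

#' Default zebrafish cohort specification
#'
#' 72 animals, one 360-trial session each, with the same structured
#' trace/sensitivity defaults as the mouse spec.
#' @param ... Overrides passed to \code{\link{cohort_spec}}.
#' @return A \code{"cohort_spec"}.
#' @export
zebrafish_cohort_spec <- function(...) {
  args <- list(n_animals = 72L, n_sessions = 1L,
               trials_per_session = 360L)
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Sample per-animal transition matrices
#'
#' Structured mode: per animal draw s ~ Normal(trace_mean, trace_sd)
#' and d ~ Normal(0, sensitivity_spread), set b = s/2 + d and
#' a = s/2 - d (so a + b = s and sensitivity moves along the
#' anti-diagonal), clip to [0.01, 0.99]. Null mode: a and b drawn
#' independently from supplied marginals — the cloud expected when
#' the diagonals are unlinked.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param mode \code{"structured"} (default) or \code{"null"}.
#' @param null_marginals For null mode, a list with functions
#'   \code{ra(n)} and \code{rb(n)} drawing the two marginals; defaults
#'   to uniform on [0.05, 0.95].
#' @param seed Overrides \code{spec$seed}.
#' @return A list of \code{\link{transition_matrix}} objects. Warns if
#'   more than 10% of draws were clipped.
#' @export
sample_individual_matrices <- function(spec,
                                       mode = c("structured", "null"),
                                       null_marginals = NULL,
                                       seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  with_seed(seed, {
    n <- spec$n_animals
    if (mode == "structured") {
      s <- stats::rnorm(n, spec$trace_mean, spec$trace_sd)
      d <- stats::rnorm(n, 0, spec$sensitivity_spread)
      a_raw <- s / 2 - d
      b_raw <- s / 2 + d
    } else {
      if (is.null(null_marginals))
        null_marginals <- list(ra = function(n) stats::runif(n, 0.05, 0.95),
                               rb = function(n) stats::runif(n, 0.05, 0.95))
      a_raw <- null_marginals$ra(n)
      b_raw <- null_marginals$rb(n)
    }
    a <- pmin(pmax(a_raw, 0.01), 0.99)
    b <- pmin(pmax(b_raw, 0.01), 0.99)
    clipped <- mean(a != a_raw | b != b_raw)
    if (clipped > 0.10)
      warning(sprintf("%.0f%% of sampled matrices were clipped to [0.01, 0.99]",
                      100 * clipped))
    lapply(seq_len(n), function(k) transition_matrix(a[k], b[k]))
  })
}

#' Generate a synthetic cohort from per-animal transition matrices
#'
#' Forward-simulates each animal's two-state chain session by session;
#' every session starts from the animal's stationary distribution (the
#' analysis window follows a long equilibration, so the chain is
#' assumed at steady state).
#'
#' @param matrices List of \code{\link{transition_matrix}} objects with
#'   both diagonals defined (and not a = b = 1).
#' @param spec A \code{\link{cohort_spec}} giving the design.
#' @param drug,concentration,unit,label Cohort metadata.
#' @param species Species of the simulated animals.
#' @param seed Overrides \code{spec$seed}.
#' @return A \code{\link{cohort}}.
#' @examples
#' sp <- cohort_spec(n_animals = 4, seed = 1)
#' co <- generate_cohort(sample_individual_matrices(sp), sp)
#' @export
generate_cohort <- function(matrices, spec, drug = "isoflurane",
                            concentration = 0.6, unit = "% atm",
                            label = "synthetic", species = "mouse",
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"),
            length(matrices) == spec$n_animals)
  for (m in matrices) {
    m <- as_transition_matrix(m)
    if (is.na(m$a) || is.na(m$b))
      stop("all matrices must have defined diagonals")
    if (m$a == 1 && m$b == 1)
      stop("a = b = 1 (two absorbing states) cannot generate a cohort")
  }
  iti <- if (species == "mouse") 180 else 30
  with_seed(seed, {
    # burn one draw so the cohort stream differs from the matrix stream
    stats::runif(1L)
    series <- lapply(seq_along(matrices), function(k) {
      m <- as_transition_matrix(matrices[[k]])
      simulate_markov_series(m$a, m$b, spec$n_sessions,
                             spec$trials_per_session,
                             animal_id = sprintf("syn%03d", k),
                             species = species,
                             inter_trial_interval = iti)
    })
    cohort(series, drug, concentration, unit, label)
  })
}

#' Specification of the zebrafish displacement mixture
#'
#' Two log-normal components produce the bimodal post-stimulus travel
#' histogram that motivates thresholding at 0.4 mm: responsive trials
#' around a 2 mm median, unresponsive trials around 0.05 mm, with
#' negligible mass near the threshold. The components are purely
#' illustrative — only the threshold and the bimodality are anchored
#' in the behavioral data.
#'
#' @param responsive_meanlog,responsive_sdlog Log-normal parameters of
#'   the responsive (above-threshold) component.
#' @param unresponsive_meanlog,unresponsive_sdlog Parameters of the
#'   unresponsive component.
#' @param threshold Classification threshold in mm.
#' @return An object of class \code{"displacement_spec"}.
#' @export
displacement_spec <- function(responsive_meanlog = log(2),
                              responsive_sdlog = 0.6,
                              unresponsive_meanlog = log(0.05),
                              unresponsive_sdlog = 0.6,
                              threshold = 0.4) {
  structure(list(responsive_meanlog = responsive_meanlog,
                 responsive_sdlog = responsive_sdlog,
                 unresponsive_meanlog = unresponsive_meanlog,
                 unresponsive_sdlog = unresponsive_sdlog,
                 threshold = threshold),
            class = "displacement_spec")
}

#' Generate per-trial displacements from a binary trial series
#'
#' Responsive trials draw from the responsive mixture component,
#' unresponsive trials from the unresponsive component; missing trials
#' give \code{NA} distances. Thresholding the output at
#' \code{z$threshold} recovers the input series up to the components'
#' small cross-threshold leakage.
#'
#' @param s A \code{\link{trial_series}}.
#' @param z A \code{\link{displacement_spec}}.
#' @param seed Optional integer seed.
#' @return A \code{\link{displacement_table}} of length
#'   \code{n_trials(s)}.
#' @export
generate_displacements <- function(s, z = displacement_spec(),
                                   seed = NULL) {
  stopifnot(inherits(s, "trial_series"), inherits(z, "displacement_spec"))
  x <- pooled_trials(s)
  with_seed(seed, {
    d <- rep(NA_real_, length(x))
    n1 <- sum(x == 1L, na.rm = TRUE)
    n0 <- sum(x == 0L, na.rm = TRUE)
    d[!is.na(x) & x == 1L] <-
      stats::rlnorm(n1, z$responsive_meanlog, z$responsive_sdlog)
    d[!is.na(x) & x == 0L] <-
      stats::rlnorm(n0, z$unresponsive_meanlog, z$unresponsive_sdlog)
    displacement_table(s$animal_id, d)
  })
}
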